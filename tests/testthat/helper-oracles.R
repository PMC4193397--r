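# Naive, loop-based oracle implementations of every descriptor family,
# written directly from the definitions. They share only the property-scale
# DATA with the package (via aa_scale()/ctd_grouping()/qso_distance_matrix());
# every computation is independent.

AAs <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len) {
  paste(sample(AAs, len, replace = TRUE), collapse = "")
}

chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

o_comp <- function(seq) {
  ch <- chars(seq)
  vapply(AAs, function(a) sum(ch == a) / length(ch), numeric(1))
}

o_gapped <- function(seq, a, b, gap) {
  ch <- chars(seq)
  n <- length(ch)
  if (n < gap + 2) return(0)
  hits <- 0
  for (i in 1:(n - gap - 1)) {
    if (ch[i] == a && ch[i + gap + 1] == b) hits <- hits + 1
  }
  hits / (n - gap - 1)
}

o_std <- function(v) (v - mean(v)) / sd(v)

o_pseaac <- function(seq, lam, w = 0.05) {
  ch <- chars(seq)
  n <- length(ch)
  props <- rbind(o_std(aggprop::aa_scale("hydrophobicity")),
                 o_std(aggprop::aa_scale("hydrophilicity")),
                 o_std(aggprop::aa_scale("side_chain_mass")))
  colnames(props) <- AAs
  theta <- numeric(lam)
  for (d in seq_len(lam)) {
    tot <- 0
    for (i in 1:(n - d)) {
      tot <- tot + mean((props[, ch[i]] - props[, ch[i + d]])^2)
    }
    theta[d] <- tot / (n - d)
  }
  f <- vapply(AAs, function(a) sum(ch == a) / n, numeric(1))
  denom <- 1 + w * sum(theta)
  c(f / denom, if (lam > 0) w * theta / denom)
}

o_autocorr <- function(seq, kind, scale_name, lag) {
  ch <- chars(seq)
  n <- length(ch)
  if (n <= lag) return(0)
  sc <- o_std(aggprop::aa_scale(scale_name))
  names(sc) <- AAs
  p <- unname(sc[ch])
  if (kind == "moreaubroto") {
    tot <- 0
    for (i in 1:(n - lag)) tot <- tot + p[i] * p[i + lag]
    return(tot / (n - lag))
  }
  m <- mean(p)
  ss <- sum((p - m)^2)
  if (ss == 0) return(0)
  if (kind == "moran") {
    tot <- 0
    for (i in 1:(n - lag)) tot <- tot + (p[i] - m) * (p[i + lag] - m)
    (tot / (n - lag)) / (ss / n)
  } else {
    tot <- 0
    for (i in 1:(n - lag)) tot <- tot + (p[i] - p[i + lag])^2
    (tot / (2 * (n - lag))) / (ss / (n - 1))
  }
}

o_group_of <- function(res, grouping) {
  g <- aggprop::ctd_grouping(grouping)
  if (res %in% g$g1) 1 else if (res %in% g$g2) 2 else 3
}

o_ctd_comp <- function(seq, grouping, group) {
  ch <- chars(seq)
  mean(vapply(ch, o_group_of, numeric(1), grouping = grouping) == group)
}

o_ctd_trans <- function(seq, grouping, from, to) {
  g <- vapply(chars(seq), o_group_of, numeric(1), grouping = grouping)
  n <- length(g)
  hits <- 0
  for (i in 1:(n - 1)) {
    if ((g[i] == from && g[i + 1] == to) ||
        (g[i] == to && g[i + 1] == from)) hits <- hits + 1
  }
  hits / (n - 1)
}

o_ctd_dist <- function(seq, grouping, group) {
  g <- vapply(chars(seq), o_group_of, numeric(1), grouping = grouping)
  pos <- which(g == group)
  n <- length(g)
  if (!length(pos)) return(c(0, 0, 0, 0, 0))
  ng <- length(pos)
  ks <- c(1, max(1, ceiling(0.25 * ng)), max(1, ceiling(0.5 * ng)),
          max(1, ceiling(0.75 * ng)), ng)
  unname(100 * pos[ks] / n)
}

o_qso <- function(seq, maxlag, w = 0.1) {
  ch <- chars(seq)
  n <- length(ch)
  dmat <- aggprop::qso_distance_matrix()
  tau <- numeric(maxlag)
  for (d in seq_len(maxlag)) {
    tot <- 0
    for (i in 1:(n - d)) tot <- tot + dmat[ch[i], ch[i + d]]^2
    tau[d] <- tot
  }
  f <- vapply(AAs, function(a) sum(ch == a) / n, numeric(1))
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

o_foldindex <- function(seq, window = 16) {
  ch <- chars(seq)
  n <- length(ch)
  kd <- aggprop::aa_scale("hydrophobicity")
  h <- (kd[ch] + 4.5) / 9
  q <- ifelse(ch %in% c("K", "R"), 1, ifelse(ch %in% c("D", "E"), -1, 0))
  if (n < window) {
    fi <- 2.785 * mean(h) - abs(mean(q)) - 1.151
  } else {
    fi <- numeric(n - window + 1)
    for (i in 1:(n - window + 1)) {
      win <- i:(i + window - 1)
      fi[i] <- 2.785 * mean(h[win]) - abs(mean(q[win])) - 1.151
    }
  }
  folded <- fi > 0
  # run-length encoding by explicit scan
  segs <- integer(0)
  cur <- 0
  for (v in folded) {
    if (v) cur <- cur + 1
    else if (cur > 0) { segs <- c(segs, cur); cur <- 0 }
  }
  if (cur > 0) segs <- c(segs, cur)
  list(avg = if (length(segs)) mean(segs) else 0, n_segs = length(segs))
}

# Brute-force AUC: all-pairs concordance with half ties.
o_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive pair-count Kendall tau (tau-b).
o_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Direct evaluation of the four printed confusion-matrix formulas.
o_metrics <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp) * (tn + fn) * (tp + fn) * (tn + fp))
  list(acc = (tp + tn) / (tp + tn + fp + fn),
       sn = tp / (tp + fn),
       sp = tn / (fp + tn),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}
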