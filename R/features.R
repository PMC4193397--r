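# Protein sequence descriptor engine.
#
# All descriptors operate on sanitized sequences over the 20-letter alphabet.
# Every function is deterministic; short-sequence degeneracies return 0 with a
# warning (so proteome scans never abort) unless noted otherwise.

.seq_idx <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    stop("sequence contains non-canonical residues; run sanitize_proteins() first")
  }
  idx
}

.as_seq <- function(p) {
  if (is.character(p) && length(p) == 1L) return(p)
  if (is.data.frame(p) && nrow(p) == 1L && "seq" %in% names(p)) return(p$seq)
  stop("expected a single sequence string or one-row protein_set")
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 residues; components sum to 1.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @return Named numeric vector of length 20.
#' @export
aa_composition <- function(p) {
  idx <- .seq_idx(.as_seq(p))
  tabulate(idx, nbins = 20L) / length(idx) -> f
  names(f) <- AA_ALPHABET
  f
}

#' Gapped amino-acid pair composition
#'
#' Frequency of residue `a` followed by residue `b` after `gap` intervening
#' positions: the count of positions `i` with `seq[i] == a` and
#' `seq[i + gap + 1] == b`, divided by the number of windows
#' `len - gap - 1`. Sequences too short for one window yield 0 with a warning.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param a,b Single residues.
#' @param gap Non-negative integer gap.
#' @return Fraction in \[0, 1\].
#' @export
gapped_pair_composition <- function(p, a, b, gap) {
  s <- .as_seq(p)
  n <- nchar(s)
  if (n < gap + 2L) {
    warning("sequence shorter than gap window; returning 0")
    return(0)
  }
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  i <- seq_len(n - gap - 1L)
  sum(ch[i] == a & ch[i + gap + 1L] == b) / (n - gap - 1L)
}

.pseaac_props <- function() {
  rbind(aa_scale("hydrophobicity", standardize = TRUE),
        aa_scale("hydrophilicity", standardize = TRUE),
        aa_scale("side_chain_mass", standardize = TRUE))
}

#' Pseudo amino-acid composition
#'
#' Chou-type PseAAC: the first 20 components are normalized residue
#' frequencies, the next `lam` are weighted sequence-order correlation factors
#' `theta_d`, where `theta_d` averages, over residue pairs `d` positions
#' apart, the mean squared difference of three standardized properties
#' (hydrophobicity, hydrophilicity, side-chain mass). All components are
#' non-negative and sum to 1.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param lam Number of correlation tiers (`0 <= lam < length`).
#' @param w Tier weight (default 0.05).
#' @return Named numeric vector of length `20 + lam`.
#' @export
pseaac <- function(p, lam = 30L, w = 0.05) {
  idx <- .seq_idx(.as_seq(p))
  n <- length(idx)
  if (lam >= n) stop("lam must be smaller than the sequence length")
  props <- .pseaac_props()
  theta <- numeric(lam)
  if (lam > 0L) {
    pv <- props[, idx, drop = FALSE]       # 3 x n property profile
    for (d in seq_len(lam)) {
      dif <- pv[, seq_len(n - d), drop = FALSE] -
             pv[, (d + 1L):n, drop = FALSE]
      theta[d] <- mean(colMeans(dif^2))
    }
  }
  f <- tabulate(idx, nbins = 20L) / n
  denom <- 1 + w * sum(theta)
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(AA_ALPHABET,
                  if (lam > 0L) paste0("theta", seq_len(lam)))
  out
}

#' Sequence autocorrelation descriptors
#'
#' Moreau-Broto, Moran and Geary autocorrelation of a residue property
#' profile at a given lag. The property scale is standardized to zero mean /
#' unit SD over the 20 residues before use. With `p_i` the property at
#' position `i`, `N` the length and `L` the lag:
#' \itemize{
#'   \item Moreau-Broto: `sum(p_i * p_(i+L)) / (N - L)`
#'   \item Moran: `[sum((p_i - m)(p_(i+L) - m)) / (N - L)] / [sum((p_i - m)^2) / N]`
#'   \item Geary: `[sum((p_i - p_(i+L))^2) / (2(N - L))] / [sum((p_i - m)^2) / (N - 1)]`
#' }
#' where `m` is the sequence mean of the property. Sequences with `N <= L`
#' return 0 with a warning; Moran/Geary on a zero-variance (homopolymer)
#' profile return 0 by convention.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param kind `"moreaubroto"`, `"moran"` or `"geary"`.
#' @param scale Scale name (see [aa_scales()]) or named 20-vector.
#' @param lag Positive integer lag.
#' @return A single numeric value.
#' @export
autocorrelation <- function(p, kind = c("moreaubroto", "moran", "geary"),
                            scale = "hydrophobicity", lag = 1L) {
  kind <- match.arg(kind)
  idx <- .seq_idx(.as_seq(p))
  n <- length(idx)
  if (n <= lag) {
    warning("sequence length <= lag; returning 0")
    return(0)
  }
  sc <- if (is.character(scale)) aa_scale(scale, standardize = TRUE) else {
    stopifnot(length(scale) == 20L)
    sc0 <- scale
    if (is.null(names(sc0))) names(sc0) <- AA_ALPHABET
    sc0[AA_ALPHABET]
  }
  pv <- sc[idx]
  i <- seq_len(n - lag)
  if (kind == "moreaubroto") {
    return(sum(pv[i] * pv[i + lag]) / (n - lag))
  }
  m <- mean(pv)
  ss <- sum((pv - m)^2)
  if (ss == 0) return(0)
  if (kind == "moran") {
    (sum((pv[i] - m) * (pv[i + lag] - m)) / (n - lag)) / (ss / n)
  } else {
    (sum((pv[i] - pv[i + lag])^2) / (2 * (n - lag))) / (ss / (n - 1))
  }
}

.ctd_group_idx <- function(idx, grouping) {
  groups <- ctd_grouping(grouping)
  g <- integer(20L)
  for (k in 1:3) g[match(groups[[k]], AA_ALPHABET)] <- k
  g[idx]
}

#' CTD descriptors
#'
#' Composition, transition and distribution descriptors over a 3-class
#' physicochemical partition of the alphabet (see [ctd_grouping()]).
#' `ctd_composition` is the fraction of residues in a group;
#' `ctd_transition` is the count of adjacent positions whose residues fall in
#' the two given distinct groups (either order), divided by `len - 1`;
#' `ctd_distribution` returns five quantile-position points: the sequence
#' position (as percent of length) of the first occurrence and of the 25%,
#' 50%, 75% and 100% occurrence quantiles of the group (0s when the group is
#' absent).
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param grouping Grouping name, see [ctd_grouping()].
#' @param group Group index 1..3.
#' @param from,to Distinct group indices for the transition count.
#' @return `ctd_composition`/`ctd_transition`: a scalar;
#'   `ctd_distribution`: a named 5-vector (percent units).
#' @export
ctd_composition <- function(p, grouping, group) {
  gi <- .ctd_group_idx(.seq_idx(.as_seq(p)), grouping)
  mean(gi == group)
}

#' @rdname ctd_composition
#' @export
ctd_transition <- function(p, grouping, from, to) {
  stopifnot(from != to)
  gi <- .ctd_group_idx(.seq_idx(.as_seq(p)), grouping)
  n <- length(gi)
  if (n < 2L) {
    warning("sequence too short for transitions; returning 0")
    return(0)
  }
  a <- gi[-n]; b <- gi[-1L]
  sum((a == from & b == to) | (a == to & b == from)) / (n - 1L)
}

#' @rdname ctd_composition
#' @export
ctd_distribution <- function(p, grouping, group) {
  gi <- .ctd_group_idx(.seq_idx(.as_seq(p)), grouping)
  n <- length(gi)
  pos <- which(gi == group)
  pts <- c(first = 0, p25 = 0, p50 = 0, p75 = 0, p100 = 0)
  if (length(pos) == 0L) return(pts)
  ng <- length(pos)
  ks <- pmax(1L, ceiling(c(1e-9, 0.25, 0.5, 0.75, 1) * ng))
  pts[] <- 100 * pos[ks] / n
  pts
}

#' Distribution of positively charged residues
#'
#' CTD-style distribution points for the positive group \{K, R, H\}.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @return Named 5-vector of percent positions (0s if no positive residues).
#' @export
charge_distribution <- function(p) {
  ctd_distribution(p, "charge", 1L)
}

#' Quasi-sequence-order descriptors
#'
#' First 20 components are weighted residue frequencies; the next `maxlag`
#' components are weighted sequence-order coupling numbers
#' `tau_d = sum_i d(seq_i, seq_(i+d))^2` computed from a physicochemical
#' inter-residue distance matrix. The full vector is normalized to sum 1.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param maxlag Maximum coupling lag (`< length`).
#' @param w Coupling weight (default 0.1).
#' @param dmat 20 x 20 distance matrix; defaults to [qso_distance_matrix()].
#' @return Named numeric vector of length `20 + maxlag`.
#' @export
quasi_sequence_order <- function(p, maxlag = 30L, w = 0.1, dmat = NULL) {
  idx <- .seq_idx(.as_seq(p))
  n <- length(idx)
  if (maxlag >= n) stop("maxlag must be smaller than the sequence length")
  if (is.null(dmat)) dmat <- qso_distance_matrix()
  tau <- vapply(seq_len(maxlag), function(d) {
    i <- seq_len(n - d)
    sum(dmat[cbind(idx[i], idx[i + d])]^2)
  }, numeric(1))
  f <- tabulate(idx, nbins = 20L) / n
  denom <- 1 + w * sum(tau)
  out <- c(f / denom, w * tau / denom)
  names(out) <- c(AA_ALPHABET, paste0("tau", seq_len(maxlag)))
  out
}

# FoldIndex inputs: Kyte-Doolittle rescaled to [0, 1]; unit charges.
.fold_hydro <- function() (aa_scale("hydrophobicity") + 4.5) / 9
.fold_charge <- function() {
  q <- stats::setNames(numeric(20L), AA_ALPHABET)
  q[c("K", "R")] <- 1
  q[c("D", "E")] <- -1
  q
}

#' FoldIndex segment statistics
#'
#' Computes the windowed foldability index
#' `2.785 * mean(hydrophobicity) - |mean(net charge)| - 1.151` (hydrophobicity
#' rescaled to \[0, 1\]), classifies each window as folded (index > 0) or
#' unfolded, and summarizes maximal runs of folded windows. Sequences shorter
#' than the window are scored as a single whole-sequence window.
#'
#' @param p Sequence string or one-row `protein_set`.
#' @param window Sliding-window width (default 16).
#' @return List: `index` (per-window values), `avg_folded_segment_length`,
#'   `n_folded_segments`, `frac_folded`.
#' @export
foldindex_features <- function(p, window = 16L) {
  idx <- .seq_idx(.as_seq(p))
  n <- length(idx)
  h <- .fold_hydro()[idx]
  q <- .fold_charge()[idx]
  if (n < window) {
    fi <- 2.785 * mean(h) - abs(mean(q)) - 1.151
  } else {
    ch <- cumsum(c(0, h)); cq <- cumsum(c(0, q))
    i <- seq_len(n - window + 1L)
    fi <- 2.785 * (ch[i + window] - ch[i]) / window -
      abs((cq[i + window] - cq[i]) / window) - 1.151
  }
  folded <- fi > 0
  r <- rle(folded)
  seg <- r$lengths[r$values]
  list(index = fi,
       avg_folded_segment_length = if (length(seg)) mean(seg) else 0,
       n_folded_segments = length(seg),
       frac_folded = mean(folded))
}
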