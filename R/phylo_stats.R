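# Comparative statistics: Kendall rank correlation, Felsenstein independent
# contrasts, through-origin contrast correlation, ANCOVA with a habitat
# interaction, and the Mann-Whitney test. These are implemented directly
# (not wrapped) so their exactness conventions are pinned down and testable.

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau. For `n <= 8` the p-value is computed by exact
#' enumeration of all permutations of `y`; otherwise by the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_max Largest n for which the permutation-exact p is used.
#' @return List: `tau`, `p_value`, `statistic` (concordant minus discordant).
#' @export
kendall_tau <- function(x, y, exact_max = 8L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("tau undefined: a vector is entirely tied")
  }
  tau_stat <- function(x, y) {
    # C - D via sign products over all pairs
    dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
    sum(dx[upper.tri(dx)] * dy[upper.tri(dy)])
  }
  Tobs <- tau_stat(x, y)
  tie_counts <- function(v) as.numeric(table(v))
  tx <- tie_counts(x); ty <- tie_counts(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- Tobs / sqrt((n0 - n1) * (n0 - n2))
  if (n <= exact_max) {
    perms <- .permutations(n)
    Tnull <- apply(perms, 1L, function(p) tau_stat(x, y[p]))
    p <- mean(abs(Tnull) >= abs(Tobs) - 1e-12)
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varT <- (v0 - vt - vu) / 18 + v1 + v2
    z <- (abs(Tobs) - 1) / sqrt(varT)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(tau = tau, p_value = p, statistic = Tobs)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Felsenstein independent contrasts
#'
#' Phylogenetically independent contrasts by the pruning algorithm: at each
#' internal node joining children with values `x1`, `x2` and adjusted branch
#' lengths `v1`, `v2`, the standardized contrast is
#' `(x1 - x2) / sqrt(v1 + v2)`, the node value is the `1/v`-weighted average,
#' and the node's parent branch is lengthened by `v1 v2 / (v1 + v2)`.
#' Polytomies are resolved arbitrarily into zero-length branches; any
#' zero-length branch is then replaced by `eps_frac` times the tree height so
#' contrast variances stay positive (PDAP-like behavior).
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param trait Named numeric vector, one value per tip label.
#' @param eps_frac Zero-branch replacement, as a fraction of tree height.
#' @return A `contrast_set`: data.frame `node`, `contrast`, `variance`
#'   (the `v1 + v2` of each contrast), with attributes `n_tips` and
#'   `tip_hash`.
#' @export
independent_contrasts <- function(tree, trait, eps_frac = 1e-8) {
  validate_tree(tree)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop("trait values missing for tip(s): ", paste(missing, collapse = ", "))
  }
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (any(tree$edge.length == 0)) {
    height <- max(ape::node.depth.edgelength(tree))
    if (height <= 0) stop("tree has zero total height")
    tree$edge.length[tree$edge.length == 0] <- eps_frac * height
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  xval <- c(trait[tree$tip.label], rep(NA_real_, nnode))
  vextra <- numeric(ntip + nnode)
  contrasts <- numeric(0); vars <- numeric(0); nodes <- integer(0)
  # postorder over edges: children are complete before their parent
  eo <- ape::reorder.phylo(tree, "postorder")
  edge <- eo$edge; elen <- eo$edge.length
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (parent in unique(edge[, 1])) {
    rows <- kids[[as.character(parent)]]
    stopifnot(length(rows) == 2L)
    c1 <- edge[rows[1], 2]; c2 <- edge[rows[2], 2]
    v1 <- elen[rows[1]] + vextra[c1]
    v2 <- elen[rows[2]] + vextra[c2]
    if (v1 + v2 <= 0) stop("zero contrast variance at node ", parent)
    contrasts <- c(contrasts, (xval[c1] - xval[c2]) / sqrt(v1 + v2))
    vars <- c(vars, v1 + v2)
    nodes <- c(nodes, parent)
    xval[parent] <- (xval[c1] / v1 + xval[c2] / v2) / (1 / v1 + 1 / v2)
    vextra[parent] <- v1 * v2 / (v1 + v2)
  }
  out <- data.frame(node = nodes, contrast = contrasts, variance = vars)
  attr(out, "n_tips") <- ntip
  attr(out, "tip_hash") <- paste(sort(tree$tip.label), collapse = "|")
  class(out) <- c("contrast_set", "data.frame")
  out
}

#' Through-origin correlation of two contrast sets
#'
#' `r = sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))`, the standard
#' through-origin correlation for independent contrasts (whose signs are
#' arbitrary); p from `t = r sqrt(df / (1 - r^2))` with `df = n - 1`.
#'
#' @param cx,cy `contrast_set`s from the same tree (same node order).
#' @return List: `r`, `p_value`, `df`.
#' @export
contrast_correlation <- function(cx, cy) {
  stopifnot(inherits(cx, "contrast_set"), inherits(cy, "contrast_set"))
  if (!identical(attr(cx, "tip_hash"), attr(cy, "tip_hash")) ||
      !identical(cx$node, cy$node)) {
    stop("contrast sets come from different trees or node orders")
  }
  n <- nrow(cx)
  if (n < 3L) stop("need at least 3 contrasts")
  r <- sum(cx$contrast * cy$contrast) /
    sqrt(sum(cx$contrast^2) * sum(cy$contrast^2))
  df <- n - 1L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df), df = df)
}

#' ANCOVA of a proteome fraction on GC content and habitat
#'
#' Fits `y ~ gc + habitat + gc:habitat` and reports Type-II F-tests: the
#' habitat main effect (`y ~ gc + habitat` vs `y ~ gc`) and the
#' GC-by-habitat interaction (full vs additive model).
#'
#' @param y Response (e.g. fAg or fC3).
#' @param gc GC-content covariate.
#' @param habitat Factor with >= 2 levels, each with >= 3 observations
#'   (a single level reduces the model to simple regression and reports
#'   `NA` p-values for the habitat terms).
#' @return List: `habitat_p`, `interaction_p`, `gc_p`, `coefficients`
#'   (of the full model).
#' @export
ancova_habitat <- function(y, gc, habitat) {
  habitat <- droplevels(as.factor(habitat))
  stopifnot(length(y) == length(gc), length(y) == length(habitat))
  if (nlevels(habitat) < 2L) {
    fit <- stats::lm(y ~ gc)
    return(list(habitat_p = NA_real_, interaction_p = NA_real_,
                gc_p = summary(fit)$coefficients["gc", 4],
                coefficients = stats::coef(fit)))
  }
  if (any(table(habitat) < 3L)) {
    stop("each habitat level needs at least 3 observations")
  }
  full <- stats::lm(y ~ gc + habitat + gc:habitat)
  if (any(is.na(stats::coef(full)))) stop("rank-deficient ANCOVA design")
  add <- stats::lm(y ~ gc + habitat)
  gc_only <- stats::lm(y ~ gc)
  hab_only <- stats::lm(y ~ habitat)
  list(habitat_p = stats::anova(gc_only, add)[2, "Pr(>F)"],
       interaction_p = stats::anova(add, full)[2, "Pr(>F)"],
       gc_p = stats::anova(hab_only, add)[2, "Pr(>F)"],
       coefficients = stats::coef(full))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' `U` is the number of (a, b) pairs with `a > b`, ties counted one half.
#' The p-value is computed by exact enumeration of all
#' `choose(na + nb, na)` group assignments when `na * nb <= exact_max`
#' (valid under ties), and by the tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b Non-empty numeric samples.
#' @param alternative `"two.sided"`, `"less"` (a tends smaller) or
#'   `"greater"`.
#' @param exact_max Use the exact null when `na * nb` is at most this.
#' @return List: `U`, `p_value`, `exact` (logical).
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater"),
                         exact_max = 400) {
  alternative <- match.arg(alternative)
  na_ <- length(a); nb_ <- length(b)
  stopifnot(na_ >= 1L, nb_ >= 1L)
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(na_)]) - na_ * (na_ + 1) / 2
  exact <- na_ * nb_ <= exact_max
  if (exact) {
    combs <- utils::combn(na_ + nb_, na_)
    Rnull <- colSums(matrix(r[combs], nrow = na_))
    Unull <- Rnull - na_ * (na_ + 1) / 2
    eps <- 1e-9
    p_le <- mean(Unull <= U + eps)
    p_ge <- mean(Unull >= U - eps)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
  } else {
    mu <- na_ * nb_ / 2
    N <- na_ + nb_
    ties <- as.numeric(table(pooled))
    v <- na_ * nb_ / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- 0.5
    z_le <- (U - mu + cc) / sqrt(v)
    z_ge <- (U - mu - cc) / sqrt(v)
    p <- switch(alternative,
                less = stats::pnorm(z_le),
                greater = stats::pnorm(z_ge, lower.tail = FALSE),
                two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                           stats::pnorm(z_ge,
                                                        lower.tail = FALSE))))
  }
  list(U = U, p_value = p, exact = exact)
}
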