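test_that("kendall tau: perfect concordance/discordance and tie handling", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(kendall_tau(x, x * 2)$tau, 1)
  expect_equal(kendall_tau(x, -x)$tau, -1)
  expect_error(kendall_tau(rep(1, 5), x), "tied")
})

test_that("kendall tau equals the exhaustive pair-count oracle (n <= 6, with ties)", {
  set.seed(40)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, o_tau(x, y), tolerance = 1e-12)
  }
})

test_that("kendall tau agrees with cor.test as an independent reference", {
  set.seed(41)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  got <- kendall_tau(x, y)
  ref <- stats::cor.test(x, y, method = "kendall")
  expect_equal(got$tau, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value,
               stats::cor.test(x, y, method = "kendall", exact = FALSE,
                               continuity = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("independent contrasts: cherry formula and equal-value degeneracy", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  ic <- independent_contrasts(tr, c(A = 3, B = 1))
  expect_equal(abs(ic$contrast), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(ic$variance, 2)
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ic0 <- independent_contrasts(tr4, c(A = 5, B = 5, C = 5, D = 5))
  expect_equal(ic0$contrast, rep(0, 3))
  expect_error(independent_contrasts(tr4, c(A = 1, B = 2, C = 3)),
               "missing for tip")
})

test_that("independent contrasts reproduce a hand-worked pruning on a balanced tree", {
  # ((A:1,B:1):1,(C:1,D:1):1); x = (4, 2, 10, 6)
  # cherry AB: contrast (4-2)/sqrt(2), node value 3, parent branch 1 + 1/2
  # cherry CD: contrast (10-6)/sqrt(2), node value 8, parent branch 1 + 1/2
  # root: contrast (3-8)/sqrt(3) with v = 1.5 + 1.5
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ic <- independent_contrasts(tr, c(A = 4, B = 2, C = 10, D = 6))
  expect_setequal(round(abs(ic$contrast), 10),
                  round(c(2 / sqrt(2), 4 / sqrt(2), 5 / sqrt(3)), 10))
  expect_setequal(ic$variance, c(2, 2, 3))
})

test_that("independent contrasts match ape::pic on random trees, including polytomies", {
  set.seed(42)
  for (rep in 1:5) {
    tt <- gen_tree_traits(30, rho = 0.5, seed = rep)
    ic <- independent_contrasts(tt$tree, tt$x)
    ref <- ape::pic(tt$x[tt$tree$tip.label], tt$tree)
    expect_equal(sort(abs(ic$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-9)
  }
  # a polytomy is resolved with near-zero internal branches
  trp <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  trp <- ape::root(ape::unroot(trp), outgroup = "A", resolve.root = TRUE)
  expect_silent(ic <- independent_contrasts(trp, c(A = 1, B = 2, C = 3, D = 4)))
  expect_equal(nrow(ic), 3L)
})

test_that("contrast correlation: exact limits and orthogonality", {
  tt <- gen_tree_traits(25, rho = 0, seed = 7)
  cx <- independent_contrasts(tt$tree, tt$x)
  cy <- cx
  cy$contrast <- 2 * cx$contrast
  expect_equal(contrast_correlation(cx, cy)$r, 1)
  # constructed orthogonality
  cz <- cx
  v <- cx$contrast
  u <- rev(v)  # make an orthogonal vector via Gram-Schmidt
  u <- u - sum(u * v) / sum(v * v) * v
  cz$contrast <- u
  expect_equal(contrast_correlation(cx, cz)$r, 0, tolerance = 1e-12)
  tt2 <- gen_tree_traits(26, rho = 0, seed = 8)
  c_other <- independent_contrasts(tt2$tree, tt2$x)
  expect_error(contrast_correlation(cx, c_other), "different trees")
})

test_that("brownian trait correlation is recovered through contrasts", {
  set.seed(43)
  rs <- vapply(1:20, function(i) {
    tt <- gen_tree_traits(120, rho = 0.7, seed = 1000 + i)
    contrast_correlation(independent_contrasts(tt$tree, tt$x),
                         independent_contrasts(tt$tree, tt$y))$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.08)
  # rho = 1 collapses to perfect correlation
  tt1 <- gen_tree_traits(40, rho = 1, seed = 5)
  expect_equal(contrast_correlation(independent_contrasts(tt1$tree, tt1$x),
                                    independent_contrasts(tt1$tree, tt1$y))$r,
               1, tolerance = 1e-6)
})

test_that("ancova: single habitat reduces to regression; planted effects are detected", {
  set.seed(44)
  n <- 60
  gc <- runif(n, 0.25, 0.7)
  y <- 0.2 + 0.5 * gc + rnorm(n, sd = 0.03)
  one <- ancova_habitat(y, gc, rep("free_living", n))
  expect_true(is.na(one$habitat_p))
  ref <- stats::lm(y ~ gc)
  expect_equal(unname(one$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-12)

  hab <- rep(c("free_living", "symbiont"), each = n / 2)
  # planted intercept offset of 3 residual SD
  y2 <- y + ifelse(hab == "symbiont", 3 * 0.03, 0)
  a2 <- ancova_habitat(y2, gc, hab)
  expect_lt(a2$habitat_p, 0.01)
  # planted slope difference
  y3 <- y + ifelse(hab == "symbiont", 0.6 * gc, 0)
  a3 <- ancova_habitat(y3, gc, hab)
  expect_lt(a3$interaction_p, 0.01)
  expect_error(ancova_habitat(y[1:5], gc[1:5],
                              c("a", "a", "a", "b", "b")),
               "at least 3")
})

test_that("mann-whitney: identity, exact separation, wilcox.test agreement", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "less")
  expect_true(mw$exact)
  expect_equal(mw$p_value, 1 / 20)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / 20)
  # identical two-point samples (spec: groups {0.1,0.1} vs {0.1,0.1})
  expect_equal(mann_whitney(c(0.1, 0.1), c(0.1, 0.1))$p_value, 1)
  # agreement with wilcox.test exact p (no ties)
  set.seed(45)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(mann_whitney(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("mann-whitney normal approximation tracks the exact null", {
  # the approximation is benchmarked away from the far tail, where the
  # continuity-corrected normal is intentionally conservative
  set.seed(46)
  checked <- 0L
  for (rep in 1:30) {
    a <- rnorm(10); b <- rnorm(10)
    pe <- mann_whitney(a, b)$p_value
    if (pe < 0.1) next
    pa <- mann_whitney(a, b, exact_max = 0)$p_value
    expect_lt(abs(pa - pe) / pe, 0.10)
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)
})

test_that("power: mann-whitney detects a 1-SD shift at n=50/50", {
  set.seed(47)
  rej <- mean(vapply(1:60, function(i) {
    mann_whitney(rnorm(50), rnorm(50, 1))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.9)
})
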