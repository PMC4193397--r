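test_that("aa_composition: point examples and normalization", {
  expect_equal(aa_composition("TTT")[["T"]], 1.0)
  expect_equal(unname(aa_composition("AC")[c("A", "C")]), c(0.5, 0.5))
  set.seed(1)
  expect_equal(sum(aa_composition(random_peptide(200))), 1, tolerance = 1e-12)
  expect_error(aa_composition(""), "empty")
})

test_that("gapped pair composition: examples and brute-force oracle", {
  expect_equal(gapped_pair_composition("HAAAAAAAAM", "H", "M", 8), 1.0)
  expect_warning(v <- gapped_pair_composition("MMMM", "H", "M", 8), "short")
  expect_equal(v, 0)
  set.seed(2)
  for (rep in 1:20) {
    s <- random_peptide(50)
    a <- sample(AAs, 1); b <- sample(AAs, 1); g <- sample(0:10, 1)
    expect_equal(gapped_pair_composition(s, a, b, g), o_gapped(s, a, b, g))
  }
})

test_that("pseaac: homopolymer degeneracies and direct-evaluation oracle", {
  v <- pseaac("DDDDDD", lam = 0)
  expect_equal(v[["D"]], 1.0)
  v2 <- pseaac("DDDDDD", lam = 3)
  expect_equal(unname(v2[21:23]), c(0, 0, 0))
  expect_equal(v2[1:20], aa_composition("DDDDDD"))
  expect_equal(unname(pseaac("ACDEFG", lam = 2, w = 0.05)),
               unname(o_pseaac("ACDEFG", lam = 2, w = 0.05)),
               tolerance = 1e-12)
  expect_error(pseaac("ACD", lam = 3), "lam")
  set.seed(3)
  s <- random_peptide(60)
  expect_equal(sum(pseaac(s, lam = 10)), 1, tolerance = 1e-12)
  expect_true(all(pseaac(s, lam = 10) >= 0))
})

test_that("autocorrelation: homopolymer conventions", {
  z <- aa_scale("hydrophobicity", standardize = TRUE)[["I"]]
  s <- strrep("I", 40)
  expect_equal(autocorrelation(s, "moreaubroto", "hydrophobicity", 1), z^2)
  expect_equal(autocorrelation(s, "moran", "hydrophobicity", 5), 0)
  expect_equal(autocorrelation(s, "geary", "residue_volume", 3), 0)
  expect_warning(v <- autocorrelation("ACD", "moran", "hydrophobicity", 10),
                 "lag")
  expect_equal(v, 0)
})

test_that("autocorrelation matches the double-loop oracle for each kind and lag", {
  set.seed(4)
  for (rep in 1:10) {
    s <- random_peptide(sample(31:80, 1))
    for (kind in c("moreaubroto", "moran", "geary")) {
      for (lag in c(1, 6, 27)) {
        sc <- sample(aa_scales(), 1)
        expect_equal(autocorrelation(s, kind, sc, lag),
                     o_autocorr(s, kind, sc, lag), tolerance = 1e-12)
      }
    }
  }
})

test_that("moreau-broto is invariant to sequence reversal", {
  set.seed(5)
  for (rep in 1:5) {
    s <- random_peptide(60)
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(autocorrelation(s, "moreaubroto", "hydrophobicity", 7),
                 autocorrelation(rs, "moreaubroto", "hydrophobicity", 7))
  }
})

test_that("CTD descriptors: degenerate cases, transitions and quantile positions", {
  g2 <- ctd_grouping("polarizability")$g2
  s_all_g2 <- paste(rep(g2[1], 12), collapse = "")
  expect_equal(ctd_composition(s_all_g2, "polarizability", 2), 1)
  expect_equal(ctd_distribution(s_all_g2, "polarizability", 2)[["p100"]], 100)
  expect_equal(ctd_distribution(s_all_g2, "polarizability", 1),
               c(first = 0, p25 = 0, p50 = 0, p75 = 0, p100 = 0))
  # alternating 10-mer between groups 1 and 3: every adjacency is a transition
  g <- ctd_grouping("vdw_volume")
  alt <- paste(rep(c(g$g1[1], g$g3[1]), 5), collapse = "")
  expect_equal(ctd_transition(alt, "vdw_volume", 1, 3), 9 / 9)
  # group residues at positions 1..5 of a 10-mer: 50% point at position 3
  s <- paste0(strrep(g$g1[1], 5), strrep(g$g3[1], 5))
  expect_equal(ctd_distribution(s, "vdw_volume", 1)[["p50"]], 30)
})

test_that("CTD matches oracle on random peptides", {
  set.seed(6)
  for (rep in 1:10) {
    s <- random_peptide(sample(31:80, 1))
    grp <- sample(c("polarizability", "vdw_volume", "charge"), 1)
    k <- sample(1:3, 1)
    expect_equal(ctd_composition(s, grp, k), o_ctd_comp(s, grp, k))
    expect_equal(unname(ctd_distribution(s, grp, k)), o_ctd_dist(s, grp, k))
    expect_equal(ctd_transition(s, grp, 1, 2), o_ctd_trans(s, grp, 1, 2))
  }
})

test_that("charge distribution: positive-group positions", {
  expect_equal(charge_distribution("KKKKK")[["p100"]], 100)
  expect_equal(charge_distribution("AAAAAAAAAK")[["first"]], 100)
  expect_equal(unname(charge_distribution("AAAA")), rep(0, 5))
})

test_that("quasi-sequence-order: degeneracies and brute-force oracle", {
  d <- qso_distance_matrix()
  expect_equal(unname(diag(d)), rep(0, 20))
  expect_equal(d, t(d))
  v <- quasi_sequence_order(strrep("A", 20), maxlag = 4)
  expect_equal(v[["A"]], 1)
  expect_equal(unname(v[21:24]), rep(0, 4))
  v2 <- quasi_sequence_order("AC", maxlag = 1)
  expect_equal(unname(v2[["tau1"]]),
               0.1 * d["A", "C"]^2 / (1 + 0.1 * d["A", "C"]^2))
  set.seed(7)
  s <- random_peptide(40)
  expect_equal(unname(quasi_sequence_order(s, maxlag = 10)),
               unname(o_qso(s, maxlag = 10)), tolerance = 1e-12)
  expect_equal(sum(quasi_sequence_order(s, maxlag = 10)), 1,
               tolerance = 1e-12)
  expect_error(quasi_sequence_order("ACD", maxlag = 5), "maxlag")
})

test_that("foldindex: sign behavior and run-length oracle", {
  poly_i <- strrep("I", 60)
  fi <- foldindex_features(poly_i)
  expect_equal(fi$avg_folded_segment_length, 60 - 16 + 1)
  expect_equal(fi$n_folded_segments, 1L)
  poly_k <- strrep("K", 60)
  fk <- foldindex_features(poly_k)
  expect_equal(fk$avg_folded_segment_length, 0)
  expect_true(all(fk$index < 0))
  # alternating folded/unfolded blocks
  set.seed(8)
  for (rep in 1:5) {
    s <- paste(sample(c("I", "K"), 80, replace = TRUE,
                      prob = c(0.6, 0.4)), collapse = "")
    got <- foldindex_features(s)
    want <- o_foldindex(s)
    expect_equal(got$avg_folded_segment_length, want$avg)
    expect_equal(got$n_folded_segments, want$n_segs)
  }
})

test_that("extract_features: schema, determinism, totality", {
  spec <- default_feature_spec()
  expect_equal(length(spec), 24L)
  set.seed(9)
  seqs <- replicate(6, random_peptide(sample(31:120, 1)))
  X <- extract_features(stats::setNames(seqs, paste0("p", 1:6)), spec)
  expect_equal(dim(X), c(6L, 24L))
  expect_true(all(is.finite(X)))
  expect_equal(colnames(X), feature_ids(spec))
  X2 <- extract_features(stats::setNames(seqs, paste0("p", 1:6)), spec)
  expect_identical(X, X2)
})

test_that("feature spec hash detects parameter changes", {
  s1 <- default_feature_spec()
  s2 <- default_feature_spec()
  s2$features[[3]]$params$gap <- 9L
  expect_false(identical(feature_spec_hash(s1), feature_spec_hash(s2)))
  expect_identical(feature_spec_hash(s1),
                   feature_spec_hash(default_feature_spec()))
})
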