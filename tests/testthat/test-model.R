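test_that("classification metrics: printed-formula behavior", {
  m <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(m), c(acc = 1, sn = 1, sp = 1, mcc = 1))
  m2 <- classification_metrics(25, 25, 25, 25)
  expect_equal(m2$acc, 0.5)
  expect_equal(m2$mcc, 0)
  # hand evaluation of the four formulas
  m3 <- classification_metrics(69, 76, 19, 11)
  o <- o_metrics(69, 76, 19, 11)
  expect_equal(m3, o)
  # degenerate margins
  expect_equal(classification_metrics(0, 5, 0, 5)$mcc, 0)
  expect_error(classification_metrics(0, 5, 5, 0), "sensitivity")
})

test_that("metrics match direct formula evaluation on random confusion matrices", {
  set.seed(30)
  for (rep in 1:50) {
    c4 <- as.list(sample(0:15, 4, replace = TRUE))
    names(c4) <- c("tp", "tn", "fp", "fn")
    if (c4$tp + c4$fn == 0 || c4$fp + c4$tn == 0) next
    expect_equal(do.call(classification_metrics, c4), do.call(o_metrics, c4))
  }
})

test_that("roc_auc: separation, ties, brute-force concordance", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))$auc, 1.0)
  expect_equal(roc_auc(rep(5, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(31)
  for (rep in 1:20) {
    n <- 10
    sc <- sample(1:6, n, replace = TRUE)  # forces ties
    tr <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(tr) || !any(tr)) next
    expect_equal(roc_auc(sc, tr)$auc, o_auc(sc, tr))
  }
  # ROC endpoints
  r <- roc_auc(rnorm(20), rep(c(TRUE, FALSE), 10))
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
})

test_that("mRMR: relevance ranking, redundancy penalty, constant features", {
  set.seed(32)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(signal = y + rnorm(n, sd = 0.05),
             weak = y + rnorm(n, sd = 1.5),
             constant = rep(1, n),
             noise = rnorm(n))
  sel <- mrmr_select(X, y, 3)
  expect_equal(sel[1], "signal")
  # a constant feature (zero relevance) never precedes an informative one
  expect_lt(match("weak", sel, nomatch = 4), match("constant", sel,
                                                   nomatch = 4))

  # a duplicated informative feature is not chosen second
  X2 <- cbind(X[, "signal", drop = FALSE],
              copy = X[, "signal"] + rnorm(n, sd = 1e-6),
              weak = 0.5 * y + rnorm(n), noise = rnorm(n))
  sel2 <- mrmr_select(X2, y, 2)
  expect_equal(sel2[1], "signal")
  expect_false(sel2[2] == "copy")

  expect_error(mrmr_select(X, rep(1, n), 2), "constant")
})

test_that("SVM CV: separable data, determinism, leakage guard", {
  set.seed(33)
  n <- 100
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = 4), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(0, 1), each = n)
  cv <- svm_train_cv(X, y, seed = 9, cost_grid = 10)
  expect_gte(cv$report$acc, 0.98)
  expect_gte(cv$report$auc, 0.99)
  # fold assignment and the whole report reproduce bit-exactly
  cv2 <- svm_train_cv(X, y, seed = 9, cost_grid = 10)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$report, cv2$report)
  expect_identical(cv$cv_decision, cv2$cv_decision)
  # class sizes below the fold count are rejected
  expect_error(svm_train_cv(X[c(1:3, 101:150), ], y[c(1:3, 101:150)],
                            seed = 1), "fewer")
})

test_that("standardization is fit on training folds only", {
  # shuffling the rows WITHIN one held-out fold must permute that fold's
  # decision values and leave every other fold's values untouched: the
  # fold's own rows contribute nothing to the statistics used to score them
  set.seed(34)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = 3), ncol = 2))
  colnames(X) <- c("a", "b")
  y <- rep(c(0, 1), each = n)
  cv <- svm_train_cv(X, y, seed = 4, cost_grid = 10)
  f1 <- which(cv$fold == 1)
  # same-class swap inside fold 1 keeps the stratified fold map identical
  cls1 <- f1[y[f1] == 1]
  swap <- cls1[1:2]
  Xp <- X
  Xp[swap, ] <- X[rev(swap), ]
  cvp <- svm_train_cv(Xp, y, seed = 4, cost_grid = 10)
  expect_identical(cv$fold, cvp$fold)
  # the SMO solver is order-sensitive at its stopping tolerance, so
  # equality holds to solver precision, not machine precision
  expect_equal(cvp$cv_decision[swap], cv$cv_decision[rev(swap)],
               tolerance = 1e-2)
  other <- setdiff(seq_len(2 * n), swap)
  expect_equal(cvp$cv_decision[other], cv$cv_decision[other],
               tolerance = 1e-2)
})

test_that("trained classifier: margin contract, determinism, calibration midpoint", {
  set.seed(35)
  # two sequence families with distinct composition
  mk <- function(n, p_ik) replicate(n, paste(
    sample(c("I", "K", "A", "G"), 60, replace = TRUE, prob = p_ik),
    collapse = ""))
  pos <- mk(30, c(0.6, 0.1, 0.15, 0.15))
  neg <- mk(30, c(0.1, 0.6, 0.15, 0.15))
  lab <- data.frame(id = paste0("t", 1:60), seq = c(pos, neg),
                    class = rep(c("aggregation_prone", "soluble"), each = 30),
                    stringsAsFactors = FALSE)
  model <- train_classifier(lab, "aggregation_prone", seed = 2,
                            cost_grid = 10)
  expect_gte(model$report$acc, 0.9)
  pred <- predict_proteins(model, protein_set(lab$id, lab$seq))
  # strong training examples sit on the right side with confidence > 0.5
  expect_gte(mean(pred$class == (lab$class == "aggregation_prone")), 0.9)
  expect_true(all((pred$confidence >= 0.5) == pred$class))
  # identical sequences give identical predictions
  p2 <- predict_proteins(model, protein_set(c("a", "b"),
                                            c(lab$seq[1], lab$seq[1])))
  expect_equal(p2$confidence[1], p2$confidence[2])
  # confidence is a monotone map of the decision value through (0, 0.5)
  expect_equal(stats::plogis(0), 0.5)
  expect_false(is.unsorted(pred$confidence[order(pred$decision)]))
})

test_that("model serialization round-trips", {
  set.seed(36)
  mk <- function(n, pr) replicate(n, paste(
    sample(c("F", "D", "A", "L"), 50, replace = TRUE, prob = pr),
    collapse = ""))
  lab <- data.frame(id = paste0("s", 1:40),
                    seq = c(mk(20, c(0.5, 0.1, 0.2, 0.2)),
                            mk(20, c(0.1, 0.5, 0.2, 0.2))),
                    class = rep(c("groel_obligate", "soluble"), each = 20),
                    stringsAsFactors = FALSE)
  model <- train_classifier(lab, "groel_obligate", seed = 3, cost_grid = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_identical(back$spec_hash, model$spec_hash)
  expect_identical(back$positive_class, model$positive_class)
  probe <- protein_set(paste0("q", 1:5),
                       replicate(5, random_peptide(60)))
  expect_equal(predict_proteins(back, probe), predict_proteins(model, probe),
               tolerance = 1e-12)
  suppressWarnings(
    expect_error(read_model(withr::local_tempfile(fileext = ".json")),
                 "cannot open|not an aggprop"))
})
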