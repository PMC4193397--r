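# Classifier layer: confusion-matrix metrics, ROC/AUC, mRMR feature
# selection, RBF-SVM training with stratified five-fold cross-validation,
# sigmoid score calibration, and prediction.

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity, specificity and the Matthews correlation
#' coefficient:
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Sn = TP/(TP+FN)`, `Sp = TN/(FP+TN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`.
#' A zero MCC denominator yields MCC = 0 by convention; `Sn` with
#' `TP + FN = 0` (no positives) is an error.
#'
#' @param tp,tn,fp,fn Non-negative integer counts (total >= 1).
#' @return List `acc`, `sn`, `sp`, `mcc`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  if (tp + fn == 0) stop("sensitivity undefined: no positive examples")
  if (fp + tn == 0) stop("specificity undefined: no negative examples")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sn <- tp / (tp + fn)
  sp <- tn / (fp + tn)
  den2 <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (den2 == 0) 0 else (tp * tn - fp * fn) / sqrt(den2)
  list(acc = acc, sn = sn, sp = sp, mcc = mcc)
}

#' ROC curve and AUC
#'
#' AUC equals the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted one half (computed via midranks). The ROC points sweep all
#' distinct score thresholds.
#'
#' @param scores Numeric decision values or probabilities.
#' @param truth Logical (or 0/1) class labels; both classes must be present.
#' @return List: `auc` and `points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(c(Inf, thr), function(t) {
    c(fpr = sum(scores[!truth] >= t) / nneg,
      tpr = sum(scores[truth] >= t) / npos)
  }, numeric(2)))
  list(auc = auc, points = as.data.frame(pts))
}

# Equal-frequency discretization into at most `bins` levels.
.discretize_ef <- function(x, bins = 5L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               type = 7))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

# Mutual information (nats) of two discrete vectors.
.mutual_info <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' mRMR feature selection
#'
#' Greedy maximum-relevance minimum-redundancy ranking (mutual-information
#' difference criterion). Continuous features are discretized into
#' equal-frequency bins; the first feature maximizes relevance `I(f; y)` and
#' each subsequent feature maximizes `I(f; y) - mean I(f; selected)`.
#'
#' @param X Numeric feature matrix (columns named).
#' @param y Class labels (two or more levels; non-constant).
#' @param k Number of features to rank.
#' @param bins Discretization bins (default 5).
#' @return Character vector of `k` feature names in selection order, with
#'   attribute `"scores"` (criterion value at each step).
#' @export
mrmr_select <- function(X, y, k, bins = 5L) {
  stopifnot(is.matrix(X), k >= 1L, k <= ncol(X))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("labels are constant")
  D <- apply(X, 2L, .discretize_ef, bins = bins)
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) .mutual_info(D[, j], y), numeric(1))
  sel <- integer(0)
  scores <- numeric(0)
  red <- matrix(NA_real_, p, p)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(j) {
      if (length(sel) == 0L) return(rel[j])
      for (s in sel) {
        if (is.na(red[j, s])) {
          red[j, s] <<- red[s, j] <<- .mutual_info(D[, j], D[, s])
        }
      }
      rel[j] - mean(red[j, sel])
    }, numeric(1))
    best <- cand[which.max(crit)]
    sel <- c(sel, best)
    scores <- c(scores, max(crit))
  }
  out <- colnames(X)[sel]
  attr(out, "scores") <- scores
  out
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mean = mu, sd = sd)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
}

# Fit an RBF SVM (+ midpoint-anchored sigmoid calibration) on standardized
# features. `class_weight = TRUE` scales C inversely to class frequency.
.svm_fit <- function(X, y01, C = 10, gamma = NULL, class_weight = TRUE) {
  stopifnot(all(y01 %in% c(0, 1)))
  st <- .standardize_fit(X)
  Z <- .standardize_apply(X, st)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  yv <- ifelse(y01 == 1, 1, -1)
  n <- length(yv)
  if (class_weight) {
    wpos <- n / (2 * sum(y01 == 1)); wneg <- n / (2 * sum(y01 == 0))
  } else {
    wpos <- wneg <- 1
  }
  fit <- .svm_smo_train(Z, yv, C * wpos, C * wneg, gamma)
  sv <- which(fit$alpha > 1e-8)
  dv <- .rbf_decision(Z[sv, , drop = FALSE], fit$alpha[sv] * yv[sv], fit$b,
                      gamma, Z)
  # single-slope logistic through the origin: p = 1/(1 + exp(-a f)), a > 0,
  # so decision value 0 maps to confidence 0.5 exactly
  a <- tryCatch({
    g <- suppressWarnings(stats::glm(y01 ~ dv - 1, family = stats::binomial()))
    unname(stats::coef(g)[1])
  }, error = function(e) NA_real_)
  if (!is.finite(a) || a <= 0) a <- 1
  a <- min(a, 500)
  list(standardize = st, gamma = gamma, C = C,
       sv = Z[sv, , drop = FALSE], coef = fit$alpha[sv] * yv[sv], b = fit$b,
       platt_slope = a, iterations = fit$iterations)
}

.svm_decision <- function(fit, X) {
  Z <- .standardize_apply(X, fit$standardize)
  .rbf_decision(fit$sv, fit$coef, fit$b, fit$gamma, Z)
}

.stratified_folds <- function(y01, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    if (length(idx) < folds) {
      stop("class ", cls, " has fewer members (", length(idx),
           ") than folds (", folds, "); use fewer folds")
    }
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated SVM training on a feature matrix
#'
#' Stratified k-fold cross-validation with standardization and (optionally)
#' hyperparameter grid search fit on training folds only. Reported metrics
#' are pooled (micro-averaged) over the held-out folds: one confusion matrix,
#' plus AUC from the pooled decision values. The final model is refit on all
#' rows with the most frequently selected hyperparameters.
#'
#' @param X Feature matrix.
#' @param y01 0/1 labels (1 = positive class).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the stratified fold assignment.
#' @param cost_grid,gamma_grid Candidate C and gamma values; when both grids
#'   have a single entry the inner search is skipped. `gamma_grid = NULL`
#'   defaults to `1/ncol(X)`.
#' @param class_weight Scale C inversely to class frequency.
#' @return List: `model` (internal SVM fit), `report` (pooled `acc`, `sn`,
#'   `sp`, `mcc`, `auc`, confusion counts, chosen hyperparameters, `folds`,
#'   `seed`), `cv_decision` (held-out decision values), `fold` assignment.
#' @export
svm_train_cv <- function(X, y01, folds = 5L, seed = 1L,
                         cost_grid = c(1, 10), gamma_grid = NULL,
                         class_weight = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y01))
  if (is.null(gamma_grid)) gamma_grid <- 1 / ncol(X)
  fold <- .stratified_folds(y01, folds, seed)
  grid <- expand.grid(C = cost_grid, gamma = gamma_grid)
  dv_out <- numeric(length(y01))
  chosen <- character(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nrow(grid) > 1L) {
      inner <- .stratified_folds(y01[tr], 3L, seed + f)
      accs <- vapply(seq_len(nrow(grid)), function(g) {
        ok <- 0
        for (j in 1:3) {
          it <- inner != j
          m <- .svm_fit(X[tr, , drop = FALSE][it, , drop = FALSE],
                        y01[tr][it], C = grid$C[g], gamma = grid$gamma[g],
                        class_weight = class_weight)
          d <- .svm_decision(m, X[tr, , drop = FALSE][!it, , drop = FALSE])
          ok <- ok + sum((d > 0) == (y01[tr][!it] == 1))
        }
        ok
      }, numeric(1))
      gbest <- which.max(accs)
    } else {
      gbest <- 1L
    }
    chosen[f] <- paste(grid$C[gbest], grid$gamma[gbest])
    m <- .svm_fit(X[tr, , drop = FALSE], y01[tr],
                  C = grid$C[gbest], gamma = grid$gamma[gbest],
                  class_weight = class_weight)
    dv_out[!tr] <- .svm_decision(m, X[!tr, , drop = FALSE])
  }
  pred <- dv_out > 0
  tp <- sum(pred & y01 == 1); tn <- sum(!pred & y01 == 0)
  fp <- sum(pred & y01 == 0); fn <- sum(!pred & y01 == 1)
  met <- classification_metrics(tp, tn, fp, fn)
  auc <- roc_auc(dv_out, y01 == 1)$auc
  pick <- names(sort(table(chosen), decreasing = TRUE))[1]
  pick <- as.numeric(strsplit(pick, " ", fixed = TRUE)[[1]])
  final <- .svm_fit(X, y01, C = pick[1], gamma = pick[2],
                    class_weight = class_weight)
  report <- c(met, list(auc = auc, tp = tp, tn = tn, fp = fp, fn = fn,
                        C = pick[1], gamma = pick[2], folds = folds,
                        seed = seed))
  list(model = final, report = report, cv_decision = dv_out, fold = fold)
}

#' Train a sequence classifier
#'
#' End-to-end training from a curated [labeled set][curate_training_set]:
#' feature extraction with `spec`, then [svm_train_cv()]. The returned
#' classifier stores the feature-spec hash and refuses to predict from a
#' mismatching spec.
#'
#' @param labeled A `labeled_set` (columns `id`, `seq`, `class`) or a
#'   data.frame with those columns.
#' @param positive_class The class label treated as positive (e.g.
#'   `"aggregation_prone"` or `"groel_obligate"`).
#' @param spec A `feature_spec`.
#' @param folds,seed,cost_grid,gamma_grid,class_weight See [svm_train_cv()].
#' @return A `seq_classifier` object with elements `svm`, `report`, `spec`,
#'   `spec_hash`, `positive_class`.
#' @export
train_classifier <- function(labeled, positive_class,
                             spec = default_feature_spec(), folds = 5L,
                             seed = 1L, cost_grid = c(1, 10),
                             gamma_grid = NULL, class_weight = TRUE) {
  stopifnot(all(c("id", "seq", "class") %in% names(labeled)))
  y01 <- as.integer(labeled$class == positive_class)
  if (sum(y01) == 0L) stop("no examples of positive class '", positive_class, "'")
  X <- extract_features(protein_set(labeled$id, labeled$seq), spec)
  cv <- svm_train_cv(X, y01, folds = folds, seed = seed,
                     cost_grid = cost_grid, gamma_grid = gamma_grid,
                     class_weight = class_weight)
  structure(list(svm = cv$model, report = cv$report, spec = spec,
                 spec_hash = feature_spec_hash(spec),
                 positive_class = positive_class),
            class = "seq_classifier")
}

#' @export
print.seq_classifier <- function(x, ...) {
  r <- x$report
  cat("<seq_classifier> positive class:", x$positive_class, "\n")
  cat(sprintf("  CV (pooled, %d-fold): Acc %.4f Sn %.4f Sp %.4f MCC %.4f AUC %.4f\n",
              r$folds, r$acc, r$sn, r$sp, r$mcc, r$auc))
  cat(sprintf("  RBF SVM: C = %g, gamma = %g, %d support vectors\n",
              r$C, r$gamma, nrow(x$svm$sv)))
  invisible(x)
}

#' Predict aggregation propensity / chaperonin dependence
#'
#' Extracts features with the classifier's own spec and returns per-protein
#' calls with calibrated confidence (probability of the positive class; the
#' call is positive iff confidence >= 0.5, equivalently decision value >= 0).
#'
#' @param model A `seq_classifier`.
#' @param proteins A `protein_set` (sanitized) or named character vector.
#' @return Data.frame: `id`, `class` (logical), `confidence` in \[0, 1\],
#'   `decision` (raw SVM decision value).
#' @export
predict_proteins <- function(model, proteins) {
  stopifnot(inherits(model, "seq_classifier"))
  if (feature_spec_hash(model$spec) != model$spec_hash) {
    stop("feature spec hash mismatch: model and spec are out of sync")
  }
  X <- extract_features(proteins, model$spec)
  dv <- .svm_decision(model$svm, X)
  conf <- 1 / (1 + exp(-model$svm$platt_slope * dv))
  data.frame(id = rownames(X), class = dv >= 0, confidence = conf,
             decision = dv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize / restore a trained classifier
#'
#' The model container is a single JSON file (metadata + full-precision
#' numeric arrays). `read_model(write_model(m, path))` restores a classifier
#' whose predictions are identical to the original's.
#'
#' @param model A `seq_classifier`.
#' @param path File path.
#' @return `write_model`: `path`, invisibly. `read_model`: a
#'   `seq_classifier`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "seq_classifier"))
  payload <- list(
    container = "aggprop-seq-classifier", version = 1L,
    positive_class = model$positive_class,
    spec_hash = model$spec_hash,
    spec = model$spec$features,
    report = model$report,
    svm = list(standardize = model$svm$standardize,
               gamma = model$svm$gamma, C = model$svm$C,
               sv = model$svm$sv, coef = model$svm$coef, b = model$svm$b,
               platt_slope = model$svm$platt_slope))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$container, "aggprop-seq-classifier")) {
    stop("'", path, "' is not an aggprop classifier container")
  }
  fix_scalar <- function(v) {
    if (is.numeric(v) && length(v) == 1L && !is.na(v) && v == round(v) &&
        abs(v) < .Machine$integer.max) as.integer(v) else v
  }
  feats <- lapply(p$spec, function(f) {
    list(id = f$id, family = f$family,
         params = lapply(f$params, fix_scalar))
  })
  spec <- feature_spec(feats)
  coef <- as.numeric(unlist(p$svm$coef))
  sv <- matrix(as.numeric(unlist(p$svm$sv)), nrow = length(coef),
               byrow = TRUE)
  svm <- list(standardize = list(
                mean = as.numeric(unlist(p$svm$standardize$mean)),
                sd = as.numeric(unlist(p$svm$standardize$sd))),
              gamma = p$svm$gamma, C = p$svm$C, sv = sv,
              coef = coef, b = p$svm$b,
              platt_slope = p$svm$platt_slope)
  structure(list(svm = svm,
                 report = lapply(p$report, function(v) unlist(v)),
                 spec = spec, spec_hash = p$spec_hash,
                 positive_class = p$positive_class),
            class = "seq_classifier")
}
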