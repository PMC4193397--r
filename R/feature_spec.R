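# FeatureSpec: an ordered list of (feature_id, family, parameters) triples.
# The shipped default spec holds the 24 descriptors selected for the
# solubility classifier; internal ids of the original tool are mapped to our
# best-reading parameterization (documented in the vignette).

FEATURE_FAMILIES <- c("composition", "gapped_pair", "pseaac",
                      "autocorrelation", "ctd", "qso", "foldindex",
                      "charge_distribution")

#' Build a feature specification
#'
#' @param features List of `list(id =, family =, params = list(...))`
#'   entries; families: composition, gapped_pair, pseaac, autocorrelation,
#'   ctd, qso, foldindex, charge_distribution.
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(features) {
  ids <- vapply(features, `[[`, character(1), "id")
  fams <- vapply(features, `[[`, character(1), "family")
  if (anyDuplicated(ids)) stop("duplicate feature ids")
  bad <- setdiff(fams, FEATURE_FAMILIES)
  if (length(bad)) stop("unknown feature families: ", paste(bad, collapse = ", "))
  structure(list(features = features), class = "feature_spec")
}

#' @export
length.feature_spec <- function(x) length(x$features)

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec> with", length(x), "features:\n")
  for (f in x$features) cat("  ", f$id, " [", f$family, "]\n", sep = "")
  invisible(x)
}

#' Feature ids of a spec
#' @param spec A `feature_spec`.
#' @return Character vector of feature ids in order.
#' @export
feature_ids <- function(spec) {
  vapply(spec$features, `[[`, character(1), "id")
}

#' Stable hash of a feature spec
#'
#' Used to bind trained classifiers to the extraction schema.
#' @param spec A `feature_spec`.
#' @return Character scalar.
#' @export
feature_spec_hash <- function(spec) {
  s <- paste(vapply(spec$features, function(f) {
    paste(f$id, f$family,
          paste(names(f$params), unlist(f$params), sep = "=", collapse = ","),
          sep = "|")
  }, character(1)), collapse = ";")
  # FNV-1a, enough to detect schema mismatch
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x-%d", as.integer(h), length(spec$features))
}

.ac <- function(id, kind, scale, lag) {
  list(id = id, family = "autocorrelation",
       params = list(kind = kind, scale = scale, lag = lag))
}

#' The default 24-feature specification
#'
#' The 24 descriptors selected for the solubility classifier: one
#' quasi-sequence-order coupling term, the positive-charge distribution,
#' one gapped residue pair, PseAAC components for D/E/F, a FoldIndex segment
#' statistic, CTD terms for polarizability and van der Waals volume,
#' threonine composition, and Moreau-Broto/Moran/Geary autocorrelation of
#' hydrophobicity, relative mutability, residue volume, polarizability,
#' steric parameter, free energy and accessible surface area at the selected
#' lags.
#'
#' @return A `feature_spec` of length 24.
#' @export
default_feature_spec <- function() {
  feature_spec(list(
    list(id = "qso_tau2", family = "qso",
         params = list(component = "tau", d = 2L, maxlag = 30L, w = 0.1)),
    list(id = "posdist_p50", family = "charge_distribution",
         params = list(point = "p50")),
    list(id = "pair_H8M", family = "gapped_pair",
         params = list(a = "H", b = "M", gap = 8L)),
    .ac("mb_hydro_1", "moreaubroto", "hydrophobicity", 1L),
    list(id = "pseaac_D", family = "pseaac",
         params = list(component = "D", lam = 30L, w = 0.05)),
    list(id = "pseaac_F", family = "pseaac",
         params = list(component = "F", lam = 30L, w = 0.05)),
    list(id = "foldindex_avgseg", family = "foldindex",
         params = list(window = 16L, stat = "avg_folded_segment_length")),
    list(id = "pseaac_E", family = "pseaac",
         params = list(component = "E", lam = 30L, w = 0.05)),
    list(id = "dist_polar_g2_p50", family = "ctd",
         params = list(part = "distribution", grouping = "polarizability",
                       group = 2L, point = "p50")),
    .ac("mb_mut_6", "moreaubroto", "relative_mutability", 6L),
    list(id = "comp_T", family = "composition", params = list(residue = "T")),
    .ac("moran_vol_27", "moran", "residue_volume", 27L),
    .ac("moran_polar_22", "moran", "polarizability", 22L),
    .ac("mb_mut_9", "moreaubroto", "relative_mutability", 9L),
    .ac("geary_steric_4", "geary", "steric_parameter", 4L),
    .ac("mb_mut_24", "moreaubroto", "relative_mutability", 24L),
    .ac("mb_hydro_12", "moreaubroto", "hydrophobicity", 12L),
    .ac("moran_asa_24", "moran", "asa_tripeptide", 24L),
    .ac("moran_hydro_23", "moran", "hydrophobicity", 23L),
    .ac("geary_free_13", "geary", "free_energy", 13L),
    list(id = "comp_vdw_g2", family = "ctd",
         params = list(part = "composition", grouping = "vdw_volume",
                       group = 2L)),
    .ac("geary_vol_20", "geary", "residue_volume", 20L),
    .ac("geary_free_14", "geary", "free_energy", 14L),
    .ac("mb_vol_30", "moreaubroto", "residue_volume", 30L)
  ))
}

.eval_feature <- function(seq, f, cache) {
  p <- f$params
  switch(f$family,
    composition = aa_composition(seq)[[p$residue]],
    gapped_pair = gapped_pair_composition(seq, p$a, p$b, p$gap),
    pseaac = {
      key <- paste0("pseaac_", p$lam, "_", p$w)
      if (is.null(cache[[key]])) {
        cache[[key]] <- pseaac(seq, lam = p$lam, w = p$w)
      }
      cache[[key]][[p$component]]
    },
    autocorrelation = autocorrelation(seq, p$kind, p$scale, p$lag),
    ctd = switch(p$part,
      composition = ctd_composition(seq, p$grouping, p$group),
      transition = ctd_transition(seq, p$grouping, p$from, p$to),
      distribution = ctd_distribution(seq, p$grouping, p$group)[[p$point]],
      stop("unknown ctd part '", p$part, "'")),
    qso = {
      key <- paste0("qso_", p$maxlag, "_", p$w)
      if (is.null(cache[[key]])) {
        cache[[key]] <- quasi_sequence_order(seq, maxlag = p$maxlag, w = p$w)
      }
      if (p$component == "tau") cache[[key]][[paste0("tau", p$d)]]
      else cache[[key]][[p$component]]
    },
    foldindex = foldindex_features(seq, window = p$window)[[p$stat]],
    charge_distribution = charge_distribution(seq)[[p$point]],
    stop("unknown feature family '", f$family, "'")
  )
}

#' Extract a feature matrix
#'
#' Evaluates every feature of `spec` on every protein. Deterministic: the
#' same sequences give a bit-identical matrix. Per-feature short-sequence
#' warnings are aggregated into one summary warning.
#'
#' @param proteins A `protein_set` (sanitized) or character vector of
#'   sequences (optionally named).
#' @param spec A `feature_spec`; default [default_feature_spec()].
#' @return Numeric matrix, one row per protein (rownames = ids), one column
#'   per feature (colnames = feature ids). All values finite.
#' @export
extract_features <- function(proteins, spec = default_feature_spec()) {
  if (is.character(proteins)) {
    ids <- if (!is.null(names(proteins))) names(proteins)
           else paste0("seq", seq_along(proteins))
    proteins <- protein_set(ids, proteins)
  }
  ids <- proteins$id
  fids <- feature_ids(spec)
  out <- matrix(NA_real_, nrow = nrow(proteins), ncol = length(fids),
                dimnames = list(ids, fids))
  n_warn <- 0L
  for (i in seq_len(nrow(proteins))) {
    seq <- proteins$seq[i]
    cache <- new.env(parent = emptyenv())
    vals <- withCallingHandlers(
      vapply(spec$features, function(f) .eval_feature(seq, f, cache),
             numeric(1)),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    out[i, ] <- vals
  }
  if (n_warn > 0L) {
    warning(n_warn, " short-sequence feature value(s) set to 0")
  }
  if (!all(is.finite(out))) stop("non-finite feature values produced")
  out
}
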