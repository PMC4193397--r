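# Proteome scanning: apply the aggregation-propensity classifier to every
# protein, the GroEL-obligate classifier within the predicted
# aggregation-prone subset, and summarize per-organism fractions.

.call_model <- function(model, proteins) {
  if (is.function(model)) {
    cls <- model(proteins)
    stopifnot(is.logical(cls), length(cls) == nrow(proteins))
    return(data.frame(id = proteins$id, class = cls,
                      confidence = ifelse(cls, 1, 0),
                      stringsAsFactors = FALSE))
  }
  predict_proteins(model, proteins)[, c("id", "class", "confidence")]
}

#' Scan a proteome
#'
#' Classifies every protein with the aggregation model; proteins called
#' aggregation-prone are then classified with the GroEL-obligate model.
#' `fAg` = predicted aggregation-prone / scanned proteins; `fC3` = predicted
#' GroEL-obligate (within the aggregation-prone calls) / scanned proteins.
#' `fC3_within_ag` (denominator = aggregation-prone calls) is also reported.
#' Proteins failing the sanitized length policy are excluded and counted.
#'
#' @param proteins A `protein_set` (raw; sanitization is applied here).
#' @param agg_model,c3_model `seq_classifier` objects, or functions
#'   `protein_set -> logical` (used by tests as stub models).
#' @param organism_id Identifier stamped into the summary row.
#' @param min_length Minimum sanitized length to scan (default 31).
#' @return List: `summary` (one-row data.frame: `organism_id`, `n_proteins`,
#'   `n_excluded`, `fAg`, `fC3`, `fC3_within_ag`) and `calls` (per-protein
#'   data.frame with both classifiers' calls).
#' @export
scan_proteome <- function(proteins, agg_model, c3_model,
                          organism_id = "organism", min_length = 31L) {
  if (nrow(proteins) == 0L) stop("empty proteome")
  clean <- suppressWarnings(sanitize_proteins(proteins, min_length))
  san <- attr(clean, "sanitization")
  keep <- !san$too_short
  n_excluded <- sum(!keep)
  scanned <- clean[keep, , drop = FALSE]
  class(scanned) <- c("protein_set", "data.frame")
  if (nrow(scanned) == 0L) stop("no protein passes the length policy")
  agg <- .call_model(agg_model, scanned)
  calls <- data.frame(id = scanned$id, aggregation_prone = agg$class,
                      agg_confidence = agg$confidence,
                      groel_obligate = FALSE, c3_confidence = NA_real_,
                      stringsAsFactors = FALSE)
  n_ag <- sum(agg$class)
  if (n_ag > 0L) {
    sub <- scanned[agg$class, , drop = FALSE]
    class(sub) <- c("protein_set", "data.frame")
    c3 <- .call_model(c3_model, sub)
    calls$groel_obligate[match(c3$id, calls$id)] <- c3$class
    calls$c3_confidence[match(c3$id, calls$id)] <- c3$confidence
  }
  n <- nrow(scanned)
  n_c3 <- sum(calls$groel_obligate)
  summary <- data.frame(
    organism_id = organism_id, n_proteins = n, n_excluded = n_excluded,
    fAg = n_ag / n, fC3 = n_c3 / n,
    fC3_within_ag = if (n_ag > 0) n_c3 / n_ag else 0,
    stringsAsFactors = FALSE)
  list(summary = summary, calls = calls)
}

#' Assemble the per-organism summary table
#'
#' Joins scan summaries with a GC table and organism metadata (groEL copy
#' number, habitat) by exact `organism_id` match. Organisms missing from any
#' table are reported in a warning and dropped from the join.
#'
#' @param scans List of `scan_proteome()` results (or a data.frame of their
#'   `summary` rows).
#' @param gc_table Data.frame with `organism_id`, `gc`.
#' @param metadata Optional data.frame with `organism_id`, `groel_copies`,
#'   `habitat`.
#' @return Data.frame in the per-organism schema: `organism_id`,
#'   `n_proteins`, `fAg`, `fC3`, `fC3_within_ag`, `gc` (+ metadata columns).
#' @export
proteome_summary_table <- function(scans, gc_table, metadata = NULL) {
  summaries <- if (is.data.frame(scans)) scans else
    do.call(rbind, lapply(scans, `[[`, "summary"))
  stopifnot(all(c("organism_id", "gc") %in% names(gc_table)))
  unmatched <- setdiff(summaries$organism_id, gc_table$organism_id)
  if (length(unmatched)) {
    warning("no GC entry for: ", paste(unmatched, collapse = ", "))
  }
  out <- merge(summaries, gc_table[, c("organism_id", "gc")],
               by = "organism_id", sort = FALSE)
  if (!is.null(metadata)) {
    miss <- setdiff(out$organism_id, metadata$organism_id)
    if (length(miss)) {
      warning("no metadata for: ", paste(miss, collapse = ", "))
    }
    out <- merge(out, metadata, by = "organism_id", sort = FALSE)
  }
  out
}

#' Stratify fC3 by groEL copy number
#'
#' Groups organisms by `groel_copies` and computes pairwise two-sided
#' Mann-Whitney p-values between the fC3 distributions of the groups
#' (exact for small groups, tie-corrected normal approximation otherwise;
#' see [mann_whitney()]).
#'
#' @param summaries Data.frame with `fC3` and `groel_copies`.
#' @return List: `groups` (named list of fC3 vectors, keyed by copy number)
#'   and `p_values` (data.frame `group1`, `group2`, `p_value`).
#' @export
stratify_by_copies <- function(summaries) {
  stopifnot(all(c("fC3", "groel_copies") %in% names(summaries)))
  groups <- split(summaries$fC3, summaries$groel_copies)
  if (length(groups) < 2L) stop("need at least two groEL copy-number groups")
  keys <- names(groups)
  pairs <- utils::combn(length(keys), 2)
  pv <- apply(pairs, 2L, function(ij) {
    mann_whitney(groups[[ij[1]]], groups[[ij[2]]],
                 alternative = "two.sided")$p_value
  })
  list(groups = groups,
       p_values = data.frame(group1 = keys[pairs[1, ]],
                             group2 = keys[pairs[2, ]],
                             p_value = pv, stringsAsFactors = FALSE))
}
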