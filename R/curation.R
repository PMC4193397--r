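# Training-set curation: threshold a continuous solubility source, integrate
# chaperone-substrate membership lists, and reduce redundancy at 30% global
# alignment identity with greedy incremental clustering.

#' Label sources
#'
#' A label source is either a continuous solubility table (percent units,
#' values in \[0, 100\]) or a membership list (ids of chaperone substrates /
#' aggregation evidence from one study).
#'
#' @param name Source name (e.g. `"eSOL"`, `"GroEL-substrates"`).
#' @param values Named numeric vector (solubility percent per protein id).
#' @param ids Character vector of member protein ids.
#' @return A `label_source` object.
#' @export
solubility_source <- function(name, values) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("solubility values must be uniquely named by protein id")
  }
  if (any(values < 0 | values > 100)) {
    bad <- names(values)[values < 0 | values > 100]
    stop("solubility outside [0,100] for: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, kind = "continuous-solubility",
                 payload = values), class = "label_source")
}

#' @rdname solubility_source
#' @export
membership_source <- function(name, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in membership source '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(name = name, kind = "membership", payload = ids),
            class = "label_source")
}

#' Threshold a solubility source
#'
#' Solubility above 70 percent labels a protein soluble; below 30 percent
#' labels it aggregation-prone; the band \[30, 70\] (inclusive; strict
#' inequalities) stays unlabeled.
#'
#' @param src A continuous-solubility `label_source`.
#' @param soluble_above,aggregating_below Thresholds in percent.
#' @return Data.frame `id`, `class` for the labeled proteins only.
#' @export
apply_solubility_thresholds <- function(src, soluble_above = 70,
                                        aggregating_below = 30) {
  stopifnot(inherits(src, "label_source"), src$kind == "continuous-solubility")
  v <- src$payload
  cls <- ifelse(v > soluble_above, "soluble",
         ifelse(v < aggregating_below, "aggregation_prone", NA_character_))
  keep <- !is.na(cls)
  data.frame(id = names(v)[keep], class = cls[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Integrate solubility labels with chaperone-substrate studies
#'
#' Any protein appearing in at least one substrate study is removed from the
#' soluble set; proteins identified as chaperone-dependent by two or more
#' distinct studies are added to the aggregation-prone set. Per-record
#' provenance lists the contributing sources.
#'
#' @param sol Data.frame from [apply_solubility_thresholds()] (may have zero
#'   rows).
#' @param substrates List of membership `label_source` objects (>= 1).
#' @param sol_name Provenance name of the solubility source.
#' @return A `labeled_ids` data.frame: `id`, `class`, `provenance`
#'   (semicolon-joined source names).
#' @export
merge_labels <- function(sol, substrates, sol_name = "solubility") {
  if (length(substrates) < 1L) stop("need at least one membership source")
  stopifnot(all(vapply(substrates, function(s)
    inherits(s, "label_source") && s$kind == "membership", logical(1))))
  sub_ids <- lapply(substrates, `[[`, "payload")
  names(sub_ids) <- vapply(substrates, `[[`, character(1), "name")
  all_sub <- unique(unlist(sub_ids))
  n_studies <- vapply(all_sub, function(id) {
    sum(vapply(sub_ids, function(s) id %in% s, logical(1)))
  }, integer(1))
  multi <- all_sub[n_studies >= 2L]

  sol_soluble <- sol$id[sol$class == "soluble"]
  sol_agg <- sol$id[sol$class == "aggregation_prone"]

  soluble <- setdiff(sol_soluble, all_sub)
  agg <- union(sol_agg, multi)

  prov <- function(id, base) {
    from_sub <- names(sub_ids)[vapply(sub_ids, function(s) id %in% s,
                                      logical(1))]
    paste(c(base[id %in% c(sol_soluble, sol_agg)], from_sub), collapse = ";")
  }
  out <- rbind(
    data.frame(id = soluble, class = rep("soluble", length(soluble)),
               provenance = vapply(soluble, prov, character(1),
                                   base = sol_name),
               stringsAsFactors = FALSE),
    data.frame(id = agg, class = rep("aggregation_prone", length(agg)),
               provenance = vapply(agg, prov, character(1), base = sol_name),
               stringsAsFactors = FALSE)
  )
  row.names(out) <- NULL
  stopifnot(!anyDuplicated(out$id))
  class(out) <- c("labeled_ids", "data.frame")
  out
}

#' Pairwise global-alignment identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, linear gap -1 by
#' default); identity = matches / alignment columns, gaps included in the
#' denominator.
#'
#' @param a,b Sequences (strings or one-row `protein_set`s).
#' @param match,mismatch,gap Alignment scores.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  .nw_align_stats(.as_seq(a), .as_seq(b), match, mismatch, gap)$identity
}

#' Greedy redundancy reduction at an identity threshold
#'
#' Incremental clustering in the longest-first order: sequences are sorted by
#' length (descending; ties broken lexicographically by id) and a sequence is
#' retained iff its global-alignment identity to every previously retained
#' sequence is at most `threshold`. Deterministic; the retained sequences are
#' the cluster representatives.
#'
#' @param proteins A `protein_set`.
#' @param threshold Identity threshold in (0, 1\]; default 0.30.
#' @return The retained `protein_set` (original input order).
#' @export
redundancy_reduce <- function(proteins, threshold = 0.30) {
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-nchar(proteins$seq), proteins$id)
  keep_ids <- character(0)
  keep_seqs <- character(0)
  for (k in ord) {
    s <- proteins$seq[k]
    redundant <- FALSE
    for (r in keep_seqs) {
      if (.nw_align_stats(s, r, 1, 0, -1)$identity > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      keep_ids <- c(keep_ids, proteins$id[k])
      keep_seqs <- c(keep_seqs, s)
    }
  }
  out <- proteins[proteins$id %in% keep_ids, , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Build a curated labeled training set
#'
#' Full curation pipeline: threshold solubility, integrate substrate studies,
#' attach sequences, drop redundancy within each class at the identity
#' threshold.
#'
#' @param proteins `protein_set` holding sequences for the labeled ids.
#' @param sol_src Continuous-solubility `label_source`.
#' @param substrates List of membership `label_source`s.
#' @param threshold Redundancy identity threshold.
#' @return A `labeled_set`: data.frame `id`, `seq`, `class`, `provenance`.
#' @export
curate_training_set <- function(proteins, sol_src, substrates,
                                threshold = 0.30) {
  labels <- merge_labels(apply_solubility_thresholds(sol_src), substrates,
                         sol_name = sol_src$name)
  labels <- labels[labels$id %in% proteins$id, , drop = FALSE]
  out <- do.call(rbind, lapply(split(labels, labels$class), function(part) {
    sub <- proteins[match(part$id, proteins$id), , drop = FALSE]
    class(sub) <- c("protein_set", "data.frame")
    kept <- redundancy_reduce(sub, threshold)
    merge(kept, part, by = "id", sort = FALSE)
  }))
  row.names(out) <- NULL
  class(out) <- c("labeled_set", "data.frame")
  out
}
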