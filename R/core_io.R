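#' Protein record sets
#'
#' The package represents a set of protein records as a plain `data.frame`
#' with character columns `id` and `seq` (class `"protein_set"`). `id` must be
#' unique within a set; `seq` is an upper-case string over the 20-letter
#' amino-acid alphabet after [sanitize_proteins()].
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of amino-acid sequences.
#' @return A `protein_set` data.frame.
#' @export
protein_set <- function(id, seq) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (anyDuplicated(id)) {
    stop("duplicate protein ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  out <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Sanitize protein sequences
#'
#' Drops non-canonical residues (B, Z, X, U, O, J, `*`) from each sequence and
#' reports how many were removed. Residues outside the amino-acid alphabet
#' altogether (digits, gaps) are also dropped and counted.
#'
#' @param proteins A `protein_set`.
#' @param min_length Records whose sanitized sequence is shorter than this are
#'   flagged (column `too_short`); downstream proteome scans exclude them.
#'   Default 31 so that autocorrelation features up to lag 30 are defined.
#' @return The sanitized `protein_set` with attribute `"sanitization"`: a
#'   data.frame of `id`, `n_dropped`, `too_short`.
#' @export
sanitize_proteins <- function(proteins, min_length = 31L) {
  seqs <- toupper(proteins$seq)
  clean <- gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), "", seqs)
  n_dropped <- nchar(seqs) - nchar(clean)
  too_short <- nchar(clean) < min_length
  if (any(n_dropped > 0L)) {
    warning(sum(n_dropped), " non-canonical residue(s) dropped from ",
            sum(n_dropped > 0L), " sequence(s)")
  }
  out <- protein_set(proteins$id, clean)
  attr(out, "sanitization") <- data.frame(
    id = proteins$id, n_dropped = n_dropped, too_short = too_short,
    stringsAsFactors = FALSE)
  out
}

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a [protein_set()]. Record ids are the first
#' whitespace-delimited token of each header; input order is preserved and
#' sequences are upper-cased. Non-canonical residues are kept verbatim here;
#' apply [sanitize_proteins()] before feature extraction.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_set`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  protein_set(ids, seqs)
}

#' Write a protein FASTA file
#'
#' @param proteins A `protein_set`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Genome GC content
#'
#' `GC content = (G + C) / total bases`. `genome_record()` stores the counts;
#' `gc_content()` evaluates the ratio. `gc_from_fasta()` computes per-record
#' GC from a nucleotide FASTA; counting is case-insensitive and by default
#' only A/C/G/T count toward the denominator (ambiguity codes are logged),
#' while `strict = TRUE` makes any non-ACGT base an error.
#'
#' @param organism_id Organism identifier.
#' @param nucleotide_len Total counted bases (> 0).
#' @param gc_count Number of G + C bases.
#' @return `genome_record()`: a list with the three fields; `gc_content()`:
#'   a fraction in \[0, 1\].
#' @export
genome_record <- function(organism_id, nucleotide_len, gc_count) {
  nucleotide_len <- as.numeric(nucleotide_len)
  gc_count <- as.numeric(gc_count)
  if (nucleotide_len <= 0) stop("nucleotide_len must be > 0")
  if (gc_count < 0 || gc_count > nucleotide_len) {
    stop("gc_count must lie in [0, nucleotide_len]")
  }
  structure(list(organism_id = as.character(organism_id),
                 nucleotide_len = nucleotide_len, gc_count = gc_count),
            class = "genome_record")
}

#' @rdname genome_record
#' @param g A `genome_record`.
#' @export
gc_content <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  g$gc_count / g$nucleotide_len
}

#' @rdname genome_record
#' @param path Nucleotide FASTA path.
#' @param strict If `TRUE`, any base outside A/C/G/T is an error; otherwise
#'   such bases are excluded from numerator and denominator and counted in the
#'   `n_other` column.
#' @export
gc_from_fasta <- function(path, strict = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  count <- function(s, chars) {
    sum(vapply(chars, function(ch) {
      lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
    }, numeric(1)))
  }
  res <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    gc <- count(s, c("G", "C"))
    at <- count(s, c("A", "T"))
    other <- nchar(s) - gc - at
    if (strict && other > 0) {
      stop("non-ACGT bases in record '", ids[i], "'")
    }
    if (gc + at == 0) stop("record '", ids[i], "' has no countable bases")
    data.frame(organism_id = ids[i], gc = gc / (gc + at),
               n_bases = gc + at, n_other = other, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read a rooted phylogenetic tree
#'
#' Reads a single newick tree and validates the invariants the comparative
#' layer needs: unique tip labels, branch lengths on every edge (zero
#' allowed), and a rooted topology.
#'
#' @param path Newick file with one tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse newick in '", path, "'")
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; lengths are required for contrasts")
  }
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
    stop("branch lengths must all be present and non-negative")
  }
  if (!ape::is.rooted(tr)) {
    stop("tree is unrooted; root it (e.g. with an outgroup) before use")
  }
  invisible(tr)
}

#' Read a TSV table with a header row
#'
#' Thin wrapper around [utils::read.delim()] used for GC tables, metadata and
#' label sources; checks that `required` columns are present.
#'
#' @param path TSV path.
#' @param required Character vector of required column names.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, required = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a TSV table
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
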