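#' @useDynLib aggprop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical residue order used throughout the package.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

NONCANONICAL <- c("B", "Z", "X", "U", "O", "J", "*")

.aa_scale <- function(values) {
  stopifnot(length(values) == 20L)
  names(values) <- AA_ALPHABET
  values
}

# Published amino-acid property scales. Accession-level provenance for the
# original classifier is unknown; these are the scales conventionally paired
# with each property name in sequence-autocorrelation work.
AA_SCALES <- list(
  # Kyte & Doolittle hydropathy
  hydrophobicity = .aa_scale(c(
     1.8, -4.5, -3.5, -3.5,  2.5, -3.5, -3.5, -0.4, -3.2,  4.5,
     3.8, -3.9,  1.9,  2.8, -1.6, -0.8, -0.7, -0.9, -1.3,  4.2)),
  # Hopp & Woods hydrophilicity (used by PseAAC and the QSO distance)
  hydrophilicity = .aa_scale(c(
    -0.5,  3.0,  0.2,  3.0, -1.0,  0.2,  3.0,  0.0, -0.5, -1.8,
    -1.8,  3.0, -1.3, -2.5,  0.0,  0.3, -0.4, -3.4, -2.3, -1.5)),
  # Dayhoff relative mutability
  relative_mutability = .aa_scale(c(
    100,  65, 134, 106,  20,  93, 102,  49,  66,  96,
     40,  56,  94,  41,  56, 120,  97,  18,  41,  74)),
  # Zamyatnin residue volume (A^3)
  residue_volume = .aa_scale(c(
     88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4,  60.1, 153.2, 166.7,
    166.7, 168.6, 162.9, 189.9, 112.7,  89.0, 116.1, 227.8, 193.6, 140.0)),
  # Charton & Charton polarizability parameter
  polarizability = .aa_scale(c(
    0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000, 0.230, 0.186,
    0.186, 0.219, 0.221, 0.290, 0.131, 0.062, 0.108, 0.409, 0.298, 0.140)),
  # Charton steric parameter
  steric_parameter = .aa_scale(c(
    0.52, 0.68, 0.76, 0.76, 0.62, 0.68, 0.68, 0.00, 0.70, 1.02,
    0.98, 0.68, 0.78, 0.70, 0.36, 0.53, 0.50, 0.70, 0.70, 0.76)),
  # Free energy of solution in water
  free_energy = .aa_scale(c(
    -0.368, -1.030,  0.000,  2.060,  4.530,  0.731,  1.770, -0.525,  0.000,  0.791,
     1.070,  0.000,  0.656,  1.060, -2.240, -0.524,  0.000,  1.600,  4.910,  0.401)),
  # Chothia accessible surface area in a tripeptide (A^2)
  asa_tripeptide = .aa_scale(c(
    115, 225, 160, 150, 135, 180, 190,  75, 195, 175,
    170, 200, 185, 210, 145, 115, 140, 255, 230, 155)),
  # Side-chain mass (Da), third PseAAC property
  side_chain_mass = .aa_scale(c(
     15, 101,  58,  59,  47,  72,  73,   1,  82,  57,
     57,  73,  75,  91,  42,  31,  45, 130, 107,  43))
)

#' Amino-acid property scale
#'
#' Returns one of the shipped 20-residue property scales, optionally
#' standardized to zero mean and unit standard deviation over the 20 canonical
#' residues (the conventional preprocessing for autocorrelation descriptors).
#'
#' @param name One of `names(aa_scales())`.
#' @param standardize Logical; standardize over the 20 residues.
#' @return Named numeric vector of length 20 (names = one-letter residues).
#' @export
aa_scale <- function(name, standardize = FALSE) {
  if (!name %in% names(AA_SCALES)) {
    stop("unknown property scale '", name, "'; available: ",
         paste(names(AA_SCALES), collapse = ", "))
  }
  v <- AA_SCALES[[name]]
  if (standardize) v <- (v - mean(v)) / stats::sd(v)
  v
}

#' @rdname aa_scale
#' @export
aa_scales <- function() names(AA_SCALES)

# Three-class CTD partitions (Dubchak-style). The van der Waals class
# boundaries 2.78 / 2.95-4.0 / 4.03-8.08 pin group 2 as {N,V,E,Q,I,L}.
CTD_GROUPS <- list(
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  vdw_volume = list(
    g1 = c("G", "A", "S", "T", "P", "D", "C"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  charge = list(
    g1 = c("K", "R", "H"),                                   # positive
    g2 = c("A", "N", "C", "Q", "G", "I", "L", "M", "F", "P",
           "S", "T", "W", "Y", "V"),                         # neutral
    g3 = c("D", "E"))                                        # negative
)

#' CTD residue groupings
#'
#' Three-class physicochemical partitions of the amino-acid alphabet used by
#' composition/transition/distribution descriptors.
#'
#' @param name `"polarizability"`, `"vdw_volume"` or `"charge"`.
#' @return List of three character vectors `g1`, `g2`, `g3` covering the
#'   20-letter alphabet.
#' @export
ctd_grouping <- function(name) {
  if (!name %in% names(CTD_GROUPS)) {
    stop("unknown CTD grouping '", name, "'")
  }
  CTD_GROUPS[[name]]
}

#' Physicochemical inter-residue distance matrix
#'
#' A 20 x 20 distance matrix for quasi-sequence-order descriptors, constructed
#' from standardized hydrophobicity, hydrophilicity and side-chain mass:
#' `d(a,b)^2 = mean of the three squared standardized property differences`.
#' This is a synthetic stand-in with the same construction as the classic
#' Schneider-Wrede physicochemical distance (whose exact published values are
#' not redistributable here); d(a,a) = 0 and the matrix is symmetric.
#'
#' @return Numeric 20 x 20 matrix with residue dimnames.
#' @export
qso_distance_matrix <- function() {
  if (!is.null(.aggprop_cache$qso_dmat)) return(.aggprop_cache$qso_dmat)
  props <- cbind(aa_scale("hydrophobicity", standardize = TRUE),
                 aa_scale("hydrophilicity", standardize = TRUE),
                 aa_scale("side_chain_mass", standardize = TRUE))
  d2 <- matrix(0, 20, 20)
  for (k in 1:3) d2 <- d2 + outer(props[, k], props[, k], "-")^2
  d <- sqrt(d2 / 3)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  .aggprop_cache$qso_dmat <- d
  d
}

.aggprop_cache <- new.env(parent = emptyenv())
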