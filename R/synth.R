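# Seeded synthetic-data generators: codon-model proteomes across a GC
# gradient, planted-signal labeled training sets, and random trees with
# correlated Brownian traits. Every generator is a pure function of
# (config, seed).

#' Synthetic-data generation config
#'
#' Defaults describe the emulated world: 60 organisms spanning genomic GC
#' 0.25-0.70 (the observed eubacterial range), 100 proteins per proteome with
#' a gamma-like length distribution (min 50, mean ~300, max 1000 residues),
#' a 400-protein labeled training set whose labels follow a logistic model on
#' three descriptor values dominated by the GC-sensitive phenylalanine PseAAC
#' component (negative weight, so aggregation propensity rises with GC), and
#' unit-rate Brownian traits with correlation 0.7 on random trees.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param n_organisms,proteome_size,gc_range Proteome ensemble shape.
#' @param length_min,length_mean,length_max Protein length model.
#' @param n_train Labeled-set size.
#' @param label_weights Named weights on default-spec feature ids.
#' @param label_intercept Logistic intercept.
#' @param trait_rho Brownian trait correlation.
#' @return A `gen_config` list.
#' @export
gen_config <- function(seed = 1L, n_organisms = 60L, proteome_size = 100L,
                       gc_range = c(0.25, 0.70), length_min = 50L,
                       length_mean = 300L, length_max = 1000L,
                       n_train = 400L,
                       label_weights = c(pseaac_F = -5, pseaac_D = 3,
                                         mb_hydro_1 = 1.5),
                       label_intercept = 0, trait_rho = 0.7) {
  stopifnot(n_organisms >= 1L, proteome_size >= 1L, n_train >= 1L,
            gc_range[1] > 0, gc_range[2] < 1, gc_range[1] <= gc_range[2],
            length_min >= 31L, length_min <= length_mean,
            length_mean <= length_max, abs(trait_rho) <= 1)
  structure(list(seed = as.integer(seed), n_organisms = n_organisms,
                 proteome_size = proteome_size, gc_range = gc_range,
                 length_min = length_min, length_mean = length_mean,
                 length_max = length_max, n_train = n_train,
                 label_weights = label_weights,
                 label_intercept = label_intercept, trait_rho = trait_rho),
            class = "gen_config")
}

#' Amino-acid frequencies implied by genomic GC content
#'
#' Closed-form expectation under the codon model: codon probability is the
#' product of per-position base probabilities with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`, stop codons excluded and renormalized, then
#' summed per encoded amino acid (standard genetic code).
#'
#' @param gc GC fraction strictly inside (0, 1).
#' @return Named 20-vector of frequencies (sums to 1), in `AA_ALPHABET`
#'   order.
#' @export
aa_freqs_from_gc <- function(gc) {
  if (gc <= 0 || gc >= 1) {
    stop("gc must be strictly inside (0,1); at the boundary some amino acids",
         " are impossible")
  }
  code <- Biostrings::GENETIC_CODE
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  pc <- vapply(names(code), function(cd) {
    prod(pb[strsplit(cd, "", fixed = TRUE)[[1]]])
  }, numeric(1))
  keep <- code != "*"
  pc <- pc[keep] / sum(pc[keep])
  f <- tapply(pc, code[keep], sum)
  out <- as.numeric(f[AA_ALPHABET])
  names(out) <- AA_ALPHABET
  out
}

.gen_lengths <- function(n, cfg) {
  len <- cfg$length_min +
    stats::rgamma(n, shape = 2, scale = (cfg$length_mean - cfg$length_min) / 2)
  pmin(as.integer(round(len)), cfg$length_max)
}

#' Generate a synthetic proteome at a given GC content
#'
#' Residues are drawn i.i.d. from [aa_freqs_from_gc()]; lengths follow the
#' config's gamma-like model. Seed the RNG before calling (the CLI and the
#' ensemble generator do this from `cfg$seed`).
#'
#' @param gc GC fraction in (0, 1).
#' @param cfg A [gen_config()].
#' @param organism_id Prefix for protein ids.
#' @return A `protein_set` of `cfg$proteome_size` records.
#' @export
gen_proteome <- function(gc, cfg = gen_config(), organism_id = "org") {
  freqs <- aa_freqs_from_gc(gc)
  lens <- .gen_lengths(cfg$proteome_size, cfg)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = freqs), collapse = "")
  }, character(1))
  protein_set(sprintf("%s_p%04d", organism_id, seq_along(seqs)), seqs)
}

#' Generate an ensemble of proteomes across a GC gradient
#'
#' Organism GC values are evenly spaced over `cfg$gc_range`; each proteome is
#' generated with [gen_proteome()]. Fully determined by `cfg$seed`.
#'
#' @param cfg A [gen_config()].
#' @return List: `proteomes` (named list of `protein_set`s), `gc_table`
#'   (data.frame `organism_id`, `gc`), `metadata` (`organism_id`,
#'   `groel_copies`, `habitat`).
#' @export
gen_proteome_set <- function(cfg = gen_config()) {
  set.seed(cfg$seed)
  gcs <- seq(cfg$gc_range[1], cfg$gc_range[2],
             length.out = cfg$n_organisms)
  ids <- sprintf("org%03d", seq_len(cfg$n_organisms))
  proteomes <- lapply(seq_along(ids), function(i) {
    gen_proteome(gcs[i], cfg, organism_id = ids[i])
  })
  names(proteomes) <- ids
  # groEL copy number loosely increasing with GC; habitat independent
  copies <- pmax(0L, as.integer(round(1 + 2 * (gcs - mean(gcs)) +
                                        stats::rnorm(length(gcs), 0, 0.7))))
  habitat <- sample(c("free_living", "symbiont"), length(ids),
                    replace = TRUE, prob = c(0.7, 0.3))
  list(proteomes = proteomes,
       gc_table = data.frame(organism_id = ids, gc = gcs,
                             stringsAsFactors = FALSE),
       metadata = data.frame(organism_id = ids, groel_copies = copies,
                             habitat = habitat, stringsAsFactors = FALSE))
}

#' Generate a planted-signal labeled training set
#'
#' Sequences are generated at GC values drawn uniformly over `cfg$gc_range`;
#' each sequence's planted features (default-spec ids named in
#' `cfg$label_weights`) are extracted, standardized over the set, and the
#' label is Bernoulli with `P(aggregation_prone) = plogis(b0 + w . z)`. The
#' realized Bayes accuracy `mean(pmax(p, 1 - p))` of the generating model is
#' attached as attribute `"bayes_accuracy"`.
#'
#' @param cfg A [gen_config()].
#' @param classes Length-2 class names `c(positive, negative)`.
#' @return A `labeled_set` data.frame (`id`, `seq`, `class`, `provenance`)
#'   with attributes `bayes_accuracy` and `true_p`.
#' @export
gen_labeled_set <- function(cfg = gen_config(),
                            classes = c("aggregation_prone", "soluble")) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_train
  gcs <- stats::runif(n, cfg$gc_range[1], cfg$gc_range[2])
  lens <- .gen_lengths(n, cfg)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, lens[i], replace = TRUE,
                 prob = aa_freqs_from_gc(gcs[i])), collapse = "")
  }, character(1))
  prots <- protein_set(sprintf("train%05d", seq_len(n)), seqs)
  w <- cfg$label_weights
  spec <- default_feature_spec()
  stopifnot(all(names(w) %in% feature_ids(spec)))
  X <- extract_features(prots, spec)[, names(w), drop = FALSE]
  Z <- scale(X)
  score <- cfg$label_intercept + as.numeric(Z %*% w)
  p <- stats::plogis(score)
  y <- stats::rbinom(n, 1L, p)
  out <- data.frame(id = prots$id, seq = prots$seq,
                    class = ifelse(y == 1L, classes[1], classes[2]),
                    provenance = "synthetic-logistic-plant",
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_set", "data.frame")
  attr(out, "bayes_accuracy") <- mean(pmax(p, 1 - p))
  attr(out, "true_p") <- p
  attr(out, "gc") <- gcs
  out
}

#' Random tree with correlated Brownian traits
#'
#' Random binary topology with exponential(1) branch lengths; two traits
#' evolve by bivariate Brownian motion from a root value of 0, with unit
#' rates and correlation `rho` (per-branch increments are bivariate normal
#' with covariance `rho * branch length`).
#'
#' @param n_tips Number of tips (>= 3).
#' @param rho Trait correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return List: `tree` ([ape::phylo]), `x`, `y` (named tip trait vectors).
#' @export
gen_tree_traits <- function(n_tips, rho = 0.7, seed = 1L) {
  stopifnot(n_tips >= 3L, abs(rho) <= 1)
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = function(n) stats::rexp(n, rate = 1))
  ntot <- n_tips + tree$Nnode
  root <- n_tips + 1L
  xv <- numeric(ntot); yv <- numeric(ntot)
  # preorder: parents before children
  eo <- ape::reorder.phylo(tree, "cladewise")
  a <- sqrt(max(0, 1 - rho^2))
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; child <- eo$edge[e, 2]
    L <- eo$edge.length[e]
    z1 <- stats::rnorm(1, 0, sqrt(L))
    z2 <- stats::rnorm(1, 0, sqrt(L))
    xv[child] <- xv[par] + z1
    yv[child] <- yv[par] + rho * z1 + a * z2
  }
  tips <- seq_len(n_tips)
  list(tree = tree,
       x = stats::setNames(xv[tips], tree$tip.label),
       y = stats::setNames(yv[tips], tree$tip.label))
  # root state is 0 by construction
}
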