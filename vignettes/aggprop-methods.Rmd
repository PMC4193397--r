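---
title: "Methods: sequence-based aggregation propensity, chaperonin dependence, and GC-content comparative genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation propensity and chaperonin dependence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Eubacterial genomes span roughly 20-70% GC content, and because codon
composition constrains amino-acid composition, proteomes of GC-poor and
GC-rich organisms differ systematically. A long-standing hypothesis holds
that GC-poor organisms (endosymbionts in particular, via population
bottlenecks) accumulate aggregation-prone proteins and compensate by
overexpressing the chaperonin GroEL. Testing this genome-wide needs two
sequence-only classifiers — is a protein aggregation-prone? is it an
obligate (Class III) GroEL substrate? — applied across many proteomes, and a
comparative layer that relates the predicted proteome fractions (`fAg`,
`fC3`) to genomic GC content while correcting for shared phylogenetic
ancestry.

`aggprop` implements that pipeline: a deterministic protein descriptor
engine, training-set curation, mRMR feature selection with an RBF-kernel SVM
trained by stratified five-fold cross-validation, proteome scanning, and
phylogenetically aware statistics, plus seeded synthetic-data generators
that let every stage be exercised and tested without any external dataset.

# The descriptor engine

All descriptors are computed on sanitized sequences over the 20-letter
alphabet ([sanitize_proteins()] drops B, Z, X, U, O, J and `*` with a
warning count; proteins left shorter than 31 residues are excluded from
scans because the selected feature set uses autocorrelation lags up to 30).

The shipped default specification ([default_feature_spec()]) holds 24
descriptors drawn from these families:

* **Composition** — residue fractions.
* **Gapped pair composition** — frequency of residue `a` followed by `b`
  after `g` intervening positions, normalized by the window count.
* **Pseudo amino-acid composition (PseAAC)** — residue frequencies extended
  by `lambda` sequence-order correlation factors; `theta_d` averages, over
  pairs `d` apart, the mean squared difference of standardized
  hydrophobicity, hydrophilicity and side-chain mass (`lambda = 30`,
  `w = 0.05`; only the 20 residue components enter the default spec, so
  these defaults act only through the normalization).
* **Autocorrelation** (Moreau-Broto, Moran, Geary) of a property profile at
  lag `L`, with the property scale standardized to zero mean / unit SD over
  the 20 residues (the conventional preprocessing; the source work names
  properties but not index accessions).
* **CTD** — composition, transition and distribution over three-class
  physicochemical partitions. The distribution points are the sequence
  positions (percent of length) of the first and 25/50/75/100% occurrence
  quantiles, the `k`-th occurrence with `k = ceiling(q * n_group)`.
* **Quasi-sequence-order (QSO)** — frequencies plus coupling numbers
  `tau_d = sum_i d(s_i, s_{i+d})^2` from an inter-residue distance matrix
  (`maxlag = 30`, `w = 0.1`).
* **FoldIndex segment statistics** — windowed index
  `2.785 <H> - |<q>| - 1.151` (window 16, hydrophobicity rescaled to [0,1],
  unit charges K/R = +1, D/E = -1); folded positions are windows with
  positive index and the feature is the mean length of maximal folded runs.
* **Positive-charge distribution** — CTD-style distribution of {K, R, H}.

Numerical conventions, chosen once and tested: every composition-type
vector sums to 1 (or 100 for percent distributions); a sequence too short
for a lag/gap yields the value 0 with a warning rather than aborting a
proteome scan (a strict mode is available at curation time by excluding
short proteins); Moran and Geary autocorrelation of a zero-variance
(homopolymer) profile are 0 by convention; a group absent from a sequence
has all distribution points 0.

Two provenance caveats, both inherited from the source material and flagged
rather than hidden. First, the exact AAindex entries behind the named
properties are unknown; the package ships the scales conventionally paired
with those names (Kyte-Doolittle hydropathy, Dayhoff relative mutability,
Zamyatnin residue volume, Charton & Charton polarizability, Charton steric
parameter, free energy of solution in water, Chothia tripeptide ASA).
Second, the QSO distance matrix is a *constructed stand-in* of the
Schneider-Wrede family — the RMS difference of standardized hydrophobicity,
hydrophilicity and side-chain mass — because the original values are not
redistributable here. The oracle-equivalence tests are unaffected: they
check the computation against naive reimplementations sharing only the
scale data. Three opaque internal feature ids were mapped to a best
reading: the QSO coupling number at lag 2, the 50% distribution point of
the positive group, and the polarizability group-2 50% point.

# Curation

Training labels are integrated from one continuous solubility source and
two or more substrate membership lists: solubility above 70% labels a
protein soluble, below 30% aggregation-prone (strict inequalities; the
[30, 70] band stays unlabeled); any protein appearing in *any* substrate
study is removed from the soluble set; proteins claimed by **two or more
distinct studies** are added to the aggregation-prone set. Redundancy is
then removed within each class at 30% identity by greedy incremental
clustering in longest-first order (ties broken lexicographically by id):
a sequence is kept iff its global-alignment identity (Needleman-Wunsch,
match 1 / mismatch 0 / linear gap -1; identity = matches / alignment
columns, gaps included) to every kept sequence is at most the threshold.
This replaces word-filter clustering heuristics with exact alignment — at
curation scale (~10^3 sequences) it is tractable and strictly more
conservative, and makes the retained-set guarantee (`no pair above
threshold`) checkable exhaustively.

# The classifier

Features are standardized (training folds only), and an RBF-kernel C-SVC is
trained by an SMO solver written for this package (maximal-violating-pair
working-set selection, per-class costs scaled inversely to class frequency
to handle the obligate-substrate imbalance). Cross-validation is stratified
five-fold; `C` and `gamma` can be grid-searched in an inner 3-fold loop fit
on training folds only. Reported metrics are **pooled** (micro-averaged)
over held-out folds — one confusion matrix, plus AUC from the pooled
decision values — matching single-table reporting; whether the original
study pooled or fold-averaged is unstated, and pooling is the package's
choice. The final model is refit on all rows with the modal
hyperparameters.

Feature selection is greedy mRMR with the mutual-information difference
criterion; continuous features are discretized into five equal-frequency
bins (common practice; unstated in the source).

Prediction confidence is a single-slope logistic `1 / (1 + exp(-a f))` of
the decision value `f`, with `a > 0` fit by maximum likelihood on training
decision values. Unlike a two-parameter Platt sigmoid this pins decision
value 0 to confidence exactly 0.5, so the class call and the 0.5 confidence
threshold can never disagree. Models serialize to a single JSON container
(full-precision numerics) that round-trips to identical predictions.

# Proteome scanning

`fAg` is the fraction of scanned proteins called aggregation-prone. The
obligate-substrate classifier is applied **within** the predicted
aggregation-prone subset, and `fC3` uses the whole scanned proteome as
denominator (so `fC3 <= fAg` by construction); the within-subset fraction
is also emitted because the original data description leaves the
denominator ambiguous. groEL copy number and habitat class are user-supplied
table columns joined by exact organism id; homolog searching is out of
scope.

# Comparative statistics

* **Kendall tau-b** (tie-corrected, since predicted fractions tie often);
  p by exact permutation enumeration for n <= 8, else the tie-corrected
  normal approximation with continuity correction.
* **Independent contrasts** by Felsenstein pruning: contrast
  `(x1 - x2) / sqrt(v1 + v2)`, node value the `1/v`-weighted average,
  parent branch extended by `v1 v2 / (v1 + v2)`. Polytomies are resolved
  arbitrarily into zero-length branches and any zero branch is replaced by
  `1e-8 x` tree height so contrast variances stay positive. Contrast
  correlation is forced through the origin (contrast signs are arbitrary),
  `r = sum(cx cy) / sqrt(sum(cx^2) sum(cy^2))`, with `t`-based p on `n - 1`
  degrees of freedom.
* **ANCOVA** `y ~ gc + habitat + gc:habitat` with Type-II F-tests (robust
  to unbalanced habitat groups; the sum-of-squares type is unstated in the
  source and Type II is the package's choice). With a single habitat level
  the model degrades to simple regression and reports NA habitat terms.
* **Mann-Whitney** U with ties counted one half; exact p by enumeration of
  all group assignments when `n_a * n_b <= 400` (valid under ties),
  otherwise the tie-corrected normal approximation with continuity
  correction. Away from the far tail (exact p >= 0.1) the approximation
  sits within a few percent of the exact value at n = 10/10; in the far
  tail it is deliberately conservative, and callers needing small exact
  tails should stay within the enumeration regime.

# The synthetic world

The generators emulate the data the pipeline would meet in the wild,
without pretending to realism they do not have:

* **Proteomes**: residues i.i.d. from the codon-model expectation at
  genomic GC `g` — codon probability proportional to the product of
  per-position base probabilities with `P(G) = P(C) = g/2`, stops excluded
  — so the GC-to-composition coupling (F/I/K/N/Y falling, A/G/P/R rising
  with GC) has a closed form the tests can check. Lengths follow a
  gamma-like model (min 50, mean ~300, max 1000 in the defaults; scans in
  the test suite use smaller proteomes, stated where they do).
* **Labeled sets**: labels are Bernoulli with logistic probability on three
  standardized descriptor values, dominated by the GC-sensitive
  phenylalanine PseAAC component with negative weight — i.e. the stated
  world is one where aggregation propensity rises with GC, which is the
  qualitative claim the end-to-end test then recovers through the full
  train-scan-correlate pipeline. The realized Bayes accuracy of the
  generating model is attached to each set.
* **Trees and traits**: random binary topologies with exponential branch
  lengths; bivariate Brownian traits with unit rate and correlation `rho`.

What a green test establishes: the machinery — descriptors, solver,
contrasts, tests — is correct against independent oracles, and the pipeline
recovers planted effects of realistic size. What it does not establish:
anything about real proteomes; i.i.d. residues have no secondary structure,
no domain architecture and no phylogenetic autocorrelation of composition,
and the planted label model is far simpler than real solubility. The
original study's empirical numbers (83.21% / MCC 0.66 solubility CV,
92.29% / 0.69 for the obligate-substrate classifier, Kendall tau 0.38, PIC
correlations 0.4 / 0.7, ANCOVA p 0.24 / 0.65 / 0.36 / 0.38) depend on
external datasets and are deliberately not asserted anywhere in this
package's tests.

# Known limitations

* The SMO solver caches the full kernel matrix; training is comfortable to
  a few thousand rows, which covers curated training sets but not
  proteome-scale refits (which the pipeline never needs).
* Exact Mann-Whitney enumeration materializes all group assignments;
  beyond `n_a * n_b = 400` the normal approximation takes over.
* Greedy exact-alignment clustering is quadratic; at many thousands of
  sequences a word-filtered tool would be preferable upstream.
* The codon-model generator draws residues independently; per-protein GC
  is homogeneous and there is no among-site rate variation.
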