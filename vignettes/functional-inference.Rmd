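---
title: "Inferring functional profiles for 16S samples by double co-inertia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional profiles for 16S samples by double co-inertia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipco)
```

## The problem

Amplicon (16S rRNA) sequencing tells you *who* is in a microbial community
but not *what they can do*. Tools that predict function from 16S data
usually map each taxon to an annotated reference genome and sum the
genome's gene content — which fails whenever close annotated relatives are
missing. This package takes a different route: it requires no genomes at
all, only a **paired reference dataset** — a cohort for which both a
taxonomic table and a functional (pathway or gene-family) table were
measured on the same samples, typically by shotgun metagenomics. If
community composition and community function co-vary across that cohort,
the co-variance itself can be transferred to a new 16S dataset.

## The model

Three tables enter, linked by identifiers:

* `R` — reference functional table (functions × reference samples),
* `L` — reference taxonomic table (taxa × the *same* reference samples),
* `Q` — query taxonomic table (taxa × query samples; the taxa identifiers
  must match `L`'s).

All three are transformed (Hellinger by default, i.e. square root of
per-sample relative abundance). The inference is the fourth-corner (RLQ)
construction:

1. Correspondence analysis of `L` (oriented samples × taxa) yields the
   chi-square residual table
   $L^\*_{it} = P_{it}/(r_i c_t) - 1$ with $P = L/\sum L$, sample weights
   $r_i$ (row sums of $P$) and taxa weights $c_t$ (column sums).
2. `R` (as samples × functions) is centered by the weighted mean with the
   sample weights $r$; the removed means form the vector
   $\mathrm{waR}_f = \sum_i r_i R_{if} / \sum_i r_i$, the weighted average
   functional profile of the reference.
3. `Q` (taxa × query samples) is centered by the weighted mean with the
   taxa weights $c$.
4. The fourth-corner cross product
   $\mathrm{prod}_{fs} = \sum_{i,t} \tilde R_{if}\, r_i\, L^\*_{it}\, c_t\, \tilde Q_{ts}$
   is an association matrix between functions and query samples mediated by
   the taxa.
5. Inferred profiles are `prod + waR` (row-wise): the association signal
   re-anchored at the reference's average functional profile.

Two modelling consequences are worth keeping in mind. The product is a
*bilinear* approximation whose capacity is bounded by the number of
reference samples: a richer reference (more samples, fewer effective taxa)
gives better feature-wise recovery. And because `waR` is added back on the
transformed scale, **inferred values live on the transformed scale of `R`**
(no inverse transform is defined for Hellinger residuals); they can be
small negatives, which `filter_low_inferred()` or the `--clamp-zero` flag
of the command-line tool deal with.

## Parameters that matter

* `transform` (default `"hellinger"`): the transformation applied to all
  three tables. The correspondence-analysis step needs a nonnegative `L`,
  so `clr`, `zscale` and the log10 variants are rejected for the inference
  path (they remain available through `transform_table()` for other
  analyses). Hellinger keeps community data Euclidean-friendly while
  preserving within-feature ranks.
* `scale` (default `FALSE`): whether the weighted centering also divides
  by the weighted standard deviation. The re-standardisation that defines
  the inferred profiles adds only the weighted *mean* back, which implies
  centering-only; the flag exists for users replicating ordination
  defaults that standardise to unit variance.
* `pseudocount` (default `1e-5`): added before logarithms (and for clr,
  for which no separate convention is fixed). Configurable everywhere.
* `min_shared_taxa_fraction` (default 0.5): if the taxa shared between
  query and reference carry less than this fraction of the query's total
  abundance, the reference cannot mediate the query and the alignment
  errors out rather than returning a silently diluted inference.
* Depth filtering (`filter_low_depth()`, default 1000 reads) removes
  samples too shallow for a stable compositional profile before any
  analysis.

## Qualifying a reference: the RV test

Inference only works when the reference's taxonomy and function co-vary.
`coinertia_rv()` measures this as the RV coefficient
$\mathrm{RV} = \|X_c' D Y_c\|_F^2 / (\|X_c' D X_c\|_F\,\|Y_c' D Y_c\|_F)$
between the (weighted-centered) tables sharing samples, and assesses
significance by permuting whole samples of one table, with the
$(k+1)/(n+1)$ p-value estimator (999 permutations by default; the p-value
is never exactly 0). A non-significant RV is a strong warning that
feature-wise inference from that reference will fail — the command-line
`coinertia` subcommand emits exactly that warning.

## Validation machinery

`bootstrap_validate()` implements the package's evaluation protocol: at
each of 100 iterations (default) the samples of a cohort with both 16S and
functional profiles are randomly partitioned into a reference side (50%
by default) and a query side, the inference is run with the functional
profiles of the query side held out, and the inferred profiles are scored
against the held-out truth by Spearman correlation in two directions —
per sample (across functions) and per function (across samples). Per-sample
and per-function correlations are averaged across iterations.

The two directions behave very differently, and deliberately so.
Functional redundancy — abundant functions shared by many taxa — makes
*sample-wise* correlation high for almost any sensible prediction. The
discriminating direction is *feature-wise* correlation, and the package's
negative control (`shuffle_reference = TRUE`, which permutes the sample
correspondence between `R` and `L` at each iteration) collapses it to zero
while leaving sample-wise correlation high. Any claimed inference quality
should therefore be read off the feature direction with the shuffle null
alongside.

`bin_by_coverage()` carries the quality-grading rule: pathways whose mean
coverage (fraction of the pathway's reactions detected, 0–1) is low are
poorly inferred. Two conventions are provided — fixed cuts (defaults 0.01
and 0.1, the KEGG-style thresholds; the stricter literal reading 0.001 of
"0.1%" can be selected via `high_cut`) and quantile cuts (defaults 1st
quartile and median, the MetaCyc-style thresholds). Boundary convention
for the quantile scheme: `[0, q_low)` low, `[q_low, q_high)` medium,
`[q_high, ∞)` high, so a degenerate distribution lands entirely in one
bin. `associate_with_metadata()` closes the loop on external validation:
all function × metabolite Spearman correlations (metabolites
log10-transformed after a `1e-5` pseudocount), Benjamini–Hochberg adjusted
across the whole family.

## What the synthetic generator emulates

`simulate_paired()` builds communities in which function is carried by
taxa, the structural premise of the method:

* a sparse **genome-content matrix** (taxa × functions): presence
  `Bernoulli(0.15)` times lognormal copy numbers (`sdlog` 0.5);
* per-sample taxon abundances: Dirichlet draws (concentration θ = 10,
  strongly overdispersed) around a geometric (Motomura) rank–abundance
  backbone (`rank_ratio = 0.75`: the top taxon holds ≈ 25 % of the
  community, effective diversity ≈ 7 taxa) with lognormal jitter
  (`base_sdlog = 0.5`). This is the dominance-skewed profile of OTU-level
  gut data, and the skew is what makes the taxon/function co-variance
  strong enough for a 40-sample reference to capture it — flatter
  communities (larger effective diversity) push feature-wise recovery
  down into the 0.5–0.7 range, mirroring the method's behaviour on harder
  real datasets. The backbone is deterministic on purpose: drawing the
  base composition from an unbounded heavy-tailed distribution instead
  occasionally collapses a whole community onto a single taxon, which is
  neither realistic nor a usable benchmark condition;
* observed counts: multinomial reads at depth 20 000 per sample;
* true functional profiles: genome-content-weighted taxon abundances, with
  optional multiplicative lognormal noise (`noise_sd`, default 0.1;
  multiplicative so nonnegativity never needs clipping), renormalised per
  sample;
* per-function **coverage**: the fraction of samples in which at least one
  detected taxon carries the function — low-coverage functions are exactly
  the ones carried by rare taxa, reproducing the coverage → quality
  relationship;
* `weak_covariance = TRUE` draws the functional table from an independent
  redraw of the community, emulating references whose taxonomy does not
  predict function (the regime where inference legitimately fails).

What it does *not* emulate: 16S copy-number and amplicon primer bias,
taxonomic misassignment, overlapping pathway definitions, or any attempt
to match real-cohort marginals. Passing benchmarks on this generator
therefore demonstrate correctness of the machinery and the qualitative
coverage/size/shuffle behaviours, not expected correlation levels on real
cohorts.

## Numerical choices and degenerate inputs

* Correspondence analysis refuses all-zero rows/columns rather than
  dropping them: alignment (`align_triplet()`) is the single place where
  taxa/samples are dropped, iteratively and with a report, so the
  decomposition stays a pure function of its input.
* `zscale` uses the population (n-denominator) standard deviation and maps
  constant features to zeros instead of erroring, keeping downstream
  centering well-defined. Constant vectors in correlations yield `NA`,
  never 0.
* Weighted centering accepts unnormalised weights (normalised internally);
  `waR` divides by the weight sum explicitly so non-normalised weights
  remain correct.
* Rarefaction is without replacement (multivariate hypergeometric, via
  vegan), seeded; the log10-rarefied transform therefore takes a seed.
* Spearman p-values: t approximation for n ≥ 10 pairs, full-enumeration
  exact permutation below (handles ties without special-casing).
* `filter_low_inferred()` uses the linear-interpolation sample quantile
  and retains means ≥ the threshold, so quantile 0 is a no-op and ties
  saturate (all-equal means are all retained below quantile 1).
* All randomness flows from explicit integer seeds; seeded code paths
  save and restore the caller's RNG state. Per-iteration sub-seeds are
  derived with a fixed 32-bit linear map so bootstrap results are
  bit-reproducible.

## A worked benchmark

The problem sizes below are the package's standard benchmark conditions:
150 taxa × 60 functions × 80 samples at depth 20 000, 100 bootstrap
iterations, equal reference/test split.

```{r benchmark}
d <- simulate_paired(seed = 42, noise_sd = 0)
v <- bootstrap_validate(d$functional_true, d$taxa_counts,
                        d$taxa_counts, d$functional_true,
                        validation_config(0.5, 100, seed = 42))
v
median(v$mean_feature_rho, na.rm = TRUE)
```

```{r shuffle}
vs <- bootstrap_validate(d$functional_true, d$taxa_counts,
                         d$taxa_counts, d$functional_true,
                         validation_config(0.5, 100, seed = 42,
                                           shuffle_reference = TRUE))
median(vs$mean_feature_rho, na.rm = TRUE)  # collapses to ~0
median(vs$mean_sample_rho, na.rm = TRUE)   # survives: functional redundancy
```

```{r coverage}
fr <- v$mean_feature_rho
cov <- d$coverage_true$values[names(fr), 1]
tapply(fr, cov >= median(cov), median)
```

## Known limitations

* Feature-wise recovery is bounded by the reference's size and effective
  dimensionality; small references (the 10% fractions in the size study)
  recover substantially less.
* Inferred values are on the transformed scale; rank-based downstream
  analyses are safe, absolute-abundance interpretations are not.
* Sample-wise correlation is *not* evidence of inference quality (see the
  shuffle null); report feature-wise correlations.
* References whose taxonomy and function do not co-vary (non-significant
  RV) cannot support inference — the tool warns rather than refusing, since
  the RV test itself is subject to sampling noise.
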