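#' Simulate a paired taxonomic/functional dataset
#'
#' Generates a community with a known taxon-by-function structure so the
#' inference can be benchmarked without external data. A sparse
#' genome-content matrix assigns functions to taxa
#' (`Bernoulli(genome_density)` presence times a lognormal copy number);
#' per-sample taxon relative abundances are Dirichlet draws over a
#' heavy-tailed (lognormal) base composition; observed taxon counts are a
#' multinomial read draw at the given depth; and the true functional
#' profile of each sample is the genome-content-weighted sum of its taxon
#' abundances, optionally perturbed by multiplicative lognormal noise and
#' renormalised. Per-function coverage is the fraction of samples in which
#' the function receives support from at least one detected carrier taxon.
#'
#' The generator emulates the regime in which taxonomy and function co-vary
#' strongly (the stool-like case); `weak_covariance` draws the functional
#' table from an independent community, emulating references whose taxonomy
#' does not predict function (the nasal/skin failure mode).
#'
#' @param n_taxa,n_functions,n_samples community dimensions (defaults 150
#'   taxa, 60 functions, 80 samples).
#' @param genome_density probability a taxon carries a function (default
#'   0.15).
#' @param abundance_model only `"lognormal_dirichlet"` is implemented.
#' @param depth reads per sample for the count draw (default 20000).
#' @param noise_sd standard deviation of the lognormal noise on the true
#'   functional profiles (default 0.1; 0 gives exact linearity).
#' @param seed integer seed; the same seed and parameters reproduce the
#'   dataset bit for bit.
#' @param rank_ratio ratio of the geometric (Motomura) rank-abundance
#'   backbone of the base composition (default 0.75: the top taxon holds
#'   about a quarter of the community, effective diversity about 7 taxa —
#'   the dominance-skewed profile typical of OTU-level gut data). A
#'   deterministic backbone keeps the community's effective diversity
#'   stable across seeds; an unbounded lognormal occasionally collapses a
#'   draw onto a single taxon.
#' @param base_sdlog lognormal sd of the multiplicative jitter on the
#'   backbone (default 0.5).
#' @param theta Dirichlet concentration controlling sample-to-sample
#'   overdispersion (default 10, strongly overdispersed).
#' @param copy_sdlog lognormal sd of genome copy numbers (default 0.5; 0
#'   gives unit copy numbers).
#' @param weak_covariance if `TRUE`, functional profiles are generated from
#'   an independent redraw of the community rather than from `taxa_counts`'
#'   own abundances.
#' @return a `synthetic_dataset` with `genome_content` (taxa x functions),
#'   `taxa_counts`, `functional_true`, `coverage_true` (all
#'   [feature_table()]s or matrices as documented), `params` and `seed`.
#' @export
simulate_paired <- function(n_taxa = 150, n_functions = 60, n_samples = 80,
                            genome_density = 0.15,
                            abundance_model = "lognormal_dirichlet",
                            depth = 20000, noise_sd = 0.1, seed = 1,
                            rank_ratio = 0.75, base_sdlog = 0.5, theta = 10,
                            copy_sdlog = 0.5,
                            weak_covariance = FALSE) {
  stopifnot(n_taxa >= 2, n_functions >= 2, n_samples >= 2,
            genome_density > 0, genome_density <= 1, noise_sd >= 0)
  abundance_model <- match.arg(abundance_model, "lognormal_dirichlet")
  taxa <- sprintf("otu_%03d", seq_len(n_taxa))
  fns <- sprintf("fn_%03d", seq_len(n_functions))
  smp <- sprintf("s%03d", seq_len(n_samples))

  out <- with_seed(seed, {
    G <- matrix(stats::rbinom(n_taxa * n_functions, 1, genome_density) *
                  stats::rlnorm(n_taxa * n_functions, 0, copy_sdlog),
                n_taxa, n_functions, dimnames = list(taxa, fns))

    base <- rank_ratio^(seq_len(n_taxa) - 1) *
      stats::rlnorm(n_taxa, 0, base_sdlog)
    alpha <- base / sum(base) * theta
    draw_props <- function() {
      g <- matrix(stats::rgamma(n_taxa * n_samples, shape = alpha),
                  n_taxa, n_samples)
      sweep(g, 2, pmax(colSums(g), .Machine$double.xmin), "/")
    }
    props <- draw_props()
    counts <- vapply(seq_len(n_samples),
                     function(j) stats::rmultinom(1, depth, props[, j])[, 1],
                     numeric(n_taxa))
    dimnames(counts) <- list(taxa, smp)

    fprops <- if (weak_covariance) draw_props() else props
    Ftrue <- crossprod(G, fprops)                      # functions x samples
    if (noise_sd > 0) {
      Ftrue <- Ftrue * exp(matrix(stats::rnorm(n_functions * n_samples,
                                               0, noise_sd),
                                  n_functions, n_samples))
    }
    cs <- colSums(Ftrue)
    Ftrue <- sweep(Ftrue, 2, ifelse(cs > 0, cs, 1), "/")
    dimnames(Ftrue) <- list(fns, smp)

    present <- counts > 0
    coverage <- crossprod(G > 0, present) > 0           # functions x samples
    list(G = G, counts = counts, Ftrue = Ftrue,
         coverage = rowMeans(coverage))
  })

  params <- list(n_taxa = n_taxa, n_functions = n_functions,
                 n_samples = n_samples, genome_density = genome_density,
                 abundance_model = abundance_model, depth = depth,
                 noise_sd = noise_sd, rank_ratio = rank_ratio,
                 base_sdlog = base_sdlog, theta = theta,
                 copy_sdlog = copy_sdlog, weak_covariance = weak_covariance)

  structure(list(
    genome_content = out$G,
    taxa_counts = feature_table(out$counts, role = "taxonomic"),
    functional_true = feature_table(out$Ftrue, role = "functional"),
    coverage_true = feature_table(matrix(out$coverage, ncol = 1,
                                         dimnames = list(fns, "mean")),
                                  role = "coverage"),
    params = params, seed = seed),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d taxa x %d functions x %d samples ",
                     "(depth %d, noise_sd %g, seed %s)\n"),
              x$params$n_taxa, x$params$n_functions, x$params$n_samples,
              x$params$depth, x$params$noise_sd, format(x$seed)))
  invisible(x)
}

#' Split a synthetic dataset into reference and query sides
#'
#' Randomly partitions the samples: the reference side supplies the paired
#' functional (`R`) and taxonomic (`L`) tables, the query side supplies the
#' query taxonomic table (`Q_taxa`) and the held-out functional truth
#' (`F_truth`).
#'
#' @param d a [simulate_paired()] result.
#' @param fraction fraction of samples on the reference side (default 0.5).
#' @param seed integer seed for the partition.
#' @return list with elements `R`, `L`, `Q_taxa`, `F_truth` (all
#'   [feature_table()]s) and `reference_samples`, `query_samples`.
#' @export
split_reference_query <- function(d, fraction = 0.5, seed = 1) {
  stopifnot(inherits(d, "synthetic_dataset"))
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  samples <- d$taxa_counts$sample_ids
  n_ref <- round(fraction * length(samples))
  if (n_ref < 3 || length(samples) - n_ref < 3)
    stopf("a side of the split would have < 3 samples")
  ref <- with_seed(seed, sample(samples, n_ref))
  qry <- setdiff(samples, ref)
  ## drop taxa unobserved on the reference side (zero L rows)
  Lr <- subset_table(d$taxa_counts, samples = ref)
  Lr <- subset_table(Lr, features = which(rowSums(Lr$values) > 0))
  list(R = subset_table(d$functional_true, samples = ref),
       L = Lr,
       Q_taxa = subset_table(d$taxa_counts, samples = qry),
       F_truth = subset_table(d$functional_true, samples = qry),
       reference_samples = ref, query_samples = qry)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Writes `R.tsv`, `L.tsv`, `Q.tsv`, `truth.tsv` (from a
#' [split_reference_query()] split), `coverage.tsv` and `params.json`.
#'
#' @param d a [simulate_paired()] result.
#' @param dir output directory (created if needed).
#' @param fraction,split_seed split passed to [split_reference_query()].
#' @export
write_synthetic_dataset <- function(d, dir, fraction = 0.5, split_seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- split_reference_query(d, fraction, seed = split_seed)
  write_feature_table(sp$R, file.path(dir, "R.tsv"))
  write_feature_table(sp$L, file.path(dir, "L.tsv"))
  write_feature_table(sp$Q_taxa, file.path(dir, "Q.tsv"))
  write_feature_table(sp$F_truth, file.path(dir, "truth.tsv"))
  write_feature_table(d$coverage_true, file.path(dir, "coverage.tsv"))
  jsonlite::write_json(c(d$params, list(seed = d$seed,
                                        split_fraction = fraction,
                                        split_seed = split_seed)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
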