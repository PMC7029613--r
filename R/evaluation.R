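#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their average rank).
#' Pairs with missing values are removed first; at least 3 complete pairs
#' are required. A constant vector has no rank ordering, so the correlation
#' is reported as `NA`, never coerced to 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation in \[-1, 1\], or `NA` for constant input.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need >= 3 complete pairs, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

## All permutations of 1..n as an n! x n matrix (n small).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman correlation with a p-value
#'
#' Two-sided test of zero rank correlation: a t approximation for
#' n >= 10 complete pairs and a full-enumeration exact permutation test
#' below that (the exact null handles ties without special-casing).
#'
#' @inheritParams spearman
#' @return list with `rho` and `p_value` (both `NA` for constant input).
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rho <- spearman(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_))
  if (n >= 10) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  } else {
    rx <- rank(x); ry <- rank(y)
    perms <- all_perms(n)
    rho_null <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(p, 1))
}

match_ids <- function(a, b, what) {
  shared <- intersect(a, b)
  if (length(shared) == 0) stopf("no shared %s", what)
  shared
}

inferred_values <- function(x) {
  if (inherits(x, "inferred_table")) x$values else x$values
}

#' Per-sample correlation of inferred vs observed profiles
#'
#' For every sample present in both tables, the Spearman correlation across
#' the shared functions between the inferred column and the observed column.
#' High values reflect how well each sample's functional profile is
#' recovered, but note that functional redundancy (abundant functions shared
#' across taxa) inflates this direction regardless of inference quality.
#'
#' @param inferred an `inferred_table` (or [feature_table()]).
#' @param observed a [feature_table()] of observed functional profiles.
#' @return named vector of correlations, one per shared sample.
#' @export
sample_correlations <- function(inferred, observed) {
  iv <- inferred_values(inferred)
  ov <- observed$values
  fns <- match_ids(rownames(iv), rownames(ov), "functions")
  if (length(fns) < 3) stopf("need >= 3 shared functions, got %d", length(fns))
  smp <- match_ids(colnames(iv), colnames(ov), "samples")
  vapply(smp, function(s) spearman(iv[fns, s], ov[fns, s]), numeric(1))
}

#' Per-function correlation of inferred vs observed profiles
#'
#' The feature direction of [sample_correlations()]: for every function
#' present in both tables, the Spearman correlation across the shared
#' samples. This is the discriminating direction of the validation — a
#' shuffled (non-covarying) reference drives it to zero while the sample
#' direction can stay high.
#'
#' @inheritParams sample_correlations
#' @return named vector of correlations, one per shared function.
#' @export
feature_correlations <- function(inferred, observed) {
  iv <- inferred_values(inferred)
  ov <- observed$values
  fns <- match_ids(rownames(iv), rownames(ov), "functions")
  smp <- match_ids(colnames(iv), colnames(ov), "samples")
  if (length(smp) < 3) stopf("need >= 3 shared samples, got %d", length(smp))
  vapply(fns, function(f) spearman(iv[f, smp], ov[f, smp]), numeric(1))
}

#' Validation configuration
#'
#' @param reference_fraction fraction of samples used as reference in each
#'   split (default 0.5, an equal reference/test split).
#' @param n_iterations number of bootstrap iterations (default 100).
#' @param transform,scale passed to [ipco_infer()].
#' @param seed integer seed driving all splits (and shuffles).
#' @param shuffle_reference if `TRUE`, the sample correspondence between the
#'   reference functional and taxonomic tables is permuted at each
#'   iteration, destroying their pairing — the negative control.
#' @return a `validation_config` list.
#' @export
validation_config <- function(reference_fraction = 0.5, n_iterations = 100,
                              transform = "hellinger", scale = FALSE,
                              seed = 1, shuffle_reference = FALSE) {
  if (reference_fraction <= 0 || reference_fraction >= 1)
    stopf("reference_fraction must be in (0, 1)")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  structure(list(reference_fraction = reference_fraction,
                 n_iterations = n_iterations, transform = transform,
                 scale = scale, seed = seed,
                 shuffle_reference = shuffle_reference),
            class = "validation_config")
}

#' Bootstrap validation of the inference
#'
#' At each iteration a random `reference_fraction` of the samples is drawn
#' without replacement as the reference side (restricting the paired
#' functional/taxonomic tables to it) and the remainder becomes the query;
#' the query samples' observed functional profiles are held out and the
#' inferred profiles are scored against them with per-sample and
#' per-function Spearman correlations. Averages are taken across
#' iterations. With `shuffle_reference` the functional/taxonomic pairing of
#' the reference is destroyed before inference, giving the null behaviour.
#'
#' @param R reference/full functional [feature_table()] (functions x
#'   samples).
#' @param L paired taxonomic [feature_table()] (taxa x samples, same
#'   samples as `R`).
#' @param Q_taxa_full taxonomic table supplying query-side profiles (same
#'   sample universe).
#' @param F_observed_full observed functional table scored against (paired
#'   with `Q_taxa_full`).
#' @param cfg a [validation_config()].
#' @return a `validation_result` with per-iteration matrices
#'   (`per_iteration_sample_rho`: iterations x samples, `NA` where a sample
#'   was not in that iteration's query; `per_iteration_feature_rho`:
#'   iterations x shared functions), their across-iteration means
#'   (`mean_sample_rho`, `mean_feature_rho`), quartile summaries and the
#'   config echo.
#' @export
bootstrap_validate <- function(R, L, Q_taxa_full, F_observed_full, cfg) {
  stopifnot(inherits(cfg, "validation_config"))
  samples <- L$sample_ids
  if (!setequal(samples, R$sample_ids))
    stopf("R and L must be paired on the same samples")
  if (!setequal(samples, Q_taxa_full$sample_ids) ||
      !setequal(samples, F_observed_full$sample_ids))
    stopf("Q_taxa_full and F_observed_full must cover the same samples as L")
  n <- length(samples)
  n_ref <- round(cfg$reference_fraction * n)
  if (n_ref < 3 || n - n_ref < 3)
    stopf("split %d/%d leaves a side with < 3 samples", n_ref, n - n_ref)

  fns <- intersect(R$feature_ids, F_observed_full$feature_ids)
  if (length(fns) < 3) stopf("fewer than 3 shared functions")

  srho <- matrix(NA_real_, cfg$n_iterations, n,
                 dimnames = list(NULL, samples))
  frho <- matrix(NA_real_, cfg$n_iterations, length(fns),
                 dimnames = list(NULL, fns))

  for (i in seq_len(cfg$n_iterations)) {
    it <- with_seed(derive_seed(cfg$seed, i), {
      ref <- sample(samples, n_ref)
      shuffled_ref <- if (cfg$shuffle_reference) sample(ref) else ref
      list(ref = ref, shuffled_ref = shuffled_ref)
    })
    ref <- it$ref
    qry <- setdiff(samples, ref)
    Rr <- subset_table(R, samples = it$shuffled_ref)
    ## relabel so the (shuffled) functional columns pair positionally with L
    colnames(Rr$values) <- ref
    Rr$sample_ids <- ref
    Lr <- subset_table(L, samples = ref)
    ## drop taxa absent from the reference split (zero L rows)
    Lr <- subset_table(Lr, features = which(rowSums(Lr$values) > 0))
    inf <- ipco_infer(Rr, Lr, subset_table(Q_taxa_full, samples = qry),
                      transform = cfg$transform, scale = cfg$scale)
    obs <- subset_table(F_observed_full, samples = qry)
    sr <- sample_correlations(inf, obs)
    fr <- feature_correlations(inf, obs)
    srho[i, names(sr)] <- sr
    frho[i, names(fr)] <- fr
  }

  mean_sample_rho <- colMeans(srho, na.rm = TRUE)
  mean_feature_rho <- colMeans(frho, na.rm = TRUE)
  structure(list(per_iteration_sample_rho = srho,
                 per_iteration_feature_rho = frho,
                 mean_sample_rho = mean_sample_rho,
                 mean_feature_rho = mean_feature_rho,
                 sample_summary = stats::quantile(mean_sample_rho, na.rm = TRUE),
                 feature_summary = stats::quantile(mean_feature_rho, na.rm = TRUE),
                 config = cfg),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("validation_result: %d iterations, reference fraction ",
                     "%.2f%s\n"),
              x$config$n_iterations, x$config$reference_fraction,
              if (x$config$shuffle_reference) " (shuffled reference)" else ""))
  cat("  mean sample rho quartiles: ",
      paste(sprintf("%.3f", x$sample_summary), collapse = " "), "\n")
  cat("  mean feature rho quartiles:",
      paste(sprintf("%.3f", x$feature_summary), collapse = " "), "\n")
  invisible(x)
}

#' Bin functions by mean pathway coverage
#'
#' Pathway coverage (a 0-1 per-sample fraction of a pathway's reactions
#' detected) grades inference quality: low-coverage pathways are poorly
#' inferred. Two binning schemes are provided. `fixed` uses absolute cuts on
#' the per-function mean coverage (defaults 0.01 and 0.1, the KEGG
#' convention: below `low_cut` low, above `high_cut` high, medium between).
#' `quantile` places the cuts at quantiles of the mean-coverage distribution
#' (defaults the 1st quartile and the median, the MetaCyc convention), with
#' bins `[0, q_low)` low, `[q_low, q_high)` medium, `[q_high, Inf)` high.
#'
#' @param coverage a coverage [feature_table()] with values in \[0, 1\].
#' @param scheme `"fixed"` or `"quantile"`.
#' @param low_cut,high_cut absolute cuts for `fixed`.
#' @param q_low,q_high quantile positions for `quantile`.
#' @return a `coverage_bins` object: `thresholds`, `assignment` (named
#'   factor with levels low/medium/high), `counts`, `mean_coverage`.
#' @export
bin_by_coverage <- function(coverage, scheme = c("fixed", "quantile"),
                            low_cut = 0.01, high_cut = 0.1,
                            q_low = 0.25, q_high = 0.5) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(coverage, "feature_table"))
  if (nrow(coverage$values) == 0) stopf("empty coverage table")
  if (any(coverage$values < 0 | coverage$values > 1))
    stopf("coverage values must lie in [0, 1]")
  means <- rowMeans(coverage$values)
  if (scheme == "fixed") {
    if (low_cut >= high_cut) stopf("low_cut must be < high_cut")
    cuts <- c(low = low_cut, high = high_cut)
    bin <- ifelse(means < low_cut, "low",
                  ifelse(means > high_cut, "high", "medium"))
  } else {
    cuts <- stats::quantile(means, c(q_low, q_high), names = FALSE)
    names(cuts) <- c("low", "high")
    bin <- ifelse(means < cuts["low"], "low",
                  ifelse(means >= cuts["high"], "high", "medium"))
  }
  assignment <- factor(bin, levels = c("low", "medium", "high"))
  names(assignment) <- names(means)
  structure(list(thresholds = cuts, scheme = scheme,
                 assignment = assignment, counts = table(assignment),
                 mean_coverage = means),
            class = "coverage_bins")
}

#' @export
print.coverage_bins <- function(x, ...) {
  cat(sprintf("coverage_bins (%s, cuts %.4g / %.4g): low %d, medium %d, high %d\n",
              x$scheme, x$thresholds[1], x$thresholds[2],
              x$counts["low"], x$counts["medium"], x$counts["high"]))
  invisible(x)
}

#' Correlate functional profiles with metabolite measurements
#'
#' Correlates every function with every metabolite across shared samples:
#' metabolite levels are log10-transformed after adding a pseudocount, all
#' pairwise Spearman correlations and p-values are computed, and p-values
#' are Benjamini-Hochberg adjusted across the full function x metabolite
#' family.
#'
#' @param func a functional [feature_table()] or `inferred_table`.
#' @param metabolites a metabolite [feature_table()].
#' @param pseudocount added to metabolite levels before log10 (default
#'   `1e-5`).
#' @param alpha significance level used for the `significant` flag on the
#'   adjusted p-values (default 0.05).
#' @return a data frame with columns `function_id`, `metabolite_id`, `rho`,
#'   `p_value`, `p_adjusted`, `direction` (sign of rho) and `significant`.
#' @export
associate_with_metadata <- function(func, metabolites, pseudocount = 1e-5,
                                    alpha = 0.05) {
  fv <- inferred_values(func)
  mv <- metabolites$values
  smp <- intersect(colnames(fv), colnames(mv))
  if (length(smp) < 3) stopf("need >= 3 shared samples, got %d", length(smp))
  fv <- fv[, smp, drop = FALSE]
  mv <- log10(mv[, smp, drop = FALSE] + pseudocount)

  grid <- expand.grid(function_id = rownames(fv), metabolite_id = rownames(mv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(f, m) {
    st <- spearman_test(fv[f, ], mv[m, ])
    c(st$rho, st$p_value)
  }, grid$function_id, grid$metabolite_id)
  grid$rho <- res[1, ]
  grid$p_value <- res[2, ]
  grid$p_adjusted <- stats::p.adjust(grid$p_value, method = "BH")
  grid$direction <- sign(grid$rho)
  grid$significant <- !is.na(grid$p_adjusted) & grid$p_adjusted <= alpha
  grid
}
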