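#' Transform an abundance table
#'
#' Applies one of the community-data transformations used upstream of the
#' inference: Hellinger (square root of per-sample relative abundance, the
#' default of the inference pipeline), proportion (per-sample relative
#' abundance), z-scaling (per-feature standardisation across samples),
#' log10 of proportions or of rarefied counts with a pseudocount, and the
#' centred log-ratio (clr). Samples are columns throughout; Hellinger,
#' proportion, clr and the log10 variants are column-local, z-scaling is
#' row-local.
#'
#' `zscale` uses the population (n denominator) standard deviation and maps
#' constant features to all-zeros, which keeps downstream weighted centering
#' well-defined.
#'
#' @param t a [feature_table()].
#' @param method one of `"hellinger"`, `"proportion"`, `"zscale"`,
#'   `"log10_proportion"`, `"log10_rarefied"`, `"clr"`, `"none"`.
#' @param pseudocount nonnegative value added before logs (default `1e-5`,
#'   also used for clr, for which no separate convention is fixed).
#' @param rarefaction_depth required for `log10_rarefied`: depth passed to
#'   [rarefy()].
#' @param seed seed for the rarefaction draw (only `log10_rarefied`).
#' @return a `transformed_table`: the feature table plus `transform` and
#'   `pseudocount` fields.
#' @examples
#' ft <- feature_table(matrix(c(1, 4, 4), 3, 1,
#'   dimnames = list(c("a", "b", "c"), "s1")))
#' transform_table(ft, "hellinger")$values  # 1/3, 2/3, 2/3
#' @export
transform_table <- function(t,
                            method = c("hellinger", "proportion", "zscale",
                                       "log10_proportion", "log10_rarefied",
                                       "clr", "none"),
                            pseudocount = 1e-5,
                            rarefaction_depth = NULL,
                            seed = NULL) {
  stopifnot(inherits(t, "feature_table"))
  method <- match.arg(method)
  v <- t$values

  colsum_or_stop <- function(v) {
    cs <- colSums(v)
    if (any(cs <= 0))
      stopf("zero-sum sample column(s): %s",
            paste(colnames(v)[cs <= 0], collapse = ", "))
    cs
  }

  out <- switch(method,
    none = v,
    proportion = sweep(v, 2, colsum_or_stop(v), "/"),
    hellinger = sqrt(sweep(v, 2, colsum_or_stop(v), "/")),
    zscale = {
      mu <- rowMeans(v)
      sdev <- sqrt(rowMeans((v - mu)^2))  # population sd
      z <- (v - mu) / ifelse(sdev > 0, sdev, 1)
      z[sdev == 0, ] <- 0
      z
    },
    log10_proportion = {
      if (pseudocount <= 0) stopf("pseudocount must be > 0 for log10 transforms")
      log10(sweep(v, 2, colsum_or_stop(v), "/") + pseudocount)
    },
    log10_rarefied = {
      if (pseudocount <= 0) stopf("pseudocount must be > 0 for log10 transforms")
      if (is.null(rarefaction_depth))
        stopf("log10_rarefied requires rarefaction_depth")
      log10(rarefy(t, rarefaction_depth, seed = seed)$values + pseudocount)
    },
    clr = {
      if (pseudocount <= 0) stopf("pseudocount must be > 0 for clr")
      lx <- log(v + pseudocount)
      sweep(lx, 2, colMeans(lx), "-")
    })

  structure(list(values = out, feature_ids = t$feature_ids,
                 sample_ids = t$sample_ids, role = t$role,
                 transform = method, pseudocount = pseudocount),
            class = c("transformed_table", "feature_table"))
}

#' @export
print.transformed_table <- function(x, ...) {
  cat(sprintf("transformed_table (%s, %s): %d features x %d samples\n",
              x$role, x$transform, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Rarefy a count table
#'
#' Subsamples every sample column without replacement to a common depth
#' (multivariate hypergeometric draw, via [vegan::rrarefy()]), so that all
#' column sums equal `depth`. Reproducible under a fixed seed.
#'
#' @param t a [feature_table()] of integer counts.
#' @param depth target depth; must not exceed any column sum.
#' @param seed integer seed for the draw.
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(t, depth, seed = NULL) {
  stopifnot(inherits(t, "feature_table"))
  if (!is_integerish(t$values)) stopf("rarefaction requires integer counts")
  cs <- colSums(t$values)
  if (any(cs < depth))
    stopf("depth %d exceeds the total count of sample(s): %s", depth,
          paste(colnames(t$values)[cs < depth], collapse = ", "))
  ## vegan heuristically warns when a table has no singleton counts; the
  ## precondition (integer counts, depth <= column sums) is checked above.
  r <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(t(round(t$values)), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  feature_table(t(r), feature_ids = t$feature_ids, sample_ids = t$sample_ids,
                role = t$role)
}
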