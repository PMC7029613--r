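#' Align a reference functional / reference taxonomic / query triplet
#'
#' The inference needs three tables linked by identifiers: the reference
#' functional table `R` and reference taxonomic table `L` share samples
#' (paired), and `L` and the query taxonomic table `Q` share taxa
#' identifiers, `L` acting as the mediator. This step reorders `R`'s samples
#' to `L`'s order, restricts taxa to the L/Q intersection, and iteratively
#' drops taxa or reference samples whose `L` margins become all-zero after
#' the intersection (correspondence analysis requires strictly positive
#' margins). Dropped identifiers are reported.
#'
#' If the taxa shared with the reference carry less than
#' `min_shared_taxa_fraction` of the query's total abundance, the reference
#' is judged unsuitable and an error is raised.
#'
#' @param R reference functional [feature_table()] (functions x reference
#'   samples).
#' @param L reference taxonomic [feature_table()] (taxa x reference samples).
#' @param Q query taxonomic [feature_table()] (taxa x query samples).
#' @param min_shared_taxa_fraction minimum fraction of the query's total
#'   abundance that must sit on taxa shared with `L` (default 0.5).
#' @return an `aligned_triplet` with aligned tables `r`, `l`, `q`,
#'   `dropped_taxa_query` (query taxa absent from the reference),
#'   `dropped_taxa_reference` (taxa dropped for zero reference margins),
#'   `dropped_samples` (reference samples dropped for zero margins),
#'   `taxa_ids` (shared ordered taxa) and `query_abundance_retained`.
#' @export
align_triplet <- function(R, L, Q, min_shared_taxa_fraction = 0.5) {
  stopifnot(inherits(R, "feature_table"), inherits(L, "feature_table"),
            inherits(Q, "feature_table"))
  if (!setequal(R$sample_ids, L$sample_ids)) {
    only_r <- setdiff(R$sample_ids, L$sample_ids)
    only_l <- setdiff(L$sample_ids, R$sample_ids)
    stopf("R and L must be paired on the same samples (only in R: %s; only in L: %s)",
          paste(only_r, collapse = ", "), paste(only_l, collapse = ", "))
  }
  R <- subset_table(R, samples = L$sample_ids)

  shared <- intersect(L$feature_ids, Q$feature_ids)
  if (length(shared) < 2)
    stopf("L and Q share %d taxa; at least 2 are required", length(shared))
  dropped_q <- setdiff(Q$feature_ids, L$feature_ids)
  q_total <- sum(Q$values)
  retained <- if (q_total > 0) sum(Q$values[shared, , drop = FALSE]) / q_total else 0
  if (retained < min_shared_taxa_fraction)
    stopf(paste0("only %.1f%% of the query abundance is on taxa shared with ",
                 "the reference (< %.1f%%); use a reference that covers the ",
                 "queried environment"),
          100 * retained, 100 * min_shared_taxa_fraction)

  lv <- L$values[shared, , drop = FALSE]
  dropped_ref_taxa <- character(0)
  dropped_samples <- character(0)
  repeat {
    zero_taxa <- rowSums(lv) == 0
    if (any(zero_taxa)) {
      dropped_ref_taxa <- c(dropped_ref_taxa, rownames(lv)[zero_taxa])
      lv <- lv[!zero_taxa, , drop = FALSE]
    }
    zero_samp <- colSums(lv) == 0
    if (any(zero_samp)) {
      dropped_samples <- c(dropped_samples, colnames(lv)[zero_samp])
      lv <- lv[, !zero_samp, drop = FALSE]
    }
    if (!any(zero_taxa) && !any(zero_samp)) break
  }
  if (nrow(lv) < 2 || ncol(lv) < 2)
    stopf("fewer than 2 taxa or samples remain in L after alignment")

  taxa <- rownames(lv)
  out <- list(
    r = subset_table(R, samples = colnames(lv)),
    l = feature_table(lv, role = L$role),
    q = subset_table(Q, features = taxa),
    dropped_taxa_query = dropped_q,
    dropped_taxa_reference = dropped_ref_taxa,
    dropped_samples = dropped_samples,
    taxa_ids = taxa,
    query_abundance_retained = retained)
  class(out) <- "aligned_triplet"
  out
}

#' @export
print.aligned_triplet <- function(x, ...) {
  cat(sprintf(paste0("aligned_triplet: %d functions, %d taxa, %d reference ",
                     "samples, %d query samples\n",
                     "  query abundance retained: %.1f%%; dropped: %d query ",
                     "taxa, %d reference taxa, %d reference samples\n"),
              nrow(x$r$values), length(x$taxa_ids), ncol(x$l$values),
              ncol(x$q$values), 100 * x$query_abundance_retained,
              length(x$dropped_taxa_query), length(x$dropped_taxa_reference),
              length(x$dropped_samples)))
  invisible(x)
}

#' Fourth-corner (R'LQ) cross product
#'
#' The association matrix between functions and query samples mediated by
#' the reference taxonomic table:
#' `product[f, s] = sum_i sum_t rc$xstar[i, f] * lw[i] * lstar[i, t] * cw[t] * qc$xstar[t, s]`,
#' evaluated as chained matrix products.
#'
#' @param rc a [weighted_center()] result over reference samples x functions
#'   (weights `ca$lw`).
#' @param ca a [correspondence_analysis()] decomposition of the reference
#'   taxonomic table.
#' @param qc a [weighted_center()] result over taxa x query samples
#'   (weights `ca$cw`).
#' @return a functions x query samples matrix.
#' @export
rlq_product <- function(rc, ca, qc) {
  stopifnot(inherits(rc, "centered_table"), inherits(ca, "ca_decomposition"),
            inherits(qc, "centered_table"))
  if (nrow(rc$xstar) != length(ca$lw))
    stopf("rc has %d rows but ca has %d sample weights",
          nrow(rc$xstar), length(ca$lw))
  if (nrow(qc$xstar) != length(ca$cw))
    stopf("qc has %d rows but ca has %d taxa weights",
          nrow(qc$xstar), length(ca$cw))
  crossprod(rc$xstar * ca$lw, ca$lstar %*% (ca$cw * qc$xstar))
}

#' Infer functional profiles for query 16S samples
#'
#' The full inference pipeline: align the triplet, transform all three
#' tables (Hellinger by default), decompose the reference taxonomic table by
#' correspondence analysis, center the reference functional table with the
#' CA sample weights (recording the weighted average functional abundance
#' `waR`), center the query taxonomic table with the CA taxa weights, form
#' the fourth-corner [rlq_product()], and re-standardise by adding `waR`
#' back to each function's row. Inferred values are reported on the
#' transformed scale of the reference functional table; no inverse transform
#' is attempted (it is not defined for Hellinger residuals). Values may be
#' small negatives; see [filter_low_inferred()].
#'
#' The correspondence-analysis step requires a nonnegative transformed `L`,
#' so transforms producing negative values (`clr`, `zscale`, the log10
#' variants) are rejected.
#'
#' @inheritParams align_triplet
#' @param transform transformation applied to all three tables; see
#'   [transform_table()]. Default `"hellinger"`.
#' @param scale whether the weighted centering also divides by the weighted
#'   standard deviation (default `FALSE`; the re-standardisation adds only
#'   the weighted mean back).
#' @param pseudocount passed to [transform_table()].
#' @return an `inferred_table` with `values` (functions x query samples),
#'   `raw_product` (the R'LQ product before re-standardisation), `waR`,
#'   `function_ids`, `query_sample_ids`, `transform`, `scale_flag` and the
#'   `alignment` report.
#' @examples
#' d <- simulate_paired(n_taxa = 40, n_functions = 12, n_samples = 24,
#'                      seed = 1)
#' sp <- split_reference_query(d, 0.5, seed = 2)
#' inf <- ipco_infer(sp$R, sp$L, sp$Q_taxa)
#' inf
#' @export
ipco_infer <- function(R, L, Q, transform = "hellinger", scale = FALSE,
                       min_shared_taxa_fraction = 0.5, pseudocount = 1e-5) {
  al <- align_triplet(R, L, Q, min_shared_taxa_fraction)
  rt <- transform_table(al$r, transform, pseudocount = pseudocount)
  lt <- transform_table(al$l, transform, pseudocount = pseudocount)
  qt <- transform_table(al$q, transform, pseudocount = pseudocount)
  if (any(lt$values < 0))
    stopf(paste0("transform '%s' yields negative values in L; the ",
                 "correspondence-analysis step requires a nonnegative table ",
                 "(use 'hellinger' or 'proportion')"), transform)

  ca <- correspondence_analysis(lt)              # samples x taxa
  rc <- weighted_center(t(rt$values), ca$lw, scale = scale)
  waR <- rc$weighted_means                       # one per function
  qc <- weighted_center(qt$values, ca$cw, scale = scale)

  prod <- rlq_product(rc, ca, qc)
  values <- prod + waR                           # waR recycled down columns

  structure(list(values = values, raw_product = prod, waR = waR,
                 function_ids = rownames(values),
                 query_sample_ids = colnames(values),
                 transform = transform, scale_flag = scale,
                 alignment = al),
            class = "inferred_table")
}

#' @export
print.inferred_table <- function(x, ...) {
  cat(sprintf(paste0("inferred_table: %d functions x %d query samples ",
                     "(transform %s, scale %s)\n"),
              nrow(x$values), ncol(x$values), x$transform, x$scale_flag))
  invisible(x)
}

#' Filter low-abundance inferred functions
#'
#' The fourth-corner algebra assigns every function a small non-zero
#' inferred abundance even where there is no real support. Functions whose
#' mean inferred abundance across query samples falls below a user-chosen
#' quantile of those means are removed (linear-interpolation sample
#' quantile; retention is mean >= threshold).
#'
#' @param t an `inferred_table`.
#' @param quantile quantile of the per-function mean abundances in \[0, 1\].
#' @return the filtered `inferred_table`.
#' @export
filter_low_inferred <- function(t, quantile) {
  stopifnot(inherits(t, "inferred_table"))
  if (quantile < 0 || quantile > 1) stopf("quantile must be in [0, 1]")
  means <- rowMeans(t$values)
  thr <- stats::quantile(means, quantile, names = FALSE, type = 7)
  keep <- means >= thr
  if (!any(keep)) stopf("no functions retained at quantile %g", quantile)
  t$values <- t$values[keep, , drop = FALSE]
  t$raw_product <- t$raw_product[keep, , drop = FALSE]
  t$waR <- t$waR[keep]
  t$function_ids <- t$function_ids[keep]
  t
}

#' Write an inferred table and its side-car reports
#'
#' Writes the inferred functions x query samples TSV, plus a side-car TSV
#' holding `waR` and the dropped-identifier report from alignment.
#'
#' @param t an `inferred_table`.
#' @param path output TSV path; the side-car is written next to it with
#'   suffix `.waR.tsv`.
#' @export
write_inferred_table <- function(t, path) {
  ft <- feature_table(t$values, t$function_ids, t$query_sample_ids,
                      role = "metabolite")  # values may be negative
  ft$values <- t$values
  write_feature_table(ft, path)
  side <- sub("(\\.tsv)?$", ".waR.tsv", path)
  al <- t$alignment
  lines <- c("function_id\twaR",
             sprintf("%s\t%.17g", t$function_ids, t$waR),
             "# dropped_taxa_query\t" %+% paste(al$dropped_taxa_query, collapse = ","),
             "# dropped_taxa_reference\t" %+% paste(al$dropped_taxa_reference, collapse = ","),
             "# dropped_samples\t" %+% paste(al$dropped_samples, collapse = ","))
  writeLines(lines, side)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)
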