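#' Correspondence analysis decomposition of a nonnegative table
#'
#' Computes the chi-square residual table and the row/column weights of
#' correspondence analysis, the quantities the fourth-corner product needs
#' from the reference taxonomic table: with `P = L / sum(L)`, the sample
#' (row) weights are the row sums of `P`, the taxa (column) weights are the
#' column sums, and the residual table is `P[i,t] / (lw[i] * cw[t]) - 1`.
#' No eigendecomposition is performed; the inference uses only weights and
#' residuals.
#'
#' @param L a [feature_table()]/`transformed_table` in the package's
#'   canonical orientation (taxa in rows, samples in columns; transposed
#'   internally), or a plain matrix already oriented samples x taxa.
#' @return a `ca_decomposition` with elements `lstar` (samples x taxa
#'   residual matrix), `lw` (sample weights, sum 1), `cw` (taxa weights,
#'   sum 1) and `grand_total`.
#' @examples
#' correspondence_analysis(matrix(c(2, 0, 0, 2), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2"))))
#' @export
correspondence_analysis <- function(L) {
  m <- if (inherits(L, "feature_table")) t(L$values) else as.matrix(L)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stopf("correspondence analysis requires nonnegative entries (found %g at [%d, %d])",
          m[bad[1], bad[2]], bad[1], bad[2])
  }
  gt <- sum(m)
  if (gt <= 0) stopf("table grand total must be positive")
  P <- m / gt
  lw <- rowSums(P)
  cw <- colSums(P)
  if (any(lw == 0))
    stopf("all-zero sample row(s): %s",
          paste(rownames(m)[lw == 0], collapse = ", "))
  if (any(cw == 0))
    stopf("all-zero taxa column(s): %s",
          paste(colnames(m)[cw == 0], collapse = ", "))
  lstar <- P / outer(lw, cw) - 1
  structure(list(lstar = lstar, lw = lw, cw = cw, grand_total = gt),
            class = "ca_decomposition")
}

#' @export
print.ca_decomposition <- function(x, ...) {
  cat(sprintf("ca_decomposition: %d samples x %d taxa (grand total %g)\n",
              nrow(x$lstar), ncol(x$lstar), x$grand_total))
  invisible(x)
}

#' Weighted-mean centering of a matrix
#'
#' Centers every column of `X` to zero weighted mean, with weights on the
#' rows (normalised internally). This is the "PCA weighted by" step of the
#' inference: applied to the reference functional table (rows = reference
#' samples, weights = CA sample weights) it yields the weighted average
#' functional abundance `waR` that is later added back to the fourth-corner
#' product; applied to the query taxonomic table (rows = taxa, weights = CA
#' taxa weights) it centers the query profiles.
#'
#' @param X numeric matrix (rows x columns).
#' @param row_weights positive weights, one per row; any positive scale.
#' @param scale if `TRUE`, also divide each column by its weighted
#'   (population) standard deviation; constant columns are left as zeros
#'   with an sd recorded as 0. The inference path uses `scale = FALSE`:
#'   the re-standardisation that defines the inferred profiles adds only
#'   the weighted mean back, with no variance term.
#' @return a `centered_table` with `xstar`, `weighted_means`,
#'   `weights_used` (as supplied), `scaled` and `weighted_sds`.
#' @export
weighted_center <- function(X, row_weights, scale = FALSE) {
  X <- as.matrix(X)
  if (length(row_weights) != nrow(X))
    stopf("row_weights length %d does not match %d rows",
          length(row_weights), nrow(X))
  if (any(row_weights <= 0) || anyNA(row_weights))
    stopf("row weights must be positive")
  w <- row_weights / sum(row_weights)
  mu <- colSums(X * w)
  xstar <- sweep(X, 2, mu, "-")
  sds <- rep(NA_real_, ncol(X))
  if (scale) {
    sds <- sqrt(colSums(xstar^2 * w))
    nz <- sds > 0
    xstar[, nz] <- sweep(xstar[, nz, drop = FALSE], 2, sds[nz], "/")
    sds[!nz] <- 0
  }
  structure(list(xstar = xstar, weighted_means = mu,
                 weights_used = row_weights, scaled = scale,
                 weighted_sds = sds),
            class = "centered_table")
}

#' RV coefficient and permutation test of co-inertia
#'
#' Measures the global concordance between two multivariate tables sharing
#' the same samples, used to qualify a paired taxonomic/functional reference
#' before inference: a reference whose taxonomy does not co-vary with its
#' functions cannot support functional inference. Both tables are centered
#' with the supplied row weights; with `D = diag(w)`,
#' `RV = ||Xc' D Yc||_F^2 / (||Xc' D Xc||_F * ||Yc' D Yc||_F)`, a matrix
#' correlation in \[0, 1\]. Significance is assessed by permuting whole
#' rows (samples) of `Y`, with the (k+1)/(n+1) p-value estimator, so the
#' p-value is never 0.
#'
#' @param X,Y matrices oriented samples x features, or
#'   [feature_table()]/`transformed_table` objects (canonical features x
#'   samples orientation, transposed and matched on shared sample ids).
#' @param row_weights positive sample weights (default uniform).
#' @param n_permutations number of row permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return an `rv_test` with `rv`, `p_value`, `n_permutations`, `seed` and
#'   `observed_coinertia` (the total squared co-covariance
#'   `||Xc' D Yc||_F^2`).
#' @export
coinertia_rv <- function(X, Y, row_weights = NULL, n_permutations = 999,
                         seed = NULL) {
  to_sample_rows <- function(a) if (inherits(a, "feature_table")) t(a$values)
                                else as.matrix(a)
  Xm <- to_sample_rows(X)
  Ym <- to_sample_rows(Y)
  if (!is.null(rownames(Xm)) && !is.null(rownames(Ym))) {
    shared <- intersect(rownames(Xm), rownames(Ym))
    if (length(shared) < 3) stopf("fewer than 3 shared samples")
    Xm <- Xm[shared, , drop = FALSE]
    Ym <- Ym[shared, , drop = FALSE]
  }
  n <- nrow(Xm)
  if (n != nrow(Ym)) stopf("tables must share the same samples (rows)")
  if (n < 3) stopf("fewer than 3 shared samples")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (is.null(row_weights)) row_weights <- rep(1, n)
  if (length(row_weights) != n || any(row_weights <= 0))
    stopf("row_weights must be positive and of length %d", n)
  w <- row_weights / sum(row_weights)

  Xc <- sweep(Xm, 2, colSums(Xm * w), "-")
  Yc <- sweep(Ym, 2, colSums(Ym * w), "-")
  Xw <- Xc * w  # rows pre-scaled by weights: crossprod(Xw, Yc) = Xc' D Yc
  covv2 <- function(Yc) sum(crossprod(Xw, Yc)^2)
  nx <- sum(crossprod(Xw, Xc)^2)
  Yw <- Yc * w
  ny <- sum(crossprod(Yw, Yc)^2)
  if (nx <= 0 || ny <= 0) stopf("a table has zero weighted variance")
  obs_co <- covv2(Yc)
  rv <- obs_co / sqrt(nx * ny)

  ## Null: permute whole rows (samples) of Y, re-center under the weights
  ## (the weights stay with the row positions), recompute RV. With uniform
  ## weights centering and ||Yc' D Yc|| are permutation-invariant, so only
  ## the cross term needs recomputing.
  uniform_w <- diff(range(w)) < 1e-12
  perm_rv <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      p <- sample.int(n)
      if (uniform_w) {
        sum(crossprod(Xw, Yc[p, , drop = FALSE])^2) / sqrt(nx * ny)
      } else {
        Yp <- Ym[p, , drop = FALSE]
        Ypc <- sweep(Yp, 2, colSums(Yp * w), "-")
        sum(crossprod(Xw, Ypc)^2) /
          sqrt(nx * sum(crossprod(Ypc * w, Ypc)^2))
      }
    }, numeric(1))
  })
  p_value <- (sum(perm_rv >= rv) + 1) / (n_permutations + 1)

  structure(list(rv = rv, p_value = p_value,
                 n_permutations = n_permutations,
                 seed = seed, observed_coinertia = obs_co),
            class = "rv_test")
}

#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf("RV = %.4f, p = %.4g (%d permutations)\n",
              x$rv, x$p_value, x$n_permutations))
  invisible(x)
}

#' Write an RV test result to a one-row TSV
#' @param x an `rv_test`.
#' @param path output path.
#' @export
write_rv_test <- function(x, path) {
  writeLines(c("rv\tp_value\tn_permutations\tseed",
               sprintf("%.17g\t%.17g\t%d\t%s", x$rv, x$p_value,
                       x$n_permutations,
                       if (is.null(x$seed)) "NA" else format(x$seed))), path)
  invisible(path)
}
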