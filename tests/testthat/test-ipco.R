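make_triplet <- function(seed = 1, nf = 4, nt = 6, nref = 5, nq = 3) {
  set.seed(seed)
  L <- ft(matrix(rpois(nt * nref, 10) + 1, nt, nref,
                 dimnames = list(sprintf("t%d", 1:nt), sprintf("r%d", 1:nref))))
  R <- ft(matrix(runif(nf * nref, 1, 5), nf, nref,
                 dimnames = list(sprintf("f%d", 1:nf), sprintf("r%d", 1:nref))),
          role = "functional")
  Q <- ft(matrix(rpois(nt * nq, 10) + 1, nt, nq,
                 dimnames = list(sprintf("t%d", 1:nt), sprintf("q%d", 1:nq))))
  list(R = R, L = L, Q = Q)
}

test_that("alignment pairs samples, intersects taxa, and reports drops", {
  tr <- make_triplet()
  al <- align_triplet(tr$R, tr$L, tr$Q)
  expect_length(al$dropped_taxa_query, 0)
  expect_length(al$dropped_taxa_reference, 0)
  expect_equal(colnames(al$r$values), colnames(al$l$values))
  expect_equal(rownames(al$l$values), rownames(al$q$values))

  ## a query taxon absent from L is dropped and reported
  tr2 <- make_triplet()
  qv <- rbind(tr2$Q$values, extra = c(5, 5, 5))
  al2 <- align_triplet(tr2$R, tr2$L, ft(qv))
  expect_equal(al2$dropped_taxa_query, "extra")
  expect_setdiff_empty <- setdiff(al2$taxa_ids, rownames(tr2$L$values))
  expect_length(expect_setdiff_empty, 0)

  ## a taxon all-zero in L after intersection is dropped from both l and q,
  ## and the CA precondition (positive margins) then holds
  tr3 <- make_triplet()
  lv <- tr3$L$values
  lv["t3", ] <- 0
  al3 <- align_triplet(tr3$R, ft(lv), tr3$Q)
  expect_equal(al3$dropped_taxa_reference, "t3")
  expect_false("t3" %in% rownames(al3$q$values))
  expect_true(all(rowSums(al3$l$values) > 0))
  expect_true(all(colSums(al3$l$values) > 0))
  expect_no_error(correspondence_analysis(al3$l))
})

test_that("alignment rejects unsuitable references", {
  tr <- make_triplet()
  ## R/L sample mismatch
  Rbad <- tr$R
  colnames(Rbad$values)[1] <- "other"
  Rbad$sample_ids[1] <- "other"
  expect_error(align_triplet(Rbad, tr$L, tr$Q), "other")

  ## almost all query abundance on taxa the reference lacks
  qv <- rbind(tr$Q$values, huge = c(1e6, 1e6, 1e6))
  expect_error(align_triplet(tr$R, tr$L, ft(qv), min_shared_taxa_fraction = 0.5),
               "reference")
})

test_that("the fourth-corner product matches hand and brute-force oracles", {
  ## 2x2x1 hand-computed case
  ca <- structure(list(lstar = matrix(c(1, -1, -1, 1), 2, 2),
                       lw = c(0.5, 0.5), cw = c(0.5, 0.5), grand_total = 4),
                  class = "ca_decomposition")
  rc <- structure(list(xstar = matrix(c(1, -1), 2, 1)),
                  class = "centered_table")
  qc <- structure(list(xstar = matrix(c(1, -1), 2, 1)),
                  class = "centered_table")
  expect_equal(unname(rlq_product(rc, ca, qc)), matrix(1.0, 1, 1))

  ## annihilation: constant functions center to zero rows
  rc0 <- structure(list(xstar = matrix(0, 2, 3)), class = "centered_table")
  expect_true(all(rlq_product(rc0, ca, qc) == 0))

  ## random instance vs the elementwise triple sum
  set.seed(17)
  nref <- 6; nt <- 5; nf <- 4; nq <- 3
  Lm <- matrix(runif(nref * nt, 0.5, 3), nref, nt)
  ca2 <- correspondence_analysis(Lm)
  rc2 <- weighted_center(matrix(rnorm(nref * nf), nref, nf), ca2$lw)
  qc2 <- weighted_center(matrix(rnorm(nt * nq), nt, nq), ca2$cw)
  got <- rlq_product(rc2, ca2, qc2)
  want <- rlq_oracle(rc2$xstar, ca2$lw, ca2$lstar, ca2$cw, qc2$xstar)
  expect_equal(unname(got), want, tolerance = 1e-10)

  expect_error(rlq_product(rc2, ca, qc2), "weights")
})

test_that("inference re-standardises additively and reproduces constants exactly", {
  tr <- make_triplet(seed = 5)
  ## plant a function constant across reference samples (untransformed path)
  tr$R$values["f2", ] <- 3.14159
  inf <- ipco_infer(tr$R, tr$L, tr$Q, transform = "none")
  expect_equal(unname(inf$values["f2", ]), rep(3.14159, 3), tolerance = 1e-12)

  ## additivity: values - raw_product is waR, constant within each row
  diffs <- inf$values - inf$raw_product
  expect_equal(unname(diffs[, 1]), unname(inf$waR))
  expect_lt(max(abs(sweep(diffs, 1, inf$waR, "-"))), 1e-15)

  ## waR is the CA-sample-weighted mean of the (transformed) R table
  ca <- correspondence_analysis(transform_table(inf$alignment$l, "none"))
  expect_equal(unname(inf$waR),
               unname(colSums(t(inf$alignment$r$values) * ca$lw)),
               tolerance = 1e-12)
})

test_that("permuting query samples permutes inferred columns identically", {
  tr <- make_triplet(seed = 7)
  inf <- ipco_infer(tr$R, tr$L, tr$Q)
  perm <- c(3, 1, 2)
  Qp <- ft(tr$Q$values[, perm])
  infp <- ipco_infer(tr$R, tr$L, Qp)
  expect_equal(infp$values, inf$values[, perm])
})

test_that("low-abundance filtering follows the quantile retention convention", {
  mk <- function(means) {
    v <- matrix(rep(means, 2), length(means), 2,
                dimnames = list(sprintf("f%d", seq_along(means)), c("q1", "q2")))
    structure(list(values = v, raw_product = v, waR = rep(0, length(means)),
                   function_ids = rownames(v), query_sample_ids = colnames(v),
                   transform = "none", scale_flag = FALSE, alignment = NULL),
              class = "inferred_table")
  }
  t4 <- mk(c(1, 2, 3, 4))
  expect_equal(filter_low_inferred(t4, 0)$function_ids, sprintf("f%d", 1:4))
  ## independent quantile: median of 1:4 under linear interpolation is 2.5
  expect_equal(filter_low_inferred(t4, 0.5)$function_ids, c("f3", "f4"))
  expect_equal(unname(quantile(c(1, 2, 3, 4), 0.5)), 2.5)

  tied <- mk(rep(2, 5))
  expect_equal(length(filter_low_inferred(tied, 0.99)$function_ids), 5)
  expect_error(filter_low_inferred(t4, 1.5), "quantile")
})
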