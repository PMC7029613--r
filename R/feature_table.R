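#' Construct a feature table
#'
#' A feature table is the package's basic data container: a numeric matrix of
#' abundances with features (taxa, pathways, gene families, metabolites or
#' coverage values) in rows and samples in columns, plus a role tag saying
#' what kind of data it holds. Taxonomic, functional and coverage tables must
#' be nonnegative; metabolite tables may contain any finite real values.
#'
#' @param values numeric matrix, features in rows and samples in columns.
#' @param feature_ids character vector of unique feature identifiers. Defaults
#'   to `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers. Defaults
#'   to `colnames(values)`.
#' @param role one of `"taxonomic"`, `"functional"`, `"coverage"`,
#'   `"metabolite"`.
#' @return an object of class `feature_table` with elements `values`
#'   (dimnamed matrix), `feature_ids`, `sample_ids` and `role`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' feature_table(m, role = "functional")
#' @export
feature_table <- function(values,
                          feature_ids = rownames(values),
                          sample_ids = colnames(values),
                          role = c("taxonomic", "functional", "coverage",
                                   "metabolite")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids))
    stopf("feature_ids and sample_ids are required (set dimnames or pass them)")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) ||
      length(sample_ids) != ncol(values))
    stopf("id lengths (%d features, %d samples) do not match values [%d x %d]",
          length(feature_ids), length(sample_ids), nrow(values), ncol(values))
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f))
    stopf("duplicated feature ids: %s", paste(dup_f, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stopf("duplicated sample ids: %s", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("missing/non-finite value at feature '%s', sample '%s'",
          feature_ids[bad[1]], sample_ids[bad[2]])
  }
  if (role != "metabolite" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stopf("negative value at feature '%s', sample '%s' (role '%s' must be nonnegative)",
          feature_ids[bad[1]], sample_ids[bad[2]], role)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, role = role),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d features x %d samples\n",
              x$role, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

## Subset a feature table by feature and/or sample ids (or indices).
subset_table <- function(t, features = NULL, samples = NULL) {
  v <- t$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  feature_table(v, role = t$role)
}

#' Read a feature table from TSV or BIOM
#'
#' The TSV dialect is the one distributed by HUMAnN-style tools: UTF-8,
#' tab-separated, a header row of sample identifiers (first header cell
#' ignored) and a first column of feature identifiers. BIOM files (JSON or
#' HDF5 dialect) are read through the biomformat package.
#'
#' @param path path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @param role role tag for the resulting table, see [feature_table()].
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, format = c("tsv", "biom"),
                               role = c("taxonomic", "functional", "coverage",
                                        "metabolite")) {
  format <- match.arg(format)
  role <- match.arg(role)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stopf("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(feature_table(m, role = role))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = NULL, colClasses = "character",
                          comment.char = "", quote = "")
  if (ncol(df) < 2) stopf("TSV must have a feature-id column and >= 1 sample")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicated feature ids in %s: %s", path, paste(dup, collapse = ", "))
  sample_ids <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow(df), length(sample_ids),
              dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(df[[j + 1]]))
    if (anyNA(col))
      stopf("non-numeric cell in %s at feature '%s', sample '%s'",
            path, ids[which(is.na(col))[1]], sample_ids[j])
    m[, j] <- col
  }
  feature_table(m, role = role)
}

#' Write a feature table to TSV
#'
#' Writes at full double precision so that a read/write round trip is
#' lossless.
#'
#' @param t a [feature_table()] or transformed table.
#' @param path output path.
#' @param id_header header for the feature-id column (ignored on read).
#' @export
write_feature_table <- function(t, path, id_header = "#ID") {
  v <- t$values
  lines <- c(paste(c(id_header, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i],
                       formatC(v[i, ], format = "g", digits = 17)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Remove samples with low sequencing depth
#'
#' Drops samples whose total read count falls below `min_reads`, the standard
#' depth filter applied to OTU count tables before inference (default 1000
#' reads). The feature set is unchanged.
#'
#' @param t a taxonomic [feature_table()] of counts.
#' @param min_reads minimum column sum a sample must reach to be retained.
#' @return the filtered [feature_table()].
#' @export
filter_low_depth <- function(t, min_reads = 1000) {
  stopifnot(inherits(t, "feature_table"))
  if (t$role != "taxonomic")
    stopf("depth filtering applies to taxonomic count tables, not role '%s'",
          t$role)
  if (!is_integerish(t$values))
    stopf("depth filtering requires integer counts")
  keep <- colSums(t$values) >= min_reads
  if (!any(keep))
    stopf("all %d samples fall below %d reads", ncol(t$values), min_reads)
  subset_table(t, samples = which(keep))
}
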