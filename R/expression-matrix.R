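#' Construct a validated expression matrix
#'
#' Bundles a gene x sample matrix of TPM values with per-sample metadata
#' (tissue, optional lactation stage, data source) and validates the pair.
#'
#' @param values Numeric gene x sample matrix, non-negative and finite, with
#'   row names (gene ids) and column names (sample ids).
#' @param metadata Data frame with columns \code{sample_id}, \code{tissue},
#'   and optionally \code{stage} (one of \code{dry}, \code{early},
#'   \code{peak}, \code{mid}, \code{late}, or \code{NA}) and \code{source}.
#'   Every sample in \code{values} must appear exactly once.
#'
#' @return An object of class \code{expression_matrix}: a list with elements
#'   \code{values} and \code{metadata} (metadata rows ordered as the matrix
#'   columns).
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  # a zero-row matrix (e.g. an empty filter result) is legal; R drops the
  # zero-length rownames to NULL, so only require them when rows exist
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values))))
    stop("`values` must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite expression values", call. = FALSE)
  if (any(values < 0))
    stop("negative expression values", call. = FALSE)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"stage" %in% names(metadata)) metadata$stage <- NA_character_
  if (!"source" %in% names(metadata)) metadata$source <- "unknown"
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)

  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  stages <- metadata$stage[!is.na(metadata$stage)]
  bad_stage <- setdiff(stages, c("dry", "early", "peak", "mid", "late"))
  if (length(bad_stage))
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  if (any(is.na(metadata$tissue) | metadata$tissue == ""))
    stop("every sample needs a tissue label", call. = FALSE)

  metadata <- metadata[match(colnames(values), metadata$sample_id),
                       c("sample_id", "tissue", "stage", "source"),
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples, %d tissue(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$metadata$tissue))))
  staged <- sum(!is.na(x$metadata$stage))
  if (staged) cat(sprintf("  %d sample(s) carry a lactation stage label\n",
                          staged))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file has gene ids in the first column and one column per
#' sample; the metadata file has columns \code{sample_id}, \code{tissue},
#' \code{stage}, \code{source}. Both are tab-separated with a header row.
#'
#' @param matrix_path Path to the gene x sample TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An \code{\link{expression_matrix}}.
#' @export
load_expression_matrix <- function(matrix_path, metadata_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("matrix file needs a gene-id column plus at least one sample",
         call. = FALSE)
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric expression values in ", matrix_path, call. = FALSE)
  rownames(vals) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  m <- expression_matrix(vals, meta)
  log_io("read", matrix_path, nrow(vals), ncol(vals))
  m
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param matrix_path Output path for the gene x sample TSV.
#' @param metadata_path Optional output path for the metadata TSV.
#' @return \code{m}, invisibly.
#' @export
write_expression_matrix <- function(m, matrix_path, metadata_path = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  out <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(m$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  log_io("wrote", matrix_path, nrow(m$values), ncol(m$values))
  invisible(m)
}

#' Keep genes detected above a TPM threshold
#'
#' Retains genes with expression strictly above \code{min_tpm} in at least
#' \code{min_samples} samples; the default (TPM > 1 in at least one sample)
#' is the usual bulk RNA-seq detection filter.
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param min_tpm Detection threshold (TPM), \eqn{\ge 0}.
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return A filtered \code{\link{expression_matrix}} with the same samples.
#' @export
filter_expressed <- function(m, min_tpm = 1, min_samples = 1L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (min_tpm < 0) stop("`min_tpm` must be >= 0", call. = FALSE)
  if (min_samples < 1L || min_samples > ncol(m$values))
    stop("`min_samples` must lie in 1..n_samples", call. = FALSE)
  keep <- rowSums(m$values > min_tpm) >= min_samples
  if (!any(keep))
    warning("no gene passes the expression filter", call. = FALSE)
  expression_matrix(m$values[keep, , drop = FALSE], m$metadata)
}

#' Average replicate samples within tissues (or stages)
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param by Grouping variable: \code{"tissue"} (default) or \code{"stage"}.
#'   With \code{by = "stage"} only samples carrying a stage label are used.
#' @return A gene x group numeric matrix of arithmetic means.
#' @export
average_replicates <- function(m, by = c("tissue", "stage")) {
  stopifnot(inherits(m, "expression_matrix"))
  by <- match.arg(by)
  grp <- m$metadata[[by]]
  use <- !is.na(grp)
  if (!any(use)) stop("no sample carries a ", by, " label", call. = FALSE)
  vals <- m$values[, use, drop = FALSE]
  grp <- grp[use]
  groups <- unique(grp)
  means <- vapply(groups, function(g)
    rowMeans(vals[, grp == g, drop = FALSE]),
    numeric(nrow(vals)))
  if (nrow(vals) == 1L) means <- matrix(means, nrow = 1L,
                                        dimnames = list(rownames(vals),
                                                        groups))
  colnames(means) <- groups
  means
}

#' Count expressed genes per tissue
#'
#' A gene counts as expressed in a tissue when at least one replicate of
#' that tissue exceeds \code{threshold} TPM (default 0, i.e. any detection).
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param threshold Detection threshold in TPM.
#' @return Named integer vector, one count per tissue.
#' @export
expressed_gene_counts <- function(m, threshold = 0) {
  stopifnot(inherits(m, "expression_matrix"))
  tissues <- unique(m$metadata$tissue)
  vapply(tissues, function(t) {
    cols <- m$metadata$tissue == t
    sum(apply(m$values[, cols, drop = FALSE] > threshold, 1L, any))
  }, integer(1L))
}

#' Pairwise column correlations with p-values
#'
#' Correlates the columns of a profile or trait matrix pairwise, dropping
#' missing values per pair, and reports two-sided p-values from the
#' t-approximation on n - 2 degrees of freedom. Spearman correlations use
#' tie-corrected average ranks.
#'
#' @param x Numeric matrix or data frame (observations in rows, variables in
#'   columns), e.g. a gene x tissue profile or a trait table.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return An object of class \code{cor_matrix}: list with symmetric
#'   matrices \code{rho} and \code{pvals}, the pairwise sample sizes
#'   \code{n}, and \code{method}.
#' @export
correlate_profiles <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  p <- ncol(x)
  labels <- colnames(x) %||% paste0("V", seq_len(p))
  rho <- matrix(NA_real_, p, p, dimnames = list(labels, labels))
  pv <- rho
  nm <- matrix(0L, p, p, dimnames = list(labels, labels))
  diag(rho) <- 1
  diag(pv) <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(x[, i], x[, j])
    n <- sum(ok)
    nm[i, j] <- nm[j, i] <- n
    if (n < 3L) {
      warning(sprintf("fewer than 3 complete pairs for %s vs %s",
                      labels[i], labels[j]), call. = FALSE)
      next
    }
    a <- x[ok, i]; b <- x[ok, j]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("zero variance: correlation %s vs %s undefined",
                      labels[i], labels[j]), call. = FALSE)
      next
    }
    if (method == "spearman") { a <- rank(a); b <- rank(b) }
    r <- stats::cor(a, b)
    # two-sided p from t = r * sqrt((n-2)/(1-r^2))
    if (abs(r) >= 1) {
      p2 <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p2 <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    rho[i, j] <- rho[j, i] <- r
    pv[i, j] <- pv[j, i] <- p2
  }
  diag(nm) <- as.integer(colSums(!is.na(x)))
  structure(list(rho = rho, pvals = pv, n = nm, method = method),
            class = "cor_matrix")
}

#' Significance stars for a p-value
#' @param p Numeric vector of p-values.
#' @return Character vector: \code{"***"} (p < 0.001), \code{"**"}
#'   (p < 0.01), \code{"*"} (p < 0.05), otherwise \code{"ns"}.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.cor_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("%s correlation matrix (%d variables)\n",
              x$method, ncol(x$rho)))
  disp <- matrix(sprintf("%.*f%s", digits, x$rho,
                         ifelse(row(x$rho) == col(x$rho), "",
                                significance_stars(x$pvals))),
                 nrow(x$rho), dimnames = dimnames(x$rho))
  print(disp, quote = FALSE)
  cat("stars: * p<0.05, ** p<0.01, *** p<0.001, ns not significant\n")
  invisible(x)
}
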