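#' Per-gene mean expression and coefficient of variation across tissues
#'
#' The CV is the sample standard deviation (n - 1 denominator) of a gene's
#' tissue means divided by their mean. Genes whose mean TPM over tissues is
#' not above \code{min_mean_tpm} are excluded first: only reasonably
#' expressed genes are candidate housekeeping genes.
#'
#' @param profile Gene x tissue matrix of replicate-averaged TPM
#'   (see \code{\link{average_replicates}}).
#' @param min_mean_tpm Pre-filter on the mean over tissues (default 1).
#' @param sd_type \code{"sample"} (n - 1, default) or \code{"population"}
#'   (n) standard deviation.
#' @return Data frame with columns \code{gene_id}, \code{mean_tpm},
#'   \code{cv}.
#' @export
compute_cv <- function(profile, min_mean_tpm = 1,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  profile <- as.matrix(profile)
  if (ncol(profile) < 2L)
    stop("need at least 2 tissues to compute a CV", call. = FALSE)
  mu <- rowMeans(profile)
  keep <- mu > min_mean_tpm
  profile <- profile[keep, , drop = FALSE]
  mu <- mu[keep]
  if (!nrow(profile))
    stop("no gene passes the mean TPM filter", call. = FALSE)
  if (any(mu == 0)) stop("zero mean expression", call. = FALSE)
  sdv <- apply(profile, 1L, stats::sd)
  if (sd_type == "population") {
    n <- ncol(profile)
    sdv <- sdv * sqrt((n - 1) / n)
  }
  data.frame(gene_id = rownames(profile), mean_tpm = unname(mu),
             cv = unname(sdv / mu), stringsAsFactors = FALSE)
}

#' Classify genes by CV quartile and expression abundance
#'
#' Quartiles of the CV distribution are computed by linear interpolation
#' (quantile type 7). Genes with CV at or below the first quartile form the
#' low-variability group, genes with CV at or above the third quartile the
#' high-variability group, the rest the medium group; when the two quartiles
#' coincide, genes on the boundary are assigned low before high. Expression
#' bins follow the mean TPM: low (1 < TPM <= 10), medium (10 < TPM <= 50),
#' high (TPM > 50). Core housekeeping genes combine low variability with
#' high expression.
#'
#' @param stats Data frame from \code{\link{compute_cv}}.
#' @param expr_threshold High-expression cutoff in TPM (default 50).
#' @return Object of class \code{hkg_classification}: the input plus
#'   \code{variability_group}, \code{expression_bin}, \code{is_core}, with
#'   the quartiles in attribute \code{quartiles}.
#' @export
classify_variability <- function(stats, expr_threshold = 50) {
  need <- c("gene_id", "mean_tpm", "cv")
  if (!all(need %in% names(stats)))
    stop("`stats` needs columns gene_id, mean_tpm, cv", call. = FALSE)
  if (nrow(stats) < 4L)
    stop("need at least 4 genes for quartile classification", call. = FALSE)
  q <- stats::quantile(stats$cv, c(0.25, 0.75), type = 7, names = FALSE)
  grp <- ifelse(stats$cv <= q[1], "low",
         ifelse(stats$cv >= q[2], "high", "medium"))
  bin <- ifelse(stats$mean_tpm > 50, "high",
         ifelse(stats$mean_tpm > 10, "medium", "low"))
  out <- data.frame(stats, variability_group = grp, expression_bin = bin,
                    is_core = grp == "low" & stats$mean_tpm > expr_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "quartiles") <- c(q1 = q[1], q3 = q[2])
  attr(out, "expr_threshold") <- expr_threshold
  class(out) <- c("hkg_classification", "data.frame")
  out
}

#' @export
print.hkg_classification <- function(x, ...) {
  q <- attr(x, "quartiles")
  cat(sprintf("hkg_classification: %d genes (CV Q1 = %.4g, Q3 = %.4g)\n",
              nrow(x), q[["q1"]], q[["q3"]]))
  tab <- table(x$variability_group)[c("low", "medium", "high")]
  cat("  variability groups:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  core housekeeping genes (low CV, mean TPM > %g): %d\n",
              attr(x, "expr_threshold"), sum(x$is_core)))
  invisible(x)
}

#' @export
summary.hkg_classification <- function(object, ...) {
  tab <- table(variability = object$variability_group,
               expression = object$expression_bin)
  structure(list(counts = tab, n_core = sum(object$is_core),
                 quartiles = attr(object, "quartiles")),
            class = "summary.hkg_classification")
}

#' @export
print.summary.hkg_classification <- function(x, ...) {
  cat("Gene counts by variability group and expression bin:\n")
  print(x$counts)
  cat(sprintf("Core housekeeping genes: %d\n", x$n_core))
  invisible(x)
}

#' Select core housekeeping genes
#'
#' Genes in the low-variability group whose mean TPM exceeds
#' \code{expr_threshold}. Raising the threshold can only shrink the set, so
#' selections at increasingly stringent cutoffs (e.g. 50, 70, 100) are
#' nested.
#'
#' @param classes An \code{\link{classify_variability}} result.
#' @param expr_threshold Mean-TPM cutoff (default 50).
#' @return Character vector of gene ids.
#' @export
select_core_hkgs <- function(classes, expr_threshold = 50) {
  stopifnot(inherits(classes, "hkg_classification"))
  classes$gene_id[classes$variability_group == "low" &
                  classes$mean_tpm > expr_threshold]
}

#' Rank the most stable core housekeeping genes
#'
#' Core genes ordered by ascending CV; ties broken by descending mean TPM,
#' then by gene id.
#'
#' @param classes An \code{\link{classify_variability}} result.
#' @param n Number of genes to return.
#' @return Character vector of up to \code{n} gene ids, most stable first.
#' @export
rank_top_stable <- function(classes, n = 100L) {
  stopifnot(inherits(classes, "hkg_classification"))
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  core <- classes[classes$is_core, , drop = FALSE]
  ord <- order(core$cv, -core$mean_tpm, core$gene_id)
  ids <- core$gene_id[ord]
  if (n > length(ids)) {
    warning(sprintf("only %d core genes available (requested %d)",
                    length(ids), n), call. = FALSE)
    return(ids)
  }
  ids[seq_len(n)]
}
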