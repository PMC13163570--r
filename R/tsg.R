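#' Call tissue-specific genes by the fold-ratio rule
#'
#' A gene is specific to tissue t when its mean expression there is at least
#' \code{fold} times the maximum mean over all other tissues. Genes below
#' \code{min_tpm} in every tissue are excluded first. When every other
#' tissue has mean 0 the fold ratio is infinite and the call is made
#' provided the target tissue reaches \code{min_tpm}. With \code{fold > 1} a
#' gene can be specific to at most one tissue.
#'
#' @param profile Gene x tissue matrix of (typically normalized,
#'   replicate-averaged) TPM means.
#' @param fold Fold threshold, > 1 (default 3).
#' @param min_tpm Expression floor in TPM (default 1).
#' @return Object of class \code{tsg_calls}: data frame with columns
#'   \code{gene_id}, \code{tissue}, \code{fold_ratio}, \code{is_marker}.
#' @export
call_tsgs <- function(profile, fold = 3, min_tpm = 1) {
  profile <- as.matrix(profile)
  if (ncol(profile) < 2L)
    stop("need at least 2 tissues", call. = FALSE)
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  keep <- apply(profile, 1L, max) >= min_tpm
  profile <- profile[keep, , drop = FALSE]
  calls <- list()
  for (g in seq_len(nrow(profile))) {
    v <- profile[g, ]
    t_max <- which.max(v)
    other_max <- if (ncol(profile) > 1L) max(v[-t_max]) else 0
    ratio <- if (other_max == 0) Inf else v[t_max] / other_max
    hit <- if (is.infinite(ratio)) v[t_max] >= min_tpm
           else v[t_max] >= fold * other_max
    if (hit)
      calls[[length(calls) + 1L]] <-
        data.frame(gene_id = rownames(profile)[g],
                   tissue = colnames(profile)[t_max],
                   fold_ratio = ratio, is_marker = FALSE,
                   stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(gene_id = character(), tissue = character(),
                         fold_ratio = numeric(), is_marker = logical(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fold") <- fold
  attr(out, "min_tpm") <- min_tpm
  class(out) <- c("tsg_calls", "data.frame")
  out
}

#' @export
print.tsg_calls <- function(x, ...) {
  cat(sprintf("tsg_calls: %d call(s) at fold >= %g\n",
              nrow(x), attr(x, "fold")))
  if (any(x$is_marker))
    cat(sprintf("  %d exclusive marker gene(s)\n", sum(x$is_marker)))
  if (nrow(x)) {
    tab <- sort(table(x$tissue), decreasing = TRUE)
    top <- utils::head(tab, 5L)
    cat("  top tissues:",
        paste(sprintf("%s=%d", names(top), top), collapse = " "), "\n")
  }
  invisible(x)
}

#' Call exclusive marker genes
#'
#' A marker gene is expressed (mean at or above
#' \code{expressed_threshold}) in exactly one tissue.
#'
#' @param profile Gene x tissue matrix of TPM means.
#' @param expressed_threshold Expression threshold in TPM (default 1).
#' @return A \code{\link{call_tsgs}}-style data frame with
#'   \code{is_marker = TRUE}; \code{fold_ratio} is the ratio to the highest
#'   other tissue (infinite when all others are 0).
#' @export
call_markers <- function(profile, expressed_threshold = 1) {
  profile <- as.matrix(profile)
  expressed <- profile >= expressed_threshold
  n_expr <- rowSums(expressed)
  idx <- which(n_expr == 1L)
  calls <- lapply(idx, function(g) {
    v <- profile[g, ]
    t_max <- which(expressed[g, ])
    other_max <- max(v[-t_max])
    data.frame(gene_id = rownames(profile)[g],
               tissue = colnames(profile)[t_max],
               fold_ratio = if (other_max == 0) Inf else v[t_max] / other_max,
               is_marker = TRUE, stringsAsFactors = FALSE)
  })
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(gene_id = character(), tissue = character(),
                         fold_ratio = numeric(), is_marker = logical(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "expressed_threshold") <- expressed_threshold
  class(out) <- c("tsg_calls", "data.frame")
  out
}

#' Call lactation-stage-specific genes
#'
#' Applies the tissue-specificity fold rule with lactation stages in place
#' of tissues: stage means are computed per gene over the stage-labelled
#' samples, and a gene is stage-specific when its mean in one stage is at
#' least \code{fold} times the maximum over the other stages.
#'
#' @param m An \code{\link{expression_matrix}} of (mammary) samples with
#'   stage labels.
#' @param stages Ordered stage labels to use (default the four lactation
#'   phases early, peak, mid, late).
#' @param fold Fold threshold, > 1 (default 3).
#' @param min_tpm Expression floor in TPM (default 1).
#' @return Named list (one element per stage) of gene-id vectors, with the
#'   full \code{\link{call_tsgs}} data frame in attribute \code{calls}.
#' @export
call_stage_specific <- function(m, stages = c("early", "peak", "mid",
                                              "late"),
                                fold = 3, min_tpm = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(stages) < 2L) stop("need at least 2 stages", call. = FALSE)
  present <- unique(m$metadata$stage[!is.na(m$metadata$stage)])
  absent <- setdiff(stages, present)
  if (length(absent))
    stop("stage(s) absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  use <- !is.na(m$metadata$stage) & m$metadata$stage %in% stages
  sub <- expression_matrix(m$values[, use, drop = FALSE],
                           m$metadata[use, , drop = FALSE])
  means <- average_replicates(sub, by = "stage")
  means <- means[, stages, drop = FALSE]
  calls <- call_tsgs(means, fold = fold, min_tpm = min_tpm)
  out <- lapply(stages, function(s) calls$gene_id[calls$tissue == s])
  names(out) <- stages
  attr(out, "calls") <- calls
  out
}

#' Fold-threshold sensitivity of tissue-specific calls
#'
#' Re-runs the fold-ratio screen at increasingly stringent thresholds and
#' reports the nested call sets together with pairwise retention fractions
#' (the share of calls at one threshold still present at another).
#'
#' @param profile Gene x tissue matrix of TPM means.
#' @param folds Ascending fold thresholds, all > 1 (default 3, 4, 5).
#' @param min_tpm Expression floor in TPM (default 1).
#' @return Object of class \code{fold_sensitivity}: list with per-fold
#'   \code{calls}, per-fold counts \code{n_calls} and the retention matrix
#'   \code{retention} (row = reference fold, column = stricter fold).
#' @export
fold_sensitivity <- function(profile, folds = c(3, 4, 5), min_tpm = 1) {
  if (is.unsorted(folds, strictly = TRUE))
    stop("`folds` must be strictly ascending", call. = FALSE)
  if (any(folds <= 1)) stop("all folds must be > 1", call. = FALSE)
  calls <- lapply(folds, function(f)
    call_tsgs(profile, fold = f, min_tpm = min_tpm))
  names(calls) <- paste0("fold_", folds)
  keys <- lapply(calls, function(cc) paste(cc$gene_id, cc$tissue))
  k <- length(folds)
  retention <- matrix(NA_real_, k, k,
                      dimnames = list(names(calls), names(calls)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    retention[i, j] <- if (length(keys[[i]]))
      length(intersect(keys[[i]], keys[[j]])) / length(keys[[i]])
    else NA_real_
  }
  structure(list(folds = folds, calls = calls,
                 n_calls = vapply(calls, nrow, integer(1L)),
                 retention = retention),
            class = "fold_sensitivity")
}

#' @export
print.fold_sensitivity <- function(x, ...) {
  cat("fold-threshold sensitivity of tissue-specific calls\n")
  print(data.frame(fold = x$folds, n_calls = unname(x$n_calls)))
  cat("retention fractions (row set retained in column set):\n")
  print(round(x$retention, 3))
  invisible(x)
}
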