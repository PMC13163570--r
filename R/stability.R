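# qPCR reference-gene stability: geNorm, NormFinder, BestKeeper, the
# comparative delta-Ct method, and their geometric-mean aggregation.

validate_cq <- function(cq, min_genes = 2L, min_samples = 2L) {
  cq <- as.matrix(cq)
  if (!is.numeric(cq) || any(!is.finite(cq)))
    stop("Cq table must be numeric and finite", call. = FALSE)
  if (is.null(rownames(cq)))
    rownames(cq) <- paste0("gene", seq_len(nrow(cq)))
  if (nrow(cq) < min_genes)
    stop(sprintf("need at least %d genes", min_genes), call. = FALSE)
  if (ncol(cq) < min_samples)
    stop(sprintf("need at least %d samples", min_samples), call. = FALSE)
  cq
}

# deterministic competition ranks: ascending value, ties by gene id
rank_by_value <- function(v, ids) {
  r <- integer(length(v))
  r[order(v, ids)] <- seq_along(v)
  names(r) <- ids
  r
}

#' Read a Cq table from CSV
#'
#' Expects candidate genes in rows (first column gene id) and samples in
#' columns, with a header row.
#'
#' @param path Path to the CSV file.
#' @return Numeric gene x sample matrix of quantification-cycle values.
#' @export
load_cq_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  cq <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(cq) <- as.character(tab[[1L]])
  cq <- validate_cq(cq)
  log_io("read", path, nrow(cq), ncol(cq))
  cq
}

#' Convert Cq values to relative quantities
#'
#' The standard delta-Cq transform: each gene's lowest Cq (highest
#' abundance) is taken as reference, so per gene the maximum quantity is 1.
#'
#' @param cq Gene x sample Cq matrix.
#' @param efficiency Amplification efficiency as a fold change per cycle
#'   (2 = perfect doubling); must be > 1.
#' @return Gene x sample matrix of relative quantities
#'   \code{efficiency^(min Cq - Cq)}.
#' @export
cq_to_relative_quantity <- function(cq, efficiency = 2) {
  cq <- validate_cq(cq, min_samples = 1L, min_genes = 1L)
  if (efficiency <= 1) stop("`efficiency` must be > 1", call. = FALSE)
  efficiency^(apply(cq, 1L, min) - cq)
}

#' geNorm expression-stability analysis
#'
#' For every gene pair the pairwise variation V is the sample standard
#' deviation across samples of the log2 ratio of their relative quantities;
#' a gene's stability measure M is the mean of its pairwise variations, a
#' lower M indicating higher stability. Stepwise exclusion repeatedly
#' removes the least stable gene (highest M, recomputed at each step); the
#' final two genes cannot be separated by M and share rank 1. A pairwise
#' variation V(k/k+1) between normalization factors built from the k and
#' k + 1 most stable genes is reported to guide how many reference genes to
#' combine.
#'
#' @param cq Gene x sample Cq matrix (at least 3 genes, 2 samples).
#' @param efficiency Amplification efficiency (default 2).
#' @return Object of class \code{genorm_fit}: \code{m_values} (full-panel
#'   M), \code{rank} (by full-panel M, ties by gene id), \code{stepwise}
#'   data frame (exclusion order with the final pair tied at rank 1),
#'   \code{pairwise_v} (V(k/k+1)), \code{v_matrix}.
#' @export
genorm <- function(cq, efficiency = 2) {
  cq <- validate_cq(cq, min_genes = 2L)
  q <- cq_to_relative_quantity(cq, efficiency)
  lx <- log2(q)
  genes <- rownames(cq)

  m_of <- function(lx) {
    n <- nrow(lx)
    v <- matrix(0, n, n, dimnames = list(rownames(lx), rownames(lx)))
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (k <= j) next
      v[j, k] <- v[k, j] <- stats::sd(lx[j, ] - lx[k, ])
    }
    list(v = v, m = rowSums(v) / (n - 1))
  }

  full <- m_of(lx)
  m_full <- full$m

  # stepwise exclusion of the least stable gene
  cur <- lx
  excluded <- character(0)
  while (nrow(cur) > 2L) {
    m_cur <- m_of(cur)$m
    worst <- names(m_cur)[order(-m_cur, rownames(cur))][1L]
    excluded <- c(excluded, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  final_pair <- rownames(cur)
  n <- length(genes)
  step_rank <- c(stats::setNames(rep(1L, 2L), final_pair),
                 stats::setNames(seq(n, 3L), excluded))
  step_rank <- step_rank[genes]

  # V(k/k+1): sd of log2 ratio of normalization factors with k vs k+1 genes
  ord <- genes[order(m_full, genes)]
  pairwise_v <- NULL
  if (n >= 3L) {
    nf <- function(k) apply(lx[ord[seq_len(k)], , drop = FALSE], 2L, mean)
    pairwise_v <- vapply(2:(n - 1L), function(k)
      stats::sd(nf(k) - nf(k + 1L)), numeric(1L))
    names(pairwise_v) <- paste0("V", 2:(n - 1L), "/", 3:n)
  }

  structure(list(m_values = m_full,
                 rank = rank_by_value(m_full, genes),
                 stepwise = data.frame(gene_id = genes,
                                       stepwise_rank = unname(step_rank),
                                       stringsAsFactors = FALSE),
                 pairwise_v = pairwise_v, v_matrix = full$v,
                 efficiency = efficiency),
            class = "genorm_fit")
}

#' @export
print.genorm_fit <- function(x, digits = 4, ...) {
  cat("geNorm stability (lower M = more stable)\n")
  ord <- order(x$rank)
  print(data.frame(gene_id = names(x$m_values)[ord],
                   M = round(x$m_values[ord], digits),
                   rank = x$rank[ord], row.names = NULL))
  if (!is.null(x$pairwise_v)) {
    cat("pairwise variation V(k/k+1):\n")
    print(round(x$pairwise_v, digits))
  }
  invisible(x)
}

#' NormFinder model-based stability
#'
#' Works on log2 relative quantities. In the ungrouped variant the additive
#' model (gene effect + sample effect + residual) is removed by two-way
#' centering; because the column (sample-effect) means mix every gene's
#' noise into each gene's residuals, the naive residual variance of gene i
#' has expectation \eqn{(1 - 2/G)\sigma_i^2 + \sum_j \sigma_j^2 / G^2}. The
#' reported stability value is the square root of the bias-corrected,
#' jointly solved variance estimate (floored at zero), so it estimates the
#' gene's own variation \eqn{\sigma_i} directly. The grouped variant
#' additionally accounts for systematic gene-by-group deviations:
#' stability is the mean over groups of the absolute intergroup deviation
#' plus the standard error of the within-group residual.
#'
#' @param cq Gene x sample Cq matrix (at least 3 genes).
#' @param groups Optional per-sample group labels (each group needs at
#'   least 2 samples).
#' @param efficiency Amplification efficiency (default 2).
#' @return Object of class \code{normfinder_fit}: \code{stability} (named,
#'   lower = more stable), \code{rank}, and (ungrouped) the residual
#'   matrix.
#' @export
normfinder <- function(cq, groups = NULL, efficiency = 2) {
  cq <- validate_cq(cq, min_genes = 3L)
  x <- log2(cq_to_relative_quantity(cq, efficiency))
  genes <- rownames(x)

  center2 <- function(x)
    x - rowMeans(x) - rep(colMeans(x), each = nrow(x)) + mean(x)

  if (is.null(groups)) {
    r <- center2(x)
    g_n <- nrow(x)
    if (g_n < 3L) stop("bias correction needs at least 3 genes",
                       call. = FALSE)
    v_naive <- apply(r, 1L, stats::var)
    # E[v_naive_i] = (1 - 2/G) sigma_i^2 + sum_j sigma_j^2 / G^2;
    # summing over i gives the total, then solve per gene
    total <- sum(v_naive) / (1 - 1 / g_n)
    stab <- sqrt(pmax((v_naive - total / g_n^2) / (1 - 2 / g_n), 0))
    names(stab) <- genes
    res <- r
  } else {
    if (length(groups) != ncol(x))
      stop("`groups` must give one label per sample", call. = FALSE)
    sizes <- table(groups)
    if (any(sizes < 2L))
      stop("every group needs at least 2 samples in grouped mode",
           call. = FALSE)
    glev <- unique(groups)
    # gene-by-group deviations after removing gene and group main effects
    a <- vapply(glev, function(g)
      rowMeans(x[, groups == g, drop = FALSE]), numeric(nrow(x)))
    z <- sweep(a, 2L, colMeans(a))          # centre genes within group
    d <- z - rowMeans(z)                    # remove the gene's own profile
    se <- vapply(glev, function(g) {
      r <- center2(x[, groups == g, drop = FALSE])
      apply(r, 1L, stats::sd) / sqrt(sum(groups == g))
    }, numeric(nrow(x)))
    stab <- rowMeans(abs(d) + se)
    names(stab) <- genes
    res <- d
  }
  structure(list(stability = stab, rank = rank_by_value(stab, genes),
                 residuals = res, grouped = !is.null(groups)),
            class = "normfinder_fit")
}

#' @export
print.normfinder_fit <- function(x, digits = 4, ...) {
  cat(sprintf("NormFinder stability (%s; lower = more stable)\n",
              if (x$grouped) "grouped" else "ungrouped"))
  ord <- order(x$rank)
  print(data.frame(gene_id = names(x$stability)[ord],
                   stability = round(x$stability[ord], digits),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' BestKeeper descriptive stability
#'
#' Works directly on Cq values: per gene the dispersion (sample standard
#' deviation by default, or the original tool's mean absolute deviation),
#' the percent coefficient of variation, and the Pearson correlation with
#' the BestKeeper index (per-sample geometric mean of all genes' Cq).
#' Genes are ranked by ascending dispersion.
#'
#' @param cq Gene x sample Cq matrix.
#' @param dispersion \code{"sd"} (default) or \code{"mad"} (mean absolute
#'   deviation from the gene's mean Cq).
#' @return Object of class \code{bestkeeper_fit}: per-gene \code{sd},
#'   \code{cv_pct}, \code{r} (vs the index), \code{rank}, and the
#'   \code{index} vector.
#' @export
bestkeeper <- function(cq, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  cq <- validate_cq(cq, min_genes = 1L)
  genes <- rownames(cq)
  mu <- rowMeans(cq)
  disp <- switch(dispersion,
                 sd = apply(cq, 1L, stats::sd),
                 mad = rowMeans(abs(cq - mu)))
  index <- apply(cq, 2L, geometric_mean)
  r <- vapply(seq_len(nrow(cq)), function(g) {
    if (stats::sd(cq[g, ]) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(cq[g, ], index)
  }, numeric(1L))
  names(r) <- genes
  structure(list(sd = disp, cv_pct = 100 * disp / mu, r = r,
                 rank = rank_by_value(disp, genes), index = index,
                 dispersion = dispersion),
            class = "bestkeeper_fit")
}

#' @export
print.bestkeeper_fit <- function(x, digits = 4, ...) {
  cat(sprintf("BestKeeper (%s dispersion of raw Cq; lower = more stable)\n",
              x$dispersion))
  ord <- order(x$rank)
  print(data.frame(gene_id = names(x$sd)[ord],
                   sd = round(x$sd[ord], digits),
                   cv_pct = round(x$cv_pct[ord], digits),
                   r_index = round(x$r[ord], digits),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' Comparative delta-Ct stability
#'
#' For each gene, the mean over all other genes of the standard deviation
#' across samples of their pairwise Cq difference. A low mean pairwise SD
#' indicates a gene that co-varies with the rest of the panel, i.e. a
#' stable reference.
#'
#' @param cq Gene x sample Cq matrix (at least 3 genes).
#' @return Object of class \code{deltact_fit}: \code{mean_sd} (named) and
#'   \code{rank}.
#' @export
delta_ct <- function(cq) {
  cq <- validate_cq(cq, min_genes = 3L)
  genes <- rownames(cq)
  n <- nrow(cq)
  s <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (k <= j) next
    s[j, k] <- s[k, j] <- stats::sd(cq[j, ] - cq[k, ])
  }
  ms <- rowSums(s) / (n - 1)
  names(ms) <- genes
  structure(list(mean_sd = ms, rank = rank_by_value(ms, genes)),
            class = "deltact_fit")
}

#' @export
print.deltact_fit <- function(x, digits = 4, ...) {
  cat("comparative delta-Ct (mean pairwise SD; lower = more stable)\n")
  ord <- order(x$rank)
  print(data.frame(gene_id = names(x$mean_sd)[ord],
                   mean_sd = round(x$mean_sd[ord], digits),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' RefFinder-style aggregation of stability ranks
#'
#' The aggregate weight of each gene is the geometric mean of its ranks
#' under the individual algorithms; the final ranking sorts ascending
#' geometric mean, with ties broken by the best single-algorithm rank and
#' then by gene id.
#'
#' @param rank_lists List of per-gene rank vectors (each a named
#'   permutation of 1..n over the same gene set), typically four: geNorm,
#'   NormFinder, BestKeeper, delta-Ct.
#' @return Data frame with \code{gene_id}, \code{geomean},
#'   \code{final_rank}.
#' @export
reffinder <- function(rank_lists) {
  if (!length(rank_lists)) stop("no rank vectors given", call. = FALSE)
  genes <- sort(names(rank_lists[[1L]]))
  for (rl in rank_lists) {
    if (is.null(names(rl)) || !setequal(names(rl), genes))
      stop("rank vectors cover mismatched gene sets", call. = FALSE)
    if (!setequal(rl, seq_along(genes)))
      stop("each rank vector must be a permutation of 1..n", call. = FALSE)
  }
  mat <- vapply(rank_lists, function(rl) rl[genes],
                numeric(length(genes)))
  if (length(genes) == 1L) mat <- matrix(mat, nrow = 1L)
  geo <- apply(mat, 1L, geometric_mean)
  best <- apply(mat, 1L, min)
  fr <- integer(length(genes))
  fr[order(geo, best, genes)] <- seq_along(genes)
  data.frame(gene_id = genes, geomean = unname(geo),
             final_rank = fr, stringsAsFactors = FALSE)
}

#' Rank candidate qPCR reference genes with four algorithms
#'
#' Runs \code{\link{genorm}}, \code{\link{normfinder}},
#' \code{\link{bestkeeper}} and \code{\link{delta_ct}} on a Cq table and
#' aggregates their rankings RefFinder-style by the geometric mean of
#' ranks.
#'
#' @param cq Gene x sample Cq matrix (at least 3 genes and 3 samples).
#' @param efficiency Amplification efficiency (default 2, i.e. perfect
#'   doubling per cycle).
#' @param groups Optional per-sample groups for NormFinder.
#' @param bestkeeper_dispersion \code{"sd"} or \code{"mad"}.
#' @return Object of class \code{stability_report}: a per-gene data frame
#'   (\code{table}) with the four stability measures, their ranks, the
#'   RefFinder geometric mean and the final rank, plus the four fitted
#'   sub-objects.
#' @export
rank_reference_genes <- function(cq, efficiency = 2, groups = NULL,
                                 bestkeeper_dispersion = c("sd", "mad")) {
  bestkeeper_dispersion <- match.arg(bestkeeper_dispersion)
  cq <- validate_cq(cq, min_genes = 3L, min_samples = 3L)
  gn <- genorm(cq, efficiency)
  nf <- normfinder(cq, groups, efficiency)
  bk <- bestkeeper(cq, bestkeeper_dispersion)
  dc <- delta_ct(cq)
  rf <- reffinder(list(genorm = gn$rank, normfinder = nf$rank,
                       bestkeeper = bk$rank, delta_ct = dc$rank))
  genes <- rownames(cq)
  tab <- data.frame(gene_id = genes,
                    genorm_m = unname(gn$m_values[genes]),
                    genorm_rank = unname(gn$rank[genes]),
                    normfinder_stability = unname(nf$stability[genes]),
                    normfinder_rank = unname(nf$rank[genes]),
                    bestkeeper_sd = unname(bk$sd[genes]),
                    bestkeeper_r = unname(bk$r[genes]),
                    bestkeeper_rank = unname(bk$rank[genes]),
                    deltact_sd = unname(dc$mean_sd[genes]),
                    deltact_rank = unname(dc$rank[genes]),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, rf, by = "gene_id", sort = FALSE)
  names(tab)[names(tab) == "geomean"] <- "reffinder_geomean"
  tab <- tab[order(tab$final_rank), ]
  rownames(tab) <- NULL
  structure(list(table = tab, genorm = gn, normfinder = nf,
                 bestkeeper = bk, delta_ct = dc,
                 efficiency = efficiency),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, digits = 4, ...) {
  cat("Reference-gene stability report (1 = most stable)\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.stability_report <- function(object, ...) {
  tab <- object$table
  agree <- stats::cor(tab$genorm_rank, tab$normfinder_rank,
                      method = "spearman")
  structure(list(best = tab$gene_id[tab$final_rank == 1L],
                 worst = tab$gene_id[tab$final_rank == nrow(tab)],
                 n_genes = nrow(tab),
                 genorm_normfinder_rank_cor = agree),
            class = "summary.stability_report")
}

#' @export
print.summary.stability_report <- function(x, ...) {
  cat(sprintf("%d candidate reference genes\n", x$n_genes))
  cat(sprintf("  most stable (RefFinder): %s\n", x$best))
  cat(sprintf("  least stable: %s\n", x$worst))
  cat(sprintf("  geNorm vs NormFinder rank agreement (Spearman): %.3f\n",
              x$genorm_normfinder_rank_cor))
  invisible(x)
}

#' @export
plot.stability_report <- function(x, ...) {
  tab <- x$table
  graphics::barplot(tab$reffinder_geomean, names.arg = tab$gene_id,
                    las = 2, ylab = "RefFinder geometric mean of ranks",
                    main = "Reference-gene stability (lower = better)",
                    ...)
  invisible(x)
}
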