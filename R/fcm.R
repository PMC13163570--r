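# fuzzy c-means trend clustering of stage expression profiles

#' Row-standardize stage expression profiles
#'
#' Each gene row is transformed to mean 0 and (sample) standard deviation 1
#' so that clustering groups genes by the shape of their trajectory rather
#' than its level. Constant rows carry no trend and are dropped with a
#' warning.
#'
#' @param stage_means Gene x stage numeric matrix.
#' @return Z-scored matrix (possibly fewer rows).
#' @export
standardize_stage_profiles <- function(stage_means) {
  x <- as.matrix(stage_means)
  if (ncol(x) < 2L) stop("need at least 2 stages", call. = FALSE)
  sds <- apply(x, 1L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping %d constant gene profile(s)", sum(drop)),
            call. = FALSE)
    x <- x[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  (x - rowMeans(x)) / sds
}

#' Fuzzy c-means clustering of expression trends
#'
#' Standard alternating optimization of the fuzzy c-means objective
#' (sum over genes and clusters of membership^m times the squared
#' Euclidean distance to the centroid). Memberships are initialized at
#' random from the given seed; the run is deterministic given the seed.
#' Convergence is declared when the largest membership change between
#' iterations falls below \code{tol}.
#'
#' @param z Gene x stage matrix, typically row-standardized
#'   (\code{\link{standardize_stage_profiles}}).
#' @param c Number of clusters (>= 1, at most the number of genes).
#' @param m Fuzzifier exponent, > 1 (default 2).
#' @param seed Integer seed for the random initialization.
#' @param tol Convergence tolerance on memberships (default 1e-6).
#' @param max_iter Iteration cap (default 300).
#' @return Object of class \code{trend_clustering}: \code{memberships}
#'   (gene x cluster, rows sum to 1), \code{centroids} (cluster x stage),
#'   \code{cluster} (hard assignment by maximal membership, ties to the
#'   lower index), \code{objective}, \code{objective_trace}, \code{iter},
#'   \code{m}, \code{c}, \code{seed}.
#' @export
fuzzy_cmeans <- function(z, c, m = 2, seed = 1L, tol = 1e-6,
                         max_iter = 300L) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (c < 1L) stop("`c` must be >= 1", call. = FALSE)
  if (c > n) stop("`c` cannot exceed the number of genes", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must be > 1", call. = FALSE)

  u <- with_seed(seed, {
    u0 <- matrix(stats::runif(n * c), n, c)
    u0 / rowSums(u0)
  })

  sq_dist <- function(v) {
    # gene x cluster matrix of squared Euclidean distances
    d <- outer(rowSums(z^2), rowSums(v^2), "+") - 2 * z %*% t(v)
    pmax(d, 0)
  }

  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    v <- (t(um) %*% z) / colSums(um)
    d2 <- sq_dist(v)
    u_new <- matrix(0, n, c)
    zero <- d2 <= .Machine$double.eps
    for (i in seq_len(n)) {
      if (any(zero[i, ])) {
        u_new[i, zero[i, ]] <- 1 / sum(zero[i, ])
      } else {
        inv <- d2[i, ]^(-1 / (m - 1))
        u_new[i, ] <- inv / sum(inv)
      }
    }
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }

  dimnames(u) <- list(rownames(z), paste0("cluster", seq_len(c)))
  dimnames(v) <- list(paste0("cluster", seq_len(c)), colnames(z))
  hard <- apply(u, 1L, which.max)   # which.max ties -> lower index
  structure(list(memberships = u, centroids = v, cluster = hard,
                 objective = trace[length(trace)],
                 objective_trace = trace, iter = iter,
                 m = m, c = c, seed = seed, converged = iter < max_iter),
            class = "trend_clustering")
}

#' @export
print.trend_clustering <- function(x, ...) {
  cat(sprintf(
    "fuzzy c-means: %d genes, %d cluster(s), m = %g (seed %d)\n",
    nrow(x$memberships), x$c, x$m, x$seed))
  cat(sprintf("  objective %.6g after %d iteration(s)%s\n", x$objective,
              x$iter, if (x$converged) "" else " (not converged)"))
  sizes <- tabulate(x$cluster, nbins = x$c)
  cat("  hard cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.trend_clustering <- function(object, ...) {
  sizes <- tabulate(object$cluster, nbins = object$c)
  structure(list(sizes = sizes, centroids = object$centroids,
                 objective = object$objective, iter = object$iter),
            class = "summary.trend_clustering")
}

#' @export
print.summary.trend_clustering <- function(x, ...) {
  cat("cluster sizes (hard assignment):", paste(x$sizes, collapse = " "),
      "\n")
  cat("centroids (z-score units):\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
plot.trend_clustering <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "b", lty = 1, pch = 16,
                    xlab = "stage", ylab = "centroid (z-score)",
                    main = "Expression trend centroids", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ncol(x$centroids)),
                 labels = colnames(x$centroids) %||%
                   seq_len(ncol(x$centroids)))
  graphics::legend("topright", legend = rownames(x$centroids),
                   col = seq_len(nrow(x$centroids)), lty = 1, pch = 16,
                   cex = 0.8)
  invisible(x)
}

#' Memberships of new profiles under fixed centroids
#'
#' @param object A \code{\link{fuzzy_cmeans}} fit.
#' @param newdata Gene x stage matrix on the same (z-score) scale.
#' @param ... Unused.
#' @return Membership matrix (rows sum to 1).
#' @export
predict.trend_clustering <- function(object, newdata, ...) {
  z <- as.matrix(newdata)
  v <- object$centroids
  m <- object$m
  d2 <- pmax(outer(rowSums(z^2), rowSums(v^2), "+") - 2 * z %*% t(v), 0)
  u <- matrix(0, nrow(z), nrow(v),
              dimnames = list(rownames(z), rownames(v)))
  for (i in seq_len(nrow(z))) {
    zero <- d2[i, ] <= .Machine$double.eps
    if (any(zero)) u[i, zero] <- 1 / sum(zero)
    else {
      inv <- d2[i, ]^(-1 / (m - 1))
      u[i, ] <- inv / sum(inv)
    }
  }
  u
}

#' Match cluster centroids to a trait trajectory
#'
#' Correlates each cluster centroid with the z-scored trait trajectory and
#' selects the best-matching cluster (highest Pearson correlation, ties to
#' the lower cluster index).
#'
#' @param tc A \code{\link{fuzzy_cmeans}} fit.
#' @param trait Numeric per-stage trait values (e.g. milk yield at the
#'   stage-representative days); length must equal the number of stages.
#' @return Object of class \code{trend_match}: \code{correlations} (per
#'   cluster), \code{best_cluster}, \code{cluster_sizes} (hard counts).
#' @export
match_trait_trend <- function(tc, trait) {
  stopifnot(inherits(tc, "trend_clustering"))
  if (length(trait) != ncol(tc$centroids))
    stop("trait vector length must equal the number of stages",
         call. = FALSE)
  if (stats::sd(trait) == 0)
    stop("constant trait trajectory: no trend to match", call. = FALSE)
  ztrait <- (trait - mean(trait)) / stats::sd(trait)
  cors <- apply(tc$centroids, 1L, function(v)
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, ztrait))
  best <- which.max(cors)
  structure(list(correlations = cors, best_cluster = unname(best),
                 cluster_sizes = tabulate(tc$cluster, nbins = tc$c)),
            class = "trend_match")
}

#' @export
print.trend_match <- function(x, ...) {
  cat("centroid-trait correlations:\n")
  print(round(x$correlations, 4))
  cat(sprintf("best-matching cluster: %d (%d genes by hard assignment)\n",
              x$best_cluster, x$cluster_sizes[x$best_cluster]))
  invisible(x)
}
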