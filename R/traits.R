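# lactation trait tables: stage representatives, Spearman correlations,
# pairwise stage comparisons

trait_cols <- c("milk_yield", "protein_pct", "fat_pct", "lactose_pct")

validate_traits <- function(t) {
  t <- as.data.frame(t, stringsAsFactors = FALSE)
  need <- c("day", trait_cols)
  miss <- setdiff(need, names(t))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(as.matrix(t[need]))))
    stop("non-finite trait values", call. = FALSE)
  if (any(t$day < 1)) stop("days must be >= 1", call. = FALSE)
  if (any(t$milk_yield < 0)) stop("negative milk yield", call. = FALSE)
  pct <- as.matrix(t[c("protein_pct", "fat_pct", "lactose_pct")])
  if (any(pct < 0 | pct > 100))
    stop("composition percentages must lie in [0, 100]", call. = FALSE)
  if (!"animal_id" %in% names(t)) t$animal_id <- "animal1"
  t
}

#' Read a lactation trait table from CSV
#'
#' Columns: \code{day}, \code{milk_yield} (kg/day), \code{protein_pct},
#' \code{fat_pct}, \code{lactose_pct}, optional \code{animal_id}.
#'
#' @param path Path to the CSV file.
#' @return Validated trait data frame.
#' @export
load_trait_table <- function(path) {
  t <- validate_traits(utils::read.csv(path, stringsAsFactors = FALSE))
  log_io("read", path, nrow(t), ncol(t))
  t
}

#' Stage-representative trait summaries
#'
#' For each lactation stage, trait values are taken at the stage's
#' representative day (falling back to the nearest recorded day within
#' \code{window} days) and averaged across animals.
#'
#' @param t Trait table (see \code{\link{load_trait_table}}).
#' @param stage_days Named day per stage; default early 7, peak 85,
#'   mid 145, late 285.
#' @param window Nearest-day fallback window in days (default 5).
#' @return Data frame with one row per stage: \code{stage},
#'   \code{day_used}, the mean of each trait, and \code{n} animals.
#' @export
stage_representatives <- function(t,
                                  stage_days = c(early = 7, peak = 85,
                                                 mid = 145, late = 285),
                                  window = 5) {
  t <- validate_traits(t)
  rows <- lapply(names(stage_days), function(s) {
    target <- stage_days[[s]]
    dd <- abs(t$day - target)
    if (min(dd) > window)
      stop(sprintf("no trait record within %g days of day %g (stage %s)",
                   window, target, s), call. = FALSE)
    day_used <- t$day[which.min(dd)]
    sel <- t[t$day == day_used, , drop = FALSE]
    data.frame(stage = s, day_used = day_used,
               t(colMeans(sel[trait_cols])), n = nrow(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlations among lactation traits
#'
#' Rank correlations (with t-approximation p-values) among milk yield and
#' the three composition traits across all records.
#'
#' @param t Trait table.
#' @return A \code{\link{correlate_profiles}} \code{cor_matrix}
#'   (method \code{spearman}).
#' @export
trait_correlations <- function(t) {
  t <- validate_traits(t)
  if (nrow(t) < 3L) stop("need at least 3 records", call. = FALSE)
  correlate_profiles(t[trait_cols], method = "spearman")
}

#' Pairwise stage comparisons of a lactation trait
#'
#' Compares the trait's stage-representative observations (values at each
#' stage's representative day, one per animal) between every pair of
#' stages with a two-sided Wilcoxon rank-sum test (or Welch t-test), then
#' adjusts p-values across the pairs by Benjamini-Hochberg.
#'
#' @param t Trait table.
#' @param trait One of \code{milk_yield}, \code{protein_pct},
#'   \code{fat_pct}, \code{lactose_pct}.
#' @param stage_days Named day per stage (see
#'   \code{\link{stage_representatives}}).
#' @param window Nearest-day fallback window in days.
#' @param test \code{"wilcoxon"} (default) or \code{"t"}.
#' @return Data frame per stage pair: \code{stage_a}, \code{stage_b},
#'   \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{significance}.
#' @export
pairwise_stage_tests <- function(t, trait = "milk_yield",
                                 stage_days = c(early = 7, peak = 85,
                                                mid = 145, late = 285),
                                 window = 5,
                                 test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  t <- validate_traits(t)
  trait <- match.arg(trait, trait_cols)
  obs <- lapply(names(stage_days), function(s) {
    target <- stage_days[[s]]
    dd <- abs(t$day - target)
    if (min(dd) > window) return(numeric(0))
    t[[trait]][t$day == t$day[which.min(dd)]]
  })
  names(obs) <- names(stage_days)
  pairs <- utils::combn(names(stage_days), 2L)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    if (length(obs[[a]]) < 2L || length(obs[[b]]) < 2L) {
      warning(sprintf("stage pair %s vs %s skipped: fewer than 2 values",
                      a, b), call. = FALSE)
      next
    }
    fit <- if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(obs[[a]], obs[[b]],
                                          alternative = "two.sided"))
    else stats::t.test(obs[[a]], obs[[b]])
    rows[[length(rows) + 1L]] <-
      data.frame(stage_a = a, stage_b = b,
                 statistic = unname(fit$statistic),
                 p_value = fit$p.value, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(stage_a = character(), stage_b = character(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significance = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significance <- significance_stars(out$p_adjusted)
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "test") <- test
  out
}
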