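# Seeded simulators with planted ground truth: a multi-tissue TPM atlas,
# qPCR Cq tables, and lactation trait/stage-expression data. These stand in
# for the raw sequencing and phenotype records of a real atlas study so the
# whole screening pipeline can be exercised end to end.

default_tissues <- c("heart", "liver", "spleen", "lung", "kidney",
                     "rumen", "reticulum", "omasum", "abomasum",
                     "duodenum", "jejunum", "ileum", "muscle", "fat",
                     "skin", "mammary", "ovary", "uterus", "testis",
                     "brain")

#' Simulate a multi-tissue expression atlas with planted gene classes
#'
#' Background genes are log-normal with gene-specific between-tissue
#' heterogeneity. Planted housekeeping genes combine high abundance (mean
#' TPM above \code{hkg_min_tpm}) with a between-tissue CV well below the
#' background range; planted tissue-specific genes have one tissue's mean
#' at least \code{tsg_fold} times every other tissue; planted markers are
#' expressed at or above 1 TPM in exactly one tissue. Replicate noise is
#' multiplicative log-normal. The three planted classes are disjoint.
#'
#' @param n_genes Total number of genes (default 5000).
#' @param tissues Tissue labels (default 20 bovid tissues).
#' @param reps_per_tissue Candidate replicate counts; each tissue draws one
#'   (default 2:4).
#' @param frac_hkg,frac_tsg,frac_marker Fractions of genes planted in each
#'   class (defaults 0.10, 0.10, 0.004); must sum to at most 1.
#' @param tsg_fold Planted tissue-mean fold enrichment (default 8).
#' @param hkg_min_tpm Lower bound of planted housekeeping-gene abundance
#'   (default 60 TPM).
#' @param background_meanlog,background_sdlog Log-normal parameters of
#'   background gene abundance (defaults 1.2, 1.2).
#' @param tissue_sdlog_range Range of the per-gene between-tissue log-SD
#'   for background genes (default 0.25-0.7).
#' @param hkg_cv_range Range of planted housekeeping between-tissue CV
#'   (default 0.03-0.08).
#' @param replicate_sdlog Multiplicative replicate noise log-SD
#'   (default 0.15).
#' @param seed Integer seed; the output is deterministic given it.
#' @return List with \code{matrix} (an \code{\link{expression_matrix}})
#'   and \code{truth}: \code{planted_hkg}, \code{planted_tsg} (named gene
#'   -> tissue), \code{planted_marker} (named gene -> tissue),
#'   \code{planted_stage} (empty; stage truth comes from
#'   \code{\link{simulate_lactation}}), \code{background}.
#' @export
simulate_atlas <- function(n_genes = 5000L, tissues = default_tissues,
                           reps_per_tissue = 2:4,
                           frac_hkg = 0.10, frac_tsg = 0.10,
                           frac_marker = 0.004, tsg_fold = 8,
                           hkg_min_tpm = 60,
                           background_meanlog = 1.2,
                           background_sdlog = 1.2,
                           tissue_sdlog_range = c(0.25, 0.7),
                           hkg_cv_range = c(0.03, 0.08),
                           replicate_sdlog = 0.15, seed = 1L) {
  if (frac_hkg + frac_tsg + frac_marker > 1)
    stop("planted fractions must sum to at most 1", call. = FALSE)
  n_t <- length(tissues)
  if (n_t < 2L) stop("need at least 2 tissues", call. = FALSE)
  with_seed(seed, {
    reps <- if (length(reps_per_tissue) == 1L)
      rep(reps_per_tissue, n_t)
    else sample(reps_per_tissue, n_t, replace = TRUE)
    tissue_of <- rep(tissues, reps)
    sample_ids <- unlist(lapply(seq_len(n_t), function(i)
      paste0(tissues[i], "_rep", seq_len(reps[i]))))
    n_s <- length(sample_ids)

    n_hkg <- round(frac_hkg * n_genes)
    n_tsg <- round(frac_tsg * n_genes)
    n_mark <- round(frac_marker * n_genes)
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    pool <- sample_int(n_genes, n_hkg + n_tsg + n_mark)
    idx_hkg <- pool[seq_len(n_hkg)]
    idx_tsg <- pool[n_hkg + seq_len(n_tsg)]
    idx_mark <- pool[n_hkg + n_tsg + seq_len(n_mark)]

    # tissue-level mean TPM for every gene
    M <- matrix(0, n_genes, n_t, dimnames = list(gene_ids, tissues))
    bg <- setdiff(seq_len(n_genes), pool)
    base_bg <- stats::rlnorm(length(bg), background_meanlog,
                             background_sdlog)
    het <- stats::runif(length(bg), tissue_sdlog_range[1],
                        tissue_sdlog_range[2])
    M[bg, ] <- base_bg * exp(matrix(stats::rnorm(length(bg) * n_t), ncol =
                                      n_t) * het)

    if (n_hkg) {
      base_h <- exp(stats::runif(n_hkg, log(hkg_min_tpm),
                                 log(5 * hkg_min_tpm)))
      cv_h <- stats::runif(n_hkg, hkg_cv_range[1], hkg_cv_range[2])
      M[idx_hkg, ] <- base_h * exp(matrix(stats::rnorm(n_hkg * n_t),
                                          ncol = n_t) * cv_h)
    }

    tsg_tissue <- character(0)
    if (n_tsg) {
      tsg_tissue <- sample(tissues, n_tsg, replace = TRUE)
      for (i in seq_len(n_tsg)) {
        g <- idx_tsg[i]
        others <- stats::rlnorm(n_t - 1L, log(2), 0.4)
        M[g, ] <- 0
        M[g, tissues != tsg_tissue[i]] <- others
        M[g, tsg_tissue[i]] <- tsg_fold * max(others) *
          exp(stats::runif(1, 0, 0.4))
      }
      names(tsg_tissue) <- gene_ids[idx_tsg]
    }

    mark_tissue <- character(0)
    if (n_mark) {
      mark_tissue <- sample(tissues, n_mark, replace = TRUE)
      for (i in seq_len(n_mark)) {
        g <- idx_mark[i]
        M[g, ] <- stats::runif(n_t, 0, 0.2)
        M[g, mark_tissue[i]] <- stats::runif(1, 5, 50)
      }
      names(mark_tissue) <- gene_ids[idx_mark]
    }

    # multiplicative replicate noise
    X <- M[, match(tissue_of, tissues), drop = FALSE] *
      exp(matrix(stats::rnorm(n_genes * n_s, 0, replicate_sdlog),
                 n_genes, n_s))
    dimnames(X) <- list(gene_ids, sample_ids)

    meta <- data.frame(sample_id = sample_ids, tissue = tissue_of,
                       stage = NA_character_, source = "simulated",
                       stringsAsFactors = FALSE)
    list(matrix = expression_matrix(X, meta),
         truth = list(planted_hkg = gene_ids[idx_hkg],
                      planted_tsg = tsg_tissue,
                      planted_marker = mark_tissue,
                      planted_stage = character(0),
                      background = gene_ids[bg],
                      tissue_means = M))
  })
}

#' Simulate a qPCR Cq table with planted per-gene noise levels
#'
#' Cq values follow gene baseline + shared per-sample offset + Gaussian
#' noise with a gene-specific standard deviation; the true stability order
#' is the ascending order of the noise SDs. Sample offsets default to 0.2
#' cycles, the residual loading variation expected after equal-mass cDNA
#' input.
#'
#' @param n_genes Number of candidate genes (default 6).
#' @param n_samples Number of tissue cDNA samples (default 5).
#' @param noise_sds Per-gene noise SD in cycles (length \code{n_genes};
#'   default 0.05, 0.2, 0.4, 0.6, 0.8, 1.0).
#' @param sample_offset_sd SD of the shared per-sample offset in cycles
#'   (default 0.2).
#' @param baseline_range Range of gene baseline Cq (default 18-30).
#' @param seed Integer seed.
#' @return List with \code{cq} (gene x sample matrix) and \code{truth}
#'   (\code{noise_sds}, \code{offsets}, \code{stability_order}).
#' @export
simulate_cq <- function(n_genes = 6L, n_samples = 5L,
                        noise_sds = c(0.05, 0.2, 0.4, 0.6, 0.8, 1.0),
                        sample_offset_sd = 0.2,
                        baseline_range = c(18, 30), seed = 1L) {
  if (length(noise_sds) != n_genes)
    stop("`noise_sds` must have one value per gene", call. = FALSE)
  if (any(noise_sds < 0)) stop("negative noise SD", call. = FALSE)
  if (sample_offset_sd < 0) stop("negative offset SD", call. = FALSE)
  with_seed(seed, {
    genes <- paste0("gene", seq_len(n_genes))
    samples <- if (n_samples == 5L)
      c("mammary", "rumen", "duodenum", "liver", "muscle")
    else paste0("sample", seq_len(n_samples))
    baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])
    offsets <- stats::rnorm(n_samples, 0, sample_offset_sd)
    cq <- outer(baseline, offsets, "+") +
      matrix(stats::rnorm(n_genes * n_samples, 0, noise_sds),
             n_genes, n_samples)   # noise_sds recycles down columns
    dimnames(cq) <- list(genes, samples)
    list(cq = cq,
         truth = list(noise_sds = stats::setNames(noise_sds, genes),
                      offsets = stats::setNames(offsets, samples),
                      stability_order = genes[order(noise_sds)]))
  })
}

#' Rise-plateau-decline lactation curve
#'
#' A Wood-type gamma curve evaluated on a time axis compressed threefold
#' between \code{plateau_start} and \code{plateau_end}, which flattens the
#' region around the peak into a plateau before the gradual decline.
#' The curve is scaled so its maximum over the requested days equals
#' \code{peak_yield}.
#'
#' @param day Days in milk (numeric vector).
#' @param peak_yield Plateau yield in kg/day (default 10).
#' @param shape Wood shape parameter (default 0.5).
#' @param plateau_start,plateau_end Plateau bounds in days (defaults 35
#'   and 115).
#' @return Expected daily yield in kg/day.
#' @export
lactation_curve <- function(day, peak_yield = 10, shape = 0.5,
                            plateau_start = 35, plateau_end = 115) {
  u <- ifelse(day <= plateau_start, day,
       ifelse(day <= plateau_end,
              plateau_start + (day - plateau_start) / 3,
              plateau_start + (plateau_end - plateau_start) / 3 +
                (day - plateau_end)))
  u_peak <- plateau_start + (plateau_end - plateau_start) / 3 / 2 +
    plateau_start / 2   # rough centre of the compressed plateau
  rate <- shape / u_peak
  w <- u^shape * exp(-rate * u)
  peak_yield * w / max(w)
}

default_sampling_days <- c(1:7, 11, 18, 25, seq(35, 305, by = 10))

# planted trend shapes over the four stage-representative days,
# z-scored rows; the first is the milk-yield trajectory shape
trend_shapes <- function(stage_days = c(7, 85, 145, 285)) {
  y <- lactation_curve(stage_days)
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  rbind(yield = zs(y),
        rising = zs(seq_along(stage_days)),
        falling = zs(rev(seq_along(stage_days))),
        inverse_yield = zs(-y))
}

#' Simulate lactation traits and a companion stage expression matrix
#'
#' Milk yield follows a rise-plateau-decline curve (Wood-type gamma curve
#' with a compressed-time plateau) with animal- and day-level noise.
#' Composition traits are coupled to the standardized yield trajectory
#' with strength \code{dilution_strength}: protein and fat negatively
#' (dilution of solids by volume), lactose positively (osmotic driver of
#' volume). The companion mammary stage expression matrix contains planted
#' trend clusters over the four stages (the first tracking the yield
#' curve) and planted stage-specific genes.
#'
#' @param n_animals Number of animals (default 6).
#' @param days Sampling schedule in days in milk (default: days 1-7, 11,
#'   18, 25, then every 10 days to day 305).
#' @param peak_yield Plateau yield in kg/day (default 10).
#' @param dilution_strength Coupling strength in [0, 1] (default 0.9).
#' @param genes_per_cluster Genes per planted trend cluster (default 150).
#' @param n_stage_specific Planted stage-specific genes, split evenly over
#'   the four stages (default 40).
#' @param reps_per_stage Replicates per stage in the companion matrix
#'   (default 3).
#' @param seed Integer seed.
#' @return List with \code{traits} (data frame: animal_id, day,
#'   milk_yield, protein_pct, fat_pct, lactose_pct), \code{stage_matrix}
#'   (an \code{\link{expression_matrix}} of mammary stage samples), and
#'   \code{truth} (\code{trend_cluster} gene -> shape name, \code{shapes},
#'   \code{planted_stage} gene -> stage, \code{stage_days},
#'   \code{yield_curve}).
#' @export
simulate_lactation <- function(n_animals = 6L,
                               days = default_sampling_days,
                               peak_yield = 10, dilution_strength = 0.9,
                               genes_per_cluster = 150L,
                               n_stage_specific = 40L,
                               reps_per_stage = 3L, seed = 1L) {
  if (dilution_strength < 0 || dilution_strength > 1)
    stop("`dilution_strength` must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    curve <- lactation_curve(days, peak_yield = peak_yield)
    zcurve <- (curve - mean(curve)) / stats::sd(curve)
    rows <- list()
    for (a in seq_len(n_animals)) {
      scale_a <- exp(stats::rnorm(1, 0, 0.08))
      yield <- curve * scale_a * exp(stats::rnorm(length(days), 0, 0.05))
      protein <- 4.6 - 0.55 * dilution_strength * zcurve +
        stats::rnorm(length(days), 0, 0.18)
      fat <- 7.5 - 0.45 * dilution_strength * zcurve +
        stats::rnorm(length(days), 0, 0.30)
      lactose <- 5.0 + 0.35 * dilution_strength * zcurve +
        stats::rnorm(length(days), 0, 0.12)
      rows[[a]] <- data.frame(animal_id = sprintf("buffalo%02d", a),
                              day = days, milk_yield = yield,
                              protein_pct = pmax(protein, 0),
                              fat_pct = pmax(fat, 0),
                              lactose_pct = pmax(lactose, 0),
                              stringsAsFactors = FALSE)
    }
    traits <- do.call(rbind, rows)
    rownames(traits) <- NULL

    # companion mammary stage matrix with planted trends and
    # stage-specific genes
    stages <- c("early", "peak", "mid", "late")
    stage_days <- c(early = 7, peak = 85, mid = 145, late = 285)
    shapes <- trend_shapes(unname(stage_days))
    n_shape <- nrow(shapes)
    n_trend <- n_shape * genes_per_cluster
    n_stage <- n_stage_specific
    gene_ids <- sprintf("mgene%05d", seq_len(n_trend + n_stage))

    stage_mean <- matrix(0, n_trend + n_stage, 4L,
                         dimnames = list(gene_ids, stages))
    cluster_of <- rep(rownames(shapes), each = genes_per_cluster)
    for (i in seq_len(n_trend)) {
      base <- stats::rlnorm(1, log(20), 0.8)
      amp <- stats::runif(1, 0.8, 1.5)
      stage_mean[i, ] <- base * 2^(amp * shapes[cluster_of[i], ])
    }
    stage_of <- rep(stages, length.out = n_stage)
    for (i in seq_len(n_stage)) {
      g <- n_trend + i
      stage_mean[g, ] <- stats::runif(4, 1, 4)
      stage_mean[g, stage_of[i]] <- stats::runif(1, 30, 100)
    }

    sample_ids <- as.vector(t(outer(stages, seq_len(reps_per_stage),
                                    function(s, r) paste0(s, "_rep", r))))
    stage_lab <- rep(stages, each = reps_per_stage)
    X <- stage_mean[, match(stage_lab, stages), drop = FALSE] *
      exp(matrix(stats::rnorm(length(gene_ids) * length(sample_ids), 0,
                              0.15), length(gene_ids)))
    dimnames(X) <- list(gene_ids, sample_ids)
    meta <- data.frame(sample_id = sample_ids, tissue = "mammary",
                       stage = stage_lab, source = "simulated",
                       stringsAsFactors = FALSE)

    list(traits = traits,
         stage_matrix = expression_matrix(X, meta),
         truth = list(trend_cluster = stats::setNames(cluster_of,
                                                      gene_ids[
                                                        seq_len(n_trend)]),
                      shapes = shapes,
                      planted_stage = stats::setNames(stage_of,
                                                      gene_ids[n_trend +
                                                        seq_len(n_stage)]),
                      stage_days = stage_days,
                      yield_curve = data.frame(day = days,
                                               yield = curve)))
  })
}
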