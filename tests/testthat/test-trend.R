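test_that("row standardization yields mean 0, SD 1 and is idempotent", {
  z <- standardize_stage_profiles(rbind(g = c(1, 2, 3)))
  expect_equal(unname(rowMeans(z)), 0)
  expect_equal(unname(apply(z, 1, sd)), 1)

  expect_warning(
    zc <- standardize_stage_profiles(rbind(a = c(1, 2, 3),
                                           b = c(5, 5, 5))),
    "constant")
  expect_equal(rownames(zc), "a")

  set.seed(171)
  x <- rand_mat(40, 5, rnorm)
  z1 <- standardize_stage_profiles(x)
  expect_equal(standardize_stage_profiles(z1), z1, tolerance = 1e-12)
})

test_that("one cluster degenerates to the column-mean centroid", {
  set.seed(181)
  z <- standardize_stage_profiles(rand_mat(30, 4, rnorm))
  fit <- fuzzy_cmeans(z, c = 1, seed = 5)
  expect_true(all(fit$memberships == 1))
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(z)))
})

test_that("memberships are a proper fuzzy partition and the objective
           never increases", {
  set.seed(191)
  for (rep in 1:5) {
    z <- standardize_stage_profiles(rand_mat(60, 4, rnorm))
    fit <- fuzzy_cmeans(z, c = 3, seed = rep)
    expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("identical seeds reproduce the clustering bit for bit", {
  set.seed(201)
  z <- standardize_stage_profiles(rand_mat(50, 4, rnorm))
  f1 <- fuzzy_cmeans(z, c = 3, seed = 42)
  f2 <- fuzzy_cmeans(z, c = 3, seed = 42)
  expect_identical(f1$memberships, f2$memberships)
  f3 <- fuzzy_cmeans(z, c = 3, seed = 43)
  expect_false(identical(f1$memberships, f3$memberships))
})

test_that("two planted opposite trends are recovered by their
           centroids", {
  t1 <- c(-1.2, -0.4, 0.4, 1.2)
  ok <- 0
  for (s in 1:20) {
    set.seed(s + 300)
    z <- rbind(matrix(rep(t1, each = 30), 30), # rising genes
               matrix(rep(-t1, each = 30), 30)) +
      matrix(rnorm(240, 0, 0.3), 60, 4)
    rownames(z) <- paste0("g", 1:60)
    zz <- standardize_stage_profiles(z)
    fit <- fuzzy_cmeans(zz, c = 2, seed = s)
    cors <- apply(fit$centroids, 1, cor, y = t1)
    ok <- ok + (max(cors) > 0.99 && min(cors) < -0.99)
  }
  expect_gte(ok, 19)
})

test_that("the final partition agrees with an independent fuzzy c-means
           implementation", {
  skip_if_not_installed("e1071")
  t1 <- c(-1.2, -0.4, 0.4, 1.2)
  set.seed(211)
  z <- rbind(matrix(rep(t1, each = 25), 25),
             matrix(rep(-t1, each = 25), 25)) +
    matrix(rnorm(200, 0, 0.25), 50, 4)
  rownames(z) <- paste0("g", 1:50)
  fit <- fuzzy_cmeans(z, c = 2, seed = 9, tol = 1e-9)
  ref <- e1071::cmeans(z, centers = 2, m = 2, iter.max = 500)
  # same optimum up to cluster relabeling
  perm <- if (cor(fit$centroids[1, ], ref$centers[1, ]) > 0) 1:2 else 2:1
  expect_equal(unname(fit$centroids), unname(ref$centers[perm, ]),
               tolerance = 1e-3)
  expect_equal(unname(fit$cluster),
               unname(match(ref$cluster, perm)))
})

test_that("trait matching picks the centroid tracking the trajectory", {
  centros <- rbind(c(-1, 0, 1, 2), c(2, 1, 0, -1), c(0.5, -0.5, 0.5,
                                                     -0.5))
  fit <- structure(list(memberships = matrix(1, 3, 3),
                        centroids = centros,
                        cluster = c(1L, 2L, 3L), c = 3L, m = 2),
                   class = "trend_clustering")
  trait <- c(-1, 0, 1, 2)
  m <- match_trait_trend(fit, trait)
  expect_equal(m$best_cluster, 1L)
  expect_equal(unname(m$correlations[1]), 1)
  expect_equal(unname(m$correlations[2]), -1)
  expect_error(match_trait_trend(fit, c(2, 2, 2, 2)), "constant")
  expect_error(match_trait_trend(fit, 1:3), "length")
})

test_that("trait matching is invariant to cluster relabeling", {
  sim <- simulate_lactation(seed = 23)
  sm <- average_replicates(sim$stage_matrix, by = "stage")
  sm <- sm[, c("early", "peak", "mid", "late")]
  z <- standardize_stage_profiles(log2(sm + 1))
  fit <- fuzzy_cmeans(z, c = 4, seed = 7)
  yield <- lactation_curve(c(7, 85, 145, 285))
  m1 <- match_trait_trend(fit, yield)
  # relabel clusters by reversing their order
  rev_fit <- fit
  rev_fit$centroids <- fit$centroids[4:1, ]
  rev_fit$memberships <- fit$memberships[, 4:1]
  rev_fit$cluster <- 5L - fit$cluster
  m2 <- match_trait_trend(rev_fit, yield)
  expect_equal(m2$best_cluster, 5L - m1$best_cluster)
  expect_equal(unname(sort(m1$correlations)),
               unname(sort(m2$correlations)))
})

test_that("predicted memberships extend the fit to new profiles", {
  t1 <- c(-1, 0, 1, 2)
  set.seed(221)
  z <- rbind(matrix(rep(t1, each = 20), 20),
             matrix(rep(-t1, each = 20), 20)) +
    matrix(rnorm(160, 0, 0.2), 40, 4)
  rownames(z) <- paste0("g", 1:40)
  fit <- fuzzy_cmeans(z, c = 2, seed = 3)
  pred <- predict(fit, z)
  expect_equal(rowSums(pred), setNames(rep(1, 40), rownames(z)))
  expect_equal(unname(apply(pred, 1, which.max)), unname(fit$cluster))
})
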