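worked_cq <- rbind(A = c(20, 21, 22), B = c(20, 21, 22),
                   C = c(20, 22, 24))

test_that("relative quantities follow the delta-Cq transform", {
  q <- cq_to_relative_quantity(rbind(g = c(20, 21, 22)), efficiency = 2)
  expect_equal(unname(q[1, ]), c(1, 0.5, 0.25))
  qc <- cq_to_relative_quantity(rbind(g = c(25, 25, 25)))
  expect_equal(unname(qc[1, ]), c(1, 1, 1))
  expect_error(cq_to_relative_quantity(worked_cq, efficiency = 1),
               "efficiency")
})

test_that("geNorm reproduces the hand-computed M values", {
  fit <- genorm(worked_cq)
  expect_equal(unname(fit$m_values[c("A", "B", "C")]), c(0.5, 0.5, 1.0))
  # C is least stable: excluded first, A and B share stepwise rank 1
  sw <- fit$stepwise
  expect_equal(sw$stepwise_rank[sw$gene_id == "C"], 3L)
  expect_equal(sw$stepwise_rank[sw$gene_id %in% c("A", "B")], c(1L, 1L))
})

test_that("geNorm is invariant to per-sample and per-gene shifts", {
  # gene proportional to another contributes 0 pairwise variation
  cq <- rbind(A = c(20, 21, 22), B = c(23, 24, 25), C = c(20, 22, 24))
  fit <- genorm(cq)
  expect_equal(unname(fit$v_matrix["A", "B"]), 0)

  shifted <- sweep(worked_cq, 2L, c(1, -2, 0.5), "+")
  expect_equal(genorm(shifted)$m_values, genorm(worked_cq)$m_values)
})

test_that("NormFinder detects the planted noisy gene", {
  # perfect additivity: all stabilities zero
  sample_eff <- c(0, 1, 2, 3.5)
  cq <- rbind(A = 20 + sample_eff, B = 24 + sample_eff,
              C = 30 + sample_eff)
  expect_equal(unname(normfinder(cq)$stability), c(0, 0, 0))

  # one gene with added noise has the largest stability value
  set.seed(131)
  for (rep in 1:10) {
    eff <- rnorm(8, 0, 1)
    cq <- rbind(A = 20 + eff, B = 24 + eff, C = 27 + eff,
                D = 22 + eff + rnorm(8, 0, 1))
    nf <- normfinder(cq)
    expect_equal(names(which.max(nf$stability)), "D")
  }

  # invariant to per-gene constants
  cqs <- rbind(A = 20 + sample_eff + rnorm(4, 0, 0.1),
               B = 24 + sample_eff + rnorm(4, 0, 0.3),
               C = 30 + sample_eff + rnorm(4, 0, 0.5))
  expect_equal(normfinder(cqs + c(1, 2, 3))$stability,
               normfinder(cqs)$stability)
})

test_that("grouped NormFinder validates group sizes", {
  set.seed(141)
  cq <- rand_mat(4, 6, function(n) 20 + rnorm(n))
  expect_error(normfinder(cq, groups = c("a", "a", "a", "a", "a", "b")),
               "at least 2 samples")
  nf <- normfinder(cq, groups = rep(c("a", "b"), each = 3))
  expect_true(all(nf$stability >= 0))
  expect_true(nf$grouped)
})

test_that("BestKeeper descriptive statistics match hand values", {
  cq <- rbind(flat = c(21, 21, 21), g = c(20, 21, 22))
  bk <- bestkeeper(cq)
  expect_equal(unname(bk$sd["flat"]), 0)
  expect_equal(unname(bk$rank["flat"]), 1L)
  expect_equal(unname(bk$sd["g"]), 1.0)
  expect_equal(bk$index, apply(cq, 2, function(v) exp(mean(log(v)))))

  single <- bestkeeper(rbind(g = c(20, 21, 22)))
  expect_equal(unname(single$index), c(20, 21, 22))
  expect_equal(unname(single$r["g"]), 1)

  mad <- bestkeeper(cq, dispersion = "mad")
  expect_equal(unname(mad$sd["g"]), mean(abs(c(20, 21, 22) - 21)))
})

test_that("delta-Ct agrees with geNorm M at efficiency 2", {
  set.seed(151)
  cq <- rand_mat(5, 6, function(n) 20 + rnorm(n, 0, 1.5))
  expect_equal(delta_ct(cq)$mean_sd, genorm(cq, efficiency = 2)$m_values)
})

test_that("rank aggregation follows the geometric mean of ranks", {
  unanimous <- lapply(1:4, function(i) c(g1 = 1L, g2 = 2L))
  rf <- reffinder(unanimous)
  expect_equal(rf$geomean[rf$gene_id == "g1"], 1)
  expect_equal(rf$final_rank[rf$gene_id == "g1"], 1L)

  # gene "a" holds ranks (1,2,3,4): geometric mean 24^(1/4)
  rl <- list(w = c(a = 1, b = 2, c = 3, d = 4),
             x = c(a = 2, b = 1, c = 4, d = 3),
             y = c(a = 3, b = 4, c = 1, d = 2),
             z = c(a = 4, b = 3, c = 2, d = 1))
  rf4 <- reffinder(rl)
  expect_equal(rf4$geomean[rf4$gene_id == "a"], 24^(1 / 4),
               tolerance = 1e-9)
  # permuting the order of the input lists changes nothing
  expect_equal(reffinder(rl[c(3, 1, 4, 2)]), rf4)
  # geomean lies between the min and max of the four ranks
  mat <- sapply(rl, function(r) r[rf4$gene_id])
  expect_true(all(rf4$geomean >= apply(mat, 1, min) &
                  rf4$geomean <= apply(mat, 1, max)))

  expect_error(reffinder(list(c(a = 1, b = 2), c(a = 1, c = 2))),
               "mismatched")
  expect_error(reffinder(list(c(a = 1, b = 3))), "permutation")
})

test_that("all four algorithms are invariant to gene order", {
  set.seed(161)
  sim <- simulate_cq(seed = 99)
  cq <- sim$cq
  perm <- sample(nrow(cq))
  rep1 <- rank_reference_genes(cq)
  rep2 <- rank_reference_genes(cq[perm, ])
  t1 <- rep1$table[order(rep1$table$gene_id), ]
  t2 <- rep2$table[order(rep2$table$gene_id), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("per-algorithm ranks are permutations and aggregate sanely", {
  sim <- simulate_cq(seed = 7)
  rep <- rank_reference_genes(sim$cq)
  tab <- rep$table
  for (col in c("genorm_rank", "normfinder_rank", "bestkeeper_rank",
                "deltact_rank", "final_rank"))
    expect_setequal(tab[[col]], seq_len(nrow(tab)))
  expect_true(all(tab$reffinder_geomean >=
                    pmin(tab$genorm_rank, tab$normfinder_rank,
                         tab$bestkeeper_rank, tab$deltact_rank) - 1e-9))
  expect_true(all(tab$reffinder_geomean <=
                    pmax(tab$genorm_rank, tab$normfinder_rank,
                         tab$bestkeeper_rank, tab$deltact_rank) + 1e-9))
})

test_that("zero planted noise gives zero geNorm M for every gene", {
  sim <- simulate_cq(noise_sds = rep(0, 6), seed = 3)
  fit <- genorm(sim$cq)
  expect_equal(unname(fit$m_values), rep(0, 6))
})
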