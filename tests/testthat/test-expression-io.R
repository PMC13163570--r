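test_that("expression matrix round-trips through TSV unchanged", {
  vals <- matrix(c(0.5, 2, 10, 1, 0, 3.25), 3, 2,
                 dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m <- make_em(vals, tissue = c("liver", "liver"))
  mp <- withr::local_tempfile(fileext = ".tsv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  suppressMessages(write_expression_matrix(m, mp, dp))
  m2 <- suppressMessages(load_expression_matrix(mp, dp))
  expect_equal(dim(m2), c(3L, 2L))
  expect_equal(m2$values, m$values)
  expect_equal(m2$metadata, m$metadata)
})

test_that("validation rejects malformed input with informative errors", {
  vals <- rand_mat(3, 2)
  bad <- vals; bad[1, 1] <- -1
  expect_error(make_em(bad), "negative expression")
  meta <- data.frame(sample_id = "s1", tissue = "liver")
  expect_error(expression_matrix(vals, meta), "s2")
  dup <- vals; rownames(dup) <- c("g1", "g1", "g3")
  expect_error(make_em(dup), "duplicate gene")
  nonfin <- vals; nonfin[2, 2] <- Inf
  expect_error(make_em(nonfin), "finite")
  expect_error(make_em(vals, stage = "weaning"), "stage")
})

test_that("expression filter keeps exactly the genes above threshold", {
  vals <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("s1", "s2")))
  m <- make_em(vals, tissue = c("a", "b"))
  kept <- filter_expressed(m, min_tpm = 1, min_samples = 1)
  expect_equal(rownames(kept$values), "G2")

  pos <- make_em(rand_mat(10, 4, function(n) runif(n, 0.1, 5)))
  expect_equal(dim(filter_expressed(pos, min_tpm = 0)), c(10L, 4L))

  set.seed(11)
  big <- make_em(rand_mat(200, 10, function(n) rexp(n, 0.5)))
  for (ms in c(1L, 3L)) {
    f <- filter_expressed(big, min_tpm = 1, min_samples = ms)
    manual <- vapply(rownames(big$values), function(g)
      sum(big$values[g, ] > 1) >= ms, logical(1L))
    expect_equal(rownames(f$values), rownames(big$values)[manual])
  }

  # idempotence
  f1 <- filter_expressed(big)
  expect_equal(filter_expressed(f1)$values, f1$values)

  none <- make_em(rand_mat(3, 2, function(n) rep(0, n)))
  expect_warning(filter_expressed(none), "no gene")
})

test_that("replicate averaging matches independent per-group means", {
  vals <- matrix(c(4, 6), 1, 2,
                 dimnames = list("g1", c("s1", "s2")))
  m <- make_em(vals, tissue = c("liver", "liver"))
  expect_equal(unname(average_replicates(m)[1, "liver"]), 5)

  single <- make_em(rand_mat(5, 1), tissue = "spleen")
  expect_equal(average_replicates(single)[, "spleen"],
               single$values[, 1])

  set.seed(21)
  vals <- rand_mat(50, 8)
  tis <- rep(c("a", "b", "c", "d"), each = 2)
  m <- make_em(vals, tissue = tis)
  prof <- average_replicates(m)
  for (t in unique(tis))
    expect_equal(prof[, t], rowMeans(vals[, tis == t]))

  # commutes with gene reordering
  perm <- sample(nrow(vals))
  mp <- make_em(vals[perm, ], tissue = tis)
  expect_equal(average_replicates(mp), prof[perm, ])
})

test_that("stage averaging uses only stage-labelled samples", {
  vals <- rand_mat(4, 4)
  m <- make_em(vals, tissue = "mammary",
               stage = c("early", "early", "late", NA))
  prof <- average_replicates(m, by = "stage")
  expect_equal(colnames(prof), c("early", "late"))
  expect_equal(prof[, "early"], rowMeans(vals[, 1:2]))
  expect_equal(prof[, "late"], vals[, 3])
})

test_that("correlation matrices match hand-derived rank results", {
  x <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  cm <- correlate_profiles(x, "pearson")
  expect_equal(cm$rho["a", "b"], 1)

  y <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(correlate_profiles(y, "spearman")$rho["a", "b"], -1)

  z <- cbind(a = c(1, 2, 3), b = c(1, 3, 2))
  expect_equal(correlate_profiles(z, "spearman")$rho["a", "b"], 0.5)
})

test_that("correlation p-values agree with the t-approximation oracle", {
  set.seed(5)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  cm <- correlate_profiles(x, "pearson")
  for (i in 1:3) for (j in (i + 1):4) {
    ct <- cor.test(x[, i], x[, j])
    expect_equal(cm$rho[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cm$pvals[i, j], ct$p.value, tolerance = 1e-12)
  }
  expect_true(all(abs(cm$rho) <= 1))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$pvals, t(cm$pvals))
})

test_that("spearman correlation is invariant to monotone transforms", {
  set.seed(6)
  x <- cbind(a = rexp(20), b = rnorm(20))
  r0 <- correlate_profiles(x, "spearman")$rho["a", "b"]
  xt <- cbind(a = log(x[, "a"]), b = x[, "b"]^3)
  expect_equal(correlate_profiles(xt, "spearman")$rho["a", "b"], r0)
})

test_that("degenerate correlation inputs warn and report missing", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  expect_warning(cm <- correlate_profiles(x), "zero variance")
  expect_true(is.na(cm$rho["a", "b"]))
})

test_that("expressed gene counts use any-replicate detection per tissue", {
  vals <- matrix(c(1, 0, 0, 0,
                   5, 2, 0, 3), 2, 4, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  m <- make_em(vals, tissue = c("a", "a", "b", "b"))
  counts <- expressed_gene_counts(m)
  expect_equal(counts[["a"]], 2L)
  expect_equal(counts[["b"]], 1L)
})
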