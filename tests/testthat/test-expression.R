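test_that("size factors match hand-computed medians of ratios", {
  # identical columns: all factors 1
  m <- matrix(c(10, 40, 90), nrow = 3, ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))
  # doubling one column doubles its factor relative to the others
  m2 <- m; m2[, 2] <- 2 * m2[, 2]
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(unname(f[3] / f[1]), 1)
  # 3x3 hand example: factor_j = median_g count_gj / geomean_g
  h <- matrix(c(2, 8, 32,
                4, 8, 16,
                8, 8, 8), nrow = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  geo <- exp(rowMeans(log(h)))
  hand <- apply(h / geo, 2, median)
  expect_equal(size_factors(h), hand)
  # genes with any zero are excluded from the reference
  z <- rbind(m, c(0, 5, 5, 5))
  expect_equal(unname(size_factors(z)), rep(1, 4))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "nonzero")
  expect_error(size_factors(matrix(-1)), "negative")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- gen_counts(n_genes = 400,
                    group_labels = rep(c("progression", "suppression"),
                                       each = 4),
                    seed = 33)
  ours <- size_factors(sim$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  # identical up to median interpolation (ratio- vs log-ratio-scale median)
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("normalization divides by factors and drops unexpressed genes", {
  m <- matrix(c(10, 40, 0,
                10, 40, 0,
                20, 80, 0), nrow = 3, byrow = FALSE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  norm <- normalize_counts(m)
  expect_equal(nrow(norm), 2L)  # g3 unexpressed
  expect_false("g3" %in% rownames(norm))
  # scaling a column leaves its normalized expression profile
  # proportional (the scale moves into the size factor)
  m2 <- m; m2[, 3] <- c(5, 20, 0)
  n1 <- normalize_counts(m2)
  m3 <- m2; m3[, 3] <- 2 * m3[, 3]
  n2 <- normalize_counts(m3)
  ratio <- n2[, 3] / n1[, 3]
  expect_equal(ratio, rep(ratio[1], length(ratio)), ignore_attr = TRUE)
  # and the relative factor of the scaled column doubles
  f1 <- size_factors(m2[rowSums(m2) > 0, ])
  f2 <- size_factors(m3[rowSums(m3) > 0, ])
  expect_equal(unname((f2[3] / f2[1]) / (f1[3] / f1[1])), 2)
})

test_that("size factors recover the simulated depths within 10%", {
  sim <- gen_counts(n_genes = 2000,
                    group_labels = rep(c("progression", "suppression",
                                         "regression"), c(10, 13, 8)),
                    seed = 77)
  est <- size_factors(sim$counts)
  est <- est / exp(mean(log(est)))  # compare on the geomean-1 scale
  expect_lt(max(abs(est / sim$truth$size_factors - 1)), 0.10)
})

test_that("expression bins partition [0, Inf) at 100 and 1000", {
  expect_equal(as.character(bin_expression(c(0, 99, 99.999))),
               c("low", "low", "low"))
  expect_equal(as.character(bin_expression(c(100, 500, 1000))),
               c("mid", "mid", "mid"))
  expect_equal(as.character(bin_expression(c(1000.5, 1e6))),
               c("high", "high"))
  expect_error(bin_expression(-1), "non-negative")
  set.seed(2)
  x <- runif(500, 0, 2000)
  b <- bin_expression(x)
  expect_true(all((b == "low") == (x < 100)))
  expect_true(all((b == "mid") == (x >= 100 & x <= 1000)))
  expect_true(all((b == "high") == (x > 1000)))
})

test_that("planted efflux-pump-high samples are recovered by binning", {
  groups <- rep(c("progression", "suppression", "regression"), c(10, 13, 8))
  sim <- gen_counts(n_genes = 800, group_labels = groups, seed = 19)
  norm <- normalize_counts(sim$counts)
  bins <- bin_expression(norm["ABCB1", ])
  high <- colnames(norm)[bins == "high"]
  expect_equal(sort(high), sort(sim$truth$abcb1_high))
  expect_equal(length(high), 2L)
  # high samples sit in the progression group
  expect_true(all(sim$meta$group[sim$meta$sample_id %in% high] ==
                    "progression"))
  # everyone else is in the low bin
  expect_true(all(bins[!colnames(norm) %in% high] == "low"))
})

test_that("permutation p-values match exhaustive enumeration on 3 vs 3", {
  set.seed(101)
  counts <- matrix(rnbinom(10 * 6, mu = 200, size = 5), nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  counts[1, 1:3] <- counts[1, 1:3] * 6  # one shifted gene
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  res <- de_test(counts, a, b)
  # oracle: enumerate all choose(6,3) = 20 label splits directly
  norm <- normalize_counts(counts)
  l2 <- log2(norm + 1)
  obs <- rowMeans(l2[, a]) - rowMeans(l2[, b])
  splits <- combn(6, 3, simplify = FALSE)
  stats <- sapply(splits, function(s) {
    rowMeans(l2[, s, drop = FALSE]) - rowMeans(l2[, -s, drop = FALSE])
  })
  p_oracle <- rowMeans(abs(stats) >= abs(obs) - 1e-12)
  expect_equal(res$p, unname(p_oracle))
  expect_equal(res$log2fc, unname(obs))
  # BH oracle on the enumerated p-values
  n <- length(p_oracle)
  o <- order(p_oracle)
  q_hand <- numeric(n)
  q_hand[o] <- rev(cummin(rev(p_oracle[o] * n / seq_len(n))))
  expect_equal(res$q, pmin(unname(q_hand), 1))
})

test_that("identical groups give zero fold change and p of 1", {
  m <- matrix(rep(c(10, 50, 200, 800), 6), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  res <- de_test(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$log2fc, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
})

test_that("a batch confined to one group is rejected", {
  groups <- rep(c("progression", "suppression"), each = 4)
  sim <- gen_counts(n_genes = 100, group_labels = groups,
                    batch_labels = rep(c("b1", "b2"), each = 4), seed = 3)
  a <- sim$meta$sample_id[1:4]
  b <- sim$meta$sample_id[5:8]
  batch <- setNames(sim$meta$batch, sim$meta$sample_id)
  expect_error(de_test(sim$counts, a, b, batch = batch),
               "entirely within one group")
  # crossing the batches makes it legal
  a2 <- sim$meta$sample_id[c(1, 2, 5, 6)]
  b2 <- sim$meta$sample_id[c(3, 4, 7, 8)]
  expect_s3_class(de_test(sim$counts, a2, b2, batch = batch, n_perm = 200),
                  "data.frame")
})

test_that("batch centering absorbs a pure batch offset", {
  set.seed(12)
  base <- matrix(rnbinom(200 * 8, mu = 150, size = 8), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  shifted <- base
  shifted[, 5:8] <- round(shifted[, 5:8] * 3)  # batch 2 scaled 3x
  batch <- setNames(rep(c("b1", "b2"), each = 4), paste0("s", 1:8))
  a <- paste0("s", c(1, 2, 5, 6)); b <- paste0("s", c(3, 4, 7, 8))
  res <- de_test(shifted, a, b, batch = batch, n_perm = 500, seed = 5)
  # no group signal: fold changes hover near zero despite the 3x batch
  expect_lt(max(abs(res$log2fc)), 1)
  expect_gt(mean(res$p), 0.3)
})

test_that("an 8-fold planted gene ranks first by q in almost every run", {
  wins <- 0
  runs <- 20
  for (s in seq_len(runs)) {
    set.seed(1000 + s)
    counts <- matrix(rnbinom(300 * 8, mu = 120, size = 6), nrow = 300,
                     dimnames = list(sprintf("g%03d", 1:300),
                                     paste0("s", 1:8)))
    counts[7, 1:4] <- rnbinom(4, mu = 960, size = 6)  # 8-fold in group A
    res <- de_test(counts, paste0("s", 1:4), paste0("s", 5:8),
                   n_perm = 500, seed = s)
    top <- res$gene[order(res$q, -abs(res$log2fc))][1]
    wins <- wins + (top == "g007")
    v <- volcano(res)
    expect_equal(v$significant, res$q <= 0.05)
  }
  expect_gte(wins, runs - 1)
})

test_that("null permutation p-values are uniform (KS at alpha 0.01)", {
  set.seed(404)
  counts <- matrix(rnbinom(400 * 10, mu = 150, size = 8), nrow = 400,
                   dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:10)))
  res <- de_test(counts, paste0("s", 1:5), paste0("s", 6:10),
                 n_perm = 2000, seed = 11)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("volcano table flags significance and handles empty input", {
  empty <- volcano(data.frame(gene = character(0), log2fc = numeric(0),
                              p = numeric(0), q = numeric(0)))
  expect_equal(nrow(empty), 0L)
  v <- volcano(data.frame(gene = c("a", "b"), log2fc = c(2, -1),
                          p = c(0.001, 0.5), q = c(0.01, 0.6)))
  expect_equal(v$significant, c(TRUE, FALSE))
  expect_equal(v$neg_log10_p, -log10(c(0.001, 0.5)))
})
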