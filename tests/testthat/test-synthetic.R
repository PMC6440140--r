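test_that("truth construction plants the requested structure deterministically", {
  t1 <- make_truth(n_genes = 6, n_reversal_pairs = 2, noise_sd = 0, seed = 5)
  t2 <- make_truth(n_genes = 6, n_reversal_pairs = 2, noise_sd = 0, seed = 5)
  expect_identical(t1, t2)
  # templates differ on exactly the 4 genes of the 2 swaps
  expect_equal(sum(t1$mature_template != t1$immature_template), 4L)
  expect_equal(nrow(t1$planted_pairs), 2L)
  expect_true(all(t1$planted_pairs$gene_a < t1$planted_pairs$gene_b))
  # different seed, different assignment
  t3 <- make_truth(6, 2, noise_sd = 0, seed = 6)
  expect_false(identical(t1$mature_template, t3$mature_template))
})

test_that("templates contain no ties and no incidental reversals", {
  for (seed in 1:6) {
    tr <- make_truth(n_genes = 80, n_reversal_pairs = 15, noise_sd = 0.3,
                     seed = seed)
    expect_false(anyDuplicated(tr$mature_template) > 0)
    expect_false(anyDuplicated(tr$immature_template) > 0)
    # exhaustively compare template orderings: reversed pairs == planted
    mat <- tr$mature_template
    imm <- tr$immature_template
    ids <- as.integer(names(mat))
    rev_pairs <- list(); k <- 0L
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
      if (sign(mat[i] - mat[j]) != sign(imm[i] - imm[j])) {
        k <- k + 1L
        rev_pairs[[k]] <- c(min(ids[i], ids[j]), max(ids[i], ids[j]))
      }
    }
    got <- do.call(rbind, rev_pairs)
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(got[, 1], tr$planted_pairs$gene_a)
    expect_equal(got[, 2], tr$planted_pairs$gene_b)
    # margins respect the feasibility guarantee
    d <- abs(mat[as.character(tr$planted_pairs$gene_a)] -
             mat[as.character(tr$planted_pairs$gene_b)])
    expect_true(all(d > 4 * tr$noise_sd))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(make_truth(10, 6, seed = 1), "n_reversal_pairs")
  expect_error(make_truth(1, 0, seed = 1), "at least 2 genes")
  expect_error(make_truth(50, 5, noise_sd = 0.5, pair_margin = 1, seed = 1),
               "infeasible")
  expect_error(make_truth(10, 2, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("samplers are seed-reproducible and noise-free samples realize the template", {
  tr <- make_truth(40, 8, noise_sd = 0.2, seed = 9)
  a <- sample_condition(tr, "mature", 5, seed = 10)
  b <- sample_condition(tr, "mature", 5, seed = 10)
  expect_identical(a, b)
  c <- sample_condition(tr, "mature", 5, seed = 11)
  expect_false(identical(a, c))
  # zero noise: every sample realizes the template ordering exactly
  z <- sample_condition(tr, "immature", 3, noise_sd = 0, seed = 1)
  expect_true(all(z == tr$immature_template[rownames(z)]))
  # noise > 0: samples are non-degenerate
  expect_gt(stats::sd(a[1, ]), 0)
})

test_that("batch distortion is strictly order-preserving per sample", {
  tr <- make_truth(50, 10, noise_sd = 0.3, seed = 12)
  plain <- sample_condition(tr, "mature", 6, batch_distortion = FALSE,
                            seed = 77)
  batch <- sample_condition(tr, "mature", 6, batch_distortion = TRUE,
                            seed = 77)
  expect_false(identical(plain, batch))   # values really change
  for (s in seq_len(ncol(plain)))
    expect_identical(order(plain[, s]), order(batch[, s]))
  # hence identical stable pairs and identical scores
  expect_identical(find_stable_pairs(plain)$pairs,
                   find_stable_pairs(batch)$pairs)
})

test_that("mixtures interpolate between the conditions", {
  tr <- make_truth(40, 8, noise_sd = 0.2, seed = 14)
  m1 <- sample_mixture(tr, 1, 2, noise_sd = 0, seed = 1)
  m0 <- sample_mixture(tr, 0, 2, noise_sd = 0, seed = 1)
  expect_true(all(m1 == tr$mature_template[rownames(m1)]))
  expect_true(all(m0 == tr$immature_template[rownames(m0)]))
  expect_error(sample_mixture(tr, 1.5, 1, seed = 1), "alpha")
})

test_that("planted DEG targets lie beyond every former partner", {
  tr <- make_truth(100, 10, noise_sd = 0.3, n_deg_genes = 6, deg_fold = 20,
                   seed = 15)
  expect_equal(nrow(tr$planted_degs), 6L)
  up <- tr$planted_degs[tr$planted_degs$direction == "up", ]
  dn <- tr$planted_degs[tr$planted_degs$direction == "down", ]
  if (nrow(up))
    expect_true(all(up$value > max(tr$mature_template) + log2(20) - 1e-9))
  if (nrow(dn))
    expect_true(all(dn$value < min(tr$mature_template) - log2(20) + 1e-9))
  # planted DEGs never overlap planted reversal pairs
  expect_length(intersect(tr$planted_degs$gene_id,
                          c(tr$planted_pairs$gene_a, tr$planted_pairs$gene_b)),
                0L)
})
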