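backbone_from <- function(df) {
  build_backbone(structure(
    list(pairs = df, condition_label = "ref", n_samples = 2L,
         stability_fraction = 1,
         gene_ids = sort(unique(c(df$gene_a, df$gene_b)))),
    class = "stable_pairs"))
}

test_that("backbone partner index agrees with a direct scan of all pairs", {
  df <- data.frame(gene_a = c(1L, 1L), gene_b = c(2L, 3L), direction = "gt")
  bb <- backbone_from(df)
  expect_setequal(bb$below[["1"]], c(2L, 3L))
  expect_setequal(bb$above[["2"]], 1L)
  expect_length(bb$below[["2"]], 0L)

  set.seed(17)
  for (rep in 1:5) {
    x <- rand_expr(20, 3, seed = 600 + rep)
    sp <- find_stable_pairs(x)
    bb <- build_backbone(sp)
    p <- sp$pairs
    for (g in bb$genes) {
      below_direct <- sort(c(p$gene_b[p$gene_a == g & p$direction == "gt"],
                             p$gene_a[p$gene_b == g & p$direction == "lt"]))
      above_direct <- sort(c(p$gene_b[p$gene_a == g & p$direction == "lt"],
                             p$gene_a[p$gene_b == g & p$direction == "gt"]))
      expect_identical(sort(bb$below[[as.character(g)]]), below_direct)
      expect_identical(sort(bb$above[[as.character(g)]]), above_direct)
      expect_length(intersect(bb$below[[as.character(g)]],
                              bb$above[[as.character(g)]]), 0L)
    }
  }
})

test_that("gene contingency cross-classifies partners with the consensus rule", {
  # gene 5 exceeds 1,2 and is exceeded by 8,9 in the reference
  df <- data.frame(gene_a = c(1L, 2L, 5L, 5L), gene_b = c(5L, 5L, 8L, 9L),
                   direction = c("lt", "lt", "lt", "lt"))
  bb <- backbone_from(df)
  # test replicates preserve every ordering
  test <- mk_expr(c(1, 1, 2, 2, 5, 5, 8, 8, 9, 9), c(1, 2, 5, 8, 9),
                  c("r1", "r2"))
  tab <- gene_contingency(5L, bb, test)
  expect_equal(unname(tab), matrix(c(2L, 0L, 0L, 2L), 2))

  # full reversal of the two below-partners (Ng=2 side)
  df2 <- data.frame(gene_a = c(1L, 2L), gene_b = c(5L, 5L),
                    direction = c("lt", "lt"))
  bb2 <- backbone_from(df2)
  test2 <- mk_expr(c(9, 9, 8, 8, 5, 5), c(1, 2, 5), c("r1", "r2"))
  tab2 <- gene_contingency(5L, bb2, test2)
  expect_equal(unname(tab2), matrix(c(0L, 0L, 2L, 0L), 2))

  # replicates disagreeing on one partner exclude it (margins shrink by 1)
  test3 <- mk_expr(c(1, 9, 2, 2, 5, 5), c(1, 2, 5), c("r1", "r2"))
  tab3 <- gene_contingency(5L, bb2, test3)
  expect_equal(sum(tab3), 1L)
  expect_equal(tab3["below", "below"], 1L)

  # a tie in any replicate also excludes the partner
  test4 <- mk_expr(c(5, 1, 2, 2, 5, 5), c(1, 2, 5), c("r1", "r2"))
  expect_equal(sum(gene_contingency(5L, bb2, test4)), 1L)

  expect_error(gene_contingency(99L, bb2, test2), "no reference partners")
  test5 <- mk_expr(c(1, 1, 2, 2), c(1, 2), c("r1", "r2"))
  expect_error(gene_contingency(5L, bb2, test5), "absent from test")
})

test_that("two-sided Fisher p matches hand-enumerated values", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-9)
  expect_equal(fisher_exact_two_sided(matrix(c(1, 1, 1, 1), 2)), 1.0)
  # degenerate margins carry no information
  expect_equal(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)), 1.0)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})

test_that("Fisher p matches the enumeration oracle on random tables", {
  set.seed(123)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    expect_equal(fisher_exact_two_sided(tab), oracle_fisher_two_sided(tab),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj <= 1))
    # permutation invariance up to matching reorder
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm])
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("planted extreme shifts are called with the right direction", {
  truth <- make_truth(120, 0, noise_sd = 0.25, n_deg_genes = 8, seed = 31)
  ref <- sample_condition(truth, "mature", 20, seed = 32)
  test <- sample_deg_replicates(truth, 3, seed = 33)
  degs <- cellcomp(ref, test)
  hits <- degs[match(truth$planted_degs$gene_id, degs$gene_id), ]
  expect_true(all(hits$fdr < 0.05))
  expect_identical(hits$direction, truth$planted_degs$direction)
})

test_that("null replicates yield no calls and single-replicate input runs", {
  truth <- make_truth(120, 0, noise_sd = 0.25, seed = 41)
  ref <- sample_condition(truth, "mature", 20, seed = 42)
  null_test <- sample_condition(truth, "mature", 3, seed = 43)
  degs <- cellcomp(ref, null_test)
  expect_equal(sum(degs$direction != "none"), 0L)

  one_rep <- sample_condition(truth, "mature", 1, seed = 44)
  degs1 <- cellcomp(ref, one_rep)
  expect_gt(nrow(degs1), 0L)
  expect_true(all(degs1$direction == "none"))
})

test_that("call_degs output is deterministic, gene-ordered, and serialisable", {
  truth <- make_truth(60, 0, noise_sd = 0.25, n_deg_genes = 4, seed = 51)
  ref <- sample_condition(truth, "mature", 15, seed = 52)
  test <- sample_deg_replicates(truth, 2, seed = 53)
  bb <- build_backbone(find_stable_pairs(ref))
  d1 <- call_degs(bb, test)
  d2 <- call_degs(bb, test)
  expect_identical(d1, d2)
  expect_false(is.unsorted(d1$gene_id))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_degs(d1, path)
  back <- utils::read.delim(path)
  expect_equal(back$gene_id, d1$gene_id)
  expect_equal(back$fdr, d1$fdr, tolerance = 1e-12)
  # more than 3 replicates violates the small-replicate design
  four <- sample_condition(truth, "mature", 4, seed = 54)
  expect_error(call_degs(bb, four), "1-3 test replicates")
})
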