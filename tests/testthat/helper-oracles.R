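# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (exhaustive enumeration,
# closed forms) and never call the package functions they are checking.

# exhaustive O(n^2 * m) stable-pair scan: every unordered pair vs every sample
oracle_stable_pairs <- function(x, fraction = 1) {
  ids <- as.integer(rownames(x))
  ord <- order(ids)
  x <- x[ord, , drop = FALSE]
  ids <- ids[ord]
  n <- nrow(x)
  m <- ncol(x)
  thresh <- ceiling(fraction * m)
  rows <- list()
  k <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gt <- sum(x[i, ] > x[j, ])
        lt <- sum(x[i, ] < x[j, ])
        dir <- if (gt >= thresh) "gt" else if (lt >= thresh) "lt" else NA
        if (!is.na(dir)) {
          k <- k + 1L
          rows[[k]] <- data.frame(gene_a = ids[i], gene_b = ids[j],
                                  direction = dir, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(gene_a = integer(0), gene_b = integer(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# enumerate pairs stable in both conditions with opposite directions
oracle_reversal <- function(mature_pairs, immature_pairs) {
  if (nrow(mature_pairs) == 0L || nrow(immature_pairs) == 0L)
    return(mature_pairs[0, ])
  keys_m <- paste(mature_pairs$gene_a, mature_pairs$gene_b)
  keys_i <- paste(immature_pairs$gene_a, immature_pairs$gene_b)
  keep <- logical(nrow(mature_pairs))
  for (r in seq_len(nrow(mature_pairs))) {
    hit <- which(keys_i == keys_m[r])
    keep[r] <- length(hit) == 1L &&
      immature_pairs$direction[hit] != mature_pairs$direction[r]
  }
  out <- mature_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with the
# observed margins, summing probabilities <= observed (min-likelihood rule)
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1.0)
  xs <- max(0L, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
  obs <- pr[xs == tab[1L, 1L]]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up rule written directly from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1L):1L) if (m > 1L)
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1L])
  pmin(1, adj_sorted)[order(o)]
}

# upper-tail hypergeometric by summing the pmf over overlap counts
oracle_hyper_tail <- function(overlap, set_size, universe_size, list_size) {
  if (overlap == 0L) return(1.0)
  xs <- overlap:min(set_size, list_size)
  sum(choose(set_size, xs) * choose(universe_size - set_size, list_size - xs)) /
    choose(universe_size, list_size)
}

# random expression matrix with integer gene IDs and no ties (continuous)
rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  ids <- sort(sample.int(10 * n_genes, n_genes))
  m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(ids, paste0("s", seq_len(n_samples))))
  m
}

mk_expr <- function(values_by_row, ids, samples) {
  matrix(values_by_row, nrow = length(ids), byrow = TRUE,
         dimnames = list(ids, samples))
}

pairs_df <- function(sp) if (inherits(sp, "stable_pairs")) sp$pairs else sp

expect_same_pairs <- function(got, want) {
  got <- pairs_df(got); want <- pairs_df(want)
  got <- got[order(got$gene_a, got$gene_b), , drop = FALSE]
  want <- want[order(want$gene_a, want$gene_b), , drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
}
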