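#' Discover gene pairs with condition-wide stable relative orderings
#'
#' For every unordered gene pair (Gi, Gj) the within-sample comparison is a
#' two-outcome event: Gi > Gj or Gi < Gj (a tie supports neither outcome).
#' A pair is *highly stable* in a condition when one outcome holds in at
#' least `ceiling(stability_fraction * n_samples)` of the accumulated
#' samples; with the default `stability_fraction = 1` this is the
#' "identical ordering in all samples" rule, and any tie disqualifies the
#' pair. Because only within-sample comparisons are used, the result is
#' invariant to any strictly increasing per-sample transformation of the
#' values (batch effects, normalisation).
#'
#' The all-pairs scan (about n^2/2 pairs for n genes) runs in gene blocks
#' of `block_size` rows, accumulating per-block ordering counts, so peak
#' memory is bounded by a few `block_size^2` matrices regardless of the
#' total number of pairs.
#'
#' @param x gene-by-sample expression matrix (see [as_expression_matrix()]).
#' @param stability_fraction required fraction of supporting samples, in
#'   (0.5, 1]. Values below 1 are an extension of the all-samples rule.
#' @param condition_label optional label stored with the result.
#' @param block_size number of gene rows per block of the pairwise scan.
#' @return an object of class `stable_pairs`: a list with `pairs` (a
#'   data.frame of `gene_a` < `gene_b` integer IDs and `direction`, `"gt"`
#'   meaning expr(gene_a) > expr(gene_b) in the supporting samples, `"lt"`
#'   the reverse), `condition_label`, `n_samples`, `stability_fraction`
#'   and the gene universe `gene_ids`. Pairs are sorted by (gene_a, gene_b).
#' @examples
#' m <- matrix(c(5, 6, 3, 4, 1, 2), nrow = 3, byrow = TRUE,
#'             dimnames = list(c(1, 2, 3), c("s1", "s2")))
#' find_stable_pairs(m)
#' @export
find_stable_pairs <- function(x, stability_fraction = 1,
                              condition_label = "condition",
                              block_size = 1024L) {
  x <- as_expression_matrix(x)
  if (!is.numeric(stability_fraction) || length(stability_fraction) != 1L ||
      stability_fraction <= 0.5 || stability_fraction > 1)
    stop("stability_fraction must be in (0.5, 1]", call. = FALSE)
  block_size <- max(2L, as.integer(block_size))
  n <- nrow(x)
  m <- ncol(x)
  ids <- gene_ids(x)
  thresh <- ceiling(stability_fraction * m)

  acc_a <- list(); acc_b <- list(); acc_d <- list(); k <- 0L
  if (n >= 2L) {
    starts <- seq.int(1L, n, by = block_size)
    nb <- length(starts)
    for (bi in seq_len(nb)) {
      ri <- starts[bi]:min(starts[bi] + block_size - 1L, n)
      A <- x[ri, , drop = FALSE]
      for (bj in bi:nb) {
        rj <- starts[bj]:min(starts[bj] + block_size - 1L, n)
        B <- x[rj, , drop = FALSE]
        gt <- matrix(0L, length(ri), length(rj))
        lt <- gt
        for (s in seq_len(m)) {
          d <- outer(A[, s], B[, s], `-`)
          gt <- gt + (d > 0)
          lt <- lt + (d < 0)
        }
        if (bi == bj) {
          # keep strict upper triangle: row index < col index <=> id_a < id_b
          keep <- .row(dim(gt)) < .col(dim(gt))
          gt[!keep] <- 0L
          lt[!keep] <- 0L
        }
        hit_gt <- which(gt >= thresh, arr.ind = TRUE, useNames = FALSE)
        hit_lt <- which(lt >= thresh, arr.ind = TRUE, useNames = FALSE)
        if (nrow(hit_gt) || nrow(hit_lt)) {
          k <- k + 1L
          acc_a[[k]] <- c(ids[ri][hit_gt[, 1L]], ids[ri][hit_lt[, 1L]])
          acc_b[[k]] <- c(ids[rj][hit_gt[, 2L]], ids[rj][hit_lt[, 2L]])
          acc_d[[k]] <- rep(c("gt", "lt"), c(nrow(hit_gt), nrow(hit_lt)))
        }
      }
    }
  }
  pairs <- data.frame(gene_a = as.integer(unlist(acc_a)),
                      gene_b = as.integer(unlist(acc_b)),
                      direction = as.character(unlist(acc_d)),
                      stringsAsFactors = FALSE)
  if (nrow(pairs)) pairs <- pairs[order(pairs$gene_a, pairs$gene_b), ,
                                  drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 condition_label = condition_label,
                 n_samples = m,
                 stability_fraction = stability_fraction,
                 gene_ids = ids),
            class = "stable_pairs")
}

#' @export
print.stable_pairs <- function(x, ...) {
  cat(sprintf(
    "Stable gene pairs [%s]: %d pairs over %d genes (%d samples, fraction %.3g)\n",
    x$condition_label, nrow(x$pairs), length(x$gene_ids), x$n_samples,
    x$stability_fraction))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 6L))
  if (nrow(x$pairs) > 6L) cat("...\n")
  invisible(x)
}

# canonical string key for unordered pairs; used for set operations
pair_key <- function(a, b) paste(a, b, sep = "_")
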