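#' Build a reference backbone of per-gene ordering partners
#'
#' From the highly stable gene pairs of an accumulated reference condition,
#' indexes for every gene the set of partner genes it exceeds (`below`) and
#' the set that exceed it (`above`) in all reference samples. Genes with no
#' partners do not appear in the backbone and cannot be tested.
#'
#' @param reference_stable a [find_stable_pairs()] result for the reference
#'   condition.
#' @return object of class `reo_backbone`: list with `below` and `above`
#'   (named lists gene ID -> integer partner vectors), `genes` (sorted
#'   integer vector of testable genes) and `condition_label`.
#' @export
build_backbone <- function(reference_stable) {
  stopifnot(inherits(reference_stable, "stable_pairs"))
  p <- reference_stable$pairs
  # pair (a, b, gt): a exceeds b; pair (a, b, lt): b exceeds a
  winner <- ifelse(p$direction == "gt", p$gene_a, p$gene_b)
  loser <- ifelse(p$direction == "gt", p$gene_b, p$gene_a)
  genes <- sort(unique(c(p$gene_a, p$gene_b)))
  below <- lapply(split(loser, factor(winner, levels = genes)), as.integer)
  above <- lapply(split(winner, factor(loser, levels = genes)), as.integer)
  structure(list(below = below, above = above, genes = genes,
                 condition_label = reference_stable$condition_label),
            class = "reo_backbone")
}

#' @export
print.reo_backbone <- function(x, ...) {
  cat(sprintf("REO reference backbone [%s]: %d genes, %d stable pairs\n",
              x$condition_label, length(x$genes),
              sum(lengths(x$below))))
  invisible(x)
}

as_test_matrix <- function(test_samples) {
  if (is.list(test_samples) && !is.data.frame(test_samples))
    test_samples <- do.call(cbind, test_samples)
  if (is.numeric(test_samples) && is.null(dim(test_samples)))
    test_samples <- cbind(replicate1 = test_samples)
  if (!is.matrix(test_samples) || is.null(rownames(test_samples)))
    stop("test samples must be a named vector, a matrix with gene rownames,",
         " or a list of named vectors", call. = FALSE)
  if (is.null(colnames(test_samples)))
    colnames(test_samples) <- paste0("replicate", seq_len(ncol(test_samples)))
  if (ncol(test_samples) < 1L || ncol(test_samples) > 3L)
    stop("CellComp is designed for 1-3 test replicates, got ",
         ncol(test_samples), call. = FALSE)
  if (!all(is.finite(test_samples)))
    stop("non-finite value in test samples", call. = FALSE)
  test_samples
}

#' Cross-classify a gene's reference partners by their test-sample ordering
#'
#' Rows are the reference classification of the gene's partners (ordered
#' below the gene, i.e. the gene exceeds them, versus ordered above);
#' columns are the same classification from the test replicates. A partner
#' enters the table only if all test replicates agree on a strict ordering
#' against the gene (the replicate consensus rule); partners tied or
#' inconsistent across replicates -- or missing from the test matrix -- are
#' excluded, shrinking the margins.
#'
#' @param gene integer gene ID present in the backbone.
#' @param backbone a [build_backbone()] result.
#' @param test_samples 1-3 test replicates: named numeric vector, list of
#'   them, or gene-by-replicate matrix.
#' @return 2x2 integer matrix with dimnames
#'   `ref` = below/above x `test` = below/above.
#' @export
gene_contingency <- function(gene, backbone, test_samples) {
  stopifnot(inherits(backbone, "reo_backbone"))
  test <- as_test_matrix(test_samples)
  key <- as.character(gene)
  below <- backbone$below[[key]]
  above <- backbone$above[[key]]
  if (length(below) + length(above) == 0L)
    stop("gene ", gene, " has no reference partners", call. = FALSE)
  if (!key %in% rownames(test))
    stop("gene ", gene, " absent from test samples", call. = FALSE)
  partners <- c(below, above)
  ref_below <- rep(c(TRUE, FALSE), c(length(below), length(above)))
  present <- as.character(partners) %in% rownames(test)
  partners <- partners[present]
  ref_below <- ref_below[present]
  g_val <- test[key, ]
  pv <- test[as.character(partners), , drop = FALSE]
  d <- rep(g_val, each = nrow(pv)) - pv
  test_below <- rowSums(d > 0) == ncol(test)   # gene exceeds partner in all reps
  test_above <- rowSums(d < 0) == ncol(test)
  consensus <- test_below | test_above
  tab <- matrix(c(sum(ref_below & consensus & test_below),
                  sum(!ref_below & consensus & test_below),
                  sum(ref_below & consensus & test_above),
                  sum(!ref_below & consensus & test_above)),
                nrow = 2L,
                dimnames = list(ref = c("below", "above"),
                                test = c("below", "above")))
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Two-sided by the minimum-likelihood rule: the p-value sums the
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed the observed table's (within relative
#' tolerance 1e-7). A table with a zero row or column margin carries no
#' information and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return the p-value, in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop("expected a 2x2 table", call. = FALSE)
  if (any(!is.finite(table)) || any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(1.0)
  # guard against p marginally above 1 from floating-point accumulation
  min(1, stats::fisher.test(table, alternative = "two.sided")$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates inputs and applies the step-up rule
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' REO-based differential expression for small-replicate test samples
#'
#' For each testable gene, compares the split of its reference ordering
#' partners (how many it exceeds, `Ng`, versus how many exceed it, `Nl`)
#' with the same split in the test-replicate consensus (`ng`, `nl`),
#' restricted to partners on which all replicates agree strictly. Fisher's
#' exact test on the condition-by-direction table `[[Ng, Nl], [ng, nl]]`
#' asks whether the gene's position in the ordering backbone has shifted;
#' BH FDR is applied across genes, and significant genes are called `up`
#' when the test proportion of exceeded partners is larger than the
#' reference proportion, `down` when smaller.
#'
#' @param backbone a [build_backbone()] result from the accumulated
#'   reference condition.
#' @param test_samples 1-3 test replicates (named vector, list, or matrix).
#' @param fdr_threshold significance threshold on the BH-adjusted p-value.
#' @param min_partners genes with fewer reference partners than this are
#'   not tested (tiny margins make the exact test uninformative).
#' @return object of class `cellcomp` (a data.frame): one row per tested
#'   gene, ordered by gene ID, with columns `gene_id`, `n_greater_ref`,
#'   `n_less_ref`, `n_greater_test`, `n_less_test`, `p_value`, `fdr`,
#'   `direction` (`up`/`down`/`none`).
#' @export
call_degs <- function(backbone, test_samples, fdr_threshold = 0.05,
                      min_partners = 5L) {
  stopifnot(inherits(backbone, "reo_backbone"))
  test <- as_test_matrix(test_samples)
  genes <- intersect(backbone$genes, as.integer(rownames(test)))
  genes <- genes[vapply(as.character(genes), function(k) {
    length(backbone$below[[k]]) + length(backbone$above[[k]]) >= min_partners
  }, TRUE)]
  if (length(genes) == 0L) {
    warning("no testable genes (none shared with test samples with >= ",
            min_partners, " partners)", call. = FALSE)
    return(empty_deg_frame())
  }
  rows <- lapply(genes, function(g) {
    tab <- gene_contingency(g, backbone, test)
    ng_ref <- sum(tab["below", ])   # partners the gene exceeds in reference
    nl_ref <- sum(tab["above", ])
    ng_test <- sum(tab[, "below"])
    nl_test <- sum(tab[, "above"])
    cond_tab <- matrix(c(ng_ref, ng_test, nl_ref, nl_test), nrow = 2L)
    data.frame(gene_id = g, n_greater_ref = ng_ref, n_less_ref = nl_ref,
               n_greater_test = ng_test, n_less_test = nl_test,
               p_value = fisher_exact_two_sided(cond_tab),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p_value)
  tot_ref <- res$n_greater_ref + res$n_less_ref
  tot_test <- res$n_greater_test + res$n_less_test
  prop_ref <- ifelse(tot_ref > 0, res$n_greater_ref / tot_ref, NA_real_)
  prop_test <- ifelse(tot_test > 0, res$n_greater_test / tot_test, NA_real_)
  res$direction <- ifelse(
    res$fdr < fdr_threshold & !is.na(prop_test) & prop_test != prop_ref,
    ifelse(prop_test > prop_ref, "up", "down"), "none")
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("cellcomp", "data.frame"),
            fdr_threshold = fdr_threshold, min_partners = min_partners,
            n_replicates = ncol(test))
}

empty_deg_frame <- function() {
  structure(
    data.frame(gene_id = integer(0), n_greater_ref = integer(0),
               n_less_ref = integer(0), n_greater_test = integer(0),
               n_less_test = integer(0), p_value = numeric(0),
               fdr = numeric(0), direction = character(0),
               stringsAsFactors = FALSE),
    class = c("cellcomp", "data.frame"))
}

#' One-step CellComp wrapper
#'
#' Builds the stable-pair backbone from accumulated reference expression
#' data and calls differentially expressed genes in 1-3 test replicates.
#'
#' @param reference reference condition: expression matrix, list of
#'   matrices (pooled), or a precomputed `stable_pairs` object.
#' @param test_samples 1-3 test replicates (named vector, list, or matrix).
#' @param stability_fraction passed to [find_stable_pairs()].
#' @param fdr_threshold,min_partners see [call_degs()].
#' @return a `cellcomp` data.frame, see [call_degs()].
#' @export
cellcomp <- function(reference, test_samples, stability_fraction = 1,
                     fdr_threshold = 0.05, min_partners = 5L) {
  ref <- as_stable_pairs(reference, stability_fraction, label = "reference",
                         block_size = 1024L)
  call_degs(build_backbone(ref), test_samples,
            fdr_threshold = fdr_threshold, min_partners = min_partners)
}

#' @export
print.cellcomp <- function(x, ...) {
  thr <- attr(x, "fdr_threshold") %||% 0.05
  cat(sprintf("CellComp: %d genes tested, %d DEGs at FDR < %g (%d up, %d down)\n",
              nrow(x), sum(x$direction != "none"), thr,
              sum(x$direction == "up"), sum(x$direction == "down")))
  invisible(x)
}

#' @export
summary.cellcomp <- function(object, ...) {
  print(object)
  sig <- object[object$direction != "none", , drop = FALSE]
  if (nrow(sig)) {
    sig <- sig[order(sig$fdr, sig$p_value), , drop = FALSE]
    cat("Top calls:\n")
    print(utils::head(as.data.frame(sig), 10L), row.names = FALSE)
  }
  invisible(object)
}

#' Write a CellComp result table to TSV
#'
#' Columns: `gene_id`, `Ng`, `Nl`, `ng_test`, `nl_test`, `p`, `fdr`,
#' `direction`.
#'
#' @param degs a `cellcomp` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_degs <- function(degs, path) {
  out <- data.frame(gene_id = degs$gene_id, Ng = degs$n_greater_ref,
                    Nl = degs$n_less_ref, ng_test = degs$n_greater_test,
                    nl_test = degs$n_less_test, p = degs$p_value,
                    fdr = degs$fdr, direction = degs$direction)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
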