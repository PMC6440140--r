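#' Score one sample against a reversal signature
#'
#' The maturity score of a sample is k/n: `k` counts signature pairs whose
#' strict within-sample ordering equals the stored mature-condition
#' direction, and the denominator is the number of *evaluable* pairs (both
#' genes measured in the sample). A tied pair is not the mature ordering,
#' so it does not count toward k, but it remains in the denominator. When
#' every signature gene is measured the denominator equals the full
#' signature size n. A score near 1 means the sample's orderings are close
#' to the mature condition; near 0, close to the immature condition.
#'
#' @param values named numeric vector: names are gene IDs, values the
#'   sample's expression on any monotone scale.
#' @param sig a [reo_signature()].
#' @param sample_id identifier recorded in the result.
#' @return one-row data.frame: `sample_id`, `k`, `n_evaluable`,
#'   `n_signature`, `score`.
#' @export
score_sample <- function(values, sig, sample_id = "sample") {
  stopifnot(inherits(sig, "reo_signature"))
  if (is.null(names(values)) || !is.numeric(values))
    stop("sample values must be a named numeric vector (names = gene IDs)",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("non-finite value in sample ", sample_id, call. = FALSE)
  va <- values[as.character(sig$pairs$gene_a)]
  vb <- values[as.character(sig$pairs$gene_b)]
  evaluable <- !is.na(va) & !is.na(vb)
  n_eval <- sum(evaluable)
  if (n_eval == 0L)
    stop("signature not evaluable on sample ", sample_id,
         ": no pair has both genes measured", call. = FALSE)
  d <- va[evaluable] - vb[evaluable]
  want_gt <- sig$pairs$direction[evaluable] == "gt"
  k <- sum(ifelse(want_gt, d > 0, d < 0))
  data.frame(sample_id = sample_id, k = as.integer(k),
             n_evaluable = as.integer(n_eval), n_signature = sig$n,
             score = k / n_eval, stringsAsFactors = FALSE)
}

#' Score every sample of an expression matrix, with replicate averaging
#'
#' Computes per-sample maturity scores and, when a replicate grouping is
#' supplied, the final score of each technical-replicate group as the
#' unweighted arithmetic mean of its members' scores.
#'
#' @param x gene-by-sample expression matrix.
#' @param sig a [reo_signature()].
#' @param groups optional replicate grouping: a data.frame with columns
#'   `sample_id` and `group_id` (extra columns ignored), or a named
#'   character vector `sample_id -> group_id`. It may cover a subset of
#'   samples; every referenced sample must exist in `x`.
#' @return object of class `maturity_scores`: list with `samples` (one row
#'   per sample, input order) and `groups` (one row per group in first-
#'   appearance order, with `members` as a comma-separated list and
#'   `final_score`; `NULL` when no grouping given).
#' @export
score_matrix <- function(x, sig, groups = NULL) {
  x <- as_expression_matrix(x)
  per_sample <- do.call(rbind, lapply(colnames(x), function(s) {
    v <- x[, s]
    names(v) <- rownames(x)
    score_sample(v, sig, sample_id = s)
  }))
  rownames(per_sample) <- NULL
  grp_df <- NULL
  if (!is.null(groups)) {
    groups <- normalize_groups(groups)
    unknown <- setdiff(groups$sample_id, colnames(x))
    if (length(unknown))
      stop("replicate group references unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    gids <- unique(groups$group_id)
    grp_df <- do.call(rbind, lapply(gids, function(g) {
      members <- groups$sample_id[groups$group_id == g]
      sc <- per_sample$score[match(members, per_sample$sample_id)]
      data.frame(group_id = g, members = paste(members, collapse = ","),
                 n_members = length(members), final_score = mean(sc),
                 stringsAsFactors = FALSE)
    }))
    rownames(grp_df) <- NULL
  }
  structure(list(samples = per_sample, groups = grp_df),
            class = "maturity_scores")
}

normalize_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group_id") %in% names(groups)))
      stop("groups data.frame needs columns sample_id and group_id",
           call. = FALSE)
    df <- groups[, c("sample_id", "group_id")]
  } else if (is.character(groups) && !is.null(names(groups))) {
    df <- data.frame(sample_id = names(groups), group_id = unname(groups),
                     stringsAsFactors = FALSE)
  } else {
    stop("groups must be a data.frame(sample_id, group_id) or a named vector",
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id))
    stop("a sample may belong to at most one replicate group", call. = FALSE)
  df
}

#' Predict method for reversal signatures: maturity scoring
#'
#' `predict(sig, newdata)` scores the samples of `newdata` against the
#' signature; it is a thin wrapper around [score_matrix()].
#'
#' @param object a [reo_signature()].
#' @param newdata gene-by-sample expression matrix.
#' @param groups optional replicate grouping, see [score_matrix()].
#' @param ... unused.
#' @return a `maturity_scores` object.
#' @export
predict.reo_signature <- function(object, newdata, groups = NULL, ...) {
  score_matrix(newdata, object, groups = groups)
}

#' @export
print.maturity_scores <- function(x, ...) {
  cat(sprintf("Maturity scores for %d sample(s) (signature n = %d)\n",
              nrow(x$samples), x$samples$n_signature[1L]))
  print(x$samples, row.names = FALSE)
  if (!is.null(x$groups)) {
    cat("Replicate-group final scores:\n")
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}

#' Write maturity scores to TSV
#'
#' Writes `sample_id<TAB>k<TAB>n_evaluable<TAB>n_signature<TAB>score`; when
#' replicate groups are present a companion file `<path>.groups.tsv` (or
#' `groups_path`) with `group_id<TAB>members<TAB>final_score` is written.
#'
#' @param scores a `maturity_scores` object from [score_matrix()].
#' @param path output TSV path for per-sample scores.
#' @param groups_path optional path for the group table.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, groups_path = NULL) {
  stopifnot(inherits(scores, "maturity_scores"))
  utils::write.table(scores$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scores$groups)) {
    gp <- groups_path %||% paste0(path, ".groups.tsv")
    utils::write.table(
      scores$groups[, c("group_id", "members", "final_score")], gp,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
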