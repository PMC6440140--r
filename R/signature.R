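#' Build a reversal REO signature between a mature and an immature condition
#'
#' A *stable reversal gene pair* is ordered one way in every accumulated
#' sample of the mature condition and the opposite way in every sample of
#' the immature condition. The signature stores, for each such pair, the
#' ordering observed in the mature condition -- the golden standard against
#' which new samples are scored (see [predict.reo_signature()] /
#' [score_matrix()]).
#'
#' `mature` and `immature` may each be an expression matrix, a list of
#' matrices (pooled over their common gene universe with
#' [pool_expression_matrices()]), or a precomputed [find_stable_pairs()]
#' result.
#'
#' @param mature,immature expression data (or `stable_pairs`) for the two
#'   conditions.
#' @param stability_fraction passed to [find_stable_pairs()] when matrices
#'   are given; 1 reproduces the all-samples rule.
#' @param mature_label,immature_label condition labels recorded in the
#'   signature (defaults taken from `stable_pairs` inputs when available).
#' @param block_size passed to [find_stable_pairs()].
#' @return an object of class `reo_signature`: list with `pairs`
#'   (data.frame `gene_a` < `gene_b`, `direction` of the *mature*
#'   condition), `n` (= number of pairs), labels, and the per-condition
#'   stable-pair counts `n_stable_mature` / `n_stable_immature`.
#' @examples
#' mat <- matrix(c(9, 8, 5, 6, 1, 2), 3, byrow = TRUE,
#'               dimnames = list(1:3, c("m1", "m2")))
#' imm <- matrix(c(1, 2, 5, 6, 9, 8), 3, byrow = TRUE,
#'               dimnames = list(1:3, c("e1", "e2")))
#' sig <- reo_signature(mat, imm)
#' sig$n
#' @export
reo_signature <- function(mature, immature, stability_fraction = 1,
                          mature_label = NULL, immature_label = NULL,
                          block_size = 1024L) {
  mat <- as_stable_pairs(mature, stability_fraction,
                         label = mature_label %||% "mature", block_size)
  imm <- as_stable_pairs(immature, stability_fraction,
                         label = immature_label %||% "immature", block_size)
  intersect_reversal(mat, imm,
                     mature_label = mature_label %||% mat$condition_label,
                     immature_label = immature_label %||% imm$condition_label)
}

as_stable_pairs <- function(x, stability_fraction, label, block_size) {
  if (inherits(x, "stable_pairs")) return(x)
  x <- pool_expression_matrices(x)
  find_stable_pairs(x, stability_fraction, condition_label = label,
                    block_size = block_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersect two stable-pair sets into a reversal signature
#'
#' Selects exactly the pairs present in both sets with opposite ordering
#' directions; the stored direction is the mature-condition one.
#'
#' @param mature,immature `stable_pairs` objects for the two conditions.
#' @param mature_label,immature_label labels recorded in the signature.
#' @return a `reo_signature` object (see [reo_signature()]).
#' @export
intersect_reversal <- function(mature, immature,
                               mature_label = mature$condition_label,
                               immature_label = immature$condition_label) {
  stopifnot(inherits(mature, "stable_pairs"),
            inherits(immature, "stable_pairs"))
  mp <- mature$pairs
  ip <- immature$pairs
  idx <- match(pair_key(mp$gene_a, mp$gene_b),
               pair_key(ip$gene_a, ip$gene_b))
  hit <- !is.na(idx) & mp$direction != ip$direction[idx]
  pairs <- mp[hit, , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L)
    warning("empty reversal signature: no stable pair reverses between ",
            "conditions", call. = FALSE)
  new_signature(pairs, mature_label, immature_label,
                n_stable_mature = nrow(mp), n_stable_immature = nrow(ip))
}

new_signature <- function(pairs, mature_label, immature_label,
                          n_stable_mature = NA_integer_,
                          n_stable_immature = NA_integer_) {
  stopifnot(all(pairs$gene_a < pairs$gene_b),
            all(pairs$direction %in% c("gt", "lt")))
  if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b)))
    stop("duplicate gene pair in signature", call. = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n = nrow(pairs),
                 mature_label = mature_label,
                 immature_label = immature_label,
                 n_stable_mature = n_stable_mature,
                 n_stable_immature = n_stable_immature),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("Reversal REO signature: %d pairs (%s vs %s)\n",
              x$n, x$mature_label, x$immature_label))
  if (!is.na(x$n_stable_mature))
    cat(sprintf("  stable pairs: %d (%s), %d (%s)\n",
                x$n_stable_mature, x$mature_label,
                x$n_stable_immature, x$immature_label))
  if (x$n) print(utils::head(x$pairs, 6L))
  if (x$n > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.reo_signature <- function(object, ...) {
  cat(sprintf("Reversal REO signature (%s vs %s)\n",
              object$mature_label, object$immature_label))
  cat(sprintf("  pairs           : %d\n", object$n))
  cat(sprintf("  genes involved  : %d\n",
              length(unique(c(object$pairs$gene_a, object$pairs$gene_b)))))
  cat(sprintf("  direction gt/lt : %d / %d\n",
              sum(object$pairs$direction == "gt"),
              sum(object$pairs$direction == "lt")))
  invisible(object)
}

#' Write / read a reversal signature as TSV
#'
#' File format: header lines `#mature=<label>`, `#immature=<label>`,
#' `#n=<count>`, then `gene_a<TAB>gene_b<TAB>direction` per pair with
#' `gene_a < gene_b` and direction `gt`/`lt` giving the mature-condition
#' ordering of gene_a versus gene_b.
#'
#' @param sig a `reo_signature`.
#' @param path output (or input) file path.
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns a `reo_signature` identical to the one written.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "reo_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#mature=", sig$mature_label),
               paste0("#immature=", sig$immature_label),
               paste0("#n=", sig$n)), con)
  if (sig$n)
    writeLines(paste(sig$pairs$gene_a, sig$pairs$gene_b, sig$pairs$direction,
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "="))]
    if (length(ln) != 1L)
      stop("signature file missing '#", key, "=' header: ", path,
           call. = FALSE)
    sub(paste0("^#", key, "="), "", ln)
  }
  mature <- get_hdr("mature")
  immature <- get_hdr("immature")
  n_decl <- as.integer(get_hdr("n"))
  if (length(body)) {
    cells <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(cells) != 3L))
      stop("malformed signature row in ", path, call. = FALSE)
    pairs <- data.frame(
      gene_a = as.integer(vapply(cells, `[[`, "", 1L)),
      gene_b = as.integer(vapply(cells, `[[`, "", 2L)),
      direction = vapply(cells, `[[`, "", 3L),
      stringsAsFactors = FALSE)
    if (anyNA(pairs$gene_a) || anyNA(pairs$gene_b))
      stop("non-integer gene ID in signature file ", path, call. = FALSE)
    if (!all(pairs$direction %in% c("gt", "lt")))
      stop("direction token outside {gt, lt} in ", path, call. = FALSE)
    if (!all(pairs$gene_a < pairs$gene_b))
      stop("non-canonical pair (gene_a must be < gene_b) in ", path,
           call. = FALSE)
    if (anyDuplicated(pair_key(pairs$gene_a, pairs$gene_b)))
      stop("duplicate pair in signature file ", path, call. = FALSE)
  } else {
    pairs <- data.frame(gene_a = integer(0), gene_b = integer(0),
                        direction = character(0), stringsAsFactors = FALSE)
  }
  if (!is.na(n_decl) && n_decl != nrow(pairs))
    stop(sprintf("signature header declares n=%d but file has %d pairs: %s",
                 n_decl, nrow(pairs), path), call. = FALSE)
  new_signature(pairs, mature, immature)
}
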