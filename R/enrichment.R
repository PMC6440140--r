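#' Read gene sets from a GMT file
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return named list of character gene-ID vectors; descriptions attached
#'   as the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) < 3L))
    stop("malformed GMT line (need name, description, >=1 gene) in ", path,
         call. = FALSE)
  nm <- vapply(cells, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in GMT file ", path, call. = FALSE)
  sets <- lapply(cells, function(r) unique(r[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(
    vapply(cells, `[[`, "", 2L), nm)
  sets
}

#' Hypergeometric over-representation test of a gene list against gene sets
#'
#' For each set S the p-value is the upper-tail hypergeometric probability
#' of drawing at least the observed overlap when `list_size` genes are
#' sampled without replacement from the universe: P(X >= overlap) with
#' X ~ Hypergeometric(universe_size, set_size, list_size). Sets and the
#' gene list are first restricted to the universe; a set with zero overlap
#' gets p = 1. BH FDR is computed across all tested sets.
#'
#' @param deg_list character or integer vector of genes of interest.
#' @param sets named list of gene-ID vectors (e.g. from [read_gmt()]).
#' @param universe vector of background gene IDs; defaults to the union of
#'   all set members and the gene list. In a DEG workflow pass all genes of
#'   the tested expression matrix.
#' @return data.frame, one row per set in input order: `set_name`,
#'   `overlap`, `set_size`, `list_size`, `universe_size`, `p_value`, `fdr`.
#' @export
hypergeom_enrich <- function(deg_list, sets,
                             universe = union(unlist(sets), deg_list)) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(as.character(universe))
  deg <- intersect(unique(as.character(deg_list)), universe)
  if (length(deg) == 0L)
    stop("gene list is disjoint from the universe", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  N <- length(universe)
  n <- length(deg)
  rows <- lapply(names(sets), function(nm) {
    S <- intersect(unique(as.character(sets[[nm]])), universe)
    K <- length(S)
    ov <- length(intersect(S, deg))
    p <- if (ov == 0L) 1.0 else
      stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = K, list_size = n,
               universe_size = N, p_value = min(1, p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p_value)
  rownames(res) <- NULL
  res
}

#' @rdname hypergeom_enrich
#' @param enrich result of `hypergeom_enrich`.
#' @param path output TSV path.
#' @export
write_enrichment <- function(enrich, path) {
  utils::write.table(enrich, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
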