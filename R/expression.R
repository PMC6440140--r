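#' Validate a gene-level expression matrix
#'
#' `reotools` represents expression data as a plain numeric matrix:
#' rows are genes (rownames are Entrez gene IDs, stored as the decimal
#' string of a positive integer), columns are samples (colnames are sample
#' IDs). All pair logic uses only within-sample comparisons, so values may
#' be on any monotone scale (linear or log); no normalisation is applied or
#' required.
#'
#' @param x numeric matrix, rownames gene IDs, colnames sample IDs.
#' @param sort if `TRUE`, reorder rows so gene IDs are ascending.
#' @return the validated (and possibly row-sorted) matrix, invisibly
#'   classed as a plain matrix.
#' @export
as_expression_matrix <- function(x, sort = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix", call. = FALSE)
  if (ncol(x) < 1L)
    stop("expression matrix needs at least 1 sample", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  ids <- suppressWarnings(as.integer(rownames(x)))
  if (anyNA(ids) || any(ids <= 0L))
    stop("gene IDs must be positive integers (Entrez); offending IDs: ",
         paste(utils::head(rownames(x)[is.na(ids) | ids <= 0], 5L),
               collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene %s, sample %s",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]), call. = FALSE)
  }
  if (sort && is.unsorted(ids)) x <- x[order(ids), , drop = FALSE]
  x
}

#' Extract gene IDs of an expression matrix as integers
#' @param x expression matrix (see [as_expression_matrix()]).
#' @return integer vector of gene IDs in row order.
#' @export
gene_ids <- function(x) as.integer(rownames(x))

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expected layout: a header row `gene_id<TAB>sample1<TAB>...` followed by
#' one row per gene with numeric values. Duplicate gene IDs, ragged rows
#' and non-numeric cells are rejected with the offending row/column named.
#'
#' @param path path to a tab-separated text file.
#' @return a validated expression matrix, rows sorted by gene ID.
#' @export
read_expression_tsv <- function(path) {
  tab <- read_tsv_table(path)
  mat_from_table(tab, path)
}

#' @rdname read_expression_tsv
#' @param x expression matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  x <- as_expression_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(format(x, trim = TRUE, scientific = FALSE, digits = 15), 1L,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

# Parse a rectangular tab-separated table with a header line.
# Returns list(header=character, ids=character, values=numeric matrix).
read_tsv_table <- function(path, lines = NULL, what = "row") {
  if (is.null(lines)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("no data rows in ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncols <- length(header)
  body <- cells[-1L]
  len <- lengths(body)
  if (any(len != ncols))
    stop(sprintf("ragged %s %d in %s: %d fields, expected %d",
                 what, which(len != ncols)[1L] + 1L, path,
                 len[len != ncols][1L], ncols), call. = FALSE)
  ids <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(ncols - 1L)))
  vals <- matrix(vals, nrow = length(body), ncol = ncols - 1L, byrow = TRUE)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                 path, ids[bad[1L]], header[bad[2L] + 1L]), call. = FALSE)
  }
  list(header = header, ids = ids, values = vals)
}

mat_from_table <- function(tab, path) {
  m <- tab$values
  rownames(m) <- tab$ids
  colnames(m) <- tab$header[-1L]
  tryCatch(as_expression_matrix(m),
           error = function(e) stop(conditionMessage(e), " (in ", path, ")",
                                    call. = FALSE))
}

#' Read a probe-level matrix from a GEO series-matrix file
#'
#' Parses the series-matrix text dialect: metadata lines prefixed `!` are
#' ignored and the probe-by-sample table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers is
#' returned. Probe IDs are kept verbatim (quotes stripped); no gene mapping
#' is performed -- pass the result to [map_probes_to_genes()].
#'
#' @param path path to a series-matrix text file.
#' @return numeric matrix, rownames probe IDs, colnames sample accessions.
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("not a series-matrix file (missing table_begin/table_end markers): ",
         path, call. = FALSE)
  tab_lines <- gsub("\"", "", lines[(beg + 1L):(end - 1L)], fixed = TRUE)
  tab <- read_tsv_table(path, lines = tab_lines, what = "table row")
  m <- tab$values
  rownames(m) <- tab$ids
  colnames(m) <- tab$header[-1L]
  if (anyDuplicated(rownames(m)))
    stop("duplicate probe IDs in ", path, call. = FALSE)
  m
}

#' Read a probe-to-gene platform annotation table
#'
#' Format: `probe_id<TAB>gene_id[;gene_id...]` per line, with an optional
#' header line starting `probe_id`. An empty second field marks an unmapped
#' probe.
#'
#' @param path path to the mapping TSV.
#' @return named list: probe ID -> integer vector of Entrez gene IDs
#'   (possibly empty).
#' @export
read_platform_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "probe_id")) lines <- lines[-1L]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  probes <- vapply(cells, `[[`, "", 1L)
  if (anyDuplicated(probes))
    stop("duplicate probe IDs in platform map: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  genes <- lapply(cells, function(r) {
    if (length(r) < 2L || !nzchar(r[2L])) return(integer(0))
    g <- suppressWarnings(as.integer(strsplit(r[2L], ";", fixed = TRUE)[[1L]]))
    if (anyNA(g) || any(g <= 0L))
      stop("invalid gene ID for probe ", r[1L], call. = FALSE)
    unique(g)
  })
  names(genes) <- probes
  genes
}

#' Collapse a probe-level matrix to a gene-level expression matrix
#'
#' Probes mapping to zero or to multiple genes are deleted; where several
#' probes map uniquely to the same gene, the gene's value in each sample is
#' the arithmetic mean over those probes. Probes absent from the platform
#' map are treated as unmapped. Rows of the result are sorted by gene ID.
#'
#' @param probes numeric probe-by-sample matrix with probe rownames.
#' @param platform named list probe ID -> integer gene IDs, as returned by
#'   [read_platform_map()].
#' @return gene-level expression matrix.
#' @export
map_probes_to_genes <- function(probes, platform) {
  if (!is.matrix(probes) || !is.numeric(probes) || is.null(rownames(probes)))
    stop("probe data must be a numeric matrix with probe rownames",
         call. = FALSE)
  if (anyDuplicated(rownames(probes)))
    stop("duplicate probe IDs", call. = FALSE)
  hit <- platform[rownames(probes)]
  hit[vapply(hit, is.null, TRUE)] <- list(integer(0))
  keep <- lengths(hit) == 1L
  if (!any(keep))
    stop("no genes after mapping: every probe maps to zero or multiple genes",
         call. = FALSE)
  g <- unlist(hit[keep], use.names = FALSE)
  sub <- probes[keep, , drop = FALSE]
  counts <- as.vector(rowsum(rep(1L, length(g)), group = g, reorder = TRUE))
  collapsed <- rowsum(sub, group = g, reorder = TRUE) / counts
  rownames(collapsed) <- sort(unique(g))
  colnames(collapsed) <- colnames(probes)
  as_expression_matrix(collapsed)
}

#' Pool expression matrices over their common gene universe
#'
#' Used to accumulate samples for one condition from several datasets.
#' The gene universe of the pooled matrix is the intersection of the genes
#' present in every contributing matrix, so that every gene pair is
#' evaluable in every accumulated sample.
#'
#' @param mats a single expression matrix or a list of them.
#' @return pooled expression matrix (columns concatenated in input order).
#' @export
pool_expression_matrices <- function(mats) {
  if (is.matrix(mats)) return(as_expression_matrix(mats))
  mats <- lapply(mats, as_expression_matrix)
  if (length(mats) == 1L) return(mats[[1L]])
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0L)
    stop("gene universes are disjoint: no common genes to pool over",
         call. = FALSE)
  common <- common[order(as.integer(common))]
  pooled <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  as_expression_matrix(pooled)
}
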