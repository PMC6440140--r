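#' Construct a synthetic two-condition truth with planted REO structure
#'
#' Builds a pair of expression templates on a log2-like intensity scale
#' emulating two cell states (a mature and an immature condition):
#'
#' * gene template values are distinct and evenly spaced (spacing `delta`)
#'   over `value_range`, assigned to gene IDs `1..n_genes` in a random
#'   (seeded) order, so there are no ties by construction;
#' * each of `n_reversal_pairs` planted reversal pairs occupies two
#'   *value-adjacent* slots separated by `pair_margin`; the immature
#'   template swaps the two values. Because no third gene's value lies
#'   between the pair's values, the swap reverses exactly that pair and no
#'   other -- the planted set is complete and free of incidental reversals;
#' * optionally, `n_deg_genes` genes (disjoint from the planted pairs,
#'   drawn from the central 60% of template ranks so that every planted
#'   DEG has ordering partners on both sides) are designated
#'   differentially expressed for CellComp simulations: in test
#'   samples their value is moved `log2(deg_fold)` beyond the template
#'   extreme (above the maximum for `up` genes, below the minimum for
#'   `down`), so they exceed / undershoot every former ordering partner by
#'   construction.
#'
#' `pair_margin` must exceed `4 * noise_sd` so that planted orderings are
#' recoverable at the stated noise level; the default is
#' `max(delta, 5 * noise_sd)`.
#'
#' @param n_genes number of genes (IDs `1..n_genes`).
#' @param n_reversal_pairs number of planted reversal pairs
#'   (`<= floor(n_genes/2)`).
#' @param noise_sd default per-gene Gaussian noise s.d. (log2 scale) used
#'   by the samplers; also sets the margin feasibility check.
#' @param n_deg_genes number of planted DEG genes for CellComp simulations.
#' @param deg_fold fold change of planted DEG genes (linear scale).
#' @param pair_margin template value gap within each planted pair.
#' @param value_range numeric length-2: span of template values
#'   (log2-intensity-like).
#' @param seed integer seed; the same seed reproduces the truth exactly.
#' @return object of class `reo_truth`: list with `mature_template` and
#'   `immature_template` (named numeric vectors), `planted_pairs`
#'   (data.frame `gene_a < gene_b`, `direction` = mature ordering),
#'   `planted_degs` (data.frame `gene_id`, `direction`, `value` or empty),
#'   `noise_sd`, `pair_margin`, `seed`.
#' @export
make_truth <- function(n_genes, n_reversal_pairs, noise_sd = 0.3,
                       n_deg_genes = 0L, deg_fold = 20,
                       pair_margin = NULL, value_range = c(4, 14),
                       seed = 1L) {
  if (n_genes < 2L) stop("need at least 2 genes", call. = FALSE)
  if (n_reversal_pairs < 0L || n_reversal_pairs > floor(n_genes / 2))
    stop("n_reversal_pairs must be in [0, floor(n_genes/2)]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  delta <- diff(value_range) / (n_genes - 1L)
  if (is.null(pair_margin)) pair_margin <- max(delta, 5 * noise_sd)
  if (n_reversal_pairs > 0L && pair_margin <= 4 * noise_sd)
    stop(sprintf(
      "infeasible pair_margin %.4g for noise_sd %.4g: planted orderings ",
      pair_margin, noise_sd),
      "need margin > 4*noise_sd; increase pair_margin or lower noise_sd",
      call. = FALSE)
  set.seed(as.integer(seed))
  # slot i holds the i-th smallest template value; planted pairs occupy
  # adjacent slots (s, s+1) with an enlarged gap between them
  gaps <- rep(delta, n_genes - 1L)
  starts <- integer(0)
  if (n_reversal_pairs > 0L) {
    odd <- seq.int(1L, n_genes - 1L, by = 2L)
    starts <- sort(sample(odd, n_reversal_pairs))
    gaps[starts] <- pair_margin
  }
  values <- value_range[1L] + c(0, cumsum(gaps))
  perm <- sample.int(n_genes)            # gene ID occupying each slot
  mature <- numeric(n_genes)
  mature[perm] <- values
  names(mature) <- seq_len(n_genes)
  immature <- mature
  planted <- data.frame(gene_a = integer(0), gene_b = integer(0),
                        direction = character(0), stringsAsFactors = FALSE)
  if (n_reversal_pairs > 0L) {
    lo_gene <- perm[starts]              # smaller template value
    hi_gene <- perm[starts + 1L]
    immature[lo_gene] <- mature[hi_gene]
    immature[hi_gene] <- mature[lo_gene]
    a <- pmin(lo_gene, hi_gene)
    b <- pmax(lo_gene, hi_gene)
    planted <- data.frame(
      gene_a = a, gene_b = b,
      # mature direction of gene_a vs gene_b
      direction = ifelse(a == hi_gene, "gt", "lt"),
      stringsAsFactors = FALSE)
    planted <- planted[order(planted$gene_a, planted$gene_b), , drop = FALSE]
    rownames(planted) <- NULL
  }
  degs <- data.frame(gene_id = integer(0), direction = character(0),
                     value = numeric(0), stringsAsFactors = FALSE)
  if (n_deg_genes > 0L) {
    # only genes with ordering partners on both sides can show a partner
    # reversal, so plant DEGs in the central rank band of the template
    rk <- rank(mature)
    central <- which(rk >= ceiling(0.2 * n_genes) & rk <= floor(0.8 * n_genes))
    pool <- setdiff(central, c(planted$gene_a, planted$gene_b))
    if (length(pool) < n_deg_genes)
      stop("not enough genes outside planted pairs for n_deg_genes",
           call. = FALSE)
    gid <- sort(sample(pool, n_deg_genes))
    dir <- sample(c("up", "down"), n_deg_genes, replace = TRUE)
    shift <- log2(deg_fold)
    degs <- data.frame(
      gene_id = gid, direction = dir,
      value = ifelse(dir == "up",
                     max(values) + shift + seq_len(n_deg_genes) * delta,
                     min(values) - shift - seq_len(n_deg_genes) * delta),
      stringsAsFactors = FALSE)
  }
  structure(list(mature_template = mature, immature_template = immature,
                 planted_pairs = planted, planted_degs = degs,
                 noise_sd = noise_sd, pair_margin = pair_margin,
                 value_range = value_range, seed = as.integer(seed)),
            class = "reo_truth")
}

#' @export
print.reo_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic REO truth: %d genes, %d planted reversal pairs, %d planted DEGs\n",
    length(x$mature_template), nrow(x$planted_pairs), nrow(x$planted_degs)))
  cat(sprintf("  pair margin %.4g, default noise_sd %.4g, seed %d\n",
              x$pair_margin, x$noise_sd, x$seed))
  invisible(x)
}

# i.i.d. Gaussian noise per gene and sample, drawn as one matrix so the
# noise stream is unaffected by whether batch distortion is also drawn
synth_samples <- function(template, n_samples, noise_sd, batch_distortion,
                          seed, prefix) {
  set.seed(as.integer(seed))
  n <- length(template)
  x <- template + matrix(stats::rnorm(n * n_samples, sd = noise_sd),
                         n, n_samples)
  if (batch_distortion)
    for (s in seq_len(n_samples)) x[, s] <- monotone_distort(x[, s])
  dimnames(x) <- list(names(template), paste0(prefix, "_s", seq_len(n_samples)))
  as_expression_matrix(x)
}

# random strictly increasing piecewise-linear map over the data range
monotone_distort <- function(v, n_knots = 6L) {
  rng <- range(v)
  pad <- max(diff(rng), 1) * 0.05
  kx <- seq(rng[1L] - pad, rng[2L] + pad, length.out = n_knots)
  ky <- cumsum(exp(stats::rnorm(n_knots, sd = 0.8)))
  shift <- stats::rnorm(1L, sd = 2)
  stats::approx(kx, ky + shift, xout = v)$y
}

#' Draw samples from one condition of a synthetic truth
#'
#' Each sample is the condition template plus i.i.d. Gaussian noise per
#' gene; with `batch_distortion = TRUE` a random strictly increasing
#' piecewise-linear map (a different one per sample) is applied to the
#' sample's values afterwards, emulating batch effects. The distortion is
#' exactly order-preserving, so within-sample orderings -- and hence stable
#' pairs, signatures and maturity scores -- are unchanged by it.
#'
#' @param truth a [make_truth()] object.
#' @param condition `"mature"` or `"immature"`.
#' @param n_samples number of samples to draw.
#' @param noise_sd noise s.d.; defaults to the truth's `noise_sd`.
#' @param batch_distortion apply per-sample monotone distortions.
#' @param seed integer seed (same seed, same matrix).
#' @return expression matrix with `n_samples` columns.
#' @export
sample_condition <- function(truth, condition = c("mature", "immature"),
                             n_samples, noise_sd = truth$noise_sd,
                             batch_distortion = FALSE, seed = 1L) {
  stopifnot(inherits(truth, "reo_truth"))
  condition <- match.arg(condition)
  tmpl <- if (condition == "mature") truth$mature_template
          else truth$immature_template
  synth_samples(tmpl, n_samples, noise_sd, batch_distortion, seed,
                prefix = condition)
}

#' Draw mixture samples interpolating immature and mature templates
#'
#' Emulates partially matured cells: the per-gene template is
#' `(1 - alpha) * immature + alpha * mature` plus Gaussian noise, so
#' `alpha = 0` and `alpha = 1` reduce to the pure conditions.
#'
#' @param truth a [make_truth()] object.
#' @param alpha mixing weight of the mature template, in \[0, 1\].
#' @param n_samples number of samples.
#' @param noise_sd,batch_distortion,seed as in [sample_condition()].
#' @return expression matrix.
#' @export
sample_mixture <- function(truth, alpha, n_samples,
                           noise_sd = truth$noise_sd,
                           batch_distortion = FALSE, seed = 1L) {
  stopifnot(inherits(truth, "reo_truth"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  tmpl <- (1 - alpha) * truth$immature_template + alpha * truth$mature_template
  synth_samples(tmpl, n_samples, noise_sd, batch_distortion, seed,
                prefix = sprintf("mix%03d", round(100 * alpha)))
}

#' Draw test replicates with the truth's planted DEG shifts applied
#'
#' Samples from the mature template in which every planted DEG gene's value
#' is replaced by its shifted target (beyond the template extremes, see
#' [make_truth()]), emulating a small-replicate test dataset for CellComp.
#'
#' @param truth a [make_truth()] object (usually with `n_deg_genes > 0`).
#' @param n_replicates number of technical replicates (1-3 for CellComp).
#' @param noise_sd,batch_distortion,seed as in [sample_condition()].
#' @return expression matrix with `n_replicates` columns.
#' @export
sample_deg_replicates <- function(truth, n_replicates = 3L,
                                  noise_sd = truth$noise_sd,
                                  batch_distortion = FALSE, seed = 1L) {
  stopifnot(inherits(truth, "reo_truth"))
  tmpl <- truth$mature_template
  if (nrow(truth$planted_degs))
    tmpl[as.character(truth$planted_degs$gene_id)] <- truth$planted_degs$value
  synth_samples(tmpl, n_replicates, noise_sd, batch_distortion, seed,
                prefix = "test")
}
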