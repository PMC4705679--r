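#' Reproducibility-optimized differential expression test
#'
#' End-to-end two-group analysis of a count matrix: all-zero genes are
#' dropped, TMM scaling factors and the log-CPM transformation are applied
#' (unless `normalize = FALSE`), bootstrap and null resampling plans are
#' drawn, reproducibility curves are computed over the `(alpha, k)` lattice,
#' the Z-maximizing statistic is selected, and the selected statistic is
#' evaluated on the original data together with a permutation FDR.
#'
#' The RNG is seeded once from `seed` and consumed in a fixed order
#' (bootstrap plan, then null plan, then FDR permutations), so a run is
#' fully reproducible from `(counts, design, options, seed)`.
#'
#' A reproducibility Z-score below 2 at the optimum indicates that the data
#' or the candidate statistics are insufficient for reliable detection; this
#' raises a warning, not an error.
#'
#' @param counts Count matrix (genes x samples) with dimnames, or a path
#'   understood by [read_counts()].
#' @param design An `rots_design` (see [group_design()], [read_design()]),
#'   or a vector of group labels, one per column of `counts`.
#' @param B Number of bootstrap pairs (and of null pairs); default 1000.
#' @param P Number of FDR permutations; default `B`.
#' @param seed Integer seed for all resampling; `NULL` leaves the RNG alone.
#' @param alpha_grid Candidate `(alpha1, alpha2)` lattice; default
#'   [alpha_grid_default()].
#' @param k_grid Top-list sizes; default [k_grid_default()] on the number of
#'   genes kept.
#' @param normalize If `FALSE`, skip TMM (all factors 1) for pre-normalized
#'   input; the log-CPM transform is still applied.
#' @param prior Pseudo-count for the log-CPM transform.
#' @param keep_curves Keep the full `rots_curves` object in the fit.
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `rots_fit`: a list with `table` (data.frame
#'   `gene_id`, `statistic`, `logfc`, `fdr`, row per kept gene, input
#'   order), `optimum` (`alpha1`, `alpha2`, `k`, `R`, `Z`), `B`, `P`,
#'   `seed`, `dropped_genes`, `sample_ids`, `design`, and (optionally)
#'   `curves`.  `logfc` is the difference of log2-scale group means,
#'   condition 2 minus condition 1.
#' @export
rots <- function(counts, design, B = 1000L, P = B, seed = NULL,
                 alpha_grid = alpha_grid_default(), k_grid = NULL,
                 normalize = TRUE, prior = 0.5, keep_curves = FALSE,
                 verbose = FALSE) {
  if (is.character(counts) && length(counts) == 1L) counts <- read_counts(counts)
  validate_counts(counts)
  if (!inherits(design, "rots_design"))
    design <- group_design(colnames(counts), design)
  design <- align_design(design, counts)

  zero <- rowSums(counts) == 0
  dropped <- sum(zero)
  if (dropped > 0L) {
    msg("dropping %d gene(s) with zero counts in all samples", dropped,
        verbose = verbose)
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) < 5L) stop("fewer than 5 non-zero genes; nothing to rank")

  factors <- if (normalize) tmm_factors(counts) else NULL
  x <- logcpm_transform(counts, factors, prior = prior)
  msg("normalized %d genes x %d samples (TMM: %s)", nrow(x), ncol(x),
      if (normalize) "yes" else "no", verbose = verbose)

  if (is.null(k_grid)) k_grid <- k_grid_default(nrow(x))
  if (!is.null(seed)) set.seed(as.integer(seed))
  boot <- make_bootstrap_pairs(design, B, seed = NULL)
  null <- make_null_pairs(design, B, seed = NULL)
  msg("computing reproducibility over %d alpha x %d k lattice, B = %d",
      nrow(alpha_grid), length(k_grid), B, verbose = verbose)
  curves <- reproducibility_curves(x, boot, null, alpha_grid, k_grid)
  opt <- rots_optimize(curves)
  msg("optimum: alpha = (%g, %g), k = %d, R = %.3f, Z = %.3f",
      opt$alpha1, opt$alpha2, opt$k, opt$R, opt$Z, verbose = verbose)
  if (is.finite(opt$Z) && opt$Z < 2)
    warning(sprintf(paste0("optimized reproducibility Z = %.2f < 2: data or ",
                           "statistics may be insufficient for reliable detection"),
                    opt$Z))

  d <- d_stat(x, design, opt$alpha1, opt$alpha2)
  sm <- group_summaries(x, design)
  fdr <- estimate_fdr(x, design, opt$alpha1, opt$alpha2, P = P, seed = NULL,
                      d = d)
  fit <- structure(
    list(table = data.frame(gene_id = rownames(x),
                            statistic = as.numeric(d),
                            logfc = sm$mean2 - sm$mean1,
                            fdr = as.numeric(fdr),
                            row.names = NULL,
                            stringsAsFactors = FALSE),
         optimum = opt, B = as.integer(B), P = as.integer(P), seed = seed,
         dropped_genes = dropped, sample_ids = colnames(counts),
         design = design),
    class = "rots_fit")
  if (keep_curves) fit$curves <- curves
  fit
}

#' @export
print.rots_fit <- function(x, ...) {
  opt <- x$optimum
  cat(sprintf("ROTS fit: %d genes, %d + %d samples (B = %d, P = %d)\n",
              nrow(x$table), x$design$n1, x$design$n2, x$B, x$P))
  cat(sprintf("  optimal statistic: alpha = (%g, %g), k = %d, R = %.3f, Z = %.3f%s\n",
              opt$alpha1, opt$alpha2, opt$k, opt$R, opt$Z,
              if (is.finite(opt$Z) && opt$Z < 2) "  [Z < 2: unreliable]" else ""))
  cat(sprintf("  genes at FDR < 0.05: %d\n", sum(x$table$fdr < 0.05)))
  invisible(x)
}
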