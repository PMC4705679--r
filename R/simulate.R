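#' Simulation parameters for spike-in style count data
#'
#' Describes a two-group negative-binomial experiment: a background of null
#' genes plus a set of control genes with known fold changes between the
#' groups, unequal library sizes, and NB noise with variance
#' \eqn{\mu + \phi\mu^2}.
#'
#' @param genes Total number of genes G (controls included).
#' @param samples_per_group Replicates n per group (2 groups).
#' @param controls data.frame with columns `count`, `fold_change`: how many
#'   control genes at each fold change.  Fold changes must be > 0; 1 means
#'   not differentially expressed.
#' @param baseline_mean_range Baseline NB means are drawn log-uniform over
#'   this range.
#' @param dispersion NB dispersion \eqn{\phi} (variance \eqn{\mu + \phi\mu^2}).
#' @param libsize_factors Per-sample depth multipliers (length 2n), or
#'   `NULL` to draw them log-uniform over `libsize_range` at simulation time.
#' @param libsize_range Range for drawn depth multipliers.
#' @param seed Integer seed.
#' @return A list of class `rots_simparams`.
#' @export
sim_params <- function(genes = 1000L, samples_per_group = 5L,
                       controls = data.frame(count = integer(0),
                                             fold_change = numeric(0)),
                       baseline_mean_range = c(10, 1e4),
                       dispersion = 0.1,
                       libsize_factors = NULL,
                       libsize_range = c(0.7, 1.4),
                       seed = 1L) {
  stopifnot(is.data.frame(controls),
            all(c("count", "fold_change") %in% names(controls)))
  if (any(controls$fold_change <= 0)) stop("fold changes must be > 0")
  if (any(controls$count < 0)) stop("control counts must be >= 0")
  if (samples_per_group < 2L) stop("need at least 2 samples per group")
  if (genes < sum(controls$count)) stop("genes must cover all control genes")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (any(baseline_mean_range <= 0) || diff(baseline_mean_range) < 0)
    stop("baseline_mean_range must be an increasing positive range")
  if (!is.null(libsize_factors)) {
    if (length(libsize_factors) != 2L * samples_per_group)
      stop("libsize_factors must have one entry per sample")
    if (any(libsize_factors <= 0)) stop("libsize_factors must be > 0")
  }
  structure(list(genes = as.integer(genes),
                 samples_per_group = as.integer(samples_per_group),
                 controls = controls,
                 baseline_mean_range = baseline_mean_range,
                 dispersion = dispersion,
                 libsize_factors = libsize_factors,
                 libsize_range = libsize_range,
                 seed = as.integer(seed)),
            class = "rots_simparams")
}

#' ERCC-like spike-in preset
#'
#' Emulates the classic two-mixture spike-in benchmark: 92 synthetic control
#' genes at fold changes 0.5, 0.67, 1 and 4 between groups A and B — 23 of
#' them non-differential (fold change 1) and the remaining 69 split evenly
#' (23 per class) across the differential fold changes — with n = 5
#' technical replicates per group, embedded in a null background.  Technical
#' replicates motivate the low default dispersion.
#'
#' @param genes Total genes including the 92 controls; default 1000.
#' @param dispersion NB dispersion; default 0.01 (technical-replicate-like).
#' @param seed Integer seed stored in the parameters.
#' @return A `rots_simparams` object.
#' @export
spikein_preset <- function(genes = 1000L, dispersion = 0.01, seed = 1L) {
  sim_params(genes = genes, samples_per_group = 5L,
             controls = data.frame(count = c(23L, 23L, 23L, 23L),
                                   fold_change = c(0.5, 0.67, 1, 4)),
             dispersion = dispersion, seed = seed)
}

#' Simulate a two-group NB count matrix with known truth
#'
#' Gene g in sample i of group j is drawn
#' \eqn{NB(\mu = \mu_g \cdot FC_g^{[j = 2]} \cdot \ell_i,\;
#' \mathrm{var} = \mu + \phi\mu^2)}: group 1 sits at the baseline, group 2
#' carries the assigned fold change, and \eqn{\ell_i} is the sample's depth
#' multiplier.  Control genes occupy the first rows of the matrix, in the
#' order of the `controls` table; all remaining genes are null background
#' (fold change 1).
#'
#' @param params A `rots_simparams`, e.g. from [spikein_preset()].
#' @return A list with `counts` (integer matrix, genes `g0001`... by
#'   samples `A1..An, B1..Bn`), `design` (an `rots_design`, A = condition
#'   1), and `truth` (data.frame `gene_id`, `fold_change`, `is_de`).
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "rots_simparams"))
  G <- params$genes
  n <- params$samples_per_group
  fc <- rep(1, G)
  ctrl <- params$controls
  if (nrow(ctrl) > 0L)
    fc[seq_len(sum(ctrl$count))] <- rep(ctrl$fold_change, ctrl$count)
  out <- with_seed(params$seed, {
    lib <- params$libsize_factors %||%
      exp(runif(2L * n, log(params$libsize_range[1L]),
                log(params$libsize_range[2L])))
    base <- exp(runif(G, log(params$baseline_mean_range[1L]),
                      log(params$baseline_mean_range[2L])))
    mu <- outer(base, lib) * cbind(matrix(1, G, n),
                                   matrix(fc, G, n))
    cnt <- array(rnbinom(length(mu), mu = mu, size = 1 / params$dispersion),
                 dim = dim(mu))
    list(lib = lib, counts = cnt)
  })
  gene_ids <- sprintf("g%0*d", max(4L, nchar(G)), seq_len(G))
  sample_ids <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  counts <- out$counts
  dimnames(counts) <- list(gene_ids, sample_ids)
  storage.mode(counts) <- "integer"
  design <- group_design(sample_ids, rep(c("A", "B"), each = n))
  truth <- data.frame(gene_id = gene_ids, fold_change = fc, is_de = fc != 1,
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth,
       libsize_factors = out$lib)
}
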