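#' Permutation-based FDR for a fixed statistic
#'
#' SAM-style estimate at the selected \eqn{(\alpha_1, \alpha_2)}.  P
#' whole-dataset label permutations (group sizes preserved) are drawn, the
#' statistic is recomputed on each, and for every gene g
#' \deqn{\mathrm{raw}(g) = \frac{\frac1P \sum_p \#\{g' : d_p(g') \ge d(g)\}}
#'                              {\#\{g' : d(g') \ge d(g)\}},}
#' clipped to \eqn{[0, 1]}.  The reported value is made monotone along the
#' ranking (step-up): \eqn{\mathrm{fdr}(g) = \min \{\mathrm{raw}(g') :
#' d(g') \le d(g)\}}, so FDR never decreases as the statistic decreases.
#'
#' @inheritParams d_stat
#' @param P Number of permutations, at least 1.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @param d Optional precomputed observed statistic (must match
#'   `d_stat(x, design, alpha1, alpha2)`); recomputed when `NULL`.
#' @return Named per-gene FDR vector in `[0, 1]`.
#' @export
estimate_fdr <- function(x, design, alpha1, alpha2, P = 1000L, seed = NULL,
                         d = NULL) {
  check_alpha(alpha1, alpha2)
  grp <- design_groups(design, ncol(x))
  if (!is.numeric(P) || length(P) != 1L || P < 1) stop("P must be at least 1")
  P <- as.integer(P)
  if (is.null(d)) d <- d_stat(x, design, alpha1, alpha2)
  g <- nrow(x)
  n <- ncol(x)
  idx1 <- which(grp == 1L)
  n1 <- length(idx1)

  perm_d <- with_seed(seed, {
    vapply(seq_len(P), function(p) {
      pidx <- sample.int(n)
      sm <- summaries_idx(x, pidx[seq_len(n1)], pidx[-seq_len(n1)])
      as.numeric(d_from_summaries(sm$mean1 - sm$mean2, sm$s, alpha1, alpha2))
    }, numeric(g))
  })

  fdr <- fdr_from_stats(as.numeric(d), perm_d)
  names(fdr) <- rownames(x)
  fdr
}

# Raw and monotone-adjusted permutation FDR from an observed statistic
# vector and a genes x P matrix of permuted statistics.  Split out from
# estimate_fdr() so the estimator can be exercised on hand-built inputs.
fdr_from_stats <- function(d, perm_d) {
  perm_d <- as.matrix(perm_d)
  P <- ncol(perm_d)
  g <- length(d)
  stopifnot(nrow(perm_d) == g)
  pool <- sort(as.numeric(perm_d), method = "radix")      # length P * g
  obs <- sort(d, method = "radix")
  # counts of values >= d(g): total minus count strictly below d(g)
  n_perm_ge <- length(pool) - findInterval(d, pool, left.open = TRUE)
  n_obs_ge <- length(obs) - findInterval(d, obs, left.open = TRUE)
  raw <- pmin(1, pmax(0, (n_perm_ge / P) / n_obs_ge))

  # monotone step-up along the ranking; tied statistics share one value
  ord <- rank_genes(d)
  adj <- rev(cummin(rev(raw[ord])))
  dd <- d[ord]
  first_of_tie <- c(TRUE, dd[-1L] != dd[-length(dd)])
  adj <- adj[cummax(ifelse(first_of_tie, seq_along(adj), 0L))]
  fdr <- numeric(g)
  fdr[ord] <- adj
  fdr
}
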