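#' Bootstrap and null reproducibility curves over the (alpha, k) lattice
#'
#' For every bootstrap pair b and every candidate \eqn{\alpha}, the statistic
#' is computed on both resampled datasets, genes are ranked, and for each
#' top-list size k the overlap \eqn{R_k^b(d_\alpha)} of the two top-k lists
#' is recorded.  The curve values are
#' \deqn{R_k(d_\alpha) = \frac1B \sum_b R_k^b(d_\alpha),}
#' \eqn{s_k(d_\alpha)} the sample SD (denominator B-1) of the B per-pair
#' overlaps, \eqn{R_k^0(d_\alpha)} the mean overlap across the null
#' (label-permutation) pairs, and
#' \deqn{Z_k(d_\alpha) = \frac{R_k(d_\alpha) - R_k^0(d_\alpha)}{s_k(d_\alpha)},}
#' flagged `NA` where \eqn{s_k = 0}.
#'
#' @param x Expression matrix (genes x samples, log2 scale).
#' @param boot Bootstrap plan from [make_bootstrap_pairs()].
#' @param null Null plan from [make_null_pairs()].
#' @param alpha_grid data.frame of candidate `(alpha1, alpha2)` rows;
#'   default [alpha_grid_default()].
#' @param k_grid Increasing top-list sizes; default [k_grid_default()] on
#'   the number of genes.
#' @return An object of class `rots_curves`: `alpha_grid`, `k_grid`, and
#'   matrices `R`, `s`, `R0`, `Z` of dimension n_alpha x n_k.
#' @export
reproducibility_curves <- function(x, boot, null,
                                   alpha_grid = alpha_grid_default(),
                                   k_grid = k_grid_default(nrow(x))) {
  stopifnot(inherits(boot, "rots_plan"), inherits(null, "rots_plan"))
  if (!identical(boot$group, null$group))
    stop("bootstrap and null plans were built on different designs")
  if (length(boot$group) != ncol(x))
    stop("plans cover ", length(boot$group), " columns but matrix has ", ncol(x))
  alpha_grid <- check_alpha_grid(alpha_grid)
  k_grid <- check_k_grid(k_grid, nrow(x))

  ob <- plan_overlaps(x, boot, alpha_grid, k_grid)   # B x n_alpha x n_k
  on <- plan_overlaps(x, null, alpha_grid, k_grid)
  R  <- colMeans(ob)
  R0 <- colMeans(on)
  s  <- apply(ob, c(2L, 3L), sd)
  Z  <- ifelse(s > 0, (R - R0) / s, NA_real_)
  structure(list(alpha_grid = alpha_grid, k_grid = k_grid,
                 R = R, s = s, R0 = R0, Z = Z,
                 B_boot = boot$B, B_null = null$B),
            class = "rots_curves")
}

# Overlap array for one plan: B x n_alpha x n_k.
plan_overlaps <- function(x, plan, alpha_grid, k_grid) {
  g <- nrow(x)
  slots1 <- which(plan$group == 1L)
  slots2 <- which(plan$group == 2L)
  n_alpha <- nrow(alpha_grid)
  n_k <- length(k_grid)
  a1 <- alpha_grid$alpha1
  a2 <- alpha_grid$alpha2
  out <- array(NA_real_, dim = c(plan$B, n_alpha, n_k))
  for (b in seq_len(plan$B)) {
    pr <- plan$pairs[[b]]
    sa <- summaries_idx(x, pr$a[slots1], pr$a[slots2])
    sb <- summaries_idx(x, pr$b[slots1], pr$b[slots2])
    da_num <- abs(sa$mean1 - sa$mean2)
    db_num <- abs(sb$mean1 - sb$mean2)
    for (j in seq_len(n_alpha)) {
      pa <- stat_positions(da_num, sa$s, a1[j], a2[j])
      pb <- stat_positions(db_num, sb$s, a1[j], a2[j])
      shared <- cumsum(tabulate(pmax(pa, pb), g))
      out[b, j, ] <- shared[k_grid] / k_grid
    }
  }
  out
}

# Rank position of each gene under d = num / (a1 + a2 * s); deterministic
# tie-breaks as in rank_genes().
stat_positions <- function(num, s, a1, a2) {
  den <- a1 + a2 * s
  if (a1 == 0 && any(den == 0)) {
    d <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
    ord <- order(-d, ifelse(is.infinite(d), -num, 0), method = "radix")
  } else {
    ord <- order(-(num / den), method = "radix")
  }
  pos <- integer(length(num))
  pos[ord] <- seq_along(num)
  pos
}

#' Select the reproducibility-maximizing lattice point
#'
#' Returns the \eqn{(\alpha_1, \alpha_2, k)} with maximal reproducibility
#' Z-score.  Exact ties break toward larger k, then smaller \eqn{\alpha_1},
#' then larger \eqn{\alpha_2}.
#'
#' @param curves An `rots_curves` object.
#' @return A list `alpha1`, `alpha2`, `k`, `R`, `Z` (R and Z at the optimum).
#' @export
rots_optimize <- function(curves) {
  stopifnot(inherits(curves, "rots_curves"))
  Z <- curves$Z
  if (all(is.na(Z))) stop("data insufficient for optimization: all Z undefined")
  zmax <- max(Z, na.rm = TRUE)
  cand <- which(!is.na(Z) & Z == zmax, arr.ind = TRUE)
  i_a <- cand[, 1L]
  i_k <- cand[, 2L]
  pick <- order(-curves$k_grid[i_k], curves$alpha_grid$alpha1[i_a],
                -curves$alpha_grid$alpha2[i_a])[1L]
  ia <- i_a[pick]; ik <- i_k[pick]
  list(alpha1 = curves$alpha_grid$alpha1[ia],
       alpha2 = curves$alpha_grid$alpha2[ia],
       k = curves$k_grid[ik],
       R = curves$R[ia, ik],
       Z = curves$Z[ia, ik])
}

#' @export
print.rots_curves <- function(x, ...) {
  cat(sprintf("Reproducibility curves: %d alpha points x %d k values (B = %d bootstrap, %d null pairs)\n",
              nrow(x$alpha_grid), length(x$k_grid), x$B_boot, x$B_null))
  opt <- rots_optimize(x)
  cat(sprintf("  max Z = %.3f at alpha = (%g, %g), k = %d (R = %.3f)\n",
              opt$Z, opt$alpha1, opt$alpha2, opt$k, opt$R))
  invisible(x)
}
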