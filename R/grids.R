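#' Default alpha lattice
#'
#' The candidate statistic family is searched over a lattice dense near
#' \eqn{\alpha_1 = 0}, where the statistic is most sensitive to
#' regularization: \eqn{\alpha_2 = 1} with
#' \eqn{\alpha_1 \in \{0, 0.01, \ldots, 1\} \cup \{1.1, 1.2, \ldots, 5\}},
#' plus the single signal log-ratio point \eqn{(\alpha_1 = 1, \alpha_2 = 0)}.
#'
#' @return A data.frame with columns `alpha1`, `alpha2` (one row per lattice
#'   point).
#' @export
alpha_grid_default <- function() {
  a1 <- c(seq(0, 1, by = 0.01), seq(1.1, 5, by = 0.1))
  rbind(data.frame(alpha1 = a1, alpha2 = 1),
        data.frame(alpha1 = 1, alpha2 = 0))
}

#' Default top-list size grid
#'
#' Approximately log-spaced sizes 5, 10, 25, 50, 100, 200, 350, 500, 750,
#' 1000, 1500, 2000, 3000, 5000, 7500, 10000, ... intersected with
#' `[5, n_genes]`, always including `n_genes` itself.
#'
#' @param n_genes Total number of genes G.
#' @return Increasing integer vector of k values.
#' @export
k_grid_default <- function(n_genes) {
  if (n_genes < 5L) stop("need at least 5 genes for a top-list grid")
  base <- c(5, 10, 25, 50, 100, 200, 350, 500, 750)
  m <- 3:ceiling(log10(max(n_genes, 1000)))
  base <- c(base, as.vector(outer(c(1, 1.5, 2, 3, 5, 7.5), 10^m)))
  sort(unique(c(base[base >= 5 & base <= n_genes], n_genes)))
}

check_alpha_grid <- function(alpha_grid) {
  if (!is.data.frame(alpha_grid) ||
      !all(c("alpha1", "alpha2") %in% names(alpha_grid)) ||
      nrow(alpha_grid) == 0L)
    stop("alpha_grid must be a non-empty data.frame with columns alpha1, alpha2")
  for (i in seq_len(nrow(alpha_grid)))
    check_alpha(alpha_grid$alpha1[i], alpha_grid$alpha2[i])
  alpha_grid
}

check_k_grid <- function(k_grid, n_genes) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0L) stop("k_grid is empty")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be strictly increasing")
  if (k_grid[1L] < 1L || k_grid[length(k_grid)] > n_genes)
    stop("k_grid values must lie in [1, ", n_genes, "]")
  k_grid
}
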