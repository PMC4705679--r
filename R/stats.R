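#' Per-gene, per-group means, variances and pooled standard error
#'
#' For gene g and condition j, the sample mean \eqn{\bar x_g^j} and unbiased
#' variance \eqn{(s_g^j)^2} (denominator \eqn{n_j - 1}), and the pooled
#' standard error
#' \deqn{s_g = \sqrt{\left(\frac{1}{n_1}+\frac{1}{n_2}\right)
#'   \frac{(n_1-1)(s_g^1)^2 + (n_2-1)(s_g^2)^2}{n_1+n_2-2}}.}
#'
#' @param x Expression matrix (genes x samples), log2 scale.
#' @param design An `rots_design` aligned with `x`'s columns (or an integer
#'   vector of group labels 1/2, one per column).
#' @return A list with vectors `mean1`, `mean2`, `var1`, `var2`, `s` (pooled
#'   SE) and sizes `n1`, `n2`.
#' @export
group_summaries <- function(x, design) {
  grp <- design_groups(design, ncol(x))
  summaries_idx(x, which(grp == 1L), which(grp == 2L))
}

# Core summary computation on explicit column index vectors (bootstrap
# resamples pass indices with repeats).  Columns may repeat; n is the length
# of the index vector.
summaries_idx <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  s <- sqrt((1 / n1 + 1 / n2) * ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  list(mean1 = m1, mean2 = m2, var1 = v1, var2 = v2, s = s, n1 = n1, n2 = n2)
}

design_groups <- function(design, n_cols) {
  grp <- if (inherits(design, "rots_design")) design$group else as.integer(design)
  if (length(grp) != n_cols)
    stop("design covers ", length(grp), " samples but matrix has ", n_cols, " columns")
  if (!all(grp %in% c(1L, 2L))) stop("group labels must be 1 or 2")
  grp
}

#' Modified t-statistic family
#'
#' \deqn{d_\alpha(g) = \frac{|\bar x_g^1 - \bar x_g^2|}{\alpha_1 + \alpha_2 s_g}}
#' with \eqn{\alpha_1 \ge 0} and \eqn{\alpha_2 \in \{0, 1\}} shared across
#' genes.  \eqn{(\alpha_1{=}0,\alpha_2{=}1)} is the ordinary pooled
#' two-sample t statistic (in absolute value); \eqn{(1, 0)} is the absolute
#' signal log-ratio.  Where the denominator is zero (\eqn{\alpha_1 = 0} and
#' \eqn{s_g = 0}) the statistic is 0 for a zero numerator and `Inf`
#' otherwise; `Inf` ranks above every finite value.
#'
#' @inheritParams group_summaries
#' @param alpha1 Non-negative regularization added to the denominator.
#' @param alpha2 0 or 1: whether the pooled SE enters the denominator.
#' @return Named numeric vector of per-gene statistics, with the absolute
#'   mean difference attached as attribute `"numerator"` (used for ranking
#'   ties among infinite values).
#' @export
d_stat <- function(x, design, alpha1, alpha2) {
  check_alpha(alpha1, alpha2)
  sm <- group_summaries(x, design)
  d <- d_from_summaries(sm$mean1 - sm$mean2, sm$s, alpha1, alpha2)
  names(d) <- rownames(x)
  d
}

check_alpha <- function(alpha1, alpha2) {
  if (!is.numeric(alpha1) || length(alpha1) != 1L || is.na(alpha1) || alpha1 < 0)
    stop("alpha1 must be a single non-negative number")
  if (!(identical(as.numeric(alpha2), 0) || identical(as.numeric(alpha2), 1)))
    stop("alpha2 must be 0 or 1")
  if (alpha1 == 0 && alpha2 == 0)
    stop("alpha1 = 0 with alpha2 = 0 leaves no denominator")
  invisible(TRUE)
}

d_from_summaries <- function(diff, s, alpha1, alpha2) {
  num <- abs(diff)
  den <- alpha1 + alpha2 * s
  d <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  attr(d, "numerator") <- num
  d
}

#' Rank genes by a statistic
#'
#' Indices sorted by statistic, descending.  Ties among finite values break
#' by ascending gene index; ties among infinite values break by descending
#' numerator (absolute mean difference), then ascending index.  Fully
#' deterministic.
#'
#' @param d Per-gene statistic vector, e.g. from [d_stat()].
#' @param numerator Optional numerator vector for infinite-value tie-breaks;
#'   taken from `attr(d, "numerator")` when present.
#' @return Integer vector of gene indices, best-ranked first.
#' @export
rank_genes <- function(d, numerator = attr(d, "numerator")) {
  inf_key <- if (is.null(numerator)) numeric(length(d)) else
    ifelse(is.infinite(d), -numerator, 0)
  order(-d, inf_key, method = "radix")  # radix is stable: index tie-break
}

#' Overlap of two top-k gene lists
#'
#' \eqn{|top_k(a) \cap top_k(b)| / k}: the proportion of genes shared by the
#' first k positions of two orderings.
#'
#' @param order_a,order_b Integer orderings of the same genes (as returned by
#'   [rank_genes()]).
#' @param k Top-list size, between 1 and the number of genes.
#' @return A number in `[0, 1]`.
#' @export
topk_overlap <- function(order_a, order_b, k) {
  g <- length(order_a)
  if (length(order_b) != g) stop("orderings have different lengths")
  if (k < 1L || k > g) stop("k must be in [1, ", g, "]")
  pos_a <- pos_b <- integer(g)
  pos_a[order_a] <- seq_len(g)
  pos_b[order_b] <- seq_len(g)
  sum(pos_a <= k & pos_b <= k) / k
}

# Overlap at every k in k_grid at once: tabulate the later of the two ranks
# per gene and take cumulative counts.
topk_overlap_grid <- function(order_a, order_b, k_grid) {
  g <- length(order_a)
  pos_a <- pos_b <- integer(g)
  pos_a[order_a] <- seq_len(g)
  pos_b[order_b] <- seq_len(g)
  shared <- cumsum(tabulate(pmax(pos_a, pos_b), g))
  shared[k_grid] / k_grid
}
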