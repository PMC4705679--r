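#' Bootstrap resampling plan
#'
#' B pairs of bootstrap datasets, each drawn from the source columns by
#' sampling with replacement *within* each group, preserving group sizes and
#' labels.  Only column indices are stored; the same plan can be replayed on
#' any matrix with matching columns.
#'
#' @param design An `rots_design` (or integer group vector).
#' @param B Number of pairs, at least 2.
#' @param seed Integer seed, or `NULL` to consume the current RNG stream.
#' @return An object of class `rots_plan`: list with `kind = "bootstrap"`,
#'   `B`, `seed`, `group` (per-slot labels, identical for every dataset) and
#'   `pairs` — a list of B elements, each a list of two index vectors `a`,
#'   `b` of length n1+n2.
#' @export
make_bootstrap_pairs <- function(design, B, seed = NULL) {
  grp <- plan_groups(design)
  if (!is.numeric(B) || length(B) != 1L || B < 2) stop("B must be at least 2")
  B <- as.integer(B)
  g1 <- which(grp == 1L); g2 <- which(grp == 2L)
  slots <- c(rep(1L, length(g1)), rep(2L, length(g2)))
  draw <- function() c(sample(g1, length(g1), replace = TRUE),
                       sample(g2, length(g2), replace = TRUE))
  pairs <- with_seed(seed, lapply(seq_len(B), function(b)
    list(a = draw(), b = draw())))
  structure(list(kind = "bootstrap", B = B, seed = seed, group = slots,
                 pairs = pairs),
            class = "rots_plan")
}

#' Null (label-permutation) resampling plan
#'
#' B pairs in which each member is an independent uniform permutation of all
#' columns into two pseudo-groups of the original sizes; every column is
#' used exactly once per member.  This is the baseline against which the
#' bootstrap overlap is standardized.
#'
#' @inheritParams make_bootstrap_pairs
#' @return An `rots_plan` with `kind = "null"`; structure as in
#'   [make_bootstrap_pairs()] (slot s of an index vector belongs to
#'   pseudo-group `group[s]`).
#' @export
make_null_pairs <- function(design, B, seed = NULL) {
  grp <- plan_groups(design)
  if (!is.numeric(B) || length(B) != 1L || B < 2) stop("B must be at least 2")
  B <- as.integer(B)
  n <- length(grp)
  n1 <- sum(grp == 1L)
  slots <- c(rep(1L, n1), rep(2L, n - n1))
  pairs <- with_seed(seed, lapply(seq_len(B), function(b)
    list(a = sample.int(n), b = sample.int(n))))
  structure(list(kind = "null", B = B, seed = seed, group = slots,
                 pairs = pairs),
            class = "rots_plan")
}

plan_groups <- function(design) {
  grp <- if (inherits(design, "rots_design")) design$group else as.integer(design)
  if (!all(grp %in% c(1L, 2L)) || length(unique(grp)) != 2L)
    stop("design must assign each sample to group 1 or 2")
  if (any(tabulate(grp, 2L) < 2L)) stop("each group needs at least 2 samples")
  grp
}

#' @export
print.rots_plan <- function(x, ...) {
  cat(sprintf("%s resampling plan: B = %d pairs, %d columns per dataset\n",
              x$kind, x$B, length(x$group)))
  invisible(x)
}
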