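#' Choose the TMM reference sample
#'
#' The reference is the sample whose 75th-percentile count fraction
#' (upper quartile of counts divided by library size) is closest to the mean
#' of that quantity across samples; ties go to the first such sample.
#'
#' @param counts Count matrix (genes x samples).
#' @return Integer column index of the reference sample.
#' @export
tmm_reference <- function(counts) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (all(lib == 0)) stop("all-zero count matrix: no reference sample")
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- apply(counts, 2L, quantile, probs = 0.75, names = FALSE) / lib
  unname(which.min(abs(f75 - mean(f75))))
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample scaling factors.  For sample k
#' against the reference r, over genes with nonzero counts in both samples:
#' \deqn{M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}, \qquad
#'       A_g = \tfrac12 \log_2\left(\frac{y_{gk}}{N_k}\cdot\frac{y_{gr}}{N_r}\right),}
#' the most extreme `trim_m` fraction by M and `trim_a` fraction by A are
#' discarded on each side, and the factor is
#' \eqn{2^{\sum w_g M_g / \sum w_g}} with inverse asymptotic-variance
#' (delta-method binomial) weights
#' \eqn{w_g = [(N_k - y_{gk})/(N_k y_{gk}) + (N_r - y_{gr})/(N_r y_{gr})]^{-1}}.
#' Factors are rescaled to geometric mean 1.
#'
#' Note the precision weights depend on absolute counts, not only on
#' within-sample proportions: factors are therefore *not* exactly invariant
#' to rescaling a single library's depth (M and A are; the weights are not).
#'
#' @param counts Count matrix.
#' @param trim_m Two-sided trim fraction on M (log-ratio); default 0.30.
#' @param trim_a Two-sided trim fraction on A (absolute expression); default 0.05.
#' @param reference Reference column index; default chosen by [tmm_reference()].
#' @return A list of class `rots_normfactors` with `factors` (named, geometric
#'   mean 1), `lib_sizes` (named library sizes) and `reference`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        reference = tmm_reference(counts)) {
  validate_counts(counts)
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  nsamp <- ncol(counts)
  r <- as.integer(reference)
  stopifnot(r >= 1L, r <= nsamp)
  yr <- counts[, r]
  Nr <- lib[r]
  f <- vapply(seq_len(nsamp), function(k) {
    if (k == r) return(1)
    pairwise_tmm(counts[, k], lib[k], yr, Nr, trim_m, trim_a,
                 id = colnames(counts)[k])
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  structure(list(factors = setNames(f, colnames(counts)),
                 lib_sizes = setNames(lib, colnames(counts)),
                 reference = r),
            class = "rots_normfactors")
}

# One sample against the reference: doubly trimmed, precision-weighted mean
# of M-values on the log2 scale.
pairwise_tmm <- function(yk, Nk, yr, Nr, trim_m, trim_a, id = "?") {
  keep <- yk > 0 & yr > 0
  yk <- yk[keep]; yr <- yr[keep]
  if (length(yk) == 0L) {
    warning("no genes expressed in both sample '", id,
            "' and the reference; factor set to 1")
    return(1)
  }
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  n <- length(M)
  # keep ranks in [floor(n t)+1, n - floor(n t)]: floor(n t) genes trimmed
  # from each end (the published double-trim window)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n - floor(n * trim_m)
  lo_a <- floor(n * trim_a) + 1; hi_a <- n - floor(n * trim_a)
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep2)) {
    warning("no genes survive trimming for sample '", id, "'; factor set to 1")
    return(1)
  }
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))[keep2]
  f <- 2^(sum(w * M[keep2]) / sum(w))
  if (!is.finite(f) || f <= 0) f <- 1
  f
}

#' @export
print.rots_normfactors <- function(x, ...) {
  cat("TMM scaling factors (reference sample:",
      names(x$factors)[x$reference], ")\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Voom-style log-CPM transformation
#'
#' Counts per million on the log2 scale against effective library sizes
#' (raw library size times TMM factor), with a pseudo-count:
#' \deqn{x_{gi} = \log_2\frac{(y_{gi} + \mathrm{prior})\cdot 10^6}{N_i f_i + 1}.}
#' This is the transformation half of voom; per-observation precision
#' weights are not produced because the downstream statistic has no weight
#' slot.
#'
#' @param counts Count matrix.
#' @param factors `rots_normfactors` computed on the same matrix, or `NULL`
#'   for unit factors (pre-normalized input).
#' @param prior Pseudo-count added to each count; must be > 0. Default 0.5.
#' @return Numeric matrix of log2-CPM values, same dimnames as `counts`.
#' @export
logcpm_transform <- function(counts, factors = tmm_factors(counts), prior = 0.5) {
  validate_counts(counts)
  if (prior <= 0) stop("prior must be > 0")
  lib <- colSums(counts)
  if (is.null(factors)) {
    f <- rep(1, ncol(counts))
  } else {
    stopifnot(inherits(factors, "rots_normfactors"))
    if (!identical(names(factors$factors), colnames(counts)))
      stop("factors were not computed on this matrix (sample ids differ)")
    f <- factors$factors
    lib <- factors$lib_sizes
  }
  eff <- lib * f + 1
  x <- log2(sweep(counts + prior, 2L, eff, "/") * 1e6)
  dimnames(x) <- dimnames(counts)
  x
}
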