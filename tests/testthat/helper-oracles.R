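# Independent oracles and tiny fixture builders.  Everything here is written
# from the definitions, deliberately avoiding the package's internal code
# paths, so implementation and oracle can disagree.

# Random count matrix with dimnames.
rand_counts <- function(g, n, mu = 100, size = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnbinom(g * n, mu = mu, size = size), g, n,
              dimnames = list(sprintf("g%03d", seq_len(g)),
                              sprintf("s%02d", seq_len(n))))
  storage.mode(m) <- "integer"
  m
}

# Random expression matrix (continuous, no tied statistics in practice).
rand_expr <- function(g, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(g * n), g, n,
         dimnames = list(sprintf("g%03d", seq_len(g)),
                         sprintf("s%02d", seq_len(n))))
}

two_group <- function(n1, n2) rep(c(1L, 2L), c(n1, n2))

# --- pooled two-sample |t|, straight from t.test -------------------------
oracle_abs_t <- function(x, grp) {
  unname(apply(x, 1L, function(row) {
    a <- row[grp == 1L]; b <- row[grp == 2L]
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) 0 else Inf
    } else {
      abs(unname(t.test(a, b, var.equal = TRUE)$statistic))
    }
  }))
}

# --- ranking: repeatedly pick the largest value, lowest index first; ties
# among infinite values prefer the larger numerator (then lowest index) ----
oracle_rank <- function(d, num = NULL) {
  n <- length(d)
  left <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    cand <- left[d[left] == max(d[left])]
    best <- if (length(cand) > 1L && is.infinite(d[cand[1L]]) && !is.null(num))
      cand[which.max(num[cand])] else cand[1L]
    out[i] <- best
    left <- setdiff(left, best)
  }
  out
}

# --- top-k overlap by literal set intersection ---------------------------
oracle_overlap <- function(a, b, k) length(intersect(a[seq_len(k)], b[seq_len(k)])) / k

# --- TMM: literal trimmed weighted mean for one sample vs reference ------
oracle_tmm_pair <- function(yk, yr, trim_m = 0.30, trim_a = 0.05) {
  Nk <- sum(yk); Nr <- sum(yr)
  keep <- yk > 0 & yr > 0
  yk <- yk[keep]; yr <- yr[keep]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  n <- length(M)
  in_window <- function(v, trim) {
    r <- rank(v)
    r >= floor(n * trim) + 1 & r <= n - floor(n * trim)
  }
  sel <- in_window(M, trim_m) & in_window(A, trim_a)
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  2^(weighted.mean(M[sel], w[sel]))
}

# --- TMM reference: brute-force re-evaluation of the selection rule ------
oracle_tmm_reference <- function(counts) {
  f <- numeric(ncol(counts))
  for (i in seq_len(ncol(counts)))
    f[i] <- quantile(counts[, i], 0.75, names = FALSE) / sum(counts[, i])
  best <- 1L
  for (i in seq_len(ncol(counts)))
    if (abs(f[i] - mean(f)) < abs(f[best] - mean(f))) best <- i
  best
}

# --- full-lattice reproducibility re-evaluation --------------------------
# Slow, literal path: per-gene loops for summaries, intersect() overlaps,
# which.max-free exhaustive scan with the documented tie-breaks.
oracle_d_on_dataset <- function(x, idx1, idx2, a1, a2) {
  m1 <- apply(x[, idx1, drop = FALSE], 1L, mean)
  m2 <- apply(x[, idx2, drop = FALSE], 1L, mean)
  v1 <- apply(x[, idx1, drop = FALSE], 1L, var)
  v2 <- apply(x[, idx2, drop = FALSE], 1L, var)
  n1 <- length(idx1); n2 <- length(idx2)
  s <- sqrt((1 / n1 + 1 / n2) *
              ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  num <- abs(m1 - m2)
  den <- a1 + a2 * s
  d <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  list(d = d, num = num)
}

oracle_curves <- function(x, boot, null, alpha_grid, k_grid) {
  g1 <- which(boot$group == 1L); g2 <- which(boot$group == 2L)
  eval_plan <- function(plan) {
    ov <- array(NA_real_, c(plan$B, nrow(alpha_grid), length(k_grid)))
    for (b in seq_len(plan$B)) {
      pr <- plan$pairs[[b]]
      for (j in seq_len(nrow(alpha_grid))) {
        da <- oracle_d_on_dataset(x, pr$a[g1], pr$a[g2],
                                  alpha_grid$alpha1[j], alpha_grid$alpha2[j])
        db <- oracle_d_on_dataset(x, pr$b[g1], pr$b[g2],
                                  alpha_grid$alpha1[j], alpha_grid$alpha2[j])
        oa <- oracle_rank(da$d, da$num); ob <- oracle_rank(db$d, db$num)
        for (m in seq_along(k_grid))
          ov[b, j, m] <- oracle_overlap(oa, ob, k_grid[m])
      }
    }
    ov
  }
  ob <- eval_plan(boot); on <- eval_plan(null)
  R <- apply(ob, c(2, 3), mean)
  s <- apply(ob, c(2, 3), sd)
  R0 <- apply(on, c(2, 3), mean)
  Z <- ifelse(s > 0, (R - R0) / s, NA_real_)
  list(R = R, s = s, R0 = R0, Z = Z)
}

# Exhaustive scan for the Z maximum with the documented tie-breaks:
# larger k, then smaller alpha1, then larger alpha2.
oracle_best_point <- function(Z, alpha_grid, k_grid) {
  best <- NULL
  for (j in seq_len(nrow(Z))) for (m in seq_len(ncol(Z))) {
    if (is.na(Z[j, m])) next
    cand <- c(Z = Z[j, m], k = k_grid[m],
              a1 = alpha_grid$alpha1[j], a2 = alpha_grid$alpha2[j])
    if (is.null(best) ||
        cand["Z"] > best["Z"] ||
        (cand["Z"] == best["Z"] &&
         (cand["k"] > best["k"] ||
          (cand["k"] == best["k"] &&
           (cand["a1"] < best["a1"] ||
            (cand["a1"] == best["a1"] && cand["a2"] > best["a2"]))))))
      best <- cand
  }
  best
}

# --- fast independent lattice re-evaluation (acceptance scale) -----------
# Same definitions as oracle_curves but with crossprod-based moments,
# rank()-based positions and indicator-sum overlaps, so it stays tractable
# on a 200-gene, B = 50 problem while sharing no code with the package path.
oracle_pos_fast <- function(d, num) {
  pos <- rank(-d, ties.method = "first")
  inf <- which(is.infinite(d))
  if (length(inf) > 1L)
    pos[inf[order(-num[inf], inf)]] <- seq_along(inf)
  pos
}

oracle_scan_curves <- function(x, boot, null, alpha_grid, k_grid) {
  g1 <- which(boot$group == 1L); g2 <- which(boot$group == 2L)
  n1 <- length(g1); n2 <- length(g2)
  moments <- function(idx) {
    xs <- x[, idx, drop = FALSE]
    list(m = apply(xs, 1L, mean), v = apply(xs, 1L, var))
  }
  dataset_positions <- function(idx) {
    a <- moments(idx[g1]); b <- moments(idx[g2])
    num <- abs(a$m - b$m)
    s <- sqrt((1 / n1 + 1 / n2) *
                ((n1 - 1) * a$v + (n2 - 1) * b$v) / (n1 + n2 - 2))
    lapply(seq_len(nrow(alpha_grid)), function(j) {
      den <- alpha_grid$alpha1[j] + alpha_grid$alpha2[j] * s
      d <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
      oracle_pos_fast(d, num)
    })
  }
  eval_plan <- function(plan) {
    ov <- array(NA_real_, c(plan$B, nrow(alpha_grid), length(k_grid)))
    for (b in seq_len(plan$B)) {
      pa <- dataset_positions(plan$pairs[[b]]$a)
      pb <- dataset_positions(plan$pairs[[b]]$b)
      for (j in seq_len(nrow(alpha_grid)))
        for (m in seq_along(k_grid))
          ov[b, j, m] <- sum(pa[[j]] <= k_grid[m] & pb[[j]] <= k_grid[m]) /
            k_grid[m]
    }
    ov
  }
  ob <- eval_plan(boot); on <- eval_plan(null)
  R <- apply(ob, c(2, 3), mean)
  s <- apply(ob, c(2, 3), sd)
  R0 <- apply(on, c(2, 3), mean)
  list(R = R, s = s, R0 = R0, Z = ifelse(s > 0, (R - R0) / s, NA_real_))
}

# --- AUC by brute force over all positive-negative pairs -----------------
oracle_auc <- function(scores, is_de) {
  pos <- scores[is_de]; neg <- scores[!is_de]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
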