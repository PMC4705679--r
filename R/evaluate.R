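#' ROC area under the curve of a gene ranking
#'
#' Mann-Whitney (rank) formulation: the probability that a randomly chosen
#' truly differential gene scores higher than a randomly chosen null gene;
#' ties contribute 1/2.
#'
#' @param scores Per-gene scores, higher = more differential (e.g. the
#'   fitted statistic).
#' @param is_de Logical truth labels (or a truth data.frame from
#'   [simulate_counts()], matched by `gene_id` to `names(scores)`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, is_de) {
  is_de <- truth_labels(is_de, scores)
  if (anyNA(scores)) stop("scores contain NA")
  n_pos <- sum(is_de)
  n_neg <- sum(!is_de)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)                       # midranks: ties count 1/2
  (sum(r[is_de]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts at an FDR cutoff
#'
#' A gene is called differentially expressed when `fdr < cutoff` (strict).
#'
#' @param fdr Per-gene FDR values in `[0, 1]`.
#' @param is_de Logical truth labels (or a truth data.frame, matched by
#'   `gene_id` to `names(fdr)`).
#' @param cutoff FDR call threshold in (0, 1); default 0.05.
#' @return A list of class `rots_eval`: `tp`, `fp`, `tn`, `fn`, `cutoff`,
#'   `n` (genes evaluated).
#' @export
confusion_at_fdr <- function(fdr, is_de, cutoff = 0.05) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be inside (0, 1)")
  is_de <- truth_labels(is_de, fdr)
  if (anyNA(fdr) || any(fdr < 0 | fdr > 1)) stop("fdr values must lie in [0, 1]")
  call <- fdr < cutoff
  structure(list(tp = sum(call & is_de), fp = sum(call & !is_de),
                 tn = sum(!call & !is_de), fn = sum(!call & is_de),
                 cutoff = cutoff, n = length(fdr)),
            class = "rots_eval")
}

#' @export
print.rots_eval <- function(x, ...) {
  cat(sprintf("Calls at FDR < %g over %d genes:\n", x$cutoff, x$n))
  cat(sprintf("  TP = %d  FP = %d  TN = %d  FN = %d\n", x$tp, x$fp, x$tn, x$fn))
  sens <- if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA
  spec <- if (x$tn + x$fp > 0) x$tn / (x$tn + x$fp) else NA
  cat(sprintf("  sensitivity = %.3f  specificity = %.3f\n", sens, spec))
  invisible(x)
}

# Accept either a logical vector aligned with the scores or a truth table
# from simulate_counts(); in the latter case genes absent from the scores
# (e.g. dropped before normalization) are excluded.
truth_labels <- function(is_de, scores) {
  if (is.data.frame(is_de)) {
    stopifnot(all(c("gene_id", "is_de") %in% names(is_de)))
    if (is.null(names(scores)))
      stop("scores must be named by gene_id to match a truth table")
    idx <- match(names(scores), is_de$gene_id)
    if (anyNA(idx)) stop("gene(s) missing from truth table: ",
                         paste(names(scores)[is.na(idx)][1L], "..."))
    return(is_de$is_de[idx])
  }
  if (length(is_de) != length(scores))
    stop("truth labels and scores differ in length")
  as.logical(is_de)
}
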