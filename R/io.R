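#' Read a count matrix from delimited text
#'
#' Expects the layout of GEO-style supplementary count files: a header row of
#' sample identifiers, a first column of gene identifiers, and a body of
#' non-negative integer read counts (genes in rows).
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter.  The default `"auto"` picks tab or comma
#'   by inspecting the header line; pass `"\t"` or `","` to force one.
#' @return An integer matrix with gene identifiers as rownames and sample
#'   identifiers as colnames, in file order.
#' @export
read_counts <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop("count file not found: ", path)
  delimiter <- detect_delimiter(path, delimiter)
  tab <- read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
                    row.names = NULL, colClasses = "character",
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (ncol(tab) < 2L) stop("count file needs a gene-id column plus >= 1 sample column")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("cell is not a non-negative integer: gene '%s', sample '%s' (value '%s')",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]],
                 body[bad[1L, 1L], bad[1L, 2L]]))
  }
  counts <- array(as.integer(num), dim = dim(num),
                  dimnames = list(gene_ids, sample_ids))
  validate_counts(counts)
  counts
}

#' Write a count matrix as tab-delimited text
#'
#' Inverse of [read_counts()]: header row of sample ids, first column of gene
#' ids, tab-delimited.
#'
#' @param counts Integer count matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks the count-matrix contract: a numeric matrix of non-negative whole
#' numbers with unique gene rownames and unique sample colnames.
#'
#' @param counts Matrix to validate.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts contain negative entries")
  if (any(counts != floor(counts))) stop("counts contain non-integer entries")
  invisible(counts)
}

detect_delimiter <- function(path, delimiter) {
  if (!identical(delimiter, "auto")) return(delimiter)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab == 0L && n_com == 0L)
    stop("could not auto-detect delimiter (no tab or comma in header): ", path)
  if (n_tab >= n_com) "\t" else ","
}

#' Construct a two-group sample design
#'
#' Group labels are arbitrary strings; they are mapped to conditions 1 and 2
#' in order of first appearance (the mapping is recorded in the returned
#' object).  Exactly two groups with at least two samples each are required —
#' group variances are undefined below n = 2.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Group label per sample (same length).
#' @return An object of class `rots_design`: a list with `sample_ids`,
#'   `group` (integer 1/2 per sample), `levels` (label mapped to condition 1
#'   and 2), `n1` and `n2`.
#' @export
group_design <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels must have equal length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in design: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("exactly two groups required, got ", length(lev), ": ",
         paste(lev, collapse = ", "))
  group <- match(labels, lev)
  n <- tabulate(group, 2L)
  if (any(n < 2L))
    stop("each group needs at least 2 samples; group '", lev[which(n < 2L)[1L]],
         "' has ", min(n))
  structure(list(sample_ids = sample_ids, group = group, levels = lev,
                 n1 = n[1L], n2 = n[2L]),
            class = "rots_design")
}

#' Read a two-group design file
#'
#' Two delimited columns without header: sample id, group label.
#'
#' @inheritParams read_counts
#' @return An `rots_design` object (see [group_design()]).
#' @export
read_design <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stop("design file not found: ", path)
  delimiter <- detect_delimiter(path, delimiter)
  tab <- read.table(path, sep = delimiter, header = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) stop("design file must have exactly two columns")
  group_design(tab[[1L]], tab[[2L]])
}

#' Write a design to disk
#' @param design An `rots_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "rots_design"))
  write.table(data.frame(design$sample_ids, design$levels[design$group]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @export
print.rots_design <- function(x, ...) {
  cat(sprintf("Two-group design: %d samples (group 1 '%s': n=%d; group 2 '%s': n=%d)\n",
              length(x$sample_ids), x$levels[1L], x$n1, x$levels[2L], x$n2))
  invisible(x)
}

#' Align a design with a count matrix
#'
#' Checks that every column of the matrix has a group assignment and returns
#' the design reordered to the matrix's column order.  The label-to-condition
#' mapping of the original design is preserved (conditions are not renumbered
#' by the new sample order).
#' @param design An `rots_design`.
#' @param counts A count or expression matrix with sample colnames.
#' @return The reordered `rots_design`.
#' @export
align_design <- function(design, counts) {
  stopifnot(inherits(design, "rots_design"))
  idx <- match(colnames(counts), design$sample_ids)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  group <- design$group[idx]
  n <- tabulate(group, 2L)
  if (any(n < 2L))
    stop("each group needs at least 2 samples after alignment; group '",
         design$levels[which(n < 2L)[1L]], "' has ", min(n))
  structure(list(sample_ids = design$sample_ids[idx], group = group,
                 levels = design$levels, n1 = n[1L], n2 = n[2L]),
            class = "rots_design")
}

#' Write a ROTS result table and run summary
#'
#' Writes a tab-delimited table (`gene_id`, `statistic`, `logfc`, `fdr`) to
#' `path` and a machine-parseable key/value summary of the optimization
#' (`alpha1`, `alpha2`, `k_opt`, `R_opt`, `Z_opt`, `B`, `P`, `seed`,
#' `n_genes`, `dropped_genes`, sample order) to `summary_path`.
#'
#' @param fit An `rots_fit` from [rots()].
#' @param path Output path for the gene table.
#' @param summary_path Output path for the run summary; default
#'   `paste0(path, ".summary")`.
#' @export
write_results <- function(fit, path, summary_path = paste0(path, ".summary")) {
  stopifnot(inherits(fit, "rots_fit"))
  tab <- fit$table[, c("gene_id", "statistic", "logfc", "fdr")]
  write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  opt <- fit$optimum
  kv <- c(alpha1 = opt$alpha1, alpha2 = opt$alpha2, k_opt = opt$k,
          R_opt = opt$R, Z_opt = opt$Z, B = fit$B, P = fit$P,
          seed = fit$seed %||% NA, n_genes = nrow(fit$table),
          dropped_genes = fit$dropped_genes,
          samples = paste(fit$sample_ids, collapse = ","))
  writeLines(paste(names(kv), unname(kv), sep = "\t"), summary_path)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path Path to the gene table.
#' @return A data.frame with columns `gene_id`, `statistic`, `logfc`, `fdr`.
#' @export
read_results <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "numeric", "numeric"))
  stopifnot(identical(names(tab), c("gene_id", "statistic", "logfc", "fdr")))
  tab
}

#' Read back a run summary written by [write_results()]
#' @param path Path to the summary file.
#' @return A named list; numeric fields are converted back to numbers.
#' @export
read_run_summary <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) {
    v <- paste(p[-1L], collapse = "\t")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(parts, `[[`, "", 1L)
  out
}
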