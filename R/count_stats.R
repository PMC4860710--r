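#' @importFrom edgeR DGEList calcNormFactors estimateCommonDisp
#'   estimateTagwiseDisp exactTest cpm
NULL

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("counts must be a non-empty matrix")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique row ids")
  invisible(counts)
}

check_two_groups <- function(group, n_cols) {
  group <- as.factor(group)
  if (length(group) != n_cols)
    stop("group must label every sample (column)")
  if (nlevels(group) != 2L)
    stop("exactly two groups are required")
  group
}

#' Retain rows at or above a row-sum percentile
#'
#' Low-abundance filter: rows whose tag-count sum falls below the `q`-th
#' percentile of all row sums are dropped. The percentile is computed by
#' linear interpolation between order statistics; rows tied with the
#' threshold are retained. Typical settings: 50 for methylation region
#' counts, 30 for gene counts.
#'
#' @param counts Integer matrix with row ids.
#' @param q Percentile in \[0, 100\].
#' @return Character vector of retained row ids.
#' @export
percentile_filter <- function(counts, q) {
  check_count_matrix(counts)
  if (length(q) != 1L || is.na(q) || q < 0 || q > 100)
    stop("q must be a single percentile in [0, 100]")
  rs <- rowSums(counts)
  thr <- stats::quantile(rs, q / 100, type = 7, names = FALSE)
  rownames(counts)[rs >= thr]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors: per-sample M- and A-values
#' against a reference library are doubly trimmed (30% on M, 5% on A) and the
#' retained M-values averaged with precision (delta-method) weights; the
#' factor is 2^(weighted mean). Factors are rescaled to geometric mean 1.
#' The reference defaults to the sample whose upper quartile is closest to
#' the mean upper quartile.
#'
#' @param counts Integer matrix (rows x samples).
#' @param lib_sizes Per-sample library sizes; default column sums.
#' @param reference Optional sample name or index to use as reference.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, reference = NULL) {
  check_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least two samples")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) match(reference, colnames(counts))
           else as.integer(reference)
    if (is.na(ref) || ref < 1L || ref > ncol(counts))
      stop("reference sample not found")
  }
  d <- DGEList(counts = counts, lib.size = as.numeric(lib_sizes))
  d <- if (is.null(ref)) calcNormFactors(d, method = "TMM")
       else calcNormFactors(d, method = "TMM", refColumn = ref)
  f <- d$samples$norm.factors
  names(f) <- colnames(counts)
  f
}

#' Estimate negative-binomial dispersion
#'
#' Common dispersion by conditional maximum likelihood on equalized
#' (quantile-adjusted) libraries; optionally tagwise dispersions shrunk
#' toward the common value by weighted likelihood.
#'
#' @param counts Integer matrix.
#' @param group Two-level factor over columns.
#' @param lib_sizes Optional library sizes (default column sums).
#' @param tagwise If `TRUE`, also return shrunken per-row dispersions.
#' @return List with `common` (scalar phi >= 0) and, when requested,
#'   `tagwise` (named vector).
#' @export
estimate_dispersion <- function(counts, group, lib_sizes = NULL,
                                tagwise = FALSE) {
  check_count_matrix(counts)
  group <- check_two_groups(group, ncol(counts))
  if (all(table(group) < 2L))
    stop("dispersion requires >= 2 samples in at least one group")
  if (all(counts == 0)) {
    warning("all counts are zero; dispersion set to 0")
    return(list(common = 0))
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  d <- DGEList(counts = counts, group = group,
               lib.size = as.numeric(lib_sizes))
  d <- estimateCommonDisp(d)
  out <- list(common = max(d$common.dispersion, 0))
  if (tagwise) {
    d <- estimateTagwiseDisp(d)
    out$tagwise <- stats::setNames(d$tagwise.dispersion, rownames(counts))
  }
  out
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Counts are quantile-adjusted to a common effective library size
#' (library size x TMM factor); conditional on each row total, the two-sided
#' exact p-value aggregates the probabilities of splits as or less likely
#' than observed (doubled smaller tail, capped at 1). The log2 fold change
#' (second group level over first) uses group-average CPM with a prior count
#' of 0.5.
#'
#' @param counts Integer matrix.
#' @param group Two-level factor; the first level is the baseline
#'   (e.g. control), the second the condition whose enrichment gives
#'   positive logFC.
#' @param lib_sizes Optional library sizes (default column sums).
#' @param norm_factors Optional TMM factors (default all 1).
#' @param dispersion NB dispersion phi (scalar, or per-row vector).
#' @return data.frame with columns `id`, `logFC`, `logCPM`, `pvalue`,
#'   plus attribute `dispersion`.
#' @export
exact_test <- function(counts, group, lib_sizes = NULL, norm_factors = NULL,
                       dispersion = 0) {
  check_count_matrix(counts)
  group <- check_two_groups(group, ncol(counts))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (any(norm_factors <= 0)) stop("normalization factors must be positive")
  d <- DGEList(counts = counts, group = group,
               lib.size = as.numeric(lib_sizes))
  d$samples$norm.factors <- as.numeric(norm_factors)
  et <- exactTest(d, pair = levels(group), dispersion = dispersion,
                  prior.count = 0.5)
  res <- data.frame(id = rownames(counts),
                    logFC = et$table$logFC,
                    logCPM = et$table$logCPM,
                    pvalue = pmin(et$table$PValue, 1),
                    stringsAsFactors = FALSE)
  attr(res, "dispersion") <- dispersion
  res
}

#' One-call differential count test
#'
#' Convenience wrapper chaining [percentile_filter()], [tmm_factors()],
#' [estimate_dispersion()] and [exact_test()] — the shared core of the
#' methylation and expression pipelines.
#'
#' @param counts Integer matrix.
#' @param group Two-level factor (first level = baseline).
#' @param filter_q Row-sum percentile filter (e.g. 50 for regions, 30 for
#'   genes).
#' @param lib_sizes Library sizes; default = column sums of the *unfiltered*
#'   matrix (total tags before row filtering).
#' @return data.frame as from [exact_test()], restricted to retained rows,
#'   with attributes `retained`, `norm_factors`, `dispersion`.
#' @export
diff_count_test <- function(counts, group, filter_q, lib_sizes = NULL) {
  check_count_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  keep <- percentile_filter(counts, filter_q)
  sub <- counts[keep, , drop = FALSE]
  f <- tmm_factors(sub, lib_sizes = lib_sizes)
  phi <- estimate_dispersion(sub, group, lib_sizes = lib_sizes)$common
  res <- exact_test(sub, group, lib_sizes = lib_sizes, norm_factors = f,
                    dispersion = phi)
  attr(res, "retained") <- keep
  attr(res, "norm_factors") <- f
  attr(res, "dispersion") <- phi
  res
}

#' Write / read a differential-test table as TSV
#'
#' @param res data.frame from [exact_test()] or [diff_count_test()].
#' @param path Output path.
#' @param header Optional `#`-prefixed comment line(s).
#' @return Invisibly, `path`.
#' @export
write_diff_table <- function(res, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_table
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @param counts Matrix to serialize (first column will hold row ids).
#' @rdname write_diff_table
#' @export
write_count_tsv <- function(counts, path, header = NULL) {
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
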