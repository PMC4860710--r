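#' Differential expression test
#'
#' Gene-level mirror of the methylation pipeline: 30th-percentile row-sum
#' filter, TMM normalization, common NB dispersion and the two-group exact
#' test, thresholded at `p_cutoff`. Rows may be transcripts (default; the
#' downstream rank-score rule collapses transcripts to genes by lowest
#' p-value) or pre-collapsed genes (`collapse = "gene"` sums transcript
#' counts per gene before testing).
#'
#' @param counts Integer matrix, transcripts (or genes) x samples.
#' @param group Two-level factor; first level = control.
#' @param tx2gene Named character vector transcript id -> gene id. Default:
#'   rows are genes already (identity map).
#' @param p_cutoff Significance threshold (default 0.001; the relaxed
#'   exploratory setting is 0.01).
#' @param filter_q Row-sum percentile filter (default 30).
#' @param collapse `"transcript"` (default) or `"gene"`.
#' @param lib_sizes Optional library sizes (default column sums before
#'   filtering).
#' @return Object of class `de_result`: list with `table` (full per-row
#'   results incl. `gene`), `de` (thresholded gene list: `gene`, `logFC`,
#'   `pvalue`, `direction` up/down, from each gene's lowest-p row),
#'   `dispersion`, `norm_factors`.
#' @export
de_test <- function(counts, group, tx2gene = NULL, p_cutoff = 0.001,
                    filter_q = 30, collapse = c("transcript", "gene"),
                    lib_sizes = NULL) {
  collapse <- match.arg(collapse)
  check_count_matrix(counts)
  if (is.null(tx2gene))
    tx2gene <- stats::setNames(rownames(counts), rownames(counts))
  if (!all(rownames(counts) %in% names(tx2gene)))
    stop("every row must map to a gene via tx2gene")
  if (collapse == "gene") {
    g <- tx2gene[rownames(counts)]
    counts <- rowsum(counts, g)
    storage.mode(counts) <- "integer"
    tx2gene <- stats::setNames(rownames(counts), rownames(counts))
  }
  res <- diff_count_test(counts, group, filter_q = filter_q,
                         lib_sizes = lib_sizes)
  tab <- data.frame(id = res$id, gene = unname(tx2gene[res$id]),
                    logFC = res$logFC, logCPM = res$logCPM,
                    pvalue = res$pvalue, stringsAsFactors = FALSE)
  # per-gene representative = lowest-p row (ties: first by id order)
  o <- order(tab$gene, tab$pvalue, tab$id)
  best <- tab[o, ][!duplicated(tab$gene[o]), , drop = FALSE]
  de <- best[best$pvalue < p_cutoff, , drop = FALSE]
  de <- data.frame(gene = de$gene, logFC = de$logFC, pvalue = de$pvalue,
                   direction = ifelse(de$logFC >= 0, "up", "down"),
                   stringsAsFactors = FALSE)
  de <- de[order(de$pvalue, de$gene), , drop = FALSE]
  rownames(de) <- NULL
  structure(list(table = tab, de = de,
                 dispersion = attr(res, "dispersion"),
                 norm_factors = attr(res, "norm_factors")),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$table), "rows tested,", nrow(x$de),
      "DE genes (", sum(x$de$direction == "up"), "up /",
      sum(x$de$direction == "down"), "down )\n")
  invisible(x)
}

#' Direction-matched DE gene intersections across three models
#'
#' Gene-id set algebra: a gene is common to a pair (or to all three) when it
#' is differentially expressed in the same direction in each.
#'
#' @param models Named list of three DE gene data.frames (`gene`,
#'   `direction`) or `de_result` objects.
#' @return List with per-direction `pairwise` (data.frame of counts and
#'   gene lists per unordered pair) and `triple` (genes common to all
#'   three), plus `totals`.
#' @export
cross_model_de <- function(models) {
  if (length(models) != 3L) stop("exactly three models are required")
  if (is.null(names(models))) names(models) <- paste0("model", 1:3)
  frames <- lapply(models, function(x)
    if (inherits(x, "de_result")) x$de else x)
  nm <- names(models)
  dir_set <- function(f, dir) unique(f$gene[f$direction == dir])
  out <- list(totals = vapply(frames, nrow, 0L))
  for (dir in c("up", "down")) {
    sets <- lapply(frames, dir_set, dir = dir)
    pw <- list()
    combos <- utils::combn(3L, 2L)
    for (k in seq_len(ncol(combos))) {
      i <- combos[1L, k]; j <- combos[2L, k]
      genes <- intersect(sets[[i]], sets[[j]])
      pw[[k]] <- data.frame(a = nm[i], b = nm[j], n = length(genes),
                            genes = paste(sort(genes), collapse = ","),
                            stringsAsFactors = FALSE)
    }
    triple <- Reduce(intersect, sets)
    out[[dir]] <- list(pairwise = do.call(rbind, pw),
                       triple = sort(triple))
  }
  out
}
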