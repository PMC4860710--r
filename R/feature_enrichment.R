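FEATURE_CLASSES <- c("cpg_island", "snp", "promoter_200", "promoter_5k",
                     "tss", "gene_body", "utr5", "coding_exon", "intron",
                     "utr3", "non_genic")

#' Build a genomic feature annotation
#'
#' Materializes the 11 feature classes used throughout the package from a
#' gene table: CpG islands, SNPs, promoters (200 bp and 5 kb upstream of the
#' TSS, strand-aware, clipped to the chromosome), TSSs (single base at the
#' gene 5' end), gene bodies (including UTRs), 5'UTRs, coding exons
#' (exons minus UTRs), introns (gene body minus exons), 3'UTRs, and
#' non-genic regions (genome complement of gene bodies and 5 kb promoters).
#' Gene bodies are assumed non-overlapping (as produced by
#' [generate_annotation()]).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open gene body including UTRs), `strand` (`+`/`-`),
#'   and optionally `utr5_len`, `utr3_len` (bp at the respective gene ends,
#'   default 0).
#' @param exons data.frame with columns `gene_id`, `start`, `end` (absolute
#'   0-based coordinates within the gene body).
#' @param cpg_islands `GRanges` (or NULL) of CpG islands.
#' @param snps Either a `GRanges` or a data.frame with `chrom`, `pos`
#'   (0-based single-base positions); may be NULL.
#' @param genome Named numeric vector of chromosome lengths.
#' @return Object of class `feature_annotation`: list with `features`
#'   (named list of `GRanges`, gene-linked classes carry `gene_id`
#'   metadata), `genes` (the gene table) and `genome`.
#' @export
build_annotation <- function(genes, exons, cpg_islands = NULL, snps = NULL,
                             genome) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  if (any(!genes$strand %in% c("+", "-")))
    stop("every gene must have strand '+' or '-'")
  if (is.null(genes$utr5_len)) genes$utr5_len <- 0L
  if (is.null(genes$utr3_len)) genes$utr3_len <- 0L
  n <- nrow(genes)
  empty_gr <- function() interval_set(character(), integer(), integer(),
                                      genome = genome)
  gene_gr <- function(start, end, id) {
    keep <- end > start
    interval_set(genes$chrom[keep], start[keep], end[keep],
                 strand = genes$strand[keep], id = id[keep], genome = genome)
  }
  plus <- genes$strand == "+"
  chrom_len <- genome[genes$chrom]
  if (n && any(genes$end > chrom_len))
    stop("gene body extends beyond chromosome length")

  tss_pos <- ifelse(plus, genes$start, genes$end - 1L)
  features <- list()
  features$gene_body <- if (n) gene_gr(genes$start, genes$end, genes$gene_id)
                        else empty_gr()
  features$tss <- if (n) gene_gr(tss_pos, tss_pos + 1L, genes$gene_id)
                  else empty_gr()
  promoter <- function(width) {
    if (!n) return(empty_gr())
    ps <- ifelse(plus, pmax(genes$start - width, 0), genes$end)
    pe <- ifelse(plus, genes$start, pmin(genes$end + width, chrom_len))
    gene_gr(ps, pe, genes$gene_id)
  }
  features$promoter_200 <- promoter(200L)
  features$promoter_5k <- promoter(5000L)
  u5s <- ifelse(plus, genes$start, genes$end - genes$utr5_len)
  u5e <- ifelse(plus, genes$start + genes$utr5_len, genes$end)
  u3s <- ifelse(plus, genes$end - genes$utr3_len, genes$start)
  u3e <- ifelse(plus, genes$end, genes$start + genes$utr3_len)
  features$utr5 <- if (n) gene_gr(u5s, u5e, genes$gene_id) else empty_gr()
  features$utr3 <- if (n) gene_gr(u3s, u3e, genes$gene_id) else empty_gr()

  if (!is.null(exons) && nrow(exons)) {
    chrom_of <- genes$chrom[match(exons$gene_id, genes$gene_id)]
    exon_gr <- interval_set(chrom_of, exons$start, exons$end,
                            id = exons$gene_id, genome = genome)
    utr_all <- reduce(c(granges_only(features$utr5),
                        granges_only(features$utr3)), ignore.strand = TRUE)
    ce <- GenomicRanges::setdiff(reduce(granges_only(exon_gr),
                                        ignore.strand = TRUE),
                                 utr_all, ignore.strand = TRUE)
    features$coding_exon <- map_gene_ids(ce, features$gene_body)
    intr <- GenomicRanges::setdiff(reduce(granges_only(features$gene_body),
                                          ignore.strand = TRUE),
                                   reduce(granges_only(exon_gr),
                                          ignore.strand = TRUE),
                                   ignore.strand = TRUE)
    features$intron <- map_gene_ids(intr, features$gene_body)
  } else {
    features$coding_exon <- empty_gr()
    features$intron <- empty_gr()
  }

  features$cpg_island <- if (is.null(cpg_islands)) empty_gr()
                         else set_genome(cpg_islands, genome)
  features$snp <- if (is.null(snps)) empty_gr()
    else if (inherits(snps, "GRanges")) set_genome(snps, genome)
    else interval_set(snps$chrom, snps$pos, snps$pos + 1L, genome = genome)

  genic <- c(granges_only(features$gene_body),
             granges_only(features$promoter_5k))
  features$non_genic <- if (length(genic)) complement_intervals(genic)
    else interval_set(names(genome), rep(0, length(genome)), genome,
                      genome = genome)
  features <- features[FEATURE_CLASSES]
  structure(list(features = features, genes = genes, genome = genome),
            class = "feature_annotation")
}

granges_only <- function(gr) {
  mcols(gr) <- NULL
  strand(gr) <- "*"
  gr
}

map_gene_ids <- function(gr, gene_body) {
  gr <- sort_intervals(gr)
  hits <- findOverlaps(gr, gene_body, ignore.strand = TRUE, select = "first")
  mcols(gr)$id <- mcols(gene_body)$id[hits]
  gr
}

#' @export
print.feature_annotation <- function(x, ...) {
  cat("feature_annotation:", nrow(x$genes), "genes on",
      length(x$genome), "chromosome(s)\n")
  for (f in names(x$features))
    cat(sprintf("  %-13s %6d intervals\n", f, length(x$features[[f]])))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test with the usual two-sided rule: the
#' p-value sums the probabilities of all tables (margins fixed) whose point
#' probability does not exceed the observed one. An empty margin yields
#' p = 1 by convention.
#'
#' @param a,b,c,d Nonnegative integer cells: `a` differential regions
#'   overlapping the feature, `b` differential not overlapping, `c`
#'   non-differential overlapping, `d` non-differential not overlapping.
#' @return Two-sided p-value.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be nonnegative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(1)
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Log2 odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a d)/(b c)`; when any cell is zero all four cells get the
#' Haldane-Anscombe +0.5 correction. The Woolf interval is
#' `ln OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)` on corrected cells, converted
#' to the log2 scale.
#'
#' @inheritParams fisher_two_sided
#' @return Numeric vector `c(log2OR, ci_lo, ci_hi)`.
#' @export
log2_or_ci <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  ln_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- (ln_or + c(-1, 1) * 1.96 * se) / log(2)
  c(log2OR = ln_or / log(2), ci_lo = ci[1], ci_hi = ci[2])
}

#' Genomic-feature enrichment profile of DMRs
#'
#' For every feature class and direction, compares differential regions
#' against the non-differential tested regions: `a` = DMRs of that direction
#' overlapping (>= 1 bp) the feature, `c` = non-differential regions
#' overlapping, with `b`, `d` their complements. Emits the log2 odds ratio
#' with Woolf 95% CI and a two-sided Fisher p. A `hyper_vs_hypo` contrast
#' per feature (increased vs decreased methylation regions) is appended.
#' The unit of analysis is the tested region; a region may count toward
#' several (non-exclusive) features.
#'
#' @param dmr_res A `dmr_result` from [call_dmrs()], or a list with `dmrs`
#'   (data.frame incl. `id`, `direction`) and `tested` (`GRanges` with ids).
#' @param ann [build_annotation()] result.
#' @param features Feature classes to profile (default all 11).
#' @return data.frame with columns `feature`, `direction`, `a`, `b`, `c`,
#'   `d`, `log2OR`, `ci_lo`, `ci_hi`, `p`, `estimable`.
#' @export
enrichment_profile <- function(dmr_res, ann,
                               features = FEATURE_CLASSES) {
  tested <- dmr_res$tested
  ids <- region_ids(tested)
  dmr_ids <- split(dmr_res$dmrs$id, dmr_res$dmrs$direction)
  hyper <- ids %in% dmr_ids[["hyper"]]
  hypo <- ids %in% dmr_ids[["hypo"]]
  nondiff <- !(hyper | hypo)
  rows <- list()
  for (f in features) {
    hit <- countOverlaps(tested, granges_only(ann$features[[f]]),
                         minoverlap = 1L, ignore.strand = TRUE) > 0
    for (dir in c("hyper", "hypo")) {
      sel <- if (dir == "hyper") hyper else hypo
      a <- sum(hit & sel); b <- sum(!hit & sel)
      cc <- sum(hit & nondiff); dd <- sum(!hit & nondiff)
      est <- (a + b) > 0
      stat <- if (est) log2_or_ci(a, b, cc, dd) else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, direction = dir, a = a, b = b, c = cc, d = dd,
        log2OR = stat[1], ci_lo = stat[2], ci_hi = stat[3],
        p = if (est) fisher_two_sided(a, b, cc, dd) else NA_real_,
        estimable = est, stringsAsFactors = FALSE)
    }
    a <- sum(hit & hyper); b <- sum(!hit & hyper)
    cc <- sum(hit & hypo); dd <- sum(!hit & hypo)
    est <- (a + b) > 0 && (cc + dd) > 0
    stat <- if (est) log2_or_ci(a, b, cc, dd) else rep(NA_real_, 3)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, direction = "hyper_vs_hypo", a = a, b = b, c = cc, d = dd,
      log2OR = stat[1], ci_lo = stat[2], ci_hi = stat[3],
      p = if (est) fisher_two_sided(a, b, cc, dd) else NA_real_,
      estimable = est, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
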