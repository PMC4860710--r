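#' Build signed rank scores from a differential-expression table
#'
#' Per gene, the transcript with the smallest p-value is taken as
#' representative and the score is `-log10(p) * sign(logFC)`: upregulated
#' genes score positive, downregulated negative. p-values are floored at
#' 1e-300 (with a warning when the floor binds). The list is sorted by
#' decreasing score, ties broken by gene id.
#'
#' @param tab data.frame with columns `gene`, `logFC`, `pvalue` (e.g. the
#'   `table` element of [de_test()]).
#' @param p_floor Smallest admissible p-value (default 1e-300).
#' @return Named numeric vector of scores, sorted descending.
#' @export
build_rank_scores <- function(tab, p_floor = 1e-300) {
  need <- c("gene", "logFC", "pvalue")
  if (!all(need %in% names(tab)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$pvalue < p_floor))
    warning("p-value(s) below ", p_floor, " floored")
  o <- order(tab$gene, tab$pvalue)
  best <- tab[o, ][!duplicated(tab$gene[o]), , drop = FALSE]
  s <- -log10(pmax(best$pvalue, p_floor)) * sign(best$logFC)
  names(s) <- best$gene
  s[order(-s, names(s))]
}

#' Methylation-derived gene sets for preranked GSEA
#'
#' Builds one gene set per (feature class, methylation direction): a gene
#' joins set (f, increased) when some hypermethylated DMR overlaps (>= 1 bp)
#' feature f of that gene, and likewise (f, decreased) for hypomethylated
#' DMRs. Features: 5 kb promoter, CpG island within the 5 kb promoter,
#' TSS, 3'UTR, coding exon, intron, 5'UTR. Empty sets are dropped; an empty
#' DMR input yields an empty collection with a warning (analysis not
#' available).
#'
#' @param dmrs DMR data.frame (columns `chrom`, `start`, `end`, `id`,
#'   `direction`, optionally `pvalue`) or a `dmr_result`.
#' @param ann [build_annotation()] result.
#' @param p_cutoff Optional p-value filter applied to `dmrs` first
#'   (e.g. 0.001).
#' @return Named list of gene-id character vectors; names are
#'   `<feature>_<increased|decreased>`.
#' @export
build_methylation_gene_sets <- function(dmrs, ann, p_cutoff = NULL) {
  dmrs <- as_dmr_frame(dmrs)
  if (!is.null(p_cutoff)) dmrs <- dmrs[dmrs$pvalue < p_cutoff, , drop = FALSE]
  if (nrow(dmrs) == 0L) {
    warning("no DMRs supplied; gene-set collection is empty ",
            "(analysis not available)")
    return(stats::setNames(list(), character()))
  }
  gr <- dmr_granges(dmrs, genome = ann$genome)
  feat_map <- c(promoter_5k = "promoter_5k", tss = "tss", utr3 = "utr3",
                exon = "coding_exon", intron = "intron", utr5 = "utr5")
  dir_lab <- c(hyper = "increased", hypo = "decreased")
  # CpG islands lying in a gene's 5 kb promoter, labelled with that gene
  cgi <- granges_only(ann$features$cpg_island)
  prom <- ann$features$promoter_5k
  cgi_hits <- findOverlaps(cgi, prom, minoverlap = 1L, ignore.strand = TRUE)
  sets <- list()
  for (dir in c("hyper", "hypo")) {
    sub <- gr[mcols(gr)$direction == dir]
    if (!length(sub)) next
    for (f in names(feat_map)) {
      feat <- ann$features[[feat_map[[f]]]]
      hits <- findOverlaps(sub, feat, minoverlap = 1L, ignore.strand = TRUE)
      genes <- sort(unique(mcols(feat)$id[subjectHits(hits)]))
      genes <- genes[!is.na(genes)]
      if (length(genes))
        sets[[paste0(f, "_", dir_lab[[dir]])]] <- genes
    }
    hits <- findOverlaps(sub, cgi, minoverlap = 1L, ignore.strand = TRUE)
    ci <- unique(subjectHits(hits))
    genes <- sort(unique(
      mcols(prom)$id[subjectHits(cgi_hits)[queryHits(cgi_hits) %in% ci]]))
    if (length(genes))
      sets[[paste0("cgi_in_promoter_", dir_lab[[dir]])]] <- genes
  }
  sets
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over the ranked list: hits advance by
#' `|score|^weight` (normalized over the set), misses by `1 / (N - |S|)`;
#' the ES is the running-sum value of largest magnitude (first such
#' position on ties, for determinism). If all member scores are zero the
#' ES is 0 by convention.
#'
#' @param scores Named numeric vector sorted descending (see
#'   [build_rank_scores()]).
#' @param set Character vector of gene ids (members outside the universe
#'   are ignored).
#' @param weight Exponent on `|score|` (default 1, the standard weighted
#'   statistic).
#' @return List with `es` and `running` (the length-N running sum).
#' @export
enrichment_score <- function(scores, set, weight = 1) {
  hit <- names(scores) %in% set
  if (!any(hit)) stop("gene set has no members in the ranked universe")
  es_running(scores, hit, weight)
}

es_running <- function(scores, hit, weight) {
  n <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight * hit
  tot <- sum(w)
  if (tot == 0) return(list(es = 0, running = numeric(n)))
  p_hit <- cumsum(w) / tot
  if (n == nh) {
    run <- p_hit
  } else {
    run <- p_hit - cumsum(!hit) / (n - nh)
  }
  run <- unname(run)
  list(es = run[which.max(abs(run))], running = run)
}

es_only <- function(scores_abs_w, hit, n, nh) {
  # fast path used by the permutation loop; scores_abs_w = |s|^weight
  w <- scores_abs_w * hit
  tot <- sum(w)
  if (tot == 0) return(0)
  run <- if (n == nh) cumsum(w) / tot
         else cumsum(w) / tot - cumsum(!hit) / (n - nh)
  unname(run[which.max(abs(run))])
}

#' Preranked GSEA with gene-set permutations
#'
#' For each gene set, the null distribution of the enrichment score is
#' obtained from `n_perm` random same-size gene sets drawn from the ranked
#' universe. The nominal p-value is the fraction of same-sign null ES at
#' least as extreme as the observed ES; NES divides the ES by the mean
#' magnitude of same-sign null ES. The FDR q-value follows the classic
#' GSEA procedure on pooled normalized nulls: for a set with NES*, the
#' tail fraction of pooled null NES beyond NES* (conditioned on sign) is
#' divided by the corresponding tail fraction of observed NES, capped at 1.
#' Sets are flagged significant at `fdr_cutoff` (default 0.25).
#'
#' @param scores Named numeric vector sorted descending.
#' @param sets Named list of gene-id vectors (see
#'   [build_methylation_gene_sets()]).
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param seed RNG seed for the permutations (default 1).
#' @param weight ES weight exponent (default 1).
#' @param fdr_cutoff Significance threshold on q (default 0.25).
#' @param min_size Sets with fewer in-universe members are dropped
#'   (default 1).
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p_nominal`,
#'   `fdr`, `significant`, sorted by `fdr` then name.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = 1,
                           weight = 1, fdr_cutoff = 0.25, min_size = 1) {
  if (is.null(names(scores))) stop("scores must be named by gene id")
  scores <- scores[order(-scores, names(scores))]
  n <- length(scores)
  sets <- lapply(sets, function(s) intersect(s, names(scores)))
  sizes <- lengths(sets)
  if (any(sizes > n)) stop("a gene set is larger than the ranked universe")
  keep <- sizes >= min_size
  sets <- sets[keep]; sizes <- sizes[keep]
  if (!length(sets)) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_nominal = numeric(),
                      fdr = numeric(), significant = logical()))
  }
  sw <- abs(scores)^weight
  obs_es <- vapply(names(sets), function(nm)
    es_only(sw, names(scores) %in% sets[[nm]], n, sizes[[nm]]), 0)
  # one shared null per distinct set size
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- with_seed(seed, {
    lapply(stats::setNames(uniq_sizes, uniq_sizes), function(s) {
      vapply(seq_len(n_perm), function(k) {
        hit <- logical(n)
        hit[sample.int(n, s)] <- TRUE
        es_only(sw, hit, n, s)
      }, 0)
    })
  })
  # sign-conditional normalization against the same-size null
  norm_stats <- lapply(null_by_size, function(null) {
    pos_m <- mean(null[null >= 0])
    neg_m <- mean(abs(null[null < 0]))
    norm <- ifelse(null >= 0,
                   if (is.nan(pos_m) || pos_m == 0) 0 else null / pos_m,
                   if (is.nan(neg_m) || neg_m == 0) 0 else null / neg_m)
    list(null = null, pos_m = pos_m, neg_m = neg_m, norm = norm)
  })
  res <- data.frame(set = names(sets), size = as.integer(sizes),
                    es = obs_es, stringsAsFactors = FALSE)
  res$nes <- NA_real_; res$p_nominal <- NA_real_
  null_nes_pool <- numeric(0)
  for (k in seq_len(nrow(res))) {
    ns <- norm_stats[[as.character(res$size[k])]]
    null <- ns$null
    e <- res$es[k]
    if (e >= 0) {
      tail_null <- null[null >= 0]
      res$p_nominal[k] <- if (length(tail_null))
        sum(tail_null >= e) / length(tail_null) else 1
      res$nes[k] <- if (is.nan(ns$pos_m) || ns$pos_m == 0) 0 else e / ns$pos_m
    } else {
      tail_null <- null[null < 0]
      res$p_nominal[k] <- if (length(tail_null))
        sum(tail_null <= e) / length(tail_null) else 1
      res$nes[k] <- if (is.nan(ns$neg_m) || ns$neg_m == 0) 0 else e / ns$neg_m
    }
    null_nes_pool <- c(null_nes_pool, ns$norm)
  }
  res$fdr <- vapply(seq_len(nrow(res)), function(k) {
    nes <- res$nes[k]
    pool <- null_nes_pool
    obs <- res$nes
    if (nes >= 0) {
      denom_null <- sum(pool >= 0)
      num <- if (denom_null) sum(pool >= nes) / denom_null else 0
      denom_obs <- sum(obs >= 0)
      den <- if (denom_obs) sum(obs >= nes) / denom_obs else 1
    } else {
      denom_null <- sum(pool < 0)
      num <- if (denom_null) sum(pool <= nes) / denom_null else 0
      denom_obs <- sum(obs < 0)
      den <- if (denom_obs) sum(obs <= nes) / denom_obs else 1
    }
    if (den == 0) return(0)
    min(num / den, 1)
  }, 0)
  res$significant <- res$fdr < fdr_cutoff
  res <- res[order(res$fdr, res$p_nominal, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Read / write gene sets in GMT format
#'
#' @param sets Named list of gene-id vectors.
#' @param path File path.
#' @param description Optional description column (recycled).
#' @return `write_gmt` returns `path` invisibly; `read_gmt` returns a named
#'   list.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 columns")
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, "", 1L))
}
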