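INTEGRATION_LOCATIONS <- c(promoter_5k = "promoter_5k", tss = "tss",
                           exon = "coding_exon", intron = "intron",
                           utr3 = "utr3", utr5 = "utr5")

#' Intersect differentially expressed and differentially methylated genes
#'
#' One record per gene that is differentially expressed AND owns at least
#' one DMR overlapping its gene body or 5 kb promoter. Per-location flags
#' (`promoter_5k`, `tss`, `exon`, `intron`, `utr3`, `utr5`, `cgi`) report
#' the methylation direction at that location (`increased`, `decreased`, or
#' `none`; the lowest-p DMR decides if both directions occur). The `cgi`
#' flag is restricted to CpG islands lying in the gene's 5 kb promoter by
#' default.
#'
#' @param de DE gene data.frame (`gene`, `direction`, `pvalue`) or a
#'   `de_result` (its thresholded `de` element is used).
#' @param dmrs DMR data.frame (already thresholded, e.g. at p < 0.001) or a
#'   `dmr_result` (then `dmr_p_cutoff` is applied to its full table).
#' @param ann [build_annotation()] result.
#' @param dmr_p_cutoff Threshold applied when `dmrs` is a `dmr_result`
#'   (default 0.001).
#' @param cgi_promoter_only If `TRUE` (default) the `cgi` flag considers
#'   only promoter CpG islands; otherwise any CpG island of the gene body
#'   or promoter.
#' @return data.frame: `gene`, `expression` (up/down), `expr_pvalue`, one
#'   column per location flag.
#' @export
de_dm_intersection <- function(de, dmrs, ann, dmr_p_cutoff = 0.001,
                               cgi_promoter_only = TRUE) {
  if (inherits(de, "de_result")) de <- de$de
  if (inherits(dmrs, "dmr_result"))
    dmrs <- dmrs$table[dmrs$table$pvalue < dmr_p_cutoff, , drop = FALSE]
  loc_names <- c(names(INTEGRATION_LOCATIONS), "cgi")
  empty <- function() {
    out <- data.frame(gene = character(), expression = character(),
                      expr_pvalue = numeric(), stringsAsFactors = FALSE)
    for (l in loc_names) out[[l]] <- character()
    out
  }
  if (nrow(de) == 0L || nrow(dmrs) == 0L) return(empty())
  gr <- dmr_granges(dmrs, genome = ann$genome)

  # direction of the lowest-p DMR per (gene, location)
  flag_hits <- function(feat) {
    hits <- findOverlaps(gr, feat, minoverlap = 1L, ignore.strand = TRUE)
    if (!length(hits)) return(NULL)
    data.frame(gene = mcols(feat)$id[subjectHits(hits)],
               direction = mcols(gr)$direction[queryHits(hits)],
               pvalue = mcols(gr)$pvalue[queryHits(hits)],
               stringsAsFactors = FALSE)
  }
  loc_tables <- lapply(INTEGRATION_LOCATIONS, function(f)
    flag_hits(ann$features[[f]]))
  # cgi flag: DMR overlapping a CpG island linked to the gene via its
  # promoter (and, optionally, its gene body)
  cgi <- granges_only(ann$features$cpg_island)
  link_feats <- list(ann$features$promoter_5k)
  if (!cgi_promoter_only) link_feats <- c(link_feats,
                                          list(ann$features$gene_body))
  cgi_tab <- NULL
  dmr_cgi <- findOverlaps(gr, cgi, minoverlap = 1L, ignore.strand = TRUE)
  if (length(dmr_cgi)) {
    for (lf in link_feats) {
      ch <- findOverlaps(cgi, lf, minoverlap = 1L, ignore.strand = TRUE)
      m <- merge(data.frame(cgi = queryHits(dmr_cgi),
                            direction = mcols(gr)$direction[queryHits(dmr_cgi)],
                            pvalue = mcols(gr)$pvalue[queryHits(dmr_cgi)]),
                 data.frame(cgi = queryHits(ch),
                            gene = mcols(lf)$id[subjectHits(ch)]),
                 by = "cgi")
      if (nrow(m))
        cgi_tab <- rbind(cgi_tab, m[, c("gene", "direction", "pvalue")])
    }
  }
  loc_tables$cgi <- cgi_tab

  # gene owns a qualifying DMR iff gene body or promoter_5k is hit
  own <- unique(c(
    if (!is.null(lt <- flag_hits(ann$features$gene_body))) lt$gene,
    if (!is.null(lt <- loc_tables$promoter_5k)) lt$gene))
  own <- own[!is.na(own)]
  sel <- de[de$gene %in% own, , drop = FALSE]
  if (nrow(sel) == 0L) return(empty())
  out <- data.frame(gene = sel$gene,
                    expression = sel$direction,
                    expr_pvalue = sel$pvalue, stringsAsFactors = FALSE)
  for (l in loc_names) {
    lt <- loc_tables[[l]]
    flag <- rep("none", nrow(out))
    if (!is.null(lt) && nrow(lt)) {
      lt <- lt[!is.na(lt$gene), , drop = FALSE]
      lt <- lt[order(lt$gene, lt$pvalue), , drop = FALSE]
      lt <- lt[!duplicated(lt$gene), , drop = FALSE]
      m <- match(out$gene, lt$gene)
      flag[!is.na(m)] <- ifelse(lt$direction[m[!is.na(m)]] == "hyper",
                                "increased", "decreased")
    }
    out[[l]] <- flag
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates every stage on generated data: annotation and simulation,
#' per-model DMR calling (heatmap/enrichment threshold and the stricter
#' GSEA/integration threshold), genomic-feature enrichment, cross-model
#' region overlap and clustering, differential expression, cross-model DE
#' intersections, methylation-anchored preranked GSEA, and the DE x DM
#' integration table. All numeric tables (TSV/BED/GMT/Newick) plus a
#' machine-readable JSON manifest are written under `out_dir` when given.
#'
#' @param cfg A [sim_config()]; its seed drives every random stage,
#'   including the GSEA permutations.
#' @param out_dir Optional output directory (created if missing).
#' @param dmr_p Region significance threshold for heatmaps/enrichment
#'   (default 0.01).
#' @param dmr_p_strict Region threshold for GSEA gene sets and integration
#'   (default 0.001).
#' @param de_p Expression significance threshold (default 0.001).
#' @param gsea_fdr GSEA significance threshold on q (default 0.25).
#' @param n_perm GSEA permutations (default 1000).
#' @return List of class `methcap_run` with elements `config`, `annotation`,
#'   `methylation`, `expression`, and per-model `dmr`, `enrichment`, `de`,
#'   `gsea`, `integration`, plus `cross_model` (region Venn, DE overlaps,
#'   clustering) and `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL, dmr_p = 0.01,
                         dmr_p_strict = 0.001, de_p = 0.001,
                         gsea_fdr = 0.25, n_perm = 1000) {
  stopifnot(inherits(cfg, "sim_config"))
  for (thr in c(dmr_p, dmr_p_strict, de_p, gsea_fdr))
    if (!(thr > 0 && thr < 1)) stop("thresholds must lie in (0, 1)")
  log_stage <- function(...) message("[methcap] ", ...)
  files <- character(0)
  emit <- function(writer, obj, name, ...) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path, ...)
    files[[name]] <<- path
    invisible(path)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stamp <- paste0("methcap ", as.character(utils::packageVersion("methcap")),
                  " seed=", cfg$seed)

  log_stage("simulate: annotation + methylation + expression (seed ",
            cfg$seed, ")")
  ann <- generate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann, output = "counts")
  expr <- simulate_expression(cfg, ann, meth)
  emit(write_bed, meth$regions, "regions.bed", header = stamp)
  emit(write_tsv_commented, meth$truth, "truth_methylation.tsv",
       header = stamp)
  emit(write_tsv_commented, expr$truth, "truth_expression.tsv",
       header = stamp)

  models <- cfg$models
  dmr_res <- list(); enr <- list(); de_res <- list()
  gsea_res <- list(); integ <- list()
  for (m in models) {
    mm <- meth$models[[m]]
    log_stage("dmr [", m, "]: ", nrow(mm$counts), " regions in")
    dr <- call_dmrs(meth$regions, mm$counts, mm$group, p_cutoff = dmr_p,
                    lib_sizes = mm$lib_sizes)
    log_stage("dmr [", m, "]: ", nrow(dr$table), " tested, ",
              nrow(dr$dmrs), " DMRs out (p<", dmr_p, ")")
    dmr_res[[m]] <- dr
    emit(write_tsv_commented, dr$dmrs, paste0("dmr_", m, ".tsv"),
         header = stamp)
    emit(write_dmr_bed, dr$dmrs, paste0("dmr_", m, ".bed"), header = stamp)
    enr[[m]] <- enrichment_profile(dr, ann)
    emit(write_tsv_commented, enr[[m]], paste0("enrichment_", m, ".tsv"),
         header = stamp)

    em <- expr$models[[m]]
    de <- de_test(em$counts, em$group, tx2gene = em$tx2gene,
                  p_cutoff = de_p, lib_sizes = em$lib_sizes)
    log_stage("de [", m, "]: ", nrow(de$table), " rows tested, ",
              nrow(de$de), " DE genes out (p<", de_p, ")")
    de_res[[m]] <- de
    emit(write_tsv_commented, de$de, paste0("de_", m, ".tsv"),
         header = stamp)

    scores <- build_rank_scores(de$table)
    sets <- suppressWarnings(
      build_methylation_gene_sets(dr$table[dr$table$pvalue < dmr_p_strict, ,
                                           drop = FALSE], ann))
    gs <- gsea_preranked(scores, sets, n_perm = n_perm,
                         seed = cfg$seed * 13L + 5L, fdr_cutoff = gsea_fdr)
    log_stage("gsea [", m, "]: ", length(sets), " sets, ",
              sum(gs$significant), " significant (FDR<", gsea_fdr, ")")
    gsea_res[[m]] <- gs
    emit(write_tsv_commented, gs, paste0("gsea_", m, ".tsv"), header = stamp)
    if (length(sets))
      emit(write_gmt, sets, paste0("gene_sets_", m, ".gmt"))

    integ[[m]] <- de_dm_intersection(de, dr, ann,
                                     dmr_p_cutoff = dmr_p_strict)
    log_stage("integrate [", m, "]: ", nrow(integ[[m]]),
              " DE genes with methylation evidence")
    emit(write_tsv_commented, integ[[m]], paste0("integration_", m, ".tsv"),
         header = stamp)
  }

  log_stage("cross-model: region overlaps + DE intersections + clustering")
  venn <- venn_three(dmr_res, genome = ann$genome)
  de_overlap <- cross_model_de(de_res)
  emit(write_tsv_commented, venn$pairwise, "crossmodel_regions.tsv",
       header = stamp)
  emit(write_tsv_commented,
       rbind(cbind(direction = "up", de_overlap$up$pairwise),
             cbind(direction = "down", de_overlap$down$pairwise)),
       "crossmodel_de.tsv", header = stamp)

  clust <- list()
  for (m in models) {
    mm <- meth$models[[m]]
    dr <- dmr_res[[m]]
    if (nrow(dr$dmrs) >= 2L) {
      z <- zscore_rows(edgeR::cpm(mm$counts[dr$dmrs$id, , drop = FALSE],
                                  lib.size = mm$lib_sizes *
                                    dr$norm_factors[colnames(mm$counts)]))
      cl <- cluster_complete_pearson(z, axis = "columns")
      clust[[m]] <- cl
      emit(write_newick, cl, paste0("clustering_", m, ".nwk"))
    }
  }

  run <- list(config = cfg, annotation = ann, methylation = meth,
              expression = expr, dmr = dmr_res, enrichment = enr,
              de = de_res, gsea = gsea_res, integration = integ,
              cross_model = list(regions = venn, de = de_overlap,
                                 clustering = clust))
  if (!is.null(out_dir)) {
    manifest <- list(
      package = "methcap",
      version = as.character(utils::packageVersion("methcap")),
      seed = cfg$seed,
      thresholds = list(dmr_p = dmr_p, dmr_p_strict = dmr_p_strict,
                        de_p = de_p, gsea_fdr = gsea_fdr, n_perm = n_perm),
      config = cfg[setdiff(names(cfg), "coupling")],
      coupling = as.list(cfg$coupling),
      outputs = lapply(files, function(p)
        list(path = basename(p),
             md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(run) <- "methcap_run"
  run
}

#' @export
print.methcap_run <- function(x, ...) {
  cat("methcap_run (seed ", x$config$seed, ")\n", sep = "")
  for (m in names(x$dmr)) {
    cat(sprintf("  %-12s %4d DMRs | %3d DE genes | %2d GSEA sets sig | %2d integrated\n",
                m, nrow(x$dmr[[m]]$dmrs), nrow(x$de[[m]]$de),
                sum(x$gsea[[m]]$significant), nrow(x$integration[[m]])))
  }
  cat("  triple-common regions:", max(x$cross_model$regions$triple), "\n")
  invisible(x)
}
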