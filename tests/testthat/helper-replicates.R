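# Seeded full-pipeline replicates under the generator's default study
# conditions, shared by the enrichment-recovery and GSEA acceptance checks
# (computing them once keeps the suite inside its time budget).

.replicate_cache <- new.env(parent = emptyenv())

planted_replicates <- function(n = 20, base_seed = 1000) {
  key <- paste0("reps_", n, "_", base_seed)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  reps <- lapply(seq_len(n), function(r) {
    cfg <- sim_config(seed = base_seed + r)
    ann <- generate_annotation(cfg)
    meth <- simulate_methylation(cfg, ann)
    expr <- simulate_expression(cfg, ann, meth)
    mm <- meth$models[[1]]; em <- expr$models[[1]]
    dr <- call_dmrs(meth$regions, mm$counts, mm$group, p_cutoff = 0.01,
                    lib_sizes = mm$lib_sizes)
    prof <- enrichment_profile(dr, ann)
    de <- de_test(em$counts, em$group, tx2gene = em$tx2gene,
                  p_cutoff = 0.001, lib_sizes = em$lib_sizes)
    scores <- build_rank_scores(de$table)
    sets <- suppressWarnings(
      build_methylation_gene_sets(dr$table, ann, p_cutoff = 0.001))
    gsea <- gsea_preranked(scores, sets, n_perm = 1000, seed = cfg$seed)
    list(
      gene_body_hyper = prof[prof$feature == "gene_body" &
                               prof$direction == "hyper", ],
      non_genic_hypo = prof[prof$feature == "non_genic" &
                              prof$direction == "hypo", ],
      promoter_up_set = gsea[gsea$set == "promoter_5k_increased", ])
  })
  .replicate_cache[[key]] <- reps
  reps
}
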