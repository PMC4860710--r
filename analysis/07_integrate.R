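# Stage 7 — genes with both expression and methylation evidence: DE genes
# (p < 0.001) owning a DMR (p < 0.001) in their gene body or 5 kb promoter,
# with per-location direction flags. Also the cross-model DE intersections.

source("analysis/00_config.R")

ann <- annotation()
meth <- methylation(ann)
expr <- expression_data(ann, meth)

des <- list()
for (m in CFG$models) {
  mm <- meth$models[[m]]; em <- expr$models[[m]]
  dr <- call_dmrs(meth$regions, mm$counts, mm$group, p_cutoff = 0.01,
                  lib_sizes = mm$lib_sizes)
  de <- de_test(em$counts, em$group, tx2gene = em$tx2gene, p_cutoff = 0.001,
                lib_sizes = em$lib_sizes)
  des[[m]] <- de
  rec <- de_dm_intersection(de, dr, ann, dmr_p_cutoff = 0.001)
  cat(sprintf("%-12s %d DE genes, %d with gene-body/promoter methylation evidence\n",
              m, nrow(de$de), nrow(rec)))
  methcap:::write_tsv_commented(
    rec, file.path(RESULTS, paste0("integration_", m, ".tsv")),
    header = stamp)
}

ov <- cross_model_de(des)
cat("\nDE genes common to model pairs (same direction):\n")
print(rbind(cbind(direction = "up", ov$up$pairwise),
            cbind(direction = "down", ov$down$pairwise)), row.names = FALSE)
cat("upregulated in all three models:",
    if (length(ov$up$triple)) paste(ov$up$triple, collapse = ", ")
    else "none", "\n")
methcap:::write_tsv_commented(
  rbind(cbind(direction = "up", ov$up$pairwise),
        cbind(direction = "down", ov$down$pairwise)),
  file.path(RESULTS, "crossmodel_de.tsv"), header = stamp)
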