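# Stage 2 — differentially methylated regions per model: 50th-percentile
# abundance filter, TMM, common NB dispersion, exact test, p < 0.01.

source("analysis/00_config.R")

ann <- annotation()
meth <- methylation(ann)

for (m in CFG$models) {
  mm <- meth$models[[m]]
  dr <- call_dmrs(meth$regions, mm$counts, mm$group, p_cutoff = 0.01,
                  lib_sizes = mm$lib_sizes)
  tr <- meth$truth[meth$truth$model == m, ]
  recall <- mean(paste(tr$id, tr$direction) %in%
                   paste(dr$dmrs$id, dr$dmrs$direction))
  cat(sprintf(
    "%-12s %d tested | %d hyper + %d hypo DMRs | phi %.3f | planted recall %.2f\n",
    m, nrow(dr$table), sum(dr$dmrs$direction == "hyper"),
    sum(dr$dmrs$direction == "hypo"), dr$dispersion, recall))
  methcap:::write_tsv_commented(dr$dmrs,
                                file.path(RESULTS, paste0("dmr_", m, ".tsv")),
                                header = stamp)
  write_dmr_bed(dr$dmrs, file.path(RESULTS, paste0("dmr_", m, ".bed")),
                header = stamp)
  methcap:::write_tsv_commented(dr$table,
                                file.path(RESULTS,
                                          paste0("dmr_table_", m, ".tsv")),
                                header = stamp)
}
cat("wrote DMR tables under", RESULTS, "\n")
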