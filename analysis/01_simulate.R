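# Stage 1 — generate the study: toy genome annotation, methyl-capture
# region counts and mRNA counts for three injury models, with planted truth.

source("analysis/00_config.R")

ann <- annotation()
meth <- methylation(ann)
expr <- expression_data(ann, meth)

cat("genome:", paste(names(CFG$chrom_lengths), CFG$chrom_lengths / 1e6,
                     "Mb", collapse = ", "), "\n")
cat("genes:", nrow(ann$genes), "| candidate regions:",
    length(meth$regions), "\n")
for (m in CFG$models) {
  tr <- meth$truth[meth$truth$model == m, ]
  cat(sprintf("%-12s planted %d hyper / %d hypo regions\n", m,
              sum(tr$direction == "hyper"), sum(tr$direction == "hypo")))
}

dir.create(file.path(RESULTS, "sim"), showWarnings = FALSE)
write_bed(meth$regions, file.path(RESULTS, "sim", "regions.bed"),
          header = stamp)
write_tsv <- function(df, name)
  methcap:::write_tsv_commented(df, file.path(RESULTS, "sim", name),
                                header = stamp)
write_tsv(ann$genes, "genes.tsv")
write_tsv(meth$truth, "truth_methylation.tsv")
write_tsv(expr$truth, "truth_expression.tsv")
for (m in CFG$models) {
  write_count_tsv(meth$models[[m]]$counts,
                  file.path(RESULTS, "sim", paste0("meth_counts_", m, ".tsv")),
                  header = stamp)
  write_count_tsv(expr$models[[m]]$counts,
                  file.path(RESULTS, "sim", paste0("rna_counts_", m, ".tsv")),
                  header = stamp)
}
cat("wrote inputs and truth under", file.path(RESULTS, "sim"), "\n")
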