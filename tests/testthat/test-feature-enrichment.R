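row_i <- function(d, i) {
  d <- d[i, , drop = FALSE]
  rownames(d) <- NULL
  d
}

test_that("annotation materializes strand-aware promoters, TSS and UTRs", {
  ann <- toy_annotation()
  f <- ann$features
  # plus-strand gene gA: [2000, 5000)
  expect_equal(row_i(df_of(f$tss), 1),
               data.frame(chrom = "chr1", start = 2000, end = 2001))
  expect_equal(row_i(df_of(f$promoter_5k), 1),
               data.frame(chrom = "chr1", start = 0, end = 2000))  # clipped
  expect_equal(row_i(df_of(f$promoter_200), 1),
               data.frame(chrom = "chr1", start = 1800, end = 2000))
  expect_equal(row_i(df_of(f$utr5), 1),
               data.frame(chrom = "chr1", start = 2000, end = 2100))
  expect_equal(row_i(df_of(f$utr3), 1),
               data.frame(chrom = "chr1", start = 4800, end = 5000))
  # minus-strand gene gB: [1000, 4000) on chr2; TSS at the right end
  expect_equal(row_i(df_of(f$tss), 2),
               data.frame(chrom = "chr2", start = 3999, end = 4000))
  expect_equal(row_i(df_of(f$promoter_5k), 2),
               data.frame(chrom = "chr2", start = 4000, end = 8000))  # clipped
  expect_equal(row_i(df_of(f$utr5), 2),
               data.frame(chrom = "chr2", start = 3850, end = 4000))
  expect_error(build_annotation(within(toy_gene_table(), strand <- "."),
                                toy_exon_table(), genome = toy_genome),
               "strand")
})

test_that("introns, coding exons and non-genic space obey set identities", {
  ann <- toy_annotation()
  f <- ann$features
  genome <- toy_genome
  mask <- function(gr) bf_mask(df_of(gr), genome)
  gb <- mask(f$gene_body); ex_utr <- df_of(f$coding_exon)
  intron <- mask(f$intron)
  exons_all <- bf_mask(toy_exon_table()[, c("start", "end")] |>
                         cbind(chrom = c(rep("chr1", 3), rep("chr2", 2))),
                       genome)
  for (chr in names(genome)) {
    # introns = gene body minus exons, base by base
    expect_equal(intron[[chr]], gb[[chr]] & !exons_all[[chr]])
  }
  # coding exons exclude both UTR masks
  ce <- mask(f$coding_exon)
  u5 <- mask(f$utr5); u3 <- mask(f$utr3)
  for (chr in names(genome)) {
    expect_true(!any(ce[[chr]] & (u5[[chr]] | u3[[chr]])))
    expect_true(all(ce[[chr]] <= exons_all[[chr]]))
  }
  # non-genic complements gene bodies + 5 kb promoters exactly
  ng <- mask(f$non_genic); pr <- mask(f$promoter_5k)
  for (chr in names(genome)) {
    expect_equal(ng[[chr]], !(gb[[chr]] | pr[[chr]]))
  }
})

test_that("two-sided Fisher p matches full hypergeometric enumeration", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_two_sided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_two_sided(0, 0, 3, 4), 1)  # empty margin convention
  set.seed(33)
  for (i in 1:200) {
    m1 <- sample(0:50, 1); m2 <- sample(0:50, 1)
    a <- if (m1) sample(0:m1, 1) else 0
    c_ <- if (m2) sample(0:m2, 1) else 0
    p_pkg <- fisher_two_sided(a, m1 - a, c_, m2 - c_)
    p_or <- fisher_oracle(a, m1 - a, c_, m2 - c_)
    expect_equal(p_pkg, p_or, tolerance = 1e-7)
  }
})

test_that("log2 odds ratio and Woolf CI follow the closed form", {
  r <- log2_or_ci(10, 10, 10, 10)
  expect_equal(unname(r["log2OR"]), 0)
  expect_equal(unname(r["ci_lo"]), -unname(r["ci_hi"]))
  r2 <- log2_or_ci(20, 10, 10, 20)
  expect_equal(unname(r2["log2OR"]), 2)
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(unname(r2["ci_hi"]), (log(4) + 1.96 * se) / log(2),
               tolerance = 1e-12)
  r3 <- log2_or_ci(5, 0, 5, 5)  # Haldane-Anscombe keeps it finite
  expect_true(all(is.finite(r3)))
  expect_equal(unname(r3["log2OR"]),
               log2((5.5 * 5.5) / (0.5 * 5.5)))
})

test_that("enrichment profile counts are internally consistent", {
  ann <- toy_annotation()
  genome <- toy_genome
  set.seed(8)
  df <- rand_intervals(80, genome, max_w = 120)
  tested <- merge_intervals(interval_set(df$chrom, df$start, df$end,
                                         genome = genome))
  S4Vectors::mcols(tested)$id <- methcap:::region_ids(tested)
  ids <- methcap:::region_ids(tested)
  bed <- as_bed_frame(tested)
  pick <- sample(length(tested), 30)
  dmrs <- data.frame(chrom = bed$chrom[pick], start = bed$start[pick],
                     end = bed$end[pick], id = ids[pick],
                     logFC = rep(c(1.5, -1.5), 15),
                     pvalue = 1e-4,
                     direction = rep(c("hyper", "hypo"), 15))
  prof <- enrichment_profile(list(dmrs = dmrs, tested = tested), ann)
  for (dir in c("hyper", "hypo")) {
    sub <- prof[prof$direction == dir, ]
    expect_true(all(sub$a + sub$b == 15))
    expect_true(all(sub$c + sub$d == length(tested) - 30))
  }
  est <- prof[prof$estimable, ]
  expect_true(all(est$ci_lo <= est$log2OR & est$log2OR <= est$ci_hi))
  expect_true(all(est$p >= 0 & est$p <= 1))

  # all DMRs of a direction inside one feature: that feature's OR maximal
  gb <- ann$features$gene_body
  inside <- which(GenomicRanges::countOverlaps(tested,
                                               methcap:::granges_only(gb)) > 0)
  dmr2 <- data.frame(chrom = bed$chrom[inside], start = bed$start[inside],
                     end = bed$end[inside], id = ids[inside],
                     logFC = 2, pvalue = 1e-4, direction = "hyper")
  prof2 <- enrichment_profile(list(dmrs = dmr2, tested = tested), ann)
  hyper2 <- prof2[prof2$direction == "hyper" & prof2$estimable, ]
  # gene_body dominates every feature not nested inside it
  outside <- c("gene_body", "cpg_island", "snp", "promoter_200",
               "promoter_5k", "tss", "non_genic")
  sub2 <- hyper2[hyper2$feature %in% outside, ]
  expect_equal(sub2$feature[which.max(sub2$log2OR)], "gene_body")
  # direction with zero DMRs flagged not estimable
  hypo2 <- prof2[prof2$direction == "hypo", ]
  expect_true(all(!hypo2$estimable))
})
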