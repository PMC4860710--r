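test_that("generator is fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 12)
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  expect_equal(a1$genes, a2$genes)
  expect_equal(lapply(a1$features, df_of), lapply(a2$features, df_of))
  m1 <- simulate_methylation(cfg, a1); m2 <- simulate_methylation(cfg, a1)
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$models[[1]]$counts, m2$models[[1]]$counts)
  e1 <- simulate_expression(cfg, a1, m1)
  e2 <- simulate_expression(cfg, a1, m1)
  expect_identical(e1$models[[1]]$counts, e2$models[[1]]$counts)
  # a different seed gives different data
  m3 <- simulate_methylation(small_cfg(seed = 13), a1)
  expect_false(identical(m1$models[[1]]$counts, m3$models[[1]]$counts))
})

test_that("generated annotation satisfies its structural invariants", {
  cfg <- small_cfg(seed = 4)
  ann <- generate_annotation(cfg)
  genes <- ann$genes
  expect_equal(nrow(genes), cfg$n_genes)
  # gene bodies do not overlap
  gb <- df_of(ann$features$gene_body)
  merged <- df_of(merge_intervals(ann$features$gene_body))
  expect_equal(sum(gb$end - gb$start), sum(merged$end - merged$start))
  # gene_body + promoter_5k + non_genic tile the genome exactly once
  genic <- merge_intervals(BiocGenerics::append(
    methcap:::granges_only(ann$features$gene_body),
    methcap:::granges_only(ann$features$promoter_5k)))
  ng <- ann$features$non_genic
  covered <- sum(GenomicRanges::width(genic)) +
    sum(GenomicRanges::width(ng))
  expect_equal(covered, sum(cfg$chrom_lengths))
  expect_equal(nrow(intersect_pairs(genic, ng)), 0L)
  # every exon sits inside its gene, UTRs at the gene ends
  tss <- df_of(ann$features$tss)
  expect_equal(nrow(tss), cfg$n_genes)
  expect_true(all(tss$end - tss$start == 1))
})

test_that("empty gene models degrade gracefully", {
  cfg <- small_cfg(seed = 2)
  cfg$n_genes <- 0
  ann <- generate_annotation(cfg)
  expect_equal(length(ann$features$gene_body), 0L)
  expect_equal(sum(GenomicRanges::width(ann$features$non_genic)),
               sum(cfg$chrom_lengths))
})

test_that("simulated counts have the configured NB moments", {
  cfg <- small_cfg(seed = 31, frac_dmr = 0, lib_cv = 0)
  ann <- generate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann)
  counts <- meth$models[[1]]$counts
  # pooled dispersion estimate across regions recovers phi
  grp <- meth$models[[1]]$group
  phi_hat <- estimate_dispersion(counts, grp)$common
  expect_gt(phi_hat, cfg$phi * 0.7)
  expect_lt(phi_hat, cfg$phi * 1.4)
  # per-region means follow the log-normal baseline scale
  expect_gt(median(rowMeans(counts)), cfg$region_mu * 0.5)
  expect_lt(median(rowMeans(counts)), cfg$region_mu * 2)
})

test_that("planted feature bias attains the configured odds", {
  reps <- lapply(1:5, function(s) {
    cfg <- small_cfg(seed = 100 + s)
    ann <- generate_annotation(cfg)
    meth <- simulate_methylation(cfg, ann)
    in_gb <- GenomicRanges::countOverlaps(
      meth$regions, methcap:::granges_only(ann$features$gene_body)) > 0
    tr <- meth$truth[meth$truth$model == cfg$models[1], ]
    hyper <- methcap:::region_ids(meth$regions) %in%
      tr$id[tr$direction == "hyper"]
    c(a = sum(in_gb & hyper), b = sum(!in_gb & hyper),
      c = sum(in_gb & !hyper), d = sum(!in_gb & !hyper))
  })
  tot <- Reduce(`+`, reps)
  or <- (tot["a"] / tot["b"]) / (tot["c"] / tot["d"])
  expect_gt(or, 1.6)
  expect_lt(or, 2.5)
})

test_that("a zero planted fraction yields calibrated downstream calls", {
  cfg <- small_cfg(seed = 77, frac_dmr = 0)
  ann <- generate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann)
  expect_equal(nrow(meth$truth), 0L)
  mm <- meth$models[[1]]
  dr <- call_dmrs(meth$regions, mm$counts, mm$group, p_cutoff = 0.01,
                  lib_sizes = mm$lib_sizes)
  # ~1% of tested regions at p < 0.01, generously bounded for a small run
  expect_lt(nrow(dr$dmrs) / nrow(dr$table), 0.05)
})

test_that("tag-track output is consistent with the planted counts", {
  cfg <- small_cfg(seed = 8, region_count = 150, region_mu = 30)
  ann <- generate_annotation(cfg)
  tg <- simulate_methylation(cfg, ann, output = "tags")
  tracks <- tg$models[[1]]$tracks
  expect_length(tracks, 2 * cfg$n_per_group)
  expect_s3_class(tracks[[1]], "tag_track")
  # same seed, same tracks
  tg2 <- simulate_methylation(cfg, ann, output = "tags")
  expect_identical(tg$models[[1]]$tracks[[1]]$positions,
                   tg2$models[[1]]$tracks[[1]]$positions)
  # region counts from the tracks correlate with the underlying intensity
  m <- count_tags_in_regions(tg$regions, lapply(tracks, dedupe_tags))
  expect_gt(stats::cor(rowSums(m),
                       rowSums(count_tags_in_regions(
                         tg2$regions, lapply(tg2$models[[1]]$tracks,
                                             dedupe_tags)))), 0.95)
})

test_that("expression coupling shifts the coupled genes as configured", {
  cfg <- small_cfg(seed = 19, frac_de = 0,
                   coupling = c(promoter_5k = -1.5))
  ann <- generate_annotation(cfg)
  meth <- simulate_methylation(cfg, ann)
  expr <- simulate_expression(cfg, ann, meth)
  tr <- expr$truth[expr$truth$model == cfg$models[1], ]
  coupled <- tr[tr$coupled_logFC != 0, ]
  expect_gt(nrow(coupled), 0)
  # hyper promoter DMR -> negative expression shift
  reg <- meth$regions[match(
    meth$truth$id[meth$truth$model == cfg$models[1] &
                    meth$truth$direction == "hyper"],
    methcap:::region_ids(meth$regions))]
  prom <- ann$features$promoter_5k
  hits <- GenomicRanges::findOverlaps(reg, prom, minoverlap = 1L,
                                      ignore.strand = TRUE)
  hyper_prom_genes <- unique(
    S4Vectors::mcols(prom)$id[S4Vectors::subjectHits(hits)])
  expect_true(all(tr$coupled_logFC[tr$gene %in% hyper_prom_genes] < 0))
  # coupling strength zero leaves expression unshifted
  cfg0 <- small_cfg(seed = 19, frac_de = 0, coupling = c(promoter_5k = 0))
  expr0 <- simulate_expression(cfg0, ann, meth)
  expect_true(all(expr0$truth$coupled_logFC == 0))
})
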