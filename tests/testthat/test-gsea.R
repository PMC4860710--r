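test_that("rank scores apply the signed -log10(p), lowest-p-per-gene rule", {
  tab <- data.frame(gene = "g1", logFC = 1, pvalue = 0.01)
  expect_equal(unname(build_rank_scores(tab)), 2)
  tab2 <- data.frame(gene = c("g1", "g1"), logFC = c(1, -2),
                     pvalue = c(0.01, 0.001))
  expect_equal(unname(build_rank_scores(tab2)), -3)
  tab3 <- data.frame(gene = "g1", logFC = 3, pvalue = 1)
  expect_equal(unname(build_rank_scores(tab3)), 0)
  expect_warning(s <- build_rank_scores(
    data.frame(gene = "g1", logFC = 1, pvalue = 0)), "floored")
  expect_equal(unname(s), 300)
  # sorted descending, ties broken by gene id
  tab4 <- data.frame(gene = c("gB", "gA", "gC"), logFC = c(1, 1, -1),
                     pvalue = c(0.1, 0.1, 0.01))
  expect_equal(names(build_rank_scores(tab4)), c("gA", "gB", "gC"))
})

test_that("methylation gene sets are built per feature and direction", {
  ann <- toy_annotation()
  # gA: [2000, 5000) +, introns at [2400, 3000) and [3400, 4500)
  hyper_intron <- data.frame(chrom = "chr1", start = 2500, end = 2600,
                             id = "d1", logFC = 2, pvalue = 1e-4,
                             direction = "hyper")
  sets <- build_methylation_gene_sets(hyper_intron, ann)
  expect_equal(sets$intron_increased, "gA")
  expect_null(sets$promoter_5k_increased)
  # promoter DMR overlapping the promoter CGI tags both set families
  hypo_prom <- data.frame(chrom = "chr1", start = 1600, end = 1700,
                          id = "d2", logFC = -2, pvalue = 1e-4,
                          direction = "hypo")
  sets2 <- build_methylation_gene_sets(hypo_prom, ann)
  expect_equal(sets2$promoter_5k_decreased, "gA")
  expect_equal(sets2$cgi_in_promoter_decreased, "gA")
  # promoter DMR away from the CGI: promoter set only
  hypo_prom2 <- data.frame(chrom = "chr1", start = 300, end = 400,
                           id = "d3", logFC = -2, pvalue = 1e-4,
                           direction = "hypo")
  sets3 <- build_methylation_gene_sets(hypo_prom2, ann)
  expect_equal(sets3$promoter_5k_decreased, "gA")
  expect_null(sets3$cgi_in_promoter_decreased)
  # a DMR spanning an exon/intron boundary joins both sets
  span <- data.frame(chrom = "chr1", start = 3300, end = 3500, id = "d4",
                     logFC = 2, pvalue = 1e-4, direction = "hyper")
  sets4 <- build_methylation_gene_sets(span, ann)
  expect_equal(sets4$exon_increased, "gA")
  expect_equal(sets4$intron_increased, "gA")
  expect_warning(empty <- build_methylation_gene_sets(
    hyper_intron[0, ], ann), "not available")
  expect_equal(length(empty), 0L)
})

test_that("enrichment score matches the naive prefix oracle", {
  set.seed(61)
  scores <- sort(rnorm(100), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:100)
  # boundary conventions
  expect_equal(enrichment_score(scores, names(scores))$es, 1)
  expect_equal(enrichment_score(scores, names(scores)[100])$es, -1)
  for (i in 1:20) {
    set <- sample(names(scores), sample(3:30, 1))
    es <- enrichment_score(scores, set)$es
    expect_equal(es, es_oracle(scores, set))
    # negating every score negates the ES
    neg <- -rev(scores)
    expect_equal(enrichment_score(neg, set)$es,
                 -es_oracle(scores, set), tolerance = 1e-12)
  }
  zero <- stats::setNames(c(1, 0, 0, -1), paste0("g", 1:4))
  expect_equal(enrichment_score(zero, c("g2", "g3"))$es, 0)
  expect_error(enrichment_score(scores, "absent"), "no members")
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  scores <- sort(rnorm(150), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:150)
  for (i in 1:10) {
    set <- sample(names(scores), 15)
    ours <- enrichment_score(scores, set)$es
    theirs <- fgsea::calcGseaStat(scores,
                                  selectedStats = which(names(scores) %in%
                                                          set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("preranked GSEA is deterministic and sign-consistent", {
  set.seed(101)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", 1:200)
  sets <- list(top = names(scores)[1:15],
               bottom = names(scores)[186:200],
               random = sample(names(scores), 20))
  r1 <- gsea_preranked(scores, sets, n_perm = 200, seed = 42)
  r2 <- gsea_preranked(scores, sets, n_perm = 200, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0))
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))
  expect_gt(r1$es[r1$set == "top"], 0)
  expect_lt(r1$es[r1$set == "bottom"], 0)
  # extreme sets beat the random one
  expect_lt(r1$p_nominal[r1$set == "top"],
            r1$p_nominal[r1$set == "random"] + 1e-9)
  expect_error(gsea_preranked(scores, list(huge = c(names(scores), "x",
                                                    "y")),
                              n_perm = 10),
               NA)  # out-of-universe members are dropped, not an error
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2"), beta = c("g3", "g4", "g5"))
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  expect_equal(read_gmt(p), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("onlyname\tdesc", bad)
  expect_error(read_gmt(bad), "line 1")
})
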