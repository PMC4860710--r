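toy_track <- function(sample, pos, genome = c(chr1 = 100000),
                      tag_length = 36) {
  tag_track(sample, list(chr1 = pos), genome, tag_length = tag_length)
}

test_that("dedupe_tags keeps one tag per position and updates library size", {
  tr <- toy_track("s1", c(5, 5, 9))
  dd <- dedupe_tags(tr)
  expect_equal(dd$positions$chr1, c(5L, 9L))
  expect_equal(dd$lib_size, 2L)
  clean <- toy_track("s2", c(1, 2, 3))
  expect_equal(dedupe_tags(clean)$positions$chr1, c(1L, 2L, 3L))
  all_dup <- toy_track("s3", rep(7, 10))
  expect_equal(dedupe_tags(all_dup)$positions$chr1, 7L)
  expect_error(toy_track("s4", c(9, 5)), "not sorted")
})

test_that("window caller finds only strong pairwise Poisson enrichment", {
  genome <- c(chr1 = 30000)
  # identical tracks: nothing is enriched anywhere
  base <- sort(sample.int(29000, 300))
  a <- tag_track("a", list(chr1 = base), genome)
  b <- tag_track("b", list(chr1 = base), genome)
  expect_equal(length(propose_candidate_regions(list(a, b))), 0L)

  # planted 40-vs-2 window at equal library size: Poisson tail << 1e-5
  set.seed(3)
  bgA <- sort(sample(20000:29000, 260))
  bgB <- sort(sample(20000:29000, 298))
  hotA <- sort(sample(6000:6264, 40))
  hotB <- c(6100, 6200)
  a <- tag_track("a", list(chr1 = sort(c(hotA, bgA))), genome)
  b <- tag_track("b", list(chr1 = sort(c(hotB, bgB))), genome)
  cand <- propose_candidate_regions(list(a, b))
  expect_gt(length(cand), 0L)
  hot <- interval_set("chr1", 6000, 6300, genome = genome)
  expect_true(any(intersect_pairs(cand, hot)$overlap_bp > 0))

  # 6-vs-3 is far from the cutoff: P(X >= 6 | lambda = 3) ~ 0.084
  weakA <- sort(c(sample(20000:29000, 294), sample(6000:6264, 6)))
  weakB <- sort(c(sample(20000:29000, 297), c(6050, 6150, 6250)))
  a2 <- tag_track("a", list(chr1 = weakA), genome)
  b2 <- tag_track("b", list(chr1 = weakB), genome)
  cand2 <- propose_candidate_regions(list(a2, b2))
  if (length(cand2))
    expect_equal(nrow(intersect_pairs(cand2, hot)), 0L)
  expect_error(propose_candidate_regions(list(a)), "two")
})

test_that("tag counting honours half-open 1 bp overlap semantics", {
  genome <- c(chr1 = 100000)
  regions <- interval_set("chr1", c(100, 500), c(200, 900), genome = genome)
  tr <- toy_track("s1", c(64, 65, 150, 470, 899))
  # tag at 64 ends at 100 (half-open): misses [100, 200); 65 reaches in.
  # 470 spans into [500, 900); 899 starts on the last base.
  m <- count_tags_in_regions(regions, list(dedupe_tags(tr)))
  expect_equal(unname(m[, 1]), c(2L, 2L))
})

test_that("tag counting matches a per-tag brute-force scan", {
  genome <- c(chr1 = 50000, chr2 = 30000)
  set.seed(14)
  df <- rand_intervals(25, genome)
  df <- df_of(merge_intervals(interval_set(df$chrom, df$start, df$end,
                                           genome = genome)))
  regions <- interval_set(df$chrom, df$start, df$end, genome = genome)
  tracks <- lapply(1:3, function(i) {
    pos <- lapply(genome, function(L) sort(sample.int(L - 36, 400)))
    tag_track(paste0("s", i), pos, genome)
  })
  got <- count_tags_in_regions(regions, tracks)
  want <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(df)), function(r) {
      p <- tr$positions[[df$chrom[r]]]
      sum(p < df$end[r] & (p + 36) > df$start[r])
    }, 0L)
  }, integer(nrow(df)))
  expect_equal(unname(got), unname(want))
})

test_that("call_dmrs recovers a planted region and respects its threshold", {
  set.seed(21)
  genome <- c(chr1 = 1e6)
  n <- 400
  w <- rep(500L, n)
  starts <- seq(0L, by = 2000L, length.out = n)
  regions <- interval_set(rep("chr1", n), starts, starts + w,
                          genome = genome)
  grp <- factor(rep(c("control", "injury"), each = 4),
                levels = c("control", "injury"))
  mu <- exp(runif(n, log(30), log(120)))
  counts <- t(vapply(seq_len(n), function(r)
    rnbinom(8, mu = mu[r] * c(1, 1, 1, 1, 4, 4, 4, 4)^(r == 1),
            size = 10), numeric(8)))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(methcap:::region_ids(regions),
                                   paste0("s", 1:8)))
  res <- call_dmrs(regions, counts, grp, p_cutoff = 0.01)
  expect_s3_class(res, "dmr_result")
  planted_id <- methcap:::region_ids(regions)[1]
  expect_true(planted_id %in% res$dmrs$id)
  expect_equal(res$dmrs$direction[res$dmrs$id == planted_id], "hyper")
  # every DMR is a tested region carrying its own test results
  expect_true(all(res$dmrs$id %in% res$table$id))
  expect_true(all(res$dmrs$pvalue < 0.01))
  expect_true(all((res$dmrs$logFC >= 0) == (res$dmrs$direction == "hyper")))
  # empty candidate set warns and returns an empty result
  expect_warning(empty <- call_dmrs(interval_set(character(), integer(),
                                                 integer(), genome = genome),
                                    counts[0, , drop = FALSE], grp),
                 "empty")
  expect_equal(nrow(empty$dmrs), 0L)
})

test_that("DMR BED export caps scores and round-trips coordinates", {
  dmrs <- data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 200),
                     id = c("d1", "d2"), logFC = c(2, -1),
                     pvalue = c(1e-200, 0.005),
                     direction = c("hyper", "hypo"))
  p <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, p, header = "toy")
  back <- read_bed(p)
  expect_equal(df_of(back), dmrs[, c("chrom", "start", "end")])
  expect_true(all(S4Vectors::mcols(back)$score <= 1000))
})
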