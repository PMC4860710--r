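# Independent brute-force / closed-form oracles used across the suite.
# Each is deliberately naive and shares no code with the package internals.

# ---- per-base interval oracles (genomes <= a few 10 kb) ----

# coverage mask per chromosome from a 0-based half-open interval data.frame
bf_mask <- function(df, genome) {
  masks <- lapply(genome, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    idx <- seq.int(df$start[i] + 1L, df$end[i])
    masks[[df$chrom[i]]][idx] <- TRUE
  }
  masks
}

# maximal runs of TRUE as a 0-based interval data.frame
bf_runs <- function(masks) {
  out <- list()
  for (chr in names(masks)) {
    r <- rle(masks[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                               end = ends[keep])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

bf_merge <- function(df, genome) bf_runs(bf_mask(df, genome))

bf_complement <- function(df, genome) {
  masks <- bf_mask(df, genome)
  bf_runs(lapply(masks, `!`))
}

# all pairs with >= 1 shared base, naive double loop
bf_intersect_pairs <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(a_idx = i, b_idx = j,
                                            overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# random 0-based interval set on a toy genome, already sorted
rand_intervals <- function(n, genome, max_w = 500) {
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  start <- floor(runif(n, 0, genome[chrom] - w))
  df <- data.frame(chrom = chrom, start = start, end = start + w,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

df_of <- function(gr) {
  d <- as_bed_frame(gr)
  d <- d[, c("chrom", "start", "end")]
  rownames(d) <- NULL
  d
}

# ---- TMM oracle: published formula, double trim + delta-method weights ----

tmm_oracle <- function(counts, lib = colSums(counts)) {
  f75 <- apply(counts, 2, function(u) stats::quantile(u, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- as.numeric(counts[, j]); r <- as.numeric(counts[, ref])
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (r / nR))
    absE <- (log2(obs / nO) + log2(r / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - r) / nR / r
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# ---- exact-test oracle: 1 vs 1 samples, equal libraries, phi = 0 ----
# Conditional on the total, the first count is Binomial(n, 1/2); two-sided
# p doubles the smaller tail, capped at 1.
binom_exact_oracle <- function(x1, x2) {
  n <- x1 + x2
  lo <- stats::pbinom(min(x1, x2), n, 0.5)
  min(2 * lo, 1)
}

# ---- Fisher oracle: full hypergeometric enumeration ----
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- GSEA enrichment-score oracle: naive prefix scan ----
es_oracle <- function(scores, set, weight = 1) {
  genes <- names(scores)
  n <- length(genes)
  in_set <- genes %in% set
  denom_hit <- sum(abs(scores[in_set])^weight)
  best <- 0
  for (i in seq_len(n)) {
    ph <- sum((abs(scores)^weight)[seq_len(i)][in_set[seq_len(i)]]) /
      denom_hit
    pm <- if (n == sum(in_set)) 0 else
      sum(!in_set[seq_len(i)]) / (n - sum(in_set))
    dev <- ph - pm
    if (abs(dev) > abs(best)) best <- dev
  }
  best
}

# ---- tiny fixtures ----

toy_genome <- c(chr1 = 10000, chr2 = 8000)

toy_gene_table <- function() {
  data.frame(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
    start = c(2000, 1000), end = c(5000, 4000),
    strand = c("+", "-"), utr5_len = c(100, 150), utr3_len = c(200, 100),
    stringsAsFactors = FALSE)
}

toy_exon_table <- function() {
  data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    start = c(2000, 3000, 4500, 1000, 3500),
    end = c(2400, 3400, 5000, 1600, 4000),
    stringsAsFactors = FALSE)
}

toy_annotation <- function() {
  build_annotation(toy_gene_table(), toy_exon_table(),
                   cpg_islands = interval_set("chr1", 1500, 2100,
                                              genome = toy_genome),
                   snps = data.frame(chrom = "chr1", pos = 2500),
                   genome = toy_genome)
}

small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, chrom_lengths = c(chr1 = 6e5, chr2 = 4e5),
               n_genes = 40, region_count = 600, n_snps = 200,
               n_cgi_nongenic = 10)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
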