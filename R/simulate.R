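#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' desk-scale methyl-capture study: a 2 x 5 Mb toy genome carrying 400
#' non-overlapping genes, three disease models with two groups (control /
#' injury) of 5 samples each, negative-binomial tag counts over ~6000
#' candidate regions at dispersion 0.15, 5% of regions differential at
#' |logFC| = 2 with hypermethylation biased toward gene bodies and
#' hypomethylation toward non-genic regions (odds 2 each), and expression
#' coupled to promoter methylation with negative sign (increased promoter
#' methylation depresses the transcript).
#'
#' @param seed Master RNG seed; every stage derives its stream from it.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_genes Number of genes to place.
#' @param gene_length_range,exon_count_range,exon_width_range Gene geometry
#'   (bp / counts).
#' @param utr5_range,utr3_range UTR lengths (bp) at the gene ends.
#' @param cgi_promoter_frac Fraction of promoters carrying a CpG island.
#' @param cgi_width_range CpG island widths (bp).
#' @param n_cgi_nongenic CpG islands placed at random non-genic sites.
#' @param n_snps SNP positions placed uniformly.
#' @param models Model labels (three by default).
#' @param n_per_group Samples per group per model.
#' @param phi NB dispersion of tag and read counts.
#' @param region_count Number of candidate methylation regions.
#' @param region_width_range Region widths (bp).
#' @param region_mu,region_sigma_log Log-normal baseline of region tag
#'   intensity (mean tags/region/sample and log-sd).
#' @param lib_cv Coefficient of variation of per-sample library factors.
#' @param frac_dmr Fraction of regions planted differential per model.
#' @param dmr_logfc Magnitude of planted methylation logFC.
#' @param hyper_gene_body_odds,hypo_non_genic_odds Feature-placement odds of
#'   planted hyper/hypo regions relative to unbiased placement.
#' @param hypo_baseline_min_quantile Hypomethylation is planted only on
#'   regions whose baseline intensity is at or above this quantile
#'   (default 0.9): capture signal can only be lost where methylation was
#'   dense to begin with, so demethylation events sit in the upper baseline
#'   intensity range and survive the abundance filter the way they do in
#'   real capture data.
#' @param sharing Fraction of each later model's planted regions copied
#'   (same region, direction, logFC) from the first model; 0 = independent.
#' @param frac_de Fraction of genes planted differentially expressed per
#'   model.
#' @param de_logfc Magnitude of planted expression logFC.
#' @param gene_mu,gene_sigma_log Log-normal baseline of gene expression.
#' @param coupling Named numeric vector, feature class -> signed strength:
#'   a gene owning a planted DMR overlapping that feature gets an
#'   expression logFC of `strength * sign` where sign is +1 for hyper and
#'   -1 for hypo DMRs.
#' @param n_tx_per_gene Transcripts simulated per gene.
#' @param tag_length Tag length (bp) for tag-track output.
#' @param background_rate Background tags per bp per sample for tag-track
#'   output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 400,
                       gene_length_range = c(5000, 15000),
                       exon_count_range = c(3, 10),
                       exon_width_range = c(150, 400),
                       utr5_range = c(30, 120),
                       utr3_range = c(50, 250),
                       cgi_promoter_frac = 0.6,
                       cgi_width_range = c(300, 1000),
                       n_cgi_nongenic = 100,
                       n_snps = 2000,
                       models = c("amygdala", "TBI", "pilocarpine"),
                       n_per_group = 5,
                       phi = 0.15,
                       region_count = 6000,
                       region_width_range = c(300, 800),
                       region_mu = 50, region_sigma_log = 0.5,
                       lib_cv = 0.2,
                       frac_dmr = 0.05,
                       dmr_logfc = 2,
                       hyper_gene_body_odds = 2,
                       hypo_non_genic_odds = 2,
                       hypo_baseline_min_quantile = 0.9,
                       sharing = 0,
                       frac_de = 0.05,
                       de_logfc = 2,
                       gene_mu = 100, gene_sigma_log = 0.6,
                       coupling = c(promoter_5k = -1.5),
                       n_tx_per_gene = 1,
                       tag_length = 36,
                       background_rate = 2e-4) {
  cfg <- as.list(environment())
  stopifnot(cfg$frac_dmr >= 0, cfg$frac_dmr <= 1,
            cfg$frac_de >= 0, cfg$frac_de <= 1,
            cfg$sharing >= 0, cfg$sharing <= 1,
            cfg$hyper_gene_body_odds > 0, cfg$hypo_non_genic_odds > 0,
            cfg$phi >= 0, cfg$n_per_group >= 2)
  structure(cfg, class = "sim_config")
}

# Place n non-overlapping intervals of the given widths on [0, total) by
# distributing the free space as uniform random gaps (n + 1 gaps).
place_nonoverlapping <- function(widths, total) {
  n <- length(widths)
  free <- total - sum(widths)
  if (free < 0) stop("intervals too dense to place without overlap; ",
                     "reduce their number or size")
  cuts <- sort(stats::runif(n, 0, free))
  starts <- floor(cuts + cumsum(c(0, widths[-n])))
  cbind(start = starts, end = starts + widths)
}

# Split a count across chromosomes proportionally to their lengths.
split_by_chrom <- function(n, chrom_lengths) {
  k <- round(n * chrom_lengths / sum(chrom_lengths))
  k[1L] <- n - sum(k[-1L])
  k
}

#' Generate a toy genome annotation
#'
#' Places non-overlapping genes (each with 3-10 exons whose first/last exon
#' flanks carry the UTRs), random strands, CpG islands in a configurable
#' fraction of promoters plus random non-genic sites, and uniform SNPs.
#' Fully deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `feature_annotation` (see [build_annotation()]).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed * 13L + 1L, {
    genome <- cfg$chrom_lengths
    n_chr <- split_by_chrom(cfg$n_genes, genome)
    genes_l <- list(); exons_l <- list(); cgi_l <- list()
    gi <- 0L
    for (chr in names(genome)) {
      k <- n_chr[[chr]]
      if (k == 0L) next
      lens <- round(stats::runif(k, cfg$gene_length_range[1],
                                 cfg$gene_length_range[2]))
      pos <- tryCatch(place_nonoverlapping(lens, genome[[chr]]),
                      error = function(e)
                        stop("genes too dense to place without overlap; ",
                             "lower n_genes", call. = FALSE))
      for (i in seq_len(k)) {
        gi <- gi + 1L
        gid <- sprintf("gene%04d", gi)
        gstart <- pos[i, "start"]; gend <- pos[i, "end"]
        glen <- gend - gstart
        ke <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1L)
        ew <- round(stats::runif(ke, cfg$exon_width_range[1],
                                 cfg$exon_width_range[2]))
        min_intron <- 50L
        spare <- glen - sum(ew) - (ke - 1L) * min_intron
        while (spare < 0 && ke > 2L) {  # shrink for short genes
          ke <- ke - 1L; ew <- ew[-length(ew)]
          spare <- glen - sum(ew) - (ke - 1L) * min_intron
        }
        gaps <- rep(min_intron, ke - 1L)
        if (ke > 1L && spare > 0) {
          cuts <- sort(stats::runif(ke - 1L, 0, spare))
          gaps <- gaps + floor(diff(c(0, cuts)))
        }
        estart <- gstart + cumsum(c(0, ew[-ke] + gaps))
        eend <- estart + ew
        eend[ke] <- gend               # last exon flush with gene end
        estart[ke] <- gend - ew[ke]
        strand <- sample(c("+", "-"), 1L)
        u5 <- round(stats::runif(1, cfg$utr5_range[1], cfg$utr5_range[2]))
        u3 <- round(stats::runif(1, cfg$utr3_range[1], cfg$utr3_range[2]))
        first_w <- ew[1L]; last_w <- ew[ke]
        if (strand == "+") {
          u5 <- min(u5, first_w); u3 <- min(u3, last_w)
        } else {
          u5 <- min(u5, last_w); u3 <- min(u3, first_w)
        }
        genes_l[[gi]] <- data.frame(gene_id = gid, chrom = chr,
                                    start = gstart, end = gend,
                                    strand = strand, utr5_len = u5,
                                    utr3_len = u3, stringsAsFactors = FALSE)
        exons_l[[gi]] <- data.frame(gene_id = gid, start = estart,
                                    end = eend, stringsAsFactors = FALSE)
        if (stats::runif(1) < cfg$cgi_promoter_frac) {
          w <- round(stats::runif(1, cfg$cgi_width_range[1],
                                  cfg$cgi_width_range[2]))
          ci <- if (strand == "+") c(max(gstart - w, 0), gstart)
                else c(gend, min(gend + w, genome[[chr]]))
          if (ci[2] > ci[1])
            cgi_l[[length(cgi_l) + 1L]] <-
              data.frame(chrom = chr, start = ci[1], end = ci[2])
        }
      }
    }
    genes <- if (gi) do.call(rbind, genes_l) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 utr5_len = integer(), utr3_len = integer())
    exons <- if (gi) do.call(rbind, exons_l) else NULL
    # non-genic CpG islands: uniform rejection against genic space
    genic <- if (gi) interval_set(genes$chrom,
                                  pmax(genes$start - 5000, 0), genes$end,
                                  genome = genome) else NULL
    placed <- 0L; rounds <- 0L
    while (placed < cfg$n_cgi_nongenic && rounds < 50L) {
      rounds <- rounds + 1L
      nb <- 4L * (cfg$n_cgi_nongenic - placed)
      chr <- sample(names(genome), nb, replace = TRUE, prob = genome)
      w <- round(stats::runif(nb, cfg$cgi_width_range[1],
                              cfg$cgi_width_range[2]))
      s <- floor(stats::runif(nb, 0, genome[chr] - w))
      cand <- GRanges(chr, IRanges(s + 1L, s + w))
      ok <- if (is.null(genic)) rep(TRUE, nb)
            else countOverlaps(cand, genic, ignore.strand = TRUE) == 0
      take <- which(ok)[seq_len(min(sum(ok), cfg$n_cgi_nongenic - placed))]
      if (length(take)) {
        cgi_l[[length(cgi_l) + 1L]] <-
          data.frame(chrom = chr[take], start = s[take], end = s[take] + w[take])
        placed <- placed + length(take)
      }
    }
    cgi <- if (length(cgi_l)) {
      df <- do.call(rbind, cgi_l)
      interval_set(df$chrom, df$start, df$end, genome = genome)
    } else NULL
    snp_chr <- sample(names(genome), cfg$n_snps, replace = TRUE,
                      prob = genome)
    snps <- data.frame(chrom = snp_chr,
                       pos = floor(stats::runif(cfg$n_snps, 0,
                                                genome[snp_chr])))
    build_annotation(genes, exons, cpg_islands = cgi, snps = snps,
                     genome = genome)
  })
}

# Feature-biased selection of planted region indices. The in-feature odds
# of a pick are `odds` times the pool's unbiased odds; the number of
# in-feature picks is drawn binomially at that target and the strata are
# then sampled uniformly without replacement, which keeps the realized odds
# unbiased (sequential accept/reject without replacement would deplete the
# in-feature stratum and undershoot the target).
sample_biased <- function(n_pick, available, in_feature, odds) {
  if (n_pick == 0L) return(integer(0))
  if (n_pick > length(available)) stop("not enough regions left to plant")
  pool_in <- available[in_feature[available]]
  pool_out <- available[!in_feature[available]]
  p_in <- odds * length(pool_in) /
    (odds * length(pool_in) + length(pool_out))
  n_in <- stats::rbinom(1L, n_pick, p_in)
  n_in <- min(max(n_in, n_pick - length(pool_out)), length(pool_in))
  if (n_in < 0L || n_pick - n_in > length(pool_out))
    stop("feature-biased placement infeasible: ",
         "odds demand more regions than the feature holds")
  picked <- c(pool_in[sample.int(length(pool_in), n_in)],
              pool_out[sample.int(length(pool_out), n_pick - n_in)])
  # random order, so any prefix (e.g. the cross-model shared subset) is an
  # unbiased sample of the planted set
  picked[sample.int(length(picked))]
}

rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu,
                                                        size = 1 / phi)
}

#' Simulate methyl-capture data with planted differential regions
#'
#' Lays out a fixed candidate-region space over the genome, draws log-normal
#' baseline intensities, and emits per-model negative-binomial tag counts
#' (or raw tag tracks). Per model, `frac_dmr` of the regions are planted
#' differential (half hyper-, half hypomethylated, the injury-group mean
#' multiplied by `2^(+-dmr_logfc)`); planted hyper regions are biased toward
#' gene bodies and hypo regions toward non-genic space at the configured
#' odds, via rejection sampling.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [generate_annotation()].
#' @param output `"counts"` (region x sample matrices; default) or
#'   `"tags"` (per-sample [tag_track()]s, exercising the proposal /
#'   dedup / counting path).
#' @return List with `regions` (`GRanges` with ids), `models` (per model:
#'   `counts` + `lib_sizes` or `tracks`, plus `group`), and `truth`
#'   (data.frame `model`, `id`, `direction`, `logFC`).
#' @export
simulate_methylation <- function(cfg, ann, output = c("counts", "tags")) {
  stopifnot(inherits(cfg, "sim_config"))
  output <- match.arg(output)
  genome <- ann$genome
  with_seed(cfg$seed * 13L + 2L, {
    n_chr <- split_by_chrom(cfg$region_count, genome)
    reg_l <- list()
    for (chr in names(genome)) {
      k <- n_chr[[chr]]
      if (k == 0L) next
      w <- round(stats::runif(k, cfg$region_width_range[1],
                              cfg$region_width_range[2]))
      pos <- place_nonoverlapping(w, genome[[chr]])
      reg_l[[chr]] <- data.frame(chrom = chr, start = pos[, "start"],
                                 end = pos[, "end"])
    }
    reg <- do.call(rbind, reg_l)
    regions <- interval_set(reg$chrom, reg$start, reg$end, genome = genome)
    mcols(regions)$id <- region_ids(regions)
    nr <- length(regions)
    mu0 <- exp(stats::rnorm(nr, log(cfg$region_mu), cfg$region_sigma_log))

    in_gb <- countOverlaps(regions, granges_only(ann$features$gene_body),
                           ignore.strand = TRUE) > 0
    in_ng <- countOverlaps(regions, granges_only(ann$features$non_genic),
                           ignore.strand = TRUE) > 0
    n_planted <- round(cfg$frac_dmr * nr)
    n_hyper <- floor(n_planted / 2); n_hypo <- n_planted - n_hyper

    # loss of capture signal presupposes baseline methylation
    hypo_eligible <- mu0 >= stats::quantile(mu0,
                                            cfg$hypo_baseline_min_quantile)
    truth_l <- list(); models_out <- list()
    first_truth <- NULL
    used <- integer(0)  # models plant disjointly unless explicitly shared
    for (mi in seq_along(cfg$models)) {
      model <- cfg$models[mi]
      hyper_idx <- integer(0); hypo_idx <- integer(0)
      if (mi > 1L && cfg$sharing > 0 && !is.null(first_truth)) {
        n_sh_hyper <- round(cfg$sharing * n_hyper)
        n_sh_hypo <- round(cfg$sharing * n_hypo)
        hyper_idx <- first_truth$hyper[seq_len(n_sh_hyper)]
        hypo_idx <- first_truth$hypo[seq_len(n_sh_hypo)]
      }
      avail <- setdiff(seq_len(nr), c(used, hyper_idx, hypo_idx))
      hyper_new <- sample_biased(n_hyper - length(hyper_idx), avail, in_gb,
                                 cfg$hyper_gene_body_odds)
      hyper_idx <- c(hyper_idx, hyper_new)
      avail <- setdiff(avail, hyper_new)
      hypo_new <- sample_biased(n_hypo - length(hypo_idx),
                                intersect(avail, which(hypo_eligible)),
                                in_ng, cfg$hypo_non_genic_odds)
      hypo_idx <- c(hypo_idx, hypo_new)
      used <- unique(c(used, hyper_idx, hypo_idx))
      if (mi == 1L) first_truth <- list(hyper = hyper_idx, hypo = hypo_idx)

      lfc <- numeric(nr)
      lfc[hyper_idx] <- cfg$dmr_logfc
      lfc[hypo_idx] <- -cfg$dmr_logfc
      n_s <- cfg$n_per_group
      group <- factor(rep(c("control", "injury"), each = n_s),
                      levels = c("control", "injury"))
      samp <- paste0(model, "_", group, "_",
                     c(seq_len(n_s), seq_len(n_s)))
      libf <- exp(stats::rnorm(2 * n_s, 0, cfg$lib_cv))
      mu <- outer(mu0, libf)
      inj <- group == "injury"
      mu[, inj] <- mu[, inj] * 2^lfc
      counts <- matrix(rnb(length(mu), mu, cfg$phi), nrow = nr,
                       dimnames = list(mcols(regions)$id, samp))
      planted <- c(hyper_idx, hypo_idx)
      truth_l[[model]] <- data.frame(
        model = rep(model, length(planted)),
        id = mcols(regions)$id[planted],
        direction = rep(c("hyper", "hypo"),
                        c(length(hyper_idx), length(hypo_idx))),
        logFC = lfc[planted], stringsAsFactors = FALSE)
      if (output == "counts") {
        models_out[[model]] <- list(counts = counts, group = group,
                                    lib_sizes = colSums(counts))
      } else {
        tracks <- lapply(seq_len(2 * n_s), function(s) {
          pos_l <- lapply(names(genome), function(chr) {
            on_chr <- as.character(seqnames(regions)) == chr
            cnt <- counts[on_chr, s]
            rs <- start(regions)[on_chr] - 1L
            ws <- width(regions)[on_chr] - cfg$tag_length
            pos <- unlist(lapply(which(cnt > 0), function(r)
              rs[r] + floor(stats::runif(cnt[r], 0, max(ws[r], 1)))),
              use.names = FALSE)
            n_bg <- stats::rpois(1, cfg$background_rate * genome[[chr]])
            bg <- floor(stats::runif(n_bg, 0,
                                     genome[[chr]] - cfg$tag_length))
            sort(as.integer(c(pos, bg)))
          })
          names(pos_l) <- names(genome)
          tag_track(samp[s], pos_l, genome, tag_length = cfg$tag_length)
        })
        models_out[[model]] <- list(tracks = tracks, group = group)
      }
    }
    list(regions = regions, models = models_out,
         truth = do.call(rbind, c(truth_l, make.row.names = FALSE)))
  })
}

#' Simulate expression data coupled to planted methylation
#'
#' Negative-binomial gene (or transcript) counts per model. Besides freely
#' planted DE genes (`frac_de`, logFC `+-de_logfc`), genes owning a planted
#' DMR that overlaps a coupled feature receive an expression shift of
#' `coupling[feature] * sign(methylation direction)` — the association that
#' preranked GSEA is meant to recover, with known direction.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [generate_annotation()].
#' @param meth Result of [simulate_methylation()] (its `truth` and `regions`
#'   drive the coupling).
#' @return List with `models` (per model: `counts` (rows = transcripts),
#'   `group`, `lib_sizes`, `tx2gene`) and `truth` (data.frame `model`,
#'   `gene`, `planted_logFC`, `coupled_logFC`).
#' @export
simulate_expression <- function(cfg, ann, meth) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- ann$genes$gene_id
  ng <- length(genes)
  coupling <- cfg$coupling
  bad <- setdiff(names(coupling), FEATURE_CLASSES)
  if (length(bad))
    stop("coupling references unknown feature(s): ",
         paste(bad, collapse = ", "))
  with_seed(cfg$seed * 13L + 3L, {
    ntx <- cfg$n_tx_per_gene
    tx <- paste0(rep(genes, each = ntx), ".t", rep(seq_len(ntx), ng))
    tx2gene <- stats::setNames(rep(genes, each = ntx), tx)
    mu0 <- exp(stats::rnorm(length(tx), log(cfg$gene_mu),
                            cfg$gene_sigma_log))
    reg_by_id <- meth$regions[match(meth$truth$id,
                                    mcols(meth$regions)$id)]
    models_out <- list(); truth_l <- list()
    for (model in cfg$models) {
      n_de <- round(cfg$frac_de * ng)
      de_genes <- sample(genes, n_de)
      planted <- stats::setNames(numeric(ng), genes)
      planted[de_genes] <- cfg$de_logfc *
        rep_len(c(1, -1), n_de)[sample.int(n_de)]
      coupled <- stats::setNames(numeric(ng), genes)
      tr <- meth$truth[meth$truth$model == model, , drop = FALSE]
      gr <- reg_by_id[meth$truth$model == model]
      for (f in names(coupling)) {
        if (coupling[[f]] == 0) next
        feat <- ann$features[[f]]
        hits <- findOverlaps(gr, feat, minoverlap = 1L, ignore.strand = TRUE)
        if (!length(hits)) next
        gid <- mcols(feat)$id[subjectHits(hits)]
        sgn <- ifelse(tr$direction[queryHits(hits)] == "hyper", 1, -1)
        # contributions accumulate; opposing events at one gene cancel
        for (k in seq_along(gid)) {
          if (is.na(gid[k])) next
          coupled[gid[k]] <- coupled[gid[k]] + coupling[[f]] * sgn[k]
        }
      }
      lfc_gene <- planted + coupled
      lfc <- lfc_gene[tx2gene[tx]]
      n_s <- cfg$n_per_group
      group <- factor(rep(c("control", "injury"), each = n_s),
                      levels = c("control", "injury"))
      samp <- paste0(model, "_rna_", group, "_",
                     c(seq_len(n_s), seq_len(n_s)))
      libf <- exp(stats::rnorm(2 * n_s, 0, cfg$lib_cv))
      mu <- outer(mu0, libf)
      inj <- group == "injury"
      mu[, inj] <- mu[, inj] * 2^lfc
      counts <- matrix(rnb(length(mu), mu, cfg$phi), nrow = length(tx),
                       dimnames = list(tx, samp))
      models_out[[model]] <- list(counts = counts, group = group,
                                  lib_sizes = colSums(counts),
                                  tx2gene = tx2gene)
      truth_l[[model]] <- data.frame(model = model, gene = genes,
                                     planted_logFC = unname(planted),
                                     coupled_logFC = unname(coupled),
                                     stringsAsFactors = FALSE)
    }
    list(models = models_out,
         truth = do.call(rbind, c(truth_l, make.row.names = FALSE)))
  })
}
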