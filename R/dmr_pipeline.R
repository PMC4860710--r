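#' Construct a tag track
#'
#' A tag track holds the aligned single-end tag start positions of one
#' methyl-capture library. Positions are 0-based tag starts; every tag has
#' the same fixed length (36 bp sequencing reads by default).
#'
#' @param sample Sample id (string).
#' @param positions Named list, chromosome -> sorted integer vector of
#'   0-based tag start positions.
#' @param genome Named numeric vector of chromosome lengths.
#' @param tag_length Tag length in bp (default 36).
#' @return Object of class `tag_track` with fields `sample`, `positions`,
#'   `genome`, `tag_length`, `lib_size` (total tag count).
#' @export
tag_track <- function(sample, positions, genome, tag_length = 36) {
  if (!is.list(positions) || is.null(names(positions)))
    stop("positions must be a named list (chromosome -> positions)")
  missing_chr <- setdiff(names(positions), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) not in genome: ", paste(missing_chr, collapse = ", "))
  positions <- lapply(positions, function(p) as.integer(p))
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (is.unsorted(p)) stop("positions on ", chr, " are not sorted")
    if (length(p) && (p[1L] < 0L || p[length(p)] + tag_length > genome[[chr]]))
      stop("tag on ", chr, " extends beyond chromosome bounds")
  }
  structure(list(sample = as.character(sample), positions = positions,
                 genome = genome, tag_length = as.integer(tag_length),
                 lib_size = sum(lengths(positions))),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("tag_track", x$sample, "-", x$lib_size, "tags of", x$tag_length,
      "bp on", length(x$positions), "chromosome(s)\n")
  invisible(x)
}

#' Remove duplicate tags
#'
#' At most one tag is kept per (chromosome, start position); tags aligned to
#' the same location are PCR duplicates under this protocol. The library
#' size is updated.
#'
#' @param track A [tag_track()].
#' @return Deduplicated `tag_track`.
#' @export
dedupe_tags <- function(track) {
  stopifnot(inherits(track, "tag_track"))
  track$positions <- lapply(track$positions, unique)
  track$lib_size <- sum(lengths(track$positions))
  track
}

track_granges <- function(track) {
  chrs <- names(track$positions)
  n <- lengths(track$positions)
  pos <- unlist(track$positions, use.names = FALSE)
  GRanges(rep(chrs, n),
          IRanges(pos + 1L, pos + track$tag_length),
          seqlengths = track$genome[sort(names(track$genome))])
}

#' Propose candidate methylated regions from pairwise window enrichment
#'
#' A simplified fixed-window surrogate for pairwise peak calling: the genome
#' is tiled with sliding windows; for every ordered pair of samples (A, B),
#' each window is tested for enrichment of A's tag count over the expectation
#' scaled from B (`countB * libA / libB`, floored at a pseudocount of 1) with
#' a Poisson upper-tail test. Windows significant below `p_cutoff` in any
#' pair are pooled and merged (bookended) into candidate regions.
#'
#' @param tracks List of [tag_track()] (deduplicated).
#' @param width Window width in bp (default 300, i.e. four times the 75 bp
#'   tag-shift scale typical for this fragment size).
#' @param step Window step in bp (default 150); must satisfy
#'   `width >= step > 0`.
#' @param p_cutoff Poisson enrichment significance cutoff (default 1e-5).
#' @param min_tags Minimum window tag count in the enriched sample
#'   (default 0).
#' @param group Optional group labels (one per track). When `pairs =
#'   "cross"`, only pairs from different groups are tested.
#' @param pairs `"all"` (default) or `"cross"`.
#' @return Sorted disjoint `GRanges` of candidate regions.
#' @export
propose_candidate_regions <- function(tracks, width = 300, step = 150,
                                      p_cutoff = 1e-5, min_tags = 0,
                                      group = NULL, pairs = c("all", "cross")) {
  pairs <- match.arg(pairs)
  if (length(tracks) < 2L) stop("need at least two tag tracks")
  if (!(width >= step && step > 0)) stop("need width >= step > 0")
  if (!(p_cutoff > 0 && p_cutoff < 1)) stop("p_cutoff must be in (0, 1)")
  libs <- vapply(tracks, `[[`, 0, "lib_size")
  if (any(libs == 0)) stop("zero library size in a track")
  genome <- tracks[[1L]]$genome
  if (pairs == "cross") {
    if (is.null(group) || length(group) != length(tracks))
      stop("pairs = \"cross\" requires one group label per track")
    group <- as.character(group)
  }
  hits <- list()
  for (chr in sort(names(genome))) {
    len <- genome[[chr]]
    if (len < width) { starts <- 0L; ends <- len } else {
      starts <- seq.int(0L, len - width, by = step)
      ends <- starts + width
    }
    win <- IRanges(starts + 1L, ends)
    cnt <- vapply(tracks, function(tr) {
      p <- tr$positions[[chr]]
      if (is.null(p) || !length(p)) return(integer(length(win)))
      countOverlaps(win, IRanges(p + 1L, p + tr$tag_length))
    }, integer(length(win)))
    cnt <- matrix(cnt, nrow = length(win))
    sig <- logical(length(win))
    for (i in seq_along(tracks)) for (j in seq_along(tracks)) {
      if (i == j) next
      if (pairs == "cross" && group[i] == group[j]) next
      lam <- pmax(cnt[, j] * libs[i] / libs[j], 1)
      p <- stats::ppois(cnt[, i] - 1, lam, lower.tail = FALSE)
      sig <- sig | (p < p_cutoff & cnt[, i] >= min_tags)
    }
    if (any(sig))
      hits[[chr]] <- GRanges(chr, win[sig],
                             seqlengths = genome[sort(names(genome))])
  }
  if (!length(hits))
    return(interval_set(character(), integer(), integer(), genome = genome))
  merge_intervals(sort_intervals(do.call(c, unname(hits))))
}

#' Count tags falling in regions
#'
#' A tag is counted in a region when its `[pos, pos + tag_length)` interval
#' shares at least one base with the region. Regions produced by
#' [merge_intervals()] are disjoint, so counts partition the tags.
#'
#' @param regions `GRanges` of regions (should carry `id` metadata; ids are
#'   generated from coordinates otherwise).
#' @param tracks List of deduplicated [tag_track()].
#' @return Integer matrix, regions x samples, with region ids as rownames.
#' @export
count_tags_in_regions <- function(regions, tracks) {
  for (tr in tracks)
    lapply(tr$positions, function(p)
      if (is.unsorted(p)) stop("track ", tr$sample, " has unsorted positions"))
  ids <- region_ids(regions)
  m <- vapply(tracks,
              function(tr) countOverlaps(regions, track_granges(tr),
                                         minoverlap = 1L,
                                         ignore.strand = TRUE),
              integer(length(regions)))
  m <- matrix(m, nrow = length(regions),
              dimnames = list(ids, vapply(tracks, `[[`, "", "sample")))
  m
}

region_ids <- function(regions) {
  if (!is.null(mcols(regions)$id)) return(mcols(regions)$id)
  paste0(as.character(seqnames(regions)), ":", start(regions) - 1L, "-",
         end(regions))
}

parse_region_ids <- function(ids, genome = NULL) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable region id: ", ids[which(bad)[1L]])
  interval_set(vapply(m, `[[`, "", 2L),
               as.numeric(vapply(m, `[[`, "", 3L)),
               as.numeric(vapply(m, `[[`, "", 4L)),
               id = ids, genome = genome)
}

#' Call differentially methylated regions
#'
#' Full region-level differential pipeline: tag counting (when tracks are
#' given), 50th-percentile row-sum filter, TMM normalization, common NB
#' dispersion, two-sided exact test, and thresholding at `p_cutoff`.
#' Direction is `hyper` for positive logFC (condition over baseline) and
#' `hypo` for negative.
#'
#' @param regions `GRanges` of candidate regions (disjoint).
#' @param x Either a list of [tag_track()] or a precomputed counts matrix
#'   (regions x samples, rownames = region ids).
#' @param group Two-level factor over samples; first level = control.
#' @param p_cutoff DMR significance threshold on the raw p-value
#'   (default 0.01).
#' @param filter_q Row-sum percentile filter (default 50).
#' @param lib_sizes Optional library sizes; defaults to track library sizes
#'   (total tags) or column sums.
#' @return Object of class `dmr_result`: list with `dmrs` (data.frame
#'   chrom/start/end/id/logFC/pvalue/direction), `table` (all tested
#'   regions), `tested` (`GRanges` of retained regions), `dispersion`,
#'   `norm_factors`.
#' @export
call_dmrs <- function(regions, x, group, p_cutoff = 0.01, filter_q = 50,
                      lib_sizes = NULL) {
  if (is.list(x) && !is.data.frame(x) && length(x) &&
      inherits(x[[1L]], "tag_track")) {
    counts <- count_tags_in_regions(regions, x)
    if (is.null(lib_sizes))
      lib_sizes <- vapply(x, `[[`, 0, "lib_size")
  } else {
    counts <- x
    if (length(regions)) check_count_matrix(counts)
  }
  if (length(regions) == 0L || nrow(counts) == 0L) {
    warning("empty candidate region set; no DMRs to call")
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), id = character(), logFC = numeric(),
                        pvalue = numeric(), direction = character())
    return(structure(list(dmrs = empty, table = empty, tested = regions,
                          dispersion = NA_real_, norm_factors = NULL),
                     class = "dmr_result"))
  }
  mcols(regions)$id <- region_ids(regions)
  res <- diff_count_test(counts, group, filter_q = filter_q,
                         lib_sizes = lib_sizes)
  keep <- attr(res, "retained")
  tested <- regions[match(keep, mcols(regions)$id)]
  bed <- as_bed_frame(tested)
  tab <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    id = res$id, logFC = res$logFC, pvalue = res$pvalue,
                    direction = ifelse(res$logFC >= 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  dmrs <- tab[tab$pvalue < p_cutoff, , drop = FALSE]
  rownames(dmrs) <- NULL
  structure(list(dmrs = dmrs, table = tab, tested = tested,
                 dispersion = attr(res, "dispersion"),
                 norm_factors = attr(res, "norm_factors")),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", nrow(x$table), "tested regions,", nrow(x$dmrs),
      "DMRs (", sum(x$dmrs$direction == "hyper"), "hyper /",
      sum(x$dmrs$direction == "hypo"), "hypo ), phi =",
      signif(x$dispersion, 3), "\n")
  invisible(x)
}

#' Convert a DMR table to a `GRanges`
#'
#' @param dmrs data.frame with chrom/start/end/id/logFC/pvalue/direction.
#' @param genome Optional chromosome lengths.
#' @return `GRanges` with the table columns as metadata.
#' @export
dmr_granges <- function(dmrs, genome = NULL) {
  gr <- interval_set(dmrs$chrom, dmrs$start, dmrs$end, id = dmrs$id,
                     genome = genome)
  ord <- match(mcols(gr)$id, dmrs$id)
  mcols(gr)$logFC <- dmrs$logFC[ord]
  mcols(gr)$pvalue <- dmrs$pvalue[ord]
  mcols(gr)$direction <- dmrs$direction[ord]
  gr
}

#' Write DMRs as BED6
#'
#' Score is `-10 * log10(p)` capped at 1000; strand is ".".
#'
#' @param dmrs DMR data.frame.
#' @param path Output path.
#' @param header Optional comment.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path, header = NULL) {
  gr <- dmr_granges(dmrs)
  mcols(gr)$score <- round(pmin(-10 * log10(pmax(mcols(gr)$pvalue, 1e-300)),
                                1000), 2)
  mcols(gr)$direction <- NULL
  mcols(gr)$logFC <- NULL
  mcols(gr)$pvalue <- NULL
  write_bed(gr, path, header = header)
}
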