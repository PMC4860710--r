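#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   "strand<-" reduce findOverlaps pintersect countOverlaps gaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqnames<-
NULL

#' Construct a genomic interval set
#'
#' Builds a sorted `GRanges` from 0-based half-open (BED convention)
#' coordinates. All region arithmetic in this package runs on these objects.
#' Iteration order is deterministic: chromosome (lexicographic), then start,
#' then end.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, exclusive end coordinates (`end > start`).
#' @param strand Strand per interval: `"+"`, `"-"` or `"*"` (unstranded,
#'   the default). Strand is carried but ignored by merge/overlap arithmetic.
#' @param id Optional character labels, stored in `mcols(x)$id`.
#' @param genome Optional named numeric vector of chromosome lengths (bp).
#'   When supplied, every interval must fit inside its chromosome.
#' @return A sorted `GRanges`; internal storage is 1-based closed, use
#'   [as_bed_frame()] to get BED coordinates back.
#' @export
interval_set <- function(chrom, start, end, strand = "*", id = NULL,
                         genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  if (n > 0L) {
    if (any(c(length(chrom), length(start), length(end)) == 0L))
      stop("chrom, start and end must all be non-empty")
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (n == 0L) {
    gr <- GRanges()
    if (!is.null(genome)) gr <- set_genome(gr, genome)
    return(gr)
  }
  chrom <- as.character(chrom)
  if (any(!nzchar(chrom)) || anyNA(chrom))
    stop("chromosome names must be non-empty")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("coordinates must be integral")
  if (any(start < 0)) stop("start coordinates must be >= 0")
  if (any(end <= start)) stop("intervals must satisfy end > start")
  strand <- rep_len(as.character(strand), n)
  strand[strand %in% c(".", "")] <- "*"
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  if (!is.null(id)) mcols(gr)$id <- rep_len(as.character(id), n)
  if (!is.null(genome)) gr <- set_genome(gr, genome)
  sort_intervals(gr)
}

# Attach chromosome lengths; seqlevels kept lexicographically sorted so that
# sort() yields the documented deterministic order.
set_genome <- function(gr, genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome lengths")
  missing_chr <- setdiff(as.character(unique(seqnames(gr))), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) not in genome: ", paste(missing_chr, collapse = ", "))
  lv <- sort(names(genome))
  seqlevels(gr) <- lv
  # own bounds check below; silence the out-of-bound note this would raise
  suppressWarnings(seqlengths(gr) <- genome[lv])
  if (length(gr) && any(end(gr) > seqlengths(gr)[as.character(seqnames(gr))]))
    stop("interval end exceeds chromosome length")
  gr
}

sort_intervals <- function(gr) {
  if (length(gr) < 2L) return(gr)
  if (any(is.na(seqlengths(gr))) || length(seqlengths(gr)) == 0L)
    seqlevels(gr) <- sort(seqlevels(gr))
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  gr[o]
}

genome_of <- function(gr) {
  sl <- seqlengths(gr)
  if (length(sl) == 0L || any(is.na(sl)))
    stop("interval set has no genome (chromosome lengths); supply `genome=`")
  sl
}

#' Convert an interval set back to BED-convention coordinates
#'
#' @param gr A `GRanges`, e.g. from [interval_set()].
#' @return A data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `strand`, and `id` when present.
#' @export
as_bed_frame <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   strand = as.character(strand(gr)),
                   stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$id)) df$id <- mcols(gr)$id
  df
}

#' Merge overlapping or near-adjacent intervals
#'
#' Intervals separated by a gap of at most `min_gap` bases are merged;
#' bookended intervals (gap of 0) merge at the default. The union of covered
#' bases is preserved and the output is disjoint and sorted. Strand is
#' ignored.
#'
#' @param s Interval set (`GRanges`).
#' @param min_gap Non-negative integer; maximum gap (bp) across which to
#'   merge. Default 0 (bookended merge).
#' @return Disjoint sorted `GRanges`.
#' @export
merge_intervals <- function(s, min_gap = 0) {
  if (length(min_gap) != 1L || is.na(min_gap) || min_gap < 0)
    stop("min_gap must be a single non-negative number")
  reduce(s, min.gapwidth = min_gap + 1L, ignore.strand = TRUE)
}

#' Test whether two intervals share at least one base
#'
#' Half-open semantics: intervals that merely touch (one's end equals the
#' other's start) do not overlap. Strand is ignored. Vectorized pairwise.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return Logical vector.
#' @export
overlaps_1bp <- function(a, b) {
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(a) != length(b)) stop("a and b must have matching lengths")
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    pmax(start(a), start(b)) <= pmin(end(a), end(b))
}

#' All overlapping interval pairs between two sets
#'
#' Returns every pair of intervals sharing >= 1 bp, with the overlap length.
#' Both sets must carry the same genome when genomes are attached.
#'
#' @param a,b Interval sets (`GRanges`).
#' @return data.frame with columns `a_idx`, `b_idx` (indices into the sorted
#'   inputs), `a_id`, `b_id` (when ids are present) and `overlap_bp`.
#' @export
intersect_pairs <- function(a, b) {
  sla <- seqlengths(a); slb <- seqlengths(b)
  if (length(sla) && length(slb) && !any(is.na(sla)) && !any(is.na(slb))) {
    if (!identical(sla[sort(names(sla))], slb[sort(names(slb))]))
      stop("interval sets have mismatched genomes")
  }
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  hits <- findOverlaps(a, b, minoverlap = 1L, ignore.strand = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- pmin(end(a)[qi], end(b)[si]) - pmax(start(a)[qi], start(b)[si]) + 1L
  out <- data.frame(a_idx = qi, b_idx = si, overlap_bp = as.integer(ov))
  if (!is.null(mcols(a)$id)) out$a_id <- mcols(a)$id[qi]
  if (!is.null(mcols(b)$id)) out$b_id <- mcols(b)$id[si]
  o <- order(out$a_idx, out$b_idx)
  out[o, , drop = FALSE]
}

#' Complement of an interval set over its genome
#'
#' Bases not covered by `merge_intervals(s)`. Together the two sets cover
#' every base of the genome exactly once.
#'
#' @param s Interval set with chromosome lengths attached.
#' @return Sorted disjoint `GRanges` covering the uncovered bases.
#' @export
complement_intervals <- function(s) {
  genome_of(s)
  red <- reduce(s, ignore.strand = TRUE)
  strand(red) <- "*"
  g <- gaps(red)
  g <- g[strand(g) == "*"]
  strand(g) <- "*"
  sort_intervals(g)
}

#' Read a BED3+ file as an interval set
#'
#' Accepts BED3 to BED6 (plus ignored extra columns). Lines starting with
#' `#`, `track` or `browser` are skipped. Coordinates are validated; a
#' malformed line raises an error naming its line number.
#'
#' @param path File path.
#' @param genome Optional named chromosome-length vector (see
#'   [interval_set()]).
#' @return Sorted `GRanges`; BED name column becomes `id`, score (when
#'   present) becomes `score`.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(interval_set(character(), integer(), integer(), genome = genome))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  st <- suppressWarnings(as.numeric(s_chr))
  en <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(st) | is.na(en) | st != floor(st) | en != floor(en))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], ": non-integer coordinates")
  bad <- which(st >= en | st < 0)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]],
         ": requires 0 <= start < end")
  id <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- interval_set(chrom, st, en,
                     strand = strand,
                     id = if (all(is.na(id))) NULL else id,
                     genome = genome)
  if (any(nf >= 5L)) {
    sc <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else "0", "")))
    # score order must follow the sorted intervals
    o <- order(chrom, st, en)
    mcols(gr)$score <- sc[o]
  }
  gr
}

#' Write an interval set as BED
#'
#' Writes BED6 when ids, scores or strands are informative, else BED3.
#' Coordinates are emitted 0-based half-open.
#'
#' @param s Interval set (`GRanges`).
#' @param path Output file path.
#' @param header Optional comment line(s) written with a leading `#`.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(s, path, header = NULL) {
  df <- as_bed_frame(s)
  has6 <- !is.null(mcols(s)$id) || !is.null(mcols(s)$score) ||
    any(df$strand != "*")
  if (has6) {
    nm <- if (!is.null(mcols(s)$id)) mcols(s)$id else rep(".", length(s))
    sc <- if (!is.null(mcols(s)$score)) mcols(s)$score else rep(0, length(s))
    strand_chr <- ifelse(df$strand == "*", ".", df$strand)
    out <- cbind(df$chrom, df$start, df$end, nm, sc, strand_chr)
  } else {
    out <- cbind(df$chrom, df$start, df$end)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(df)) writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a two-column genome file (chrom, length)
#'
#' @param path TSV path with columns chromosome name and length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}
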