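#' Direction-consistent common regions between two models
#'
#' Intersects two DMR sets: pairs of regions sharing >= 1 bp are partitioned
#' into same-direction (common) and opposite-direction pairs. Pair counts
#' enumerate overlap pairs (a region overlapping several partners appears
#' once per partner); anchor counts count each region of `a` at most once.
#'
#' @param a,b DMR data.frames (columns `chrom`, `start`, `end`, `id`,
#'   `direction`) or `dmr_result` objects.
#' @param genome Optional chromosome lengths for coordinate validation.
#' @return List with `same` and `opposite` pair tables (columns `a_id`,
#'   `b_id`, `overlap_bp`, `direction_a`, `direction_b`), `n_same`,
#'   `n_opposite` (pair counts), and `n_same_anchors` (distinct `a` regions
#'   with a same-direction partner).
#' @export
common_regions <- function(a, b, genome = NULL) {
  a <- as_dmr_frame(a); b <- as_dmr_frame(b)
  ga <- dmr_granges(a, genome); gb <- dmr_granges(b, genome)
  pairs <- intersect_pairs(ga, gb)
  dir_a <- mcols(ga)$direction[pairs$a_idx]
  dir_b <- mcols(gb)$direction[pairs$b_idx]
  tab <- data.frame(a_id = mcols(ga)$id[pairs$a_idx],
                    b_id = mcols(gb)$id[pairs$b_idx],
                    overlap_bp = pairs$overlap_bp,
                    direction_a = dir_a, direction_b = dir_b,
                    stringsAsFactors = FALSE)
  same <- tab[dir_a == dir_b, , drop = FALSE]
  opp <- tab[dir_a != dir_b, , drop = FALSE]
  rownames(same) <- rownames(opp) <- NULL
  list(same = same, opposite = opp,
       n_same = nrow(same), n_opposite = nrow(opp),
       n_same_anchors = length(unique(same$a_id)))
}

as_dmr_frame <- function(x) {
  if (inherits(x, "dmr_result")) x$dmrs else x
}

#' Three-way direction-consistent overlap (Venn) counts
#'
#' Counting unit: an anchor region counted once however many partners it
#' overlaps. A region of one model is pairwise-common when it has a
#' same-direction >= 1 bp overlap with some region of the other model;
#' triple-common when it has such partners in both other models.
#'
#' @param models Named list of three DMR data.frames / `dmr_result`s.
#' @param genome Optional chromosome lengths.
#' @return List with `totals` (regions per model), `pairwise` (data.frame of
#'   same/opposite anchor counts per ordered pair) and `triple` (named
#'   vector: triple-common anchors per model).
#' @export
venn_three <- function(models, genome = NULL) {
  if (length(models) != 3L) stop("exactly three models are required")
  if (is.null(names(models))) names(models) <- paste0("model", 1:3)
  frames <- lapply(models, as_dmr_frame)
  grs <- lapply(frames, dmr_granges, genome = genome)
  nm <- names(models)
  same_anchor <- function(i, j) {
    cr <- common_regions(frames[[i]], frames[[j]], genome)
    unique(cr$same$a_id)
  }
  pw <- list()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    cr <- common_regions(frames[[i]], frames[[j]], genome)
    pw[[length(pw) + 1L]] <- data.frame(
      a = nm[i], b = nm[j],
      same_anchors = length(unique(cr$same$a_id)),
      same_pairs = cr$n_same, opposite_pairs = cr$n_opposite,
      stringsAsFactors = FALSE)
  }
  triple <- vapply(1:3, function(i) {
    others <- setdiff(1:3, i)
    length(intersect(same_anchor(i, others[1]), same_anchor(i, others[2])))
  }, 0L)
  names(triple) <- nm
  list(totals = vapply(frames, nrow, 0L),
       pairwise = do.call(rbind, pw), triple = triple)
}

#' Row-wise z-scores within model blocks
#'
#' Standardizes each row to mean 0 and sample SD 1 separately within each
#' model's block of columns — the preprocessing behind the cross-model
#' heatmaps. Constant rows map to zeros with a warning.
#'
#' @param m Numeric matrix.
#' @param blocks Factor/character vector over columns giving the model of
#'   each sample; default one block.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m, blocks = NULL) {
  if (is.null(blocks)) blocks <- rep("all", ncol(m))
  if (length(blocks) != ncol(m)) stop("blocks must label every column")
  warned <- FALSE
  for (b in unique(blocks)) {
    j <- which(blocks == b)
    if (length(j) < 2L) stop("model block '", b, "' has a single column")
    sub <- m[, j, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    z <- (sub - mu) / sdv
    const <- sdv == 0
    if (any(const)) { z[const, ] <- 0; warned <- TRUE }
    m[, j] <- z
  }
  if (warned) warning("constant row(s) mapped to zero z-scores")
  m
}

#' Complete-linkage clustering with Pearson correlation distance
#'
#' Distance is `1 - Pearson correlation` between items (columns by default);
#' a constant item, whose correlation is undefined, is assigned distance 1
#' to everything by convention. Merging uses complete linkage with
#' deterministic lowest-index tie-breaking (as in [stats::hclust()]).
#'
#' @param m Numeric matrix.
#' @param axis `"columns"` (cluster samples) or `"rows"`.
#' @return List with `hclust` (the merge tree), `order` (leaf order) and
#'   `labels`.
#' @export
cluster_complete_pearson <- function(m, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  x <- if (axis == "columns") m else t(m)
  if (ncol(x) < 2L) stop("need at least two items to cluster")
  cm <- suppressWarnings(stats::cor(x))
  cm[is.na(cm)] <- 0  # constant vector: distance 1 - 0 = 1 to everything
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "complete")
  list(hclust = hc, order = hc$order, labels = hc$labels)
}

#' Cut a clustering into k groups
#'
#' @param cl Result of [cluster_complete_pearson()].
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_clusters <- function(cl, k) stats::cutree(cl$hclust, k = k)

#' Export a clustering as Newick
#'
#' @param cl Result of [cluster_complete_pearson()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(cl, path) {
  ph <- ape::as.phylo(cl$hclust)
  ape::write.tree(ph, file = path)
  invisible(path)
}
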