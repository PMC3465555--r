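#' Binary occupancy matrix over the merged peak universe
#'
#' The universe is the merged union of all factors' peaks; entry (r, f) is
#' 1 iff factor f has at least one peak overlapping universe region r.
#' Every row therefore contains at least one 1.
#'
#' @param peaksets List of [peak_set()] objects (names default to each
#'   set's factor attribute).
#' @return An `occupancy_matrix`: list with `regions` ([region_set()]),
#'   `factors`, and binary `values` (rows = regions, columns = factors).
#' @export
binary_peak_matrix <- function(peaksets) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  if (!length(peaksets)) stopf("binary_peak_matrix() needs >= 1 peak set")
  if (!all(vapply(peaksets, inherits, TRUE, "peak_set")))
    stopf("all inputs must be peak_set objects")
  factors <- names(peaksets) %||% vapply(peaksets, peak_factor, "")
  if (is.null(names(peaksets))) names(peaksets) <- factors
  empty <- !vapply(peaksets, nrow, 0L)
  if (any(empty))
    stopf("empty peak set for factor(s): %s",
          paste(factors[empty], collapse = ", "))
  if (anyDuplicated(factors)) stopf("duplicate factor names")
  universe <- merge_intervals(peaksets, label = "union")
  values <- matrix(0L, nrow = nrow(universe), ncol = length(factors),
                   dimnames = list(region_id(universe$chrom, universe$start,
                                             universe$end), factors))
  for (f in factors) {
    hit <- overlaps(universe, peaksets[[f]])
    values[unique(hit$a), f] <- 1L
  }
  structure(list(regions = universe, factors = factors, values = values),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("<occupancy_matrix> %d regions x %d factors (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' Write an occupancy matrix as TSV
#'
#' Region coordinates plus one 0/1 column per factor.
#'
#' @param matrix An `occupancy_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occupancy_matrix <- function(matrix, path) {
  df <- cbind(as.data.frame(matrix$regions),
              as.data.frame(matrix$values, row.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hierarchical clustering of factor occupancy profiles
#'
#' Pairwise distance between factors is 1 - Pearson correlation of their
#' binary occupancy columns, followed by agglomerative clustering.
#' Factors are ordered by name before clustering so ties resolve
#' deterministically. A zero-variance column (a factor occupying all or
#' none of the universe) makes the correlation undefined and is an error.
#'
#' @param matrix An `occupancy_matrix` with >= 2 factors.
#' @param linkage Agglomeration rule: "average" (default), "complete" or
#'   "single".
#' @return A `cluster_result`: list with `distance` (symmetric matrix of
#'   1 - r), `merge`, `height`, `order`, `labels`, `linkage`, and the
#'   underlying `hclust` object.
#' @export
cluster_factors <- function(matrix,
                            linkage = c("average", "complete", "single")) {
  stopifnot(inherits(matrix, "occupancy_matrix"))
  linkage <- match.arg(linkage)
  v <- matrix$values[, order(colnames(matrix$values), method = "radix"),
                     drop = FALSE]
  if (ncol(v) < 2) stopf("cluster_factors() needs >= 2 factors")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance occupancy column (correlation undefined) for factor(s): %s",
          paste(colnames(v)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(v)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(distance = d, merge = hc$merge, height = hc$height,
                 order = hc$order, labels = hc$labels, linkage = linkage,
                 hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d factors, %s linkage; merge heights: %s\n",
              length(x$labels), x$linkage,
              paste(signif(x$height, 4), collapse = ", ")))
  invisible(x)
}

#' Export a cluster result
#'
#' Writes the agglomerative merge table as TSV and returns (optionally
#' writes) the dendrogram as a Newick tree string.
#'
#' @param cluster A `cluster_result`.
#' @param merge_path Optional path for the merge-table TSV.
#' @param newick_path Optional path for the Newick string.
#' @return The Newick string, invisibly if any path was written.
#' @export
export_cluster <- function(cluster, merge_path = NULL, newick_path = NULL) {
  stopifnot(inherits(cluster, "cluster_result"))
  if (!is.null(merge_path)) {
    df <- data.frame(step = seq_along(cluster$height),
                     merge1 = cluster$merge[, 1], merge2 = cluster$merge[, 2],
                     height = cluster$height)
    utils::write.table(df, merge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  nwk <- ape::write.tree(ape::as.phylo(cluster$hclust))
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (is.null(merge_path) && is.null(newick_path)) nwk else invisible(nwk)
}

venn_signatures <- function(nms) {
  sig <- character(0)
  for (k in seq_along(nms))
    sig <- c(sig, utils::combn(nms, k, paste, collapse = "&"))
  sig
}

new_venn_counts <- function(counts, mode, universe_size) {
  structure(list(cell_counts = counts, mode = mode,
                 universe_size = universe_size),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> mode=%s, universe=%d\n", x$mode,
              x$universe_size))
  print(x$cell_counts)
  invisible(x)
}

#' Region-level Venn intersection of 2-3 binding profiles
#'
#' The universe is the merged union of all inputs; each universe region is
#' labeled with the subset of inputs having at least one overlapping
#' peak/region, and cells count regions per subset signature (signatures
#' joined with "&" in input order). Counts sum to the universe size.
#' With `count = "peaks"` the cells instead count original input peaks
#' falling in regions of each signature (a secondary mode; cells then sum
#' to the total peak count rather than the universe size).
#'
#' @param ... 2-3 named [peak_set()]/[region_set()] inputs (or one named
#'   list). Unnamed peak sets take their factor attribute as name.
#' @param top_n Optional: restrict each peak-set input to its top-n scored
#'   peaks before intersection.
#' @param count "regions" (default) or "peaks".
#' @return A `venn_counts` with `mode = "regions"`.
#' @export
region_venn <- function(..., top_n = NULL, count = c("regions", "peaks")) {
  count <- match.arg(count)
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  if (length(sets) < 2 || length(sets) > 3)
    stopf("region_venn() supports 2 or 3 inputs, got %d", length(sets))
  nms <- names(sets)
  if (is.null(nms)) nms <- rep("", length(sets))
  for (i in seq_along(sets)) {
    if (!nzchar(nms[i]))
      nms[i] <- if (inherits(sets[[i]], "peak_set")) peak_factor(sets[[i]])
                else attr(sets[[i]], "label")
  }
  if (anyDuplicated(nms)) stopf("input names must be distinct")
  if (!is.null(top_n))
    sets <- lapply(sets, function(s)
      if (inherits(s, "peak_set")) top_n_peaks(s, top_n) else s)
  if (any(!vapply(sets, nrow, 0L)))
    stopf("each input must be non-empty (after any top_n restriction)")
  universe <- merge_intervals(sets, label = "union")
  member <- matrix(FALSE, nrow(universe), length(sets),
                   dimnames = list(NULL, nms))
  for (i in seq_along(sets))
    member[unique(overlaps(universe, sets[[i]])$a), i] <- TRUE
  sig_of <- apply(member, 1, function(m) paste(nms[m], collapse = "&"))
  cells <- stats::setNames(integer(length(venn_signatures(nms))),
                           venn_signatures(nms))
  if (count == "regions") {
    tab <- table(sig_of)
    cells[names(tab)] <- as.integer(tab)
  } else {
    for (i in seq_along(sets)) {
      hit <- overlaps(sets[[i]], universe)
      # each input interval lies inside exactly one merged universe region;
      # count it under that region's signature
      per_peak <- table(sig_of[hit$b[!duplicated(hit$a)]])
      cells[names(per_peak)] <- cells[names(per_peak)] + as.integer(per_peak)
    }
  }
  new_venn_counts(cells, mode = "regions", universe_size = nrow(universe))
}

#' Gene-level Venn intersection of 2-3 target sets
#'
#' Standard finite-set Venn cells over the union universe.
#'
#' @param ... 2-3 named character vectors of gene ids (or one named list).
#' @return A `venn_counts` with `mode = "genes"`.
#' @export
gene_venn <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  if (length(sets) < 2 || length(sets) > 3)
    stopf("gene_venn() supports 2 or 3 inputs, got %d", length(sets))
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms))) stopf("inputs must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, nms))
  sig_of <- apply(member, 1, function(m) paste(nms[m], collapse = "&"))
  cells <- stats::setNames(integer(length(venn_signatures(nms))),
                           venn_signatures(nms))
  tab <- table(sig_of)
  cells[names(tab)] <- as.integer(tab)
  new_venn_counts(cells, mode = "genes", universe_size = length(universe))
}

#' Fraction of a primary gene set shared with other sets
#'
#' Used for statements of the form "over 90\% of factor X's predicted
#' targets are also targets of the other factors".
#'
#' @param primary Non-empty character vector of gene ids.
#' @param others Character vector (typically a union of other factors'
#'   target sets).
#' @return List with `fraction` (= shared/total), `shared`, and `total`.
#' @export
shared_fraction <- function(primary, others) {
  primary <- unique(as.character(primary))
  if (!length(primary))
    stopf("shared_fraction() is undefined for an empty primary set")
  shared <- sum(primary %in% unique(as.character(others)))
  list(fraction = shared / length(primary), shared = shared,
       total = length(primary))
}
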