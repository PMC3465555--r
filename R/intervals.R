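#' Merge peak/region sets into a minimal disjoint region set
#'
#' Computes the base-level union of all inputs and returns it as the
#' minimal set of disjoint regions. Half-open intervals that touch
#' end-to-start (e.g. `[10,20)` and `[20,30)`) are merged.
#'
#' @param ... One or more [peak_set()]/[region_set()] objects, or a single
#'   list of them.
#' @param label Label for the resulting set.
#' @return A [region_set()] covering exactly the union of the inputs.
#' @examples
#' a <- peak_set("chr1", c(10, 15), c(20, 30), factor = "A")
#' merge_intervals(a)  # one region [10, 30)
#' @export
merge_intervals <- function(..., label = "merged") {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  if (!length(sets)) stopf("merge_intervals() needs at least one input set")
  ok <- vapply(sets, function(s)
    inherits(s, "peak_set") || inherits(s, "region_set"), TRUE)
  if (!all(ok)) stopf("inputs must be peak_set or region_set objects")
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               stringsAsFactors = FALSE)))
  if (!nrow(df)) return(region_set(label = label))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  ))
  out <- granges_to_df(gr)
  region_set(out$chrom, out$start, out$end, label = label)
}

#' All overlapping pairs between two interval sets
#'
#' Two half-open intervals overlap iff they share at least one base;
#' abutting intervals (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b A [peak_set()] or [region_set()].
#' @return A data.frame with integer columns `a` and `b` (row indices into
#'   the sorted inputs), sorted lexicographically; zero rows if none.
#' @export
overlaps <- function(a, b) {
  for (s in list(a, b))
    if (!(inherits(s, "peak_set") || inherits(s, "region_set")))
      stopf("inputs must be peak_set or region_set objects")
  if (!nrow(a) || !nrow(b))
    return(data.frame(a = integer(), b = integer()))
  hits <- GenomicRanges::findOverlaps(set_to_granges(a), set_to_granges(b))
  out <- data.frame(a = S4Vectors::queryHits(hits),
                    b = S4Vectors::subjectHits(hits))
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total bases covered by a region set
#' @param x A [region_set()] (or [peak_set()]; overlaps counted once via merge).
#' @return Integer number of covered bases.
#' @export
covered_bases <- function(x) {
  if (inherits(x, "peak_set")) x <- merge_intervals(x)
  sum(x$end - x$start)
}
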