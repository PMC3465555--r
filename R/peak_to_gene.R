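#' Peak-to-gene assignment rule parameters
#'
#' Defaults encode the uniform mapping rule used across the ChIP-seq
#' compendium: a peak within `tss_window` bp of a TSS is associated with
#' that gene alone; all other peaks can be associated with up to
#' `max_genes_per_peak` genes by examining `flank` bp of flanking sequence
#' on either side of the peak.
#'
#' @param tss_window TSS proximity window in bp (default 100). A TSS at
#'   exactly this distance counts as within (inclusive boundary).
#' @param flank Flanking search distance in bp on each side (default 50000).
#' @param max_genes_per_peak Maximum genes linked per non-proximal peak
#'   (default 2: nearest TSS on each side of the peak midpoint).
#' @param anchor Distance anchor: `"interval"` (default; distance 0 when
#'   the TSS lies inside the peak) or `"summit"` (absolute distance from
#'   the peak summit, requiring summit annotation).
#' @return An `assignment_rule` list.
#' @export
assignment_rule <- function(tss_window = 100L, flank = 50000L,
                            max_genes_per_peak = 2L,
                            anchor = c("interval", "summit")) {
  anchor <- match.arg(anchor)
  if (!is_count(tss_window)) stopf("tss_window must be a non-negative integer")
  if (!is_count(flank) || flank < tss_window)
    stopf("flank must be an integer >= tss_window")
  if (!is_count(max_genes_per_peak) || max_genes_per_peak < 1)
    stopf("max_genes_per_peak must be >= 1")
  structure(list(tss_window = as.integer(tss_window),
                 flank = as.integer(flank),
                 max_genes_per_peak = as.integer(max_genes_per_peak),
                 anchor = anchor),
            class = "assignment_rule")
}

#' Distance between a peak and a gene TSS
#'
#' Under the interval anchor the distance is 0 when the TSS coordinate lies
#' inside `[start, end)`; otherwise it is the gap to the nearest covered
#' base, so a TSS one base past the (exclusive) end has distance 1.
#' Vectorised over peaks.
#'
#' @param tss TSS coordinate(s), 0-based.
#' @param start,end Peak interval(s), 0-based half-open.
#' @param summit Optional absolute summit position(s); when supplied the
#'   distance is `|tss - summit|`.
#' @return Integer distance(s) in bp, >= 0.
#' @export
peak_gene_distance <- function(tss, start, end, summit = NULL) {
  if (!is.null(summit) && !all(is.na(summit)))
    return(as.integer(abs(tss - summit)))
  as.integer(ifelse(tss >= start & tss < end, 0L,
                    ifelse(tss >= end, tss - end + 1L, start - tss)))
}

#' Assign ChIP-seq peaks to candidate target genes
#'
#' Applies the two-tier rule per peak: (i) if at least one TSS lies within
#' `tss_window` of the peak, a single `tss_proximal` link is made to the
#' nearest such TSS and the peak is associated with that gene alone;
#' (ii) otherwise the nearest TSS within `flank` on each side of the peak
#' midpoint contributes one `flanking` link (at most
#' `max_genes_per_peak` links); (iii) peaks with no qualifying TSS
#' contribute no links. Equidistant ties are broken deterministically by
#' (chromosome order, tss, gene_id).
#'
#' @param peakset A [peak_set()].
#' @param annotation A [gene_annotation()].
#' @param rule An [assignment_rule()].
#' @return A `target_assignment`: list with `factor`, `rule`, and `links`
#'   (data.frame: peak_index, gene_id, distance, rule_tag).
#' @export
assign_peaks_to_genes <- function(peakset, annotation,
                                  rule = assignment_rule()) {
  stopifnot(inherits(peakset, "peak_set"),
            inherits(annotation, "gene_annotation"),
            inherits(rule, "assignment_rule"))
  if (rule$anchor == "summit" && nrow(peakset) && anyNA(peakset$summit))
    stopf("summit anchor requires summit annotation on every peak")
  chrom_order <- attr(annotation, "chrom_order")
  links <- vector("list", nrow(peakset))
  ann_by_chrom <- split(seq_len(nrow(annotation)), annotation$chrom)
  for (i in seq_len(nrow(peakset))) {
    p <- peakset[i, ]
    gi <- ann_by_chrom[[p$chrom]]
    if (is.null(gi)) next
    g <- annotation[gi, ]
    d <- peak_gene_distance(g$tss, p$start, p$end,
                            summit = if (rule$anchor == "summit") p$summit)
    prox <- which(d <= rule$tss_window)
    if (length(prox)) {
      sel <- prox[order(d[prox], g$tss[prox], g$gene_id[prox],
                        method = "radix")[1]]
      links[[i]] <- data.frame(peak_index = i, gene_id = g$gene_id[sel],
                               distance = d[sel], rule_tag = "tss_proximal",
                               stringsAsFactors = FALSE)
    } else {
      mid <- (p$start + p$end) %/% 2L
      picks <- list(left = which(g$tss < mid & d <= rule$flank),
                    right = which(g$tss >= mid & d <= rule$flank))
      rows <- lapply(picks, function(cand) {
        if (!length(cand)) return(NULL)
        sel <- cand[order(d[cand], g$tss[cand], g$gene_id[cand],
                          method = "radix")[1]]
        data.frame(peak_index = i, gene_id = g$gene_id[sel],
                   distance = d[sel], rule_tag = "flanking",
                   stringsAsFactors = FALSE)
      })
      rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      if (!is.null(rows) && nrow(rows) > rule$max_genes_per_peak)
        rows <- rows[order(rows$distance, rows$gene_id,
                           method = "radix")[seq_len(rule$max_genes_per_peak)], ]
      links[[i]] <- rows
    }
  }
  links <- do.call(rbind, links[!vapply(links, is.null, TRUE)])
  if (is.null(links))
    links <- data.frame(peak_index = integer(), gene_id = character(),
                        distance = integer(), rule_tag = character(),
                        stringsAsFactors = FALSE)
  rownames(links) <- NULL
  structure(list(factor = peak_factor(peakset), rule = rule, links = links),
            class = "target_assignment")
}

#' @export
print.target_assignment <- function(x, ...) {
  cat(sprintf("<target_assignment> factor=%s, %d links (%d proximal, %d flanking), %d genes\n",
              x$factor, nrow(x$links),
              sum(x$links$rule_tag == "tss_proximal"),
              sum(x$links$rule_tag == "flanking"),
              length(target_genes(x))))
  invisible(x)
}

#' Candidate target gene set of an assignment
#'
#' @param assignment A `target_assignment`.
#' @param annotation Optional [gene_annotation()]; if supplied, multi-TSS
#'   expanded records are collapsed by reporting symbols instead of ids.
#' @return Sorted character vector of distinct gene ids (or symbols).
#' @export
target_genes <- function(assignment, annotation = NULL) {
  stopifnot(inherits(assignment, "target_assignment"))
  ids <- unique(assignment$links$gene_id)
  if (!is.null(annotation)) {
    m <- match(ids, annotation$gene_id)
    ids <- unique(annotation$symbol[m[!is.na(m)]])
  }
  sort(ids, method = "radix")
}

#' Restrict a peak set to its top-scoring n peaks
#'
#' Used to normalise for ChIP-efficiency differences across factors before
#' co-binding comparisons: only each factor's n highest-scoring peaks are
#' retained. Ties on score are broken by (chrom, start, end); the result is
#' re-sorted genomically.
#'
#' @param peakset A [peak_set()].
#' @param n Number of peaks to keep (`n >= nrow` returns all peaks).
#' @return A [peak_set()] with at most `n` peaks.
#' @export
top_n_peaks <- function(peakset, n) {
  stopifnot(inherits(peakset, "peak_set"))
  if (!is_count(n)) stopf("n must be a non-negative integer")
  if (n >= nrow(peakset)) return(peakset)
  ord <- order(-peakset$score, peakset$chrom, peakset$start, peakset$end,
               method = "radix")
  keep <- ord[seq_len(n)]
  df <- as.data.frame(peakset)[keep, , drop = FALSE]
  peak_set(df$chrom, df$start, df$end, df$score, df$summit,
           factor = peak_factor(peakset))
}

#' Export a target assignment as TSV
#'
#' Columns: `factor peak_chrom peak_start peak_end gene_id distance rule_tag`.
#'
#' @param assignment A `target_assignment`.
#' @param peakset The [peak_set()] the assignment indexes into.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assignment <- function(assignment, peakset, path) {
  l <- assignment$links
  df <- data.frame(factor = assignment$factor,
                   peak_chrom = peakset$chrom[l$peak_index],
                   peak_start = peakset$start[l$peak_index],
                   peak_end = peakset$end[l$peak_index],
                   gene_id = l$gene_id, distance = l$distance,
                   rule_tag = l$rule_tag, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
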