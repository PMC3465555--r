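#' Construct a validated peak set
#'
#' A peak set holds one transcription factor's scored ChIP-seq peaks as
#' 0-based, half-open genomic intervals, sorted by (chrom, start, end).
#' The score column is the rank statistic used by [top_n_peaks()]; peaks
#' read from 3/4-column BED default to score 0.
#'
#' @param chrom Character vector of chromosome names (matched as exact
#'   strings; no "chr" prefix normalization).
#' @param start,end Integer vectors; 0-based inclusive start, exclusive end.
#' @param score Numeric peak scores (recycled); must be finite.
#' @param summit Optional integer absolute summit positions, each within
#'   `[start, end)`; `NA` when unknown.
#' @param factor Single non-empty string naming the profiled factor.
#' @return A `peak_set`: a data.frame with columns chrom, start, end, score,
#'   summit and attribute `factor`.
#' @examples
#' peak_set("chr1", c(100, 500), c(200, 900), score = c(3, 7), factor = "Tcf3")
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     score = 0, summit = NA_integer_, factor = "peaks") {
  if (!is.character(factor) || length(factor) != 1L || !nzchar(factor))
    stopf("`factor` must be a single non-empty string")
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep_len(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stopf("chrom, start and end must have equal length")
  start <- as.integer(start)
  end <- as.integer(end)
  score <- rep_len(as.numeric(score), n)
  summit <- rep_len(as.integer(summit), n)
  if (n > 0) {
    if (anyNA(start) || anyNA(end) || any(start < 0))
      stopf("peak coordinates must be non-negative integers")
    if (any(start >= end))
      stopf("peak start must be < end (0-based half-open)")
    if (any(!is.finite(score)))
      stopf("peak scores must be finite")
    bad <- !is.na(summit) & (summit < start | summit >= end)
    if (any(bad))
      stopf("summit must lie within [start, end)")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   score = score, summit = summit, stringsAsFactors = FALSE)
  df <- df[genomic_order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, factor = factor, class = c("peak_set", "data.frame"))
}

strip_df <- function(x) {
  df <- x
  class(df) <- "data.frame"
  attr(df, "factor") <- NULL
  attr(df, "label") <- NULL
  attr(df, "chrom_order") <- NULL
  attr(df, "study_id") <- NULL
  df
}

#' @export
as.data.frame.peak_set <- function(x, ...) strip_df(x)

#' @export
as.data.frame.region_set <- function(x, ...) strip_df(x)

#' @export
as.data.frame.gene_annotation <- function(x, ...) strip_df(x)

#' @export
as.data.frame.expression_study <- function(x, ...) strip_df(x)

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> factor=%s, %d peaks\n", peak_factor(x), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Factor name of a peak set
#' @param x A `peak_set`.
#' @return The factor name string.
#' @export
peak_factor <- function(x) attr(x, "factor", exact = TRUE)

#' Construct a validated region set
#'
#' A region set is a label plus pairwise-disjoint, sorted, 0-based half-open
#' intervals — typically the merged union of one or more peak sets
#' (see [merge_intervals()]).
#'
#' @param chrom,start,end Interval columns as in [peak_set()].
#' @param label Single string naming the set.
#' @return A `region_set` data.frame with attribute `label`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       label = "regions") {
  if (!is.character(label) || length(label) != 1L)
    stopf("`label` must be a single string")
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (n > 0 && (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end)))
    stopf("regions must be 0-based half-open with start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[genomic_order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  # disjointness within chromosome
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)]))
      stopf("regions within a chromosome must be pairwise disjoint")
  }
  structure(df, label = label, class = c("region_set", "data.frame"))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> label=%s, %d regions, %d bp covered\n",
              attr(x, "label"), nrow(x), sum(x$end - x$start)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Construct a validated gene annotation
#'
#' An annotation is an ordered table of genes with a single strand-aware TSS
#' coordinate per record. Genes with several alternative TSSs should be
#' expanded upstream to one record per TSS (suffixed ids);
#' [target_genes()] deduplicates at the gene level.
#'
#' @param gene_id Unique gene identifiers.
#' @param symbol Display symbols (defaults to `gene_id`).
#' @param chrom Chromosome names.
#' @param strand "+" or "-".
#' @param tss 0-based TSS coordinates (non-negative integers).
#' @return A `gene_annotation` data.frame sorted by (chrom, tss), with the
#'   deterministic chromosome ordering stored in attribute `chrom_order`.
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, chrom, strand, tss) {
  n <- length(gene_id)
  if (length(symbol) != n || length(chrom) != n || length(strand) != n ||
      length(tss) != n)
    stopf("annotation columns must have equal length")
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stopf("duplicate gene_id in annotation: %s",
          paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  strand <- as.character(strand)
  if (n > 0 && !all(strand %in% c("+", "-")))
    stopf("unknown strand value(s): %s",
          paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  tss <- as.integer(tss)
  if (n > 0 && (anyNA(tss) || any(tss < 0)))
    stopf("tss must be a non-negative integer coordinate")
  df <- data.frame(gene_id = gene_id, symbol = as.character(symbol),
                   chrom = as.character(chrom), strand = strand, tss = tss,
                   stringsAsFactors = FALSE)
  chrom_order <- sort(unique(df$chrom), method = "radix")
  df <- df[order(match(df$chrom, chrom_order), df$tss, df$gene_id,
                 method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, chrom_order = chrom_order,
            class = c("gene_annotation", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes on %d chromosome(s)\n",
              nrow(x), length(attr(x, "chrom_order"))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
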