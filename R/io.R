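#' Read a BED file of ChIP-seq peaks
#'
#' Accepts BED3 and wider dialects (tab-separated, 0-based half-open).
#' Column 5 is parsed as the peak score when present; otherwise scores
#' default to 0. Malformed lines (fewer than 3 columns, non-integer
#' coordinates, start >= end) raise an error naming the line number.
#'
#' @param path Path to an existing BED file.
#' @param factor Factor name to attach to the resulting set.
#' @param normalize_chrom If `TRUE`, strip a leading "chr" prefix from
#'   chromosome names. Off by default: chromosome names are matched as
#'   exact strings, since silent renaming corrupts intersections.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, factor = "peaks", normalize_chrom = FALSE) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]
  if (!length(lines)) return(peak_set(factor = factor))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("BED parse error at line %d: fewer than 3 columns",
          which(nf < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("BED parse error at line %d: non-integer coordinates", bad[1])
  bad <- which(start >= end)
  if (length(bad))
    stopf("BED parse error at line %d: start >= end", bad[1])
  score <- rep(0, length(lines))
  has5 <- nf >= 5
  if (any(has5)) {
    s <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5L)))
    s[is.na(s)] <- 0
    score[has5] <- s
  }
  if (normalize_chrom) chrom <- sub("^chr", "", chrom)
  peak_set(chrom = chrom, start = start, end = end, score = score,
           factor = factor)
}

#' Write a peak set as 5-column BED
#'
#' Emits tab-separated chrom, start, end, name, score in genomic order.
#' `read_bed(write_bed(x))` is lossless for coordinates and scores.
#'
#' @param peakset A [peak_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peakset, path) {
  stopifnot(inherits(peakset, "peak_set"))
  nm <- if (nrow(peakset)) {
    sprintf("%s_%d", peak_factor(peakset), seq_len(nrow(peakset)))
  } else character()
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", peakset$chrom, peakset$start,
                   peakset$end, nm, format(peakset$score, trim = TRUE,
                                           scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation (TSV or BED6)
#'
#' Two dialects are recognised. A header line starting with `gene_id`
#' selects the TSV dialect with columns `gene_id symbol chrom strand tss`
#' (tss 0-based). Otherwise the file is read as BED6
#' (`chrom start end name score strand`) and the TSS is derived from
#' strand: `start` for "+", `end - 1` for "-" (0-based half-open).
#'
#' @param path Path to the annotation file.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (grepl("^gene_id\\b", first)) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("gene_id", "symbol", "chrom", "strand", "tss")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("annotation TSV missing column(s): %s", paste(miss, collapse = ", "))
    gene_annotation(df$gene_id, df$symbol, df$chrom, df$strand,
                    as.integer(df$tss))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6)
      stopf("BED6 annotation requires 6 columns (chrom start end name score strand)")
    strand <- as.character(df[[6]])
    start <- as.integer(df[[2]])
    end <- as.integer(df[[3]])
    if (any(start >= end)) stopf("BED6 annotation has start >= end")
    tss <- ifelse(strand == "+", start, end - 1L)
    gene_annotation(as.character(df[[4]]), as.character(df[[4]]),
                    as.character(df[[1]]), strand, tss)
  }
}

#' Write a gene annotation as TSV
#'
#' Emits the documented dialect `gene_id symbol chrom strand tss` with a
#' header; `read_annotation()` round-trips it losslessly.
#'
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression study table
#'
#' Tab-separated `symbol fold_change` with a header; fold changes are on
#' the linear scale (perturbed over control, so > 1 means upregulated).
#'
#' @param path Path to the TSV.
#' @param study_id Identifier attached to the study.
#' @return An [expression_study()].
#' @export
read_expression_study <- function(path, study_id = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("symbol", "fold_change") %in% names(df)))
    stopf("expression table must have columns `symbol` and `fold_change`")
  expression_study(df$symbol, as.numeric(df$fold_change), study_id = study_id)
}

#' Read an expression-level (RPKM) table
#'
#' Tab-separated `gene_id rpkm` with a header; values must be >= 0.
#'
#' @param path Path to the TSV.
#' @return A named numeric vector of RPKM keyed by gene_id.
#' @export
read_expression_levels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% names(df)))
    stopf("RPKM table must have columns `gene_id` and `rpkm`")
  v <- as.numeric(df$rpkm)
  if (any(!is.finite(v) | v < 0)) stopf("RPKM values must be finite and >= 0")
  stats::setNames(v, as.character(df$gene_id))
}
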