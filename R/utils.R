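# Internal helpers shared across modules.

# Convert a peak_set/region_set (0-based half-open) to GRanges (1-based closed).
set_to_granges <- function(x) {
  df <- as.data.frame(x)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Convert GRanges back to a 0-based half-open data.frame (chrom, start, end).
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

genomic_order <- function(chrom, start, end) {
  order(chrom, start, end, method = "radix")
}

region_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start, end)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

# Derive a per-stage seed from a base seed and a stream name, so each
# generator stage has an independent reproducible stream and adding a stage
# never perturbs earlier stages' draws. Result stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- 0
  for (c in utf8ToInt(stream)) h <- (h * 131 + c) %% 1000003
  as.integer((abs(seed) %% 2147000000 + h * 1009) %% 2147483647)
}

# Evaluate `expr` under the RNG stream (seed, stream), restoring global
# RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
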