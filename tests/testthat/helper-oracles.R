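# Independent brute-force oracles and small random-instance generators.
# These deliberately use naive per-base / all-pairs / full-enumeration
# logic, separate from the package's implementations.

rand_peaks <- function(n, chroms = "chr1", L = 10000, max_w = 500,
                       factor = "X") {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  peak_set(chrom, start, start + w, score = stats::runif(n), factor = factor)
}

# per-base coverage vector (TRUE at covered 0-based positions) per chromosome
bf_coverage <- function(sets, chroms, L) {
  cov <- lapply(stats::setNames(nm = chroms), function(c) logical(L))
  for (s in sets) {
    for (i in seq_len(nrow(s))) {
      c <- s$chrom[i]
      if (c %in% chroms)
        cov[[c]][(s$start[i] + 1):s$end[i]] <- TRUE
    }
  }
  cov
}

# all-pairs overlap oracle (half-open semantics)
bf_overlaps <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        max(a$start[i], b$start[j]) < min(a$end[i], b$end[j]))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) data.frame(a = integer(), b = integer())
  else data.frame(a = out[, 1], b = out[, 2])
}

# per-base distance oracle: min over covered bases of |tss - base|
bf_distance <- function(tss, start, end) {
  min(abs(tss - (start:(end - 1))))
}

# literal scalar implementation of the two-tier assignment rule
bf_assign <- function(peakset, annotation, tss_window = 100,
                      flank = 50000, max_genes = 2) {
  links <- NULL
  for (i in seq_len(nrow(peakset))) {
    g <- annotation[annotation$chrom == peakset$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- vapply(g$tss, bf_distance, 0, start = peakset$start[i],
                end = peakset$end[i])
    prox <- which(d <= tss_window)
    if (length(prox)) {
      o <- prox[order(d[prox], g$tss[prox], g$gene_id[prox])[1]]
      links <- rbind(links, data.frame(peak_index = i,
                                       gene_id = g$gene_id[o],
                                       distance = d[o],
                                       rule_tag = "tss_proximal"))
    } else {
      mid <- (peakset$start[i] + peakset$end[i]) %/% 2
      rows <- NULL
      for (side in c("left", "right")) {
        cand <- if (side == "left") which(g$tss < mid & d <= flank)
                else which(g$tss >= mid & d <= flank)
        if (length(cand)) {
          o <- cand[order(d[cand], g$tss[cand], g$gene_id[cand])[1]]
          rows <- rbind(rows, data.frame(peak_index = i,
                                         gene_id = g$gene_id[o],
                                         distance = d[o],
                                         rule_tag = "flanking"))
        }
      }
      if (!is.null(rows) && nrow(rows) > max_genes)
        rows <- rows[order(rows$distance, rows$gene_id)[1:max_genes], ]
      links <- rbind(links, rows)
    }
  }
  if (is.null(links))
    links <- data.frame(peak_index = integer(), gene_id = character(),
                        distance = integer(), rule_tag = character())
  links <- links[order(links$peak_index, links$gene_id), ]
  rownames(links) <- NULL
  links
}

# exhaustive hypergeometric upper tail: enumerate all C(N, n) draws
bf_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the "bound" ones
  mean(hits >= k)
}

# naive O(k^3) agglomerative clustering on a distance matrix; returns the
# merge heights and the partition (set of sets of labels) after each merge
bf_agglomerate <- function(d, linkage = "average") {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cross <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- switch(linkage, average = mean(cross), complete = max(cross),
                  single = min(cross))
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions <- c(partitions,
                    list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# partition of labels from an hclust at each merge step
hclust_partitions <- function(hc) {
  n <- length(hc$labels)
  lapply(seq_len(n - 1), function(step) {
    ct <- stats::cutree(hc, k = n - step)
    unname(lapply(split(names(ct), ct), sort))
  })
}

same_partition <- function(p, q) {
  key <- function(part) sort(vapply(part, paste, "", collapse = "|"))
  identical(key(p), key(q))
}

# base-wise region Venn oracle: reconstruct merged universe regions from
# per-base coverage, then label each region by the inputs covering >= 1
# of its bases
bf_region_venn <- function(sets, chroms, L) {
  nms <- names(sets)
  covs <- lapply(sets, function(s) bf_coverage(list(s), chroms, L))
  union_cov <- bf_coverage(sets, chroms, L)
  cells <- integer(0)
  n_regions <- 0
  for (c in chroms) {
    r <- rle(union_cov[[c]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      idx <- starts[seg]:ends[seg]
      members <- nms[vapply(covs, function(cv) any(cv[[c]][idx]), TRUE)]
      sig <- paste(members, collapse = "&")
      cells[sig] <- (if (is.na(cells[sig])) 0L else cells[sig]) + 1L
      n_regions <- n_regions + 1
    }
  }
  list(cells = cells, n_regions = n_regions)
}
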