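test_that("binary_peak_matrix handles single and identical factors", {
  one <- peak_set("chr1", 100, 200, factor = "A")
  m <- binary_peak_matrix(list(one))
  expect_equal(unname(m$values), matrix(1L, 1, 1))

  a <- rand_peaks(20, factor = "A")
  b <- peak_set(a$chrom, a$start, a$end, a$score, factor = "B")
  m2 <- binary_peak_matrix(list(A = a, B = b))
  expect_true(all(m2$values == 1L))
  expect_equal(m2$values[, "A"], m2$values[, "B"])
})

test_that("binary_peak_matrix equals the per-base occupancy oracle", {
  set.seed(61)
  for (rep in 1:5) {
    sets <- list(A = rand_peaks(30, L = 50000, factor = "A"),
                 B = rand_peaks(25, L = 50000, factor = "B"),
                 C = rand_peaks(20, L = 50000, factor = "C"))
    m <- binary_peak_matrix(sets)
    covs <- lapply(sets, function(s) bf_coverage(list(s), "chr1", 50000))
    for (r in seq_len(nrow(m$regions))) {
      idx <- (m$regions$start[r] + 1):m$regions$end[r]
      for (f in names(sets)) {
        expect_equal(m$values[r, f],
                     as.integer(any(covs[[f]]$chr1[idx])))
      }
    }
    expect_true(all(rowSums(m$values) >= 1))
    # column sums cross-checked against overlaps()
    for (f in names(sets))
      expect_equal(sum(m$values[, f]),
                   length(unique(overlaps(m$regions, sets[[f]])$a)))
  }
})

test_that("factor clustering distances hit the correlation extremes", {
  regions <- rand_peaks(40, L = 100000, factor = "A")
  b <- peak_set(regions$chrom, regions$start, regions$end, factor = "B")
  # identical columns -> distance 0, merged at height 0
  m <- binary_peak_matrix(list(A = regions, B = b,
                               C = rand_peaks(30, L = 100000, factor = "C")))
  cl <- cluster_factors(m)
  expect_equal(cl$distance["A", "B"], 0)
  expect_equal(min(cl$height), 0)
  # exactly complementary columns -> distance 2
  v <- matrix(c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  fake <- structure(list(regions = NULL, factors = c("A", "B"), values = v),
                    class = "occupancy_matrix")
  expect_equal(cluster_factors(fake)$distance["A", "B"], 2)
})

test_that("zero-variance occupancy columns are an error naming the factor", {
  v <- matrix(c(1L, 1L, 1L, 0L, 1L, 0L), ncol = 2,
              dimnames = list(NULL, c("AllOnes", "Mixed")))
  fake <- structure(list(regions = NULL, factors = colnames(v), values = v),
                    class = "occupancy_matrix")
  expect_error(cluster_factors(fake), "AllOnes")
})

test_that("cluster_factors matches a naive agglomeration oracle", {
  set.seed(71)
  for (linkage in c("average", "complete", "single")) {
    for (rep in 1:5) {
      v <- matrix(rbinom(200, 1, 0.5), nrow = 40,
                  dimnames = list(NULL, c("A", "B", "C", "D", "E")))
      if (any(apply(v, 2, sd) == 0)) next
      fake <- structure(list(regions = NULL, factors = colnames(v),
                             values = v),
                        class = "occupancy_matrix")
      cl <- cluster_factors(fake, linkage = linkage)
      oracle <- bf_agglomerate(cl$distance, linkage)
      expect_equal(cl$height, oracle$heights, tolerance = 1e-12)
      got_parts <- hclust_partitions(cl$hclust)
      for (s in seq_along(oracle$partitions))
        expect_true(same_partition(got_parts[[s]], oracle$partitions[[s]]))
      # row permutation invariance
      cl2 <- cluster_factors(structure(list(regions = NULL,
                                            factors = colnames(v),
                                            values = v[sample(nrow(v)), ]),
                                       class = "occupancy_matrix"),
                             linkage = linkage)
      expect_equal(cl2$height, cl$height)
      expect_equal(cl2$distance, cl$distance)
    }
  }
})

test_that("cluster exports produce a merge table and a Newick string", {
  set.seed(72)
  v <- matrix(rbinom(120, 1, 0.5), nrow = 30,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  fake <- structure(list(regions = NULL, factors = colnames(v), values = v),
                    class = "occupancy_matrix")
  cl <- cluster_factors(fake)
  mp <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".nwk")
  nwk <- export_cluster(cl, merge_path = mp, newick_path = np)
  expect_equal(nrow(read.delim(mp)), 3)
  expect_match(readLines(np), "^\\(.*\\);$")
})

test_that("region_venn trivial geometries behave as stated", {
  a <- peak_set("chr1", c(0, 100), c(50, 150), factor = "A")
  b <- peak_set("chr2", c(0, 100), c(50, 150), factor = "B")
  v <- region_venn(A = a, B = b)
  expect_equal(unname(v$cell_counts[c("A", "B", "A&B")]), c(2L, 2L, 0L))
  expect_equal(sum(v$cell_counts), v$universe_size)

  v2 <- region_venn(A = a, B2 = peak_set(a$chrom, a$start, a$end, factor = "B2"))
  expect_equal(unname(v2$cell_counts["A&B2"]), v2$universe_size)
  expect_equal(unname(v2$cell_counts[c("A", "B2")]), c(0L, 0L))

  expect_error(region_venn(A = a), "2 or 3")
})

test_that("region_venn equals the base-wise labeling oracle and conserves counts", {
  set.seed(81)
  for (rep in 1:10) {
    sets <- list(A = rand_peaks(25, L = 30000, factor = "A"),
                 B = rand_peaks(20, L = 30000, factor = "B"),
                 C = rand_peaks(15, L = 30000, factor = "C"))
    v <- region_venn(sets)
    oracle <- bf_region_venn(sets, "chr1", 30000)
    expect_equal(v$universe_size, oracle$n_regions)
    expect_equal(sum(v$cell_counts), v$universe_size)
    for (sig in names(oracle$cells))
      expect_equal(unname(v$cell_counts[sig]), unname(oracle$cells[sig]))
    expect_equal(sum(v$cell_counts > 0), length(oracle$cells))
  }
})

test_that("gene_venn matches exhaustive membership enumeration", {
  v <- gene_venn(A = c("a", "b", "c"), B = c("b", "c", "d"))
  expect_equal(unname(v$cell_counts[c("A", "B", "A&B")]), c(1L, 1L, 2L))
  v2 <- gene_venn(A = character(0), B = c("x", "y"))
  expect_equal(unname(v2$cell_counts["B"]), 2L)
  expect_equal(sum(v2$cell_counts), 2L)
  set.seed(91)
  for (rep in 1:10) {
    pool <- sprintf("g%03d", 1:60)
    sets <- list(A = sample(pool, 30), B = sample(pool, 25),
                 C = sample(pool, 20))
    v3 <- gene_venn(sets)
    uni <- unique(unlist(sets))
    expect_equal(v3$universe_size, length(uni))
    expect_equal(sum(v3$cell_counts), length(uni))
    # per-element enumeration
    cnt <- integer(0)
    for (g in uni) {
      sig <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                   collapse = "&")
      cnt[sig] <- (if (is.na(cnt[sig])) 0L else cnt[sig]) + 1L
    }
    for (sig in names(cnt))
      expect_equal(unname(v3$cell_counts[sig]), unname(cnt[sig]))
  }
})

test_that("shared_fraction counts correctly and rejects empty primaries", {
  expect_equal(shared_fraction(c("a", "b"), c("a", "b", "c"))$fraction, 1)
  expect_equal(shared_fraction(c("a", "b"), c("x"))$fraction, 0)
  expect_error(shared_fraction(character(0), "a"), "empty")
  set.seed(92)
  for (rep in 1:10) {
    p <- sample(letters, 10); o <- sample(letters, 12)
    sf <- shared_fraction(p, o)
    expect_equal(sf$shared, sum(unique(p) %in% o))
    expect_equal(sf$fraction, sf$shared / sf$total)
  }
})
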