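small_config <- function(seed = 1, planted = 5, chrom_length = 5e5, ...) {
  simulation_config(seed = seed, n_chromosomes = 1,
                    chrom_length = chrom_length, n_genes = 100,
                    factors = lapply(c("A", "B", "C"), function(nm)
                      list(name = nm, n_peaks = 60L, width_mean = 200,
                           width_sd = 50, score_rate = 1)),
                    planted_candidates = planted, ...)
}

test_that("every generator stage is deterministic given the seed", {
  cfg <- small_config(seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1$annotation), as.data.frame(d2$annotation))
  expect_identical(d1$peaksets, d2$peaksets)
  expect_identical(d1$truth$planted_candidate_ids,
                   d2$truth$planted_candidate_ids)
  expect_identical(lapply(d1$studies, as.data.frame),
                   lapply(d2$studies, as.data.frame))
  expect_identical(d1$levels, d2$levels)
  d3 <- simulate_dataset(small_config(seed = 100))
  expect_false(identical(d1$peaksets, d3$peaksets))
})

test_that("generated annotations have uniform TSS placement", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 2, chrom_length = 1e6,
                           n_genes = 1000)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 1000)
  expect_true(all(ann$tss >= 0 & ann$tss < 1e6))
  expect_true(all(table(ann$chrom) == 500))
  expect_false(anyDuplicated(ann$gene_id) > 0)
  # uniform order statistics: KS distance within resampled null range
  for (c in c("chr1", "chr2")) {
    x <- ann$tss[ann$chrom == c] / 1e6
    ks <- suppressWarnings(stats::ks.test(x, "punif"))
    expect_gt(ks$p.value, 1e-4)
  }
  expect_error(generate_annotation(
    simulation_config(n_chromosomes = 1, chrom_length = 50, n_genes = 100,
                      planted_candidates = 0)),
    "exceeds")
  single <- generate_annotation(
    simulation_config(n_chromosomes = 1, chrom_length = 1000, n_genes = 1,
                      planted_candidates = 0))
  expect_equal(nrow(single), 1)
})

test_that("generated peak sets satisfy the core interval invariants", {
  d <- simulate_dataset(small_config(seed = 3))
  for (ps in d$peaksets) {
    expect_s3_class(ps, "peak_set")
    expect_true(all(ps$start < ps$end))
    expect_true(all(ps$start >= 0 & ps$end <= 5e5))
    expect_true(all(is.finite(ps$score)))
    expect_equal(nrow(ps), 60)
  }
  expect_true(all(d$truth$planted_candidate_ids %in% d$annotation$gene_id))
  for (f in names(d$peaksets))
    expect_true(all(d$truth$planted_candidate_ids %in%
                    d$truth$target_sets[[f]]))
})

test_that("zero co-binding yields near-disjoint factors; full sharing yields identical regions", {
  # rho = 0: pairwise peak overlap below 5% of peaks across seeds
  rates <- vapply(1:10, function(s) {
    cfg0 <- small_config(seed = s, planted = 0, cobinding = 0,
                         tss_targeting_fraction = 0, chrom_length = 2e6)
    d <- generate_peaksets(cfg0, generate_annotation(cfg0))
    r <- d$truth$cobinding_rates
    max(r[upper.tri(r)])
  }, 0)
  expect_lt(mean(rates), 0.05)
  # rho = 1, no TSS targeting, no specific peaks: identical merged regions
  cfg1 <- small_config(seed = 4, planted = 0, cobinding = 1,
                       tss_targeting_fraction = 0)
  d1 <- generate_peaksets(cfg1, generate_annotation(cfg1))
  merged <- lapply(d1$peaksets, merge_intervals)
  expect_equal(as.data.frame(merged[[1]]), as.data.frame(merged[[2]]))
  expect_equal(as.data.frame(merged[[1]]), as.data.frame(merged[[3]]))
})

test_that("full TSS targeting makes every peak TSS-proximal", {
  cfg <- small_config(seed = 6, tss_targeting_fraction = 1,
                      chrom_length = 2e6)
  ann <- generate_annotation(cfg)
  d <- generate_peaksets(cfg, ann)
  for (f in names(d$peaksets)) {
    asn <- assign_peaks_to_genes(d$peaksets[[f]], ann)
    prox <- asn$links$peak_index[asn$links$rule_tag == "tss_proximal"]
    expect_setequal(prox, seq_len(nrow(d$peaksets[[f]])))
    # realized targets match the recorded truth
    expect_true(all(d$truth$target_sets[[f]] %in% target_genes(asn)))
  }
})

test_that("planted responders clear the fold-change filter; a degenerate fc_up always does", {
  cfg <- small_config(seed = 7,
                      fc_up = list(meanlog = log(2), sdlog = 0))
  d <- simulate_dataset(cfg)
  for (st in d$studies) {
    up <- filter_upregulated(st, 1.4)
    planted_sym <- d$annotation$symbol[d$annotation$gene_id %in%
                                       d$truth$planted_candidate_ids]
    expect_true(all(planted_sym %in% up))
    expect_true(all(abs(st$fold_change[st$symbol %in% planted_sym] - 2) < 1e-12))
  }
  expect_gt(min(d$levels), 0)
})

test_that("with no planted signal the double-filter rate matches the null tail", {
  # P(pass both studies) = P(lognormal tail > 1.4)^2; check the realized
  # count across seeds against a Monte-Carlo binomial envelope
  p_tail <- (1 - plnorm(1.4, 0, 0.3))^2
  n_pass <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s, planted = 0,
                        fc_null = list(meanlog = 0, sdlog = 0.3))
    d <- simulate_dataset(cfg)
    length(intersect_studies(filter_upregulated(d$studies[[1]], 1.4),
                             filter_upregulated(d$studies[[2]], 1.4)))
  }, 0)
  expected <- 100 * p_tail
  se <- sqrt(20 * 100 * p_tail * (1 - p_tail))
  expect_lt(abs(sum(n_pass) - 20 * expected), 5 * se)
})

test_that("infeasible co-binding specs are config errors", {
  expect_error(simulation_config(cobinding = 1.2), "\\[0,1\\]|matrix")
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.1, 0.9, 0.1, 1), 3, 3)
  cfg <- small_config(seed = 1, cobinding = bad)
  ann <- generate_annotation(cfg)
  expect_error(generate_peaksets(cfg, ann), "infeasible")
  asym <- matrix(c(1, 0.2, 0.3, 0.9, 1, 0.2, 0.9, 0.2, 1), 3, 3)
  expect_error(small_config(seed = 1, cobinding = asym), "symmetric")
})

test_that("simulations round-trip through the on-disk bundle", {
  d <- simulate_dataset(small_config(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_simulation(d, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_bed(paths$peaks_A, factor = "A")
  expect_equal(as.data.frame(back)[c("chrom", "start", "end")],
               as.data.frame(d$peaksets$A)[c("chrom", "start", "end")])
  ann <- read_annotation(paths$annotation)
  expect_equal(as.data.frame(ann), as.data.frame(d$annotation))
  st <- read_expression_study(paths$study_ko, "ko")
  expect_equal(st$symbol, d$studies[[1]]$symbol)
  expect_equal(st$fold_change, d$studies[[1]]$fold_change, tolerance = 1e-8)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$planted_candidate_ids,
                  d$truth$planted_candidate_ids)
})
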