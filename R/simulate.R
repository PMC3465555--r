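#' Simulation configuration for synthetic pipeline inputs
#'
#' Defines a synthetic genome annotation, per-factor peak sets with
#' controllable co-binding and TSS targeting, and a pair of
#' differential-expression studies with a planted set of bound,
#' upregulated candidate genes. Every generated object is a pure function
#' of (config, seed): each generator stage draws from its own named RNG
#' stream derived from `seed`.
#'
#' Co-binding is modeled at region level: shared "master" regions are
#' drawn first and factor f occupies each with probability a_f, where the
#' a_f reproduce the requested pairwise co-binding probabilities via the
#' rank-1 relation rho_fg = a_f * a_g (exact for <= 3 factors, log-space
#' least squares otherwise). A scalar rho means a_f = sqrt(rho) for all
#' factors.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes Number of chromosomes (named chr1, chr2, ...).
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Total genes, split evenly across chromosomes.
#' @param factors List of per-factor specs: `list(name=, n_peaks=,
#'   width_mean=, width_sd=, score_rate=)`. Peak widths are truncated
#'   normal (minimum 50 bp); scores are exponential with the given rate so
#'   top-N selection is non-degenerate.
#' @param cobinding Scalar pairwise co-binding probability in [0,1], or a
#'   symmetric matrix of pairwise probabilities (diagonal ignored).
#' @param tss_targeting_fraction Fraction of each factor's peaks centered
#'   on a gene TSS (these define the factor's true target set).
#' @param planted_candidates Number of genes planted as bound-by-all
#'   upregulated responders.
#' @param fc_up Fold-change distribution for planted responders:
#'   `list(meanlog=, sdlog=)` on the log scale (default centered on 2).
#' @param fc_null Background fold-change distribution (median 1).
#' @param rpkm_lognormal RPKM distribution `list(meanlog=, sdlog=)`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 5e6,
                              n_genes = 1000L,
                              factors = default_factors(),
                              cobinding = 0.5,
                              tss_targeting_fraction = 0.3,
                              planted_candidates = 20L,
                              fc_up = list(meanlog = log(2), sdlog = 0.05),
                              fc_null = list(meanlog = 0, sdlog = 0.12),
                              rpkm_lognormal = list(meanlog = 1, sdlog = 1)) {
  if (!is_count(abs(seed))) stopf("seed must be an integer")
  if (!is_count(n_chromosomes) || n_chromosomes < 1)
    stopf("n_chromosomes must be >= 1")
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be >= 1")
  if (!length(factors) || is.null(names2(factors)))
    stopf("factors must be a non-empty list of specs with a `name` each")
  factors <- lapply(factors, function(f) {
    f$n_peaks <- as.integer(f$n_peaks %||% 500L)
    f$width_mean <- f$width_mean %||% 300
    f$width_sd <- f$width_sd %||% 100
    f$score_rate <- f$score_rate %||% 1
    f
  })
  names(factors) <- vapply(factors, `[[`, "", "name")
  k <- length(factors)
  if (is.matrix(cobinding)) {
    if (nrow(cobinding) != k || ncol(cobinding) != k)
      stopf("cobinding matrix must be %d x %d", k, k)
    if (!isSymmetric(unname(cobinding)))
      stopf("cobinding matrix must be symmetric")
    if (any(cobinding < 0 | cobinding > 1))
      stopf("co-binding probabilities must be in [0,1]")
  } else {
    if (length(cobinding) != 1 || cobinding < 0 || cobinding > 1)
      stopf("cobinding must be a scalar in [0,1] or a matrix")
  }
  if (tss_targeting_fraction < 0 || tss_targeting_fraction > 1)
    stopf("tss_targeting_fraction must be in [0,1]")
  if (!is_count(planted_candidates) || planted_candidates > n_genes)
    stopf("planted_candidates must be an integer <= n_genes")
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes), factors = factors,
                 cobinding = cobinding,
                 tss_targeting_fraction = tss_targeting_fraction,
                 planted_candidates = as.integer(planted_candidates),
                 fc_up = fc_up, fc_null = fc_null,
                 rpkm_lognormal = rpkm_lognormal),
            class = "simulation_config")
}

default_factors <- function() {
  lapply(c("Tcf3", "Oct4", "Nanog"), function(nm)
    list(name = nm, n_peaks = 500L, width_mean = 300, width_sd = 100,
         score_rate = 1))
}

names2 <- function(factors) {
  nm <- vapply(factors, function(f) f$name %||% "", "")
  if (any(!nzchar(nm))) NULL else nm
}

# Per-factor master-region occupancy probabilities from the co-binding
# spec: rank-1 fit rho_fg = a_f * a_g in log space.
occupancy_probs <- function(config) {
  k <- length(config$factors)
  rho <- config$cobinding
  if (!is.matrix(rho)) {
    return(stats::setNames(rep(sqrt(rho), k), names(config$factors)))
  }
  off <- rho[upper.tri(rho)]
  if (all(off == 0)) return(stats::setNames(rep(0, k), names(config$factors)))
  if (any(off == 0))
    stopf("mixed zero/non-zero co-binding probabilities are infeasible under the rank-1 model")
  # least squares on log a: for each pair (f,g), log a_f + log a_g = log rho_fg
  pairs <- utils::combn(k, 2)
  A <- matrix(0, ncol(pairs), k)
  for (j in seq_len(ncol(pairs))) A[j, pairs[, j]] <- 1
  loga <- stats::lsfit(A, log(rho[t(pairs)]), intercept = FALSE)$coefficients
  a <- exp(loga)
  if (any(a > 1 + 1e-8))
    stopf("cobinding matrix is infeasible (implied occupancy probability > 1)")
  stats::setNames(pmin(a, 1), names(config$factors))
}

#' Generate a synthetic gene annotation
#'
#' Genes are split evenly across chromosomes; TSSs are placed uniformly at
#' random without replacement and strands are Bernoulli(0.5).
#' Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return A [gene_annotation()] with ids G0001, G0002, ... in genomic
#'   order (symbols equal ids).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  per <- diff(floor(seq(0, config$n_genes,
                        length.out = config$n_chromosomes + 1)))
  if (any(per > config$chrom_length))
    stopf("n_genes exceeds placeable TSS positions on a chromosome")
  with_stream(config$seed, "annotation", {
    tss <- integer(0); chrom <- character(0)
    for (c in seq_len(config$n_chromosomes)) {
      pos <- sort(sample.int(config$chrom_length, per[c]) - 1L)
      tss <- c(tss, pos)
      chrom <- c(chrom, rep(sprintf("chr%d", c), per[c]))
    }
    strand <- c("+", "-")[stats::rbinom(config$n_genes, 1, 0.5) + 1L]
    ids <- sprintf("G%04d", seq_len(config$n_genes))
    gene_annotation(ids, ids, chrom, strand, tss)
  })
}

truncnorm_width <- function(n, mean, sd) {
  pmax(50L, as.integer(round(stats::rnorm(n, mean, sd))))
}

#' Generate co-binding-structured synthetic peak sets
#'
#' Draws shared master regions first; each factor occupies a master region
#' with its rank-1 occupancy probability, contributing co-bound peaks.
#' A `tss_targeting_fraction` of each factor's peaks is centered on gene
#' TSSs (always including every planted candidate gene, so planted genes
#' are bound by all factors); the remaining budget is factor-specific
#' background. Scores are exponential; peaks are clipped to chromosome
#' bounds. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param annotation The matching [generate_annotation()] output.
#' @return List with `peaksets` (named list of [peak_set()]) and `truth`
#'   (`synthetic_truth`: `planted_candidate_ids`, per-factor
#'   `target_sets`, and realized pairwise `cobinding_rates`).
#' @export
generate_peaksets <- function(config, annotation) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(annotation, "gene_annotation"))
  a_prob <- occupancy_probs(config)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  # Genes with isolated promoters (no neighbouring TSS within 2.5 kb) are
  # preferred for TSS targeting: a peak planted on such a TSS is
  # unambiguously assigned to that gene, so true target sets are known.
  gap_prev <- ifelse(c(TRUE, annotation$chrom[-1] != annotation$chrom[-nrow(annotation)]),
                     Inf, c(Inf, diff(annotation$tss)))
  gap_next <- c(gap_prev[-1], Inf)
  isolated <- annotation$gene_id[gap_prev > 2500 & gap_next > 2500]
  pick_genes <- function(n, exclude = character()) {
    pool1 <- setdiff(isolated, exclude)
    pool2 <- setdiff(annotation$gene_id, c(pool1, exclude))
    got <- sample(pool1, min(n, length(pool1)))
    if (length(got) < n) got <- c(got, sample(pool2, n - length(got)))
    sort(got)
  }
  planted <- with_stream(config$seed, "planted", {
    pick_genes(config$planted_candidates)
  })
  budgets <- vapply(config$factors, function(f)
    f$n_peaks - round(config$tss_targeting_fraction * f$n_peaks), 0)
  n_master <- max(0, max(budgets))
  # master regions are shared sites: interval drawn once so that co-bound
  # factors occupy identical coordinates
  master <- with_stream(config$seed, "master", {
    w <- truncnorm_width(n_master,
                         mean(vapply(config$factors, `[[`, 0, "width_mean")),
                         mean(vapply(config$factors, `[[`, 0, "width_sd")))
    center <- sample.int(config$chrom_length, n_master, replace = TRUE) - 1L
    data.frame(chrom = sample(chroms, n_master, replace = TRUE),
               start = center - w %/% 2L, width = w,
               stringsAsFactors = FALSE)
  })
  peaksets <- list()
  target_sets <- list()
  for (f in config$factors) {
    res <- with_stream(config$seed, paste0("factor:", f$name), {
      n_tss <- round(config$tss_targeting_fraction * f$n_peaks)
      extra <- max(0, n_tss - length(planted))
      tss_genes <- if (n_tss > 0) {
        sort(unique(c(planted, pick_genes(extra, exclude = planted))))
      } else if (length(planted)) planted else character(0)
      gi <- match(tss_genes, annotation$gene_id)
      w_tss <- truncnorm_width(length(gi), f$width_mean, f$width_sd)
      off <- floor(stats::runif(length(gi)) * w_tss)  # TSS inside [start,end)
      tss_df <- data.frame(chrom = annotation$chrom[gi],
                           start = annotation$tss[gi] - off,
                           stringsAsFactors = FALSE)
      tss_df$width <- w_tss
      # master (co-bound) peaks
      hit <- which(stats::runif(n_master) < a_prob[[f$name]])
      budget <- f$n_peaks - nrow(tss_df)
      if (length(hit) > budget) hit <- sort(sample(hit, max(0, budget)))
      m_df <- master[hit, , drop = FALSE]
      # factor-specific background
      n_spec <- max(0, f$n_peaks - nrow(tss_df) - nrow(m_df))
      w_s <- truncnorm_width(n_spec, f$width_mean, f$width_sd)
      s_df <- data.frame(chrom = sample(chroms, n_spec, replace = TRUE),
                         start = sample.int(config$chrom_length, n_spec,
                                            replace = TRUE) - 1L,
                         width = w_s, stringsAsFactors = FALSE)
      df <- rbind(tss_df, m_df, s_df)
      df$start <- pmax(0L, pmin(df$start, config$chrom_length - df$width))
      df$end <- df$start + df$width
      score <- stats::rexp(nrow(df), rate = f$score_rate)
      list(ps = peak_set(df$chrom, df$start, df$end, score, factor = f$name),
           targets = tss_genes)
    })
    peaksets[[f$name]] <- res$ps
    target_sets[[f$name]] <- res$targets
  }
  nms <- names(peaksets)
  rates <- matrix(NA_real_, length(nms), length(nms),
                  dimnames = list(nms, nms))
  diag(rates) <- 1
  for (i in seq_along(nms)) for (j in seq_along(nms)) if (i != j) {
    ov <- overlaps(peaksets[[i]], peaksets[[j]])
    rates[i, j] <- length(unique(ov$a)) / nrow(peaksets[[i]])
  }
  truth <- structure(list(planted_candidate_ids = planted,
                          target_sets = target_sets,
                          cobinding_rates = rates),
                     class = "synthetic_truth")
  list(peaksets = peaksets, truth = truth)
}

#' Generate synthetic expression studies and RPKM levels
#'
#' Planted candidate genes draw fold changes from `fc_up` independently in
#' each of the two studies; all other genes draw from `fc_null`. RPKM is
#' lognormal for every gene. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @param truth The `synthetic_truth` from [generate_peaksets()].
#' @param annotation The matching annotation.
#' @return List with `studies` (two [expression_study()] objects, ids
#'   "ko" and "kd") and `levels` (named RPKM vector).
#' @export
generate_expression_studies <- function(config, truth, annotation) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "synthetic_truth"))
  syms <- annotation$symbol
  is_planted <- annotation$gene_id %in% truth$planted_candidate_ids
  draw_study <- function(stream, id) {
    with_stream(config$seed, stream, {
      fc <- stats::rlnorm(length(syms), config$fc_null$meanlog,
                          config$fc_null$sdlog)
      fc[is_planted] <- stats::rlnorm(sum(is_planted),
                                      config$fc_up$meanlog,
                                      config$fc_up$sdlog)
      expression_study(syms, fc, study_id = id)
    })
  }
  studies <- list(draw_study("expression:ko", "ko"),
                  draw_study("expression:kd", "kd"))
  levels <- with_stream(config$seed, "expression:rpkm", {
    stats::setNames(stats::rlnorm(nrow(annotation),
                                  config$rpkm_lognormal$meanlog,
                                  config$rpkm_lognormal$sdlog),
                    annotation$gene_id)
  })
  list(studies = studies, levels = levels)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running all generator stages.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation`, `peaksets`, `truth`, `studies`,
#'   `levels`, and the `config` used.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  annotation <- generate_annotation(config)
  pk <- generate_peaksets(config, annotation)
  ex <- generate_expression_studies(config, pk$truth, annotation)
  list(annotation = annotation, peaksets = pk$peaksets, truth = pk$truth,
       studies = ex$studies, levels = ex$levels, config = config)
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Emits one BED file per factor, the annotation TSV, one expression TSV
#' per study, an RPKM TSV, the ground truth as JSON, and the config used.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_simulation <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(dataset$peaksets)) {
    p <- file.path(dir, paste0(nm, ".bed"))
    write_bed(dataset$peaksets[[nm]], p)
    paths[[paste0("peaks_", nm)]] <- p
  }
  paths$annotation <- file.path(dir, "annotation.tsv")
  write_annotation(dataset$annotation, paths$annotation)
  for (st in dataset$studies) {
    id <- attr(st, "study_id")
    p <- file.path(dir, paste0("expression_", id, ".tsv"))
    utils::write.table(as.data.frame(st), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[paste0("study_", id)]] <- p
  }
  paths$rpkm <- file.path(dir, "rpkm.tsv")
  utils::write.table(data.frame(gene_id = names(dataset$levels),
                                rpkm = dataset$levels),
                     paths$rpkm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    planted_candidate_ids = dataset$truth$planted_candidate_ids,
    target_sets = dataset$truth$target_sets,
    cobinding_rates = dataset$truth$cobinding_rates), paths$truth,
    pretty = TRUE, digits = NA)
  paths$config <- file.path(dir, "config.yaml")
  cfg <- dataset$config
  cfg$factors <- unname(cfg$factors)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(paths)
}
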