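#' Pipeline configuration
#'
#' Collects input paths and rule parameters for the two headline analyses:
#' the direct-target screen ([run_tcf3_screen()]) and the co-binding
#' report ([run_cobinding_report()]). All thresholds default to the
#' compendium's uniform mapping parameters (100 bp TSS window, 50 kb
#' flanks, 2 genes per peak, top 5,000 peaks, 1.4-fold, 0.5 RPKM) and are
#' overridable; the values used are logged into the run manifest.
#'
#' @param peaks Named list: factor name -> BED path(s). Several paths for
#'   one factor are treated as replicates and combined per
#'   `replicate_mode`.
#' @param annotation Path to the gene annotation (TSV or BED6).
#' @param studies Character vector of 2 expression-study TSV paths.
#' @param rpkm Optional RPKM TSV path.
#' @param out_dir Output directory for report bundles.
#' @param tss_window,flank,max_genes Peak-to-gene rule parameters.
#' @param top_n Top-N peak restriction for the co-binding report.
#' @param fc_threshold Fold-change cutoff for the screen (strict).
#' @param rpkm_threshold Expression cutoff for expressed-gene fractions.
#' @param required_factors Factors a candidate must be bound by.
#' @param enrichment_factor Factor tested for enrichment (default: first
#'   required factor).
#' @param direction "up" (derepression screen) or "down" (control).
#' @param screen_top_n Optional top-N restriction for the screen stage
#'   (default `NULL`: the screen uses full peak lists).
#' @param composite Optional composite factor for the co-binding report,
#'   e.g. `list(name = "OST", members = c("Oct4", "Sox2", "Tcf3"))`:
#'   members are individually top-N-restricted, then merged into one
#'   "bound by at least one" input.
#' @param replicate_mode "union" (concatenate and merge, default) or
#'   "intersect" (bases covered by every replicate).
#' @param seed Seed recorded for simulate-mode provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(peaks, annotation, studies = NULL, rpkm = NULL,
                            out_dir = ".", tss_window = 100L,
                            flank = 50000L, max_genes = 2L, top_n = 5000L,
                            fc_threshold = 1.4, rpkm_threshold = 0.5,
                            required_factors = names(peaks),
                            enrichment_factor = required_factors[1],
                            direction = c("up", "down"),
                            screen_top_n = NULL, composite = NULL,
                            replicate_mode = c("union", "intersect"),
                            seed = 1L) {
  direction <- match.arg(direction)
  replicate_mode <- match.arg(replicate_mode)
  if (is.null(names(peaks)) || any(!nzchar(names(peaks))))
    stopf("`peaks` must be a named list of factor -> path(s)")
  structure(list(peaks = peaks, annotation = annotation, studies = studies,
                 rpkm = rpkm, out_dir = out_dir,
                 rule = assignment_rule(tss_window, flank, max_genes),
                 top_n = as.integer(top_n), fc_threshold = fc_threshold,
                 rpkm_threshold = rpkm_threshold,
                 required_factors = required_factors,
                 enrichment_factor = enrichment_factor,
                 direction = direction, screen_top_n = screen_top_n,
                 composite = composite, replicate_mode = replicate_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline config from a YAML or JSON file
#'
#' The file holds the same fields as [pipeline_config()] arguments.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

# Combine replicate peak files for one factor.
combine_replicates <- function(sets, factor, mode) {
  if (length(sets) == 1) return(sets[[1]])
  if (mode == "union") {
    merged <- merge_intervals(sets)
    all_pk <- do.call(rbind, lapply(sets, as.data.frame))
    ps <- peak_set(all_pk$chrom, all_pk$start, all_pk$end, all_pk$score,
                   factor = factor)
    hit <- overlaps(merged, ps)
    score <- vapply(split(ps$score[hit$b], hit$a), max, 0)
    idx <- as.integer(names(score))
    peak_set(merged$chrom[idx], merged$start[idx], merged$end[idx], score,
             factor = factor)
  } else {
    grl <- lapply(sets, set_to_granges)
    gr <- Reduce(GenomicRanges::intersect, grl)
    df <- granges_to_df(gr)
    if (!nrow(df)) return(peak_set(factor = factor))
    ps <- peak_set(df$chrom, df$start, df$end, factor = factor)
    all_pk <- do.call(rbind, lapply(sets, as.data.frame))
    src <- peak_set(all_pk$chrom, all_pk$start, all_pk$end, all_pk$score,
                    factor = factor)
    hit <- overlaps(ps, src)
    score <- rep(0, nrow(ps))
    mx <- vapply(split(src$score[hit$b], hit$a), max, 0)
    score[as.integer(names(mx))] <- mx
    peak_set(ps$chrom, ps$start, ps$end, score, factor = factor)
  }
}

load_peaksets <- function(config) {
  out <- list()
  for (f in names(config$peaks)) {
    paths <- config$peaks[[f]]
    miss <- paths[!file.exists(paths)]
    if (length(miss))
      stopf("peak file(s) missing for factor %s: %s", f,
            paste(miss, collapse = ", "))
    sets <- lapply(paths, read_bed, factor = f)
    out[[f]] <- combine_replicates(sets, f, config$replicate_mode)
  }
  out
}

run_manifest <- function(config, stage_counts) {
  inputs <- c(unlist(config$peaks, use.names = FALSE), config$annotation,
              config$studies, config$rpkm)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  list(tool = "regulonscreen",
       version = as.character(utils::packageVersion("regulonscreen")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = list(tss_window = config$rule$tss_window,
                         flank = config$rule$flank,
                         max_genes = config$rule$max_genes_per_peak,
                         top_n = config$top_n,
                         fc_threshold = config$fc_threshold,
                         rpkm_threshold = config$rpkm_threshold,
                         direction = config$direction,
                         replicate_mode = config$replicate_mode),
       input_md5 = as.list(tools::md5sum(unlist(inputs))),
       stage_counts = stage_counts)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Run the direct-target screen
#'
#' Executes the headline screen end to end: per-factor peak-to-gene
#' assignment, target-set derivation, responder calling in two
#' perturbation studies (fold change > threshold in both), intersection
#' with the bound sets of the required factors, and hypergeometric
#' enrichment of the repressor-bound set among responders. Writes
#' `candidates.tsv`, `enrichment.json`, `venn.json` (responder/bound
#' three-way intersection), and `manifest.json` into `out_dir`.
#'
#' @param config A [pipeline_config()] with >= 1 required factor's peaks
#'   and two expression studies.
#' @return Invisibly, a list with `assignments`, `bound_sets`, `screen`
#'   (see [candidate_screen()]), `venn`, `manifest`, and output `paths`.
#' @export
run_tcf3_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  missing_f <- setdiff(config$required_factors, names(config$peaks))
  if (length(missing_f))
    stopf("required factor(s) without peak files: %s",
          paste(missing_f, collapse = ", "))
  if (length(config$studies) != 2)
    stopf("the screen needs exactly two expression studies")
  peaksets <- load_peaksets(config)
  if (!is.null(config$screen_top_n))
    peaksets <- lapply(peaksets, top_n_peaks, n = config$screen_top_n)
  annotation <- read_annotation(config$annotation)
  studies <- lapply(config$studies, read_expression_study)
  assignments <- lapply(peaksets, assign_peaks_to_genes, annotation,
                        config$rule)
  bound_sets <- lapply(assignments, target_genes, annotation = annotation)
  screen <- candidate_screen(bound_sets, studies[[1]], studies[[2]],
                             required_factors = config$required_factors,
                             fc_threshold = config$fc_threshold,
                             direction = config$direction,
                             enrichment_factor = config$enrichment_factor)
  up <- lapply(studies, function(s)
    normalize_symbols(filter_upregulated(s, config$fc_threshold,
                                         config$direction), "case_fold"))
  bound_all <- Reduce(intersect, lapply(
    bound_sets[config$required_factors], normalize_symbols, "case_fold"))
  venn_in <- stats::setNames(
    list(up[[1]], up[[2]], bound_all),
    c(paste0("up_", vapply(studies, attr, "", "study_id")), "bound"))
  venn <- gene_venn(venn_in)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(candidates = file.path(config$out_dir, "candidates.tsv"),
                enrichment = file.path(config$out_dir, "enrichment.json"),
                venn = file.path(config$out_dir, "venn.json"),
                manifest = file.path(config$out_dir, "manifest.json"))
  utils::write.table(screen$candidates, paths$candidates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_json_out(unclass(screen$enrichment), paths$enrichment)
  write_json_out(list(mode = venn$mode, universe_size = venn$universe_size,
                      cell_counts = as.list(venn$cell_counts)), paths$venn)
  counts <- list(peaks = vapply(peaksets, nrow, 0L),
                 links = vapply(assignments, function(a) nrow(a$links), 0L),
                 bound_genes = vapply(bound_sets, length, 0L),
                 responders = length(screen$responders),
                 candidates = nrow(screen$candidates))
  manifest <- run_manifest(config, counts)
  write_json_out(manifest, paths$manifest)
  invisible(list(assignments = assignments, bound_sets = bound_sets,
                 screen = screen, venn = venn, manifest = manifest,
                 paths = paths))
}

#' Run the co-binding report
#'
#' Restricts each factor to its top-N scored peaks (normalising for ChIP
#' efficiency), optionally builds a "bound by at least one of" composite,
#' and produces the region-level and target-gene-level Venn
#' intersections, shared-target fractions of each non-composite input
#' against the union of the others, the binary occupancy matrix, and its
#' Pearson-correlation hierarchical clustering. Writes
#' `region_venn.json`, `gene_venn.json`, `shared_fractions.json`,
#' `occupancy_matrix.tsv`, `cluster_merges.tsv`, `cluster.nwk`, and
#' `manifest.json`.
#'
#' @param config A [pipeline_config()] with >= 2 factors.
#' @return Invisibly, a list with `peaksets` (top-N restricted),
#'   `region_venn`, `gene_venn`, `shared`, `matrix`, `cluster`,
#'   `manifest`, and `paths`. Venns are only computed when the number of
#'   (composite-collapsed) inputs is 2 or 3.
#' @export
run_cobinding_report <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$peaks) < 2)
    stopf("the co-binding report needs >= 2 factors")
  peaksets <- load_peaksets(config)
  annotation <- read_annotation(config$annotation)
  topped <- lapply(peaksets, top_n_peaks, n = config$top_n)
  # Venn inputs: composite members are individually top-N restricted,
  # then merged into one "bound by at least one" input
  venn_in <- topped
  if (!is.null(config$composite)) {
    members <- config$composite$members
    miss <- setdiff(members, names(topped))
    if (length(miss))
      stopf("composite member(s) missing: %s", paste(miss, collapse = ", "))
    comp <- merge_intervals(topped[members], label = config$composite$name)
    venn_in <- c(stats::setNames(list(comp), config$composite$name),
                 topped[setdiff(names(topped), members)])
  }
  rv <- gv <- NULL
  assignments <- lapply(topped, assign_peaks_to_genes, annotation,
                        config$rule)
  targets <- lapply(assignments, target_genes, annotation = annotation)
  gene_in <- targets
  if (!is.null(config$composite)) {
    members <- config$composite$members
    comp_genes <- sort(unique(unlist(targets[members], use.names = FALSE)))
    gene_in <- c(stats::setNames(list(comp_genes), config$composite$name),
                 targets[setdiff(names(targets), members)])
  }
  if (length(venn_in) %in% 2:3) {
    rv <- region_venn(venn_in)
    gv <- gene_venn(gene_in)
  }
  shared <- lapply(stats::setNames(nm = names(gene_in)), function(nm) {
    others <- unique(unlist(gene_in[setdiff(names(gene_in), nm)],
                            use.names = FALSE))
    shared_fraction(gene_in[[nm]], others)
  })
  mat <- binary_peak_matrix(topped)
  cl <- cluster_factors(mat)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(region_venn = file.path(config$out_dir, "region_venn.json"),
                gene_venn = file.path(config$out_dir, "gene_venn.json"),
                shared = file.path(config$out_dir, "shared_fractions.json"),
                matrix = file.path(config$out_dir, "occupancy_matrix.tsv"),
                merges = file.path(config$out_dir, "cluster_merges.tsv"),
                newick = file.path(config$out_dir, "cluster.nwk"),
                manifest = file.path(config$out_dir, "manifest.json"))
  if (!is.null(rv))
    write_json_out(list(mode = rv$mode, universe_size = rv$universe_size,
                        cell_counts = as.list(rv$cell_counts)),
                   paths$region_venn)
  if (!is.null(gv))
    write_json_out(list(mode = gv$mode, universe_size = gv$universe_size,
                        cell_counts = as.list(gv$cell_counts)),
                   paths$gene_venn)
  write_json_out(shared, paths$shared)
  write_occupancy_matrix(mat, paths$matrix)
  export_cluster(cl, merge_path = paths$merges, newick_path = paths$newick)
  counts <- list(peaks_top_n = vapply(topped, nrow, 0L),
                 universe_regions = nrow(mat$regions),
                 target_genes = vapply(targets, length, 0L))
  manifest <- run_manifest(config, counts)
  write_json_out(manifest, paths$manifest)
  invisible(list(peaksets = topped, region_venn = rv, gene_venn = gv,
                 shared = shared, matrix = mat, cluster = cl,
                 manifest = manifest, paths = paths))
}
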