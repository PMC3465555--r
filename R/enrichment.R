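#' Construct a validated expression study
#'
#' A differential-expression table mapping gene symbols to linear-scale
#' fold changes (perturbed over control; > 1 means upregulated).
#'
#' @param symbol Character vector of gene symbols.
#' @param fold_change Positive finite numeric fold changes.
#' @param study_id Identifier string.
#' @return An `expression_study` data.frame with attribute `study_id`.
#' @export
expression_study <- function(symbol, fold_change, study_id = "study") {
  symbol <- as.character(symbol)
  fold_change <- as.numeric(fold_change)
  if (length(symbol) != length(fold_change))
    stopf("symbol and fold_change must have equal length")
  if (any(!is.finite(fold_change) | fold_change <= 0))
    stopf("fold changes must be positive and finite")
  if (anyDuplicated(symbol))
    stopf("duplicate symbols in study %s", study_id)
  df <- data.frame(symbol = symbol, fold_change = fold_change,
                   stringsAsFactors = FALSE)
  structure(df, study_id = study_id,
            class = c("expression_study", "data.frame"))
}

#' Normalize gene symbols for cross-study matching
#'
#' @param raw Character vector of symbols.
#' @param policy "exact" (identity) or "case_fold" (case-insensitive
#'   comparison, reported in upper case).
#' @return Character vector of distinct normalized symbols.
#' @export
normalize_symbols <- function(raw, policy = c("exact", "case_fold")) {
  policy <- match.arg(policy)
  raw <- as.character(raw)
  unique(if (policy == "case_fold") toupper(raw) else raw)
}

#' Genes upregulated beyond a fold-change threshold
#'
#' Strict inequality: a gene at exactly the threshold is excluded
#' (the screen's ">1.4-fold" filter).
#'
#' @param study An [expression_study()].
#' @param threshold Linear fold-change cutoff, > 1 (default 1.4).
#' @param direction "up" selects fold change > threshold; "down" selects
#'   fold change < 1/threshold (the mirrored derepression control).
#' @return Character vector of symbols passing the filter.
#' @export
filter_upregulated <- function(study, threshold = 1.4,
                               direction = c("up", "down")) {
  stopifnot(inherits(study, "expression_study"))
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1)
    stopf("threshold must be a single number > 1")
  keep <- if (direction == "up") study$fold_change > threshold
          else study$fold_change < 1 / threshold
  study$symbol[keep]
}

#' Intersection of two responder sets
#'
#' Genes called in both studies are considered the most likely specific
#' responders. Symbol normalization must be applied upstream.
#'
#' @param a,b Character vectors of gene symbols.
#' @return Character vector of common symbols.
#' @export
intersect_studies <- function(a, b) {
  sort(intersect(as.character(a), as.character(b)), method = "radix")
}

#' Upper-tail hypergeometric enrichment of bound genes among responders
#'
#' With universe size N, K bound genes, n responder genes, and overlap k,
#' computes P(X >= k) under sampling without replacement — the probability
#' of an overlap at least as large by chance. One-sided by design; no
#' multiple-testing correction (a single hypothesis is tested).
#'
#' @param bound Character vector of bound gene ids/symbols.
#' @param responders Character vector of responder ids/symbols.
#' @param universe Non-empty character vector defining the testable
#'   universe; bound and responders are restricted to it.
#' @return An `enrichment_result`: list with `N`, `K`, `n`, `k`, `p_value`,
#'   `fold_enrichment` ((k/n)/(K/N)) and logical `warning` (set when
#'   n = 0, where p is reported as 1).
#' @export
hypergeometric_enrichment <- function(bound, responders, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("universe must be non-empty")
  bound <- intersect(unique(as.character(bound)), universe)
  responders <- intersect(unique(as.character(responders)), universe)
  N <- length(universe)
  K <- length(bound)
  n <- length(responders)
  k <- length(intersect(bound, responders))
  warn <- FALSE
  if (n == 0) {
    p <- 1
    warn <- TRUE
    warning("no responders in universe; enrichment p reported as 1")
  } else {
    # P(X >= k); phyper computes the tail stably in log space internally
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  structure(list(N = N, K = K, n = n, k = k, p_value = p,
                 fold_enrichment = fold, warning = warn),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> N=%d K=%d n=%d k=%d  p=%.4g  fold=%.3g%s\n",
    x$N, x$K, x$n, x$k, x$p_value, x$fold_enrichment,
    if (x$warning) "  [warning: empty responder set]" else ""))
  invisible(x)
}

#' Candidate direct-target screen
#'
#' The genome-scale screen for direct targets of a repressor: genes called
#' upregulated (fold change > threshold) in both perturbation studies are
#' the responders; responders bound by all `required_factors` are the
#' candidates; enrichment of the repressor-bound set among responders is
#' assessed by [hypergeometric_enrichment()].
#'
#' @param bound_sets Named list (factor -> character vector of bound gene
#'   symbols).
#' @param study1,study2 Two [expression_study()] objects.
#' @param universe Character vector of testable genes; defaults to the
#'   genes assayed in both studies (a gene must be assayable to respond).
#' @param required_factors Factors whose bound sets candidates must all
#'   belong to; defaults to all of `bound_sets`.
#' @param fc_threshold Linear fold-change cutoff (default 1.4, strict).
#' @param direction "up" (derepression, default) or "down" (control
#'   screen on downregulated genes).
#' @param enrichment_factor Factor whose bound set is tested for
#'   enrichment among responders; defaults to the first required factor.
#' @param policy Symbol-matching policy, see [normalize_symbols()].
#' @return List with `candidates` (data.frame: symbol, fold changes in
#'   both studies, one bound_<factor> flag per factor, sorted by
#'   descending minimum fold change), `responders`, and `enrichment`.
#' @export
candidate_screen <- function(bound_sets, study1, study2, universe = NULL,
                             required_factors = names(bound_sets),
                             fc_threshold = 1.4,
                             direction = c("up", "down"),
                             enrichment_factor = required_factors[1],
                             policy = c("case_fold", "exact")) {
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  if (is.null(names(bound_sets)) || any(!nzchar(names(bound_sets))))
    stopf("bound_sets must be a named list")
  missing_f <- setdiff(required_factors, names(bound_sets))
  if (length(missing_f))
    stopf("required factor(s) missing from bound_sets: %s",
          paste(missing_f, collapse = ", "))
  if (!enrichment_factor %in% names(bound_sets))
    stopf("enrichment_factor %s missing from bound_sets", enrichment_factor)
  norm <- function(x) normalize_symbols(x, policy)
  bound_sets <- lapply(bound_sets, norm)
  up1 <- norm(filter_upregulated(study1, fc_threshold, direction))
  up2 <- norm(filter_upregulated(study2, fc_threshold, direction))
  if (is.null(universe))
    universe <- intersect(norm(study1$symbol), norm(study2$symbol))
  else universe <- norm(universe)
  responders <- intersect(intersect_studies(up1, up2), universe)
  bound_all <- Reduce(intersect,
                      bound_sets[sort(required_factors, method = "radix")])
  candidates <- sort(intersect(responders, bound_all), method = "radix")
  enrichment <- withCallingHandlers(
    hypergeometric_enrichment(bound_sets[[enrichment_factor]], responders,
                              universe),
    warning = function(w) invokeRestart("muffleWarning"))
  fc_of <- function(study, sym) {
    key <- normalize_symbols(study$symbol, policy)
    study$fold_change[match(sym, key)]
  }
  tab <- data.frame(symbol = candidates,
                    fold_change_1 = fc_of(study1, candidates),
                    fold_change_2 = fc_of(study2, candidates),
                    stringsAsFactors = FALSE)
  for (f in sort(names(bound_sets), method = "radix"))
    tab[[paste0("bound_", f)]] <- tab$symbol %in% bound_sets[[f]]
  tab <- tab[order(-pmin(tab$fold_change_1, tab$fold_change_2), tab$symbol,
                   method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  list(candidates = tab, responders = responders, enrichment = enrichment)
}

#' Fraction of expressed genes bound by a factor
#'
#' Expressed genes are those with RPKM strictly above `rpkm_threshold`;
#' the returned fraction is |targets intersect expressed| / |expressed|.
#'
#' @param targets Character vector of a factor's candidate target gene ids.
#' @param levels Named numeric vector of RPKM keyed by gene id (see
#'   [read_expression_levels()]).
#' @param rpkm_threshold Expression cutoff (default 0.5, strict).
#' @return List with `fraction`, `bound_expressed`, and `expressed`.
#' @export
expressed_binding_fraction <- function(targets, levels,
                                       rpkm_threshold = 0.5) {
  if (!length(levels)) stopf("expression levels must be non-empty")
  if (is.null(names(levels))) stopf("levels must be named by gene id")
  expressed <- unique(names(levels)[levels > rpkm_threshold])
  if (!length(expressed))
    stopf("no genes above %.3g RPKM; fraction undefined", rpkm_threshold)
  k <- sum(expressed %in% unique(as.character(targets)))
  list(fraction = k / length(expressed), bound_expressed = k,
       expressed = length(expressed))
}
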