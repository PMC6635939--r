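# barcode_id: barcoding-gap analysis and distance-based identification
# (minimum distance and best close match) with leave-one-out replication.

#' Barcoding-gap summary
#'
#' Compares the distributions of within-group and between-group pairwise
#' distances at the chosen level. The gap is positive iff the smallest
#' between-group distance exceeds the largest within-group distance.
#'
#' @param dm An `hg_distmatrix` (typically K2P).
#' @param pm Population map.
#' @param level Grouping column: `"population"`, `"region"` or
#'   `"species"`.
#' @param breaks Number of histogram bins.
#' @return List with the [within_between_summary()] fields plus
#'   `max_within`, `min_between` and `positive_gap`.
#' @export
barcoding_gap <- function(dm, pm, level = "population", breaks = 20) {
  pm <- check_level(pm, level)
  smry <- within_between_summary(dm, pm, level = level, breaks = breaks)
  idx <- match(dm$ids, pm$sample)
  groups <- pm[[level]][idx]
  sp <- split_pairs(dm, groups)
  smry$max_within <- max(sp$within)
  smry$min_between <- min(sp$between)
  smry$positive_gap <- smry$min_between > smry$max_within
  smry
}

# Leave-one-out classification of a single query. Returns the outcome and
# the assigned group(s).
classify_query <- function(query_id, dm, groups, threshold = Inf) {
  i <- match(query_id, dm$ids)
  if (is.na(i)) hg_input_error(sprintf("unknown query id '%s'", query_id))
  d <- dm$mat[i, -i]
  g <- groups[-i]
  ok <- !is.na(d)
  d <- d[ok]; g <- g[ok]
  if (length(d) == 0L) hg_input_error("empty reference set")
  dmin <- min(d)
  if (dmin > threshold) {
    return(list(outcome = "no_identification", assigned = character(0),
                min_distance = dmin))
  }
  hit_groups <- unique(g[d <= dmin + 1e-12])
  truth <- groups[i]
  outcome <- if (length(hit_groups) > 1L) "ambiguous"
             else if (hit_groups == truth) "correct" else "incorrect"
  list(outcome = outcome, assigned = hit_groups, min_distance = dmin)
}

#' Minimum-distance (MD) classification of one query
#'
#' The query (left out of the reference set) is assigned to the group of
#' its nearest reference; ties spanning several groups are ambiguous.
#'
#' @param query_id Sample id of the query.
#' @param dm An `hg_distmatrix` over all samples.
#' @param pm Population map.
#' @param level Grouping level.
#' @return List with `outcome` (correct / incorrect / ambiguous /
#'   no_identification), `assigned` groups, `min_distance`.
#' @export
classify_md <- function(query_id, dm, pm, level = "population") {
  pm <- check_level(pm, level)
  groups <- pm[[level]][match(dm$ids, pm$sample)]
  classify_query(query_id, dm, groups, threshold = Inf)
}

#' Best-close-match (BCM) classification of one query
#'
#' As [classify_md()], but queries whose nearest reference lies beyond
#' `threshold` are declared unidentifiable. The default threshold is the
#' 95th percentile of within-group pairwise distances at the chosen
#' level.
#'
#' @inheritParams classify_md
#' @param threshold Distance threshold (>= 0); `NULL` for the default.
#' @return As [classify_md()].
#' @export
classify_bcm <- function(query_id, dm, pm, level = "population",
                         threshold = NULL) {
  pm <- check_level(pm, level)
  groups <- pm[[level]][match(dm$ids, pm$sample)]
  if (is.null(threshold)) threshold <- bcm_threshold(dm, groups)
  if (threshold < 0) hg_input_error("threshold must be >= 0")
  classify_query(query_id, dm, groups, threshold = threshold)
}

bcm_threshold <- function(dm, groups, prob = 0.95) {
  sp <- split_pairs(dm, groups)
  if (length(sp$within) == 0L)
    hg_numeric_error("no within-group pairs: BCM threshold undefined")
  stats::quantile(sp$within, prob, names = FALSE)
}

#' Leave-one-out identification success with replication
#'
#' The deterministic core classifies every sample as a query against all
#' remaining samples (single-sequence omission). Because that core has no
#' randomness, each of the `n_reps` replications draws a bootstrap
#' resample of query ids (with replacement, size N) and records its
#' success rate; the report carries the mean rate and a
#' normal-approximation 95% interval (mean +/- 1.96 SD of the replication
#' rates). Ambiguous and unidentifiable queries count as failures for the
#' headline rate; the full outcome breakdown is also reported.
#'
#' @param aln An [hg_alignment()] (used to build a K2P matrix), or an
#'   `hg_distmatrix` directly.
#' @param pm Population map.
#' @param method `"md"` or `"bcm"`.
#' @param level Grouping level (`"population"`, `"region"`, `"species"`).
#' @param n_reps Number of bootstrap replications.
#' @param seed Optional RNG seed.
#' @param threshold BCM threshold; `NULL` for the default percentile rule.
#' @return Object of class `hg_idreport`: `method`, `level`,
#'   `outcomes` (per-sample leave-one-out outcome), `outcome_counts`,
#'   `rates` (per replication), `mean_rate`, `ci` (low, high),
#'   `n_reps`, `threshold`.
#' @export
loo_success <- function(aln, pm, method = c("md", "bcm"),
                        level = "population", n_reps = 500, seed = NULL,
                        threshold = NULL) {
  method <- match.arg(method)
  dm <- if (inherits(aln, "hg_distmatrix")) aln
        else distance_matrix(aln, metric = "k2p")
  pm <- check_level(pm, level)
  groups <- pm[[level]][match(dm$ids, pm$sample)]
  if (anyNA(groups)) hg_input_error("samples missing from population map")
  if (length(unique(groups)) < 2L)
    hg_input_error("need >= 2 groups at the chosen level")
  hg_seed(seed)
  thr <- if (method == "bcm") {
    if (is.null(threshold)) bcm_threshold(dm, groups) else threshold
  } else Inf
  outcomes <- vapply(dm$ids, function(id)
    classify_query(id, dm, groups, threshold = thr)$outcome, character(1))
  correct <- outcomes == "correct"
  N <- length(outcomes)
  rates <- vapply(seq_len(max(n_reps, 1L)), function(r) {
    mean(correct[sample.int(N, N, replace = TRUE)])
  }, numeric(1))
  if (n_reps == 0L) rates <- mean(correct)
  m <- mean(rates)
  se <- stats::sd(rates)
  ci <- c(max(0, m - 1.96 * se), min(1, m + 1.96 * se))
  cnt <- table(factor(outcomes, levels = c("correct", "incorrect",
                                           "ambiguous", "no_identification")))
  structure(list(method = toupper(method), level = level,
                 outcomes = outcomes,
                 outcome_counts = as.list(cnt),
                 rates = rates, mean_rate = m,
                 ci = stats::setNames(ci, c("low", "high")),
                 ci_method = "normal approximation over replication rates",
                 n_reps = n_reps,
                 threshold = if (is.finite(thr)) thr else NULL),
            class = "hg_idreport")
}

#' @export
print.hg_idreport <- function(x, ...) {
  cat(sprintf(
    "<hg_idreport> %s @ %s level: mean success %.2f%% (95%% CI %.2f-%.2f%%), %d reps\n",
    x$method, x$level, 100 * x$mean_rate, 100 * x$ci[["low"]],
    100 * x$ci[["high"]], x$n_reps))
  cat("  outcomes:", paste(sprintf("%s=%d", names(x$outcome_counts),
                                   unlist(x$outcome_counts)),
                           collapse = "  "), "\n")
  invisible(x)
}
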