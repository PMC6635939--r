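# structure: AMOVA (2- and 3-level), pairwise FST, Mantel test.
# SAMOVA lives in samova.R.

# Squared molecular distances for the variance decomposition. A raw
# difference count is already a squared Euclidean distance (one-hot site
# embedding), so it is used as-is; continuous metrics (K2P) are squared.
squared_distances <- function(dm) {
  if (inherits(dm, "hg_distmatrix") && dm$metric == "raw") dm$mat
  else if (inherits(dm, "hg_distmatrix")) dm$mat^2
  else as.matrix(dm)
}

# Aggregate squared distances by population: M[p,q] = sum over ordered
# pairs (i in p, j in q) of d2[i,j] (diagonal therefore double-counts
# unordered within pairs). All SS terms derive from these aggregates.
pop_pair_sums <- function(d2, pop) {
  f <- factor(pop)
  M <- rowsum(t(rowsum(d2, f)), f)
  list(M = as.matrix(M), sizes = as.vector(table(f)),
       pops = levels(f))
}

# Sums of squares and variance components for a (possibly degenerate)
# hierarchical design, from population aggregates.
#   grp: group label per population (same order as agg$pops)
amova_components <- function(agg, grp) {
  M <- agg$M; n_p <- agg$sizes
  N <- sum(n_p); P <- length(n_p)
  gf <- factor(grp)
  G <- nlevels(gf)
  ss_total <- sum(M) / 2 / N
  ss_wp <- sum(diag(M) / 2 / n_p)
  Ng <- as.vector(tapply(n_p, gf, sum))
  ss_wg <- sum(vapply(levels(gf), function(g) {
    sel <- which(gf == g)
    sum(M[sel, sel]) / 2 / sum(n_p[sel])
  }, numeric(1)))
  ss_ap_wg <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg

  df_wp <- N - P
  df_ap <- P - G
  df_ag <- G - 1

  sig_c <- if (df_wp > 0) ss_wp / df_wp else 0
  sum_np2_over_Ng <- sum(tapply(n_p^2, gf, sum) / Ng)
  if (G > 1L) {
    n1 <- (N - sum_np2_over_Ng) / df_ap
    n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(Ng^2) / N) / df_ag
    ms_ap <- ss_ap_wg / df_ap
    ms_ag <- ss_ag / df_ag
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    df <- c(among_groups = df_ag, among_pops = df_ap, within_pops = df_wp)
    ss <- c(ss_ag, ss_ap_wg, ss_wp)
    sig <- c(sig_a, sig_b, sig_c)
  } else {
    n1 <- (N - sum(n_p^2) / N) / (P - 1)
    ms_ap <- ss_ap_wg / (P - 1)
    sig_b <- (ms_ap - sig_c) / n1
    df <- c(among_pops = P - 1, within_pops = df_wp)
    ss <- c(ss_ap_wg, ss_wp)
    sig <- c(sig_b, sig_c)
  }
  list(df = df, ss = ss, sigma = sig)
}

fixation_indices <- function(sig) {
  tot <- sum(sig)
  if (length(sig) == 3L) {
    c(FCT = sig[[1]] / tot,
      FSC = sig[[2]] / (sig[[2]] + sig[[3]]),
      FST = (sig[[1]] + sig[[2]]) / tot)
  } else {
    c(FST = sig[[1]] / tot)
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of molecular variance from squared raw
#' difference counts (the Arlequin convention for haplotypic data), with
#' permutation p-values per level: individuals among all populations for
#' FST, individuals among populations within groups for FSC, and whole
#' populations among groups for FCT. Negative variance components are
#' retained in sums (and flagged) rather than truncated.
#'
#' @param dm An `hg_distmatrix`; with `metric = "raw"` the difference
#'   counts are used directly as squared distances, continuous metrics
#'   are squared.
#' @param pm Population map covering all `dm$ids`.
#' @param grouping Either `NULL` (two-level: populations/within), the name
#'   of a map column (e.g. `"region"`), or a named vector population ->
#'   group (three-level).
#' @param n_perm Permutations for significance.
#' @param seed Optional RNG seed.
#' @return Object of class `hg_amova`: `table` (df, SS, variance
#'   component, percentage of variation), `indices`, `p_values`,
#'   `negative_components` flag.
#' @export
amova <- function(dm, pm, grouping = NULL, n_perm = 1000, seed = NULL) {
  hg_seed(seed)
  if (!inherits(pm, "hg_popmap")) pm <- population_map(pm)
  idx <- match(dm$ids, pm$sample)
  if (anyNA(idx)) hg_input_error("distance matrix ids missing from population map")
  pop <- pm$population[idx]
  if (length(unique(pop)) < 2L)
    hg_input_error("AMOVA needs at least two populations")
  d2 <- squared_distances(dm)
  if (all(d2 == 0))
    hg_numeric_error("all distances are zero: fixation indices undefined")

  grp_of_pop <- resolve_grouping(pm, grouping, unique(pop))
  three <- !is.null(grp_of_pop) && length(unique(grp_of_pop)) > 1L

  agg <- pop_pair_sums(d2, pop)
  grp <- if (three) grp_of_pop[agg$pops] else rep("all", length(agg$pops))
  comp <- amova_components(agg, grp)
  idxs <- fixation_indices(comp$sigma)

  # permutation schemes
  grp_of_ind <- if (three) grp_of_pop[pop] else NULL
  stat_fst <- function(pop_perm) {
    a <- pop_pair_sums(d2, pop_perm)
    g <- if (three) grp_of_pop[a$pops] else rep("all", length(a$pops))
    fixation_indices(amova_components(a, g)[["sigma"]])[["FST"]]
  }
  p <- c(FST = NA_real_, FSC = NA_real_, FCT = NA_real_)
  if (n_perm > 0) {
    # FST: permute individuals among all populations
    obs <- idxs[["FST"]]
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (stat_fst(sample(pop)) >= obs - 1e-12) hits <- hits + 1L
    }
    p[["FST"]] <- perm_pvalue(hits, n_perm)
    if (three) {
      # FSC: permute individuals among populations within their group
      obs <- idxs[["FSC"]]
      hits <- 0L
      for (b in seq_len(n_perm)) {
        pp <- pop
        for (g in unique(grp_of_ind)) {
          sel <- which(grp_of_ind == g)
          pp[sel] <- pop[sel][sample.int(length(sel))]
        }
        a <- pop_pair_sums(d2, pp)
        cg <- grp_of_pop[a$pops]
        v <- fixation_indices(amova_components(a, cg)[["sigma"]])[["FSC"]]
        if (v >= obs - 1e-12) hits <- hits + 1L
      }
      p[["FSC"]] <- perm_pvalue(hits, n_perm)
      # FCT: permute whole populations among groups
      obs <- idxs[["FCT"]]
      hits <- 0L
      pops <- agg$pops
      base_grp <- grp_of_pop[pops]
      for (b in seq_len(n_perm)) {
        gp <- stats::setNames(base_grp[sample.int(length(pops))], pops)
        v <- fixation_indices(amova_components(agg, gp[agg$pops])[["sigma"]])[["FCT"]]
        if (v >= obs - 1e-12) hits <- hits + 1L
      }
      p[["FCT"]] <- perm_pvalue(hits, n_perm)
    }
  }

  lvl <- if (three) c("Among groups", "Among populations within groups",
                      "Within populations")
         else c("Among populations", "Within populations")
  tab <- data.frame(source = c(lvl, "Total"),
                    df = c(comp$df, sum(comp$df)),
                    SS = c(comp$ss, sum(comp$ss)),
                    variance = c(comp$sigma, sum(comp$sigma)),
                    percent = c(100 * comp$sigma / sum(comp$sigma), 100))
  structure(list(table = tab, indices = idxs,
                 p_values = p[names(idxs)],
                 n_perm = n_perm,
                 negative_components = any(comp$sigma < 0)),
            class = "hg_amova")
}

resolve_grouping <- function(pm, grouping, pops) {
  if (is.null(grouping)) return(NULL)
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% names(pm)) {
    first <- !duplicated(pm$population)
    return(stats::setNames(as.character(pm[[grouping]][first]),
                           pm$population[first]))
  }
  if (!is.null(names(grouping))) {
    miss <- setdiff(pops, names(grouping))
    if (length(miss) > 0L)
      hg_input_error(sprintf("grouping misses populations: %s",
                             paste(miss, collapse = ", ")))
    return(stats::setNames(as.character(grouping), names(grouping)))
  }
  hg_input_error("grouping must be NULL, a map column name, or a named vector")
}

#' @export
print.hg_amova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("Fixation indices:",
      paste(sprintf("%s = %.4f", names(x$indices), x$indices), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write an AMOVA table as TSV
#' @param x An `hg_amova`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amova <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise FST between populations
#'
#' Two-level AMOVA restricted to each population pair; p-values by
#' permuting individuals between the two populations.
#'
#' @param dm An `hg_distmatrix` (raw metric).
#' @param pm Population map.
#' @param n_perm Permutations per pair.
#' @param seed Optional RNG seed.
#' @return List with symmetric matrices `fst` and `p` (NA for skipped
#'   pairs involving singleton populations).
#' @export
pairwise_fst <- function(dm, pm, n_perm = 999, seed = NULL) {
  hg_seed(seed)
  if (!inherits(pm, "hg_popmap")) pm <- population_map(pm)
  idx <- match(dm$ids, pm$sample)
  if (anyNA(idx)) hg_input_error("distance matrix ids missing from population map")
  pop <- pm$population[idx]
  pops <- unique(pop)
  sizes <- table(pop)
  if (any(sizes < 2))
    warning(sprintf("singleton population(s) skipped: %s",
                    paste(names(sizes)[sizes < 2], collapse = ", ")))
  np <- length(pops)
  fst <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  pv <- fst
  diag(fst) <- 0
  d2 <- squared_distances(dm)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if (sizes[[pops[i]]] < 2 || sizes[[pops[j]]] < 2) next
    sel <- which(pop %in% c(pops[i], pops[j]))
    sub <- d2[sel, sel, drop = FALSE]
    sp <- pop[sel]
    f <- function(labels) {
      a <- pop_pair_sums(sub, labels)
      fixation_indices(amova_components(a, rep("all", 2))[["sigma"]])[["FST"]]
    }
    obs <- f(sp)
    hits <- 0L
    for (b in seq_len(n_perm)) if (f(sample(sp)) >= obs - 1e-12) hits <- hits + 1L
    fst[i, j] <- fst[j, i] <- obs
    pv[i, j] <- pv[j, i] <- perm_pvalue(hits, n_perm)
  }
  list(fst = fst, p = pv, n_perm = n_perm)
}

#' Mantel test
#'
#' Pearson correlation between the lower triangles of two symmetric
#' matrices over the same ordered labels; significance by permuting the
#' row/column order of the second matrix.
#'
#' @param mat_a,mat_b Symmetric numeric matrices (or `hg_distmatrix`)
#'   with identical dimensions and label order.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @param alternative `"greater"` (one-tailed, default), `"less"`, or
#'   `"two.sided"`.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(mat_a, mat_b, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  hg_seed(seed)
  A <- if (inherits(mat_a, "hg_distmatrix")) mat_a$mat else as.matrix(mat_a)
  B <- if (inherits(mat_b, "hg_distmatrix")) mat_b$mat else as.matrix(mat_b)
  if (!identical(dim(A), dim(B)))
    hg_input_error("matrices differ in dimension")
  lw <- lower.tri(A)
  a <- A[lw]; b <- B[lw]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    hg_numeric_error("zero variance in a matrix lower triangle")
  r_obs <- stats::cor(a, b)
  n <- nrow(A)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    s <- sample.int(n)
    r_p <- stats::cor(a, B[s, s][lw])
    extreme <- switch(alternative,
      greater = r_p >= r_obs - 1e-12,
      less = r_p <= r_obs + 1e-12,
      two.sided = abs(r_p) >= abs(r_obs) - 1e-12)
    if (extreme) hits <- hits + 1L
  }
  list(r = r_obs, p = perm_pvalue(hits, n_perm), n_perm = n_perm)
}
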