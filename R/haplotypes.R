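# haplotypes: collapsing, diversity statistics, GST/NST differentiation.

#' Collapse an alignment into haplotypes
#'
#' Sequences identical at all retained columns share a haplotype. Retained
#' columns are those with no ambiguity code or gap in any sequence
#' (complete deletion), so that haplotype identity is a transitive
#' relation. Haplotypes are labelled H1, H2, ... in order of first
#' observation.
#'
#' @param aln An [hg_alignment()].
#' @param pm Optional population map; when omitted all samples form a
#'   single population `"all"`.
#' @return Object of class `hg_catalog`: list with `labels`, `seqs`
#'   (haplotype strings over retained columns), `representative` (one
#'   sample id per haplotype), `counts` (population x haplotype matrix),
#'   `assignment` (named haplotype label per sample), `retained_sites`
#'   (1-based indices), `N`, `Nh`.
#' @export
collapse_haplotypes <- function(aln, pm = NULL) {
  stopifnot(inherits(aln, "hg_alignment"))
  enc <- encode_alignment(aln)
  keep <- which(colSums(is.na(enc)) == 0L)
  if (length(keep) == 0L)
    hg_numeric_error("no columns free of ambiguity codes/gaps; cannot collapse")
  sub <- aln$seq[, keep, drop = FALSE]
  key <- apply(sub, 1L, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  labels <- paste0("H", seq_along(uniq))
  hap_of <- labels[match(key, uniq)]
  names(hap_of) <- aln$ids
  if (is.null(pm)) {
    pop_of <- rep("all", length(aln$ids))
  } else {
    pm2 <- match_map(aln, pm)
    pop_of <- pm2$population
  }
  counts <- table(factor(pop_of, levels = unique(pop_of)),
                  factor(hap_of, levels = labels))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(labels = labels,
                 seqs = stats::setNames(uniq, labels),
                 representative = stats::setNames(aln$ids[first], labels),
                 counts = counts,
                 assignment = hap_of,
                 retained_sites = keep,
                 N = length(aln$ids),
                 Nh = length(labels)),
            class = "hg_catalog")
}

#' Build a catalog from a population x haplotype count table
#'
#' For analyses that start from printed frequency tables rather than
#' sequences (no haplotype sequences attached, so distance-based
#' statistics are unavailable).
#'
#' @param counts Integer matrix, populations in rows, haplotypes in
#'   columns, both dimnames required.
#' @return An `hg_catalog` with `seqs = NULL`.
#' @export
catalog_from_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    hg_input_error("count matrix needs population rownames and haplotype colnames")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) hg_input_error("negative haplotype counts")
  structure(list(labels = colnames(counts), seqs = NULL,
                 representative = NULL, counts = counts,
                 assignment = NULL, retained_sites = NULL,
                 N = sum(counts), Nh = ncol(counts)),
            class = "hg_catalog")
}

#' @export
print.hg_catalog <- function(x, ...) {
  cat(sprintf("<hg_catalog> N = %d samples, Nh = %d haplotypes, %d population(s)\n",
              x$N, x$Nh, nrow(x$counts)))
  invisible(x)
}

#' Export a catalog's count table as TSV
#' @param cat An `hg_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path) {
  df <- data.frame(population = rownames(cat$counts), cat$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export haplotype sequences as FASTA (H-labels as ids)
#' @param cat An `hg_catalog` built from sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(cat, path) {
  if (is.null(cat$seqs)) hg_input_error("catalog carries no sequences")
  write_fasta_alignment(hg_alignment(cat$seqs), path)
}

#' Haplotype (gene) diversity with sampling variance
#'
#' Nei's unbiased estimator h = n(1 - sum p_i^2)/(n - 1) and its sampling
#' variance
#' V(h) = (2/(n(n-1))) (2(n-2)\[sum p^3 - (sum p^2)^2\] + sum p^2 - (sum p^2)^2).
#'
#' @param counts Vector of per-haplotype counts (zeros allowed).
#' @param n Sample size; defaults to `sum(counts)`.
#' @return List with `h` and `sd`.
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (n < 2) hg_numeric_error("haplotype diversity requires n >= 2")
  if (abs(sum(counts) - n) > 1e-9)
    hg_input_error("counts do not sum to n")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd = sqrt(max(v, 0)))
}

#' Species-level (pooled) haplotype diversity
#'
#' Applies [haplotype_diversity()] to the column sums of the catalog's
#' count matrix.
#'
#' @param cat An `hg_catalog`.
#' @return List with `h`, `sd`, `pooled_counts`.
#' @export
pooled_diversity <- function(cat) {
  tot <- colSums(cat$counts)
  hd <- haplotype_diversity(tot, cat$N)
  c(hd, list(pooled_counts = tot))
}

#' Per-population diversity table
#'
#' n, Nh, h (SD) and nucleotide diversity for every population plus the
#' pooled total; the table mirrors the usual "locations and diversity"
#' layout of phylogeographic studies.
#'
#' @param aln An [hg_alignment()].
#' @param pm Population map.
#' @return Data frame with one row per population plus a `Total` row.
#' @export
diversity_table <- function(aln, pm) {
  pm2 <- match_map(aln, pm)
  cat <- collapse_haplotypes(aln, pm2)
  pops <- rownames(cat$counts)
  rows <- lapply(pops, function(p) {
    ids <- aln$ids[pm2$population == p]
    n <- length(ids)
    cn <- cat$counts[p, ]
    if (n >= 2) {
      hd <- haplotype_diversity(cn, n)
      pi <- nucleotide_diversity(subset_alignment(aln, ids))
    } else {
      hd <- list(h = NA_real_, sd = NA_real_); pi <- NA_real_
    }
    data.frame(population = p, n = n, Nh = sum(cn > 0),
               h = hd$h, h_sd = hd$sd, pi = pi)
  })
  tot <- pooled_diversity(cat)
  rows <- c(rows, list(data.frame(
    population = "Total", n = cat$N, Nh = cat$Nh,
    h = tot$h, h_sd = tot$sd, pi = nucleotide_diversity(aln))))
  do.call(rbind, rows)
}

#' Nucleotide diversity
#'
#' Mean over unordered sequence pairs of the per-pair proportion of
#' differing sites (pairwise deletion).
#'
#' @param aln An [hg_alignment()].
#' @return Numeric pi.
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "hg_alignment"))
  if (length(aln$ids) < 2L)
    hg_numeric_error("nucleotide diversity requires >= 2 sequences")
  dm <- distance_matrix(aln, metric = "p")
  mean(dm$mat[lower.tri(dm$mat)])
}

# Nei & Chesser-corrected HS / HT (and their distance-weighted analogues
# vS / vT) from a population frequency matrix P (pops x haplotypes), deme
# sizes n, and an optional haplotype distance matrix D. When D is the
# "all pairs equally different" matrix the v-statistics reduce exactly to
# the h-statistics, forcing NST = GST.
hs_ht_components <- function(P, n, D = NULL) {
  s <- nrow(P)
  ntilde <- s / sum(1 / n)
  if (is.null(D)) {
    within <- 1 - rowSums(P^2)
  } else {
    within <- vapply(seq_len(s), function(i) drop(P[i, ] %*% D %*% P[i, ]),
                     numeric(1))
  }
  # unweighted average of unbiased per-population diversities
  hs <- mean(within * n / (n - 1))
  pbar <- colMeans(P)
  if (is.null(D)) {
    total0 <- 1 - sum(pbar^2)
  } else {
    total0 <- drop(pbar %*% D %*% pbar)
  }
  ht <- total0 + hs / (ntilde * s)
  list(hs = hs, ht = ht)
}

#' GST and NST differentiation with a permutation test
#'
#' HS is the average of per-population unbiased gene diversities, HT the
#' pooled (unweighted mean-frequency) diversity with the small-sample
#' correction HT = 1 - sum(pbar^2) + HS/(ntilde s); GST = (HT - HS)/HT.
#' NST applies the same functional to frequencies weighted by
#' inter-haplotype distances (raw per-site differences by default):
#' NST = (vT - vS)/vT. The test for phylogeographic structure permutes
#' haplotype identities on the distance matrix and asks how often
#' NST - GST is at least as large as observed.
#'
#' Standard errors are delete-one-population jackknife estimates.
#'
#' @param cat An `hg_catalog` (with sequences, unless `hap_dm` is given).
#' @param hap_dm Optional `hg_distmatrix` (or plain matrix) of distances
#'   between haplotypes, ordered like `cat$labels`. Default: raw
#'   differences between haplotype sequences.
#' @param n_perm Number of permutations for the NST > GST test.
#' @param seed Optional RNG seed.
#' @param min_n Populations with fewer samples are dropped (the unbiased
#'   per-population diversity needs n >= 2).
#' @return List of class `hg_diffstats` with `HS`, `HT`, `GST`, `NST`,
#'   `se` (named vector), `p_nst_gt_gst`, `n_perm`, `n_pops_used`.
#' @export
gst_nst <- function(cat, hap_dm = NULL, n_perm = 1000, seed = NULL,
                    min_n = 2L) {
  stopifnot(inherits(cat, "hg_catalog"))
  hg_seed(seed)
  if (is.null(hap_dm)) {
    if (is.null(cat$seqs))
      hg_input_error("catalog has no sequences; supply 'hap_dm'")
    hap_aln <- hg_alignment(cat$seqs)
    D <- distance_matrix(hap_aln, metric = "raw")$mat
  } else {
    D <- if (inherits(hap_dm, "hg_distmatrix")) hap_dm$mat else as.matrix(hap_dm)
  }
  if (!identical(dim(D), c(cat$Nh, cat$Nh)))
    hg_input_error("haplotype distance matrix does not match catalog size")
  n <- rowSums(cat$counts)
  use <- n >= min_n
  if (sum(use) < 2L)
    hg_input_error("need >= 2 populations with >= 2 samples")
  C <- cat$counts[use, , drop = FALSE]
  n <- n[use]
  P <- C / n

  comp_h <- hs_ht_components(P, n)
  comp_v <- hs_ht_components(P, n, D)
  if (comp_h$ht <= 0)
    hg_numeric_error("HT = 0: differentiation undefined")
  gst <- (comp_h$ht - comp_h$hs) / comp_h$ht
  nst <- (comp_v$ht - comp_v$hs) / comp_v$ht
  obs <- nst - gst

  n_extreme <- 0L
  H <- ncol(P)
  for (b in seq_len(n_perm)) {
    sig <- sample.int(H)
    cv <- hs_ht_components(P, n, D[sig, sig, drop = FALSE])
    nst_p <- (cv$ht - cv$hs) / cv$ht
    if (nst_p - gst >= obs - 1e-12) n_extreme <- n_extreme + 1L
  }

  # jackknife over populations
  jk <- function(stat_fun) {
    s <- nrow(P)
    if (s < 3L) return(NA_real_)
    vals <- vapply(seq_len(s), function(i) {
      stat_fun(P[-i, , drop = FALSE], n[-i])
    }, numeric(1))
    sqrt((s - 1) / s * sum((vals - mean(vals))^2))
  }
  se <- c(
    HS = jk(function(P2, n2) hs_ht_components(P2, n2)$hs),
    HT = jk(function(P2, n2) hs_ht_components(P2, n2)$ht),
    GST = jk(function(P2, n2) {
      cc <- hs_ht_components(P2, n2); (cc$ht - cc$hs) / cc$ht
    }),
    NST = jk(function(P2, n2) {
      cc <- hs_ht_components(P2, n2, D); (cc$ht - cc$hs) / cc$ht
    })
  )

  structure(list(HS = comp_h$hs, HT = comp_h$ht, GST = gst, NST = nst,
                 se = se, p_nst_gt_gst = perm_pvalue(n_extreme, n_perm),
                 n_perm = n_perm, n_pops_used = sum(use)),
            class = "hg_diffstats")
}

#' @export
print.hg_diffstats <- function(x, ...) {
  cat(sprintf(
    "<hg_diffstats> HS = %.3f  HT = %.3f  GST = %.3f  NST = %.3f  p(NST>GST) = %.4g\n",
    x$HS, x$HT, x$GST, x$NST, x$p_nst_gt_gst))
  invisible(x)
}
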