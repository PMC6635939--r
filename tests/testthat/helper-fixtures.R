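# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately written as naive enumerations, separate from the package's
# code paths.

aln4 <- function() {
  hg_alignment(c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", s4 = "ATTT"))
}

random_alignment <- function(n, k, chars = c("A", "C", "G", "T")) {
  m <- matrix(sample(chars, n * k, replace = TRUE), n, k)
  rownames(m) <- sprintf("r%02d", seq_len(n))
  hg_alignment(m)
}

simple_map <- function(aln, pops, regions = NULL, lat = NULL, lon = NULL) {
  df <- data.frame(sample = aln$ids, population = pops,
                   stringsAsFactors = FALSE)
  if (!is.null(regions)) df$region <- regions
  if (!is.null(lat)) { df$lat <- lat; df$lon <- lon }
  population_map(df)
}

# Oracle: per-column tally of segregating / parsimony-informative sites.
oracle_site_counts <- function(aln) {
  S <- 0; PI <- 0
  for (j in seq_len(aln$k)) {
    col <- aln$seq[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    tb <- table(col)
    if (length(tb) >= 2) {
      S <- S + 1
      if (sum(tb >= 2) >= 2) PI <- PI + 1
    }
  }
  list(S = S, PI = PI)
}

# Oracle: gene diversity as the pair-counting probability that two draws
# without replacement differ, times nothing else (the n/(n-1) factor is
# implicit in drawing without replacement).
oracle_h_pairs <- function(counts) {
  n <- sum(counts)
  ids <- rep(seq_along(counts), counts)
  diff_pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff_pairs <- diff_pairs + (ids[i] != ids[j])
  diff_pairs / choose(n, 2) * 1  # P(two random draws differ)
}

# Oracle: AMOVA sums of squares and variance components from the one-hot
# site embedding (raw difference counts are squared Euclidean distances
# in this space), using centroid deviations and the textbook unbalanced
# nested moment equations, written independently of the package.
oracle_amova <- function(aln, pop, grp = NULL) {
  lv <- c("A", "C", "G", "T")
  X <- NULL
  for (j in seq_len(aln$k)) {
    oh <- t(vapply(aln$seq[, j], function(b) as.numeric(lv == b),
                   numeric(4)))
    X <- cbind(X, oh / sqrt(2))
  }
  N <- nrow(X)
  if (is.null(grp)) grp <- rep("all", N)
  ctr <- function(M) colMeans(M)
  sqn <- function(v) sum(v^2)
  ss_dev <- function(M) sum(sweep(M, 2, ctr(M))^2)
  pops <- unique(pop)
  ss_wp <- sum(vapply(pops, function(p) ss_dev(X[pop == p, , drop = FALSE]),
                      numeric(1)))
  groups <- unique(grp)
  ss_wg <- sum(vapply(groups, function(g) ss_dev(X[grp == g, , drop = FALSE]),
                      numeric(1)))
  ss_tot <- ss_dev(X)
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_tot - ss_wg
  n_p <- as.vector(table(factor(pop, levels = pops)))
  grp_of_pop <- vapply(pops, function(p) grp[pop == p][1], character(1))
  Ng <- vapply(groups, function(g) sum(n_p[grp_of_pop == g]), numeric(1))
  P <- length(pops); G <- length(groups)
  sig_c <- ss_wp / (N - P)
  if (G > 1) {
    sum_np2_over_Ng <- sum(vapply(groups, function(g)
      sum(n_p[grp_of_pop == g]^2) / Ng[groups == g], numeric(1)))
    n1 <- (N - sum_np2_over_Ng) / (P - G)
    n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(Ng^2) / N) / (G - 1)
    sig_b <- (ss_ap / (P - G) - sig_c) / n1
    sig_a <- (ss_ag / (G - 1) - sig_c - n2 * sig_b) / n3
    list(ss = c(ss_ag, ss_ap, ss_wp), sigma = c(sig_a, sig_b, sig_c))
  } else {
    n1 <- (N - sum(n_p^2) / N) / (P - 1)
    sig_b <- (ss_ap / (P - 1) - sig_c) / n1
    list(ss = c(ss_ap, ss_wp), sigma = c(sig_b, sig_c))
  }
}

# Oracle: Kruskal-grouping minimum spanning network (union of all MSTs)
# over a hamming distance matrix, by weight-class component merging.
oracle_msn <- function(D) {
  n <- nrow(D)
  comp <- seq_len(n)
  edges <- NULL
  for (w in sort(unique(D[upper.tri(D)]))) {
    cand <- which(upper.tri(D) & D == w, arr.ind = TRUE)
    keep <- cand[comp[cand[, 1]] != comp[cand[, 2]], , drop = FALSE]
    if (nrow(keep) > 0) edges <- rbind(edges, cbind(keep, w))
    for (r in seq_len(nrow(keep))) {
      a <- comp[keep[r, 1]]; b <- comp[keep[r, 2]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) == 1) break
  }
  edges
}

two_pop_fixed_alignment <- function() {
  # two populations each fixed for a distinct haplotype, 1 difference
  m <- rbind(a1 = c("A", "A", "C"), a2 = c("A", "A", "C"),
             b1 = c("A", "T", "C"), b2 = c("A", "T", "C"))
  hg_alignment(m)
}
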