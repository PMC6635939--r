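# structure: AMOVA, pairwise FST, Mantel.

test_that("AMOVA: two fixed populations give FST = 1 and 100% among", {
  aln <- two_pop_fixed_alignment()
  pm <- simple_map(aln, c("P1", "P1", "P2", "P2"))
  dm <- distance_matrix(aln, metric = "raw")
  res <- amova(dm, pm, n_perm = 0)
  expect_equal(res$indices[["FST"]], 1)
  expect_equal(res$table$percent[1], 100)
  expect_equal(sum(res$table$percent[-nrow(res$table)]), 100, tolerance = 1e-8)
  expect_equal(res$table$df[nrow(res$table)], 3)  # N - 1
})

test_that("AMOVA rejects degenerate inputs", {
  aln <- two_pop_fixed_alignment()
  dm <- distance_matrix(aln, metric = "raw")
  expect_error(amova(dm, simple_map(aln, rep("P1", 4)), n_perm = 0),
               "two populations", class = "haplogeo_input_error")
  ident <- hg_alignment(c(a = "AC", b = "AC", c = "AC", d = "AC"))
  dm0 <- distance_matrix(ident, metric = "raw")
  expect_error(amova(dm0, simple_map(ident, c("P1", "P1", "P2", "P2")),
                     n_perm = 0), "zero", class = "haplogeo_numeric_error")
})

test_that("AMOVA components equal the centroid-embedding oracle", {
  set.seed(31)
  for (rep in 1:8) {
    n_pops <- sample(3:4, 1)
    sizes <- sample(2:4, n_pops, replace = TRUE)
    aln <- random_alignment(sum(sizes), 12)
    pop <- rep(paste0("P", seq_len(n_pops)), sizes)
    grp <- c("G1", "G2")[1 + (seq_len(n_pops) %% 2)][factor(pop)]
    pm <- simple_map(aln, pop, regions = grp)
    dm <- distance_matrix(aln, metric = "raw")
    if (all(dm$mat == 0)) next
    # three-level
    res3 <- amova(dm, pm, grouping = "region", n_perm = 0)
    orc3 <- oracle_amova(aln, pop, grp)
    expect_equal(res3$table$SS[1:3], orc3$ss, tolerance = 1e-9)
    expect_equal(res3$table$variance[1:3], orc3$sigma, tolerance = 1e-9)
    # two-level
    res2 <- amova(dm, pm, n_perm = 0)
    orc2 <- oracle_amova(aln, pop)
    expect_equal(res2$table$SS[1:2], orc2$ss, tolerance = 1e-9)
    expect_equal(res2$table$variance[1:2], orc2$sigma, tolerance = 1e-9)
  }
})

test_that("AMOVA on a hand-built 2-group x 2-pop x 3-seq toy", {
  # groups fixed for blocks of sites: within-pop variation on site 12,
  # pop effect on sites 1-2, group effect on sites 3-6
  m <- rbind(
    a1 = c("A","A","A","A","A","A","C","C","C","C","C","A"),
    a2 = c("A","A","A","A","A","A","C","C","C","C","C","G"),
    a3 = c("A","A","A","A","A","A","C","C","C","C","C","A"),
    b1 = c("T","T","A","A","A","A","C","C","C","C","C","A"),
    b2 = c("T","T","A","A","A","A","C","C","C","C","C","G"),
    b3 = c("T","T","A","A","A","A","C","C","C","C","C","A"),
    c1 = c("A","A","T","T","T","T","C","C","C","C","C","A"),
    c2 = c("A","A","T","T","T","T","C","C","C","C","C","G"),
    c3 = c("A","A","T","T","T","T","C","C","C","C","C","A"),
    d1 = c("T","T","T","T","T","T","C","C","C","C","C","A"),
    d2 = c("T","T","T","T","T","T","C","C","C","C","C","G"),
    d3 = c("T","T","T","T","T","T","C","C","C","C","C","A"))
  aln <- hg_alignment(m)
  pop <- rep(c("PA", "PB", "PC", "PD"), each = 3)
  grp <- rep(c("G1", "G1", "G2", "G2"), each = 3)
  pm <- simple_map(aln, pop, regions = grp)
  dm <- distance_matrix(aln, metric = "raw")
  res <- amova(dm, pm, grouping = "region", n_perm = 0)
  orc <- oracle_amova(aln, pop, grp)
  expect_equal(res$table$variance[1:3], orc$sigma, tolerance = 1e-9)
  expect_equal(res$table$df[1:3], c(1, 2, 8))
  expect_gt(res$indices[["FCT"]], 0)
  expect_gt(res$indices[["FSC"]], 0)
})

test_that("permutation p-values are seeded, bounded and directionally sane", {
  set.seed(32)
  aln <- random_alignment(16, 40)
  pm <- simple_map(aln, rep(c("P1", "P2"), each = 8))
  dm <- distance_matrix(aln, metric = "raw")
  r1 <- amova(dm, pm, n_perm = 99, seed = 9)
  r2 <- amova(dm, pm, n_perm = 99, seed = 9)
  expect_identical(r1$p_values, r2$p_values)  # bit-reproducible
  expect_gte(r1$p_values[["FST"]], 1 / 100)
  expect_lte(r1$p_values[["FST"]], 1)
  # random labels: differentiation should not look significant
  expect_gt(r1$p_values[["FST"]], 0.05)

  # 2 x 5 fixed haplotypes: only 2 of choose(10,5) splits reach the
  # observed FST, so the permutation p must be small
  m <- rbind(matrix("A", 5, 6), matrix(c("A", "A", "A", "T", "T", "T"),
                                       5, 6, byrow = TRUE))
  rownames(m) <- sprintf("s%02d", 1:10)
  strong <- hg_alignment(m)
  pms <- simple_map(strong, rep(c("P1", "P2"), each = 5))
  dms <- distance_matrix(strong, metric = "raw")
  rs <- amova(dms, pms, n_perm = 99, seed = 1)
  expect_lte(rs$p_values[["FST"]], 0.05)
})

test_that("pairwise FST agrees with full AMOVA restricted to the pair", {
  set.seed(33)
  aln <- random_alignment(18, 50)
  pop <- rep(c("P1", "P2", "P3"), each = 6)
  pm <- simple_map(aln, pop)
  dm <- distance_matrix(aln, metric = "raw")
  pw <- suppressWarnings(pairwise_fst(dm, pm, n_perm = 19, seed = 2))
  for (pair in list(c("P1", "P2"), c("P1", "P3"), c("P2", "P3"))) {
    keep <- aln$ids[pop %in% pair]
    sub <- subset_alignment(aln, keep)
    subpm <- simple_map(sub, pop[pop %in% pair])
    ref <- amova(distance_matrix(sub, "raw"), subpm, n_perm = 0)
    expect_equal(pw$fst[pair[1], pair[2]], ref$indices[["FST"]],
                 tolerance = 1e-12)
  }
  # fixed different haplotypes -> FST = 1; identical pops -> ~0, p ~ 1
  alnf <- two_pop_fixed_alignment()
  pmf <- simple_map(alnf, c("P1", "P1", "P2", "P2"))
  pwf <- pairwise_fst(distance_matrix(alnf, "raw"), pmf, n_perm = 19, seed = 1)
  expect_equal(pwf$fst["P1", "P2"], 1)
})

test_that("singleton populations are skipped with a warning", {
  aln <- hg_alignment(c(a = "AAC", b = "AAC", c = "ATC", d = "TTC", e = "TTA"))
  pm <- simple_map(aln, c("P1", "P1", "P2", "P3", "P3"))
  dm <- distance_matrix(aln, "raw")
  expect_warning(pw <- pairwise_fst(dm, pm, n_perm = 9, seed = 1),
                 "singleton")
  expect_true(is.na(pw$fst["P1", "P2"]))
  expect_false(is.na(pw$fst["P1", "P3"]))
})

test_that("Mantel statistic hits the closed-form endpoints", {
  set.seed(34)
  A <- matrix(0, 5, 5)
  A[upper.tri(A)] <- runif(10)
  A <- A + t(A)
  expect_equal(mantel_test(A, A, n_perm = 19, seed = 1)$r, 1)
  expect_equal(mantel_test(A, -A, n_perm = 19, seed = 1)$r, -1)
  B0 <- matrix(1, 5, 5); diag(B0) <- 0
  expect_error(mantel_test(A, B0 * 0, n_perm = 9),
               class = "haplogeo_numeric_error")
})

test_that("Mantel permutation p matches the exhaustive-permutation oracle", {
  set.seed(35)
  A <- matrix(0, 5, 5); A[upper.tri(A)] <- runif(10); A <- A + t(A)
  B <- matrix(0, 5, 5); B[upper.tri(B)] <- runif(10); B <- B + t(B)
  lw <- lower.tri(A)
  r_obs <- cor(A[lw], B[lw])
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  r_all <- apply(perms, 1, function(p) cor(A[lw], B[p, p][lw]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  got <- mantel_test(A, B, n_perm = 4999, seed = 3)
  expect_equal(got$p, p_exact, tolerance = 0.03)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 999)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
})
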