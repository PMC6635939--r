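# haplotypes: collapsing, diversity, GST/NST.

test_that("collapsing groups identical sequences and drops ambiguous columns", {
  two <- hg_alignment(c(a = "ACGT", b = "ACGT"))
  expect_identical(collapse_haplotypes(two)$Nh, 1L)

  # ambiguity in one sequence removes the column for everyone, merging
  # haplotypes that differ only there (complete deletion => transitivity)
  m <- rbind(a = c("A", "C", "G"), b = c("A", "N", "G"), c = c("A", "T", "G"))
  cat <- collapse_haplotypes(hg_alignment(m))
  expect_identical(cat$Nh, 1L)
  expect_identical(cat$retained_sites, c(1L, 3L))

  allN <- hg_alignment(c(a = "NN", b = "NN"))
  expect_error(collapse_haplotypes(allN), class = "haplogeo_numeric_error")
})

test_that("planted haplotype classes are recovered exactly", {
  set.seed(21)
  base <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  haps <- lapply(1:4, function(i) { s <- base; s[i * 3] <- "T"; s })
  assign <- sample(1:4, 30, replace = TRUE)
  m <- do.call(rbind, haps[assign])
  rownames(m) <- sprintf("s%02d", 1:30)
  cat <- collapse_haplotypes(hg_alignment(m))
  key <- vapply(assign, function(i) paste(haps[[i]], collapse = ""), "")
  oracle_classes <- as.integer(factor(key, levels = unique(key)))
  got_classes <- as.integer(factor(cat$assignment,
                                   levels = unique(cat$assignment)))
  expect_identical(got_classes, oracle_classes)
  expect_identical(cat$Nh, length(unique(key)))
  expect_identical(sum(cat$counts), 30L)
})

test_that("haplotype diversity reproduces published table rows", {
  gxlc <- haplotype_diversity(c(2, 2, 1, 1))
  expect_equal(round(gxlc$h, 3), 0.867)
  expect_equal(round(gxlc$sd, 3), 0.129)
  expect_equal(round(haplotype_diversity(c(8, 2, 1, 1))$h, 3), 0.561)
  hbcd <- haplotype_diversity(c(15, 8, 12))
  expect_equal(round(hbcd$h, 3), 0.666)
  expect_equal(round(hbcd$sd, 3), 0.032)
  mono <- haplotype_diversity(c(4))
  expect_equal(mono$h, 0)
  expect_equal(mono$sd, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  expect_error(haplotype_diversity(c(1)), class = "haplogeo_numeric_error")
})

test_that("h matches the unordered-pair brute-force oracle", {
  set.seed(22)
  for (rep in 1:15) {
    counts <- sample(1:6, sample(2:5, 1), replace = TRUE)
    got <- haplotype_diversity(counts)$h
    expect_equal(got, oracle_h_pairs(counts), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("pooled diversity over the bundled survey matches the reported totals", {
  cat <- punctatus_coi_counts()
  expect_identical(cat$N, 236L)
  expect_identical(cat$Nh, 51L)
  pd <- pooled_diversity(cat)
  expect_equal(round(pd$h, 3), 0.952)
  expect_equal(max(pd$pooled_counts), 33)
  expect_identical(names(which.max(pd$pooled_counts)), "H2")
  expect_equal(sum(pd$pooled_counts == 1), 18)
  # per-population rows straight from the count matrix
  expect_equal(round(haplotype_diversity(cat$counts["GXLC", ])$h, 3), 0.867)
  expect_equal(haplotype_diversity(cat$counts["SCLX", ])$h, 0)
})

test_that("pooled diversity of a single-population catalog is that population's h", {
  cat <- catalog_from_counts(matrix(c(3L, 2L, 1L), 1,
                                    dimnames = list("P1", c("H1", "H2", "H3"))))
  expect_equal(pooled_diversity(cat)$h, haplotype_diversity(c(3, 2, 1))$h)
})

test_that("nucleotide diversity matches hand-enumerated pairs and is order-invariant", {
  expect_equal(nucleotide_diversity(aln4()), (10 / 6) / 4, tolerance = 1e-12)
  ident <- hg_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(nucleotide_diversity(ident), 0)
  set.seed(23)
  aln <- random_alignment(8, 30)
  shuffled <- hg_alignment(aln$seq[sample(8), , drop = FALSE])
  expect_equal(nucleotide_diversity(aln), nucleotide_diversity(shuffled))
  expect_error(nucleotide_diversity(hg_alignment(c(a = "ACGT"))),
               class = "haplogeo_numeric_error")
})

make_two_clade_catalog <- function() {
  # two regions fixed for distinct clades of mutually similar haplotypes
  haps <- c(H1 = "AAAAAAAAAA", H2 = "AAAAAAAAAT", H3 = "AAAAAAAATT",
            H4 = "TTTTTTTTAA", H5 = "TTTTTTTTAT", H6 = "TTTTTTTTTT")
  counts <- rbind(P1 = c(4L, 3L, 3L, 0L, 0L, 0L),
                  P2 = c(3L, 4L, 3L, 0L, 0L, 0L),
                  P3 = c(0L, 0L, 0L, 4L, 3L, 3L),
                  P4 = c(0L, 0L, 0L, 3L, 4L, 3L))
  colnames(counts) <- names(haps)
  cat <- catalog_from_counts(counts)
  cat$seqs <- haps
  cat
}

test_that("GST/NST: frequency-identical populations carry no differentiation signal", {
  # with the small-sample corrections the point estimate on fixed equal
  # counts is slightly negative (HS is unbiased per population, HT mixes
  # in the plug-in pooled term); the estimator is unbiased around 0
  # under multinomial resampling of the same world
  counts <- rbind(P1 = c(5L, 5L), P2 = c(5L, 5L), P3 = c(5L, 5L))
  colnames(counts) <- c("H1", "H2")
  cat <- catalog_from_counts(counts)
  D <- matrix(c(0, 2, 2, 0), 2)
  res <- gst_nst(cat, hap_dm = D, n_perm = 49, seed = 1)
  expect_lte(res$GST, 0)
  expect_gte(res$GST, -0.12)
  expect_equal(res$NST, res$GST, tolerance = 1e-10)
  set.seed(26)
  gsts <- vapply(1:300, function(i) {
    cm <- t(stats::rmultinom(3, 10, c(0.5, 0.5)))
    dimnames(cm) <- list(paste0("P", 1:3), c("H1", "H2"))
    gst_nst(catalog_from_counts(cm), hap_dm = D, n_perm = 0)$GST
  }, numeric(1))
  expect_equal(mean(gsts), 0, tolerance = 0.03)
})

test_that("GST/NST: equal inter-haplotype distances force NST = GST", {
  set.seed(24)
  for (rep in 1:5) {
    H <- sample(3:6, 1); P <- sample(2:4, 1)
    counts <- matrix(rpois(H * P, 3) + 1L, P, H,
                     dimnames = list(paste0("P", 1:P), paste0("H", 1:H)))
    cat <- catalog_from_counts(counts)
    D <- matrix(1, H, H); diag(D) <- 0
    res <- gst_nst(cat, hap_dm = D, n_perm = 0, seed = 1)
    expect_equal(res$NST, res$GST, tolerance = 1e-10)
  }
})

test_that("GST/NST: two-clade geography yields NST > GST with small p", {
  cat <- make_two_clade_catalog()
  res <- gst_nst(cat, n_perm = 999, seed = 5)
  expect_gt(res$NST, res$GST)
  expect_lt(res$p_nst_gt_gst, 0.05)
  expect_true(res$HS <= res$HT + 1e-9)
})

test_that("NST - GST permutation p-value is well calibrated under the null", {
  # exchangeable world: haplotype distances carry no information because
  # they are i.i.d. across haplotype pairs, independent of geography
  set.seed(25)
  pvals <- vapply(1:40, function(i) {
    counts <- matrix(rpois(4 * 6, 2) + 1L, 4, 6,
                     dimnames = list(paste0("P", 1:4), paste0("H", 1:6)))
    D <- matrix(0, 6, 6)
    D[upper.tri(D)] <- sample(1:9, 15, replace = TRUE)
    D <- D + t(D)
    gst_nst(catalog_from_counts(counts), hap_dm = D, n_perm = 99)$p_nst_gt_gst
  }, numeric(1))
  # add-one p-values live on {1/100, ..., 1}; check uniform-ish coverage
  expect_gt(min(pvals), 0)
  expect_lt(mean(pvals < 0.25), 0.5)
  expect_gt(mean(pvals < 0.5), 0.2)
})

test_that("catalog export round-trips counts", {
  cat <- punctatus_coi_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
  expect_equal(as.matrix(back), cat$counts, ignore_attr = TRUE)
})
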