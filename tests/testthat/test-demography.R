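# demography: neutrality tests, mismatch machinery, expansion time.

test_that("Tajima's D matches an independent step-by-step oracle", {
  aln <- aln4()
  got <- tajimas_d(aln, n_sim = 0)
  # oracle: textbook constants computed from scratch
  n <- 4; S <- 3
  kbar <- mean(c(1, 2, 3, 1, 2, 1))  # enumerated pairwise differences
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  D_oracle <- (kbar - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  expect_equal(got$D, D_oracle, tolerance = 1e-12)
  expect_equal(round(got$D, 3), 0.168)
  expect_equal(got$theta_pi, 5 / 3)
})

test_that("Tajima's D requires segregating sites and n >= 4", {
  mono <- hg_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_error(tajimas_d(mono, n_sim = 0), class = "haplogeo_numeric_error")
  expect_error(tajimas_d(hg_alignment(c(a = "AT", b = "AA", c = "AT")),
                         n_sim = 0), class = "haplogeo_input_error")
})

test_that("neutral simulations centre D near 0 with ~nominal rejections", {
  # reduced replicate counts to stay inside the test budget
  set.seed(81)
  sims <- replicate(150, {
    cfg <- sim_config("D1", 12, theta = 3, seq_length = 400,
                      seed = sample.int(1e6, 1))
    tajimas_d(simulate_dataset(cfg)$alignment, n_sim = 0)$D
  })
  expect_lt(abs(mean(sims)), 0.25)
  aln <- simulate_dataset(sim_config("D1", 15, theta = 3, seq_length = 400,
                                     seed = 99))$alignment
  res <- tajimas_d(aln, n_sim = 400, seed = 1)
  expect_gt(res$p, 0.05)  # neutral data should not reject
})

test_that("Fu's Fs reproduces the explicit Ewens enumeration", {
  a3 <- hg_alignment(c(x = "AA", y = "AT", z = "AT"))  # alleles (2,1)
  got <- fus_fs(a3, n_sim = 0)
  # oracle: P(K >= 2 | theta = 2/3, n = 3) by direct Ewens enumeration:
  # theta(theta+1)(theta+2) = 80/27; P(K=2) = 3 theta^2 / ..., P(K=3) = theta^3 / ...
  theta <- 2 / 3
  denom <- theta * (theta + 1) * (theta + 2)
  expect_equal(denom, 80 / 27)
  sp <- (3 * theta^2 + theta^3) / denom
  expect_equal(sp, 0.55)
  expect_equal(got$Fs, log(sp / (1 - sp)), tolerance = 1e-10)
  expect_equal(round(got$Fs, 3), 0.201)
  expect_error(fus_fs(hg_alignment(c(a = "AA", b = "AA", c = "AA")),
                      n_sim = 0), class = "haplogeo_numeric_error")
})

test_that("a star genealogy drives Fs strongly negative", {
  # many singleton haplotypes radiating from one centre
  center <- strrep("A", 60)
  seqs <- c(center, vapply(1:14, function(i) {
    s <- strsplit(center, "")[[1]]; s[i] <- "T"; paste(s, collapse = "")
  }, character(1)))
  names(seqs) <- sprintf("s%02d", 0:14)
  res <- fus_fs(hg_alignment(seqs), n_sim = 200, seed = 3)
  expect_lt(res$Fs, -3)
  expect_lt(res$p, 0.05)
})

test_that("mismatch histogram enumerates unordered pairs", {
  h <- mismatch_observed(aln4())
  expect_identical(h, stats::setNames(c(0L, 3L, 2L, 1L), 0:3))
  expect_equal(sum(h), choose(4, 2))
  ident <- hg_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  hi <- mismatch_observed(ident)
  expect_equal(sum(hi), 3L)
  expect_identical(hi[["0"]], 3L)
  set.seed(82)
  aln <- random_alignment(9, 20)
  expect_equal(sum(mismatch_observed(aln)), choose(9, 2))
})

test_that("sudden-expansion expectation normalizes and hits its limits", {
  for (pars in list(c(3, 1, 100), c(0.5, 0.01, 5), c(10, 2, 50))) {
    f <- expected_mismatch(400, pars[1], pars[2], pars[3])
    expect_equal(sum(f), 1, tolerance = 1e-6)
    expect_true(all(f >= 0))
  }
  # tau = 0 collapses to the theta0 equilibrium
  expect_equal(expected_mismatch(50, 0, 1, 100),
               1^(0:50) / (1 + 1)^(1:51), tolerance = 1e-12)
})

test_that("raggedness follows the appended-zero convention", {
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  expect_equal(raggedness(1), 1)  # single class: (0 - 1)^2
  expect_gte(raggedness(runif(5)), 0)
})

test_that("fitting the exact expectation recovers tau with ~zero SSD", {
  f <- expected_mismatch(40, tau = 3, theta0 = 1, theta1 = 100)
  counts <- round(f * 1e6)
  fit <- fit_sudden_expansion(counts, n_boot = 0)
  expect_lt(fit$ssd, 1e-6)
  expect_equal(fit$tau, 3, tolerance = 0.05)
})

test_that("fit output respects the declared invariants", {
  set.seed(83)
  cfg <- sim_config("D1", 40, theta = 8, t_expansion = 0.6,
                    expansion_ratio = 0.02, seq_length = 500, seed = 17)
  aln <- simulate_dataset(cfg)$alignment
  fit <- fit_sudden_expansion(mismatch_observed(aln), n_boot = 30, seed = 2)
  expect_gte(fit$tau, 0)
  expect_lte(fit$theta0, fit$theta1)
  expect_equal(sum(fit$observed), 1, tolerance = 1e-9)
  expect_gte(fit$p_ssd, 1 / 31)
  expect_lte(fit$p_ssd, 1)
  expect_gte(fit$raggedness, 0)
})

test_that("expansion-time conversion matches the published endpoints", {
  expect_equal(round(expansion_time(3.262, 1.15e-8, 586, 1)$t_mya, 3), 0.242)
  expect_equal(round(expansion_time(3.262, 1.77e-8, 586, 1)$t_mya, 3), 0.157)
  expect_equal(round(expansion_time(4.826, 1.15e-8, 586, 1)$t_mya, 3), 0.358)
  expect_equal(expansion_time(0, 1e-8, 500, 1)$t_years, 0)
  expect_error(expansion_time(1, 0, 500, 1), class = "haplogeo_input_error")
  expect_error(expansion_time(1, 1e-8, 500, -1), class = "haplogeo_input_error")
})

test_that("expansion time is linear in tau and inversely linear in mu, k, g", {
  set.seed(84)
  for (rep in 1:10) {
    tau <- runif(1, 0.5, 8); mu <- runif(1, 1e-9, 1e-7)
    k <- sample(200:1000, 1); g <- runif(1, 0.5, 3)
    base <- expansion_time(tau, mu, k, g)$t_years
    expect_equal(expansion_time(2 * tau, mu, k, g)$t_years, 2 * base)
    expect_equal(expansion_time(tau, 2 * mu, k, g)$t_years, base / 2)
    expect_equal(expansion_time(tau, mu, 2 * k, g)$t_years, base / 2)
    expect_equal(expansion_time(tau, mu, k, 2 * g)$t_years, base / 2)
  }
})
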