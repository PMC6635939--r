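# demography: neutrality tests, mismatch distributions, sudden-expansion
# fitting, expansion-time conversion.

# ---- shared coalescent machinery -------------------------------------

# Kingman coalescent genealogy for n lineages in a single panmictic
# population, with an optional instantaneous size change: looking back,
# beyond time t_change the population is rho times its current size
# (rho < 1 = expansion happened t_change ago). Time is in units of the
# current population's coalescent time scale. Returns the 2n-2 branches
# as leaf sets with lengths.
sim_coal_tree <- function(n, t_change = Inf, rho = 1) {
  sets <- as.list(seq_len(n))
  born <- rep(0, n)
  t <- 0
  branches <- vector("list", 2L * (n - 1L))
  lens <- numeric(2L * (n - 1L))
  nb <- 0L
  m <- n
  while (m > 1L) {
    rate <- m * (m - 1) / 2 * (if (t < t_change) 1 else 1 / rho)
    dt <- stats::rexp(1, rate)
    if (t < t_change && t + dt > t_change) {
      t <- t_change
      next
    }
    t <- t + dt
    pick <- sample.int(m, 2L)
    i <- pick[1]; j <- pick[2]
    for (v in c(i, j)) {
      nb <- nb + 1L
      branches[[nb]] <- sets[[v]]
      lens[nb] <- t - born[v]
    }
    sets[[i]] <- c(sets[[i]], sets[[j]])
    born[i] <- t
    sets[[j]] <- NULL
    born <- born[-j]
    m <- m - 1L
  }
  list(leafsets = branches, lengths = lens, n = n)
}

# Drop Poisson(theta/2 * length) mutations on each branch; returns the
# per-branch mutation counts.
drop_mutations <- function(tree, theta) {
  stats::rpois(length(tree$lengths), theta / 2 * tree$lengths)
}

# Summaries of a mutated genealogy under infinite sites.
tree_summaries <- function(tree, muts) {
  n <- tree$n
  sizes <- lengths(tree$leafsets)
  S <- sum(muts)
  kbar <- sum(muts * sizes * (n - sizes)) / (n * (n - 1) / 2)
  sig <- rep("", n)
  hit <- which(muts > 0L)
  for (b in hit) {
    ls <- tree$leafsets[[b]]
    sig[ls] <- paste0(sig[ls], ",", b)
  }
  list(S = S, kbar = kbar, K = length(unique(sig)))
}

# Pairwise-difference matrix implied by a mutated genealogy.
tree_pairdiffs <- function(tree, muts) {
  n <- tree$n
  D <- matrix(0L, n, n)
  for (b in which(muts > 0L)) {
    ind <- rep(0L, n)
    ind[tree$leafsets[[b]]] <- 1L
    D <- D + muts[b] * abs(outer(ind, ind, "-"))
  }
  D
}

# ---- Tajima's D -------------------------------------------------------

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_value <- function(n, S, kbar) {
  cc <- tajima_constants(n)
  denom <- sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
  (kbar - S / cc$a1) / denom
}

#' Tajima's D with a simulation p-value
#'
#' D contrasts the mean pairwise difference with the scaled number of
#' segregating sites. Significance is the two-tailed fraction of neutral
#' constant-size coalescent simulations (conditioned on n, with theta =
#' S/a1) whose |D| is at least the observed |D|.
#'
#' @param aln An [hg_alignment()].
#' @param n_sim Number of coalescent simulations (0 skips the p-value).
#' @param seed Optional RNG seed.
#' @return List with `D`, `p`, `n`, `S`, `theta_pi` (mean pairwise
#'   differences), `n_sim`.
#' @export
tajimas_d <- function(aln, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(aln, "hg_alignment"))
  n <- length(aln$ids)
  if (n < 4L) hg_input_error("Tajima's D requires n >= 4")
  S <- site_summary(aln)$S
  if (S < 1L) hg_numeric_error("no segregating sites: D undefined")
  hg_seed(seed)
  dm <- distance_matrix(aln, metric = "raw")
  kbar <- mean(dm$mat[lower.tri(dm$mat)])
  D <- tajima_d_value(n, S, kbar)
  p <- NA_real_
  if (n_sim > 0) {
    theta <- S / tajima_constants(n)$a1
    hits <- 0L; valid <- 0L
    for (b in seq_len(n_sim)) {
      tr <- sim_coal_tree(n)
      mu <- drop_mutations(tr, theta)
      sm <- tree_summaries(tr, mu)
      if (sm$S < 1L) next
      valid <- valid + 1L
      if (abs(tajima_d_value(n, sm$S, sm$kbar)) >= abs(D) - 1e-12)
        hits <- hits + 1L
    }
    p <- perm_pvalue(hits, valid)
  }
  list(D = D, p = p, n = n, S = S, theta_pi = kbar, n_sim = n_sim)
}

# ---- Fu's Fs ----------------------------------------------------------

# log unsigned Stirling numbers of the first kind, |S(n, k)| for k = 1..n.
log_stirling1 <- function(n) {
  row <- 0  # |S(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 2:n) {
    prev <- c(-Inf, row, -Inf)  # pad k = 0 and k = m
    new <- numeric(m)
    for (k in seq_len(m)) {
      a <- log(m - 1) + prev[k + 1]  # (m-1) |S(m-1, k)|
      b <- prev[k]                   # |S(m-1, k-1)|
      new[k] <- logsumexp(c(a, b))
    }
    row <- new
  }
  row
}

# P(K >= k_obs) under the Ewens sampling formula with parameter theta.
ewens_tail <- function(n, k_obs, theta, lst = log_stirling1(n)) {
  if (theta <= 0) return(if (k_obs <= 1L) 1 else 0)
  lp <- lst + seq_len(n) * log(theta)
  lp <- lp - logsumexp(lp)  # normalizes: sum_k |S(n,k)| theta^k = theta^(n)
  sum(exp(lp[k_obs:n]))
}

fs_value <- function(n, k_obs, theta, lst = log_stirling1(n)) {
  sp <- ewens_tail(n, k_obs, theta, lst)
  if (sp >= 1) return(-Inf)
  if (sp <= 0) return(Inf)
  log(sp / (1 - sp))
}

#' Fu's Fs with a simulation p-value
#'
#' Fs = ln(S'/(1-S')) where S' is the Ewens-sampling-formula probability
#' of observing at least the observed number of distinct haplotypes given
#' theta = theta_pi (mean pairwise differences). Large negative values
#' signal an excess of rare haplotypes, the footprint of expansion.
#' Significance is the fraction of neutral coalescent simulations with
#' Fs at most the observed value.
#'
#' @param aln An [hg_alignment()].
#' @param n_sim Number of simulations (0 skips the p-value).
#' @param seed Optional RNG seed.
#' @return List with `Fs`, `p`, `n`, `K` (haplotype count), `theta_pi`,
#'   `n_sim`.
#' @export
fus_fs <- function(aln, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(aln, "hg_alignment"))
  n <- length(aln$ids)
  if (n < 3L) hg_input_error("Fu's Fs requires n >= 3")
  if (site_summary(aln)$S < 1L)
    hg_numeric_error("no segregating sites: Fs undefined")
  hg_seed(seed)
  dm <- distance_matrix(aln, metric = "raw")
  theta <- mean(dm$mat[lower.tri(dm$mat)])
  K <- collapse_haplotypes(aln)$Nh
  lst <- log_stirling1(n)
  Fs <- fs_value(n, K, theta, lst)
  p <- NA_real_
  if (n_sim > 0) {
    hits <- 0L
    for (b in seq_len(n_sim)) {
      tr <- sim_coal_tree(n)
      mu <- drop_mutations(tr, theta)
      sm <- tree_summaries(tr, mu)
      fsb <- fs_value(n, sm$K, sm$kbar, lst)
      if (fsb <= Fs + 1e-12) hits <- hits + 1L
    }
    p <- perm_pvalue(hits, n_sim)
  }
  list(Fs = Fs, p = p, n = n, K = K, theta_pi = theta, n_sim = n_sim)
}

# ---- mismatch distribution -------------------------------------------

#' Observed mismatch distribution
#'
#' Histogram of raw pairwise difference counts over all unordered pairs.
#'
#' @param x An [hg_alignment()] or an `hg_distmatrix` with raw metric.
#' @return Integer vector of counts named "0", "1", ..., up to the
#'   maximum observed difference.
#' @export
mismatch_observed <- function(x) {
  if (inherits(x, "hg_alignment")) {
    if (length(x$ids) < 2L) hg_input_error("need >= 2 sequences")
    x <- distance_matrix(x, metric = "raw")
  }
  stopifnot(inherits(x, "hg_distmatrix"))
  d <- x$mat[lower.tri(x$mat)]
  d <- round(d)
  tab <- tabulate(d + 1L, nbins = max(d) + 1L)
  stats::setNames(tab, 0:max(d))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The classical closed form for the distribution of pairwise differences
#' j after an instantaneous expansion from theta0 to theta1 at mutational
#' time tau:
#' F_j = Fhat_j(theta1) + exp(-tau (theta1+1)/theta1) *
#'       sum_i tau^(j-i)/(j-i)! (Fhat_i(theta0) - Fhat_i(theta1)),
#' with Fhat the geometric equilibrium distribution.
#'
#' @param j_max Largest difference class.
#' @param tau Scaled expansion time (>= 0).
#' @param theta0,theta1 Pre-/post-expansion population-mutation
#'   parameters, 0 <= theta0 <= theta1, theta1 > 0.
#' @return Numeric vector of probabilities for j = 0..j_max.
#' @export
expected_mismatch <- function(j_max, tau, theta0, theta1) {
  if (tau < 0 || theta0 < 0 || theta1 <= 0 || theta0 > theta1)
    hg_input_error("need tau >= 0 and 0 <= theta0 <= theta1, theta1 > 0")
  j <- 0:j_max
  fhat <- function(th) {
    if (th == 0) return(c(1, rep(0, j_max)))
    exp(j * log(th) - (j + 1) * log(1 + th))
  }
  F1 <- fhat(theta1)
  diffs <- fhat(theta0) - F1
  if (tau == 0) return(pmax(F1 + diffs, 0))
  # e^{-tau(theta1+1)/theta1} tau^m/m! = e^{-tau/theta1} Pois(m; tau):
  # numerically stable for any tau, and the sum over i is a convolution
  pois <- stats::dpois(j, tau)
  conv <- stats::convolve(diffs, rev(pois), type = "open")[seq_len(j_max + 1)]
  pmax(F1 + exp(-tau / theta1) * conv, 0)
}

#' Harpending's raggedness index
#'
#' r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2 over the relative frequencies of
#' the difference classes, with an appended zero class x_{d+1} = 0
#' (conventions differ across software; this one is documented and used
#' consistently, including in bootstrap replicates).
#'
#' @param freqs Relative frequencies of difference classes 0..d.
#' @return Numeric raggedness.
#' @export
raggedness <- function(freqs) {
  x <- c(freqs, 0)
  sum(diff(x)^2)
}

# Parameters live on the log scale with hard caps: beyond a few times
# the observed difference range, tau and theta1 are indistinguishable
# from infinity on the SSD surface, and an unbounded optimizer can run
# away to astronomical values (which would also make the parametric
# bootstrap simulate absurdly diverse data).
fit_par_transform <- function(par_log, d) {
  tau <- min(exp(par_log[1]), 10 * (d + 1))
  theta0 <- min(exp(par_log[2]), 10 * (d + 1))
  theta1 <- theta0 + min(exp(par_log[3]), 50 * (d + 1))
  c(tau, theta0, theta1)
}

fit_ssd <- function(obs_freq, par_log) {
  d <- length(obs_freq) - 1L
  p <- fit_par_transform(par_log, d)
  f <- expected_mismatch(d, p[1], p[2], p[3])
  sum((obs_freq - f)^2)
}

fit_expansion_core <- function(hist_counts) {
  obs <- hist_counts / sum(hist_counts)
  d <- length(obs) - 1L
  grid_tau <- c(0.05, seq(0.25, max(1, 1.5 * d), length.out = 10))
  grid_t0 <- c(0.01, 0.5, 2)
  grid_t1 <- c(1, 10, 100, 1000)
  best <- NULL; best_val <- Inf
  for (ta in grid_tau) for (t0 in grid_t0) for (t1 in grid_t1) {
    if (t0 >= t1) next
    v <- fit_ssd(obs, log(c(ta, t0, t1 - t0)))
    if (v < best_val) { best_val <- v; best <- log(c(ta, t0, t1 - t0)) }
  }
  opt <- stats::optim(best, function(p) fit_ssd(obs, p),
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-10))
  p <- fit_par_transform(opt$par, d)
  list(tau = p[1], theta0 = p[2], theta1 = p[3], ssd = opt$value,
       raggedness = raggedness(obs), converged = opt$convergence == 0)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) to the observed relative
#' frequencies (coarse grid followed by Nelder-Mead on log-scale
#' parameters), with parametric-bootstrap p-values for the sum of squared
#' deviations (SSD) and Harpending's raggedness r: data are re-simulated
#' under the fitted model (coalescent with instantaneous size change),
#' refitted, and the p-value is the fraction of replicates whose
#' statistic is at least the observed one.
#'
#' @param hist_counts Observed mismatch histogram (counts for classes
#'   0..d), e.g. from [mismatch_observed()].
#' @param n_boot Parametric bootstrap replicates (0 skips p-values).
#' @param seed Optional RNG seed.
#' @return Object of class `hg_mismatchfit`: `tau`, `theta0`, `theta1`,
#'   `ssd`, `raggedness`, `p_ssd`, `p_raggedness`, `observed`
#'   (relative frequencies), `expected`, `n`, `n_boot`, `converged`.
#' @export
fit_sudden_expansion <- function(hist_counts, n_boot = 1000, seed = NULL) {
  if (length(hist_counts) == 0L || sum(hist_counts) == 0)
    hg_input_error("empty mismatch histogram")
  hg_seed(seed)
  n_pairs <- sum(hist_counts)
  n <- round((1 + sqrt(1 + 8 * n_pairs)) / 2)
  fit <- fit_expansion_core(hist_counts)
  obs <- hist_counts / n_pairs
  expd <- expected_mismatch(length(obs) - 1L, fit$tau, fit$theta0, fit$theta1)
  p_ssd <- NA_real_; p_rag <- NA_real_
  if (n_boot > 0) {
    if (!fit$converged) hg_log("optimizer flagged non-convergence; best-found parameters used")
    t_change <- fit$tau / fit$theta1
    rho <- max(fit$theta0 / fit$theta1, 1e-6)
    hits_ssd <- 0L; hits_rag <- 0L
    for (b in seq_len(n_boot)) {
      tr <- sim_coal_tree(n, t_change = t_change, rho = rho)
      mu <- drop_mutations(tr, fit$theta1)
      Db <- tree_pairdiffs(tr, mu)
      db <- Db[lower.tri(Db)]
      hb <- tabulate(db + 1L, nbins = max(db) + 1L)
      fb <- fit_expansion_core(hb)
      if (fb$ssd >= fit$ssd - 1e-12) hits_ssd <- hits_ssd + 1L
      if (fb$raggedness >= fit$raggedness - 1e-12) hits_rag <- hits_rag + 1L
    }
    p_ssd <- perm_pvalue(hits_ssd, n_boot)
    p_rag <- perm_pvalue(hits_rag, n_boot)
  }
  structure(list(tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
                 ssd = fit$ssd, raggedness = fit$raggedness,
                 p_ssd = p_ssd, p_raggedness = p_rag,
                 observed = obs, expected = expd, n = n, n_boot = n_boot,
                 converged = fit$converged),
            class = "hg_mismatchfit")
}

#' @export
print.hg_mismatchfit <- function(x, ...) {
  cat(sprintf(
    "<hg_mismatchfit> tau = %.3f  theta0 = %.3g  theta1 = %.3g  SSD = %.4g (p = %.3g)  r = %.4g (p = %.3g)\n",
    x$tau, x$theta0, x$theta1, x$ssd, x$p_ssd, x$raggedness,
    x$p_raggedness))
  invisible(x)
}

#' Parametric bootstrap confidence interval for tau
#'
#' Re-simulates data under the fitted sudden-expansion model, refits each
#' replicate, and returns quantiles of the refitted tau values.
#'
#' @param fit An `hg_mismatchfit`.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional RNG seed.
#' @return List with `lower`, `upper`, `tau_boot`.
#' @export
tau_bootstrap_ci <- function(fit, n_boot = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "hg_mismatchfit"))
  hg_seed(seed)
  t_change <- fit$tau / fit$theta1
  rho <- max(fit$theta0 / fit$theta1, 1e-6)
  taus <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tr <- sim_coal_tree(fit$n, t_change = t_change, rho = rho)
    mu <- drop_mutations(tr, fit$theta1)
    Db <- tree_pairdiffs(tr, mu)
    db <- Db[lower.tri(Db)]
    hb <- tabulate(db + 1L, nbins = max(db) + 1L)
    taus[b] <- fit_expansion_core(hb)$tau
  }
  qs <- stats::quantile(taus, c((1 - level) / 2, 1 - (1 - level) / 2))
  list(lower = qs[[1]], upper = qs[[2]], tau_boot = taus)
}

# ---- expansion time ---------------------------------------------------

#' Convert a fitted tau to an expansion time
#'
#' t = tau / (2u) with u = mu * k * g: mu the substitution rate per site
#' per year, k the sequence length in sites, g the generation time in
#' years.
#'
#' @param tau Fitted expansion parameter (>= 0).
#' @param mu Substitutions per site per year (> 0).
#' @param k Average sequence length in sites (> 0).
#' @param g Generation time in years (> 0).
#' @return List with `t_years`, `t_mya`, `tau`, `u`, `mu`, `k`, `g`.
#' @export
expansion_time <- function(tau, mu, k, g = 1) {
  if (tau < 0) hg_input_error("tau must be >= 0")
  if (mu <= 0 || k <= 0 || g <= 0)
    hg_input_error("mu, k and g must all be positive")
  u <- mu * k * g
  t_years <- tau / (2 * u)
  list(t_years = t_years, t_mya = t_years / 1e6, tau = tau, u = u,
       mu = mu, k = k, g = g)
}
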