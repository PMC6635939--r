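# synthetic_data: structured-coalescent simulator producing alignments
# and population maps with a controllable two-group, post-expansion
# population structure.

#' Build a simulation configuration
#'
#' Describes an island-model structured coalescent with two groups of
#' demes, optional instantaneous population expansion, and K2P-style
#' finite-sites mutation.
#'
#' @param demes Character vector of deme names.
#' @param samples Integer vector of sample counts per deme.
#' @param groups Group label per deme (at most two distinct values).
#' @param theta Scaled per-locus mutation parameter on the current
#'   population scale; the expected pairwise difference count within a
#'   panmictic constant-size population equals `theta`.
#' @param mig_within Scaled migration rate between demes of the same
#'   group (`Inf` = panmixia within the group).
#' @param mig_between Scaled migration rate between demes of different
#'   groups (must be > 0 when both groups are sampled).
#' @param t_expansion Time of an instantaneous expansion, in coalescent
#'   units of the current size; `NULL` for constant size.
#' @param expansion_ratio Ancestral/current size ratio (< 1 means the
#'   population expanded at `t_expansion`).
#' @param seq_length Number of sites.
#' @param tstv Transition/transversion rate ratio kappa; a mutation is a
#'   transition with probability kappa/(kappa + 2).
#' @param coords Optional data frame `population, lat, lon`; default is a
#'   deterministic west/east grid matching the two groups.
#' @param seed RNG seed stored with the configuration.
#' @return List of class `hg_simconfig`.
#' @export
sim_config <- function(demes, samples, groups = rep("G1", length(demes)),
                       theta = 2, mig_within = 5, mig_between = 0.5,
                       t_expansion = NULL, expansion_ratio = 1,
                       seq_length = 586, tstv = 5, coords = NULL,
                       seed = 1L) {
  if (length(demes) == 0L || length(samples) != length(demes) ||
      length(groups) != length(demes))
    hg_input_error("demes, samples and groups must have equal length")
  if (any(samples < 1L)) hg_input_error("every deme needs >= 1 sample")
  if (length(unique(groups)) > 2L)
    hg_input_error("at most two groups are supported")
  if (theta <= 0 || seq_length < 1 || tstv <= 0)
    hg_input_error("theta, seq_length and tstv must be positive")
  if (mig_within < 0 || mig_between < 0)
    hg_input_error("migration rates must be >= 0")
  if (length(unique(groups)) == 2L && mig_between == 0)
    hg_input_error("mig_between must be > 0 when two groups are sampled")
  if (!is.null(t_expansion) &&
      (t_expansion <= 0 || expansion_ratio <= 0))
    hg_input_error("t_expansion and expansion_ratio must be positive")
  if (is.null(coords)) {
    glev <- unique(groups)
    xo <- stats::setNames(c(100, 114)[seq_along(glev)], glev)
    pos <- stats::ave(seq_along(demes), groups, FUN = seq_along)
    coords <- data.frame(population = demes,
                         lat = 24 + 0.8 * (pos %% 4),
                         lon = unname(xo[groups]) + 1.3 * pos)
  }
  structure(list(demes = as.character(demes), samples = as.integer(samples),
                 groups = as.character(groups), theta = theta,
                 mig_within = mig_within, mig_between = mig_between,
                 t_expansion = t_expansion,
                 expansion_ratio = expansion_ratio,
                 seq_length = as.integer(seq_length), tstv = tstv,
                 coords = coords, seed = as.integer(seed)),
            class = "hg_simconfig")
}

# Structured-coalescent genealogy under the configured island model.
# Returns branches (leafsets + lengths + birth/death times) for mutation
# placement.
sim_structured_tree <- function(cfg) {
  n_tot <- sum(cfg$samples)
  deme_of <- rep(seq_along(cfg$demes), cfg$samples)
  grp <- cfg$groups
  panmictic <- is.infinite(cfg$mig_within) &&
    (length(unique(grp)) == 1L || is.infinite(cfg$mig_between))
  if (panmictic) deme_of <- rep(1L, n_tot)
  sets <- as.list(seq_len(n_tot))
  born <- rep(0, n_tot)
  t <- 0
  t_change <- if (is.null(cfg$t_expansion)) Inf else cfg$t_expansion
  rho <- cfg$expansion_ratio
  branches <- vector("list", 2L * (n_tot - 1L))
  lens <- numeric(2L * (n_tot - 1L)); starts <- numeric(2L * (n_tot - 1L))
  nb <- 0L
  cur_deme <- deme_of
  ngrp <- if (panmictic) 1L else length(unique(grp))
  demes_in_grp <- if (panmictic) list(1L) else split(seq_along(cfg$demes), grp)
  grp_of_deme <- if (panmictic) rep(1L, 1) else match(grp, names(demes_in_grp))
  guard <- 0L
  while (length(sets) > 1L) {
    guard <- guard + 1L
    if (guard > 5e6) hg_numeric_error("coalescent failed to complete (migration too low?)")
    m_d <- tabulate(cur_deme, nbins = if (panmictic) 1L else length(cfg$demes))
    sfac <- if (t < t_change) 1 else 1 / rho
    coal_d <- m_d * (m_d - 1) / 2 * sfac
    coal_tot <- sum(coal_d)
    n_lin <- length(sets)
    if (panmictic) {
      mig_tot <- 0
    } else {
      rate_w <- vapply(cur_deme, function(d) {
        if (length(demes_in_grp[[grp_of_deme[d]]]) > 1L && is.finite(cfg$mig_within))
          cfg$mig_within / 2 else 0
      }, numeric(1))
      rate_b <- if (ngrp > 1L) rep(cfg$mig_between / 2, n_lin) else rep(0, n_lin)
      mig_tot <- sum(rate_w) + sum(rate_b)
    }
    total <- coal_tot + mig_tot
    if (total <= 0) hg_numeric_error("no feasible events: lineages isolated")
    dt <- stats::rexp(1, total)
    if (t < t_change && t + dt > t_change) { t <- t_change; next }
    t <- t + dt
    if (stats::runif(1) < coal_tot / total) {
      d <- sample.int(length(coal_d), 1L, prob = coal_d)
      here <- which(cur_deme == d)
      pick <- here[sample.int(length(here), 2L)]
      i <- pick[1]; j <- pick[2]
      for (v in c(i, j)) {
        nb <- nb + 1L
        branches[[nb]] <- sets[[v]]
        starts[nb] <- born[v]
        lens[nb] <- t - born[v]
      }
      sets[[i]] <- c(sets[[i]], sets[[j]])
      born[i] <- t
      sets[[j]] <- NULL
      born <- born[-j]
      cur_deme <- cur_deme[-j]
    } else {
      pr <- rate_w + rate_b
      l <- sample.int(n_lin, 1L, prob = pr)
      d <- cur_deme[l]
      g <- grp_of_deme[d]
      to_between <- ngrp > 1L && stats::runif(1) < rate_b[l] / pr[l]
      pool <- if (to_between) unlist(demes_in_grp[-g])
              else setdiff(demes_in_grp[[g]], d)
      cur_deme[l] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
  }
  list(leafsets = branches[seq_len(nb)], lengths = lens[seq_len(nb)],
       starts = starts[seq_len(nb)], n = n_tot)
}

BASES <- c("A", "G", "C", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# Finite-sites K2P-style mutation of a genealogy into sequences. Events
# are applied root-down per site so reverse and parallel changes can and
# do occur.
mutate_tree <- function(tree, theta, k, tstv) {
  n <- tree$n
  n_mut <- stats::rpois(length(tree$lengths), theta / 2 * tree$lengths)
  events <- NULL
  if (sum(n_mut) > 0) {
    idx <- rep(seq_along(n_mut), n_mut)
    events <- data.frame(
      branch = idx,
      site = sample.int(k, length(idx), replace = TRUE),
      age = tree$starts[idx] + stats::runif(length(idx)) * tree$lengths[idx],
      is_ts = stats::runif(length(idx)) < tstv / (tstv + 2),
      u = stats::runif(length(idx)))
  }
  root <- sample(BASES, k, replace = TRUE)
  seqs <- matrix(rep(root, each = n), nrow = n)
  if (!is.null(events) && nrow(events) > 0) {
    events <- events[order(-events$age), , drop = FALSE]  # oldest first
    for (e in seq_len(nrow(events))) {
      leaves <- tree$leafsets[[events$branch[e]]]
      s <- events$site[e]
      cur <- seqs[leaves[1], s]  # leaves under a branch share state here
      new <- if (events$is_ts[e]) TRANSITION[[cur]]
             else TRANSVERSIONS[[cur]][1 + (events$u[e] > 0.5)]
      seqs[leaves, s] <- new
    }
  }
  seqs
}

#' Simulate a dataset under a configuration
#'
#' Backward-in-time structured coalescent (island model with
#' group-dependent migration, optional instantaneous size change),
#' followed by finite-sites K2P-style mutation. Deterministic for a given
#' `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return Object of class `hg_simdata`: `alignment`, `popmap`, and a
#'   `truth` record (parameters, per-deme groups, and the implied
#'   mismatch-scale expansion time `tau_mismatch = theta * t_expansion`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "hg_simconfig"))
  hg_seed(config$seed)
  tree <- sim_structured_tree(config)
  seqs <- mutate_tree(tree, config$theta, config$seq_length, config$tstv)
  ids <- sprintf("%s_%03d", rep(config$demes, config$samples),
                 unlist(lapply(config$samples, seq_len)))
  rownames(seqs) <- ids
  aln <- hg_alignment(seqs)
  cmap <- config$coords[match(config$demes, config$coords$population), ]
  pm <- population_map(data.frame(
    sample = ids,
    population = rep(config$demes, config$samples),
    region = rep(config$groups, config$samples),
    lat = rep(cmap$lat, config$samples),
    lon = rep(cmap$lon, config$samples),
    stringsAsFactors = FALSE))
  truth <- list(theta = config$theta,
                mig_within = config$mig_within,
                mig_between = config$mig_between,
                t_expansion = config$t_expansion,
                expansion_ratio = config$expansion_ratio,
                tau_mismatch = if (is.null(config$t_expansion)) NULL
                               else config$theta * config$t_expansion,
                groups = stats::setNames(config$groups, config$demes),
                seed = config$seed)
  structure(list(alignment = aln, popmap = pm, truth = truth),
            class = "hg_simdata")
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA + population-map CSV consumable by
#' [read_fasta_alignment()] / [read_population_map()], and the truth
#' record as JSON.
#'
#' @param sim An `hg_simdata`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  utils::write.csv(as.data.frame(sim$popmap),
                   file.path(dir, "population_map.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Two-refugium simulation preset
#'
#' The 23 demes, their sample sizes and coordinates follow the bundled
#' reference sampling table (see [punctatus_populations()]); demes are
#' split into a 10-deme southwestern and a 13-deme eastern group by
#' longitude. Migration is free within groups and strongly restricted
#' between them, and the whole species underwent an instantaneous
#' expansion, so simulated datasets carry the phylogeographic signal
#' (NST > GST, star-like within-group clusters) that the analysis stack
#' is designed to detect.
#'
#' @param seed RNG seed stored in the configuration.
#' @return An [sim_config()] with 23 demes and 236 samples.
#' @export
make_two_refugia_preset <- function(seed = 1L) {
  pops <- punctatus_populations()
  sim_config(demes = pops$population,
             samples = pops$n,
             groups = pops$region,
             theta = 3,
             mig_within = 5,
             mig_between = 0.05,
             t_expansion = 0.5,
             expansion_ratio = 0.05,
             seq_length = 586,
             tstv = 5,
             coords = pops[, c("population", "lat", "lon")],
             seed = seed)
}
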