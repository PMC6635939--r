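# pipeline_cli: orchestrate the full analysis from one configuration
# file, with per-stage JSON/TSV outputs.

# Flat INI-style configuration: "[section]" headers and "key = value"
# lines; '#' starts a comment.
read_config <- function(path) {
  if (!file.exists(path)) hg_input_error(sprintf("config not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[section]][[key]] <- if (!is.na(num)) num else val
    } else {
      hg_input_error(sprintf("cannot parse config line: '%s'", ln))
    }
  }
  cfg
}

cfg_get <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}

ALL_STAGES <- c("collapse", "diversity", "differentiation", "structure",
                "samova", "network", "demography", "barcode")

#' Run the full phylogeographic analysis from a configuration file
#'
#' Stages run in the order collapse -> diversity -> differentiation ->
#' structure (AMOVA, pairwise FST, Mantel) -> samova -> network ->
#' demography -> barcode, each writing self-describing JSON/TSV outputs
#' (embedded parameters and seeds) into the output directory. All
#' randomness derives from one master seed, expanded deterministically
#' per stage, so a rerun with the same configuration is reproducible.
#'
#' Configuration sections/keys (defaults in parentheses):
#' `[input] alignment, population_map`; `[run] out_dir, seed (1), stages
#' (all)`; `[differentiation] n_perm (1000)`; `[structure] n_perm
#' (1000)`; `[samova] k (2), n_restarts (25)`; `[demography] n_sim
#' (1000), n_boot (200), mu (1.15e-8), g (1)`; `[barcode] n_reps (500),
#' level (population)`.
#'
#' @param config_path Path to the configuration file, or an equivalent
#'   nested list.
#' @return Invisibly, a list with the per-stage result objects.
#' @export
run_full_analysis <- function(config_path) {
  cfg <- if (is.character(config_path)) read_config(config_path) else config_path
  aln_path <- cfg_get(cfg, "input", "alignment")
  map_path <- cfg_get(cfg, "input", "population_map")
  out_dir <- cfg_get(cfg, "run", "out_dir")
  if (is.null(aln_path) || is.null(map_path) || is.null(out_dir))
    hg_input_error("config must provide [input] alignment, population_map and [run] out_dir")
  seed <- as.integer(cfg_get(cfg, "run", "seed", 1))
  stages <- cfg_get(cfg, "run", "stages", paste(ALL_STAGES, collapse = ","))
  stages <- trimws(strsplit(stages, ",")[[1]])
  bad <- setdiff(stages, ALL_STAGES)
  if (length(bad) > 0L)
    hg_input_error(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  aln <- read_fasta_alignment(aln_path)
  pm <- read_population_map(map_path)
  match_map(aln, pm)
  # one master seed, expanded per stage
  stage_seed <- stats::setNames(seed * 100L + seq_along(ALL_STAGES), ALL_STAGES)

  res <- list()
  run_log <- list(package = "haplogeo",
                  version = as.character(utils::packageVersion("haplogeo")),
                  seed = seed, stages = stages,
                  alignment = aln_path, population_map = map_path,
                  n_samples = length(aln$ids), n_sites = aln$k)

  need <- function(stage, what, ok) {
    if (!ok) hg_input_error(sprintf("stage '%s' needs %s", stage, what))
  }

  if ("collapse" %in% stages) {
    hg_log("stage collapse")
    res$catalog <- collapse_haplotypes(aln, pm)
    write_catalog(res$catalog, file.path(out_dir, "haplotype_counts.tsv"))
    write_haplotype_fasta(res$catalog, file.path(out_dir, "haplotypes.fasta"))
    ss <- site_summary(aln)
    write_json_out(list(N = res$catalog$N, Nh = res$catalog$Nh,
                        S = ss$S, parsimony_informative = ss$PI),
                   file.path(out_dir, "collapse.json"))
  }
  if ("diversity" %in% stages) {
    hg_log("stage diversity")
    res$diversity <- diversity_table(aln, pm)
    utils::write.table(res$diversity, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("differentiation" %in% stages) {
    hg_log("stage differentiation")
    need("differentiation", "the collapse stage", !is.null(res$catalog))
    res$differentiation <- gst_nst(
      res$catalog, n_perm = cfg_get(cfg, "differentiation", "n_perm", 1000),
      seed = stage_seed[["differentiation"]])
    d <- res$differentiation
    write_json_out(list(HS = d$HS, HT = d$HT, GST = d$GST, NST = d$NST,
                        se = as.list(d$se), p_nst_gt_gst = d$p_nst_gt_gst,
                        n_perm = d$n_perm, seed = stage_seed[["differentiation"]]),
                   file.path(out_dir, "differentiation.json"))
  }
  dm_raw <- NULL
  if (any(c("structure", "samova", "demography", "barcode") %in% stages))
    dm_raw <- distance_matrix(aln, metric = "raw")
  if ("structure" %in% stages) {
    hg_log("stage structure")
    np <- cfg_get(cfg, "structure", "n_perm", 1000)
    grouping <- if ("region" %in% names(pm)) "region" else NULL
    res$amova <- amova(dm_raw, pm, grouping = grouping, n_perm = np,
                       seed = stage_seed[["structure"]])
    write_amova(res$amova, file.path(out_dir, "amova.tsv"))
    write_json_out(list(indices = as.list(res$amova$indices),
                        p_values = as.list(res$amova$p_values),
                        n_perm = np, seed = stage_seed[["structure"]]),
                   file.path(out_dir, "amova.json"))
    res$pairwise_fst <- pairwise_fst(dm_raw, pm,
                                     n_perm = min(np, 199),
                                     seed = stage_seed[["structure"]])
    utils::write.table(round(res$pairwise_fst$fst, 6),
                       file.path(out_dir, "pairwise_fst.tsv"),
                       sep = "\t", quote = FALSE)
    if (all(c("lat", "lon") %in% names(pm))) {
      co <- population_coords(pm)
      geo <- outer(seq_len(nrow(co)), seq_len(nrow(co)),
                   Vectorize(function(i, j)
                     great_circle_km(co$lat[i], co$lon[i], co$lat[j], co$lon[j])))
      dimnames(geo) <- list(co$population, co$population)
      gen <- res$pairwise_fst$fst[co$population, co$population]
      if (!anyNA(gen)) {
        res$mantel <- mantel_test(gen, geo, n_perm = np,
                                  seed = stage_seed[["structure"]])
        write_json_out(res$mantel, file.path(out_dir, "mantel.json"))
      }
    }
  }
  if ("samova" %in% stages) {
    hg_log("stage samova")
    res$samova <- samova(dm_raw, pm, K = cfg_get(cfg, "samova", "k", 2),
                         n_restarts = cfg_get(cfg, "samova", "n_restarts", 25),
                         seed = stage_seed[["samova"]])
    write_json_out(list(K = res$samova$K,
                        partition = as.list(res$samova$partition),
                        fct = res$samova$fct,
                        fct_trajectory = res$samova$fct_trajectory,
                        seed = stage_seed[["samova"]]),
                   file.path(out_dir, "samova.json"))
  }
  if ("network" %in% stages) {
    hg_log("stage network")
    need("network", "the collapse stage", !is.null(res$catalog))
    res$network <- median_joining(res$catalog)
    write_network(res$network, file.path(out_dir, "network_nodes.tsv"),
                  file.path(out_dir, "network_edges.tsv"))
  }
  if ("demography" %in% stages) {
    hg_log("stage demography")
    ns <- cfg_get(cfg, "demography", "n_sim", 1000)
    nb <- cfg_get(cfg, "demography", "n_boot", 200)
    taj <- tajimas_d(aln, n_sim = ns, seed = stage_seed[["demography"]])
    fs <- fus_fs(aln, n_sim = ns, seed = stage_seed[["demography"]] + 1L)
    hist <- mismatch_observed(dm_raw)
    fit <- fit_sudden_expansion(hist, n_boot = nb,
                                seed = stage_seed[["demography"]] + 2L)
    et <- expansion_time(fit$tau, mu = cfg_get(cfg, "demography", "mu", 1.15e-8),
                         k = aln$k, g = cfg_get(cfg, "demography", "g", 1))
    res$demography <- list(tajima = taj, fs = fs, mismatch = fit,
                           expansion_time = et)
    utils::write.table(
      data.frame(differences = as.integer(names(hist)), count = as.integer(hist),
                 observed_freq = fit$observed, expected_freq = fit$expected),
      file.path(out_dir, "mismatch.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_json_out(list(
      tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
      SSD = fit$ssd, p_SSD = fit$p_ssd,
      RAG = fit$raggedness, p_RAG = fit$p_raggedness,
      tajima_D = taj$D, p_D = taj$p, fu_Fs = fs$Fs, p_Fs = fs$p,
      t_years = et$t_years, t_mya = et$t_mya, mu = et$mu, k = et$k,
      g = et$g, n_sim = ns, n_boot = nb,
      seed = stage_seed[["demography"]]),
      file.path(out_dir, "demography.json"))
  }
  if ("barcode" %in% stages) {
    hg_log("stage barcode")
    lvl <- cfg_get(cfg, "barcode", "level", "population")
    nr <- cfg_get(cfg, "barcode", "n_reps", 500)
    dm_k2p <- distance_matrix(aln, metric = "k2p")
    gap <- barcoding_gap(dm_k2p, pm, level = lvl)
    md <- loo_success(dm_k2p, pm, method = "md", level = lvl, n_reps = nr,
                      seed = stage_seed[["barcode"]])
    bcm <- loo_success(dm_k2p, pm, method = "bcm", level = lvl, n_reps = nr,
                       seed = stage_seed[["barcode"]] + 1L)
    res$barcode <- list(gap = gap, md = md, bcm = bcm)
    utils::write.table(gap$histogram, file.path(out_dir, "barcoding_gap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report1 <- function(x) list(
      method = x$method, level = x$level,
      mean_rate = x$mean_rate, ci_low = x$ci[["low"]],
      ci_high = x$ci[["high"]], ci_method = x$ci_method,
      n_reps = x$n_reps, threshold = x$threshold,
      outcome_counts = x$outcome_counts)
    write_json_out(list(
      gap = list(mean_within = gap$mean_within,
                 mean_between = gap$mean_between, ratio = gap$ratio,
                 positive_gap = gap$positive_gap),
      md = report1(md), bcm = report1(bcm), seed = stage_seed[["barcode"]]),
      file.path(out_dir, "barcode.json"))
  }
  write_json_out(run_log, file.path(out_dir, "run_log.json"))
  invisible(res)
}
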