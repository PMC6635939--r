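# Seeded small worlds and enumeration oracles shared by the SAMOVA and
# acceptance suites.

# Exhaustive oracle over contiguous K=2 bipartitions, evaluating each
# candidate with the full amova() code path (independent of samova's
# internal aggregate FCT shortcut).
oracle_best_bipartition <- function(dm, pm) {
  pops <- unique(pm$population)
  coords <- data.frame(population = pops,
                       lat = pm$lat[match(pops, pm$population)],
                       lon = pm$lon[match(pops, pm$population)])
  A <- gabriel_graph(coords)
  connected <- function(members) {
    if (length(members) <= 1) return(TRUE)
    seen <- members[1]
    repeat {
      nb <- unique(unlist(lapply(seen, function(v) which(A[v, ]))))
      nb <- intersect(nb, members)
      if (all(nb %in% seen)) break
      seen <- union(seen, nb)
    }
    length(seen) == length(members)
  }
  P <- length(pops)
  best <- -Inf; best_set <- NULL
  for (code in 1:(2^(P - 1) - 1)) {
    inset <- which(as.logical(bitwAnd(code, 2^(0:(P - 1)))))
    outset <- setdiff(seq_len(P), inset)
    if (!connected(inset) || !connected(outset)) next
    grouping <- stats::setNames(ifelse(seq_len(P) %in% inset, "A", "B"), pops)
    fct <- amova(dm, pm, grouping = grouping, n_perm = 0)$indices[["FCT"]]
    if (fct > best) { best <- fct; best_set <- pops[inset] }
  }
  list(fct = best, set = best_set)
}

# Stepping-stone chain: deme d is fixed for an increasingly divergent
# haplotype, so finer contiguous partitions keep raising FCT.
make_chain_world <- function(per = 3, n_demes = 6, seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
  seqs <- list(); pop <- character(0)
  for (d in seq_len(n_demes)) {
    hap <- base
    if (d > 1) hap[seq_len(3 * (d - 1))] <- "T"
    for (i in seq_len(per)) {
      s <- hap
      if (i == 2) s[40] <- "C"
      seqs[[paste0("D", d, "_", i)]] <- paste(s, collapse = "")
      pop <- c(pop, paste0("D", d))
    }
  }
  aln <- hg_alignment(unlist(seqs))
  pm <- simple_map(aln, pop,
                   lat = rep(seq(24, 29, by = 1)[1:n_demes], each = per),
                   lon = rep(seq(100, 110, by = 2)[1:n_demes], each = per))
  list(aln = aln, pm = pm)
}

# Six demes in two divergent geographic clades with deme-private
# variants and mild within-deme noise.
make_cluster_world <- function(n_demes = 6, per = 4, seed = 51) {
  set.seed(seed)
  half <- n_demes / 2
  base <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  seqs <- list(); pop <- character(0)
  for (d in seq_len(n_demes)) {
    hap <- base
    if (d > half) hap[1:6] <- "T"      # divergent eastern clade
    hap[10 + d] <- "G"                 # deme-private variant
    for (i in seq_len(per)) {
      s <- hap
      if (i == 2) s[25] <- "C"         # a little within-deme noise
      seqs[[paste0("D", d, "_", i)]] <- paste(s, collapse = "")
      pop <- c(pop, paste0("D", d))
    }
  }
  aln <- hg_alignment(unlist(seqs))
  pm <- simple_map(aln, pop,
                   regions = rep(c("W", "E"), each = half * per),
                   lat = rep(c(24, 24.5, 25, 26, 26.5, 27)[1:n_demes], each = per),
                   lon = rep(c(101, 103, 105, 114, 116, 118)[1:n_demes], each = per))
  list(aln = aln, pm = pm)
}
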