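# Spatial AMOVA: simulated-annealing search for the K-group partition of
# populations, constrained to geographic contiguity, that maximizes FCT.

#' Gabriel neighbourhood graph over population coordinates
#'
#' Populations i and j are neighbours iff no third population k lies in
#' the circle with diameter (i, j): d(i,k)^2 + d(j,k)^2 <= d(i,j)^2, with
#' great-circle distances. Deterministic, and the standard contiguity
#' notion for SAMOVA-style searches.
#'
#' @param coords Data frame with columns `population`, `lat`, `lon`.
#' @return Symmetric logical adjacency matrix with population dimnames.
#' @export
gabriel_graph <- function(coords) {
  n <- nrow(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- great_circle_km(coords$lat[i], coords$lon[i],
                              coords$lat, coords$lon)
  }
  A <- matrix(FALSE, n, n, dimnames = list(coords$population,
                                           coords$population))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    others <- setdiff(seq_len(n), c(i, j))
    blocked <- any(D[i, others]^2 + D[j, others]^2 <= D[i, j]^2 + 1e-9)
    A[i, j] <- A[j, i] <- !blocked
  }
  A
}

# Is the set of vertices `members` connected in adjacency matrix A?
is_connected <- function(A, members) {
  if (length(members) <= 1L) return(TRUE)
  seen <- members[1]
  frontier <- seen
  while (length(frontier) > 0L) {
    nb <- which(apply(A[frontier, , drop = FALSE], 2, any))
    nb <- setdiff(intersect(nb, members), seen)
    seen <- c(seen, nb)
    frontier <- nb
  }
  length(seen) == length(members)
}

# FCT from precomputed population aggregates for an arbitrary grouping.
fct_from_agg <- function(agg, grp) {
  fixation_indices(amova_components(agg, grp)[["sigma"]])[["FCT"]]
}

# Random contiguous K-partition: K seeds, then region-growing on A.
grow_partition <- function(A, K) {
  n <- nrow(A)
  part <- rep(NA_integer_, n)
  seeds <- sample.int(n, K)
  part[seeds] <- seq_len(K)
  while (anyNA(part)) {
    frontier <- which(!is.na(part))
    cand <- which(is.na(part) & apply(A[frontier, , drop = FALSE], 2, any))
    if (length(cand) == 0L) {
      # disconnected contiguity graph: attach an arbitrary unassigned
      # vertex to a random group
      v <- which(is.na(part))[1]
      part[v] <- sample.int(K, 1)
    } else {
      v <- if (length(cand) == 1L) cand else sample(cand, 1)
      nb <- which(A[v, ] & !is.na(part))
      g <- if (length(nb) > 0) part[sample(nb, 1)] else sample.int(K, 1)
      part[v] <- g
    }
  }
  part
}

#' SAMOVA group search
#'
#' Maximizes the among-group fixation index FCT over partitions of
#' populations into K geographically contiguous groups, by simulated
#' annealing (geometric cooling, best-of-restarts). Contiguity is read
#' from the Gabriel graph of the population coordinates; set
#' `contiguity = FALSE` to search unconstrained partitions.
#'
#' @param dm An `hg_distmatrix` (raw metric).
#' @param pm Population map with coordinates.
#' @param K Number of groups, 2 <= K < number of populations.
#' @param n_restarts Independent annealing restarts.
#' @param anneal_params List with `t0` (initial temperature), `cooling`
#'   (geometric factor per sweep), `n_iter` (proposals per restart).
#' @param seed Optional RNG seed.
#' @param contiguity Constrain moves to keep groups connected?
#' @return Object of class `hg_samova`: `K`, `partition` (named group id
#'   per population), `fct`, `fct_trajectory` (best FCT per restart),
#'   `amova` (full AMOVA at the optimum, without permutations),
#'   `anneal_params`.
#' @export
samova <- function(dm, pm, K, n_restarts = 25,
                   anneal_params = list(t0 = 0.05, cooling = 0.95,
                                        n_iter = 400),
                   seed = NULL, contiguity = TRUE) {
  hg_seed(seed)
  if (!inherits(pm, "hg_popmap")) pm <- population_map(pm)
  idx <- match(dm$ids, pm$sample)
  if (anyNA(idx)) hg_input_error("distance matrix ids missing from population map")
  pop <- pm$population[idx]
  agg <- pop_pair_sums(squared_distances(dm), pop)
  P <- length(agg$pops)
  if (K < 2 || K >= P)
    hg_input_error(sprintf("K must satisfy 2 <= K < %d populations", P))
  if (contiguity) {
    coords <- population_coords(pm)
    coords <- coords[match(agg$pops, coords$population), ]
    A <- gabriel_graph(coords)
  } else {
    A <- matrix(TRUE, P, P, dimnames = list(agg$pops, agg$pops))
    diag(A) <- FALSE
  }

  eval_fct <- function(part) fct_from_agg(agg, as.character(part))

  move_ok <- function(part, v, g_to) {
    g_from <- part[v]
    if (g_from == g_to) return(FALSE)
    if (sum(part == g_from) == 1L) return(FALSE)  # group would empty
    if (!contiguity) return(TRUE)
    # target must be adjacent and source group must stay connected
    if (!any(A[v, part == g_to])) return(FALSE)
    is_connected(A, setdiff(which(part == g_from), v))
  }

  best_part <- NULL; best_fct <- -Inf
  traj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    part <- grow_partition(A, K)
    cur <- eval_fct(part)
    loc_best <- cur; loc_part <- part
    temp <- anneal_params$t0
    for (it in seq_len(anneal_params$n_iter)) {
      v <- sample.int(P, 1)
      g_to <- sample.int(K, 1)
      if (!move_ok(part, v, g_to)) next
      cand <- part
      cand[v] <- g_to
      val <- eval_fct(cand)
      if (val >= cur || stats::runif(1) < exp((val - cur) / temp)) {
        part <- cand; cur <- val
        if (cur > loc_best) { loc_best <- cur; loc_part <- part }
      }
      temp <- temp * anneal_params$cooling^(1 / anneal_params$n_iter * 50)
    }
    traj[r] <- loc_best
    if (loc_best > best_fct) { best_fct <- loc_best; best_part <- loc_part }
  }

  partition <- stats::setNames(as.integer(best_part), agg$pops)
  grouping <- stats::setNames(paste0("G", partition), agg$pops)
  am <- amova(dm, pm, grouping = grouping, n_perm = 0)
  structure(list(K = K, partition = partition, fct = best_fct,
                 fct_trajectory = traj, amova = am,
                 anneal_params = anneal_params, contiguity = contiguity),
            class = "hg_samova")
}

#' @export
print.hg_samova <- function(x, ...) {
  cat(sprintf("<hg_samova> K = %d, FCT = %.4f\n", x$K, x$fct))
  for (g in sort(unique(x$partition))) {
    cat(sprintf("  group %d: %s\n", g,
                paste(names(x$partition)[x$partition == g], collapse = ", ")))
  }
  invisible(x)
}
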