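# network_mj: median-joining haplotype networks.

# Hamming distance matrix over equal-length strings (split into a char
# matrix once).
hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  D <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    jj <- (i + 1L):n
    v <- rowSums(m[jj, , drop = FALSE] != rep(m[i, ], each = length(jj)))
    D[i, jj] <- v; D[jj, i] <- v
  }
  D
}

# Minimax (bottleneck) path weights by Floyd-style DP. An edge (u, v)
# belongs to some minimum spanning tree iff D[u,v] equals the minimax
# weight between u and v, so {D <= minimax + eps} is the epsilon-relaxed
# minimum spanning network.
minimax_weights <- function(D) {
  mm <- D
  n <- nrow(D)
  for (k in seq_len(n)) {
    mk <- pmax(matrix(mm[, k], n, n), matrix(mm[k, ], n, n, byrow = TRUE))
    mm <- pmin(mm, mk)
  }
  mm
}

msn_edges <- function(D, eps = 0) {
  mm <- minimax_weights(D)
  sel <- which(upper.tri(D) & D <= mm + eps, arr.ind = TRUE)
  data.frame(from = sel[, 1], to = sel[, 2],
             weight = D[sel])
}

# Majority-consensus median of three sequences; ties (all three states
# distinct in a column) resolved to the state of the shared/central node
# so the construction is deterministic.
triplet_median <- function(a, b, c_, central) {
  n <- length(a)
  out <- character(n)
  for (i in seq_len(n)) {
    st <- c(a[i], b[i], c_[i])
    tb <- table(st)
    if (max(tb) >= 2L) out[i] <- names(tb)[which.max(tb)]
    else out[i] <- central[i]
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds the Bandelt-style median-joining network over the observed
#' haplotypes of a catalog: the epsilon-relaxed minimum spanning network
#' is iteratively augmented with consensus (median) vectors of linked
#' triplets whenever the star connection through the median is strictly
#' cheaper than the triplet's own spanning links, then median vectors
#' that end up with degree < 3 are pruned. Distances are raw per-site
#' differences over the catalog's retained columns. Deterministic for a
#' fixed input order.
#'
#' @param cat An `hg_catalog` built from sequences.
#' @param epsilon Weight tolerance of the minimum spanning network
#'   (default 0).
#' @param max_iter Safety cap on median-addition rounds.
#' @return Object of class `hg_mjnet`: `nodes` (data frame: label, freq,
#'   median flag, population composition string), `edges` (from, to,
#'   weight in mutation steps), `epsilon`, `star_likeness`
#'   (max degree / number of observed haplotypes).
#' @export
median_joining <- function(cat, epsilon = 0, max_iter = 20L) {
  stopifnot(inherits(cat, "hg_catalog"))
  if (is.null(cat$seqs)) hg_input_error("catalog carries no sequences")
  seqs <- cat$seqs
  is_median <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
  n_median <- 0L

  split_mat <- function(s) do.call(rbind, strsplit(s, "", fixed = TRUE))

  if (length(seqs) > 1L) {
    for (iter in seq_len(max_iter)) {
      D <- hamming_matrix(seqs)
      ed <- msn_edges(D, epsilon)
      # adjacency list of the feasible graph
      adj <- vector("list", length(seqs))
      for (r in seq_len(nrow(ed))) {
        adj[[ed$from[r]]] <- c(adj[[ed$from[r]]], ed$to[r])
        adj[[ed$to[r]]] <- c(adj[[ed$to[r]]], ed$from[r])
      }
      m <- split_mat(seqs)
      new_meds <- character(0)
      for (v in seq_along(seqs)) {
        nb <- adj[[v]]
        if (length(nb) < 2L) next
        prs <- utils::combn(sort(nb), 2L)
        for (cix in seq_len(ncol(prs))) {
          u <- prs[1, cix]; w <- prs[2, cix]
          med <- paste(triplet_median(m[u, ], m[w, ], m[v, ], m[v, ]),
                       collapse = "")
          if (med %in% seqs || med %in% new_meds) next
          mv <- strsplit(med, "")[[1]]
          du <- sum(mv != m[u, ]); dw <- sum(mv != m[w, ]); dv <- sum(mv != m[v, ])
          tri <- c(D[u, w], D[u, v], D[v, w])
          # star through the median must beat the triplet's own MST
          if (du + dw + dv < sum(tri) - max(tri)) new_meds <- c(new_meds, med)
        }
      }
      if (length(new_meds) == 0L) break
      new_meds <- sort(unique(new_meds))
      labs <- paste0("mv", n_median + seq_along(new_meds))
      n_median <- n_median + length(new_meds)
      seqs <- c(seqs, stats::setNames(new_meds, labs))
      is_median <- c(is_median, stats::setNames(rep(TRUE, length(labs)), labs))
    }
    # prune median vectors with degree <= 2 (raw differences obey the
    # triangle inequality, so the spanning network stays connected)
    repeat {
      D <- hamming_matrix(seqs)
      ed <- msn_edges(D, epsilon)
      deg <- tabulate(c(ed$from, ed$to), nbins = length(seqs))
      drop <- which(is_median[names(seqs)] & deg <= 2L)
      if (length(drop) == 0L) break
      seqs <- seqs[-drop]
      is_median <- is_median[names(seqs)]
    }
    D <- hamming_matrix(seqs)
    ed <- msn_edges(D, epsilon)
  } else {
    ed <- data.frame(from = integer(0), to = integer(0), weight = integer(0))
  }

  freq <- stats::setNames(rep(0L, length(seqs)), names(seqs))
  obs <- intersect(names(seqs), cat$labels)
  freq[obs] <- colSums(cat$counts)[obs]
  comp <- vapply(names(seqs), function(lb) {
    if (!(lb %in% cat$labels)) return("")
    cc <- cat$counts[, lb]
    paste(sprintf("%s:%d", rownames(cat$counts)[cc > 0], cc[cc > 0]),
          collapse = ";")
  }, character(1))
  deg <- tabulate(c(ed$from, ed$to), nbins = length(seqs))
  nodes <- data.frame(label = names(seqs), freq = as.integer(freq),
                      median = unname(is_median[names(seqs)]),
                      degree = deg, populations = unname(comp),
                      sequence = unname(seqs), stringsAsFactors = FALSE)
  edges <- data.frame(from = names(seqs)[ed$from], to = names(seqs)[ed$to],
                      weight = as.integer(ed$weight), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 star_likeness = if (cat$Nh > 0) max(deg, 0) / cat$Nh else NA),
            class = "hg_mjnet")
}

#' @export
print.hg_mjnet <- function(x, ...) {
  cat(sprintf("<hg_mjnet> %d nodes (%d median), %d edges, eps = %g\n",
              nrow(x$nodes), sum(x$nodes$median), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Write a network as node/edge TSV files
#'
#' Node attributes (frequency, population composition, median flag) are
#' GraphML-compatible; the edge list carries mutation-step weights.
#'
#' @param net An `hg_mjnet`.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, nodes_path, edges_path) {
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
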