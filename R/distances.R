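# distances: K2P and raw-difference kernels, full matrices, and
# within/between-population distance summaries.

# Pairwise-deletion comparison of two encoded sequences. Returns counts of
# comparable sites, transitions and transversions.
pq_counts <- function(ea, eb) {
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0L) return(list(n = 0L, ts = 0L, tv = 0L))
  a <- ea[ok]; b <- eb[ok]
  diff <- a != b
  # purines coded {1,2}, pyrimidines {3,4}: same class + different base
  # is a transition
  same_class <- ((a + 1L) %/% 2L) == ((b + 1L) %/% 2L)
  ts <- sum(diff & same_class)
  tv <- sum(diff & !same_class)
  list(n = n, ts = ts, tv = tv)
}

#' Kimura two-parameter distance between two sequences
#'
#' Computes d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), where P and Q are
#' the proportions of transitional and transversional differences among
#' sites where both sequences carry an unambiguous base (pairwise
#' deletion).
#'
#' @param seq_a,seq_b Sequences as single strings or character vectors of
#'   bases; equal length required.
#' @return List with `d` (NA when saturated), `P`, `Q`, `n_sites` and
#'   `saturated`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b))
    hg_input_error("sequences differ in length")
  cc <- pq_counts(encode_bases(a), encode_bases(b))
  if (cc$n == 0L)
    hg_numeric_error("no comparable sites between the two sequences")
  P <- cc$ts / cc$n
  Q <- cc$tv / cc$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, n_sites = cc$n, saturated = TRUE))
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, n_sites = cc$n, saturated = FALSE)
}

#' Raw number of differences between two sequences
#'
#' Counts columns where the two sequences carry different unambiguous
#' bases (pairwise deletion).
#'
#' @inheritParams k2p_distance
#' @return Integer count.
#' @export
raw_differences <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b))
    hg_input_error("sequences differ in length")
  ea <- encode_bases(a); eb <- encode_bases(b)
  ok <- !is.na(ea) & !is.na(eb)
  sum(ea[ok] != eb[ok])
}

#' Pairwise distance matrix over an alignment
#'
#' @param aln An [hg_alignment()].
#' @param metric `"k2p"` (substitutions/site), `"raw"` (difference counts)
#'   or `"p"` (proportion of differing comparable sites).
#' @return Object of class `hg_distmatrix`: list with `ids`, symmetric
#'   `mat`, `metric`, and `saturated` (logical matrix flagging pairs where
#'   the K2P transform is undefined; such entries are NA in `mat`).
#' @export
distance_matrix <- function(aln, metric = c("k2p", "raw", "p")) {
  stopifnot(inherits(aln, "hg_alignment"))
  metric <- match.arg(metric)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  mat <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  sat <- matrix(FALSE, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    valid <- !is.na(enc)
    cls <- (enc + 1L) %/% 2L
    for (i in seq_len(n - 1L)) {
      jj <- (i + 1L):n
      vi <- valid[i, ]
      ok <- valid[jj, , drop = FALSE] & rep(vi, each = length(jj))
      nn <- rowSums(ok)
      di <- ok & (enc[jj, , drop = FALSE] != rep(enc[i, ], each = length(jj)))
      if (metric == "raw") {
        v <- rowSums(di)
      } else if (metric == "p") {
        if (any(nn == 0L))
          hg_numeric_error(sprintf("no comparable sites for a pair involving '%s'", aln$ids[i]))
        v <- rowSums(di) / nn
      } else {
        if (any(nn == 0L))
          hg_numeric_error(sprintf("no comparable sites for a pair involving '%s'", aln$ids[i]))
        ts <- rowSums(di & (cls[jj, , drop = FALSE] == rep(cls[i, ], each = length(jj))))
        P <- ts / nn
        Q <- (rowSums(di) - ts) / nn
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
        bad <- w1 <= 0 | w2 <= 0
        v <- ifelse(bad, NA_real_, -0.5 * log(pmax(w1, 1e-300)) -
                      0.25 * log(pmax(w2, 1e-300)))
        sat[i, jj] <- bad
        sat[jj, i] <- bad
      }
      mat[i, jj] <- v
      mat[jj, i] <- v
    }
  }
  n_sat <- sum(sat) / 2
  if (n_sat > 0) hg_log("%d saturated pair(s) flagged in K2P matrix", n_sat)
  structure(list(ids = aln$ids, mat = mat, metric = metric, saturated = sat),
            class = "hg_distmatrix")
}

#' @export
print.hg_distmatrix <- function(x, ...) {
  cat(sprintf("<hg_distmatrix> %d x %d (%s)\n", length(x$ids), length(x$ids),
              x$metric))
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param dm An `hg_distmatrix`.
#' @param path Output path.
#' @param phylip If TRUE, prepend the PHYLIP-style count line.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, phylip = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip) writeLines(sprintf("%5d", length(dm$ids)), con)
  for (i in seq_along(dm$ids)) {
    writeLines(paste(c(dm$ids[i], format(dm$mat[i, ], digits = 10)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# Classify unordered pairs as within- or between-group given a grouping
# vector aligned with dm$ids. Returns the two distance vectors (NAs from
# saturated pairs dropped with a logged count).
split_pairs <- function(dm, groups) {
  n <- length(dm$ids)
  if (length(groups) != n) hg_input_error("grouping length mismatch")
  lower <- lower.tri(dm$mat)
  same <- outer(groups, groups, "==")
  w <- dm$mat[lower & same]
  b <- dm$mat[lower & !same]
  n_na <- sum(is.na(w)) + sum(is.na(b))
  if (n_na > 0) hg_log("%d saturated pair(s) excluded from distance summary", n_na)
  list(within = w[!is.na(w)], between = b[!is.na(b)])
}

#' Within- vs between-population distance summary
#'
#' Means over unordered sample pairs within the same population and
#' between different populations, their ratio, and class histograms for
#' barcoding-gap style plots.
#'
#' @param dm An `hg_distmatrix`.
#' @param pm Population map (see [population_map()]).
#' @param level Grouping column: `"population"`, `"region"` or `"species"`.
#' @param breaks Passed to [graphics::hist()]-style binning via
#'   [base::cut()]; default 20 equal bins over the pooled range.
#' @return List with `mean_within`, `mean_between`, `ratio`,
#'   `n_within`, `n_between`, and `histogram` (data frame of bin mids and
#'   per-class counts).
#' @export
within_between_summary <- function(dm, pm, level = "population", breaks = 20) {
  pm <- check_level(pm, level)
  idx <- match(dm$ids, pm$sample)
  if (anyNA(idx)) hg_input_error("distance matrix ids missing from population map")
  groups <- pm[[level]][idx]
  if (length(unique(groups)) < 2L)
    hg_input_error("need at least two groups for a within/between summary")
  sp <- split_pairs(dm, groups)
  if (length(sp$within) == 0L)
    hg_numeric_error("no within-group pairs (all groups are singletons)")
  rng <- range(c(sp$within, sp$between))
  if (diff(rng) == 0) rng <- rng + c(0, 1e-9)
  edges <- seq(rng[1], rng[2], length.out = breaks + 1)
  hw <- graphics::hist(sp$within, breaks = edges, plot = FALSE)
  hb <- graphics::hist(sp$between, breaks = edges, plot = FALSE)
  list(mean_within = mean(sp$within),
       mean_between = mean(sp$between),
       ratio = mean(sp$between) / mean(sp$within),
       n_within = length(sp$within), n_between = length(sp$between),
       histogram = data.frame(mid = hw$mids, within = hw$counts,
                              between = hb$counts))
}

check_level <- function(pm, level) {
  if (!inherits(pm, "hg_popmap")) pm <- population_map(pm)
  if (!level %in% names(pm))
    hg_input_error(sprintf("population map has no '%s' column", level))
  pm
}
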