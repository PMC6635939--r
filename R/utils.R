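# Internal helpers shared across modules.

# Classed error constructors. Two broad families are distinguished so the
# command-line driver can map them onto distinct exit codes:
#   haplogeo_input_error  - malformed/inconsistent user input
#   haplogeo_numeric_error - statistic undefined on this input
hg_input_error <- function(msg) {
  stop(structure(
    class = c("haplogeo_input_error", "haplogeo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

hg_numeric_error <- function(msg) {
  stop(structure(
    class = c("haplogeo_numeric_error", "haplogeo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

hg_log <- function(fmt, ...) {
  message(sprintf(paste0("[haplogeo] ", fmt), ...))
}

# Seed any stochastic entry point; NULL leaves the RNG stream untouched.
hg_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      hg_input_error("'seed' must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# IUPAC nucleotide alphabet accepted in alignments.
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# Encode unambiguous bases as integers; everything else becomes NA.
# Codes are chosen so that purines are {1,2} and pyrimidines {3,4}:
# a substitution is a transition iff both codes fall in the same class.
BASE_CODE <- c(A = 1L, G = 2L, C = 3L, T = 4L)

encode_bases <- function(x) {
  out <- BASE_CODE[x]
  names(out) <- NULL
  out
}

# Permutation-test p-value, add-one convention (never exactly zero).
perm_pvalue <- function(n_extreme, n_perm) {
  (n_extreme + 1) / (n_perm + 1)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Great-circle distance (km) between decimal-degree coordinates.
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}
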