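# io_core: alignments, population maps, site summaries.

#' Construct an alignment object
#'
#' An alignment is a set of equal-length, uppercase IUPAC nucleotide
#' sequences with unique identifiers. It is the object every downstream
#' statistic consumes.
#'
#' @param seqs Named character vector of sequences (names are sample ids),
#'   or a character matrix (rows = samples, one column per site).
#' @return An object of class `hg_alignment` with fields `ids`,
#'   `seq` (character matrix, samples x sites) and `k` (number of sites).
#' @export
hg_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
    ids <- rownames(m)
  } else {
    if (length(seqs) == 0L) hg_input_error("empty alignment")
    ids <- names(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      hg_input_error(sprintf(
        "ragged alignment: sequence lengths differ (%s)",
        paste(unique(lens), collapse = ", ")))
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- ids
  }
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    hg_input_error("all sequences must carry a non-empty id")
  if (anyDuplicated(ids))
    hg_input_error(sprintf("duplicate sequence ids: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (ncol(m) < 1L) hg_input_error("alignment must have at least one site")
  m[] <- toupper(m)
  bad <- setdiff(unique(as.vector(m)), IUPAC_CHARS)
  if (length(bad) > 0L)
    hg_input_error(sprintf("invalid characters in alignment: %s",
                           paste(bad, collapse = ", ")))
  structure(list(ids = ids, seq = m, k = ncol(m)), class = "hg_alignment")
}

#' @export
print.hg_alignment <- function(x, ...) {
  cat(sprintf("<hg_alignment> %d sequences x %d sites\n",
              length(x$ids), x$k))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet; ragged records, duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file of pre-aligned sequences.
#' @return An [hg_alignment()] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) hg_input_error(sprintf("file not found: %s", path))
  dna <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                  error = function(e) hg_input_error(
                    sprintf("could not parse FASTA '%s': %s", path, conditionMessage(e))))
  if (is.null(dna) || length(dna) == 0L)
    hg_input_error(sprintf("empty FASTA file: %s", path))
  chr <- as.character(dna)
  seqs <- vapply(chr, function(s) paste(s, collapse = ""), character(1))
  names(seqs) <- names(dna)
  hg_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln An [hg_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hg_alignment"))
  m <- tolower(aln$seq)
  dna <- ape::as.DNAbin(m)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Subset an alignment by sample id
#' @param aln An [hg_alignment()].
#' @param ids Character vector of sample ids to keep (order respected).
#' @return An [hg_alignment()].
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "hg_alignment"))
  missing <- setdiff(ids, aln$ids)
  if (length(missing) > 0L)
    hg_input_error(sprintf("ids not in alignment: %s",
                           paste(missing, collapse = ", ")))
  hg_alignment(aln$seq[ids, , drop = FALSE])
}

# Integer-coded alignment: samples x sites, NA for ambiguity codes/gaps.
encode_alignment <- function(aln) {
  enc <- encode_bases(aln$seq)
  dim(enc) <- dim(aln$seq)
  rownames(enc) <- aln$ids
  enc
}

#' Read a population map
#'
#' The map assigns each sample to a population, each population to a
#' region, and carries site coordinates in decimal degrees. The delimiter
#' (comma or tab) is auto-detected from the header line.
#'
#' @param path Delimited text file with header
#'   `sample,population,region,lat,lon`.
#' @return A `data.frame` of class `hg_popmap`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) hg_input_error(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  population_map(df)
}

#' Construct/validate a population map from a data frame
#'
#' @param df Data frame with columns `sample`, `population`, `region`
#'   (optional), `lat` and `lon` (optional). Extra columns (e.g. `species`)
#'   are kept.
#' @return A `data.frame` of class `hg_popmap`.
#' @export
population_map <- function(df) {
  need <- c("sample", "population")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    hg_input_error(sprintf("population map is missing columns: %s",
                           paste(miss, collapse = ", ")))
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  if (anyDuplicated(df$sample))
    hg_input_error("duplicate sample ids in population map")
  if (nrow(df) == 0L) hg_input_error("empty population map")
  if ("region" %in% names(df)) {
    df$region <- as.character(df$region)
    per_pop <- tapply(df$region, df$population, function(r) length(unique(r)))
    if (any(per_pop > 1L))
      hg_input_error("each population must belong to exactly one region")
  }
  if (all(c("lat", "lon") %in% names(df))) {
    if (!is.numeric(df$lat) || !is.numeric(df$lon) ||
        anyNA(df$lat) || anyNA(df$lon))
      hg_input_error("lat/lon must be numeric and non-missing")
    if (any(df$lat < -90 | df$lat > 90))
      hg_input_error("latitude out of range [-90, 90]")
    if (any(df$lon < -180 | df$lon > 180))
      hg_input_error("longitude out of range [-180, 180]")
  }
  class(df) <- c("hg_popmap", "data.frame")
  df
}

# Check that every alignment id is mapped; returns map rows in alignment
# order (the pairing step where sample <-> population consistency is
# enforced).
match_map <- function(aln, pm) {
  stopifnot(inherits(aln, "hg_alignment"))
  if (!inherits(pm, "hg_popmap")) pm <- population_map(pm)
  idx <- match(aln$ids, pm$sample)
  if (anyNA(idx))
    hg_input_error(sprintf("samples missing from population map: %s",
                           paste(aln$ids[is.na(idx)], collapse = ", ")))
  pm[idx, , drop = FALSE]
}

# Per-population coordinate table (first occurrence wins; populations are
# sampled at one site each).
population_coords <- function(pm) {
  if (!all(c("lat", "lon") %in% names(pm)))
    hg_input_error("population map carries no coordinates")
  first <- !duplicated(pm$population)
  data.frame(population = pm$population[first],
             lat = pm$lat[first], lon = pm$lon[first],
             stringsAsFactors = FALSE)
}

#' Summarise variable alignment columns
#'
#' `S` counts polymorphic (segregating) sites: columns with at least two
#' distinct unambiguous bases. `PI` counts parsimony-informative sites:
#' columns with at least two bases each carried by at least two sequences.
#' Columns varying only through ambiguity codes or gaps are not counted,
#' mirroring common population-genetics software.
#'
#' @param aln An [hg_alignment()].
#' @return List with `S`, `PI` and `variable_sites` (1-based column
#'   indices of the S segregating sites).
#' @export
site_summary <- function(aln) {
  stopifnot(inherits(aln, "hg_alignment"))
  enc <- encode_alignment(aln)
  S <- 0L; PI <- 0L; var_idx <- integer(0)
  for (j in seq_len(ncol(enc))) {
    cnt <- tabulate(enc[, j], nbins = 4L)
    n_alleles <- sum(cnt > 0L)
    if (n_alleles >= 2L) {
      S <- S + 1L
      var_idx <- c(var_idx, j)
      if (sum(cnt >= 2L) >= 2L) PI <- PI + 1L
    }
  }
  list(S = S, PI = PI, variable_sites = var_idx)
}
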