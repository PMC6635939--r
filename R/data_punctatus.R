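# Bundled reference tables for the Masson pine moth (Dendrolimus
# punctatus) COI survey: 23 populations across subtropical China, 236
# individuals, 51 mitochondrial haplotypes. These are the published
# per-population haplotype frequencies, not sequences; they drive
# count-based statistics (diversity, pooled diversity) and the
# two-refugium simulation preset.

#' Sampling locations of the bundled COI survey
#'
#' One row per population: abbreviation, locality, decimal-degree
#' coordinates, sample size, and the regional group (a 10-population
#' southwestern group versus a 13-population eastern group; the split
#' assigns the ten westernmost sites, longitude <= 108.3 E, to the
#' southwest).
#'
#' @return Data frame with columns `population`, `locality`, `lat`,
#'   `lon`, `n`, `region`.
#' @export
punctatus_populations <- function() {
  path <- system.file("extdata", "punctatus_populations.tsv",
                      package = "haplogeo", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Per-population COI haplotype counts of the bundled survey
#'
#' The published population x haplotype frequency table (H1-H51, 236
#' individuals), as an `hg_catalog` ready for count-based statistics
#' such as [haplotype_diversity()] and [pooled_diversity()].
#'
#' @return An `hg_catalog` (no sequences attached).
#' @export
punctatus_coi_counts <- function() {
  path <- system.file("extdata", "punctatus_coi_counts.tsv",
                      package = "haplogeo", mustWork = TRUE)
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  pops <- unique(long$population)
  haps <- paste0("H", sort(as.integer(sub("^H", "", unique(long$haplotype)))))
  m <- matrix(0L, length(pops), length(haps), dimnames = list(pops, haps))
  m[cbind(match(long$population, pops), match(long$haplotype, haps))] <-
    as.integer(long$count)
  catalog_from_counts(m)
}
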