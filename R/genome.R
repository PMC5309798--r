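#' Construct a genome build
#'
#' A genome build is the minimal reference description needed by the
#' CNV analysis: a name and the per-chromosome lengths in base pairs.
#' It is the denominator for genome-fraction statistics and the bound
#' for CNV length filtering and location randomization.
#'
#' @param name Character scalar naming the assembly (e.g. `"GRCh37"`).
#' @param chrom_lengths Named numeric vector of chromosome lengths in
#'   bp; names are chromosome labels without a `"chr"` prefix.
#' @return An object of class `genome_build`: a list with elements
#'   `name` and `chrom_lengths`.
#' @examples
#' toy <- genome_build("toy", c(`1` = 1e6, `2` = 5e5))
#' genome_size(toy)
#' @export
genome_build <- function(name, chrom_lengths) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named by chromosome")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(list(name = name,
                 chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                                 names(chrom_lengths))),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", x$name, "-", length(x$chrom_lengths),
      "chromosomes,", format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Total genome size of a build
#'
#' @param build A [genome_build()].
#' @return Total length in bp (numeric scalar).
#' @export
genome_size <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  sum(build$chrom_lengths)
}

# GRCh37 (hg19) autosome lengths in bp, chromosomes 1-22.
.grch37_autosome_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566)

#' GRCh37 autosomes
#'
#' The 22 human autosome lengths of assembly GRCh37, bundled so that
#' genome fractions and length filters need no external download. Only
#' autosomes are modelled: the analysis is restricted to autosomal
#' germline CNVs and sex chromosomes are rejected at ingest.
#'
#' @return A [genome_build()] named `"GRCh37"` with chromosomes
#'   `"1"`..`"22"`.
#' @export
grch37_autosomes <- function() {
  genome_build("GRCh37", .grch37_autosome_lengths)
}

#' The 13 mammalian genomes used for copy-number conservation
#'
#' Default species set for orthology profiles: cow, marmoset, dog,
#' horse, cat, gorilla, macaque, mouse, rabbit, sheep, chimpanzee,
#' rat and pig.
#'
#' @return Character vector of 13 species identifiers.
#' @export
mammal_species_13 <- function() {
  c("bos_taurus", "callithrix_jacchus", "canis_familiaris",
    "equus_caballus", "felis_catus", "gorilla_gorilla",
    "macaca_mulatta", "mus_musculus", "oryctolagus_cuniculus",
    "ovis_aries", "pan_troglodytes", "rattus_norvegicus", "sus_scrofa")
}

# Autosome labels accepted at ingest (after stripping any "chr" prefix).
.autosome_labels <- as.character(1:22)

# Sex/mitochondrial labels silently dropped at ingest.
.non_autosome_labels <- c("X", "Y", "MT", "M")

# Order chromosome labels numerically where possible, else lexically.
chrom_order <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  ord <- order(is.na(n), n, chrom)
  ord
}

# Internal: 0-based half-open data.frame intervals -> GRanges (1-based closed).
intervals_to_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

# Internal: GRanges -> 0-based half-open data.frame.
granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
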