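#' @importFrom stats setNames median quantile pchisq pnorm phyper runif
#'   rbinom rlnorm rbeta fligner.test chisq.test ks.test
#' @importFrom utils read.table write.table
NULL

# Required columns of the internal CNV record data.frame.
.cnv_columns <- c("id", "chrom", "start", "end", "type", "interpretation",
                  "study")

# Validate a CNV record frame against the domain invariants:
# 0-based half-open coordinates, start < end, length in [50, 0.1 * chrom],
# autosomal chromosome present in the build, type/interpretation enums.
validate_cnvs <- function(cnvs, build = NULL, check_length = TRUE) {
  if (!is.data.frame(cnvs))
    stop("cnvs must be a data.frame")
  missing_cols <- setdiff(.cnv_columns, names(cnvs))
  if (length(missing_cols))
    stop("cnvs is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(cnvs) == 0L) return(invisible(cnvs))
  if (any(cnvs$start >= cnvs$end))
    stop("CNV records must satisfy start < end (0-based half-open)")
  if (!all(cnvs$type %in% c("gain", "loss")))
    stop("cnv type must be 'gain' or 'loss'")
  if (!all(cnvs$interpretation %in% c("benign", "pathogenic")))
    stop("cnv interpretation must be 'benign' or 'pathogenic'")
  if (!is.null(build)) {
    unknown <- setdiff(unique(cnvs$chrom), names(build$chrom_lengths))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    if (check_length) {
      len <- cnvs$end - cnvs$start
      L <- build$chrom_lengths[cnvs$chrom]
      if (any(len < 50))
        stop("CNV records shorter than 50 bp violate the minimum-length filter")
      if (any(len > 0.1 * L))
        stop("CNV records longer than a tenth of their chromosome violate ",
             "the maximum-length filter")
      if (any(cnvs$end > L))
        stop("CNV extends beyond chromosome end")
    }
  }
  invisible(cnvs)
}

# Strip an optional "chr" prefix from chromosome labels.
strip_chr <- function(x) sub("^chr", "", x)

#' Read a CNV table, applying the ingestion filters
#'
#' Reads CNV calls with clinical interpretation from a tab-separated
#' table and applies the study's ingestion rules: calls shorter than
#' 50 bp are dropped (the minimum CNV length in the source data),
#' calls longer than a tenth of their chromosome are dropped (they
#' inflate gene counts and confound the analysis), and non-autosomal
#' calls are dropped (the analysis is restricted to autosomal germline
#' variants).
#'
#' Two dialects are supported. `"dbvar_tsv"` has a header line with
#' columns `id`, `chrom`, `start`, `end`, `type`, `interpretation`,
#' `study` and 1-based inclusive coordinates, which are converted to
#' the internal 0-based half-open convention at this boundary.
#' `"bed_like"` is headerless with columns `chrom`, `start`, `end`,
#' `id`, `type`, `interpretation`, `study` and is already 0-based
#' half-open.
#'
#' @param path Path to the table.
#' @param dialect `"dbvar_tsv"` (default) or `"bed_like"`.
#' @param build A [genome_build()]; every autosomal chromosome
#'   referenced by the table must be present, otherwise an error is
#'   raised. Sex chromosomes / mitochondria (`X`, `Y`, `MT`, `M`) are
#'   silently dropped.
#' @return A data.frame of CNV records (columns `id`, `chrom`,
#'   `start`, `end`, `type`, `interpretation`, `study`; 0-based
#'   half-open) sorted by (chromosome, start). May have zero rows.
#' @export
read_cnv_table <- function(path, dialect = c("dbvar_tsv", "bed_like"),
                           build = grch37_autosomes()) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  header <- dialect == "dbvar_tsv"
  raw <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", colClasses = "character")
  if (dialect == "bed_like") {
    if (ncol(raw) < 7)
      stop("bed_like dialect requires 7 columns: ",
           "chrom, start, end, id, type, interpretation, study")
    raw <- raw[, 1:7]
    names(raw) <- c("chrom", "start", "end", "id", "type",
                    "interpretation", "study")
  } else {
    missing_cols <- setdiff(.cnv_columns, names(raw))
    if (length(missing_cols))
      stop("dbvar_tsv dialect is missing columns: ",
           paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    out <- raw[, .cnv_columns]
    out$start <- numeric(0); out$end <- numeric(0)
    return(out)
  }
  line_offset <- if (header) 1L else 0L
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop("unparsable coordinates at line ", bad[1] + line_offset,
         " of ", path)
  if (dialect == "dbvar_tsv") start <- start - 1  # 1-based incl. -> 0-based
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", bad[1] + line_offset, " of ", path)
  bad <- which(!raw$type %in% c("gain", "loss"))
  if (length(bad))
    stop("unknown CNV type '", raw$type[bad[1]], "' at line ",
         bad[1] + line_offset, " of ", path)
  bad <- which(!raw$interpretation %in% c("benign", "pathogenic"))
  if (length(bad))
    stop("unknown interpretation '", raw$interpretation[bad[1]],
         "' at line ", bad[1] + line_offset, " of ", path)

  chrom <- strip_chr(raw$chrom)
  keep <- !(chrom %in% .non_autosome_labels)
  unknown <- setdiff(unique(chrom[keep]), names(build$chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))

  cnvs <- data.frame(id = raw$id, chrom = chrom, start = start, end = end,
                     type = raw$type, interpretation = raw$interpretation,
                     study = raw$study, stringsAsFactors = FALSE)[keep, ]
  # Length filters: >= 50 bp and <= 10% of the chromosome.
  len <- cnvs$end - cnvs$start
  L <- build$chrom_lengths[cnvs$chrom]
  cnvs <- cnvs[len >= 50 & len <= 0.1 * L & cnvs$end <= L, , drop = FALSE]
  cnvs <- cnvs[order(match(cnvs$chrom, names(build$chrom_lengths)),
                     cnvs$start), , drop = FALSE]
  rownames(cnvs) <- NULL
  validate_cnvs(cnvs, build)
  cnvs
}

#' Write CNV records as a dbVar-style TSV
#'
#' Inverse of [read_cnv_table()] for the `"dbvar_tsv"` dialect:
#' internal 0-based half-open coordinates are written 1-based
#' inclusive with a header line.
#'
#' @param cnvs CNV record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cnvs, path) {
  out <- cnvs[, .cnv_columns]
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Gene table columns. Coordinates in the file are 1-based inclusive
# (Ensembl-style) and converted at this boundary.
.gene_required <- c("gene_id", "chrom", "start", "end", "strand")
.gene_flags <- c("developmental", "complex_member", "ohnologue",
                 "omim_disease")
.gene_numeric <- c("hi_score", "max_expression")

#' Read a protein-coding gene table
#'
#' Reads a flat tab-separated gene annotation table (a pre-joined
#' stand-in for an Ensembl-style annotation plus per-gene attribute
#' joins). Required columns: `gene_id`, `chrom`, `start`, `end`
#' (1-based inclusive, converted to 0-based half-open), `strand`.
#' Optional boolean flags (`developmental`, `complex_member`,
#' `ohnologue`, `omim_disease`, `ancestral`, `dosage_sensitive`)
#' default to `FALSE` when the column is absent; optional numeric
#' attributes (`hi_score`, the probability of loss-of-function
#' intolerance used as a haploinsufficiency proxy, and
#' `max_expression`, the maximum RPKM over tissues) default to `NA`.
#'
#' @param path Path to the table.
#' @return Data.frame of gene records sorted by (chromosome, start).
#'   Duplicate `gene_id` values raise an error naming the id.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  missing_cols <- setdiff(.gene_required, names(raw))
  if (length(missing_cols))
    stop("gene table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", dup[1])
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  if (any(!is.finite(start) | !is.finite(end)))
    stop("malformed gene coordinates in ", path)
  genes <- data.frame(gene_id = as.character(raw$gene_id),
                      chrom = strip_chr(as.character(raw$chrom)),
                      start = start - 1, end = end,
                      strand = as.character(raw$strand),
                      stringsAsFactors = FALSE)
  if (any(genes$start >= genes$end))
    stop("malformed gene coordinates (start >= end) in ", path)
  for (fl in c(.gene_flags, "ancestral", "dosage_sensitive"))
    genes[[fl]] <- if (fl %in% names(raw)) as.logical(raw[[fl]])
                   else rep(FALSE, nrow(genes))
  for (nm in .gene_numeric)
    genes[[nm]] <- if (nm %in% names(raw)) as.numeric(raw[[nm]])
                   else rep(NA_real_, nrow(genes))
  if (any(!is.na(genes$hi_score) &
          (genes$hi_score < 0 | genes$hi_score > 1)))
    stop("hi_score outside [0, 1]")
  genes <- genes[order(match(genes$chrom,
                             unique(genes$chrom)[chrom_order(unique(genes$chrom))]),
                       genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write a gene table
#'
#' Inverse of [read_gene_table()]; coordinates are written 1-based
#' inclusive.
#'
#' @param genes Gene record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$start <- format(out$start + 1, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.orthology_statuses <- c("one2one", "one2many", "none")

#' Read a long-format orthology table into per-gene profiles
#'
#' Reads rows of `(human_gene, species, status)` with status one of
#' `one2one`, `one2many` or `none`, and returns one orthology profile
#' per human gene covering exactly the given species list. A
#' (gene, species) pair absent from the file is recorded as `none`
#' (no orthologue detected). A `many2many` status is rejected: it must
#' be resolved upstream by recent-paralogue grouping (see
#' [group_recent_paralogues()]).
#'
#' @param path Path to the TSV (header: `human_gene`, `species`,
#'   `status`).
#' @param species_list Character vector of species; defaults to the
#'   13-mammal set of [mammal_species_13()].
#' @return An orthology profile data.frame: column `unit_id`, one
#'   status column per species, and a `group_members` list column
#'   (singletons here); `attr(x, "species")` holds the species list.
#' @export
read_orthology_table <- function(path, species_list = mammal_species_13()) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  need <- c("human_gene", "species", "status")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("orthology table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(raw$status), .orthology_statuses)
  if (length(bad))
    stop("unknown orthology status token: ", bad[1])
  bad <- setdiff(unique(raw$species), species_list)
  if (length(bad))
    stop("species not in species_list: ", bad[1])
  if (anyDuplicated(raw[, c("human_gene", "species")]))
    stop("duplicated (human_gene, species) row in ", path)
  genes <- unique(raw$human_gene)
  status <- matrix("none", nrow = length(genes), ncol = length(species_list),
                   dimnames = list(genes, species_list))
  status[cbind(raw$human_gene, raw$species)] <- raw$status
  profiles <- data.frame(unit_id = genes, stringsAsFactors = FALSE)
  for (sp in species_list) profiles[[sp]] <- unname(status[, sp])
  profiles$group_members <- as.list(genes)
  attr(profiles, "species") <- species_list
  profiles
}

#' Write orthology profiles as a long-format TSV
#'
#' Inverse of [read_orthology_table()]. `none` rows are written
#' explicitly so the round trip is exact.
#'
#' @param profiles Orthology profile data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthology_table <- function(profiles, path) {
  species <- attr(profiles, "species")
  long <- do.call(rbind, lapply(species, function(sp)
    data.frame(human_gene = profiles$unit_id, species = sp,
               status = profiles[[sp]], stringsAsFactors = FALSE)))
  long <- long[order(long$human_gene, long$species), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write intervals as BED4/BED5
#'
#' Writes 0-based half-open intervals as standard BED lines
#' (tab-separated, sorted by chromosome and start). With a `score`
#' column present, BED5 is written; otherwise BED4.
#'
#' @param intervals Data.frame with columns `chrom`, `start`, `end`,
#'   `name` and optionally `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end", "name")
  if ("score" %in% names(intervals)) cols <- c(cols, "score")
  missing_cols <- setdiff(cols, names(intervals))
  if (length(missing_cols))
    stop("write_bed needs columns: ", paste(missing_cols, collapse = ", "))
  out <- intervals[, cols, drop = FALSE]
  if (nrow(out)) {
    out <- out[order(match(out$chrom,
                           unique(out$chrom)[chrom_order(unique(out$chrom))]),
                     out$start), , drop = FALSE]
    out$start <- format(out$start, scientific = FALSE, trim = TRUE)
    out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4/BED5 file
#'
#' @param path Path to a BED file as written by [write_bed()].
#' @return Data.frame with columns `chrom`, `start`, `end`, `name`
#'   and, for BED5 input, `score`; 0-based half-open.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  info <- file.info(path)
  if (info$size == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  names(raw)[1:4] <- c("chrom", "start", "end", "name")
  if (ncol(raw) >= 5) names(raw)[5] <- "score"
  raw$chrom <- as.character(raw$chrom)
  raw$name <- as.character(raw$name)
  raw
}
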