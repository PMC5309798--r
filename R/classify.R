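#' Gene-interval intersection
#'
#' A gene intersects a CNV or region if any of the gene sequence is
#' overlapped by one or more bases, on either strand (strand is
#' ignored). Half-open abutment (gene end equal to interval start) is
#' not an overlap.
#'
#' @param genes Gene record data.frame.
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Named logical vector over `genes$gene_id`.
#' @export
intersect_genes <- function(genes, intervals) {
  if (nrow(genes) == 0L)
    return(stats::setNames(logical(0), character(0)))
  if (nrow(intervals) == 0L)
    return(stats::setNames(rep(FALSE, nrow(genes)), genes$gene_id))
  hit <- GenomicRanges::countOverlaps(intervals_to_granges(genes),
                                      intervals_to_granges(intervals)) > 0
  stats::setNames(hit, genes$gene_id)
}

.class_labels <- c("B", "P", "X", "BL_PG", "BG_PL", "unclassified")

#' Dosage-class label from CNV membership flags
#'
#' Pure truth table mapping the four membership booleans to a class
#' label. Genes covered exclusively by benign CNVs are Class B; genes
#' exclusive to pathogenic peak regions are Class P; genes covered by
#' both clinical interpretations for the same CNV type (gain or loss)
#' are inconsistent "passengers", Class X, and this condition
#' dominates regardless of other flags; the two exclusive cross-type
#' patterns benign-loss + pathogenic-gain and benign-gain +
#' pathogenic-loss are labelled BL_PG and BG_PL; genes with no
#' membership are unclassified.
#'
#' @param in_benign_gain,in_benign_loss,in_path_gain_peak,in_path_loss_peak
#'   Logical vectors (recycled to common length).
#' @return Character vector of labels in
#'   `c("B","P","X","BL_PG","BG_PL","unclassified")`.
#' @export
class_from_membership <- function(in_benign_gain, in_benign_loss,
                                  in_path_gain_peak, in_path_loss_peak) {
  n <- max(length(in_benign_gain), length(in_benign_loss),
           length(in_path_gain_peak), length(in_path_loss_peak))
  bg <- rep_len(in_benign_gain, n); bl <- rep_len(in_benign_loss, n)
  pg <- rep_len(in_path_gain_peak, n); pl <- rep_len(in_path_loss_peak, n)
  benign <- bg | bl
  path <- pg | pl
  x <- (bg & pg) | (bl & pl)   # same-type contradiction dominates
  lab <- rep("unclassified", n)
  lab[!x & benign & !path] <- "B"
  lab[!x & path & !benign] <- "P"
  lab[x] <- "X"
  lab[!x & bl & pg] <- "BL_PG"  # !x forces exactly {benign loss, path gain}
  lab[!x & bg & pl] <- "BG_PL"
  lab
}

#' Assign dosage classes to genes
#'
#' Classifies every gene by its pattern of CNV overlap, considering
#' all CNVs simultaneously: full CNVs for the benign side (the entire
#' benign call is presumed benign) and peak regions only for the
#' pathogenic side (the recurrent subregions most likely to contain
#' the causative genes).
#'
#' @param genes Gene record data.frame.
#' @param benign_gain_cnvs,benign_loss_cnvs Full benign CNV records of
#'   the respective type (data.frames with `chrom`, `start`, `end`).
#' @param path_gain_peaks,path_loss_peaks Pathogenic peak regions from
#'   typed-scope [find_peaks()] runs.
#' @return Data.frame with `gene_id`, the four membership booleans and
#'   `label`.
#' @export
assign_classes <- function(genes, benign_gain_cnvs, benign_loss_cnvs,
                           path_gain_peaks, path_loss_peaks) {
  bg <- intersect_genes(genes, benign_gain_cnvs)
  bl <- intersect_genes(genes, benign_loss_cnvs)
  pg <- intersect_genes(genes, path_gain_peaks)
  pl <- intersect_genes(genes, path_loss_peaks)
  data.frame(gene_id = genes$gene_id,
             in_benign_gain = unname(bg), in_benign_loss = unname(bl),
             in_path_gain_peak = unname(pg), in_path_loss_peak = unname(pl),
             label = class_from_membership(bg, bl, pg, pl),
             stringsAsFactors = FALSE)
}

#' Solitary Class P genes per region
#'
#' For each pathogenic peak region (or CNVR), lists the Class P genes
#' it overlaps and flags regions containing exactly one — the
#' "solitary" candidate causative gene, pathogenic by exclusion.
#'
#' @param peaks Data.frame of peak regions (or CNVRs) with `peak_id`
#'   or `region_id`, `chrom`, `start`, `end`, and optionally `scope`.
#' @param assignments An [assign_classes()] result.
#' @param genes Gene record data.frame (same universe as
#'   `assignments`).
#' @return Data.frame with one row per region: `peak_id`,
#'   `class_p_gene_ids` (list column), `n_class_p`, `solitary`.
#' @export
find_solitary <- function(peaks, assignments, genes) {
  id_col <- if ("peak_id" %in% names(peaks)) "peak_id" else "region_id"
  p_genes <- genes[genes$gene_id %in%
                     assignments$gene_id[assignments$label == "P"], ,
                   drop = FALSE]
  out <- data.frame(peak_id = peaks[[id_col]], stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) {
    out$class_p_gene_ids <- I(list())
    out$n_class_p <- integer(0)
    out$solitary <- logical(0)
    return(out)
  }
  if (nrow(p_genes) == 0L) {
    out$class_p_gene_ids <- I(replicate(nrow(peaks), character(0),
                                        simplify = FALSE))
  } else {
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(peaks),
                                        intervals_to_granges(p_genes))
    out$class_p_gene_ids <- I(unname(split(
      p_genes$gene_id[S4Vectors::subjectHits(hits)],
      factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(peaks))))))
  }
  out$n_class_p <- lengths(out$class_p_gene_ids)
  out$solitary <- out$n_class_p == 1L
  if ("scope" %in% names(peaks)) out$scope <- peaks$scope
  rownames(out) <- NULL
  out
}

#' Summary of solitary Class P genes across regions
#'
#' Counts solitary regions, the unique solitary genes across regions,
#' and (when the calls carry a typed `scope`) the subset of genes that
#' are the solitary Class P gene for both a duplication and a deletion
#' region.
#'
#' @param calls A [find_solitary()] result.
#' @return List with `n_regions`, `n_solitary_regions`,
#'   `n_regions_without_class_p`, `solitary_genes` (character),
#'   `dual_type_solitary_genes` (character; empty when no `scope`
#'   column is present).
#' @export
solitary_summary <- function(calls) {
  sol <- calls[calls$solitary, , drop = FALSE]
  sol_genes <- unique(unlist(sol$class_p_gene_ids))
  if (is.null(sol_genes)) sol_genes <- character(0)
  dual <- character(0)
  if ("scope" %in% names(calls) && nrow(sol)) {
    g <- unlist(sol$class_p_gene_ids)
    s <- rep(sol$scope, lengths(sol$class_p_gene_ids))
    dual <- intersect(unique(g[s == "gain_only"]),
                      unique(g[s == "loss_only"]))
  }
  list(n_regions = nrow(calls),
       n_solitary_regions = sum(calls$solitary),
       n_regions_without_class_p = sum(calls$n_class_p == 0L),
       solitary_genes = sol_genes,
       dual_type_solitary_genes = dual)
}

#' Per-CNV fraction of flagged genes
#'
#' For each interval (CNV, CNVR or peak), the proportion of
#' overlapping genes carrying a boolean flag (e.g. `developmental`) —
#' the study's correction for CNV length when comparing gene content.
#' Intervals overlapping no genes yield `NA` (the proportion is
#' undefined and such CNVs are excluded from downstream medians).
#'
#' @param intervals Data.frame with `chrom`, `start`, `end`.
#' @param genes Gene record data.frame.
#' @param flag_name Name of a logical gene column.
#' @return Numeric vector, one value (or `NA`) per interval row.
#' @export
annotation_fraction_per_cnv <- function(intervals, genes, flag_name) {
  if (!flag_name %in% names(genes) || !is.logical(genes[[flag_name]]))
    stop("unknown or non-logical gene flag: ", flag_name)
  if (nrow(intervals) == 0L) return(numeric(0))
  n_total <- rep(0L, nrow(intervals))
  n_flag <- rep(0L, nrow(intervals))
  if (nrow(genes)) {
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(intervals),
                                        intervals_to_granges(genes))
    q <- S4Vectors::queryHits(hits)
    fl <- genes[[flag_name]][S4Vectors::subjectHits(hits)]
    tt <- tabulate(q, nbins = nrow(intervals))
    tf <- tabulate(q[fl %in% TRUE], nbins = nrow(intervals))
    n_total <- tt
    n_flag <- tf
  }
  ifelse(n_total == 0L, NA_real_, n_flag / n_total)
}

#' Distance to the nearest flagged gene
#'
#' Gap in bp from each query gene to the nearest other gene carrying
#' the flag on the same chromosome; 0 when overlapping or book-ended
#' with a flagged gene, `NA` when the chromosome has no other flagged
#' gene. The query gene itself is excluded.
#'
#' @param query Gene record data.frame (rows to measure from).
#' @param genes Gene record data.frame (the universe searched).
#' @param flag_name Name of a logical gene column.
#' @return Numeric vector of distances (bp), one per query row.
#' @export
distance_to_nearest_flagged <- function(query, genes, flag_name) {
  if (!flag_name %in% names(genes) || !is.logical(genes[[flag_name]]))
    stop("unknown or non-logical gene flag: ", flag_name)
  flagged <- genes[genes[[flag_name]] %in% TRUE, , drop = FALSE]
  vapply(seq_len(nrow(query)), function(i) {
    f <- flagged[flagged$chrom == query$chrom[i] &
                   flagged$gene_id != query$gene_id[i], , drop = FALSE]
    if (nrow(f) == 0L) return(NA_real_)
    # half-open gap; 0 when intervals overlap or abut
    gap <- pmax(f$start - query$end[i], query$start[i] - f$end, 0)
    min(gap)
  }, numeric(1))
}
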