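#' Merge CNVs into CNV regions (CNVRs)
#'
#' Sets of partially overlapping CNVs sharing one clinical
#' interpretation are grouped into CNVRs: maximal overlap-connected
#' components of the interval graph. Book-ended (abutting) CNVs are
#' merged, matching the default behaviour of standard interval-merge
#' tools. With a typed scope, only gains (or only losses) are merged,
#' so that duplication and deletion CNVRs can be built separately.
#'
#' @param cnvs CNV record data.frame (one interpretation only).
#' @param scope `"grouped"` (gains and losses merged together),
#'   `"gain_only"` or `"loss_only"`.
#' @return Data.frame of CNVRs sorted by (chromosome, start) with
#'   columns `region_id`, `chrom`, `start`, `end`, `n_members`,
#'   `scope`, `interpretation` and a `members` list column of member
#'   CNV ids.
#' @export
merge_cnvrs <- function(cnvs, scope = c("grouped", "gain_only", "loss_only")) {
  scope <- match.arg(scope)
  validate_cnvs(cnvs)
  interp <- unique(cnvs$interpretation)
  if (length(interp) > 1)
    stop("mixed clinical interpretations; merge benign and pathogenic ",
         "CNVs separately")
  if (scope == "gain_only") cnvs <- cnvs[cnvs$type == "gain", , drop = FALSE]
  if (scope == "loss_only") cnvs <- cnvs[cnvs$type == "loss", , drop = FALSE]
  if (nrow(cnvs) == 0L)
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_members = integer(0), scope = character(0),
                      interpretation = character(0),
                      members = I(list()), stringsAsFactors = FALSE))
  gr <- intervals_to_granges(cnvs)
  # reduce() merges overlapping and book-ended ranges (min.gapwidth = 1).
  red <- GenomicRanges::reduce(gr)
  red <- GenomicRanges::sort(red)
  regions <- granges_to_intervals(red)
  ord <- order(match(regions$chrom,
                     unique(regions$chrom)[chrom_order(unique(regions$chrom))]),
               regions$start)
  regions <- regions[ord, , drop = FALSE]
  red <- red[ord]
  hits <- GenomicRanges::findOverlaps(gr, red, type = "within")
  members <- split(cnvs$id[S4Vectors::queryHits(hits)],
                   factor(S4Vectors::subjectHits(hits),
                          levels = seq_len(nrow(regions))))
  regions$region_id <- sprintf("CNVR_%s_%s_%04d",
                               substr(interp, 1, 1),
                               switch(scope, grouped = "all",
                                      gain_only = "gain", loss_only = "loss"),
                               seq_len(nrow(regions)))
  regions$n_members <- lengths(members)
  regions$scope <- scope
  regions$interpretation <- interp
  regions$members <- I(unname(members))
  rownames(regions) <- NULL
  regions[, c("region_id", "chrom", "start", "end", "n_members",
              "scope", "interpretation", "members")]
}

#' Coverage step-function of a CNVR
#'
#' Computes CNV coverage — the number of member CNVs overlapping each
#' base — as a step function over the CNVR, by sweeping the sorted
#' member endpoints. Adjacent segments of equal depth are fused, so
#' consecutive segments always differ in depth, and the segments tile
#' the region exactly.
#'
#' @param region One row of a [merge_cnvrs()] result.
#' @param cnvs The CNV record data.frame the region was built from.
#' @return Data.frame with columns `region_id`, `chrom`, `start`,
#'   `end`, `depth`, ordered by position; depths are positive and
#'   satisfy sum(depth * width) = sum of member CNV lengths.
#' @export
coverage_profile <- function(region, cnvs) {
  stopifnot(nrow(region) == 1L)
  ids <- region$members[[1]]
  if (length(ids) == 0L) stop("region has no member CNVs")
  m <- cnvs[match(ids, cnvs$id), , drop = FALSE]
  if (anyNA(m$start)) stop("member CNV ids missing from cnvs")
  bp <- sort(unique(c(m$start, m$end)))
  seg_start <- bp[-length(bp)]
  seg_end <- bp[-1]
  # depth of each elementary segment: members covering it entirely
  depth <- vapply(seq_along(seg_start), function(i)
    sum(m$start <= seg_start[i] & m$end >= seg_end[i]), numeric(1))
  if (any(depth < 1))
    stop("zero-coverage gap inside CNVR; members are not overlap-connected")
  # fuse runs of equal depth
  r <- rle(depth)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  out <- data.frame(region_id = region$region_id,
                    chrom = region$chrom,
                    start = seg_start[idx_start],
                    end = seg_end[idx_end],
                    depth = r$values,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect local-maximum peak regions in a coverage profile
#'
#' A peak region is any local maximum in CNV coverage: a maximal
#' constant-depth plateau whose two neighbouring depths are both
#' strictly lower, with depth taken as 0 beyond the CNVR ends. A CNVR
#' may contain multiple peaks; where a CNVR consists of a single CNV,
#' the entire CNV is the peak (coverage 1 everywhere beats the zero
#' flanks). Plateaus at the CNVR edges qualify when their depth
#' exceeds the single interior neighbour.
#'
#' @param profile A [coverage_profile()] result.
#' @return Data.frame of peaks with columns `peak_id`, `region_id`,
#'   `chrom`, `start`, `end`, `depth`; at least one row per CNVR.
#' @export
find_peak_regions <- function(profile) {
  stopifnot(nrow(profile) >= 1L)
  d <- c(0, profile$depth, 0)  # depth is 0 outside the CNVR
  n <- nrow(profile)
  is_peak <- d[2:(n + 1)] > d[1:n] & d[2:(n + 1)] > d[3:(n + 2)]
  peaks <- profile[is_peak, c("region_id", "chrom", "start", "end", "depth"),
                   drop = FALSE]
  peaks$peak_id <- sprintf("%s_peak%02d", peaks$region_id,
                           seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks[, c("peak_id", "region_id", "chrom", "start", "end", "depth")]
}

#' Peaks of every CNVR in a region set
#'
#' Convenience wrapper applying [coverage_profile()] and
#' [find_peak_regions()] to each CNVR.
#'
#' @param regions A [merge_cnvrs()] result.
#' @param cnvs The CNV records the regions were built from.
#' @return Data.frame of all peaks, with the parent region's `scope`
#'   and `interpretation` carried along.
#' @export
find_peaks <- function(regions, cnvs) {
  if (nrow(regions) == 0L)
    return(data.frame(peak_id = character(0), region_id = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), depth = numeric(0),
                      scope = character(0), interpretation = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    p <- find_peak_regions(coverage_profile(regions[i, , drop = FALSE], cnvs))
    p$scope <- regions$scope[i]
    p$interpretation <- regions$interpretation[i]
    p
  }))
  rownames(out) <- NULL
  out
}

# Union of 0-based half-open intervals (data.frame chrom/start/end).
union_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  granges_to_intervals(GenomicRanges::sort(
    GenomicRanges::reduce(intervals_to_granges(intervals))))
}

#' Fraction of the genome covered by a set of intervals
#'
#' Total unioned interval length divided by the total length of the
#' build's chromosomes (for the bundled GRCh37 set, the sum of the 22
#' autosomes — the data are autosomal).
#'
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); overlapping intervals are unioned first.
#' @param build A [genome_build()].
#' @return Fraction in `[0, 1]`.
#' @export
genome_fraction <- function(intervals, build) {
  if (nrow(intervals) == 0L) return(0)
  u <- union_intervals(intervals)
  unknown <- setdiff(unique(u$chrom), names(build$chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (any(u$end > build$chrom_lengths[u$chrom]))
    stop("interval extends beyond chromosome end")
  sum(u$end - u$start) / genome_size(build)
}

#' Base-pair overlap between two interval sets
#'
#' Each side is unioned internally, then intersected; reports the
#' overlap in bp and as a fraction of the first set's unioned length
#' (e.g. the fraction of benign CNVR territory overlapped by
#' pathogenic CNVs).
#'
#' @param a,b Data.frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return List with `bp_overlap` and `fraction_of_a`. An empty `a`
#'   makes the fraction undefined and raises an error.
#' @export
region_overlap <- function(a, b) {
  ua <- union_intervals(a)
  total_a <- sum(ua$end - ua$start)
  if (!is.finite(total_a) || total_a == 0)
    stop("union of 'a' is empty; fraction_of_a is undefined")
  if (nrow(b) == 0L) return(list(bp_overlap = 0, fraction_of_a = 0))
  inter <- GenomicRanges::intersect(intervals_to_granges(ua),
                                    intervals_to_granges(union_intervals(b)))
  bp <- sum(as.numeric(GenomicRanges::width(inter)))
  list(bp_overlap = bp, fraction_of_a = bp / total_a)
}
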