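#' Randomize CNV locations
#'
#' Places each CNV at a uniformly random position on its own
#' chromosome, preserving its length, type and interpretation: the
#' new start is drawn uniformly from `[0, L - len]` where `L` is the
#' chromosome length. Randomization is within-chromosome so that
#' chromosome-level gene density is not confounded, and placed CNVs
#' may overlap each other. This is the length-correction null for
#' "how many CNVs would contain a flagged gene by chance".
#'
#' @param cnvs CNV record data.frame.
#' @param build A [genome_build()] containing every referenced
#'   chromosome.
#' @param seed Optional integer seed; when `NULL` the current RNG
#'   stream is used (as inside [permutation_test()]).
#' @return A CNV record data.frame with the same ids and lengths at
#'   new positions.
#' @export
randomize_cnv_locations <- function(cnvs, build, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(cnvs) == 0L) return(cnvs)
  unknown <- setdiff(unique(cnvs$chrom), names(build$chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  len <- cnvs$end - cnvs$start
  L <- unname(build$chrom_lengths[cnvs$chrom])
  if (any(len > L))
    stop("CNV longer than its chromosome cannot be placed")
  max_start <- L - len
  new_start <- floor(stats::runif(nrow(cnvs)) * (max_start + 1))
  new_start <- pmin(new_start, max_start)  # guard the open upper bound
  out <- cnvs
  out$start <- new_start
  out$end <- new_start + len
  out
}

#' Permutation test against the CNV location-randomization null
#'
#' Evaluates a statistic on the observed CNV set and on `n_reps`
#' location-randomized draws, and summarizes the null distribution:
#' mean, sd, maximum, the Z-score `(observed - mean) / sd`, and the
#' add-one empirical p-value `(1 + #(null >= observed)) / (n_reps + 1)`
#' for the upper tail (so p is never exactly 0). A normal-approximation
#' p-value from the Z-score is also reported for comparison with
#' headline "P < 1e-16"-style claims.
#'
#' @param statistic Function of a CNV record data.frame returning one
#'   number; must be deterministic given the CNV set.
#' @param cnvs Observed CNV records.
#' @param build A [genome_build()].
#' @param n_reps Number of randomizations (>= 1).
#' @param seed Integer seed; the whole computation is reproducible
#'   given the seed.
#' @return Object of class `randomization_result`: list with
#'   `observed`, `null_mean`, `null_sd`, `null_max`, `z`,
#'   `p_empirical`, `p_normal`, `n_reps`, `seed`. When the null has
#'   zero spread `z` is `NA` and a warning is issued.
#' @export
permutation_test <- function(statistic, cnvs, build, n_reps = 1000,
                             seed = 1) {
  stopifnot(is.function(statistic), n_reps >= 1)
  set.seed(seed)
  observed <- statistic(cnvs)
  null <- vapply(seq_len(n_reps), function(i)
    statistic(randomize_cnv_locations(cnvs, build)), numeric(1))
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  z <- if (is.finite(null_sd) && null_sd > 0) (observed - null_mean) / null_sd
       else NA_real_
  if (is.na(z))
    warning("null distribution has zero spread; Z-score undefined")
  structure(list(observed = observed,
                 null_mean = null_mean,
                 null_sd = null_sd,
                 null_max = max(null),
                 z = z,
                 p_empirical = (1 + sum(null >= observed)) / (n_reps + 1),
                 p_normal = if (is.na(z)) NA_real_ else
                   stats::pnorm(z, lower.tail = FALSE),
                 n_reps = n_reps,
                 seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("CNV location-randomization test\n")
  cat(sprintf("  observed: %.4g  null mean: %.4g (sd %.4g, max %.4g)\n",
              x$observed, x$null_mean, x$null_sd, x$null_max))
  cat(sprintf("  Z = %.3f, empirical p = %.4g (%d reps, seed %d)\n",
              x$z, x$p_empirical, x$n_reps, x$seed))
  invisible(x)
}

# Fast per-chromosome interval overlap indicator used by the built-in
# statistics: for each interval in a, TRUE if it overlaps any in b.
overlaps_any <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  out <- logical(length(a_start))
  for (ch in unique(a_chrom)) {
    ai <- which(a_chrom == ch)
    bi <- which(b_chrom == ch)
    if (!length(bi)) next
    # overlap iff a.start < b.end and a.end > b.start (half-open)
    out[ai] <- vapply(ai, function(i)
      any(a_start[i] < b_end[bi] & a_end[i] > b_start[bi]), logical(1))
  }
  out
}

#' Statistic: fraction of CNVs containing a flagged gene
#'
#' Builds a statistic closure for [permutation_test()]: the fraction
#' of CNVs in the set that overlap at least one gene carrying the
#' given flag (e.g. the fraction of pathogenic CNVs containing a
#' developmental gene).
#'
#' @param genes Gene record data.frame.
#' @param flag_name Logical gene column.
#' @return Function of a CNV data.frame returning a fraction.
#' @export
stat_frac_with_flagged_gene <- function(genes, flag_name) {
  if (!flag_name %in% names(genes) || !is.logical(genes[[flag_name]]))
    stop("unknown or non-logical gene flag: ", flag_name)
  fg <- genes[genes[[flag_name]] %in% TRUE, , drop = FALSE]
  force(fg)
  function(cnvs) {
    if (nrow(cnvs) == 0L) return(NA_real_)
    mean(overlaps_any(cnvs$chrom, cnvs$start, cnvs$end,
                      fg$chrom, fg$start, fg$end))
  }
}

#' Statistic: fraction of flagged genes covered by the CNV set
#'
#' Complementary statistic: the proportion of flagged genes that are
#' overlapped by at least one CNV of the set.
#'
#' @inheritParams stat_frac_with_flagged_gene
#' @return Function of a CNV data.frame returning a fraction.
#' @export
stat_frac_flagged_genes_covered <- function(genes, flag_name) {
  if (!flag_name %in% names(genes) || !is.logical(genes[[flag_name]]))
    stop("unknown or non-logical gene flag: ", flag_name)
  fg <- genes[genes[[flag_name]] %in% TRUE, , drop = FALSE]
  force(fg)
  function(cnvs) {
    if (nrow(fg) == 0L) return(NA_real_)
    mean(overlaps_any(fg$chrom, fg$start, fg$end,
                      cnvs$chrom, cnvs$start, cnvs$end))
  }
}
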