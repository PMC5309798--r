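# Independent brute-force oracles and toy-data builders shared across
# the suite. These are deliberately naive (per-base counting,
# exhaustive enumeration) so they stay independent of the package's
# sweep/merge implementations.

# Per-base CNV coverage over [lo, hi): depth of each integer base.
per_base_coverage <- function(starts, ends, lo, hi) {
  vapply(lo:(hi - 1), function(b) sum(starts <= b & b < ends), numeric(1))
}

# Per-base local-maximum peak oracle: a base is a peak base iff its
# depth is strictly greater than the nearest differing depth on each
# side (depth 0 beyond the ends). Returns 0-based half-open intervals
# of maximal peak-base runs, relative to lo.
per_base_peaks <- function(depth, lo = 0) {
  n <- length(depth)
  is_peak <- vapply(seq_len(n), function(i) {
    d <- depth[i]
    left <- 0
    for (j in rev(seq_len(i - 1))) if (depth[j] != d) { left <- depth[j]; break }
    right <- 0
    if (i < n) for (j in (i + 1):n) if (depth[j] != d) { right <- depth[j]; break }
    d > left && d > right
  }, logical(1))
  r <- rle(is_peak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = lo + starts[keep] - 1, end = lo + ends[keep],
             depth = depth[starts[keep]])
}

# Independently written 16-row truth table for dosage classes
# (bg = benign gain, bl = benign loss, pg/pl = pathogenic gain/loss
# peak membership).
class_truth_table <- function() {
  tt <- expand.grid(bg = c(FALSE, TRUE), bl = c(FALSE, TRUE),
                    pg = c(FALSE, TRUE), pl = c(FALSE, TRUE))
  lookup <- c(
    "FFFF" = "unclassified",
    "TFFF" = "B", "FTFF" = "B", "TTFF" = "B",
    "FFTF" = "P", "FFFT" = "P", "FFTT" = "P",
    "TFTF" = "X", "TFTT" = "X", "FTFT" = "X", "FTTT" = "X",
    "TTTF" = "X", "TTFT" = "X", "TTTT" = "X",
    "FTTF" = "BL_PG", "TFFT" = "BG_PL")
  key <- apply(tt, 1, function(r)
    paste(ifelse(r, "T", "F"), collapse = ""))
  tt$label <- unname(lookup[key])
  tt
}

# Random CNV record frame on a toy build (lengths respect the
# ingestion invariants for that build).
random_cnvs <- function(n, build, interpretation = "pathogenic") {
  chrom <- sample(names(build$chrom_lengths), n, replace = TRUE)
  L <- build$chrom_lengths[chrom]
  len <- floor(runif(n, 50, 0.1 * L))
  start <- floor(runif(n) * (L - len))
  data.frame(id = sprintf("rc%04d", seq_len(n)), chrom = chrom,
             start = start, end = start + len,
             type = sample(c("gain", "loss"), n, replace = TRUE),
             interpretation = interpretation, study = "test",
             stringsAsFactors = FALSE)
}

# Small dense CNV set on one chromosome with tight coordinates, for
# coverage/peak oracle comparisons.
random_profile_cnvs <- function(n_members, span = 400) {
  start <- sample.int(span, n_members, replace = TRUE) - 1
  len <- sample(5:80, n_members, replace = TRUE)
  data.frame(id = sprintf("m%03d", seq_len(n_members)), chrom = "1",
             start = start, end = start + len,
             type = "loss", interpretation = "pathogenic", study = "test",
             stringsAsFactors = FALSE)
}

toy_build <- function(lengths = c(`1` = 1e5, `2` = 8e4)) {
  genome_build("toy", lengths)
}

# Minimal gene frame builder.
toy_genes <- function(chrom, start, end, ...) {
  n <- length(start)
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                  chrom = chrom, start = start, end = end,
                  strand = rep("+", n), stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) g[[nm]] <- extra[[nm]]
  for (fl in c("developmental", "complex_member", "ohnologue",
               "omim_disease", "ancestral", "dosage_sensitive"))
    if (is.null(g[[fl]])) g[[fl]] <- FALSE
  if (is.null(g$hi_score)) g$hi_score <- NA_real_
  if (is.null(g$max_expression)) g$max_expression <- NA_real_
  g
}

# Fligner-Killeen statistic recomputed from the rank-score formula,
# independent of stats::fligner.test.
fligner_by_formula <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  dev <- unlist(lapply(groups, function(v) abs(v - median(v))))
  N <- length(x)
  a <- qnorm(0.5 + rank(dev) / (2 * (N + 1)))
  abar <- mean(a)
  v <- sum((a - abar)^2) / (N - 1)
  sum(tapply(a, g, function(ai) length(ai) * (mean(ai) - abar)^2)) / v
}

# Exact Mann-Whitney U by pairwise comparison (ties count 1/2).
u_by_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
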