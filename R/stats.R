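#' Pearson chi-squared test with adjusted residuals
#'
#' Uncorrected Pearson chi-squared test of independence on an r x c
#' contingency table, with the per-cell adjusted (standardized)
#' residual `(obs - exp) / sqrt(exp * (1 - row_total/N) *
#' (1 - col_total/N))`. Residuals beyond +/-2 flag the cells driving
#' the association. No continuity correction is applied.
#'
#' @param table Numeric matrix of non-negative counts, at least 2x2.
#' @return List with `chi2`, `df`, `p` and `adjusted_residuals` (a
#'   matrix matching `table`). Zero row or column totals are an
#'   error.
#' @export
chi2_with_residuals <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2x2")
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("counts must be finite and non-negative")
  rt <- rowSums(tab); ct <- colSums(tab); N <- sum(tab)
  if (any(rt == 0) || any(ct == 0))
    stop("zero marginal total in contingency table")
  expd <- outer(rt, ct) / N
  chi2 <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  adj <- (tab - expd) / sqrt(expd * outer(1 - rt / N, 1 - ct / N))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       adjusted_residuals = adj)
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Two-sided rank-sum comparison of two samples. The U statistic is
#' reported for the first sample; the p-value uses the normal
#' approximation with the tie-corrected variance and no continuity
#' correction. When every value in both samples is identical the
#' comparison is vacuous and p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U`, `z` and `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)  # all values identical across both samples
    return(list(U = U, z = 0, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Fligner-Killeen scale test
#'
#' Rank-based test for homogeneity of variances across two or more
#' groups, using normal scores of the ranked absolute deviations from
#' each group's median, referred to a chi-squared distribution. Robust
#' to non-normality, which suits skewed per-gene conservation counts.
#' Backed by [stats::fligner.test()]; the degenerate case where every
#' group has zero spread is flagged and returns p = 1.
#'
#' @param groups List of >= 2 numeric samples, each of length >= 2.
#' @return List with `statistic`, `df`, `p` and `degenerate`.
#' @export
fligner_killeen <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  dev <- unlist(lapply(groups, function(g) abs(g - stats::median(g))))
  # all deviations equal (e.g. every group constant): the normal
  # scores have zero variance and the statistic is undefined
  if (length(unique(dev)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1, p = 1,
                degenerate = TRUE))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ft <- stats::fligner.test(x, g)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, degenerate = FALSE)
}

#' Hypergeometric term enrichment with a custom background
#'
#' Upper-tail hypergeometric enrichment of each term's gene set in a
#' query list against a custom background universe (e.g. solitary
#' Class P genes against all genes in full pathogenic CNVRs), with
#' Bonferroni correction over the number of terms tested. Term gene
#' sets are intersected with the background before testing.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `background` (a query gene outside the background is an error
#'   naming the gene).
#' @param background Character vector of gene ids (the universe).
#' @param term_map Named list: term id -> character vector of gene
#'   ids.
#' @return Data.frame with one row per term: `term`, `k` (query
#'   hits), `n` (query size), `K` (background hits), `N` (background
#'   size), `p_raw`, `p_bonferroni` (`min(1, m * p_raw)` with `m` the
#'   number of terms tested, echoed as attribute `m`).
#' @export
hypergeom_enrichment <- function(query, background, term_map) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene absent from background: ", outside[1])
  n <- length(query); N <- length(background)
  m <- length(term_map)
  out <- do.call(rbind, lapply(names(term_map), function(tm) {
    hits <- intersect(term_map[[tm]], background)
    K <- length(hits)
    k <- length(intersect(hits, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  }))
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  attr(out, "m") <- m
  rownames(out) <- NULL
  out
}

#' Dosage-class enrichment battery
#'
#' For each boolean gene attribute (developmental, protein-complex
#' membership, ohnologue, OMIM disease, and "haploinsufficient" =
#' `hi_score > hi_threshold`), reports the per-class percentage and
#' count plus a chi-squared test with adjusted residuals across the
#' classes; for the numeric attributes (`hi_score`,
#' `max_expression`), per-class medians plus pairwise Mann-Whitney
#' comparisons. All p-values are Bonferroni-corrected over the number
#' of simultaneous comparisons in the emitted table, and the family
#' size used is echoed for auditability.
#'
#' @param assignments An [assign_classes()] result.
#' @param genes Gene record data.frame.
#' @param classes Classes to compare (default B, P, X, BL_PG, BG_PL;
#'   classes with no genes are dropped).
#' @param flags Boolean columns to test.
#' @param numeric_attrs Numeric columns to compare by medians.
#' @param hi_threshold Threshold defining "haploinsufficient" genes
#'   from `hi_score` (default 0.9).
#' @return List with `flag_tests` (data.frame), `flag_details` (list
#'   of [chi2_with_residuals()] results), `median_tests` (data.frame
#'   of pairwise Mann-Whitney results), `m` (Bonferroni family size).
#' @export
enrichment_battery <- function(assignments, genes,
                               classes = c("B", "P", "X", "BL_PG", "BG_PL"),
                               flags = c("developmental", "complex_member",
                                         "ohnologue", "omim_disease"),
                               numeric_attrs = c("hi_score",
                                                 "max_expression"),
                               hi_threshold = 0.9) {
  merged <- merge(assignments[, c("gene_id", "label")], genes,
                  by = "gene_id")
  merged <- merged[merged$label %in% classes, , drop = FALSE]
  classes <- classes[classes %in% unique(merged$label)]
  if (length(classes) < 2)
    stop("need at least two non-empty classes to compare")
  flags <- flags[flags %in% names(merged)]
  if ("hi_score" %in% names(merged) && any(!is.na(merged$hi_score)))
    merged$haploinsufficient <- merged$hi_score > hi_threshold
  test_flags <- c(flags,
                  if ("haploinsufficient" %in% names(merged))
                    "haploinsufficient")
  lab <- factor(merged$label, levels = classes)

  flag_details <- list()
  flag_rows <- list()
  for (fl in test_flags) {
    v <- merged[[fl]]
    ok <- !is.na(v)
    tab <- table(factor(v[ok], levels = c(FALSE, TRUE)), lab[ok])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    res <- if (all(rowSums(tab) > 0) && ncol(tab) >= 2)
      chi2_with_residuals(unclass(tab)) else NULL
    flag_details[[fl]] <- res
    pct <- vapply(classes, function(cl)
      100 * mean(v[ok & lab == cl]), numeric(1))
    cnt <- vapply(classes, function(cl)
      sum(v[ok & lab == cl]), numeric(1))
    row <- data.frame(attribute = fl, stringsAsFactors = FALSE)
    for (cl in classes) {
      row[[paste0("pct_", cl)]] <- pct[[cl]]
      row[[paste0("n_", cl)]] <- cnt[[cl]]
    }
    row$p_raw <- if (is.null(res)) NA_real_ else res$p
    flag_rows[[fl]] <- row
  }
  flag_tests <- do.call(rbind, flag_rows)

  median_rows <- list()
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  for (at in numeric_attrs[numeric_attrs %in% names(merged)]) {
    v <- merged[[at]]
    for (pr in pairs) {
      a <- v[lab == pr[1] & !is.na(v)]
      b <- v[lab == pr[2] & !is.na(v)]
      if (length(a) == 0 || length(b) == 0) next
      mw <- mann_whitney(a, b)
      median_rows[[paste(at, pr[1], pr[2], sep = ".")]] <-
        data.frame(attribute = at, class_a = pr[1], class_b = pr[2],
                   median_a = stats::median(a), median_b = stats::median(b),
                   U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
    }
  }
  median_tests <- if (length(median_rows)) do.call(rbind, median_rows)
                  else NULL
  m <- nrow(flag_tests) + if (is.null(median_tests)) 0 else nrow(median_tests)
  flag_tests$p_bonferroni <- pmin(1, m * flag_tests$p_raw)
  if (!is.null(median_tests)) {
    median_tests$p_bonferroni <- pmin(1, m * median_tests$p_raw)
    rownames(median_tests) <- NULL
  }
  rownames(flag_tests) <- NULL
  list(flag_tests = flag_tests, flag_details = flag_details,
       median_tests = median_tests, m = m)
}
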