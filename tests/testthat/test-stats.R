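test_that("chi-squared statistic, p and adjusted residuals match hand evaluation", {
  # table equal to its expected values -> everything zero
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- chi2_with_residuals(flat)
  expect_equal(res$chi2, 0)
  expect_equal(unname(res$adjusted_residuals), matrix(0, 2, 2))

  # hand evaluation: all expected counts are 15, chi2 = 4 * 25/15 = 20/3
  tab <- matrix(c(10, 20, 20, 10), 2)
  res <- chi2_with_residuals(tab)
  expect_equal(res$chi2, 20 / 3)
  expect_equal(res$df, 1)

  # 2x2 adjusted residuals are equal in magnitude, antisymmetric diagonal
  tab2 <- matrix(c(30, 10, 12, 18), 2)
  r <- chi2_with_residuals(tab2)$adjusted_residuals
  expect_equal(abs(r[1, 1]), abs(r[1, 2]))
  expect_equal(abs(r[1, 1]), abs(r[2, 1]))
  expect_equal(r[1, 1], -r[1, 2])
  expect_gt(r[1, 1], 2)  # the inflated cell drives the association

  expect_error(chi2_with_residuals(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("chi-squared agrees with the reference implementation on random tables", {
  set.seed(42)
  for (i in 1:100) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    tab <- matrix(rpois(nr * nc, 20) + 1, nr, nc)
    res <- chi2_with_residuals(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_lt(abs(res$chi2 - unname(ref$statistic)), 1e-8)
    expect_lt(abs(res$p - ref$p.value), 1e-8)
    expect_lt(max(abs(res$adjusted_residuals - ref$stdres)), 1e-8)
  }
})

test_that("Mann-Whitney matches the exact pairwise U and the reference p-value", {
  # identical samples: U = n^2/2 and the comparison is vacuous
  x <- c(1, 2, 3, 4)
  res <- mann_whitney(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$p, 1)
  # complete separation
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)

  set.seed(7)
  for (i in 1:100) {
    a <- round(rnorm(sample(5:40, 1)), sample(0:2, 1))
    b <- round(rnorm(sample(5:40, 1), 0.3), sample(0:2, 1))
    res <- mann_whitney(a, b)
    expect_equal(res$U, u_by_pairs(a, b))
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE))
    expect_lt(abs(res$U - unname(ref$statistic)), 1e-8)
    expect_lt(abs(res$p - ref$p.value), 1e-8)
  }

  # a 1-sd shift at n = 200 is decisively detected
  set.seed(8)
  expect_lt(mann_whitney(rnorm(200), rnorm(200, 1))$p, 0.001)
})

test_that("Fligner-Killeen matches the rank-score formula and detects scale change", {
  set.seed(15)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(5:30, 1), sd = j))
    res <- fligner_killeen(groups)
    expect_lt(abs(res$statistic - fligner_by_formula(groups)), 1e-8)
    ref <- fligner.test(unlist(groups),
                        factor(rep(seq_len(k),
                                   vapply(groups, length, integer(1)))))
    expect_lt(abs(res$p - ref$p.value), 1e-8)
  }

  set.seed(16)
  expect_lt(fligner_killeen(list(rnorm(200, sd = sqrt(0.5)),
                                 rnorm(200, sd = 2)))$p, 0.001)
  # duplicated identical groups are a degenerate (zero-spread) case
  res <- fligner_killeen(list(rep(2, 10), rep(5, 12)))
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("Fligner-Killeen p-values are calibrated under label permutation", {
  set.seed(17)
  x <- rnorm(60)
  p <- replicate(300, {
    idx <- sample(60, 30)
    fligner_killeen(list(x[idx], x[-idx]))$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("hypergeometric enrichment reproduces exhaustive subset enumeration", {
  background <- sprintf("g%02d", 1:10)
  term_map <- list(hit5 = background[1:5],
                   all10 = background,
                   other = background[6:10])
  res <- hypergeom_enrichment(background[1:3], background, term_map)
  # C(5,3)/C(10,3) = 10/120, from enumerating all 3-subsets
  expect_equal(res$p_raw[res$term == "hit5"], choose(5, 3) / choose(10, 3))
  expect_equal(res$p_raw[res$term == "all10"], 1)   # term covers everything
  expect_equal(res$p_raw[res$term == "other"], 1)   # zero hits
  expect_equal(res$p_bonferroni, pmin(1, 3 * res$p_raw))
  expect_error(hypergeom_enrichment(c("g01", "zz"), background, term_map),
               "zz")

  # monotone decreasing in k at fixed (n, K, N)
  p_at_k <- vapply(0:3, function(k) {
    q <- c(background[seq_len(k)], background[6:10][seq_len(3 - k)])
    hypergeom_enrichment(q, background, term_map["hit5"])$p_raw
  }, numeric(1))
  expect_true(all(diff(p_at_k) < 0))
})

test_that("the class enrichment battery reports per-class rates, residuals and medians", {
  set.seed(30)
  cfg <- simulation_config(seed = 30)
  sim <- simulate_genome(cfg)
  cnvs <- simulate_cnvs(sim$genes, sim$build, cfg)
  benign <- cnvs[cnvs$interpretation == "benign", ]
  path <- cnvs[cnvs$interpretation == "pathogenic", ]
  peaks_g <- find_peaks(merge_cnvrs(path, "gain_only"), path)
  peaks_l <- find_peaks(merge_cnvrs(path, "loss_only"), path)
  asg <- assign_classes(sim$genes, benign[benign$type == "gain", ],
                        benign[benign$type == "loss", ], peaks_g, peaks_l)
  bat <- enrichment_battery(asg, sim$genes)
  expect_true(all(c("developmental", "complex_member", "ohnologue") %in%
                    bat$flag_tests$attribute))
  expect_true(all(bat$flag_tests$p_bonferroni >=
                    bat$flag_tests$p_raw, na.rm = TRUE))
  expect_equal(bat$m, nrow(bat$flag_tests) + nrow(bat$median_tests))
  # dosage-sensitive genes are enriched in Class P relative to Class B,
  # so expression medians order the same way
  mt <- bat$median_tests
  row <- mt[mt$attribute == "max_expression" & mt$class_a == "B" &
              mt$class_b == "P", ]
  expect_gt(row$median_b, row$median_a)
})
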