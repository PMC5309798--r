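test_that("gene-interval intersection needs >= 1 bp and ignores strand", {
  genes <- toy_genes("1", 100, 200)
  expect_true(unname(intersect_genes(genes,
    data.frame(chrom = "1", start = 199, end = 300))))   # 1 bp overlap
  expect_false(unname(intersect_genes(genes,
    data.frame(chrom = "1", start = 200, end = 300))))   # half-open abutment
  minus <- toy_genes("1", 100, 200)
  minus$strand <- "-"
  expect_true(unname(intersect_genes(minus,
    data.frame(chrom = "1", start = 150, end = 160))))
})

test_that("class labels match the independent 16-row truth table and partition genes", {
  tt <- class_truth_table()
  got <- class_from_membership(tt$bg, tt$bl, tt$pg, tt$pl)
  expect_equal(got, tt$label)
  # spot checks of the named examples
  expect_equal(class_from_membership(TRUE, FALSE, FALSE, FALSE), "B")
  expect_equal(class_from_membership(FALSE, FALSE, TRUE, TRUE), "P")
  expect_equal(class_from_membership(TRUE, FALSE, TRUE, FALSE), "X")
  expect_equal(class_from_membership(FALSE, TRUE, TRUE, FALSE), "BL_PG")
  # partition: every membership combination yields exactly one label,
  # and unclassified iff no membership at all
  expect_true(all(got %in% c("B", "P", "X", "BL_PG", "BG_PL", "unclassified")))
  expect_equal(got == "unclassified", !(tt$bg | tt$bl | tt$pg | tt$pl))
})

test_that("assign_classes wires gene overlap into the truth table", {
  genes <- toy_genes("1", c(0, 300, 600, 900), c(100, 400, 700, 1000))
  benign_gain <- data.frame(chrom = "1", start = 0, end = 50)
  benign_loss <- data.frame(chrom = "1", start = 300, end = 350)
  path_gain <- data.frame(chrom = "1", start = c(320, 650), end = c(380, 660))
  path_loss <- data.frame(chrom = "1", start = 990, end = 995)
  got <- assign_classes(genes, benign_gain, benign_loss, path_gain, path_loss)
  expect_equal(got$label, c("B", "BL_PG", "P", "P"))
})

test_that("solitary Class P detection counts exactly-one regions", {
  genes <- toy_genes("1", c(0, 200, 400), c(100, 300, 500))
  assignments <- data.frame(gene_id = genes$gene_id,
                            label = c("P", "X", "B"),
                            stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = c("pk1", "pk2", "pk3"), chrom = "1",
                      start = c(0, 0, 350), end = c(500, 100, 360),
                      stringsAsFactors = FALSE)
  calls <- find_solitary(peaks, assignments, genes)
  # pk1 overlaps {P, X, B}: solitary with the single P gene
  expect_true(calls$solitary[1])
  expect_equal(calls$class_p_gene_ids[[1]], "g001")
  # pk2 overlaps one P gene; pk3 overlaps none
  expect_true(calls$solitary[2])
  expect_false(calls$solitary[3])
  expect_equal(calls$n_class_p[3], 0L)

  two_p <- assignments
  two_p$label <- c("P", "P", "B")
  calls2 <- find_solitary(peaks[1, ], two_p, genes)
  expect_false(calls2$solitary[1])
})

test_that("solitary summary reports unique and dual-type genes", {
  genes <- toy_genes("1", c(0, 1000), c(100, 1100))
  assignments <- data.frame(gene_id = genes$gene_id, label = "P",
                            stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = c("gk1", "lk1", "lk2"), chrom = "1",
                      start = c(0, 0, 1000), end = c(100, 100, 1100),
                      scope = c("gain_only", "loss_only", "loss_only"),
                      stringsAsFactors = FALSE)
  calls <- find_solitary(peaks, assignments, genes)
  s <- solitary_summary(calls)
  expect_equal(s$n_solitary_regions, 3)
  expect_equal(sort(s$solitary_genes), c("g001", "g002"))
  # g001 is solitary for both a gain and a loss region; g002 loss-only
  expect_equal(s$dual_type_solitary_genes, "g001")
  expect_gte(s$n_solitary_regions, length(s$solitary_genes))
})

test_that("per-CNV annotation fractions exclude gene-empty intervals", {
  genes <- toy_genes("1", c(0, 100, 200, 300), c(50, 150, 250, 350),
                     developmental = c(TRUE, FALSE, FALSE, FALSE))
  iv <- data.frame(chrom = "1", start = c(0, 500, 0), end = c(400, 600, 60))
  fr <- annotation_fraction_per_cnv(iv, genes, "developmental")
  expect_equal(fr[1], 0.25)       # 4 genes overlapped, 1 flagged
  expect_true(is.na(fr[2]))       # no genes -> undefined
  expect_equal(fr[3], 1)          # only the flagged gene overlapped
  expect_error(annotation_fraction_per_cnv(iv, genes, "nope"), "flag")
})

test_that("distance to nearest flagged gene is a half-open gap with NA off-chromosome", {
  genes <- toy_genes("1", c(0, 40, 2000), c(100, 140, 2100),
                     developmental = c(FALSE, TRUE, TRUE))
  d <- distance_to_nearest_flagged(genes[1, ], genes, "developmental")
  expect_equal(d, 0)              # overlaps flagged g002
  d <- distance_to_nearest_flagged(genes[3, ], genes, "developmental")
  expect_equal(d, 2000 - 140)     # nearest flagged is g002, gap in bp
  other <- toy_genes("2", 0, 100)
  other$gene_id <- "g999"
  d <- distance_to_nearest_flagged(other, genes, "developmental")
  expect_true(is.na(d))
  # exhaustive pairwise-scan oracle on a random layout
  set.seed(5)
  starts <- sort(sample.int(1e5, 30)) * 10
  g <- toy_genes("1", starts, starts + 500,
                 developmental = runif(30) < 0.3)
  for (i in c(1, 10, 30)) {
    got <- distance_to_nearest_flagged(g[i, ], g, "developmental")
    f <- g[g$developmental & g$gene_id != g$gene_id[i], ]
    oracle <- if (nrow(f) == 0) NA_real_ else
      min(pmax(f$start - g$end[i], g$start[i] - f$end, 0))
    expect_equal(got, oracle)
  }
})
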