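mk_cnvs <- function(start, end, type = "loss", interp = "pathogenic") {
  n <- length(start)
  data.frame(id = sprintf("c%02d", seq_len(n)), chrom = "1",
             start = start, end = end,
             type = rep_len(type, n), interpretation = interp,
             study = "t", stringsAsFactors = FALSE)
}

test_that("overlap-connected CNVs merge into one CNVR, disjoint ones into two", {
  one <- merge_cnvrs(mk_cnvs(c(100, 150), c(200, 300)))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100, 300))
  expect_equal(one$n_members, 2)

  two <- merge_cnvrs(mk_cnvs(c(100, 300), c(200, 400)))
  expect_equal(nrow(two), 2)

  # book-ended CNVs merge (bedtools-merge default)
  abut <- merge_cnvrs(mk_cnvs(c(100, 200), c(200, 300)))
  expect_equal(nrow(abut), 1)
})

test_that("typed scope merges only that CNV type and mixed interpretations error", {
  cnvs <- mk_cnvs(c(100, 150), c(200, 300), type = c("gain", "loss"))
  gain <- merge_cnvrs(cnvs, "gain_only")
  expect_equal(nrow(gain), 1)
  expect_equal(c(gain$start, gain$end), c(100, 200))
  expect_equal(gain$n_members, 1)

  mixed <- cnvs
  mixed$interpretation <- c("benign", "pathogenic")
  expect_error(merge_cnvrs(mixed), "interpretation")
})

test_that("coverage profile matches the worked example and trivial cases", {
  cnvs <- mk_cnvs(c(100, 150), c(200, 300))
  r <- merge_cnvrs(cnvs)
  prof <- coverage_profile(r[1, ], cnvs)
  expect_equal(prof$start, c(100, 150, 200))
  expect_equal(prof$end, c(150, 200, 300))
  expect_equal(prof$depth, c(1, 2, 1))

  single <- mk_cnvs(0, 50)
  r <- merge_cnvrs(single)
  prof <- coverage_profile(r[1, ], single)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$depth, 1)

  triple <- mk_cnvs(c(10, 10, 10), c(60, 60, 60))
  r <- merge_cnvrs(triple)
  prof <- coverage_profile(r[1, ], triple)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$depth, 3)
})

test_that("peak detection handles singletons, multiple peaks and monotone profiles", {
  # a single-CNV region: the entire CNV is the peak, depth 1
  single <- mk_cnvs(500, 900)
  r <- merge_cnvrs(single)
  pk <- find_peak_regions(coverage_profile(r[1, ], single))
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end, pk$depth), c(500, 900, 1))

  # depth sequence 1,2,1,3,1 -> two peaks at the depth-2 and depth-3 plateaus
  prof <- data.frame(region_id = "r", chrom = "1",
                     start = c(0, 10, 20, 30, 40),
                     end = c(10, 20, 30, 40, 50),
                     depth = c(1, 2, 1, 3, 1))
  pk <- find_peak_regions(prof)
  expect_equal(pk$depth, c(2, 3))
  expect_equal(pk$start, c(10, 30))

  # monotone rise then fall -> unique maximum
  prof$depth <- c(1, 2, 3, 2, 1)
  pk <- find_peak_regions(prof)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$depth, 3)
})

test_that("coverage and peaks agree with per-base brute-force oracles on random profiles", {
  set.seed(101)
  for (i in 1:200) {
    cnvs <- random_profile_cnvs(sample(1:8, 1))
    regions <- merge_cnvrs(cnvs)
    for (j in seq_len(nrow(regions))) {
      reg <- regions[j, ]
      prof <- coverage_profile(reg, cnvs)
      m <- cnvs[cnvs$id %in% reg$members[[1]], ]
      oracle_depth <- per_base_coverage(m$start, m$end, reg$start, reg$end)
      # segment representation reproduces the per-base depths
      got_depth <- rep(prof$depth, prof$end - prof$start)
      expect_equal(got_depth, oracle_depth)
      # conservation: sum depth x width equals total member length
      expect_equal(sum(prof$depth * (prof$end - prof$start)),
                   sum(m$end - m$start))
      # adjacent segments always differ in depth
      if (nrow(prof) > 1)
        expect_true(all(diff(prof$depth) != 0))
      # peaks agree with the per-base scan
      pk <- find_peak_regions(prof)
      oracle_pk <- per_base_peaks(oracle_depth, lo = reg$start)
      expect_equal(pk$start, oracle_pk$start)
      expect_equal(pk$end, oracle_pk$end)
      expect_equal(pk$depth, oracle_pk$depth)
      # structural invariants: >= 1 peak, disjoint, nested in the CNVR
      expect_gte(nrow(pk), 1)
      expect_true(all(pk$start >= reg$start & pk$end <= reg$end))
      if (nrow(pk) > 1)
        expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
    }
  }
})

test_that("every CNV lands in exactly one CNVR and the partition ignores input order", {
  set.seed(77)
  build <- toy_build()
  cnvs <- random_cnvs(60, build)
  regions <- merge_cnvrs(cnvs)
  members <- unlist(regions$members)
  expect_equal(sort(members), sort(cnvs$id))   # each CNV exactly once
  shuffled <- cnvs[sample(nrow(cnvs)), ]
  regions2 <- merge_cnvrs(shuffled)
  expect_equal(regions[, c("chrom", "start", "end", "n_members")],
               regions2[, c("chrom", "start", "end", "n_members")])
})

test_that("genome fractions and region overlaps follow the interval arithmetic", {
  b1 <- genome_build("one", c(`1` = 100))
  expect_equal(genome_fraction(data.frame(chrom = "1", start = 0, end = 100), b1), 1)
  expect_equal(genome_fraction(data.frame(chrom = "1", start = 0, end = 25), b1), 0.25)
  expect_equal(genome_fraction(data.frame(chrom = character(0),
                                          start = numeric(0),
                                          end = numeric(0)), b1), 0)
  expect_error(genome_fraction(data.frame(chrom = "1", start = 0, end = 101), b1),
               "beyond")

  a <- data.frame(chrom = "1", start = 0, end = 100)
  b <- data.frame(chrom = "1", start = 50, end = 150)
  ov <- region_overlap(a, b)
  expect_equal(ov$bp_overlap, 50)
  expect_equal(ov$fraction_of_a, 0.5)
  expect_equal(region_overlap(a, a)$fraction_of_a, 1)

  a2 <- data.frame(chrom = "1", start = c(0, 20), end = c(10, 30))
  b2 <- data.frame(chrom = "1", start = 5, end = 25)
  ov2 <- region_overlap(a2, b2)
  expect_equal(ov2$bp_overlap, 10)
  expect_equal(ov2$fraction_of_a, 0.5)

  expect_error(region_overlap(a[0, ], b), "undefined")
})
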