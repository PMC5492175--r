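test_that("raw coverage adds blocks on the right strand and excludes Pol I/III", {
  g <- tiny_genome()
  sg <- make_segments(
    chrom = rep("chr1", 5),
    strand = c("+", "+", "-", "+", "+"),
    blocks = c("1001-1050", "1001-1050",   # two stacked plus reads
               "1310-1350",                # sense tRNA (minus) -> excluded
               "2651-2690",                # sense rRNA -> excluded
               "851-900;1001-1020"),       # spliced: intron gets nothing
    tag = c("AAA", "CCC", "GGG", "TTT", "ACG"), genome = g)
  tr <- build_coverage(sg, g)
  expect_equal(tr$norm, "raw")
  expect_equal(tr$lib_size, 3L)            # tRNA and rRNA reads excluded
  p <- as.numeric(tr$plus$chr1)
  expect_true(all(p[1001:1020] == 3))      # 2 stacked + spliced block 2
  expect_true(all(p[1021:1050] == 2))
  expect_true(all(p[901:1000] == 0))       # intron bases untouched
  expect_true(all(p[851:900] == 1))
  expect_true(all(p[2651:2690] == 0))      # excluded rRNA read
  expect_true(all(as.numeric(tr$minus$chr1) == 0))
  # conservation: track total = sum of included block lengths
  expect_equal(sum(as.numeric(sum(tr$plus))) + sum(as.numeric(sum(tr$minus))),
               50 + 50 + (50 + 20))
  # unknown chromosome is an explicit error
  bad <- make_segments("chrX", "+", "1-50", "AAA")
  expect_error(build_coverage(bad, g), "chrX")
})

test_that("RPM normalization scales by included library size", {
  g <- tiny_genome()
  sg <- make_segments(rep("chr1", 4), rep("+", 4),
                      c("1001-1050", "1001-1050", "1001-1050", "1001-1050"),
                      tag = c("AAA", "CCC", "GGG", "TTT"), genome = g)
  raw <- build_coverage(sg, g)
  rpm <- normalize_rpm(raw)
  expect_equal(rpm$norm, "rpm")
  expect_equal(as.numeric(rpm$plus$chr1)[1001], 4 * 1e6 / 4)
  expect_error(normalize_rpm(rpm), "already")
  # all-zero raw track stays all-zero
  empty_cov <- build_coverage(make_segments("chr1", "-", "1310-1350", "AAA",
                                            genome = g), g,
                              exclusion_classes = character())
  expect_equal(sum(as.numeric(sum(normalize_rpm(empty_cov)$plus))), 0)
  # zero library size is an error
  excl <- build_coverage(make_segments("chr1", "-", "1310-1350", "AAA",
                                       genome = g), g)
  expect_equal(excl$lib_size, 0L)
  expect_error(normalize_rpm(excl), "library size")
})

test_that("RPM tracks are invariant under uniform read duplication", {
  g <- tiny_genome()
  one <- make_segments(rep("chr1", 3), c("+", "+", "-"),
                       c("151-200", "401-460", "1601-1650"),
                       tag = c("AAA", "CCC", "GGG"), genome = g)
  two <- make_segments(rep("chr1", 6), rep(c("+", "+", "-"), 2),
                       rep(c("151-200", "401-460", "1601-1650"), 2),
                       tag = rep(c("AAA", "CCC", "GGG"), 2), genome = g)
  r1 <- normalize_rpm(build_coverage(one, g))
  r2 <- normalize_rpm(build_coverage(two, g))
  expect_identical(as.numeric(r1$plus$chr1), as.numeric(r2$plus$chr1))
  expect_identical(as.numeric(r1$minus$chr1), as.numeric(r2$minus$chr1))
})

test_that("replicate averaging is a commutative per-base mean", {
  g <- tiny_genome()
  t1 <- fake_track(g, plus = list(chr1 = rep(1, 4000)))
  t3 <- fake_track(g, plus = list(chr1 = rep(3, 4000)))
  avg <- average_replicates(list(t1, t3))
  expect_equal(as.numeric(avg$plus$chr1)[1], 2)
  avg_rev <- average_replicates(list(t3, t1))
  expect_equal(as.numeric(avg$plus$chr1), as.numeric(avg_rev$plus$chr1))
  self <- average_replicates(list(t1))
  expect_equal(as.numeric(self$plus$chr1), as.numeric(t1$plus$chr1))
  raw <- fake_track(g, norm = "raw")
  expect_error(average_replicates(list(t1, raw)), "RPM")
})

test_that("enrichment is pseudocounted, finite and antisymmetric", {
  g <- tiny_genome()
  a <- fake_track(g, plus = list(chr1 = c(rep(11, 2000), rep(0, 2000))))
  b <- fake_track(g, plus = list(chr1 = c(rep(3, 2000), rep(0, 2000))))
  et <- enrichment_track(a, b, pseudocount = 5)
  v <- as.numeric(et$plus$chr1)
  expect_equal(v[1], 1.0)            # log2(16/8)
  expect_equal(v[3000], 0.0)         # 0 vs 0 -> log2(5/5)
  expect_true(all(is.finite(v)))
  # identical tracks -> exactly 0 everywhere
  self <- enrichment_track(a, a)
  expect_true(all(as.numeric(self$plus$chr1) == 0))
  expect_true(all(as.numeric(self$minus$chr1) == 0))
  # antisymmetry
  rev <- enrichment_track(b, a, pseudocount = 5)
  expect_equal(as.numeric(rev$plus$chr1), -v)
  expect_error(enrichment_track(a, b, pseudocount = 0), "pseudocount")
})

test_that("feature statistics compute totals, CV, RPKM and strict flags", {
  g <- tiny_genome()
  # mRNA_001 spans [101,700] (+): plant per-base signal 10/10/10 in three
  # replicates for CV 0, and 1/10/100 on mRNA_002 (-) for CV ~ 1.48
  mk <- function(v1, v2) fake_track(
    g, plus = list(chr1 = c(rep(0, 100), rep(v1 / 600, 600), rep(0, 3300))),
    minus = list(chr1 = c(rep(0, 1500), rep(v2 / 400, 400), rep(0, 2100))),
    lib_size = 1e6)
  tracks <- list(mk(10, 1), mk(10, 10), mk(10, 100))
  # 100 reads on mRNA_001 per replicate -> RPKM 100/(0.6 * 1) = 166.7
  # reads clear of the nested snoRNA so the priority rule keeps them on
  # the mRNA
  segs <- lapply(1:3, function(i) {
    s <- sample(301:651, 100, replace = TRUE)
    make_segments(rep("chr1", 100), rep("+", 100),
                  sprintf("%d-%d", s, s + 49L),
                  tag = replicate(100, paste(sample(LETTERS[1:4], 3, TRUE),
                                             collapse = "")), genome = g)
  })
  st <- feature_stats(tracks, segs, g)
  r1 <- st[st$feature_id == "mRNA_001", ]
  expect_equal(r1$mean_total, 10, tolerance = 1e-9)
  expect_equal(r1$cv, 0)
  expect_true(r1$passes_reproducibility)
  expect_equal(r1$rpkm, 100 / (0.6 * 1), tolerance = 1e-9)
  expect_true(r1$passes_abundance)
  expect_true(r1$selected)
  r2 <- st[st$feature_id == "mRNA_002", ]
  expect_equal(r2$cv, sd(c(1, 10, 100)) / 37, tolerance = 1e-9)
  expect_gt(r2$cv, 0.5)
  expect_false(r2$passes_reproducibility)
  expect_false(r2$selected)
  # spliced gene totals use exonic bases only
  ri <- st[st$feature_id == "mRNAi_001", ]
  expect_equal(ri$length, 300L)
})

test_that("scatter table pairs selected features and is antisymmetric", {
  g <- tiny_genome()
  mkc <- function(v) fake_track(
    g, plus = list(chr1 = c(rep(0, 100), rep(v, 600), rep(0, 3300))))
  segs <- lapply(1:2, function(i)
    make_segments(rep("chr1", 60), rep("+", 60),
                  sprintf("%d-%d", round(seq(301, 651, length.out = 60)),
                          round(seq(301, 651, length.out = 60)) + 40),
                  tag = replicate(60, paste(sample(LETTERS[1:4], 3, TRUE),
                                            collapse = "")), genome = g))
  stA <- feature_stats(list(mkc(8), mkc(8)), segs, g)
  stB <- feature_stats(list(mkc(1), mkc(1)), segs, g)
  sc <- scatter_table(stA, stB, pseudocount = 5)
  expect_true(all(sc$feature_id %in% stA$feature_id[stA$selected]))
  m <- sc[sc$feature_id == "mRNA_001", ]
  expect_equal(m$enrichment,
               log2((8 * 600 + 5) / (1 * 600 + 5)), tolerance = 1e-9)
  # identical stats -> enrichment 0; swapped operands negate
  sc0 <- scatter_table(stA, stA)
  expect_true(all(sc0$enrichment == 0))
  scBA <- scatter_table(stB, stA, pseudocount = 5)
  mu <- scBA[scBA$feature_id == "mRNA_001", ]
  expect_equal(mu$enrichment, -m$enrichment)
  stBad <- stB[stB$feature_id != "mRNA_002", ]
  expect_error(scatter_table(stA, stBad), "mRNA_002")
})
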