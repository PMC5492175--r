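test_that("anchored rows follow transcript orientation and masking", {
  g <- tiny_genome()
  # uniform 2.0 RPM over mRNA_001 [101,700] (+)
  tr <- fake_track(g, plus = list(chr1 = c(rep(0, 100), rep(2, 600),
                                           rep(0, 3300))))
  mat <- anchored_matrix(tr, g, features = "mRNA_001", anchor = "tss",
                         window = c(-100, 1500), flank = 100)
  row <- mat["mRNA_001", ]
  expect_equal(unname(row[as.character(0:599)]), rep(2, 600))
  # masked beyond transcript end + flank
  expect_true(all(is.na(row[as.character(701:1500)])))
  expect_equal(unname(row[as.character(600:699)]), rep(0, 100))  # flank
  # minus-strand orientation: gradient on mRNA_002 [1501,1900] (-)
  vals <- numeric(4000); vals[1900] <- 7; vals[1899] <- 3
  trm <- fake_track(g, minus = list(chr1 = vals))
  matm <- anchored_matrix(trm, g, features = "mRNA_002", anchor = "tss",
                          window = c(0, 5))
  expect_equal(unname(matm["mRNA_002", c("0", "1")]), c(7, 3))
  # pA anchoring: position 0 is the last transcribed base
  matp <- anchored_matrix(trm, g, features = "mRNA_002", anchor = "pa",
                          window = c(-5, 0))
  # pA of mRNA_002 (-) is genomic 1501
  vals2 <- numeric(4000); vals2[1501] <- 9
  trp <- fake_track(g, minus = list(chr1 = vals2))
  matp2 <- anchored_matrix(trp, g, features = "mRNA_002", anchor = "pa",
                           window = c(-5, 0))
  expect_equal(unname(matp2["mRNA_002", "0"]), 9)
  expect_equal(unname(matp2["mRNA_002", "-1"]), 0)
})

test_that("metagene profiles aggregate with the documented modes", {
  g <- tiny_genome()
  tr <- fake_track(g, plus = list(chr1 = rep(1, 4000)),
                   minus = list(chr1 = rep(3, 4000)))
  mat <- anchored_matrix(tr, g, features = c("mRNA_001", "mRNA_002"),
                         anchor = "tss", window = c(0, 300))
  pr_mean <- metagene_profile(mat, mode = "mean")
  expect_true(all(pr_mean$value == 2))
  pr_sum <- metagene_profile(mat, mode = "sum")
  expect_true(all(pr_sum$value == 4))
  expect_true(all(pr_sum$n_features == 2))
  # single-row matrix: profile equals the row
  m1 <- anchored_matrix(tr, g, features = "mRNA_001", anchor = "tss",
                        window = c(0, 100))
  expect_equal(metagene_profile(m1, "sum")$value,
               unname(m1["mRNA_001", ]))
  # all-masked columns are reported missing
  mfar <- anchored_matrix(tr, g, features = "snoRNA_001", anchor = "tss",
                          window = c(0, 1000))
  prf <- metagene_profile(mfar, "mean")
  expect_true(all(is.na(prf$value[prf$position > 60 + 100])))
  # absolute tracks default to sum, enrichment tracks to mean
  expect_equal(attr(metagene_profile(mat), "mode"), "sum")
  et <- enrichment_track(tr, tr)
  me <- anchored_matrix(et, g, features = "mRNA_001", anchor = "tss")
  expect_equal(attr(metagene_profile(me), "mode"), "mean")
})

test_that("relative metagene matches the closed-form enrichment", {
  g <- tiny_genome()
  x <- 40
  prot <- fake_track(g, plus = list(chr1 = rep(2 * x, 4000)),
                     minus = list(chr1 = rep(2 * x, 4000)))
  ref <- fake_track(g, plus = list(chr1 = rep(x, 4000)),
                    minus = list(chr1 = rep(x, 4000)))
  pr <- relative_metagene(prot, ref, g, features = "mRNA_001",
                          anchor = "tss", window = c(0, 400))
  expect_equal(unique(pr$value), log2((2 * x + 5) / (x + 5)))
  # protein == reference -> flat 0
  pr0 <- relative_metagene(ref, ref, g, features = "mRNA_001",
                           anchor = "tss", window = c(0, 400))
  expect_true(all(pr0$value == 0))
})

test_that("expression matching pairs classes within tolerance", {
  g <- tiny_genome()
  stats <- data.frame(
    feature_id = c("m1", "m2", "m3", "s1", "s2", "s3", "c1", "c2"),
    class = c("mRNA", "mRNA", "mRNA", "SUT", "SUT", "SUT", "CUT", "CUT"))
  # identical multisets: everything matches
  sig <- c(m1 = 10, m2 = 100, m3 = 1000,
           s1 = 10, s2 = 100, s3 = 1000, c1 = 10, c2 = 100)
  mm <- expression_match(stats, sig, classes = c("mRNA", "SUT", "CUT"),
                         tolerance = 0.05)
  expect_equal(sum(mm$class == "mRNA"), 2L)   # only 2 CUTs available
  grp <- split(mm$log10_signal, mm$group)
  expect_true(all(vapply(grp, function(v) max(v) - min(v), 1) <= 0.05))
  # matched-class mean log10 signals agree within tolerance
  mns <- tapply(mm$log10_signal, mm$class, mean)
  expect_lt(max(mns) - min(mns), 0.05)
  # disjoint ranges: nothing matches
  sig2 <- c(m1 = 1, m2 = 2, m3 = 3, s1 = 1e4, s2 = 2e4, s3 = 3e4,
            c1 = 1e7, c2 = 2e7)
  mm2 <- expression_match(stats, sig2, classes = c("mRNA", "SUT", "CUT"))
  expect_equal(nrow(mm2), 0L)
  # each feature used at most once
  expect_false(anyDuplicated(mm$feature_id) > 0)
  # a class without eligible features warns and returns empty
  sig3 <- sig; sig3[c("c1", "c2")] <- 0
  expect_warning(mm3 <- expression_match(stats, sig3,
                                         classes = c("mRNA", "SUT", "CUT")),
                 "CUT")
  expect_equal(nrow(mm3), 0L)
})

test_that("tss_signal sums the first transcribed nucleotides", {
  g <- tiny_genome()
  vals <- numeric(4000)
  vals[101:400] <- 1          # first 300 nt of mRNA_001
  vals[401:700] <- 100        # rest of the gene: not counted
  tr <- fake_track(g, plus = list(chr1 = vals))
  sig <- tss_signal(tr, g, features = "mRNA_001", window = 300)
  expect_equal(unname(sig["mRNA_001"]), 300)
  # minus strand: window runs leftward from the TSS at the right end
  valm <- numeric(4000); valm[1801:1900] <- 2
  trm <- fake_track(g, minus = list(chr1 = valm))
  sigm <- tss_signal(trm, g, features = "mRNA_002", window = 100)
  expect_equal(unname(sigm["mRNA_002"]), 200)
  # window clips at the transcript end (snoRNA_001 is 60 nt long)
  vals_s <- numeric(4000); vals_s[201:300] <- 1
  trs <- fake_track(g, plus = list(chr1 = vals_s))
  expect_equal(unname(tss_signal(trs, g, features = "snoRNA_001",
                                 window = 300)["snoRNA_001"]), 60)
})

test_that("heat-map export orders rows and is byte-stable", {
  g <- tiny_genome()
  vals <- numeric(4000)
  vals[101:700] <- 9 / 600     # mRNA_001 total 9
  tr <- fake_track(g, plus = list(chr1 = vals),
                   minus = list(chr1 = rep(5 / 400, 4000)))
  mat <- anchored_matrix(tr, g, features = c("mRNA_001", "mRNA_002"),
                         anchor = "tss", window = c(0, 399))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "h1.tsv")
  heatmap_export(mat, f1, sort_key = "total")
  out <- read.table(f1, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(out$feature_id, c("mRNA_001", "mRNA_002"))
  f2 <- file.path(d, "h2.tsv")
  heatmap_export(mat, f2, sort_key = "total")
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  # length ordering agrees with an independent sort of the annotation
  f3 <- file.path(d, "h3.tsv")
  heatmap_export(mat, f3, sort_key = "length", genome = g)
  out3 <- read.table(f3, sep = "\t", header = TRUE, check.names = FALSE)
  w <- setNames(width(g$features), mcols(g$features)$feature_id)
  expect_equal(out3$feature_id,
               names(sort(w[c("mRNA_001", "mRNA_002")], decreasing = TRUE)))
  expect_error(heatmap_export(mat, f3, sort_key = "external"), "ranking")
})
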