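ADAPT <- "TGGAATTCTCGGGTGCCAAGG"

read_dt <- function(seqs, quals = NULL, ids = NULL) {
  data.table::data.table(
    id = ids %||% sprintf("r%03d", seq_along(seqs)),
    seq = seqs,
    qual = quals %||% strrep("I", nchar(seqs)))
}

test_that("demultiplexing splits off tag and barcode by layout", {
  insert <- "ACGTACGTACGTACGTACGT"
  reads <- read_dt(c(paste0("ACG", "TTAGC", insert),
                     paste0("TGA", "GGGGG", insert),
                     "ACGTT"))   # shorter than tag + barcode
  dm <- demultiplex(reads, c(s1 = "TTAGC", s2 = "CCAAT"))
  expect_equal(nrow(dm$samples$s1), 1L)
  expect_equal(dm$samples$s1$tag, "ACG")
  expect_equal(dm$samples$s1$seq, insert)
  expect_equal(dm$samples$s1$barcode, "TTAGC")
  expect_equal(nrow(dm$samples$s2), 0L)
  expect_equal(nrow(dm$unassigned), 2L)
  expect_setequal(dm$unassigned$reason, c("no_barcode_match", "too_short"))
  expect_error(demultiplex(reads, c(a = "TTAGC", b = "TTAGC")), "duplicate")
})

test_that("demultiplexing partitions a generated pool exactly", {
  set.seed(42)
  bcs <- c(s1 = "AACCG", s2 = "GGTTA", s3 = "CTCTC")
  mk <- function(bc) paste0(
    replicate(100, paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                         collapse = "")),
    bc,
    replicate(100, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                         collapse = "")))
  reads <- read_dt(as.vector(sapply(bcs, mk)))
  dm <- demultiplex(reads, bcs)
  expect_equal(unname(dm$counts[c("s1", "s2", "s3")]), c(100L, 100L, 100L))
  expect_equal(sum(dm$counts), nrow(reads))
  # one Hamming mismatch is rescued only when tolerance allows it
  one_off <- read_dt(paste0("ACG", "AACCT", strrep("ACGT", 8)))
  expect_equal(nrow(demultiplex(one_off, bcs)$unassigned), 1L)
  dm2 <- demultiplex(one_off, bcs, max_mismatch = 1L)
  expect_equal(nrow(dm2$samples$s1), 1L)
})

test_that("trimming recovers inserts and applies the four thresholds", {
  insert <- strrep("ACGTGATCCA", 4)      # 40 nt
  tr <- trim_reads(read_dt(paste0(insert, ADAPT)))
  expect_equal(tr$kept$seq, insert)

  # post-trim length 16 < minimum 17 -> discarded
  tr16 <- trim_reads(read_dt(paste0(substr(insert, 1, 16), ADAPT)))
  expect_equal(nrow(tr16$kept), 0L)
  expect_equal(tr16$discarded$reason, "too_short")
  # length exactly 17 kept
  tr17 <- trim_reads(read_dt(paste0(substr(insert, 1, 17), ADAPT)))
  expect_equal(nrow(tr17$kept), 1L)

  # more than 3 uncalled bases -> discarded
  trN <- trim_reads(read_dt(paste0("ACGTN", "NACGTN", "ACGTN", "ACGTACGT")))
  expect_equal(trN$discarded$reason, "too_many_N")
  trN3 <- trim_reads(read_dt(paste0("ACGTN", "NACGTN", "ACGTACGTACGT")))
  expect_equal(nrow(trN3$kept), 1L)

  # trailing low-quality bases are trimmed before the length check
  q <- paste0(strrep("I", 20), strrep("#", 10))   # 20 x Q40 then 10 x Q2
  trq <- trim_reads(read_dt(strrep("A", 30), quals = q))
  expect_equal(nchar(trq$kept$seq), 20L)

  # partial adapter at the 3' end needs >= 3 nt of overlap
  tr_part <- trim_reads(read_dt(paste0(insert, substr(ADAPT, 1, 5))))
  expect_equal(tr_part$kept$seq, insert)
  tr_two <- trim_reads(read_dt(paste0(insert, substr(ADAPT, 1, 2))))
  expect_equal(nchar(tr_two$kept$seq), 42L)   # 2 nt overlap: not trimmed
})

test_that("collapse keeps one record per (tag, sequence) with counts", {
  r <- read_dt(c("AAACCC", "AAACCC", "GGGTTT"))
  r$tag <- c("ACG", "ACG", "ACG")
  cl <- collapse_identical(r)
  expect_equal(cl$seq, c("AAACCC", "GGGTTT"))
  expect_equal(cl$mult, c(2L, 1L))
  # same sequence, different tag: distinct molecules
  r2 <- read_dt(c("AAACCC", "AAACCC"))
  r2$tag <- c("ACG", "ACT")
  expect_equal(nrow(collapse_identical(r2)), 2L)
  # empty stream
  e <- read_dt(character(0))
  e$tag <- character(0)
  expect_equal(nrow(collapse_identical(e)), 0L)
})

test_that("collapse matches a nested-loop multiset count and is idempotent", {
  set.seed(7)
  n <- 1000L
  pool_seq <- replicate(120, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                                   collapse = ""))
  pool_tag <- replicate(8, paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                                 collapse = ""))
  r <- read_dt(sample(pool_seq, n, replace = TRUE))
  r$tag <- sample(pool_tag, n, replace = TRUE)
  cl <- collapse_identical(r)
  # O(n^2)-style oracle: multiset count per (tag, seq) pair
  key <- paste(r$tag, r$seq)
  expected <- vapply(paste(cl$tag, cl$seq),
                     function(k) sum(key == k), integer(1))
  expect_equal(cl$mult, unname(expected))
  expect_equal(sum(cl$mult), n)
  # first-occurrence order and idempotence
  expect_equal(cl$id, r$id[!duplicated(key)])
  cl2 <- collapse_identical(cl)
  expect_equal(cl2, cl)
})

test_that("low-complexity rule is strict at 80% and counts N correctly", {
  keep <- function(s) filter_low_complexity(read_dt(s))
  expect_false(keep("AAAAAAAAAA"))
  expect_true(keep("ACGTACGTACGTACGTACGT"))
  # exactly 80%: kept (rule is strictly more than 80%)
  expect_true(keep(paste0(strrep("A", 16), "CGTC")))
  expect_false(keep(paste0(strrep("A", 17), "CGT")))
  # N inflates the denominator but is never the majority base
  expect_true(keep(paste0(strrep("A", 8), "NN")))    # 8/10 = 80%
  expect_false(keep(paste0(strrep("A", 9), "N")))    # 9/10 > 80%
  expect_true(keep(strrep("N", 10)))                 # all-N: max ACGT = 0
})

test_that("preprocessing conserves every read across fates", {
  g <- generate_genome(synthetic_genome_spec(seed = 2L))
  m <- binding_model("uniform", weights = default_expression_weights(g, 2L))
  libs <- list(
    simulate_library(g, m, library_spec("s1", "ATCGA", n_molecules = 500L,
                                        seed = 1L)),
    simulate_library(g, m, library_spec("s2", "GGTCA", n_molecules = 500L,
                                        seed = 2L)))
  pool <- pool_reads(libs)
  bcs <- c(s1 = "ATCGA", s2 = "GGTCA")
  pre <- preprocess_pool(pool, bcs)
  s <- pre$summary
  expect_equal(attr(s, "input"),
               sum(s$assigned) + attr(s, "unassigned"))
  expect_equal(s$assigned,
               s$kept + s$trim_discarded + s$low_complexity)
  # with errors off the collapsed counts equal the truth prediction
  truth <- data.table::rbindlist(lapply(libs, `[[`, "truth"))
  pred <- predict_collapsed_counts(truth)
  expect_equal(s$collapsed, unname(pred[s$sample]))
  # FASTQ round trip preserves collapsed reads with tag and multiplicity
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(pre$samples$s1, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, pre$samples$s1$seq)
  expect_equal(back$tag, pre$samples$s1$tag)
  expect_equal(back$mult, pre$samples$s1$mult)
})
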