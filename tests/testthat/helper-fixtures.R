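suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Deterministic toy genome with hand-placed features, including a snoRNA
# nested inside an mRNA and an intron-containing gene on each strand.
tiny_genome <- function(chr_len = 4000L) {
  set.seed(99)
  seqs <- DNAStringSet(setNames(
    paste(sample(c("A", "C", "G", "T"), chr_len, replace = TRUE),
          collapse = ""), "chr1"))
  df <- data.frame(
    feature_id = c("mRNA_001", "snoRNA_001", "mRNAi_001", "tRNA_001",
                   "mRNA_002", "mRNAi_002", "rRNA_001"),
    class = c("mRNA", "snoRNA", "mRNA", "tRNA", "mRNA", "mRNA", "rRNA"),
    start = c(101L, 201L, 801L, 1301L, 1501L, 2001L, 2601L),
    end   = c(700L, 260L, 1200L, 1380L, 1900L, 2400L, 3100L),
    strand = c("+", "+", "+", "-", "-", "-", "+"))
  gr <- GRanges("chr1", IRanges(df$start, df$end), strand = df$strand)
  mcols(gr)$feature_id <- df$feature_id
  mcols(gr)$class <- df$class
  # mRNAi_001 (+): exons [801,900] and [1001,1200], intron [901,1000]
  # mRNAi_002 (-): exons [2301,2400] and [2001,2200], intron [2201,2300]
  exons <- GRangesList(
    mRNA_001 = GRanges("chr1", IRanges(101, 700), strand = "+"),
    snoRNA_001 = GRanges("chr1", IRanges(201, 260), strand = "+"),
    mRNAi_001 = GRanges("chr1", IRanges(c(801, 1001), c(900, 1200)),
                        strand = "+"),
    tRNA_001 = GRanges("chr1", IRanges(1301, 1380), strand = "-"),
    mRNA_002 = GRanges("chr1", IRanges(1501, 1900), strand = "-"),
    mRNAi_002 = GRanges("chr1", IRanges(c(2301, 2001), c(2400, 2200)),
                        strand = "-"),
    rRNA_001 = GRanges("chr1", IRanges(2601, 3100), strand = "+"))
  crac_genome(seqs, gr, exons)
}

# Build a segment set from a block table: one row per read, blocks given
# as "start-end[;start-end]" strings (1-based closed, ascending).
make_segments <- function(chrom, strand, blocks, tag,
                          genome = NULL, mult = 1L) {
  parts <- strsplit(blocks, ";", fixed = TRUE)
  nblk <- lengths(parts)
  se <- do.call(rbind, lapply(unlist(parts), function(p)
    as.integer(strsplit(p, "-", fixed = TRUE)[[1]])))
  gr <- GRanges(rep(chrom, nblk), IRanges(se[, 1], se[, 2]),
                strand = rep(strand, nblk))
  if (!is.null(genome)) {
    seqlevels(gr) <- seqlevels(genome$features)
    seqlengths(gr) <- seqlengths(genome$features)
  }
  grl <- relist(gr, PartitioningByWidth(nblk))
  mcols(grl)$tag <- tag
  mcols(grl)$mult <- rep(as.integer(mult), length.out = length(grl))
  metadata(grl)$skipped <- c(unmapped = 0L, secondary = 0L,
                             supplementary = 0L)
  grl
}

# Fabricated RPM coverage track with chosen per-base values.
# values: list(plus = list(chr1 = numeric), minus = ...)
fake_track <- function(genome, plus = NULL, minus = NULL, lib_size = 1e6,
                       norm = "rpm") {
  sl <- seqlengths(genome$features)
  mk <- function(vals) {
    out <- lapply(names(sl), function(chr) {
      v <- vals[[chr]]
      if (is.null(v)) v <- numeric(sl[[chr]])
      stopifnot(length(v) == sl[[chr]])
      S4Vectors::Rle(v)
    })
    names(out) <- names(sl)
    methods::as(out, "SimpleRleList")
  }
  structure(list(plus = mk(plus %||% list()), minus = mk(minus %||% list()),
                 norm = norm, lib_size = lib_size, samples = "fake"),
            class = "coverage_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force all-pairs duplicate collapse on (tag, chrom, strand,
# 5' coord): a read survives iff no earlier read agrees on all four
# fields.  O(n^2) comparisons, fully independent of the dedup path.
brute_force_dedup <- function(tag, chrom, strand, fp) {
  eq <- outer(tag, tag, "==") & outer(chrom, chrom, "==") &
    outer(strand, strand, "==") & outer(fp, fp, "==")
  eq[upper.tri(eq, diag = TRUE)] <- FALSE
  which(rowSums(eq) == 0)
}
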