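#' Specification for a synthetic annotated genome
#'
#' Describes a miniature genome used to exercise the pipeline end to end:
#' chromosome lengths, the number of features per transcript class, and the
#' intergenic spacing.  Classes cover RNA polymerase II transcripts (mRNA,
#' intron-containing mRNA, SUT, CUT, XUT, snoRNA), the Pol I/III exclusion
#' classes (rRNA, tRNA), a Ty-like retrotransposon transcript and an
#' rDNA-IGS-like noncoding transcript.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (nt).
#' @param n_mRNA,n_intron_mRNA,n_SUT,n_CUT,n_XUT,n_snoRNA,n_rRNA,n_tRNA,n_Ty,n_IGS
#'   Feature counts per class.  Intron-containing mRNAs have two exons
#'   separated by an intron of at least 30 nt.
#' @param gap_range Intergenic gap range in nt, length-2 integer.
#' @param seed Integer seed; the same spec and seed always generate the
#'   same genome.
#' @return An object of class `genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chrI = 60000L, chrII = 40000L),
                                  n_mRNA = 12L, n_intron_mRNA = 4L,
                                  n_SUT = 4L, n_CUT = 4L, n_XUT = 3L,
                                  n_snoRNA = 3L, n_rRNA = 2L, n_tRNA = 4L,
                                  n_Ty = 1L, n_IGS = 2L,
                                  gap_range = c(100L, 400L), seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)), !anyDuplicated(names(chrom_lengths)))
  counts <- c(mRNA = n_mRNA, intron_mRNA = n_intron_mRNA, SUT = n_SUT,
              CUT = n_CUT, XUT = n_XUT, snoRNA = n_snoRNA, rRNA = n_rRNA,
              tRNA = n_tRNA, Ty = n_Ty, IGS_ncRNA = n_IGS)
  if (any(counts < 0)) stop("feature counts must be non-negative")
  if (length(gap_range) != 2 || gap_range[1] < 0 || gap_range[2] < gap_range[1])
    stop("gap_range must be a non-decreasing pair of non-negative integers")
  structure(list(chrom_lengths = as.integer(chrom_lengths) |>
                   setNames(names(chrom_lengths)),
                 counts = counts, gap_range = as.integer(gap_range),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Per-class feature length ranges (nt).  Intron-containing mRNAs are built
# from (exon1, intron, exon2) parts; others are single-exon.
.class_length_ranges <- list(
  mRNA        = c(500L, 2000L),
  intron_exon1 = c(100L, 400L),
  intron_intron = c(50L, 300L),
  intron_exon2 = c(400L, 1200L),
  SUT         = c(200L, 800L),
  CUT         = c(200L, 600L),
  XUT         = c(200L, 800L),
  snoRNA      = c(80L, 200L),
  rRNA        = c(1500L, 3000L),
  tRNA        = c(70L, 120L),
  Ty          = c(1500L, 3000L),
  IGS_ncRNA   = c(300L, 1000L)
)

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic annotated genome
#'
#' Lays the requested features out along the chromosomes with random
#' intergenic gaps and random strands; features never overlap (in
#' particular never on the same strand).  Chromosome sequences are random
#' uniform DNA.  The output is deterministic for a fixed spec and seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return An object of class `crac_genome`: a list with `seqs` (a
#'   [Biostrings::DNAStringSet]), `features` (a [GenomicRanges::GRanges]
#'   with metadata columns `feature_id` and `class`), and `exons` (a
#'   [GenomicRanges::GRangesList] named by feature id, in transcript
#'   5'-to-3' order).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    counts <- spec$counts
    feats <- list()
    for (cls in names(counts)) {
      n <- counts[[cls]]
      if (n == 0) next
      if (cls == "intron_mRNA") {
        e1 <- .runif_int(n, .class_length_ranges$intron_exon1)
        it <- .runif_int(n, .class_length_ranges$intron_intron)
        e2 <- .runif_int(n, .class_length_ranges$intron_exon2)
        feats[[cls]] <- data.frame(class = "mRNA", intronic = TRUE,
                                   len = e1 + it + e2, exon1 = e1, intron = it)
      } else {
        len <- .runif_int(n, .class_length_ranges[[cls]])
        feats[[cls]] <- data.frame(class = cls, intronic = FALSE, len = len,
                                   exon1 = NA_integer_, intron = NA_integer_)
      }
    }
    tab <- do.call(rbind, feats)
    if (is.null(tab) || nrow(tab) == 0) stop("spec requests no features")
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    tab$strand <- sample(c("+", "-"), nrow(tab), replace = TRUE)
    cls_n <- stats::ave(seq_len(nrow(tab)), tab$class, FUN = seq_along)
    tab$feature_id <- sprintf("%s_%03d", tab$class, cls_n)
    # rename the intron-containing mRNAs so ids stay unique and recognisable
    tab$feature_id[tab$intronic] <- sprintf("mRNAi_%03d",
                                            seq_len(sum(tab$intronic)))

    # sequential packing with random gaps, spilling into the next chromosome
    chroms <- names(spec$chrom_lengths)
    ci <- 1L
    pos <- 1L
    starts <- integer(nrow(tab)); chrom <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      gap <- .runif_int(1, spec$gap_range)
      repeat {
        s <- pos + gap
        e <- s + tab$len[i] - 1L
        if (e <= spec$chrom_lengths[[ci]]) break
        ci <- ci + 1L
        pos <- 1L
        if (ci > length(chroms))
          stop(sprintf(
            "infeasible packing: feature %s (%d nt) does not fit on chromosome %s",
            tab$feature_id[i], tab$len[i], chroms[length(chroms)]))
      }
      starts[i] <- s
      chrom[i] <- chroms[ci]
      pos <- s + tab$len[i]
    }
    tab$start <- starts
    tab$chrom <- chrom

    sl <- spec$chrom_lengths
    gr <- GRanges(tab$chrom, IRanges(tab$start, width = tab$len),
                  strand = tab$strand,
                  seqinfo = Seqinfo(names(sl), sl))
    mcols(gr)$feature_id <- tab$feature_id
    mcols(gr)$class <- tab$class
    names(gr) <- tab$feature_id

    # exon structure, in transcript order (5' -> 3')
    exons <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (!tab$intronic[i]) {
        ex <- GRanges(tab$chrom[i], IRanges(tab$start[i], width = tab$len[i]),
                      strand = tab$strand[i])
      } else {
        e1 <- tab$exon1[i]; it <- tab$intron[i]
        s <- tab$start[i]; e <- s + tab$len[i] - 1L
        if (tab$strand[i] == "+") {
          ex <- GRanges(tab$chrom[i],
                        IRanges(c(s, s + e1 + it), c(s + e1 - 1L, e)),
                        strand = "+")
        } else {
          # transcript starts at the right end: exon1 is the rightmost block
          ex <- GRanges(tab$chrom[i],
                        IRanges(c(e - e1 + 1L, s), c(e, e - e1 - it)),
                        strand = "-")
        }
      }
      seqlevels(ex) <- names(sl)
      exons[[i]] <- ex
    }
    exons <- GRangesList(exons)
    names(exons) <- tab$feature_id

    seqs <- DNAStringSet(vapply(sl, random_dna, character(1)))
    names(seqs) <- names(sl)

    g <- structure(list(seqs = seqs, features = gr, exons = exons, spec = spec),
                   class = "crac_genome")
    g
  })
}

#' Assemble a genome container from components
#'
#' Low-level constructor for callers that already hold sequences and
#' annotation (see also [read_genome()] for the FASTA/GFF3 route).
#'
#' @param seqs A named [Biostrings::DNAStringSet] of chromosomes.
#' @param features A [GenomicRanges::GRanges] with metadata columns
#'   `feature_id` and `class`.
#' @param exons Optional [GenomicRanges::GRangesList] named by feature
#'   id, exons in transcript 5'-to-3' order; defaults to one exon
#'   spanning each feature.
#' @return A `crac_genome`.
#' @export
crac_genome <- function(seqs, features, exons = NULL) {
  stopifnot(is(seqs, "DNAStringSet"), !is.null(names(seqs)),
            is(features, "GRanges"),
            !is.null(mcols(features)$feature_id),
            !is.null(mcols(features)$class))
  sl <- setNames(width(seqs), names(seqs))
  seqlevels(features) <- names(seqs)
  seqlengths(features) <- sl
  names(features) <- mcols(features)$feature_id
  if (is.null(exons)) {
    exons <- as(granges(features), "GRangesList")
    names(exons) <- mcols(features)$feature_id
  }
  structure(list(seqs = seqs, features = features, exons = exons,
                 spec = NULL),
            class = "crac_genome")
}

#' @export
print.crac_genome <- function(x, ...) {
  cat("crac_genome:", length(x$seqs), "chromosome(s),",
      length(x$features), "features\n")
  print(table(mcols(x$features)$class))
  invisible(x)
}

#' Transcription start sites and polyadenylation sites
#'
#' The TSS is the first transcribed base and the pA site the last, in
#' genomic coordinates (1-based): on the plus strand `start(feature)` and
#' `end(feature)`, mirrored on the minus strand.
#'
#' @param genome A `crac_genome`.
#' @return Named integer vector of genomic positions.
#' @export
feature_tss <- function(genome) {
  gr <- genome$features
  setNames(ifelse(as.character(strand(gr)) == "+", start(gr), end(gr)),
           mcols(gr)$feature_id)
}

#' @rdname feature_tss
#' @export
feature_pa <- function(genome) {
  gr <- genome$features
  setNames(ifelse(as.character(strand(gr)) == "+", end(gr), start(gr)),
           mcols(gr)$feature_id)
}

# Mature (spliced) transcript length per feature.
feature_mature_length <- function(genome) {
  setNames(sum(width(genome$exons)), names(genome$exons))
}

#' Annotated introns
#'
#' @param genome A `crac_genome`.
#' @return A [GenomicRanges::GRanges] of introns with a `feature_id`
#'   metadata column; empty if no feature has more than one exon.
#' @export
feature_introns <- function(genome) {
  ex <- genome$exons
  multi <- ex[lengths(ex) > 1]
  if (length(multi) == 0)
    return(GRanges(seqinfo = seqinfo(genome$features)))
  intr <- psetdiff(unlist(range(multi)), multi)
  out <- unlist(intr)
  mcols(out)$feature_id <- rep(names(multi), lengths(intr))
  names(out) <- NULL
  out
}

#' Write a genome as FASTA + GFF3
#'
#' Feature rows use the transcript class as the GFF3 `type` column and
#' carry `ID`; exon rows of intron-containing genes carry `Parent`.
#'
#' @param genome A `crac_genome`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_genome <- function(genome, fasta, gff3) {
  writeXStringSet(genome$seqs, fasta)
  gr <- genome$features
  rows <- gr
  mcols(rows) <- NULL
  mcols(rows)$source <- "cracpipe"
  mcols(rows)$type <- mcols(gr)$class
  mcols(rows)$ID <- mcols(gr)$feature_id
  multi <- genome$exons[lengths(genome$exons) > 1]
  if (length(multi) > 0) {
    exr <- unlist(multi, use.names = FALSE)
    mcols(exr)$source <- "cracpipe"
    mcols(exr)$type <- "exon"
    mcols(exr)$Parent <- rep(names(multi), lengths(multi))
    names(exr) <- NULL
    nm <- names(rows)
    rows <- c(rows, exr)
    names(rows) <- NULL
  } else names(rows) <- NULL
  rows <- sort(rows, ignore.strand = TRUE)
  rtracklayer::export(rows, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Read a genome from FASTA + GFF3
#'
#' Inverse of [write_genome()]: reconstructs the `crac_genome` container
#' from the two files.
#'
#' @param fasta,gff3 Input paths.
#' @return A `crac_genome` (without a generating spec).
#' @export
read_genome <- function(fasta, gff3) {
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- rtracklayer::import(gff3, format = "gff3")
  seqlengths(ann) <- width(seqs)[match(seqlevels(ann), names(seqs))]
  is_exon <- as.character(mcols(ann)$type) == "exon"
  feats <- ann[!is_exon]
  gr <- granges(feats)
  mcols(gr)$feature_id <- as.character(mcols(feats)$ID)
  mcols(gr)$class <- as.character(mcols(feats)$type)
  names(gr) <- mcols(gr)$feature_id
  exr <- ann[is_exon]
  exons <- vector("list", length(gr))
  names(exons) <- mcols(gr)$feature_id
  parent <- as.character(unlist(mcols(exr)$Parent))
  for (i in seq_along(gr)) {
    fid <- mcols(gr)$feature_id[i]
    mine <- exr[parent == fid]
    if (length(mine) == 0) {
      exons[[i]] <- granges(gr[i])
    } else {
      mine <- granges(mine)
      # transcript order: ascending for +, descending for -
      o <- order(start(mine),
                 decreasing = as.character(strand(gr[i])) == "-")
      exons[[i]] <- mine[o]
    }
    mcols(exons[[i]]) <- NULL
  }
  structure(list(seqs = seqs, features = gr,
                 exons = GRangesList(exons), spec = NULL),
            class = "crac_genome")
}
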