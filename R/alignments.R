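# Aligned segments are held as a GRangesList: one element per read, one
# range per aligned block (N-gaps split blocks), with per-read metadata
# columns `tag` (random tag) and `mult` (pre-alignment collapse count).
# Skipped-record counts from loading live in metadata(x)$skipped.
new_segments <- function(grl, skipped = c(unmapped = 0L, secondary = 0L,
                                          supplementary = 0L)) {
  stopifnot(is(grl, "GRangesList"))
  if (is.null(mcols(grl)$tag)) mcols(grl)$tag <- NA_character_
  if (is.null(mcols(grl)$mult)) mcols(grl)$mult <- 1L
  metadata(grl)$skipped <- skipped
  grl
}

#' Skipped-record counts recorded while loading alignments
#'
#' @param segments A segment set from [load_alignments()].
#' @return Named integer vector (`unmapped`, `secondary`, `supplementary`).
#' @export
segments_skipped <- function(segments) metadata(segments)$skipped

#' Number of aligned segments
#'
#' @param segments A `crac_segments` object.
#' @return Integer count of reads (not blocks).
#' @export
n_segments <- function(segments) length(segments)

# One O(n) pass over the unlisted blocks: per-segment chromosome,
# strand and 5' coordinate (blocks are ascending within a segment).
seg_fields <- function(segments) {
  len <- lengths(segments)
  last <- cumsum(len)
  first <- last - len + 1L
  ul <- unlist(segments, use.names = FALSE)
  str <- as.character(strand(ul))[first]
  list(chrom = as.character(seqnames(ul))[first],
       strand = str,
       fp = ifelse(str == "+", start(ul)[first], end(ul)[last]))
}

#' Genomic 5' coordinate of each segment
#'
#' The cross-linking-relevant coordinate used for duplicate collapsing:
#' the leftmost block start on the plus strand, the rightmost block end
#' on the minus strand (1-based).
#'
#' @param segments A `crac_segments` object.
#' @return Integer vector, one position per segment.
#' @export
five_prime_pos <- function(segments) seg_fields(segments)$fp

segment_strand <- function(segments) seg_fields(segments)$strand

segment_chrom <- function(segments) seg_fields(segments)$chrom

#' Load aligned reads from SAM/BAM
#'
#' Reads primary alignments only; secondary, supplementary and unmapped
#' records are skipped and counted (see [segments_skipped()]).  `N`
#' operations in the CIGAR split an alignment into blocks.  The random
#' tag is parsed from the read-name suffix `#TAG:xxx` (as written by the
#' preprocessing stage) or, failing that, from an `RX` tag; a read-name
#' suffix `#N:k` carries the pre-alignment collapse multiplicity.
#'
#' @param path SAM or BAM file.
#' @param no_tags If `TRUE`, missing random tags are tolerated (and
#'   [deduplicate()] refuses to run on the result); otherwise a missing
#'   tag is an error.
#' @return A `crac_segments` object.
#' @export
load_alignments <- function(path, no_tags = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  flags <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  skipped <- c(unmapped = sum(bitwAnd(flags, 4L) > 0),
               secondary = sum(bitwAnd(flags, 256L) > 0),
               supplementary = sum(bitwAnd(flags, 2048L) > 0))
  gal <- GenomicAlignments::readGAlignments(bam,
    param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      tag = "RX"),
    use.names = TRUE)
  nm <- names(gal)
  tag <- sub(".*#TAG:([ACGTN]+).*", "\\1", nm)
  tag[!grepl("#TAG:", nm)] <- NA_character_
  rx <- mcols(gal)$RX
  if (!is.null(rx)) tag[is.na(tag)] <- rx[is.na(tag)]
  if (anyNA(tag) && !no_tags)
    stop("random tag missing from ", sum(is.na(tag)),
         " read names (expected '#TAG:xxx' suffix or RX tag); ",
         "use no_tags = TRUE to load anyway")
  mult <- rep(1L, length(gal))
  has_n <- grepl("#N:", nm)
  mult[has_n] <- as.integer(sub(".*#N:(\\d+).*", "\\1", nm[has_n]))
  grl <- GenomicAlignments::grglist(gal, drop.D.ranges = FALSE)
  names(grl) <- NULL
  mcols(grl) <- NULL
  mcols(grl)$tag <- unname(tag)
  mcols(grl)$mult <- mult
  new_segments(grl, skipped)
}

#' Collapse PCR duplicates by random tag and genomic 5' coordinate
#'
#' Two reads are duplicates when they carry the same random tag and
#' their 5' ends map to the same genomic coordinate on the same strand
#' of the same chromosome.  The first-seen read of each duplicate class
#' survives (representatives are interchangeable for counting).  The
#' operation is idempotent.
#'
#' @param segments A `crac_segments` object with tags.
#' @return A `crac_segments` object, one representative per duplicate
#'   class, in input order.
#' @export
deduplicate <- function(segments) {
  tags <- mcols(segments)$tag
  if (anyNA(tags))
    stop("cannot deduplicate: random tags missing (loaded with no_tags?)")
  f <- seg_fields(segments)
  key <- paste(tags, f$chrom, f$strand, f$fp, sep = "\r")
  out <- segments[!duplicated(key)]
  new_segments(out, metadata(segments)$skipped)
}

#' Default transcript-class priority for read assignment
#'
#' Abundant structured-RNA classes outrank the RNAPII classes so that a
#' read overlapping, say, a snoRNA nested inside an mRNA is credited to
#' the snoRNA.  Fully configurable; results should always report the
#' order used.
#'
#' @return Character vector, highest priority first.
#' @export
default_class_priority <- function() {
  c("rRNA", "tRNA", "other_PolIII", "snoRNA", "snRNA",
    "mRNA", "SUT", "CUT", "XUT", "Ty", "IGS_ncRNA")
}

#' Assign reads to transcript classes
#'
#' Each read gets exactly one class: the highest-priority class among
#' same-strand features overlapping any of its blocks by at least 1 nt.
#' Reads with no sense overlap are `antisense` when an opposite-strand
#' feature overlaps (by default only mRNAs are considered for antisense
#' calls) and `intergenic` otherwise.
#'
#' @param segments A `crac_segments` object.
#' @param genome A `crac_genome`.
#' @param priority Character vector of classes, highest first; every
#'   annotation class must appear (or be mapped via `other_class`).
#' @param antisense_to Classes eligible for antisense assignment.
#' @return A list with `labels` (character per read, input order) and
#'   `counts` (named integer vector over all classes in priority order,
#'   then `antisense` and `intergenic`).
#' @export
classify_reads <- function(segments, genome,
                           priority = default_class_priority(),
                           antisense_to = "mRNA") {
  if (anyDuplicated(priority)) stop("priority classes must be unique")
  feats <- genome$features
  cls <- mcols(feats)$class
  missing_cls <- setdiff(unique(cls), priority)
  if (length(missing_cls) > 0)
    stop("annotation classes absent from priority: ",
         paste(missing_cls, collapse = ", "))
  rank <- match(cls, priority)

  ov <- findOverlaps(segments, feats, ignore.strand = FALSE)
  best <- rep(NA_integer_, length(segments))
  if (length(ov) > 0) {
    dt <- data.table(q = queryHits(ov), r = rank[subjectHits(ov)])
    m <- dt[, list(r = min(r)), by = "q"]
    best[m$q] <- m$r
  }
  labels <- priority[best]

  none <- is.na(best)
  if (any(none)) {
    anti_feats <- feats[cls %in% antisense_to]
    ov2 <- findOverlaps(invertStrand(segments[none]), anti_feats,
                        ignore.strand = FALSE)
    anti <- logical(sum(none))
    anti[unique(queryHits(ov2))] <- TRUE
    labels[none] <- ifelse(anti, "antisense", "intergenic")
  }

  lev <- c(priority, "antisense", "intergenic")
  counts <- table(factor(labels, levels = lev))
  list(labels = labels, counts = setNames(as.integer(counts), lev),
       priority = priority)
}

#' Assign each read to a single feature
#'
#' Used for per-feature read counting (RPKM): among same-strand features
#' overlapping a read by at least 1 nt, the feature of the
#' highest-priority class wins; ties within a class go to the leftmost
#' feature.
#'
#' @inheritParams classify_reads
#' @return Character vector of feature ids (`NA` where no sense
#'   overlap), one per read.
#' @export
assign_features <- function(segments, genome,
                            priority = default_class_priority()) {
  feats <- genome$features
  rank <- match(mcols(feats)$class, priority)
  pos_rank <- order(start(feats))        # tie-break: leftmost feature
  pos_order <- match(seq_along(feats), pos_rank)
  ov <- findOverlaps(segments, feats, ignore.strand = FALSE)
  out <- rep(NA_character_, length(segments))
  if (length(ov) > 0) {
    dt <- data.table(q = queryHits(ov), s = subjectHits(ov),
                     r = rank[subjectHits(ov)],
                     p = pos_order[subjectHits(ov)])
    setorder(dt, q, r, p)
    first <- dt[!duplicated(dt$q), ]
    out[first$q] <- mcols(feats)$feature_id[first$s]
  }
  out
}
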