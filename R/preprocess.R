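#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers around the Biostrings FASTQ reader/writer operating on
#' the data.table read representation used throughout the package
#' (`id`, `seq`, `qual`, optionally `tag` and `mult`).  Collapsed reads
#' are written with the tag and multiplicity encoded in the read name
#' as `id#TAG:ACG#N:5`.
#'
#' @param path FASTQ file.
#' @return `read_fastq`: a data.table with `id`, `seq`, `qual`; if the
#'   names carry `#TAG:`/`#N:` suffixes these are split out into `tag`
#'   and `mult` columns.
#' @export
read_fastq <- function(path) {
  fq <- suppressWarnings(readQualityScaledDNAStringSet(path))
  id <- names(fq)
  dt <- data.table(id = id, seq = as.character(fq),
                   qual = as.character(fq@quality))
  if (any(grepl("#TAG:", id))) {
    dt$tag <- ifelse(grepl("#TAG:", id),
                     sub(".*#TAG:([ACGTN]+).*", "\\1", id), NA_character_)
    dt$mult <- ifelse(grepl("#N:", id),
                      as.integer(sub(".*#N:(\\d+).*", "\\1", id)), 1L)
    dt$id <- sub("#TAG:.*$", "", id)
  }
  dt
}

#' @rdname read_fastq
#' @param reads data.table of reads.
#' @export
write_fastq <- function(reads, path) {
  id <- reads$id
  if (!is.null(reads$tag))
    id <- sprintf("%s#TAG:%s#N:%d", id, reads$tag,
                  if (is.null(reads$mult)) rep(1L, nrow(reads)) else reads$mult)
  # suppress the harmless note about dropped metadata columns
  suppressWarnings({
    fq <- QualityScaledDNAStringSet(DNAStringSet(reads$seq),
                                    PhredQuality(reads$qual))
    names(fq) <- id
    writeQualityScaledXStringSet(fq, path)
  })
  invisible(path)
}

#' Demultiplex linkered reads
#'
#' Each read starts with the 5' linker: a random tag of `tag_length` nt
#' followed by the sample barcode.  Both are removed from the stored
#' sequence and recorded on the read.  Reads whose barcode matches no
#' sample go to the unassigned stream; with `max_mismatch > 0` a barcode
#' matches if within that Hamming distance, but a read ambiguous between
#' two samples is unassigned.  Reads shorter than tag + barcode are
#' unassigned (`reason = "too_short"`).
#'
#' @param reads data.table with `id`, `seq`, `qual`.
#' @param barcodes Named character vector `sample -> barcode`; barcodes
#'   must be equal-length and mutually distinct.
#' @param tag_length Random-tag length (default 3).
#' @param max_mismatch Barcode Hamming tolerance (default 0, exact).
#' @return List with `samples` (named list of per-sample data.tables
#'   with `id`, `seq`, `qual`, `tag`, `barcode`), `unassigned` (with a
#'   `reason` column), and `counts`.
#' @export
demultiplex <- function(reads, barcodes, tag_length = 3L, max_mismatch = 0L) {
  if (is.null(names(barcodes)) || any(names(barcodes) == ""))
    stop("barcodes must be a named vector (sample -> barcode)")
  if (anyDuplicated(barcodes))
    stop("duplicate barcode in map: ",
         paste(barcodes[duplicated(barcodes)], collapse = ", "))
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1) stop("barcodes must be equal-length")
  tl <- as.integer(tag_length)

  too_short <- nchar(reads$seq) < tl + bl
  tag <- substr(reads$seq, 1L, tl)
  bc <- substr(reads$seq, tl + 1L, tl + bl)

  if (max_mismatch == 0L) {
    hit <- match(bc, barcodes)
  } else {
    bcs <- do.call(rbind, strsplit(unname(barcodes), ""))
    obs <- do.call(rbind, strsplit(bc, ""))
    dist <- sapply(seq_len(nrow(bcs)), function(j)
      rowSums(obs != matrix(bcs[j, ], nrow(obs), bl, byrow = TRUE)))
    if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1)
    ok <- dist <= max_mismatch
    nok <- rowSums(ok)
    hit <- ifelse(nok == 1L, max.col(ok, ties.method = "first"), NA_integer_)
    hit[nok > 1L] <- NA_integer_   # ambiguous -> unassigned
  }
  hit[too_short] <- NA_integer_

  assigned <- !is.na(hit)
  samples <- vector("list", length(barcodes))
  names(samples) <- names(barcodes)
  for (j in seq_along(barcodes)) {
    sel <- which(assigned & hit == j)
    samples[[j]] <- data.table(id = reads$id[sel],
                               seq = substr(reads$seq[sel], tl + bl + 1L,
                                            nchar(reads$seq[sel])),
                               qual = substr(reads$qual[sel], tl + bl + 1L,
                                             nchar(reads$qual[sel])),
                               tag = tag[sel],
                               barcode = unname(barcodes[j]))
  }
  un_sel <- which(!assigned)
  unassigned <- data.table(id = reads$id[un_sel], seq = reads$seq[un_sel],
                           qual = reads$qual[un_sel],
                           reason = ifelse(too_short[un_sel], "too_short",
                                           "no_barcode_match"))
  counts <- c(setNames(vapply(samples, nrow, integer(1)), names(barcodes)),
              unassigned = nrow(unassigned))
  list(samples = samples, unassigned = unassigned, counts = counts)
}

#' Trimming policy
#'
#' Adapter/quality trimming contract: remove the 3' adapter at its
#' leftmost match with at least `min_overlap` nt, trim 3' bases below
#' the quality threshold, then discard reads that are shorter than
#' `min_length` or contain more than `max_uncalled` N bases.
#'
#' @param adapter 3' adapter sequence.
#' @param max_uncalled Maximum N bases tolerated (default 3).
#' @param quality_threshold Minimum 3' Phred quality (default 30).
#' @param min_length Minimum post-trim length (default 17).
#' @param min_overlap Minimum adapter overlap at the read 3' end
#'   (default 3).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                        max_uncalled = 3L, quality_threshold = 30L,
                        min_length = 17L, min_overlap = 3L) {
  stopifnot(nchar(adapter) >= 1, max_uncalled >= 0, quality_threshold >= 0,
            min_length >= 1, min_overlap >= 1)
  structure(list(adapter = adapter, max_uncalled = as.integer(max_uncalled),
                 quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length),
                 min_overlap = as.integer(min_overlap)),
            class = "trim_policy")
}

# Leftmost adapter match position in each read (NA if none): either a
# full adapter occurrence, or an adapter prefix (>= min_overlap nt)
# flush with the read's 3' end.  Exact matching; sequencing errors in
# the adapter defeat it, as they do for any exact trimmer.
.adapter_start <- function(seqs, adapter, min_overlap) {
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  pos <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  nc <- nchar(seqs)
  for (k in seq(nchar(adapter) - 1L, min_overlap)) {
    if (k < min_overlap) break
    pref <- substr(adapter, 1L, k)
    at <- nc - k + 1L
    hit <- is.na(pos) & at >= 1L & substr(seqs, at, nc) == pref
    pos[hit] <- at[hit]
  }
  pos
}

#' Trim adapters and low-quality 3' ends
#'
#' Applies a [trim_policy()] to demultiplexed reads: adapter removal,
#' 3' quality trimming, then the length and uncalled-base filters.
#' Discarding is a normal outcome; discarded reads are returned with
#' their reason.
#'
#' @param reads data.table with `id`, `seq`, `qual` (plus any carried
#'   columns such as `tag`).
#' @param policy A [trim_policy()].
#' @return List with `kept` (trimmed reads), `discarded` (with a
#'   `reason` column: `"too_short"` or `"too_many_N"`), and `counts`.
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(policy, "trim_policy"))
  seqs <- reads$seq
  quals <- reads$qual
  apos <- .adapter_start(seqs, policy$adapter, policy$min_overlap)
  keep_len <- ifelse(is.na(apos), nchar(seqs), apos - 1L)
  seqs <- substr(seqs, 1L, keep_len)
  quals <- substr(quals, 1L, keep_len)

  # 3' quality trim: drop the maximal trailing run of bases below the
  # threshold (Phred+33)
  thr_char <- rawToChar(as.raw(policy$quality_threshold + 33L))
  low <- lapply(quals, function(q) utf8ToInt(q) < utf8ToInt(thr_char))
  keep_len2 <- vapply(low, function(v) {
    n <- length(v)
    while (n > 0 && v[n]) n <- n - 1L
    n
  }, integer(1))
  seqs <- substr(seqs, 1L, keep_len2)
  quals <- substr(quals, 1L, keep_len2)

  n_N <- vapply(gregexpr("N", seqs, fixed = TRUE),
                function(m) sum(m > 0), integer(1))
  short <- nchar(seqs) < policy$min_length
  many_n <- !short & n_N > policy$max_uncalled
  ok <- !short & !many_n

  kept <- copy(reads)[, `:=`(seq = seqs, qual = quals)][ok]
  discarded <- copy(reads)[!ok]
  discarded$reason <- ifelse(short[!ok], "too_short", "too_many_N")
  list(kept = kept, discarded = discarded,
       counts = c(kept = sum(ok), too_short = sum(short),
                  too_many_N = sum(many_n)))
}

#' Collapse identical reads
#'
#' One record per distinct (random tag, sequence) pair, keeping the
#' first occurrence and recording the copy count in `mult`.  This is
#' the pre-alignment PCR-duplicate collapse; duplicates that survive it
#' (e.g. through differential 3' trimming in real data) are caught by
#' the genomic [deduplicate()] step.  Idempotent: collapsing a
#' collapsed stream sums the multiplicities unchanged.
#'
#' @param reads data.table with `seq` and `tag` columns (and `mult` if
#'   already collapsed).
#' @return data.table in first-occurrence order with updated `mult`.
#' @export
collapse_identical <- function(reads) {
  if (nrow(reads) == 0) {
    out <- copy(reads)
    if (is.null(out$mult)) out$mult <- integer(0)
    return(out)
  }
  dt <- copy(reads)
  if (is.null(dt$mult)) dt$mult <- 1L
  dt$.ord <- seq_len(nrow(dt))
  grp <- dt[, list(mult = sum(mult), .first = min(.ord)),
            by = c("tag", "seq")]
  setorder(grp, .first)          # first-occurrence order
  out <- dt[grp$.first]
  out$mult <- grp$mult
  out$.ord <- NULL
  out[]
}

#' Low-complexity read filter
#'
#' Drops a read when more than 80% of its bases are a single
#' nucleotide (strictly more; a read with exactly 80% of one base is
#' kept).  `N` counts toward the length but can never be the majority
#' base.  Guards against non-genome-encoded oligo(A) tails mapping to
#' A-rich genomic regions.
#'
#' @param reads data.table with a `seq` column.
#' @param max_fraction Drop threshold (default 0.8, strict).
#' @return Logical vector: `TRUE` = keep.
#' @export
filter_low_complexity <- function(reads, max_fraction = 0.8) {
  seqs <- reads$seq
  if (any(nchar(seqs) == 0)) stop("empty sequence in low-complexity filter")
  freq <- Biostrings::letterFrequency(DNAStringSet(seqs),
                                      letters = c("A", "C", "G", "T"))
  apply(freq, 1, max) / nchar(seqs) <= max_fraction
}

#' Run the full pre-alignment stage for one multiplexed pool
#'
#' demultiplex -> trim -> low-complexity filter -> collapse, per sample,
#' with a per-fate accounting that satisfies read conservation:
#' input = assigned + unassigned, and per sample
#' assigned = kept + discarded(trim) + dropped(complexity).
#'
#' @param reads Pooled reads (data.table `id`, `seq`, `qual`).
#' @param barcodes Named `sample -> barcode` map.
#' @param tag_length Random-tag length.
#' @param policy A [trim_policy()].
#' @param max_mismatch Barcode tolerance for [demultiplex()].
#' @return List with `samples` (named list of collapsed per-sample
#'   data.tables), `unassigned`, and `summary` (data.frame of counts per
#'   sample and fate).
#' @export
preprocess_pool <- function(reads, barcodes, tag_length = 3L,
                            policy = trim_policy(), max_mismatch = 0L) {
  dm <- demultiplex(reads, barcodes, tag_length = tag_length,
                    max_mismatch = max_mismatch)
  out <- vector("list", length(dm$samples))
  names(out) <- names(dm$samples)
  rows <- list()
  for (s in names(dm$samples)) {
    tr <- trim_reads(dm$samples[[s]], policy)
    keep <- filter_low_complexity(tr$kept)
    flt <- tr$kept[keep]
    out[[s]] <- collapse_identical(flt)
    rows[[s]] <- data.frame(
      sample = s, assigned = nrow(dm$samples[[s]]),
      trim_discarded = nrow(tr$discarded),
      low_complexity = sum(!keep), kept = sum(keep),
      collapsed = nrow(out[[s]]), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  attr(summary, "input") <- nrow(reads)
  attr(summary, "unassigned") <- nrow(dm$unassigned)
  list(samples = out, unassigned = dm$unassigned, summary = summary)
}

#' Truth-based prediction of collapsed read counts
#'
#' With sequencing errors off, the preprocessing outcome is exactly
#' predictable from the truth table: every emitted read trims back to
#' its insert, oligo(A) contaminants fail the complexity filter, and
#' collapsing keeps one record per distinct (tag, insert) pair.  Used to
#' validate [preprocess_pool()] on simulated data.
#'
#' @param truth Truth table from [simulate_library()].
#' @param max_fraction Complexity threshold (default 0.8).
#' @return Named integer vector: predicted collapsed-record count per
#'   library.
#' @export
predict_collapsed_counts <- function(truth, max_fraction = 0.8) {
  freq <- Biostrings::letterFrequency(DNAStringSet(truth$insert_seq),
                                      letters = c("A", "C", "G", "T"))
  pass <- apply(freq, 1, max) / nchar(truth$insert_seq) <= max_fraction
  tr <- truth[pass]
  key <- paste(tr$library, tr$tag, tr$insert_seq)
  res <- tapply(!duplicated(key), tr$library, sum)
  setNames(as.integer(res), names(res))
}
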