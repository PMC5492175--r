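#' Default exclusion classes for library-size normalization
#'
#' RNA polymerase I and III transcript classes whose reads are excluded
#' from coverage tracks and from the library size, together with any
#' mitochondrial chromosome (see `exclude_chroms`).
#'
#' @return Character vector of class names.
#' @export
default_exclusion_classes <- function() c("rRNA", "tRNA", "other_PolIII")

new_coverage_track <- function(plus, minus, norm, lib_size, samples) {
  structure(list(plus = plus, minus = minus, norm = norm,
                 lib_size = lib_size, samples = samples),
            class = "coverage_track")
}

#' Build a strand-specific raw coverage track
#'
#' Every included segment adds 1 to each base of each of its aligned
#' blocks on its strand.  Segments whose class assignment falls in
#' `exclusion_classes` (sense overlap, under the configured priority) or
#' whose chromosome is in `exclude_chroms` contribute neither to the
#' track nor to the library size.  The library size is the number of
#' included segments.
#'
#' @param segments A deduplicated segment set.
#' @param genome A `crac_genome`.
#' @param exclusion_classes Classes to exclude (default Pol I/III:
#'   [default_exclusion_classes()]).
#' @param exclude_chroms Chromosome names to exclude entirely (e.g. a
#'   mitochondrial chromosome).
#' @param priority Class priority used for the exclusion assignment.
#' @param sample Sample identifier recorded on the track.
#' @return A `coverage_track`: per-strand [IRanges::RleList]s (`plus`,
#'   `minus`), `norm = "raw"`, `lib_size`, `samples`.
#' @export
build_coverage <- function(segments, genome,
                           exclusion_classes = default_exclusion_classes(),
                           exclude_chroms = character(),
                           priority = default_class_priority(),
                           sample = NA_character_) {
  chroms <- segment_chrom(segments)
  unknown <- setdiff(unique(chroms), seqlevels(genome$features))
  if (length(unknown) > 0)
    stop("segments on chromosome(s) absent from the annotation: ",
         paste(unknown, collapse = ", "))
  labels <- classify_reads(segments, genome, priority = priority)$labels
  included <- !(labels %in% exclusion_classes) & !(chroms %in% exclude_chroms)
  blocks <- unlist(segments[included], use.names = FALSE)
  sl <- seqlengths(genome$features)
  gr_p <- blocks[as.character(strand(blocks)) == "+"]
  gr_m <- blocks[as.character(strand(blocks)) == "-"]
  new_coverage_track(coverage(gr_p), coverage(gr_m),
                     norm = "raw", lib_size = sum(included),
                     samples = sample)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s]: %d chromosome(s), library size %d (%s)\n",
              x$norm, length(x$plus), x$lib_size,
              paste(x$samples, collapse = ",")))
  invisible(x)
}

#' Normalize a raw coverage track to reads per million
#'
#' Scales every per-base value by `1e6 / lib_size`, where the library
#' size is the included-read count recorded on the track.
#'
#' @param track A raw `coverage_track`.
#' @return The RPM-normalized `coverage_track`.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$norm != "raw") stop("track is already normalized (", track$norm, ")")
  if (track$lib_size == 0) stop("cannot normalize: library size is 0")
  f <- 1e6 / track$lib_size
  new_coverage_track(track$plus * f, track$minus * f,
                     norm = "rpm", lib_size = track$lib_size,
                     samples = track$samples)
}

#' Average replicate RPM tracks
#'
#' Per-base arithmetic mean across tracks; all inputs must be RPM
#' tracks over the same genome.
#'
#' @param tracks A list of RPM `coverage_track`s.
#' @return A `coverage_track` (norm `"rpm"`); its `lib_size` is the mean
#'   of the replicate library sizes, recorded for reference only.
#' @export
average_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, logical(1), "coverage_track")))
  norms <- vapply(tracks, `[[`, character(1), "norm")
  if (!all(norms == "rpm")) stop("all tracks must be RPM-normalized")
  lens <- lapply(tracks, function(t) lengths(t$plus))
  if (length(unique(lens)) != 1) stop("tracks cover different genomes")
  n <- length(tracks)
  plus <- Reduce(`+`, lapply(tracks, `[[`, "plus")) / n
  minus <- Reduce(`+`, lapply(tracks, `[[`, "minus")) / n
  new_coverage_track(plus, minus, norm = "rpm",
                     lib_size = mean(vapply(tracks, `[[`, numeric(1),
                                            "lib_size")),
                     samples = unlist(lapply(tracks, `[[`, "samples")))
}

#' Pseudocounted log2 enrichment track
#'
#' Per-base `log2((numerator + pc) / (denominator + pc))` between two
#' RPM tracks; the pseudocount (default 5) keeps the ratio finite and
#' shrinks low-coverage positions toward 0.  Antisymmetric under operand
#' swap.
#'
#' @param numerator,denominator RPM `coverage_track`s over the same
#'   genome (e.g. a cross-linked factor vs total RNA polymerase II).
#' @param pseudocount Positive pseudocount added to both operands.
#' @return An `enrichment_track`: per-strand RleLists (`plus`, `minus`),
#'   `pseudocount`, `num_samples`, `den_samples`.
#' @export
enrichment_track <- function(numerator, denominator, pseudocount = 5) {
  stopifnot(inherits(numerator, "coverage_track"),
            inherits(denominator, "coverage_track"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (numerator$norm != "rpm" || denominator$norm != "rpm")
    stop("both tracks must be RPM-normalized")
  if (!identical(lengths(numerator$plus), lengths(denominator$plus)))
    stop("tracks cover different genomes")
  pc <- pseudocount
  structure(list(
    plus = log2((numerator$plus + pc) / (denominator$plus + pc)),
    minus = log2((numerator$minus + pc) / (denominator$minus + pc)),
    pseudocount = pc,
    num_samples = numerator$samples, den_samples = denominator$samples),
    class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("enrichment_track: log2((%s + %g) / (%s + %g))\n",
              paste(x$num_samples, collapse = ","), x$pseudocount,
              paste(x$den_samples, collapse = ","), x$pseudocount))
  invisible(x)
}

#' Export a track as strand-specific bedGraph files
#'
#' Writes `<prefix>.plus.bedgraph` and `<prefix>.minus.bedgraph`
#' (bedGraph is 0-based half-open; conversion is handled by the
#' exporter).
#'
#' @param track A `coverage_track` or `enrichment_track`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
export_bedgraph <- function(track, prefix) {
  out <- c(plus = paste0(prefix, ".plus.bedgraph"),
           minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("plus", "minus")) {
    gr <- methods::as(track[[s]], "GRanges")
    gr <- gr[mcols(gr)$score != 0]
    rtracklayer::export(gr, out[[s]], format = "bedGraph")
  }
  invisible(out)
}

# Sum of track values over each feature's exonic bases on its strand.
track_feature_totals <- function(track, genome) {
  ex <- genome$exons
  exu <- unlist(ex, use.names = FALSE)
  fidx <- rep(seq_along(ex), lengths(ex))
  vals <- numeric(length(exu))
  strnm <- ifelse(as.character(strand(exu)) == "+", "plus", "minus")
  for (s in c("plus", "minus")) {
    covs <- track[[s]]
    sel <- which(strnm == s)
    if (length(sel) == 0) next
    by_chr <- split(sel, as.character(seqnames(exu))[sel])
    for (chr in names(by_chr)) {
      i <- by_chr[[chr]]
      vals[i] <- viewSums(Views(covs[[chr]], ranges(exu)[i]))
    }
  }
  tot <- tapply(vals, fidx, sum)
  setNames(as.numeric(tot), names(ex)[as.integer(names(tot))])
}
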