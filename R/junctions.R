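#' Count exon-exon and exon-intron junction reads
#'
#' For every annotated intron, three junction events are recognised:
#' \describe{
#'   \item{EE}{a gapped segment whose adjacent blocks flank the intron
#'     exactly (the gap equals the intron) with at least `min_overhang`
#'     aligned nt on each side — evidence for the spliced transcript;}
#'   \item{EI}{a contiguous block crossing the exon/intron boundary at
#'     the intron's transcript-5' end with at least `min_overhang` nt on
#'     each side — unspliced pre-mRNA;}
#'   \item{IE}{the same at the intron/exon boundary at the intron's
#'     transcript-3' end.}
#' }
#' A segment contributes at most once per event type per intron.
#'
#' @param segments A segment set (see [load_alignments()]),
#'   normally deduplicated.
#' @param genome A `crac_genome` with intron-containing genes.
#' @param min_overhang Minimum aligned nt on each side of a junction
#'   (default 3).
#' @return A list of class `junction_counts`: `EE`, `EI`, `IE` (totals),
#'   `min_overhang`, and `per_gene` (data.frame of the three counts per
#'   intron-containing gene).
#' @export
count_junctions <- function(segments, genome, min_overhang = 3L) {
  if (min_overhang < 1) stop("min_overhang must be >= 1")
  oh <- as.integer(min_overhang)
  introns <- feature_introns(genome)
  genes <- mcols(introns)$feature_id
  if (length(introns) == 0)
    stop("annotation contains no intron-containing genes")

  blocks <- unlist(segments, use.names = FALSE)
  segid <- rep(seq_along(segments), lengths(segments))
  nblk <- lengths(segments)

  ee <- ei <- ie <- integer(length(introns))

  # --- EE: adjacent block pairs whose gap equals the intron ---------------
  multi <- which(nblk[segid] > 1)
  if (length(multi) > 0) {
    b <- blocks[multi]
    sid <- segid[multi]
    # within-segment block index (blocks are ascending within a segment)
    bi <- sequence(nblk[nblk > 1])
    left <- bi < nblk[sid]
    dtL <- data.table(sid = sid[left], chrom = as.character(seqnames(b))[left],
                      strand = as.character(strand(b))[left],
                      end = end(b)[left], w = width(b)[left],
                      key_pos = end(b)[left] + 1L)
    right <- bi > 1L
    dtR <- data.table(sid = sid[right], start = start(b)[right],
                      w2 = width(b)[right],
                      key_pos2 = start(b)[right] - 1L)
    # pair block i with block i+1 of the same segment
    dtL$start_next <- dtR$start
    dtL$w2 <- dtR$w2
    idt <- data.table(ii = seq_along(introns),
                      chrom = as.character(seqnames(introns)),
                      strand = as.character(strand(introns)),
                      is = start(introns), ie_ = end(introns))
    hit <- merge(dtL, idt,
                 by.x = c("chrom", "strand", "key_pos"),
                 by.y = c("chrom", "strand", "is"))
    hit <- hit[hit$start_next == hit$ie_ + 1L & hit$w >= oh & hit$w2 >= oh, ]
    if (nrow(hit) > 0) {
      hit <- unique(hit[, c("sid", "ii")])
      tab <- table(factor(hit$ii, levels = seq_along(introns)))
      ee <- as.integer(tab)
    }
  }

  # --- EI / IE: contiguous blocks crossing an intron boundary -------------
  # Boundary windows: a block must fully cover [pos - oh, pos + oh - 1]
  # around the first intronic base (left boundary) or
  # [pos - oh + 1, pos + oh] around the last (right boundary).
  winL <- GRanges(seqnames(introns),
                  IRanges(start(introns) - oh, start(introns) + oh - 1L),
                  strand = strand(introns))
  winR <- GRanges(seqnames(introns),
                  IRanges(end(introns) - oh + 1L, end(introns) + oh),
                  strand = strand(introns))
  plus <- as.character(strand(introns)) == "+"

  cross <- function(win) {
    ov <- findOverlaps(win, blocks, type = "within", ignore.strand = FALSE)
    if (length(ov) == 0) return(integer(length(introns)))
    u <- unique(data.table(ii = queryHits(ov), sid = segid[subjectHits(ov)]))
    as.integer(table(factor(u$ii, levels = seq_along(introns))))
  }
  nL <- cross(winL)
  nR <- cross(winR)
  # transcript orientation: on '+' the left genomic boundary is exon->intron
  ei <- ifelse(plus, nL, nR)
  ie <- ifelse(plus, nR, nL)

  per_gene <- data.frame(feature_id = genes, EE = ee, EI = ei, IE = ie,
                         stringsAsFactors = FALSE)
  structure(list(EE = sum(ee), EI = sum(ei), IE = sum(ie),
                 min_overhang = oh, per_gene = per_gene),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: EE=%d EI=%d IE=%d (overhang %d nt)\n",
              x$EE, x$EI, x$IE, x$min_overhang))
  invisible(x)
}

#' Spliced/unspliced ratio across replicates
#'
#' The per-replicate statistic is `EE / (EI + IE)`: the abundance of
#' exon-exon junction fragments relative to fragments spanning
#' intron-exon and exon-intron junctions.  Replicates with `EI + IE = 0`
#' are undefined; they are excluded from the mean with a warning.
#'
#' @param counts A `junction_counts` object or a list of them (one per
#'   replicate).
#' @return A list with `per_replicate` (numeric, `NA` where undefined),
#'   `mean`, and `sd` (the across-replicate standard deviation; `NA`
#'   with a single replicate).
#' @export
splice_ratio <- function(counts) {
  if (inherits(counts, "junction_counts")) counts <- list(counts)
  ratios <- vapply(counts, function(x) {
    if (x$EI + x$IE == 0) NA_real_ else x$EE / (x$EI + x$IE)
  }, numeric(1))
  if (anyNA(ratios))
    warning(sum(is.na(ratios)),
            " replicate(s) with EI + IE = 0: ratio undefined, excluded")
  ok <- !is.na(ratios)
  list(per_replicate = ratios,
       mean = if (any(ok)) mean(ratios[ok]) else NA_real_,
       sd = if (sum(ok) > 1) sd(ratios[ok]) else NA_real_)
}
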