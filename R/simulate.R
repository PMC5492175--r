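#' Positional binding model for a cross-linked factor
#'
#' Describes where along its target transcripts a factor cross-links.
#' Three shapes are supported: `tss_peaked` confines molecules to a
#' window downstream of the TSS (a 5'-enriched factor such as Set1);
#' `body` confines them to the transcript body between a 5' and a 3'
#' margin (a co-transcriptional factor such as Set2); `uniform` covers
#' the whole transcript (a polymerase-like baseline).  Windows are
#' expressed in transcript coordinates (nt downstream of the TSS) and
#' are clipped to each transcript; a window that vanishes after clipping
#' falls back to the full transcript.
#'
#' @param kind One of `"tss_peaked"`, `"body"`, `"uniform"`.
#' @param tss_window Length-2 numeric, half-open window `[from, to)` in nt
#'   from the TSS (used when `kind = "tss_peaked"`).
#' @param body_margin Length-2 numeric: nt excluded after the TSS and
#'   before the pA site (used when `kind = "body"`).
#' @param weights Named numeric vector of relative expression weights per
#'   feature id (> 0); features absent from `weights` are never sampled.
#'   See [default_expression_weights()].
#' @param spliced_fraction Probability in `[0, 1]` that a molecule from an
#'   intron-containing gene derives from the spliced (mature) transcript.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(kind = c("tss_peaked", "body", "uniform"),
                          tss_window = c(0L, 500L),
                          body_margin = c(150L, 150L),
                          weights = NULL,
                          spliced_fraction = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(tss_window) == 2, tss_window[2] > tss_window[1],
            length(body_margin) == 2, all(body_margin >= 0),
            spliced_fraction >= 0, spliced_fraction <= 1)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(weights <= 0))
      stop("weights must be a named numeric vector with positive values")
  }
  structure(list(kind = kind, tss_window = as.integer(tss_window),
                 body_margin = as.integer(body_margin), weights = weights,
                 spliced_fraction = spliced_fraction),
            class = "binding_model")
}

#' Default per-feature expression weights
#'
#' Log-normal relative transcription rates with a class-dependent scale:
#' rRNA and tRNA are given a higher baseline to mimic the abundant
#' structured-RNA background of cross-linking libraries.
#'
#' @param genome A `crac_genome`.
#' @param seed Integer seed.
#' @param class_scale Named multipliers applied on top of the log-normal
#'   draw; classes not named get scale 1.
#' @return Named numeric vector over all features.
#' @export
default_expression_weights <- function(genome, seed = 1L,
                                       class_scale = c(rRNA = 5, tRNA = 2)) {
  gr <- genome$features
  with_seed(seed, {
    w <- exp(stats::rnorm(length(gr), 0, 1))
    sc <- class_scale[mcols(gr)$class]
    sc[is.na(sc)] <- 1
    setNames(w * sc, mcols(gr)$feature_id)
  })
}

#' Library specification for read simulation
#'
#' Layout of an emitted read: `[random tag][sample barcode][insert]`,
#' padded with the 3' adapter out to `read_length`.  PCR duplication is
#' drawn per molecule from a geometric distribution truncated at
#' `dup_max` (a synthetic choice; duplication rates are library facts
#' that the simulation has to posit).
#'
#' @param name Sample name.
#' @param barcode Barcode sequence (A/C/G/T).
#' @param tag_length Random-tag length in nt (default 3).
#' @param read_length Emitted read length in nt.
#' @param insert_range Length-2 integer, inclusive range of insert sizes;
#'   must fit within `read_length` after tag and barcode.
#' @param n_molecules Number of unique cross-linked molecules.
#' @param dup_prob Success probability of the geometric duplication draw;
#'   duplicate count per molecule is `min(rgeom(prob) + 1, dup_max)`.
#' @param dup_max Truncation of the duplication factor.
#' @param dup_fixed If not `NULL`, every molecule is emitted exactly this
#'   many times (overrides the geometric draw).
#' @param adapter 3' sequencing adapter.
#' @param background_fraction Fraction of molecules drawn uniformly over
#'   all annotated transcripts instead of from the binding model
#'   (non-specific background, as in an untagged control).
#' @param low_complexity_fraction Fraction of additional contaminant
#'   molecules with homopolymer (oligo-A) inserts.
#' @param error_rate Per-base substitution rate (default 0: preprocessing
#'   oracles stay exact).
#' @param seed Integer seed for this library.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(name, barcode, tag_length = 3L, read_length = 112L,
                         insert_range = c(20L, 80L), n_molecules = 10000L,
                         dup_prob = 0.5, dup_max = 10L, dup_fixed = NULL,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         background_fraction = 0.05,
                         low_complexity_fraction = 0.01,
                         error_rate = 0, seed = 1L) {
  stopifnot(nchar(name) > 0, grepl("^[ACGT]+$", barcode), tag_length >= 1,
            length(insert_range) == 2, insert_range[1] >= 1,
            insert_range[2] >= insert_range[1],
            n_molecules >= 1, dup_prob > 0, dup_prob <= 1, dup_max >= 1,
            background_fraction >= 0, background_fraction <= 1,
            low_complexity_fraction >= 0, low_complexity_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  if (insert_range[2] > read_length - tag_length - nchar(barcode))
    stop("insert_range must fit within read_length after tag and barcode")
  if (!is.null(dup_fixed)) stopifnot(dup_fixed >= 1)
  structure(list(name = name, barcode = barcode,
                 tag_length = as.integer(tag_length),
                 read_length = as.integer(read_length),
                 insert_range = as.integer(insert_range),
                 n_molecules = as.integer(n_molecules),
                 dup_prob = dup_prob, dup_max = as.integer(dup_max),
                 dup_fixed = if (is.null(dup_fixed)) NULL
                             else as.integer(dup_fixed),
                 adapter = adapter,
                 background_fraction = background_fraction,
                 low_complexity_fraction = low_complexity_fraction,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "library_spec")
}

# random tags as a character vector
.random_tags <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a cross-linking read library with full ground truth
#'
#' Samples unique molecules from the binding model's positional density
#' over each target transcript, applies PCR duplication, assembles the
#' linkered reads (`tag + barcode + insert + adapter`), and returns both
#' the FASTQ-ready reads and a per-molecule truth table.  Molecules from
#' intron-containing genes derive from the mature transcript with
#' probability `spliced_fraction` (two genomic blocks when they span the
#' junction) and from the pre-mRNA otherwise.
#'
#' @param genome A `crac_genome`.
#' @param model A [binding_model()]; its `weights` must name features of
#'   `genome` (defaults to [default_expression_weights()] on the library
#'   seed if `NULL`).
#' @param lib A [library_spec()].
#' @return A list of class `crac_library`: `reads` (data.table with
#'   `id`, `seq`, `qual`), `truth` (per-molecule data.table), `lib` (the
#'   spec).  Truth columns include the genomic blocks (1-based closed,
#'   ascending), the 5' genomic coordinate, the random tag, duplicate
#'   count, spliced flag, and the exact insert sequence.
#' @export
simulate_library <- function(genome, model, lib) {
  stopifnot(inherits(genome, "crac_genome"), inherits(model, "binding_model"),
            inherits(lib, "library_spec"))
  weights <- model$weights
  if (is.null(weights)) weights <- default_expression_weights(genome, lib$seed)
  gr <- genome$features
  fid <- mcols(gr)$feature_id
  if (!all(names(weights) %in% fid))
    stop("model weights name features absent from the genome: ",
         paste(setdiff(names(weights), fid), collapse = ", "))

  with_seed(lib$seed, {
    n <- lib$n_molecules
    n_bg <- round(n * lib$background_fraction)
    n_sig <- n - n_bg
    n_lc <- round(n * lib$low_complexity_fraction)

    # --- feature assignment ------------------------------------------------
    f_sig <- sample(names(weights), n_sig, replace = TRUE,
                    prob = weights / sum(weights))
    f_bg <- if (n_bg > 0) sample(fid, n_bg, replace = TRUE) else character(0)
    feat <- c(f_sig, f_bg)
    is_bg <- c(rep(FALSE, n_sig), rep(TRUE, n_bg))
    ix <- match(feat, fid)

    f_strand <- as.character(strand(gr))[ix]
    f_chrom <- as.character(seqnames(gr))[ix]
    f_start <- start(gr)[ix]
    f_end <- end(gr)[ix]
    glen <- width(gr)[ix]

    # exon geometry (2 exons at most by construction)
    nex <- lengths(genome$exons)[feat]
    mlen <- feature_mature_length(genome)[feat]
    exu <- unlist(genome$exons)
    exdt <- data.table(fid = rep(names(genome$exons), lengths(genome$exons)),
                       k = unlist(lapply(lengths(genome$exons), seq_len)),
                       s = start(exu), e = end(exu))
    ex1 <- exdt[exdt$k == 1L, ]
    ex2 <- exdt[exdt$k == 2L, ]
    a1 <- ex1$s[match(feat, ex1$fid)]; b1 <- ex1$e[match(feat, ex1$fid)]
    a2 <- ex2$s[match(feat, ex2$fid)]; b2 <- ex2$e[match(feat, ex2$fid)]
    e1len <- ifelse(f_strand == "+", b1 - a1 + 1L, b1 - a1 + 1L)

    # spliced status: only meaningful on intron-containing features
    spliced <- rep(NA, n)
    has_intron <- nex > 1
    spliced[has_intron] <- stats::runif(sum(has_intron)) < model$spliced_fraction

    # coordinate-space length: mature for spliced molecules, genomic else
    L <- ifelse(!is.na(spliced) & spliced, mlen, glen)

    # --- positional window -------------------------------------------------
    w0 <- rep(0L, n); w1 <- L   # half-open [w0, w1) in transcript coords
    use_model <- !is_bg
    if (model$kind == "tss_peaked") {
      w0[use_model] <- pmin(model$tss_window[1], L[use_model])
      w1[use_model] <- pmin(model$tss_window[2], L[use_model])
    } else if (model$kind == "body") {
      w0[use_model] <- model$body_margin[1]
      w1[use_model] <- L[use_model] - model$body_margin[2]
    }
    bad <- w1 - w0 < lib$insert_range[1]   # degenerate window: full transcript
    w0[bad] <- 0L; w1[bad] <- L[bad]

    ins <- .runif_int(n, lib$insert_range)
    ins <- pmin(ins, w1 - w0)
    off <- w0 + floor(stats::runif(n) * (w1 - w0 - ins + 1))

    # --- transcript offset -> genomic blocks -------------------------------
    sp <- !is.na(spliced) & spliced
    two <- sp & (off < e1len) & (off + ins > e1len)   # spans the junction
    in2 <- sp & (off >= e1len)                        # fully in exon 2

    bs1 <- be1 <- integer(n); bs2 <- be2 <- rep(NA_integer_, n)
    plus <- f_strand == "+"

    # unspliced (or intronless): one block over the genomic span
    un <- !sp
    bs1[un & plus] <- f_start[un & plus] + off[un & plus]
    be1[un & plus] <- bs1[un & plus] + ins[un & plus] - 1L
    be1[un & !plus] <- f_end[un & !plus] - off[un & !plus]
    bs1[un & !plus] <- be1[un & !plus] - ins[un & !plus] + 1L

    # spliced, fully within exon 1
    w <- sp & !two & !in2
    bs1[w & plus] <- a1[w & plus] + off[w & plus]
    be1[w & plus] <- bs1[w & plus] + ins[w & plus] - 1L
    be1[w & !plus] <- b1[w & !plus] - off[w & !plus]
    bs1[w & !plus] <- be1[w & !plus] - ins[w & !plus] + 1L

    # spliced, fully within exon 2 (offset q from the exon-2 5' end)
    q <- off - e1len
    bs1[in2 & plus] <- a2[in2 & plus] + q[in2 & plus]
    be1[in2 & plus] <- bs1[in2 & plus] + ins[in2 & plus] - 1L
    be1[in2 & !plus] <- b2[in2 & !plus] - q[in2 & !plus]
    bs1[in2 & !plus] <- be1[in2 & !plus] - ins[in2 & !plus] + 1L

    # spliced, spanning: part1 at exon-1 3' end, part2 at exon-2 5' start.
    # Blocks stored in ascending genomic order (on '-' exon 2 lies left).
    p1 <- e1len - off; p2 <- ins - p1
    tp <- two & plus
    bs1[tp] <- a1[tp] + off[tp]; be1[tp] <- b1[tp]
    bs2[tp] <- a2[tp]; be2[tp] <- a2[tp] + p2[tp] - 1L
    tm <- two & !plus
    bs1[tm] <- b2[tm] - p2[tm] + 1L; be1[tm] <- b2[tm]
    bs2[tm] <- a1[tm]; be2[tm] <- b1[tm] - off[tm]

    five_prime <- integer(n)
    first_s <- ifelse(two & !plus, bs2, bs1)   # start of the 5'-most tx block
    first_e <- ifelse(two & !plus, be2, be1)
    five_prime[plus] <- first_s[plus]
    five_prime[!plus] <- first_e[!plus]

    # --- insert sequences --------------------------------------------------
    chrseq <- setNames(as.character(genome$seqs), names(genome$seqs))
    part_a <- substr(chrseq[f_chrom], bs1, be1)
    part_b <- ifelse(is.na(bs2), "", substr(chrseq[f_chrom], bs2, be2))
    fwd <- paste0(part_a, part_b)              # genome forward strand
    insert <- fwd
    if (any(!plus)) insert[!plus] <- revcomp(fwd[!plus])

    # --- contaminants (oligo-A) -------------------------------------------
    if (n_lc > 0) {
      lc_len <- .runif_int(n_lc, lib$insert_range)
      insert <- c(insert, strrep("A", lc_len))
      feat <- c(feat, rep(NA_character_, n_lc))
      f_chrom <- c(f_chrom, rep(NA_character_, n_lc))
      f_strand <- c(f_strand, rep(NA_character_, n_lc))
      bs1 <- c(bs1, rep(NA_integer_, n_lc)); be1 <- c(be1, rep(NA_integer_, n_lc))
      bs2 <- c(bs2, rep(NA_integer_, n_lc)); be2 <- c(be2, rep(NA_integer_, n_lc))
      five_prime <- c(five_prime, rep(NA_integer_, n_lc))
      spliced <- c(spliced, rep(NA, n_lc))
      is_bg <- c(is_bg, rep(FALSE, n_lc))
    }
    ntot <- n + n_lc
    contaminant <- c(rep(FALSE, n), rep(TRUE, n_lc))

    tags <- .random_tags(ntot, lib$tag_length)
    dup <- if (is.null(lib$dup_fixed))
      pmin(stats::rgeom(ntot, lib$dup_prob) + 1L, lib$dup_max)
    else rep(lib$dup_fixed, ntot)
    dup[contaminant] <- 1L

    cls <- mcols(gr)$class[match(feat, fid)]
    truth <- data.table(
      molecule_id = sprintf("%s_m%07d", lib$name, seq_len(ntot)),
      library = lib$name, feature_id = feat, class = cls,
      chrom = f_chrom, strand = f_strand,
      b1_start = bs1, b1_end = be1, b2_start = bs2, b2_end = be2,
      five_prime = five_prime, tag = tags, dup_count = dup,
      spliced = spliced, background = is_bg, contaminant = contaminant,
      insert_seq = insert, insert_len = nchar(insert))

    # --- emitted reads -----------------------------------------------------
    ridx <- rep(seq_len(ntot), dup)
    dupn <- sequence(dup)
    pad <- strrep(lib$adapter,
                  ceiling(lib$read_length / nchar(lib$adapter)) + 1L)
    raw <- substr(paste0(truth$tag[ridx], lib$barcode, truth$insert_seq[ridx],
                         pad),
                  1L, lib$read_length)
    if (lib$error_rate > 0) raw <- .apply_errors(raw, lib$error_rate)
    reads <- data.table(
      id = sprintf("%s.d%d", truth$molecule_id[ridx], dupn),
      seq = raw,
      qual = strrep(rawToChar(as.raw(40L + 33L)), lib$read_length))

    structure(list(reads = reads, truth = truth, lib = lib),
              class = "crac_library")
  })
}

# uniform substitution errors; slow path, only used when error_rate > 0
.apply_errors <- function(seqs, rate) {
  nc <- nchar(seqs)
  hit <- which(stats::runif(length(seqs)) < 1 - (1 - rate)^nc)
  for (i in hit) {
    v <- strsplit(seqs[i], "")[[1]]
    k <- which(stats::runif(length(v)) < rate)
    if (length(k)) {
      v[k] <- vapply(v[k], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      seqs[i] <- paste(v, collapse = "")
    }
  }
  seqs
}

#' Pool simulated libraries into one multiplexed read set
#'
#' @param libs List of `crac_library` objects; their barcodes must be
#'   mutually distinct and of equal length.
#' @return data.table of pooled reads (`id`, `seq`, `qual`).
#' @export
pool_reads <- function(libs) {
  bcs <- vapply(libs, function(x) x$lib$barcode, character(1))
  if (anyDuplicated(bcs))
    stop("barcode collision between libraries: ",
         paste(bcs[duplicated(bcs)], collapse = ", "))
  if (length(unique(nchar(bcs))) > 1)
    stop("library barcodes must have equal length")
  rbindlist(lapply(libs, `[[`, "reads"))
}

#' Per-feature and per-library truth totals
#'
#' @param truth A truth table from [simulate_library()] (or several
#'   row-bound together).
#' @return `truth_feature_counts`: data.table with unique-molecule and
#'   emitted-read counts per library and feature.
#' @export
truth_feature_counts <- function(truth) {
  tr <- truth[!truth$contaminant & !is.na(truth$feature_id), ]
  out <- tr[, list(n_mol = .N, n_reads = sum(dup_count)),
            by = c("library", "feature_id", "class")]
  setorder(out, library, feature_id)
  out[]
}

#' @rdname truth_feature_counts
#' @return `truth_library_totals`: per-library molecule and emitted-read
#'   totals, split by background/contaminant status.
#' @export
truth_library_totals <- function(truth) {
  out <- truth[, list(n_mol = .N, n_reads = sum(dup_count)),
               by = c("library", "background", "contaminant")]
  setorder(out, library)
  out[]
}

#' Emit truth alignments as SAM
#'
#' Writes one primary alignment per emitted read (PCR duplicates
#' included) at its true genomic locus, bypassing an external aligner.
#' Spliced molecules get an `N`-gap CIGAR across the intron.  The random
#' tag travels both in the read-name suffix (`#TAG:xxx#N:1`) and in an
#' `RX` tag.  Contaminant reads have no genomic origin and are omitted.
#'
#' @param truth A truth table from [simulate_library()].
#' @param genome The `crac_genome` the truth refers to.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
emit_truth_alignments <- function(truth, genome, path) {
  sl <- seqlengths(genome$features)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
  tr <- truth[!truth$contaminant & !is.na(truth$chrom), ]
  ridx <- rep(seq_len(nrow(tr)), tr$dup_count)
  dupn <- sequence(tr$dup_count)
  tr <- tr[ridx]
  w1 <- tr$b1_end - tr$b1_start + 1L
  gapped <- !is.na(tr$b2_start)
  cigar <- paste0(w1, "M")
  cigar[gapped] <- paste0(w1[gapped], "M",
                          tr$b2_start[gapped] - tr$b1_end[gapped] - 1L, "N",
                          tr$b2_end[gapped] - tr$b2_start[gapped] + 1L, "M")
  lines <- paste(
    sprintf("%s.d%d#TAG:%s#N:1", tr$molecule_id, dupn, tr$tag),
    ifelse(tr$strand == "-", 16L, 0L),
    tr$chrom, tr$b1_start, 255L, cigar, "*", 0L, 0L, "*", "*",
    paste0("RX:Z:", tr$tag),
    sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Aligned segments straight from a truth table
#'
#' Builds the in-memory aligned-segment container directly from truth
#' blocks, short-circuiting SAM round trips in simulations.
#'
#' @param truth Truth table.
#' @param genome The `crac_genome`.
#' @param emitted If `TRUE`, one segment per emitted read (duplicates
#'   expanded); if `FALSE`, one per unique molecule.
#' @return A `crac_segments` object (see [load_alignments()]).
#' @export
truth_segments <- function(truth, genome, emitted = TRUE) {
  tr <- truth[!truth$contaminant & !is.na(truth$chrom), ]
  if (emitted) {
    ridx <- rep(seq_len(nrow(tr)), tr$dup_count)
    tr <- tr[ridx]
  }
  gapped <- !is.na(tr$b2_start)
  nblk <- 1L + gapped
  s <- c(rbind(tr$b1_start, ifelse(gapped, tr$b2_start, NA_integer_)))
  e <- c(rbind(tr$b1_end, ifelse(gapped, tr$b2_end, NA_integer_)))
  keep <- !is.na(s)
  chrv <- rep(tr$chrom, each = 2)[keep]
  strv <- rep(tr$strand, each = 2)[keep]
  blocks <- GRanges(chrv, IRanges(s[keep], e[keep]), strand = strv,
                    seqinfo = seqinfo(genome$features))
  grl <- relist(blocks, PartitioningByWidth(nblk))
  mcols(grl)$tag <- tr$tag
  mcols(grl)$mult <- 1L
  new_segments(grl)
}
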