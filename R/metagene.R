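#' Anchor-aligned per-feature signal matrix
#'
#' One row per feature, one column per position relative to the anchor
#' (TSS or pA site), in transcript orientation: position 0 is the first
#' (TSS) or last (pA) transcribed base, positive positions run
#' downstream in the direction of transcription, and minus-strand
#' features are mirrored.  Cells more than `flank` nt outside the
#' transcript, or beyond the chromosome ends, are masked (`NA`) and
#' excluded from aggregation.
#'
#' @param track A `coverage_track` (RPM or raw) or `enrichment_track`.
#'   For stranded tracks the value is taken from the feature's strand.
#' @param genome A `crac_genome`.
#' @param features Feature ids to include (default: all).
#' @param anchor `"tss"` or `"pa"`.
#' @param window Length-2 integer: relative positions `window[1]` to
#'   `window[2]` inclusive.  Defaults: TSS `c(-100, 1500)`, pA
#'   `c(-1500, 100)`.
#' @param flank Masking flank in nt outside the transcript (default 100).
#' @param min_length If not `NULL`, drop features shorter than this
#'   instead of masking beyond their ends.
#' @return Numeric matrix of class `anchored_matrix` with feature ids as
#'   rownames, relative positions as colnames, and attributes `anchor`,
#'   `window`, `value_kind` (`"rpm"`, `"raw"` or `"log2_enrichment"`).
#' @export
anchored_matrix <- function(track, genome, features = NULL,
                            anchor = c("tss", "pa"), window = NULL,
                            flank = 100L, min_length = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window))
    window <- if (anchor == "tss") c(-100L, 1500L) else c(-1500L, 100L)
  stopifnot(length(window) == 2, window[1] <= window[2])
  value_kind <- if (inherits(track, "enrichment_track")) "log2_enrichment"
                else track$norm

  gr <- genome$features
  if (!is.null(features)) {
    keep <- mcols(gr)$feature_id %in% features
    gr <- gr[keep]
  }
  if (!is.null(min_length)) gr <- gr[width(gr) >= min_length]
  if (length(gr) == 0) stop("no features to anchor")
  fid <- mcols(gr)$feature_id

  pos <- seq(window[1], window[2])
  mat <- matrix(NA_real_, nrow = length(gr), ncol = length(pos),
                dimnames = list(fid, pos))

  tssv <- feature_tss(genome)[fid]
  sl <- seqlengths(genome$features)
  # decode each needed chromosome strand once
  dec <- new.env(parent = emptyenv())
  get_vec <- function(chr, strand_name) {
    key <- paste0(chr, "_", strand_name)
    if (is.null(dec[[key]]))
      dec[[key]] <- as.numeric(track[[strand_name]][[chr]])
    dec[[key]]
  }

  for (i in seq_along(gr)) {
    chr <- as.character(seqnames(gr[i]))
    str <- as.character(strand(gr[i]))
    len <- width(gr[i])
    a <- if (anchor == "tss") tssv[i] else feature_pa(genome)[fid[i]]
    gpos <- if (str == "+") a + pos else a - pos
    # transcript coordinate of each column (0 = TSS)
    tpos <- if (anchor == "tss") pos else (len - 1L) + pos
    vals <- rep(NA_real_, length(pos))
    inside <- gpos >= 1L & gpos <= sl[[chr]] &
      tpos >= -flank & tpos <= len - 1L + flank
    if (any(inside)) {
      v <- get_vec(chr, if (str == "+") "plus" else "minus")
      vals[inside] <- v[gpos[inside]]
    }
    mat[i, ] <- vals
  }
  structure(mat, anchor = anchor, window = window, value_kind = value_kind,
            class = c("anchored_matrix", class(mat)))
}

#' Aggregate an anchored matrix into a metagene profile
#'
#' Per-position aggregate over unmasked rows.  The default mode follows
#' the track type: absolute coverage matrices are summed (total
#' coverage across transcripts), enrichment matrices are averaged
#' (per-base enrichment is a ratio; summing it is meaningless).
#'
#' @param mat An [anchored_matrix()].
#' @param mode `"auto"`, `"sum"` or `"mean"`.
#' @return data.frame: `position`, `value` (`NA` where every row is
#'   masked), `n_features` (unmasked rows per position), with the mode
#'   used as an attribute.
#' @export
metagene_profile <- function(mat, mode = c("auto", "sum", "mean")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (identical(attr(mat, "value_kind"), "log2_enrichment"))
      "mean" else "sum"
  n_ok <- colSums(!is.na(mat))
  agg <- if (mode == "sum") colSums(mat, na.rm = TRUE)
         else colMeans(mat, na.rm = TRUE)
  agg[n_ok == 0] <- NA_real_
  out <- data.frame(position = as.integer(colnames(mat)), value = agg,
                    n_features = n_ok, row.names = NULL)
  attr(out, "mode") <- mode
  out
}

#' Enrichment metagene relative to a reference factor
#'
#' Computes the per-base pseudocounted log2 enrichment of `protein` over
#' `reference`, anchors it across `features`, and averages per position.
#' Per-base enrichment is computed before aggregation (the mean of
#' ratios, not the ratio of means) — at low coverage the pseudocount
#' shrinks values toward 0.
#'
#' @param protein,reference RPM `coverage_track`s.
#' @inheritParams anchored_matrix
#' @param pseudocount Positive pseudocount (default 5).
#' @return A metagene profile data.frame (see [metagene_profile()]).
#' @export
relative_metagene <- function(protein, reference, genome, features = NULL,
                              anchor = c("tss", "pa"), window = NULL,
                              pseudocount = 5, flank = 100L) {
  et <- enrichment_track(protein, reference, pseudocount = pseudocount)
  mat <- anchored_matrix(et, genome, features = features, anchor = anchor,
                         window = window, flank = flank)
  metagene_profile(mat, mode = "mean")
}

#' Reference signal over the first transcribed nucleotides
#'
#' Total reference-track signal over `[TSS, TSS + window)` of each
#' feature (clipped at the transcript end), the expression proxy used
#' for expression matching.
#'
#' @param track An RPM `coverage_track` (the reference factor).
#' @param genome A `crac_genome`.
#' @param features Feature ids (default: all).
#' @param window Window length in nt (default 300).
#' @return Named numeric vector of signals.
#' @export
tss_signal <- function(track, genome, features = NULL, window = 300L) {
  gr <- genome$features
  if (!is.null(features)) gr <- gr[mcols(gr)$feature_id %in% features]
  fid <- mcols(gr)$feature_id
  w <- pmin(window, width(gr))
  plus <- as.character(strand(gr)) == "+"
  win <- GRanges(seqnames(gr),
                 IRanges(start = ifelse(plus, start(gr), end(gr) - w + 1L),
                         width = w),
                 strand = strand(gr))
  vals <- numeric(length(gr))
  for (s in c("plus", "minus")) {
    sel <- which(if (s == "plus") plus else !plus)
    if (length(sel) == 0) next
    by_chr <- split(sel, as.character(seqnames(win))[sel])
    for (chr in names(by_chr)) {
      i <- by_chr[[chr]]
      vals[i] <- viewSums(Views(track[[s]][[chr]], ranges(win)[i]))
    }
  }
  setNames(vals, fid)
}

#' Expression-matched feature subsets across classes
#'
#' Greedy nearest-neighbour matching without replacement in log10
#' reference signal: features of the first class are visited in order
#' of feature id; for each, the closest unused feature of every other
#' class is taken, and the group is kept only when all pairwise log10
#' differences stay within `tolerance`.  Ties go to the lowest feature
#' id.  Features with zero reference signal are ineligible.
#'
#' @param stats A `feature_stats` table (provides classes and the
#'   feature universe).
#' @param signal Named numeric vector of reference signals per feature
#'   (see [tss_signal()]).
#' @param classes Classes to match across (default mRNA, SUT, CUT).
#' @param tolerance Maximum |log10 signal difference| within a matched
#'   group (default 0.05).
#' @return data.frame: `group`, `class`, `feature_id`, `log10_signal`;
#'   zero rows (with a warning) when a class has no eligible feature.
#' @export
expression_match <- function(stats, signal,
                             classes = c("mRNA", "SUT", "CUT"),
                             tolerance = 0.05) {
  empty <- data.frame(group = integer(0), class = character(0),
                      feature_id = character(0), log10_signal = numeric(0))
  pools <- lapply(classes, function(cl) {
    ids <- stats$feature_id[stats$class == cl]
    sig <- signal[ids]
    ids <- ids[!is.na(sig) & sig > 0]
    d <- data.frame(feature_id = ids, log10_signal = log10(signal[ids]),
                    stringsAsFactors = FALSE)
    d[order(d$feature_id), ]
  })
  names(pools) <- classes
  if (any(vapply(pools, nrow, integer(1)) == 0)) {
    warning("class(es) with no eligible feature: ",
            paste(classes[vapply(pools, nrow, integer(1)) == 0],
                  collapse = ", "))
    return(empty)
  }
  anchor_pool <- pools[[1]]
  used <- lapply(pools[-1], function(p) rep(FALSE, nrow(p)))
  groups <- list()
  g <- 0L
  for (i in seq_len(nrow(anchor_pool))) {
    s0 <- anchor_pool$log10_signal[i]
    picks <- integer(length(pools) - 1L)
    ok <- TRUE
    for (j in seq_along(pools[-1])) {
      p <- pools[-1][[j]]
      avail <- which(!used[[j]])
      if (length(avail) == 0) { ok <- FALSE; break }
      d <- abs(p$log10_signal[avail] - s0)
      # nearest; ties -> lowest feature id (pools are id-sorted)
      best <- avail[which.min(d)]
      if (abs(p$log10_signal[best] - s0) > tolerance) { ok <- FALSE; next }
      picks[j] <- best
    }
    if (!ok || any(picks == 0)) next
    # check all pairwise differences within the group
    sigs <- c(s0, vapply(seq_along(picks), function(j)
      pools[-1][[j]]$log10_signal[picks[j]], numeric(1)))
    if (max(sigs) - min(sigs) > tolerance) next
    g <- g + 1L
    rows <- data.frame(
      group = g,
      class = classes,
      feature_id = c(anchor_pool$feature_id[i],
                     vapply(seq_along(picks), function(j)
                       pools[-1][[j]]$feature_id[picks[j]], character(1))),
      log10_signal = sigs, stringsAsFactors = FALSE)
    groups[[g]] <- rows
    for (j in seq_along(picks)) used[[j]][picks[j]] <- TRUE
  }
  if (length(groups) == 0) return(empty)
  do.call(rbind, groups)
}

#' Export an anchored matrix as an ordered TSV heat-map table
#'
#' Rows ordered by the sort key, descending; masked cells written as
#' `NA`.  Re-exporting the same matrix produces a byte-identical file.
#'
#' @param mat An [anchored_matrix()].
#' @param path Output TSV path.
#' @param sort_key `"total"` (row sum of unmasked cells), `"length"`
#'   (feature length from `genome`), or `"external"` (use `ranking`).
#' @param genome Required for `sort_key = "length"`.
#' @param ranking Named numeric vector for `sort_key = "external"`.
#' @return The path, invisibly.
#' @export
heatmap_export <- function(mat, path, sort_key = c("total", "length",
                                                   "external"),
                           genome = NULL, ranking = NULL) {
  sort_key <- match.arg(sort_key)
  key <- switch(sort_key,
    total = rowSums(mat, na.rm = TRUE),
    length = {
      if (is.null(genome)) stop("sort_key = 'length' requires genome")
      width(genome$features)[match(rownames(mat),
                                   mcols(genome$features)$feature_id)]
    },
    external = {
      if (is.null(ranking)) stop("sort_key = 'external' requires ranking")
      if (!all(rownames(mat) %in% names(ranking)))
        stop("ranking does not cover all features")
      ranking[rownames(mat)]
    })
  o <- order(key, decreasing = TRUE)
  out <- data.frame(feature_id = rownames(mat)[o], unclass(mat)[o, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
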