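#' Per-feature statistics with reproducibility and abundance filters
#'
#' For every annotated feature: the per-replicate coverage total (sum of
#' RPM signal over the feature's exonic bases on its strand), the
#' coefficient of variation of those totals across replicates (sample
#' SD over mean), and the RPKM from included-read counts (reads
#' assigned to the feature per kilobase of mature length per million
#' included reads, averaged over replicates).  A feature is selected
#' when it is reproducible (CV strictly below `cv_max`) and confidently
#' bound (RPKM strictly above `rpkm_min`).
#'
#' @param tracks List of per-replicate RPM `coverage_track`s.
#' @param segments List of per-replicate deduplicated segment sets
#'   (same order as `tracks`), used for read counting.
#' @param genome A `crac_genome`.
#' @param cv_max Reproducibility threshold on the CV (default 0.5).
#' @param rpkm_min Abundance threshold on RPKM (default 30).
#' @param priority Class priority for read-to-feature assignment.
#' @return A data.frame of class `feature_stats`: `feature_id`, `class`,
#'   `length` (mature nt), one `total_<i>` column per replicate,
#'   `mean_total`, `cv`, `rpkm`, `passes_reproducibility`,
#'   `passes_abundance`, `selected`.  Thresholds and the priority used
#'   are recorded as attributes.
#' @export
feature_stats <- function(tracks, segments, genome,
                          cv_max = 0.5, rpkm_min = 30,
                          priority = default_class_priority()) {
  stopifnot(length(tracks) >= 2, length(tracks) == length(segments))
  norms <- vapply(tracks, `[[`, character(1), "norm")
  if (!all(norms == "rpm")) stop("all tracks must be RPM-normalized")
  gr <- genome$features
  fid <- mcols(gr)$feature_id
  len <- feature_mature_length(genome)[fid]
  if (any(len == 0)) stop("zero-length feature(s): ",
                          paste(fid[len == 0], collapse = ", "))
  nrep <- length(tracks)

  totals <- vapply(tracks, function(t) track_feature_totals(t, genome)[fid],
                   numeric(length(fid)))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = length(fid))

  rpkm_rep <- vapply(seq_len(nrep), function(i) {
    asn <- assign_features(segments[[i]], genome, priority = priority)
    cnt <- table(factor(asn, levels = fid))
    as.integer(cnt) / ((len / 1e3) * (tracks[[i]]$lib_size / 1e6))
  }, numeric(length(fid)))
  if (is.null(dim(rpkm_rep))) rpkm_rep <- matrix(rpkm_rep, nrow = length(fid))

  mean_total <- rowMeans(totals)
  cv <- apply(totals, 1, sd) / mean_total
  cv[!is.finite(cv)] <- NA_real_
  rpkm <- rowMeans(rpkm_rep)

  passes_repro <- !is.na(cv) & cv < cv_max
  passes_abund <- rpkm > rpkm_min

  out <- data.frame(feature_id = fid, class = mcols(gr)$class,
                    length = as.integer(len), stringsAsFactors = FALSE)
  for (i in seq_len(nrep)) out[[paste0("total_", i)]] <- totals[, i]
  out$mean_total <- mean_total
  out$cv <- cv
  out$rpkm <- rpkm
  out$passes_reproducibility <- passes_repro
  out$passes_abundance <- passes_abund
  out$selected <- passes_repro & passes_abund
  attr(out, "cv_max") <- cv_max
  attr(out, "rpkm_min") <- rpkm_min
  attr(out, "priority") <- priority
  attr(out, "cv_estimator") <- "sample SD (n-1) / mean"
  class(out) <- c("feature_stats", class(out))
  out
}

#' Feature-level comparison table between two factors
#'
#' Restricted to features selected in `statsA`, pairs each feature's
#' coverage total in A with its total in B and computes the
#' pseudocounted log2 enrichment `log2((A + pc) / (B + pc))` on the
#' totals — the quantity behind factor-versus-polymerase scatter plots.
#'
#' @param statsA,statsB `feature_stats` tables over the same feature
#'   universe (A: the factor; B: the reference).
#' @param pseudocount Positive pseudocount (default 5).
#' @return data.frame: `feature_id`, `class`, `coverage_a`,
#'   `coverage_b`, `enrichment`.
#' @export
scatter_table <- function(statsA, statsB, pseudocount = 5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  missing_ids <- setdiff(statsA$feature_id, statsB$feature_id)
  if (length(missing_ids) > 0 ||
      length(setdiff(statsB$feature_id, statsA$feature_id)) > 0)
    stop("feature universes differ; missing from B: ",
         paste(missing_ids, collapse = ", "))
  a <- statsA[statsA$selected, ]
  b <- statsB[match(a$feature_id, statsB$feature_id), ]
  data.frame(feature_id = a$feature_id, class = a$class,
             coverage_a = a$mean_total, coverage_b = b$mean_total,
             enrichment = log2((a$mean_total + pseudocount) /
                               (b$mean_total + pseudocount)),
             stringsAsFactors = FALSE)
}
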