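#' Default pipeline parameters
#'
#' The resolved defaults used by [validate_config()] when a key is not
#' supplied: trimming thresholds (max 3 uncalled bases, 3' quality 30,
#' minimum length 17, adapter overlap 3), pseudocount 5, CV threshold
#' 0.5, RPKM threshold 30, junction overhang 3 nt, Pol I/III exclusion
#' classes, and the metagene windows.
#'
#' @return Named list of parameter defaults.
#' @export
default_params <- function() {
  list(tag_length = 3L, max_uncalled = 3L, quality_threshold = 30L,
       min_length = 17L, min_overlap = 3L,
       adapter = "TGGAATTCTCGGGTGCCAAGG",
       max_mismatch = 0L,
       pseudocount = 5, cv_max = 0.5, rpkm_min = 30,
       min_overhang = 3L,
       exclusion_classes = default_exclusion_classes(),
       exclude_chroms = character(),
       class_priority = default_class_priority(),
       tss_window = c(-100L, 1500L), pa_window = c(-1500L, 100L),
       flank = 100L, match_window = 300L, match_tolerance = 0.05)
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML file path or a list.  Fills documented defaults and
#' collects every violated constraint instead of stopping at the first.
#' A configuration names the output directory, a global seed, the
#' synthetic-genome parameters, a sample sheet (name, barcode,
#' replicate group, role: `protein`, `reference` or `background`, and
#' binding-model parameters per group), and stage parameters.
#'
#' @param config Path to a YAML file, or a list.
#' @return The resolved config (class `crac_config`); errors with the
#'   full list of violations otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)

  p <- default_params()
  for (k in names(config$params)) {
    if (!k %in% names(p)) push(sprintf("unknown parameter '%s'", k))
    else p[[k]] <- config$params[[k]]
  }
  if (p$pseudocount <= 0) push("pseudocount must be > 0")
  if (p$cv_max <= 0) push("cv_max must be > 0")
  if (p$rpkm_min < 0) push("rpkm_min must be >= 0")
  if (p$min_overhang < 1) push("min_overhang must be >= 1")
  if (p$min_length < 1) push("min_length must be >= 1")

  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) push("missing key 'outdir'")

  if (is.null(config$samples) || length(config$samples) == 0) {
    push("missing key 'samples'")
  } else {
    nm <- vapply(config$samples, function(s) s$name %||% NA_character_,
                 character(1))
    bc <- vapply(config$samples, function(s) s$barcode %||% NA_character_,
                 character(1))
    role <- vapply(config$samples, function(s) s$role %||% "protein",
                   character(1))
    if (anyNA(nm)) push("every sample needs a 'name'")
    if (anyDuplicated(stats::na.omit(nm)))
      push("duplicate sample names")
    if (anyNA(bc)) push("every sample needs a 'barcode'")
    if (anyDuplicated(stats::na.omit(bc)))
      push(paste("duplicate barcode:",
                 paste(bc[duplicated(bc)], collapse = ", ")))
    bad_role <- !role %in% c("protein", "reference", "background")
    if (any(bad_role))
      push(paste("invalid role(s):", paste(role[bad_role], collapse = ", ")))
    ref_groups <- unique(vapply(
      config$samples[role == "reference"],
      function(s) s$group %||% s$name, character(1)))
    if (length(ref_groups) > 1)
      push("exactly one reference replicate group is required, found: " |>
             paste0(paste(ref_groups, collapse = ", ")))
    if (length(ref_groups) == 0)
      push("a sample with role 'reference' is required for enrichment")
  }
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  config$params <- p
  class(config) <- c("crac_config", class(config))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demo configuration for the packaged synthetic study
#'
#' Four sample groups over a miniature two-chromosome genome: two
#' replicates of a 5'-peaked factor (Set1-like), two of a
#' body-distributed factor (Set2-like), two of a uniform polymerase
#' baseline (the reference), and one untagged background library.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @param n_molecules Unique molecules per library.
#' @return A config list suitable for [validate_config()] /
#'   [run_pipeline()].
#' @export
demo_config <- function(outdir, seed = 42L, n_molecules = 8000L) {
  list(
    outdir = outdir, seed = as.integer(seed),
    genome = list(),               # synthetic_genome_spec() defaults
    samples = list(
      list(name = "set1_rep1", barcode = "ATCGA", group = "set1",
           role = "protein", model = "tss_peaked",
           n_molecules = n_molecules),
      list(name = "set1_rep2", barcode = "GCTAA", group = "set1",
           role = "protein", model = "tss_peaked",
           n_molecules = n_molecules),
      list(name = "set2_rep1", barcode = "CGATC", group = "set2",
           role = "protein", model = "body",
           n_molecules = n_molecules),
      list(name = "set2_rep2", barcode = "TTAGC", group = "set2",
           role = "protein", model = "body",
           n_molecules = n_molecules),
      list(name = "pol2_rep1", barcode = "AAGGC", group = "pol2",
           role = "reference", model = "uniform",
           n_molecules = n_molecules),
      list(name = "pol2_rep2", barcode = "CCATG", group = "pol2",
           role = "reference", model = "uniform",
           n_molecules = n_molecules),
      list(name = "untagged", barcode = "GGTCA", group = "untagged",
           role = "background", model = "uniform",
           n_molecules = round(n_molecules / 4))),
    params = list())
}

.stage_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 1000L + k

#' Run the full pipeline on a configuration
#'
#' Executes simulate -> preprocess -> truth alignments -> deduplicate ->
#' classify -> junctions -> coverage -> enrichment -> feature statistics
#' -> metagene, writing TSV/bedGraph/FASTQ/SAM outputs and a JSON run
#' report into the output directory.  All randomness derives from the
#' single global seed, expanded deterministically into per-stage seeds;
#' rerunning with the same config produces byte-identical tables.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @return Invisibly, a list with the run report and the main in-memory
#'   results (`genome`, `stats`, `profiles`, ...).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  report <- list(version = as.character(utils::packageVersion("cracpipe")),
                 seed = config$seed, params = p)

  # --- stage 1: genome ----------------------------------------------------
  gspec <- do.call(synthetic_genome_spec,
                   c(config$genome, list(seed = .stage_seed(config$seed, 1L))))
  genome <- generate_genome(gspec)
  write_genome(genome, file.path(out, "genome.fasta"),
               file.path(out, "annotation.gff3"))

  # --- stage 2: libraries -------------------------------------------------
  weights <- default_expression_weights(genome,
                                        seed = .stage_seed(config$seed, 2L))
  roles <- vapply(config$samples, function(s) s$role %||% "protein",
                  character(1))
  libs <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    model <- binding_model(kind = s$model %||% "uniform", weights = weights,
                           spliced_fraction = s$spliced_fraction %||% 0.5)
    lib <- library_spec(name = s$name, barcode = s$barcode,
                        tag_length = p$tag_length,
                        n_molecules = s$n_molecules %||% 5000L,
                        background_fraction =
                          if (roles[i] == "background") 1 else
                            s$background_fraction %||% 0.05,
                        seed = .stage_seed(config$seed, 10L + i))
    libs[[s$name]] <- simulate_library(genome, model, lib)
  }
  truth_all <- rbindlist(lapply(libs, `[[`, "truth"))
  fwrite(truth_all, file.path(out, "truth_molecules.tsv"), sep = "\t")
  fwrite(truth_library_totals(truth_all),
         file.path(out, "truth_library_totals.tsv"), sep = "\t")
  pool <- pool_reads(libs)
  write_fastq(pool, file.path(out, "pooled.fastq"))

  # --- stage 3: preprocessing --------------------------------------------
  barcodes <- setNames(vapply(config$samples, `[[`, character(1), "barcode"),
                       vapply(config$samples, `[[`, character(1), "name"))
  policy <- trim_policy(adapter = p$adapter, max_uncalled = p$max_uncalled,
                        quality_threshold = p$quality_threshold,
                        min_length = p$min_length,
                        min_overlap = p$min_overlap)
  pre <- preprocess_pool(pool, barcodes, tag_length = p$tag_length,
                         policy = policy, max_mismatch = p$max_mismatch)
  write.table(pre$summary, file.path(out, "preprocess_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$preprocess <- list(
    input = nrow(pool), unassigned = attr(pre$summary, "unassigned"),
    per_sample = pre$summary)
  stopifnot(nrow(pool) ==
              attr(pre$summary, "unassigned") + sum(pre$summary$assigned))

  # --- stage 4: alignments + dedup ---------------------------------------
  segs <- list()
  dedup_counts <- data.frame(sample = names(libs), aligned = NA_integer_,
                             deduplicated = NA_integer_)
  for (i in seq_along(libs)) {
    nm <- names(libs)[i]
    sam <- file.path(out, paste0(nm, ".truth.sam"))
    emit_truth_alignments(libs[[nm]]$truth, genome, sam)
    sg <- load_alignments(sam)
    dedup_counts$aligned[i] <- n_segments(sg)
    sg <- deduplicate(sg)
    dedup_counts$deduplicated[i] <- n_segments(sg)
    segs[[nm]] <- sg
  }
  write.table(dedup_counts, file.path(out, "dedup_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 5: classes + junctions --------------------------------------
  class_rows <- lapply(names(segs), function(nm) {
    cc <- classify_reads(segs[[nm]], genome, priority = p$class_priority)
    data.frame(sample = nm, class = names(cc$counts),
               reads = unname(cc$counts), stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, class_rows),
              file.path(out, "class_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- vapply(config$samples, function(s) s$group %||% s$name,
                   character(1))
  names(groups) <- names(barcodes)
  jx_rows <- list()
  for (grp in unique(groups[roles != "background"])) {
    members <- names(groups)[groups == grp]
    jc <- lapply(members, function(nm)
      count_junctions(segs[[nm]], genome, min_overhang = p$min_overhang))
    sr <- splice_ratio(jc)
    jx_rows[[grp]] <- data.frame(
      group = grp,
      EE = sum(vapply(jc, `[[`, numeric(1), "EE")),
      EI = sum(vapply(jc, `[[`, numeric(1), "EI")),
      IE = sum(vapply(jc, `[[`, numeric(1), "IE")),
      ratio_mean = sr$mean, ratio_sd = sr$sd, stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, jx_rows), file.path(out, "splice_ratios.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 6: coverage + averaging -------------------------------------
  rpm <- lapply(names(segs), function(nm)
    normalize_rpm(build_coverage(segs[[nm]], genome,
                                 exclusion_classes = p$exclusion_classes,
                                 exclude_chroms = p$exclude_chroms,
                                 priority = p$class_priority, sample = nm)))
  names(rpm) <- names(segs)
  grp_tracks <- list()
  for (grp in unique(groups)) {
    members <- names(groups)[groups == grp]
    grp_tracks[[grp]] <- average_replicates(rpm[members])
    export_bedgraph(grp_tracks[[grp]], file.path(out, paste0(grp, ".rpm")))
  }

  # --- stage 7: enrichment ------------------------------------------------
  ref_grp <- unique(groups[roles == "reference"])
  prot_grps <- unique(groups[roles == "protein"])
  for (grp in prot_grps) {
    et <- enrichment_track(grp_tracks[[grp]], grp_tracks[[ref_grp]],
                           pseudocount = p$pseudocount)
    export_bedgraph(et, file.path(out, paste0(grp, ".enrichment")))
  }

  # --- stage 8: feature statistics ---------------------------------------
  stats_by_grp <- list()
  for (grp in c(prot_grps, ref_grp)) {
    members <- names(groups)[groups == grp]
    if (length(members) < 2) next
    st <- feature_stats(rpm[members], segs[members], genome,
                        cv_max = p$cv_max, rpkm_min = p$rpkm_min,
                        priority = p$class_priority)
    stats_by_grp[[grp]] <- st
    write.table(st, file.path(out, paste0(grp, ".feature_stats.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (ref_grp %in% names(stats_by_grp)) {
    for (grp in intersect(prot_grps, names(stats_by_grp))) {
      sc <- scatter_table(stats_by_grp[[grp]], stats_by_grp[[ref_grp]],
                          pseudocount = p$pseudocount)
      write.table(sc, file.path(out, paste0(grp, ".vs_reference.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 9: metagene --------------------------------------------------
  mrna <- mcols(genome$features)$feature_id[
    mcols(genome$features)$class == "mRNA"]
  profiles <- list()
  for (grp in c(prot_grps, ref_grp)) {
    for (anch in c("tss", "pa")) {
      win <- if (anch == "tss") p$tss_window else p$pa_window
      m <- anchored_matrix(grp_tracks[[grp]], genome, features = mrna,
                           anchor = anch, window = win, flank = p$flank)
      pr <- metagene_profile(m)
      profiles[[paste(grp, anch, sep = "_")]] <- pr
      write.table(pr, file.path(out, sprintf("metagene_%s_%s.tsv", grp, anch)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      heatmap_export(m, file.path(out, sprintf("heatmap_%s_%s.tsv", grp, anch)),
                     sort_key = "total")
    }
  }
  for (grp in prot_grps) {
    for (anch in c("tss", "pa")) {
      win <- if (anch == "tss") p$tss_window else p$pa_window
      pr <- relative_metagene(grp_tracks[[grp]], grp_tracks[[ref_grp]],
                              genome, features = mrna, anchor = anch,
                              window = win, pseudocount = p$pseudocount,
                              flank = p$flank)
      profiles[[paste(grp, anch, "rel", sep = "_")]] <- pr
      write.table(pr,
                  file.path(out, sprintf("metagene_%s_%s_rel.tsv", grp, anch)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$outputs <- sort(list.files(out))
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(report = report, genome = genome, truth = truth_all,
                 segments = segs, tracks = grp_tracks,
                 stats = stats_by_grp, profiles = profiles))
}
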