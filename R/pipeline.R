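#' Pipeline run configuration
#'
#' Bundles the synthetic-data configuration with every analysis-stage
#' parameter into one reproducible unit. A single top-level `rng_seed` is
#' fanned out deterministically to each stochastic stage, so a run is fully
#' determined by its configuration. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim a [sim_config()]; its `rng_seed` is overridden by `rng_seed`.
#' @param window_w,n_perm,fdr_alpha peak-calling parameters
#'   (see [call_peaks()]).
#' @param flank half-width of the positional nucleotide profile.
#' @param n_perm_proximity permutations for the seed-proximity test.
#' @param rng_seed top-level integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(rng_seed = rng_seed),
                       window_w = 15L, n_perm = 1000L, fdr_alpha = 0.05,
                       flank = 10L, n_perm_proximity = 500L,
                       rng_seed = 1L) {
  structure(list(sim = sim, window_w = as.integer(window_w),
                 n_perm = as.integer(n_perm), fdr_alpha = fdr_alpha,
                 flank = as.integer(flank),
                 n_perm_proximity = as.integer(n_perm_proximity),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # yaml drops names of atomic vectors; keep base_probs as a map
  x$sim$base_probs <- as.list(x$sim$base_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim
  sim_args$base_probs <- unlist(sim_args$base_probs)
  sim <- do.call(sim_config, sim_args)
  run_config(sim = sim, window_w = x$window_w, n_perm = x$n_perm,
             fdr_alpha = x$fdr_alpha, flank = x$flank,
             n_perm_proximity = x$n_perm_proximity, rng_seed = x$rng_seed)
}

#' Run the full synthetic iCLIP analysis pipeline
#'
#' Executes simulate -> demultiplex -> map -> crosslink events -> peaks ->
#' targets -> feature distribution -> 3'UTR length statistics -> k-mer
#' profiles and bound/unbound comparisons -> set-overlap enrichment ->
#' positional nucleotide profile (peak events) -> seed-proximity test, and,
#' because the simulation carries ground truth, parameter-recovery metrics
#' (target recall/precision, crosslink-position accuracy, true 3'UTR event
#' fraction). Deterministic given `config$rng_seed`.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, every intermediate artifact
#'   (FASTA, FASTQ, truth tables, CE BED, peaks, targets, profiles) and the
#'   JSON report are written there.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scfg <- config$sim
  scfg$rng_seed <- stage_seed(config$rng_seed, 0L)
  class(scfg) <- "sim_config"

  tr <- stage("simulate_transcriptome", simulate_transcriptome(scfg))
  rd <- stage("simulate_iclip_reads", simulate_iclip_reads(tr))

  spec <- barcode_spec(scfg$random_prefix_len, nchar(scfg$sample_code),
                       scfg$random_suffix_len)
  samples <- c(sample1 = scfg$sample_code)
  dm <- stage("demultiplex", demultiplex(rd$reads, spec, samples))
  mp <- stage("map_reads_exact", map_reads_exact(dm$reads, tr$sequences))
  ce <- stage("call_crosslink_events",
              suppressWarnings(call_crosslink_events(mp$placements)))

  peaks <- stage("call_peaks",
                 suppressWarnings(call_peaks(ce, tr$annotation,
                                             window_w = config$window_w,
                                             n_perm = config$n_perm,
                                             fdr_alpha = config$fdr_alpha,
                                             seed = stage_seed(config$rng_seed, 2L))))
  targets <- stage("derive_targets", derive_targets(peaks, tr$annotation, ce))
  feat <- stage("feature_distribution",
                feature_distribution(ce, tr$annotation, weight = "events"))
  utr_stats <- stage("utr_length_stats", utr_length_stats(targets))

  seed_site <- seed_site_7merA1(scfg$mirna_seq)
  panel <- c(polyU = "UUUUUUU", seed = seed_site)
  profiles <- stage("profile_utrs",
                    profile_utrs(tr$annotation, tr$sequences, panel))
  cmp_polyU <- stage("compare_bound_unbound polyU",
                     compare_bound_unbound(profiles, targets, "polyU"))
  cmp_seed <- stage("compare_bound_unbound seed",
                    compare_bound_unbound(profiles, targets, "seed"))

  bound_set <- targets$transcript_id[targets$bound]
  seed_prof <- profiles[profiles$kmer == "seed", ]
  mir_set <- seed_prof$transcript_id[seed_prof$count >= 1L]
  overlap <- stage("overlap_enrichment",
                   overlap_enrichment(bound_set, mir_set,
                                      nrow(targets)))

  # motif analysis at binding sites: events inside called peaks
  peak_ce <- ce[peak_member(ce, peaks), , drop = FALSE]
  profile <- if (nrow(peak_ce)) {
    stage("positional_profile",
          positional_profile(peak_ce, tr$sequences, flank = config$flank))
  } else NULL

  seed_pos <- stage("kmer_sites", kmer_sites(tr$annotation, tr$sequences,
                                             seed_site))
  # proximity is asked of binding sites, not of individual reads: use one
  # position per peak (the summit) so the test's unit is the binding site
  summit_ce <- if (nrow(peaks)) {
    data.frame(transcript_id = peaks$transcript_id, position = peaks$summit,
               strand = "+", sample = "pooled", unique_count = 1L,
               stringsAsFactors = FALSE)
  } else ce
  prox <- tryCatch(
    seed_proximity_bias(summit_ce, seed_pos,
                        tr$annotation, n_perm = config$n_perm_proximity,
                        seed = stage_seed(config$rng_seed, 3L)),
    error = function(e) list(median_abs_distance = NA_real_,
                             p_value = NA_real_, n_events = 0L,
                             note = conditionMessage(e)))

  # parameter recovery against the generator's ground truth
  tt <- tr$truth$transcripts
  truth_flag <- tt$is_rbp_target[match(targets$transcript_id,
                                       tt$transcript_id)]
  tp <- sum(targets$bound & truth_flag)
  recall <- if (sum(truth_flag)) tp / sum(truth_flag) else NA_real_
  precision <- if (sum(targets$bound)) tp / sum(targets$bound) else NA_real_
  ce_key <- paste(ce$transcript_id, ce$position)
  true_key <- paste(rd$true_ce$transcript_id, rd$true_ce$start)
  ce_accuracy <- if (nrow(ce)) mean(ce_key %in% true_key) else NA_real_
  true_feat <- feature_distribution(
    data.frame(transcript_id = rd$true_ce$transcript_id,
               position = rd$true_ce$start,
               unique_count = rd$true_ce$score),
    tr$annotation)

  report <- structure(list(
    config_hash = config_hash(unclass(config)),
    seed = config$rng_seed,
    reads = list(total = nrow(rd$reads),
                 demultiplexed = unname(dm$summary[1]),
                 undetermined = unname(dm$summary["undetermined"]),
                 mapped = unname(mp$summary["mapped"]),
                 multimapped = unname(mp$summary["multimapped"]),
                 unmapped = unname(mp$summary["unmapped"])),
    duplication = list(
      unique_molecules = nrow(rd$molecules),
      unique_events = sum(ce$unique_count),
      ratio = if (sum(ce$unique_count))
        unname(mp$summary["mapped"]) / sum(ce$unique_count) else NA_real_),
    ce = list(n_rows = nrow(ce), n_transcripts = length(unique(ce$transcript_id))),
    peaks = list(n_peaks = nrow(peaks),
                 n_bound = sum(targets$bound),
                 n_unbound = sum(!targets$bound)),
    feature_fractions = as.list(feat),
    utr_lengths = utr_stats,
    kmer_tests = list(polyU = cmp_polyU, seed = cmp_seed),
    overlap = overlap,
    positional_profile = if (!is.null(profile)) {
      list(central_u = unname(profile["U", as.character(0)]),
           flank = config$flank,
           n_events = attr(profile, "n_events"))
    } else NULL,
    proximity = prox,
    recovery = list(target_recall = recall, target_precision = precision,
                    n_true_targets = sum(truth_flag),
                    ce_position_accuracy = ce_accuracy,
                    utr3_fraction_reported = fraction_of(feat, "three_prime_utr"),
                    utr3_fraction_truth = fraction_of(true_feat, "three_prime_utr"))
  ), class = "run_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(tr$sequences, file.path(outdir, "transcripts.fa"))
    write_fastq(rd$reads, file.path(outdir, "reads.fastq"))
    write_tsv(tr$annotation, file.path(outdir, "annotation.tsv"))
    write_tsv(tr$truth$transcripts, file.path(outdir, "truth_transcripts.tsv"))
    write_tsv(tr$truth$sites, file.path(outdir, "truth_sites.tsv"))
    write_tsv(rd$true_ce, file.path(outdir, "true_ce.bed"))
    write_ce_bed(ce, file.path(outdir, "crosslink_events.bed"))
    write_tsv(peaks, file.path(outdir, "peaks.tsv"))
    write_tsv(targets, file.path(outdir, "targets.tsv"))
    write_tsv(profiles, file.path(outdir, "utr_kmer_profiles.tsv"))
    if (!is.null(profile)) {
      utils::write.table(profile, file.path(outdir, "positional_profile.tsv"),
                         sep = "\t", quote = FALSE)
    }
    write_run_config(config, file.path(outdir, "config.yaml"))
    write_run_report(report, file.path(outdir, "report.json"))
  }
  report
}

fraction_of <- function(v, nm) if (nm %in% names(v)) unname(v[nm]) else 0

# membership of CE rows in peak intervals
peak_member <- function(ce, peaks) {
  if (!nrow(peaks) || !nrow(ce)) return(rep(FALSE, nrow(ce)))
  out <- rep(FALSE, nrow(ce))
  for (tx in unique(peaks$transcript_id)) {
    pk <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    i <- which(ce$transcript_id == tx)
    if (!length(i)) next
    p <- ce$position[i]
    hit <- rep(FALSE, length(p))
    for (r in seq_len(nrow(pk))) {
      hit <- hit | (p >= pk$start[r] & p < pk$end[r])
    }
    out[i] <- hit
  }
  out
}

#' @rdname run_pipeline
#' @param report a `run_report`.
#' @param path JSON output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (config ", x$config_hash, ", seed ", x$seed, ")\n",
      "  reads: ", x$reads$total, " total, ", x$reads$mapped, " mapped\n",
      "  unique CEs: ", x$duplication$unique_events,
      " (duplication ratio ", round(x$duplication$ratio, 2), ")\n",
      "  peaks: ", x$peaks$n_peaks, "; bound transcripts: ",
      x$peaks$n_bound, "/", x$peaks$n_bound + x$peaks$n_unbound, "\n",
      "  3'UTR CE fraction: ",
      round(x$recovery$utr3_fraction_reported, 3), "\n",
      "  target recall ", round(x$recovery$target_recall, 3),
      ", precision ", round(x$recovery$target_precision, 3), "\n",
      sep = "")
  invisible(x)
}
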