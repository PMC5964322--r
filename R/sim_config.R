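#' Simulation configuration for the synthetic iCLIP experiment
#'
#' Bundles every tunable of the synthetic-data generator: transcriptome
#' composition, target fractions and their overlap, region-length
#' distributions, the uridine-rich motif model, the miRNA whose 7mer-A1 site
#' is co-planted, and the read/barcode/PCR model. Defaults describe a
#' doxycycline-inducible cell-line iCLIP experiment for a 3'UTR-specific,
#' U-rich-motif-binding protein: bound transcripts carry planted U-rich
#' stretches in long 3'UTRs (median ~1.99 kb versus ~0.72 kb for unbound
#' mRNAs), sequencing depth is PCR-amplified with mean duplication 3.5
#' (below 4 unique-copy average), and reads carry a 3+4+2 nt
#' random/sample/random barcode introduced at reverse transcription.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param fraction_rbp_targets fraction of transcripts designated RBP targets
#'   (these receive planted U-rich 3'UTR motifs).
#' @param fraction_mir_targets fraction of transcripts designated miRNA
#'   targets (these receive a planted 7mer-A1 seed site).
#' @param target_overlap_fraction fraction of RBP targets that are also miRNA
#'   targets.
#' @param fraction_lincRNA fraction of transcripts simulated as lincRNAs
#'   (noncoding exons + introns, no UTRs; never targets).
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,intron_meanlog,intron_sdlog
#'   log-normal parameters (nt) for 5'UTR, CDS and intron lengths.
#' @param utr3_meanlog_target,utr3_meanlog_background,utr3_sdlog log-normal
#'   3'UTR length parameters; the target/background split reproduces the
#'   longer 3'UTRs of bound transcripts.
#' @param intron_prob probability that a protein-coding transcript carries an
#'   intron inside its CDS.
#' @param motif_length_range integer range (nt) for planted U-rich site
#'   lengths.
#' @param motif_u_content per-base probability of U inside a planted site
#'   (must be >= 0.8 so sites are genuine U runs).
#' @param motif_sites_per_utr number of U-rich sites planted per target 3'UTR.
#' @param mirna_seq mature miRNA sequence (5'->3', RNA alphabet) whose
#'   7mer-A1 site is planted in miRNA-target 3'UTRs.
#' @param base_probs background base composition (named A/C/G/T or A/C/G/U
#'   probabilities; uniform by default).
#' @param expression_sdlog log-normal sd of per-transcript expression weights.
#' @param n_reads target total number of sequenced reads (FASTQ records,
#'   PCR duplicates included).
#' @param signal_fraction fraction of unique cDNA molecules that are signal
#'   (crosslinked inside a planted motif) rather than background.
#' @param read_length total read length including the barcode.
#' @param random_prefix_len,random_suffix_len lengths of the random barcode
#'   (UMI) positions flanking the sample code.
#' @param sample_code sample barcode (DNA/RNA string).
#' @param pcr_duplication_mean mean number of PCR copies per unique cDNA
#'   (>= 1; each molecule is emitted `1 + Poisson(mean - 1)` times).
#' @param rng_seed mandatory integer seed; all generator randomness derives
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_transcripts = 500L,
                       fraction_rbp_targets = 0.2,
                       fraction_mir_targets = 0.3,
                       target_overlap_fraction = 0.5,
                       fraction_lincRNA = 0.1,
                       utr5_meanlog = log(150), utr5_sdlog = 0.4,
                       cds_meanlog = log(1200), cds_sdlog = 0.35,
                       intron_meanlog = log(800), intron_sdlog = 0.6,
                       utr3_meanlog_target = log(1990),
                       utr3_meanlog_background = log(720),
                       utr3_sdlog = 0.6,
                       intron_prob = 0.8,
                       motif_length_range = c(10L, 20L),
                       motif_u_content = 0.9,
                       motif_sites_per_utr = 2L,
                       mirna_seq = "UCACAGUGAACCGGUCUCUUU",
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       expression_sdlog = 1,
                       n_reads = 200000L,
                       signal_fraction = 0.75,
                       read_length = 50L,
                       random_prefix_len = 3L,
                       random_suffix_len = 2L,
                       sample_code = "ACGT",
                       pcr_duplication_mean = 3.5,
                       rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) {
    stop("`rng_seed` is mandatory in sim_config()")
  }
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    fraction_rbp_targets = fraction_rbp_targets,
    fraction_mir_targets = fraction_mir_targets,
    target_overlap_fraction = target_overlap_fraction,
    fraction_lincRNA = fraction_lincRNA,
    utr5_meanlog = utr5_meanlog, utr5_sdlog = utr5_sdlog,
    cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
    intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
    utr3_meanlog_target = utr3_meanlog_target,
    utr3_meanlog_background = utr3_meanlog_background,
    utr3_sdlog = utr3_sdlog,
    intron_prob = intron_prob,
    motif_length_range = as.integer(motif_length_range),
    motif_u_content = motif_u_content,
    motif_sites_per_utr = as.integer(motif_sites_per_utr),
    mirna_seq = toupper(mirna_seq),
    base_probs = base_probs,
    expression_sdlog = expression_sdlog,
    n_reads = as.integer(n_reads),
    signal_fraction = signal_fraction,
    read_length = as.integer(read_length),
    random_prefix_len = as.integer(random_prefix_len),
    random_suffix_len = as.integer(random_suffix_len),
    sample_code = norm_ut(sample_code),
    pcr_duplication_mean = pcr_duplication_mean,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$fraction_rbp_targets, cfg$fraction_mir_targets,
          cfg$target_overlap_fraction, cfg$fraction_lincRNA,
          cfg$signal_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$n_transcripts < 1L) stop("n_transcripts must be positive")
  if (cfg$n_reads < 0L) stop("n_reads must be non-negative")
  if (cfg$read_length < 1L) stop("read_length must be positive")
  if (cfg$pcr_duplication_mean < 1) {
    stop("pcr_duplication_mean must be >= 1 (each molecule appears at least once)")
  }
  if (cfg$motif_u_content < 0.8 || cfg$motif_u_content > 1) {
    stop("motif_u_content must lie in [0.8, 1] (planted sites are U runs)")
  }
  if (length(cfg$motif_length_range) != 2L ||
      any(cfg$motif_length_range < 1L) || diff(cfg$motif_length_range) < 0L) {
    stop("motif_length_range must be an increasing positive integer pair")
  }
  if (nchar(cfg$mirna_seq) < 8L) stop("mirna_seq must be at least 8 nt")
  bp <- cfg$base_probs
  names(bp) <- norm_ut(names(bp))
  if (!setequal(names(bp), c("A", "C", "G", "T")) || abs(sum(bp) - 1) > 1e-9) {
    stop("base_probs must be named A/C/G/T (or U) and sum to 1")
  }
  # target bookkeeping must fit into the protein-coding compartment
  n <- cfg$n_transcripts
  n_cod <- n - round(cfg$fraction_lincRNA * n)
  n_rbp <- round(cfg$fraction_rbp_targets * n)
  n_mir <- round(cfg$fraction_mir_targets * n)
  n_ov <- round(cfg$target_overlap_fraction * n_rbp)
  if (n_ov > min(n_rbp, n_mir) || (n_rbp + n_mir - n_ov) > n_cod) {
    stop("infeasible target configuration: ", n_rbp, " RBP targets, ", n_mir,
         " miRNA targets and overlap ", n_ov, " do not fit into ", n_cod,
         " protein-coding transcripts")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts,",
      round(x$fraction_rbp_targets * x$n_transcripts), "RBP targets,",
      round(x$fraction_mir_targets * x$n_transcripts), "miRNA targets;",
      x$n_reads, "reads, PCR mean", x$pcr_duplication_mean,
      ", seed", x$rng_seed, "\n")
  invisible(x)
}
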