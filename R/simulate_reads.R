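#' Simulate multiplexed iCLIP reads under the cDNA truncation model
#'
#' Draws unique cDNA molecules, places their crosslink positions (signal
#' molecules uniformly within planted U-rich sites of RBP-target transcripts,
#' background molecules uniformly along transcripts weighted by expression),
#' truncates each cDNA so that its insert begins exactly one nucleotide 3' of
#' the crosslink, prepends the random/sample/random barcode, and PCR-amplifies
#' each molecule `1 + Poisson(pcr_duplication_mean - 1)` times. The target
#' total read count is `config$n_reads`; the number of unique molecules drawn
#' is `round(n_reads / pcr_duplication_mean)`.
#'
#' @param annotation,sequences,truth outputs of [simulate_transcriptome()]
#'   (or pass the `sim_transcriptome` object itself as `annotation`).
#' @param config the [sim_config()] used for the transcriptome.
#' @return list of class `sim_reads` with
#'   \describe{
#'     \item{reads}{data.frame `read_id`, `seq`, `qual` (constant quality).}
#'     \item{true_ce}{BED-like data.frame of every unique crosslink event:
#'       `transcript_id`, `start`, `end` (= start + 1), `name`, `score`
#'       (unique-molecule count), `strand` ("+", transcript space).}
#'     \item{molecules}{per-molecule truth: origin (signal/background), true
#'       crosslink position, UMI, PCR copy number, truncation flag.}
#'   }
#' @export
simulate_iclip_reads <- function(annotation, sequences = NULL, truth = NULL,
                                 config = NULL) {
  if (inherits(annotation, "sim_transcriptome")) {
    tr <- annotation
    annotation <- tr$annotation
    sequences <- sequences %||% tr$sequences
    truth <- truth %||% tr$truth
    config <- config %||% tr$config
  }
  stopifnot(inherits(config, "sim_config"))
  seqs <- as_seq_vector(sequences)
  tt <- truth$transcripts
  set.seed(stage_seed(config$rng_seed, 1L))

  barcode_len <- config$random_prefix_len + nchar(config$sample_code) +
    config$random_suffix_len
  insert_len <- config$read_length - barcode_len
  if (insert_len <= 0L) {
    stop("read_length (", config$read_length,
         ") must exceed the barcode length (", barcode_len, ")")
  }

  empty <- list(
    reads = data.frame(read_id = character(0), seq = character(0),
                       qual = character(0), stringsAsFactors = FALSE),
    true_ce = data.frame(transcript_id = character(0), start = integer(0),
                         end = integer(0), name = character(0),
                         score = integer(0), strand = character(0),
                         stringsAsFactors = FALSE),
    molecules = data.frame()
  )
  n_mol <- round(config$n_reads / config$pcr_duplication_mean)
  if (config$n_reads == 0L || n_mol == 0L) {
    return(structure(empty, class = "sim_reads"))
  }

  motif <- truth$sites[truth$sites$type == "motif", , drop = FALSE]
  n_sig <- sum(stats::runif(n_mol) < config$signal_fraction)
  if (n_sig > 0L && nrow(motif) == 0L) {
    stop("signal_fraction > 0 but no planted motif sites exist")
  }
  n_bg <- n_mol - n_sig
  tx_len <- tt$length
  names(tx_len) <- tt$transcript_id

  # signal: choose a planted site with probability proportional to its
  # transcript's expression weight split evenly across the transcript's sites
  if (n_sig > 0L) {
    w_tx <- tt$expression_weight[match(motif$transcript_id, tt$transcript_id)]
    w_site <- w_tx / as.vector(table(motif$transcript_id)[motif$transcript_id])
    row_s <- sample.int(nrow(motif), n_sig, replace = TRUE, prob = w_site)
    site_len <- motif$end[row_s] - motif$start[row_s]
    pos_s <- motif$start[row_s] + floor(stats::runif(n_sig) * site_len)
    tx_s <- motif$transcript_id[row_s]
  } else {
    pos_s <- integer(0); tx_s <- character(0)
  }
  if (n_bg > 0L) {
    bi <- sample.int(nrow(tt), n_bg, replace = TRUE,
                     prob = tt$expression_weight)
    pos_b <- floor(stats::runif(n_bg) * (tt$length[bi] - 1L))
    tx_b <- tt$transcript_id[bi]
  } else {
    pos_b <- integer(0); tx_b <- character(0)
  }

  tx <- c(tx_s, tx_b)
  pos <- as.integer(c(pos_s, pos_b))
  origin <- rep(c("signal", "background"), c(n_sig, n_bg))

  # truncation model: the insert starts one nt 3' of the crosslink
  L <- tx_len[tx]
  ins_start <- pos + 1L
  ins_end <- pmin(ins_start + insert_len, L)
  truncated <- (ins_start + insert_len) > L
  insert <- substr(seqs[tx], ins_start + 1L, ins_end)

  umi_chars <- config$random_prefix_len + config$random_suffix_len
  umi_mat <- matrix(sample(c("A", "C", "G", "T"), n_mol * umi_chars,
                           replace = TRUE), nrow = n_mol)
  umi <- apply(umi_mat, 1, paste, collapse = "")
  prefix <- substr(umi, 1L, config$random_prefix_len)
  suffix <- substr(umi, config$random_prefix_len + 1L, umi_chars)

  copies <- 1L + stats::rpois(n_mol, config$pcr_duplication_mean - 1)
  molecules <- data.frame(
    molecule_id = sprintf("mol%07d", seq_len(n_mol)),
    transcript_id = tx, position = pos, origin = origin, umi = umi,
    n_copies = copies, truncated = truncated, stringsAsFactors = FALSE
  )

  rep_i <- rep(seq_len(n_mol), copies)
  read_seq <- paste0(prefix[rep_i], config$sample_code, suffix[rep_i],
                     insert[rep_i])
  reads <- data.frame(
    read_id = sprintf("%s_d%02d", molecules$molecule_id[rep_i],
                      sequence(copies)),
    seq = read_seq,
    qual = strrep("I", nchar(read_seq)),
    stringsAsFactors = FALSE
  )

  # unique crosslink events: distinct (transcript, position, UMI) molecules
  uniq <- !duplicated(paste(tx, pos, umi, sep = "\r"))
  key <- paste(tx[uniq], pos[uniq], sep = "\r")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  true_ce <- data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
  true_ce$end <- true_ce$start + 1L
  true_ce$name <- "true_CE"
  true_ce$score <- as.integer(cnt)
  true_ce$strand <- "+"
  true_ce <- true_ce[order(true_ce$transcript_id, true_ce$start), ,
                     drop = FALSE]
  rownames(true_ce) <- NULL

  structure(list(reads = reads, true_ce = true_ce, molecules = molecules),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "reads from", nrow(x$molecules),
      "unique molecules;", nrow(x$true_ce), "true crosslink positions\n")
  invisible(x)
}
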