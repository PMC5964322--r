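#' Simulate a transcriptome with planted binding motifs and seed sites
#'
#' Generates unspliced-coordinate transcript models (each transcript is one
#' sequence that still contains its introns, so intronic crosslink events
#' exist without a genome model), i.i.d. background sequence, and ground
#' truth. Designated RBP targets carry uridine-rich stretches planted in
#' their 3'UTRs; designated miRNA targets carry the 7mer-A1 site of the
#' configured miRNA. The overlap between the two target sets is controlled
#' by `target_overlap_fraction`. Everything is deterministic given
#' `config$rng_seed`.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `sim_transcriptome` with elements
#'   \describe{
#'     \item{annotation}{data.frame of region intervals: `transcript_id`,
#'       `gene_id`, `biotype`, `strand`, `start`, `end` (0-based half-open,
#'       transcript coordinates), `label` (five_prime_utr / cds /
#'       three_prime_utr / intron / noncoding_exon). Intervals tile
#'       `[0, length)` exactly.}
#'     \item{sequences}{named character vector of transcript sequences
#'       (DNA alphabet; U written as T).}
#'     \item{truth}{list with `transcripts` (per-transcript flags,
#'       expression weights) and `sites` (planted intervals, 0-based
#'       half-open, `type` motif/seed).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_transcripts

  n_linc <- round(config$fraction_lincRNA * n)
  biotype <- sample(rep(c("protein_coding", "lincRNA"), c(n - n_linc, n_linc)))
  tx_id <- sprintf("tx%05d", seq_len(n))
  gene_id <- sprintf("gene%05d", seq_len(n))

  n_rbp <- round(config$fraction_rbp_targets * n)
  n_mir <- round(config$fraction_mir_targets * n)
  n_ov <- round(config$target_overlap_fraction * n_rbp)
  cod <- which(biotype == "protein_coding")
  rbp_idx <- if (n_rbp > 0L) sort(sample(cod, n_rbp)) else integer(0)
  ov_idx <- if (n_ov > 0L) sort(sample(rbp_idx, n_ov)) else integer(0)
  mir_extra <- n_mir - n_ov
  pool <- setdiff(cod, rbp_idx)
  mir_idx <- sort(c(ov_idx, if (mir_extra > 0L) sample(pool, mir_extra)))

  is_rbp <- seq_len(n) %in% rbp_idx
  is_mir <- seq_len(n) %in% mir_idx

  rlen <- function(meanlog, sdlog, lo) pmax(lo, round(stats::rlnorm(n, meanlog, sdlog)))
  site_max <- max(config$motif_length_range)
  # minimum 3'UTR able to host all planted sites plus spacers and end margin
  utr3_min <- config$motif_sites_per_utr * (site_max + 5L) + 7L + 20L

  utr5 <- rlen(config$utr5_meanlog, config$utr5_sdlog, 20L)
  cds <- rlen(config$cds_meanlog, config$cds_sdlog, 150L)
  intr <- rlen(config$intron_meanlog, config$intron_sdlog, 60L)
  has_intron <- stats::runif(n) < config$intron_prob
  utr3_meanlog <- ifelse(is_rbp, config$utr3_meanlog_target,
                         config$utr3_meanlog_background)
  utr3 <- pmax(1L, round(stats::rlnorm(n, utr3_meanlog, config$utr3_sdlog)))
  # redraw undersized 3'UTRs for transcripts that must host planted sites
  need <- is_rbp | is_mir
  for (attempt in seq_len(50L)) {
    short <- which(need & utr3 < utr3_min)
    if (!length(short)) break
    utr3[short] <- pmax(1L, round(stats::rlnorm(length(short),
                                                utr3_meanlog[short],
                                                config$utr3_sdlog)))
  }
  if (any(need & utr3 < utr3_min)) {
    stop("could not draw a 3'UTR long enough to host planted sites ",
         "after 50 redraws; raise utr3 length parameters")
  }

  ann <- vector("list", n)
  seqs <- character(n)
  bp <- config$base_probs
  names(bp) <- norm_ut(names(bp))
  bp <- bp[c("A", "C", "G", "T")]

  for (i in seq_len(n)) {
    if (biotype[i] == "protein_coding") {
      if (has_intron[i]) {
        c1 <- cds[i] %/% 2L
        regions <- data.frame(
          label = c("five_prime_utr", "cds", "intron", "cds", "three_prime_utr"),
          len = c(utr5[i], c1, intr[i], cds[i] - c1, utr3[i])
        )
      } else {
        regions <- data.frame(
          label = c("five_prime_utr", "cds", "three_prime_utr"),
          len = c(utr5[i], cds[i], utr3[i])
        )
      }
    } else {
      e1 <- max(60L, round(cds[i] / 2))
      regions <- data.frame(
        label = c("noncoding_exon", "intron", "noncoding_exon"),
        len = c(e1, intr[i], max(60L, utr3[i]))
      )
    }
    ends <- as.integer(cumsum(regions$len))
    ann[[i]] <- data.frame(
      transcript_id = tx_id[i], gene_id = gene_id[i], biotype = biotype[i],
      strand = "+", start = c(0L, utils::head(ends, -1L)), end = ends,
      label = regions$label, stringsAsFactors = FALSE
    )
    seqs[i] <- paste(random_bases(ends[length(ends)], bp), collapse = "")
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  names(seqs) <- tx_id

  tt <- data.frame(
    transcript_id = tx_id, gene_id = gene_id, biotype = biotype,
    length = vapply(ann, function(a) max(a$end), integer(1)),
    utr3_length = ifelse(biotype == "protein_coding", utr3, 0L),
    is_rbp_target = is_rbp, is_mir_target = is_mir,
    expression_weight = stats::rlnorm(n, 0, config$expression_sdlog),
    stringsAsFactors = FALSE
  )

  # plant sites inside 3'UTRs; keep a margin from the transcript 3' end so a
  # crosslink inside a site always leaves a non-empty cDNA insert
  planted <- list()
  seed_site_dna <- norm_ut(seed_site_7merA1(config$mirna_seq))
  end_margin <- 10L
  for (i in which(is_rbp | is_mir)) {
    L <- tt$length[i]
    u3_start <- L - utr3[i]
    u3_end <- L - end_margin
    taken <- matrix(numeric(0), ncol = 2)
    place <- function(len) {
      for (try in seq_len(200L)) {
        s <- u3_start + sample.int(u3_end - u3_start - len + 1L, 1L) - 1L
        e <- s + len
        if (!nrow(taken) || all(e + 2L <= taken[, 1] | s >= taken[, 2] + 2L)) {
          return(c(s, e))
        }
      }
      stop("failed to place a site in the 3'UTR of ", tx_id[i],
           " after 200 attempts")
    }
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    if (is_rbp[i]) {
      for (k in seq_len(config$motif_sites_per_utr)) {
        len <- sample(seq(config$motif_length_range[1],
                          config$motif_length_range[2]), 1L)
        iv <- place(len)
        taken <- rbind(taken, iv)
        is_u <- stats::runif(len) < config$motif_u_content
        ch[(iv[1] + 1):iv[2]] <- ifelse(is_u, "T",
                                        sample(c("A", "C", "G"), len, TRUE))
        planted[[length(planted) + 1L]] <- data.frame(
          transcript_id = tx_id[i], start = iv[1], end = iv[2],
          type = "motif", stringsAsFactors = FALSE
        )
      }
    }
    if (is_mir[i]) {
      iv <- place(7L)
      taken <- rbind(taken, iv)
      ch[(iv[1] + 1):iv[2]] <- strsplit(seed_site_dna, "", fixed = TRUE)[[1]]
      planted[[length(planted) + 1L]] <- data.frame(
        transcript_id = tx_id[i], start = iv[1], end = iv[2],
        type = "seed", stringsAsFactors = FALSE
      )
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  sites <- if (length(planted)) do.call(rbind, planted) else
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), type = character(0))
  rownames(sites) <- NULL

  structure(list(annotation = annotation, sequences = seqs,
                 truth = list(transcripts = tt, sites = sites),
                 config = config),
            class = "sim_transcriptome")
}

#' Per-transcript summary of a region annotation
#'
#' Collapses a region-interval annotation into one row per transcript with
#' its biotype, total (unspliced) length and summed 3'UTR length.
#'
#' @param annotation region annotation data.frame as produced by
#'   [simulate_transcriptome()].
#' @return data.frame with `transcript_id`, `gene_id`, `biotype`, `length`,
#'   `utr3_length`.
#' @export
transcript_table <- function(annotation) {
  sp <- split(annotation, annotation$transcript_id)
  out <- do.call(rbind, lapply(sp, function(a) {
    data.frame(
      transcript_id = a$transcript_id[1], gene_id = a$gene_id[1],
      biotype = a$biotype[1], length = max(a$end),
      utr3_length = sum((a$end - a$start)[a$label == "three_prime_utr"]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$transcript_id), , drop = FALSE]
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  tt <- x$truth$transcripts
  cat("sim_transcriptome:", nrow(tt), "transcripts (",
      sum(tt$biotype == "lincRNA"), "lincRNA ),",
      sum(tt$is_rbp_target), "RBP targets,",
      sum(tt$is_mir_target), "miRNA targets,",
      nrow(x$truth$sites), "planted sites\n")
  invisible(x)
}
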