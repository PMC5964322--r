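#' Barcode layout specification
#'
#' Describes the read 5' barcode introduced during reverse transcription:
#' `random_prefix_len` random nucleotides, a fixed-length sample code, then
#' `random_suffix_len` random nucleotides. The random positions jointly form
#' the unique molecular identifier (UMI) used to collapse PCR duplicates.
#'
#' @param random_prefix_len,random_suffix_len number of random nt before and
#'   after the sample code.
#' @param code_len sample-code length.
#' @return a `barcode_spec` list.
#' @export
barcode_spec <- function(random_prefix_len = 3L, code_len = 4L,
                         random_suffix_len = 2L) {
  stopifnot(random_prefix_len >= 0L, random_suffix_len >= 0L, code_len >= 1L,
            random_prefix_len + random_suffix_len >= 1L)
  structure(list(random_prefix_len = as.integer(random_prefix_len),
                 code_len = as.integer(code_len),
                 random_suffix_len = as.integer(random_suffix_len)),
            class = "barcode_spec")
}

#' Demultiplex iCLIP reads by sample barcode
#'
#' Splits raw reads into per-sample streams by exact (0-mismatch) match of
#' the sample code, strips the barcode, and records the UMI (concatenated
#' random prefix and suffix). Reads whose code matches no configured sample,
#' or that are too short to contain an insert, are counted under
#' "undetermined".
#'
#' @param reads data.frame with `read_id`, `seq` (and optionally `qual`), or
#'   a FASTQ path.
#' @param spec a [barcode_spec()].
#' @param samples named character vector `c(sample_name = code, ...)`.
#' @return list with `reads` (data.frame `read_id`, `sample`, `umi`,
#'   `insert`) and `summary` (named integer counts per sample plus
#'   `undetermined`).
#' @export
demultiplex <- function(reads, spec, samples) {
  stopifnot(inherits(spec, "barcode_spec"))
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  samples <- vapply(samples, norm_ut, character(1))
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("`samples` must be a named vector: c(sample_name = code)")
  }
  if (anyDuplicated(samples)) {
    stop("two configured samples share a barcode code: ",
         paste(samples[duplicated(samples)], collapse = ", "))
  }
  if (any(nchar(samples) != spec$code_len)) {
    stop("all sample codes must have length ", spec$code_len)
  }

  barcode_len <- spec$random_prefix_len + spec$code_len + spec$random_suffix_len
  sq <- norm_ut(reads$seq)
  long_enough <- nchar(sq) > barcode_len
  code <- substr(sq, spec$random_prefix_len + 1L,
                 spec$random_prefix_len + spec$code_len)
  hit <- match(code, samples)
  ok <- long_enough & !is.na(hit)

  umi <- paste0(substr(sq, 1L, spec$random_prefix_len),
                substr(sq, spec$random_prefix_len + spec$code_len + 1L,
                       barcode_len))
  out <- data.frame(
    read_id = reads$read_id[ok],
    sample = names(samples)[hit[ok]],
    umi = umi[ok],
    insert = substr(sq[ok], barcode_len + 1L, nchar(sq[ok])),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(out$sample, levels = names(samples)))
  summary <- c(as.integer(counts), sum(!ok))
  names(summary) <- c(names(samples), "undetermined")
  list(reads = out, summary = summary)
}

#' Place reads on transcripts by unique exact match
#'
#' A deliberately simple stand-in for a read aligner, adequate for
#' error-free reads: each insert is placed only if it occurs as a substring
#' of exactly one transcript at exactly one position. Multi-mapping inserts
#' and inserts with no match are discarded and counted.
#'
#' @param reads demultiplexed reads (`$reads` element of [demultiplex()] or
#'   any data.frame with `read_id`, `sample`, `umi`, `insert`).
#' @param sequences named character vector or DNAStringSet of transcript
#'   sequences.
#' @return list with `placements` (data.frame `read_id`, `sample`, `umi`,
#'   `transcript_id`, `start`, `end` 0-based half-open, `strand`) and
#'   `summary` (counts: mapped, multimapped, unmapped).
#' @export
map_reads_exact <- function(reads, sequences) {
  if (!length(sequences)) stop("empty transcript database")
  seqs <- as_seq_vector(sequences)
  ins <- norm_ut(reads$insert)

  widths <- nchar(seqs)
  # concatenate transcripts with single-N separators: N never matches an
  # A/C/G/T pattern base, so no placement can span a boundary
  subject <- Biostrings::DNAString(paste(seqs, collapse = "N"))
  offset1 <- cumsum(c(1L, utils::head(widths + 1L, -1L)))  # 1-based tx starts

  uq <- unique(ins)
  clean <- !grepl("[^ACGT]", uq)
  n_hits <- integer(length(uq))
  hit_start <- rep(NA_integer_, length(uq))
  for (w in unique(nchar(uq[clean]))) {
    idx <- which(clean & nchar(uq) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uq[idx]))
    m <- Biostrings::matchPDict(pd, subject)
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    n_hits[idx] <- cnt
    one <- cnt == 1L
    hit_start[idx[one]] <- unlist(st[one], use.names = FALSE)
  }

  j <- match(ins, uq)
  cnt_r <- n_hits[j]
  keep <- cnt_r == 1L
  g <- hit_start[j[keep]]
  tx_i <- findInterval(g, offset1)
  start0 <- g - offset1[tx_i]  # 0-based within transcript

  placements <- data.frame(
    read_id = reads$read_id[keep], sample = reads$sample[keep],
    umi = reads$umi[keep], transcript_id = names(seqs)[tx_i],
    start = start0, end = start0 + nchar(ins[keep]),
    strand = rep("+", sum(keep)), stringsAsFactors = FALSE
  )
  list(placements = placements,
       summary = c(mapped = sum(keep), multimapped = sum(cnt_r > 1L),
                   unmapped = sum(cnt_r == 0L)))
}

#' Call crosslink events from read placements
#'
#' Applies the iCLIP truncation model: the protein-RNA crosslink sits one
#' nucleotide 5' of the cDNA insert start, so the event position is
#' `start - 1`. Reads with identical (transcript, position, sample, UMI) are
#' PCR copies of one molecule and collapse to a single unique event;
#' `unique_count` is the number of distinct UMIs observed per
#' (transcript, position, sample). Reads mapping at transcript start (the
#' crosslink would fall at position -1) are dropped with a warning.
#'
#' @param placements data.frame from [map_reads_exact()] (`$placements`), or
#'   any table with `transcript_id`, `start`, `sample`, `umi`.
#' @return crosslink-event table: data.frame `transcript_id`, `position`
#'   (0-based), `strand`, `sample`, `unique_count`, sorted by transcript and
#'   position. The number of dropped transcript-start reads is attached as
#'   attribute `n_dropped_start`.
#' @export
call_crosslink_events <- function(placements) {
  if (is.list(placements) && !is.data.frame(placements) &&
      !is.null(placements$placements)) {
    placements <- placements$placements
  }
  at_start <- placements$start == 0L
  n_drop <- sum(at_start)
  if (n_drop > 0L) {
    warning(n_drop, " read(s) map at transcript start; crosslink position ",
            "-1 is undefined and these reads were dropped")
    placements <- placements[!at_start, , drop = FALSE]
  }
  if (!nrow(placements)) {
    out <- data.frame(transcript_id = character(0), position = integer(0),
                      strand = character(0), sample = character(0),
                      unique_count = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped_start") <- n_drop
    return(out)
  }
  pos <- placements$start - 1L
  mol_key <- paste(placements$transcript_id, pos, placements$sample,
                   placements$umi, sep = "\r")
  first <- !duplicated(mol_key)
  ev_key <- paste(placements$transcript_id, pos, placements$sample,
                  sep = "\r")[first]
  cnt <- table(ev_key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    position = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = "+",
    sample = vapply(parts, `[`, character(1), 3L),
    unique_count = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$transcript_id, out$position, out$sample), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_start") <- n_drop
  out
}
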