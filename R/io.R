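#' Read and write the pipeline's plain-text interchange formats
#'
#' Thin wrappers around Biostrings for FASTA/FASTQ and base R for the
#' BED6-style crosslink-event tables. Sequences are stored on disk in DNA
#' alphabet (U written as T); coordinates in BED output are 0-based
#' half-open with strand fixed to "+" (transcript space).
#'
#' @param sequences named character vector (or DNAStringSet) of sequences.
#' @param path file path.
#' @name clip_io
NULL

#' @rdname clip_io
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(as_seq_vector(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname clip_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x)
}

#' @rdname clip_io
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname clip_io
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", path)
  i <- seq(1L, length(lines), by = 4L)
  data.frame(read_id = sub("^@", "", lines[i]),
             seq = toupper(lines[i + 1L]),
             qual = lines[i + 3L], stringsAsFactors = FALSE)
}

#' @rdname clip_io
#' @param ce crosslink-event table (`transcript_id`, `position`, `strand`,
#'   `sample`, `unique_count`).
#' @export
write_ce_bed <- function(ce, path) {
  bed <- data.frame(chrom = ce$transcript_id, start = ce$position,
                    end = ce$position + 1L,
                    name = if ("sample" %in% names(ce)) ce$sample else "CE",
                    score = ce$unique_count, strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname clip_io
#' @export
read_ce_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           stringsAsFactors = FALSE)
  data.frame(transcript_id = bed$chrom, position = bed$start,
             strand = bed$strand, sample = bed$name,
             unique_count = bed$score, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
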