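# Shared fixtures, built in code at test time.

small_sim <- function(seed = 11, n_reads = 20000L, ...) {
  sim_config(n_transcripts = 60L, n_reads = n_reads, rng_seed = seed, ...)
}

# A tiny annotation with one protein-coding transcript (5'UTR 0-100,
# CDS 100-400, intron 400-600, CDS 600-900, 3'UTR 900-1500) and one lincRNA
# (exon 0-200, intron 200-500, exon 500-800).
toy_annotation <- function() {
  rbind(
    data.frame(transcript_id = "txA", gene_id = "gA",
               biotype = "protein_coding", strand = "+",
               start = c(0L, 100L, 400L, 600L, 900L),
               end = c(100L, 400L, 600L, 900L, 1500L),
               label = c("five_prime_utr", "cds", "intron", "cds",
                         "three_prime_utr"),
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "txB", gene_id = "gB", biotype = "lincRNA",
               strand = "+", start = c(0L, 200L, 500L),
               end = c(200L, 500L, 800L),
               label = c("noncoding_exon", "intron", "noncoding_exon"),
               stringsAsFactors = FALSE)
  )
}

toy_sequences <- function(seed = 3) {
  set.seed(seed)
  c(txA = paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = ""),
    txB = paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""))
}

ce_row <- function(tx, pos, count = 1L, sample = "s1") {
  n <- length(pos)
  data.frame(transcript_id = rep_len(tx, n), position = as.integer(pos),
             strand = rep_len("+", n), sample = rep_len(sample, n),
             unique_count = rep_len(as.integer(count), n),
             stringsAsFactors = FALSE)
}

# straight radial dendrite in the XY plane: nodes every `step` um out to
# `len` um along direction `ang`, attached to a soma at the origin
radial_neuron <- function(len, ang = 0, step = 5, z = 0) {
  k <- ceiling(len / step)
  d <- pmin(seq_len(k) * step, len)
  as_neuron_trace(data.frame(
    id = c(1L, seq_len(k) + 1L), type = c(1L, rep(3L, k)),
    x = c(0, d * cos(ang)), y = c(0, d * sin(ang)),
    z = c(0, rep(z, k)), radius = 0.5,
    parent = c(-1L, 1L, seq_len(k - 1L) + 1L)
  ))
}
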