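# Internal helpers shared across modules.

# Uppercase and write RNA as DNA (U -> T); all matching happens in DNA space.
norm_ut <- function(x) chartr("Uu", "Tt", toupper(x))

# Display convention for sequence output: T -> U.
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_bases <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Deterministic per-stage seed fan-out from one top-level seed; keeps every
# stage's RNG stream independent while staying inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 104729 * as.double(stage)) %% 2147483647)
}

# Tiny FNV-1a string hash (hex) used to fingerprint configurations in reports.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_seq_vector <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences)) {
    out <- norm_ut(sequences)
  } else {
    stop("`sequences` must be a named character vector or a DNAStringSet")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("all sequences must be named by transcript id")
  }
  out
}
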