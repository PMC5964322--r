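#' 7mer-A1 seed-match site of a mature miRNA
#'
#' Returns the canonical 7mer-A1 target site (TargetScan convention): the
#' reverse complement of miRNA positions 2-7 followed by an adenosine
#' opposite miRNA position 1. Output is 5'->3' on the target strand in RNA
#' alphabet.
#'
#' @param mature_seq mature miRNA sequence, 5'->3', at least 8 nt.
#' @return 7-nt site string (RNA alphabet).
#' @examples
#' seed_site_7merA1("UCACAGUGAACCGGUCUCUUU")  # "ACUGUGA"
#' @export
seed_site_7merA1 <- function(mature_seq) {
  s <- norm_ut(mature_seq)
  if (nchar(s) < 8L) {
    stop("mature miRNA sequence must be at least 8 nt (positions 1-8)")
  }
  if (grepl("[^ACGT]", s)) stop("mature_seq contains non-A/C/G/U characters")
  core <- substr(s, 2L, 7L)
  to_rna(paste0(revcomp_dna(core), "A"))
}

#' Count k-mer occurrences in a sequence
#'
#' Counts occurrences of `kmer` in `seq` after U/T normalization.
#' Overlapping occurrences are counted by default (e.g. UUUUUUU occurs three
#' times in a run of nine U).
#'
#' @param seq character vector of nucleotide sequences.
#' @param kmer the k-mer to count (RNA or DNA alphabet).
#' @param overlapping count overlapping matches (default) or disjoint
#'   left-to-right matches.
#' @return integer vector of counts; 0 when the k-mer is longer than the
#'   sequence.
#' @export
count_kmer <- function(seq, kmer, overlapping = TRUE) {
  stopifnot(nchar(kmer) >= 1L)
  km <- norm_ut(kmer)
  sq <- norm_ut(seq)
  pat <- if (overlapping) paste0("(?=", km, ")") else km
  vapply(sq, function(s) {
    if (nchar(s) < nchar(km) || nchar(s) == 0L) return(0L)
    m <- gregexpr(pat, s, perl = overlapping, fixed = !overlapping)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

# 3'UTR sequence of each transcript: concatenation of three_prime_utr
# intervals in transcript order, plus a map back to transcript coordinates.
utr3_sequences <- function(annotation, sequences, with_map = FALSE) {
  seqs <- as_seq_vector(sequences)
  tt <- transcript_table(annotation)
  missing <- setdiff(tt$transcript_id, names(seqs))
  if (length(missing)) {
    stop("transcript missing from the sequence set: ", missing[1])
  }
  ann_sp <- split(annotation, annotation$transcript_id)
  out <- lapply(tt$transcript_id, function(tx) {
    a <- ann_sp[[tx]]
    a <- a[a$label == "three_prime_utr", , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (!nrow(a)) {
      return(list(seq = "", map = integer(0)))
    }
    pieces <- substr(rep(seqs[tx], nrow(a)), a$start + 1L, a$end)
    map <- unlist(mapply(function(s, e) seq.int(s, e - 1L), a$start, a$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    list(seq = paste(pieces, collapse = ""), map = map)
  })
  names(out) <- tt$transcript_id
  if (with_map) out else vapply(out, `[[`, character(1), "seq")
}

#' Per-transcript 3'UTR k-mer counts and densities
#'
#' Counts overlapping occurrences of each panel k-mer in every transcript's
#' 3'UTR (the concatenation of its three_prime_utr intervals) and normalizes
#' per kilobase of 3'UTR. Transcripts without a 3'UTR get count 0 and
#' density 0.
#'
#' @param annotation region annotation.
#' @param sequences transcript sequences (named vector or DNAStringSet).
#' @param kmers named character vector of k-mers (names label the panel;
#'   unnamed k-mers are labelled by their own sequence). The poly-U 7mer is
#'   written `"UUUUUUU"`.
#' @param overlapping passed to [count_kmer()].
#' @return data.frame `transcript_id`, `utr3_length`, `kmer`, `count`,
#'   `density` (per kb), one row per transcript per k-mer.
#' @export
profile_utrs <- function(annotation, sequences, kmers = c(polyU = "UUUUUUU"),
                         overlapping = TRUE) {
  if (is.null(names(kmers))) names(kmers) <- kmers
  names(kmers)[names(kmers) == ""] <- kmers[names(kmers) == ""]
  utr <- utr3_sequences(annotation, sequences)
  len <- nchar(utr)
  out <- do.call(rbind, lapply(names(kmers), function(nm) {
    cnt <- count_kmer(utr, kmers[[nm]], overlapping = overlapping)
    data.frame(transcript_id = names(utr), utr3_length = as.integer(len),
               kmer = nm, count = cnt,
               density = ifelse(len > 0L, cnt / (len / 1000), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value from the Student-t distribution.
#'
#' @param x,y numeric vectors of length >= 2.
#' @return list `statistic` (t), `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples must have at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    stop("both samples have zero variance; Welch degrees of freedom undefined")
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       mean_x = mean(x), mean_y = mean(y))
}

#' Compare a k-mer between bound and unbound 3'UTRs
#'
#' Tests the per-3'UTR occurrence count and the per-kilobase density of one
#' panel k-mer between bound and unbound transcripts with Welch's t-test.
#' The two scales answer different questions: raw counts confound motif
#' enrichment with 3'UTR length; densities do not.
#'
#' @param profiles k-mer profile table from [profile_utrs()].
#' @param targets target table from [derive_targets()] (the bound/unbound
#'   partition of the profile universe).
#' @param kmer panel label of the k-mer to compare.
#' @return list with `kmer`, group sizes, and `count` / `density` sublists
#'   (`mean_bound`, `mean_unbound`, `statistic`, `df`, `p_value`).
#' @export
compare_bound_unbound <- function(profiles, targets, kmer) {
  d <- profiles[profiles$kmer == kmer, , drop = FALSE]
  if (!nrow(d)) stop("k-mer ", kmer, " not present in the profile table")
  j <- match(d$transcript_id, targets$transcript_id)
  if (anyNA(j)) {
    stop("profile transcripts missing from the target table: ",
         d$transcript_id[which(is.na(j))[1]])
  }
  bound <- targets$bound[j]
  if (sum(bound) < 2L || sum(!bound) < 2L) {
    stop("both groups need at least 2 transcripts")
  }
  one <- function(v) {
    w <- welch_t_test(v[bound], v[!bound])
    list(mean_bound = w$mean_x, mean_unbound = w$mean_y,
         statistic = w$statistic, df = w$df, p_value = w$p_value)
  }
  list(kmer = kmer, n_bound = sum(bound), n_unbound = sum(!bound),
       count = one(d$count), density = one(d$density))
}

#' Hypergeometric set-overlap enrichment
#'
#' Exact upper-tail probability that two sets drawn from a common universe
#' share at least the observed number of members, with the fold enrichment
#' over the expected overlap `|A|*|B|/N`.
#'
#' @param set_a,set_b character vectors of member ids (duplicates ignored).
#' @param universe_size size N of the common universe.
#' @return list `overlap`, `size_a`, `size_b`, `universe`, `expected`,
#'   `fold`, `p_value` (P[X >= overlap]).
#' @export
overlap_enrichment <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  N <- as.integer(universe_size)
  if (N < length(union(a, b))) {
    stop("universe_size (", N, ") smaller than |A union B| (",
         length(union(a, b)), ")")
  }
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  p <- stats::phyper(k - 1L, length(a), N - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, size_a = length(a), size_b = length(b), universe = N,
       expected = expected,
       fold = if (expected > 0) k / expected else NaN,
       p_value = p)
}

#' Positional nucleotide profile around crosslink sites
#'
#' Frequency of A/C/G/U at each offset within +/- `flank` nt of the
#' crosslinked nucleotide, weighted by unique-event counts. Windows that do
#' not fit inside their transcript are skipped and counted.
#'
#' @param ce crosslink-event table.
#' @param sequences transcript sequences.
#' @param flank window half-width (nt, >= 1).
#' @return 4 x (2*flank+1) matrix (rows A, C, G, U; columns -flank..flank);
#'   every column sums to 1 over non-N bases. Attributes `n_events` (weight
#'   used) and `n_skipped` (out-of-range windows).
#' @export
positional_profile <- function(ce, sequences, flank = 10L) {
  stopifnot(flank >= 1L)
  seqs <- as_seq_vector(sequences)
  L <- nchar(seqs)[match(ce$transcript_id, names(seqs))]
  if (anyNA(L)) {
    stop("transcript missing from the sequence set: ",
         ce$transcript_id[which(is.na(L))[1]])
  }
  ok <- ce$position - flank >= 0L & ce$position + flank <= L - 1L
  n_skipped <- sum(!ok)
  d <- ce[ok, , drop = FALSE]
  if (!nrow(d)) stop("no crosslink events with a full in-range window")
  win <- substr(seqs[d$transcript_id], d$position - flank + 1L,
                d$position + flank + 1L)
  chars <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                  ncol = 2L * flank + 1L, byrow = TRUE)
  w <- as.numeric(d$unique_count)
  bases <- c("A", "C", "G", "T")
  mat <- vapply(bases, function(b) colSums((chars == b) * w),
                numeric(2L * flank + 1L))
  mat <- t(mat)  # 4 x width
  denom <- colSums(mat)
  denom[denom == 0] <- NA_real_
  mat <- sweep(mat, 2L, denom, "/")
  rownames(mat) <- c("A", "C", "G", "U")
  colnames(mat) <- as.character(seq(-flank, flank))
  attr(mat, "n_events") <- sum(w)
  attr(mat, "n_skipped") <- n_skipped
  mat
}

#' Locate k-mer sites inside 3'UTRs
#'
#' Finds all (overlapping) occurrences of a k-mer within the 3'UTR of each
#' transcript and reports them in transcript coordinates.
#'
#' @param annotation region annotation.
#' @param sequences transcript sequences.
#' @param kmer the k-mer (e.g. a 7mer-A1 site from [seed_site_7merA1()]).
#' @return data.frame `transcript_id`, `start`, `end` (0-based half-open,
#'   transcript coordinates).
#' @export
kmer_sites <- function(annotation, sequences, kmer) {
  km <- norm_ut(kmer)
  utr <- utr3_sequences(annotation, sequences, with_map = TRUE)
  out <- lapply(names(utr), function(tx) {
    u <- utr[[tx]]
    if (nchar(u$seq) < nchar(km)) return(NULL)
    m <- gregexpr(paste0("(?=", km, ")"), u$seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    s <- u$map[as.integer(m)]  # transcript coordinate of the match start
    data.frame(transcript_id = tx, start = s, end = s + nchar(km),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Permutation test for crosslink proximity to seed sites
#'
#' Tests whether crosslink events sit closer to miRNA seed sites than
#' expected by chance within the same 3'UTRs. The statistic is the median
#' absolute distance between each crosslinked position and the start of its
#' nearest seed site on the same transcript's 3'UTR; the null re-places the
#' same number of events uniformly within the same 3'UTRs.
#'
#' @param ce crosslink-event table (events inside 3'UTRs of transcripts
#'   carrying at least one seed site are used; others are ignored).
#' @param sites seed-site table (`transcript_id`, `start`, `end`), e.g. from
#'   [kmer_sites()].
#' @param annotation region annotation.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list `median_abs_distance`, `p_value`
#'   (`(1 + #\{perm median <= observed\}) / (1 + n_perm)`), `n_events`,
#'   `n_transcripts`, `n_perm`.
#' @export
seed_proximity_bias <- function(ce, sites, annotation, n_perm = 1000L,
                                seed = 1L) {
  set.seed(seed)
  utr <- annotation[annotation$label == "three_prime_utr", , drop = FALSE]
  shared <- intersect(unique(sites$transcript_id), unique(ce$transcript_id))
  shared <- intersect(shared, unique(utr$transcript_id))
  if (!length(shared)) {
    stop("no transcripts share crosslink events, seed sites and a 3'UTR")
  }

  nearest <- function(p, starts) {
    i <- findInterval(p, starts)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(starts))
    pmin(abs(p - starts[lo]), abs(p - starts[hi]))
  }

  obs <- numeric(0)
  perm <- matrix(numeric(0), nrow = 0, ncol = n_perm)
  n_events <- 0L
  for (tx in shared) {
    iv <- utr[utr$transcript_id == tx, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    map <- unlist(mapply(function(s, e) seq.int(s, e - 1L), iv$start, iv$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    p <- ce$position[ce$transcript_id == tx]
    p <- p[p %in% map]
    if (!length(p)) next
    st <- sort(sites$start[sites$transcript_id == tx])
    obs <- c(obs, nearest(p, st))
    n_events <- n_events + length(p)
    draws <- map[sample.int(length(map), length(p) * n_perm, replace = TRUE)]
    perm <- rbind(perm, matrix(nearest(draws, st), ncol = n_perm))
  }
  if (!length(obs)) {
    stop("no crosslink events fall inside seed-bearing 3'UTRs")
  }
  obs_med <- stats::median(obs)
  perm_med <- apply(perm, 2, stats::median)
  list(median_abs_distance = obs_med,
       p_value = (1 + sum(perm_med <= obs_med)) / (1 + n_perm),
       n_events = n_events, n_transcripts = length(shared), n_perm = n_perm)
}

#' Bundled mature miRNA panel
#'
#' Loads the package's panel of conserved mature miRNA sequences (TSV under
#' `inst/extdata`): ubiquitous (let-7a, miR-125b), stem-cell (miR-302a),
#' muscle (miR-1a), blood (miR-150) and nervous-system (miR-9, miR-124,
#' miR-128, miR-132, miR-138) miRNAs.
#'
#' @return data.frame `name`, `mature_seq` (RNA alphabet).
#' @export
mirna_panel <- function() {
  path <- system.file("extdata", "mirna_panel.tsv", package = "crosslinkr")
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
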