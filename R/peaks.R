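#' Call significant crosslink-event peaks per transcript
#'
#' Scans each transcript with a centered window of width `window_w`: the
#' score of a candidate position (any position carrying at least one unique
#' crosslink event, samples pooled) is the sum of unique-event counts within
#' +/- (window_w - 1)/2. The null distribution is obtained per transcript by
#' scattering the transcript's total unique events uniformly over its length
#' `n_perm` times and recording the maximal windowed score of each scatter
#' (windows centered on scattered events, the same scanning rule as the
#' observed statistic). The empirical p-value of a candidate is
#' `(1 + #\{permutation maxima >= score\}) / (1 + n_perm)`;
#' Benjamini-Hochberg correction is applied pipeline-wide across all
#' candidate windows. Significant positions (q <= fdr_alpha) closer than
#' `window_w` are merged into peaks; the summit is the (leftmost) position of
#' maximal windowed score.
#'
#' @param ce crosslink-event table from [call_crosslink_events()].
#' @param annotation region annotation (for transcript lengths).
#' @param window_w odd window width in nt.
#' @param n_perm number of permutations (>= 100). The default 1000 keeps the
#'   attainable empirical p-value floor, 1/(n_perm + 1), below the
#'   Benjamini-Hochberg threshold when many thousands of candidate windows
#'   are tested pipeline-wide.
#' @param fdr_alpha FDR threshold on BH-adjusted q-values.
#' @param seed integer seed for the permutation scatters.
#' @return data.frame of peaks: `transcript_id`, `start`, `end` (0-based
#'   half-open), `summit`, `height` (windowed unique-event score at the
#'   summit), `empirical_p`, `fdr_q`. Candidate-level statistics are attached
#'   as attribute `candidates`.
#' @export
call_peaks <- function(ce, annotation, window_w = 15L, n_perm = 1000L,
                       fdr_alpha = 0.05, seed = 1L) {
  stopifnot(window_w %% 2L == 1L, window_w >= 1L, n_perm >= 100L,
            fdr_alpha > 0, fdr_alpha <= 1)
  set.seed(seed)
  half <- (window_w - 1L) %/% 2L
  tt <- transcript_table(annotation)
  empty <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      height = integer(0), empirical_p = numeric(0),
                      fdr_q = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(ce)) return(empty)

  # pool samples: total unique events per (transcript, position)
  key <- paste(ce$transcript_id, ce$position, sep = "\r")
  agg <- rowsum(ce$unique_count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  pooled <- data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    position = as.integer(vapply(parts, `[`, character(1), 2L)),
    count = as.integer(agg[, 1]), stringsAsFactors = FALSE
  )
  pooled <- pooled[order(pooled$transcript_id, pooled$position), ,
                   drop = FALSE]

  sp <- split(pooled, pooled$transcript_id)
  cand <- vector("list", length(sp))
  for (k in seq_along(sp)) {
    d <- sp[[k]]
    tx <- d$transcript_id[1]
    L <- tt$length[match(tx, tt$transcript_id)]
    if (is.na(L)) stop("transcript ", tx, " missing from annotation")
    if (L < window_w) {
      warning("transcript ", tx, " shorter than the window (", L, " < ",
              window_w, "); skipped")
      next
    }
    pos <- d$position
    wts <- d$count
    cw <- cumsum(wts)
    hi <- findInterval(pos + half, pos)
    lo <- findInterval(pos - half - 1L, pos)
    s <- cw[hi] - c(0L, cw)[lo + 1L]

    n_ev <- sum(wts)
    draws <- matrix(sample.int(L, n_ev * n_perm, replace = TRUE) - 1L,
                    nrow = n_ev)
    perm_max <- integer(n_perm)
    for (j in seq_len(n_perm)) {
      x <- sort.int(draws[, j], method = "radix")
      perm_max[j] <- max(findInterval(x + half, x) -
                           findInterval(x - half - 1L, x))
    }
    perm_sorted <- sort.int(perm_max, method = "radix")
    n_ge <- n_perm - findInterval(s - 0.5, perm_sorted)
    p <- (1 + n_ge) / (1 + n_perm)
    cand[[k]] <- data.frame(transcript_id = tx, position = pos, score = s,
                            empirical_p = p, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand$fdr_q <- stats::p.adjust(cand$empirical_p, method = "BH")

  sig <- cand[cand$fdr_q <= fdr_alpha, , drop = FALSE]
  attr(empty, "candidates") <- cand
  if (!nrow(sig)) return(empty)

  peaks <- do.call(rbind, lapply(split(sig, sig$transcript_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(d$position) > window_w)))
    do.call(rbind, lapply(split(d, grp), function(g) {
      summit_i <- which.max(g$score)  # leftmost on ties
      data.frame(transcript_id = g$transcript_id[1],
                 start = min(g$position), end = max(g$position) + 1L,
                 summit = g$position[summit_i],
                 height = g$score[summit_i],
                 empirical_p = min(g$empirical_p), fdr_q = min(g$fdr_q),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(peaks) <- NULL
  peaks <- peaks[order(peaks$transcript_id, peaks$start), , drop = FALSE]
  attr(peaks, "candidates") <- cand
  peaks
}

#' Derive the bound-target set from called peaks
#'
#' Every annotated transcript forms the universe; a transcript is bound iff
#' it carries at least one significant peak.
#'
#' @param peaks peak table from [call_peaks()].
#' @param annotation region annotation.
#' @param ce optional crosslink-event table, used to report the total unique
#'   events per transcript.
#' @return data.frame `transcript_id`, `bound`, `n_peaks`,
#'   `total_unique_CEs`, `utr3_length` covering every annotated transcript.
#' @export
derive_targets <- function(peaks, annotation, ce = NULL) {
  tt <- transcript_table(annotation)
  np <- table(factor(peaks$transcript_id, levels = tt$transcript_id))
  total <- if (!is.null(ce) && nrow(ce)) {
    v <- rowsum(ce$unique_count, ce$transcript_id)
    as.integer(v[match(tt$transcript_id, rownames(v)), 1])
  } else NA_integer_
  out <- data.frame(
    transcript_id = tt$transcript_id,
    bound = as.integer(np) >= 1L,
    n_peaks = as.integer(np),
    total_unique_CEs = ifelse(is.na(total), 0L, total),
    utr3_length = tt$utr3_length,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Attribute transcript positions to annotation features
#'
#' Maps 0-based positions to the region label of the transcript model.
#' Exonic positions of lincRNAs are reported as "lincRNA"; intronic
#' positions (of any biotype) as "intron".
#'
#' @param position integer vector of 0-based positions.
#' @param transcript_id character vector (recycled against `position`).
#' @param annotation region annotation.
#' @return character vector of feature labels.
#' @export
assign_feature <- function(position, transcript_id, annotation) {
  n <- max(length(position), length(transcript_id))
  position <- rep_len(as.integer(position), n)
  transcript_id <- rep_len(transcript_id, n)
  out <- character(n)
  sp <- split(seq_len(n), transcript_id)
  ann_sp <- split(annotation, annotation$transcript_id)
  for (tx in names(sp)) {
    a <- ann_sp[[tx]]
    if (is.null(a)) stop("transcript ", tx, " missing from annotation")
    a <- a[order(a$start), , drop = FALSE]
    idx <- sp[[tx]]
    p <- position[idx]
    L <- max(a$end)
    if (any(p < 0L | p >= L)) {
      stop("position outside [0, ", L, ") for transcript ", tx, ": ",
           paste(p[p < 0L | p >= L][1], collapse = ","))
    }
    lab <- a$label[findInterval(p, a$start)]
    if (a$biotype[1] == "lincRNA") {
      lab[lab == "noncoding_exon"] <- "lincRNA"
    }
    out[idx] <- lab
  }
  out
}

#' Distribution of crosslink events over transcript features
#'
#' Fractions of unique crosslink events (default) or of distinct crosslinked
#' positions per feature class.
#'
#' @param ce crosslink-event table.
#' @param annotation region annotation.
#' @param weight "events" weighs positions by `unique_count` (the unique-CE
#'   distribution); "positions" counts each crosslinked position once.
#' @return named numeric vector of fractions summing to 1.
#' @export
feature_distribution <- function(ce, annotation,
                                 weight = c("events", "positions")) {
  weight <- match.arg(weight)
  if (!nrow(ce)) stop("empty crosslink-event table")
  lab <- assign_feature(ce$position, ce$transcript_id, annotation)
  w <- if (weight == "events") ce$unique_count else rep(1L, nrow(ce))
  tot <- rowsum(as.numeric(w), lab)
  out <- tot[, 1] / sum(tot)
  names(out) <- rownames(tot)
  sort(out, decreasing = TRUE)
}

#' Compare 3'UTR lengths of bound versus unbound transcripts
#'
#' Reports median 3'UTR lengths (kb) of the bound and unbound groups and a
#' two-sided Mann-Whitney U (Wilcoxon rank-sum) p-value for the difference.
#'
#' @param targets target table from [derive_targets()].
#' @return list `median_bound_kb`, `median_unbound_kb`, `p_value`, `test`,
#'   `n_bound`, `n_unbound`.
#' @export
utr_length_stats <- function(targets) {
  b <- targets$utr3_length[targets$bound] / 1000
  u <- targets$utr3_length[!targets$bound] / 1000
  if (!length(b) || !length(u)) {
    stop("both a bound and an unbound group are required")
  }
  p <- suppressWarnings(stats::wilcox.test(b, u, alternative = "two.sided",
                                           exact = FALSE)$p.value)
  list(median_bound_kb = stats::median(b),
       median_unbound_kb = stats::median(u),
       p_value = p, test = "Mann-Whitney U (two-sided)",
       n_bound = length(b), n_unbound = length(u))
}
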