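test_that("7mer-A1 site is revcomp of miRNA positions 2-7 plus A", {
  expect_identical(seed_site_7merA1("UAGGUAGUU"), "CUACCUA")
  expect_identical(seed_site_7merA1("AAAAAAAA"), "UUUUUUA")
  # the canonical miR-128 site
  expect_identical(seed_site_7merA1("UCACAGUGAACCGGUCUCUUU"), "ACUGUGA")
  expect_error(seed_site_7merA1("UAGGUAG"), "at least 8")
})

test_that("k-mer counting is overlapping and U/T-insensitive", {
  expect_identical(count_kmer("UUUUUUUUU", "UUUUUUU"), 3L)
  expect_identical(count_kmer("TTTTTTTTT", "UUUUUUU"), 3L)
  expect_identical(count_kmer("ACGUACGU", "UUUUUUU"), 0L)
  expect_identical(count_kmer("ACG", "ACGU"), 0L)  # kmer longer than seq
  expect_identical(count_kmer("UUUUUUUUU", "UUUUUUU", overlapping = FALSE), 1L)
})

test_that("k-mer counts match a brute-force sliding-window oracle", {
  brute <- function(s, k) {
    n <- nchar(s) - nchar(k) + 1L
    if (n < 1L) return(0L)
    sum(vapply(seq_len(n),
               function(i) substr(s, i, i + nchar(k) - 1L) == k, logical(1)))
  }
  set.seed(14)
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.4)), collapse = "")
    for (k in c("TTTTTTT", "ACTGTGA", "TT", "ACGT")) {
      expect_identical(count_kmer(s, k), brute(s, k))
    }
  }
})

test_that("profile_utrs computes counts and per-kb densities over 3'UTRs", {
  ann <- toy_annotation()
  seqs <- toy_sequences()
  # plant 4 disjoint poly-U 7mers in txA's 600 nt 3'UTR
  ch <- strsplit(seqs["txA"], "")[[1]]
  for (s in c(901, 1001, 1101, 1201)) ch[s:(s + 6)] <- "T"
  # guard the flanks so no accidental run extends a site
  for (s in c(900, 908, 1000, 1008, 1100, 1108, 1200, 1208)) ch[s] <- "G"
  seqs["txA"] <- paste(ch, collapse = "")
  prof <- profile_utrs(ann, seqs, kmers = c(polyU = "UUUUUUU"))
  a <- prof[prof$transcript_id == "txA", ]
  expect_identical(a$utr3_length, 600L)
  expect_identical(a$count, 4L)
  expect_equal(a$density, 4 / 0.6)
  # lincRNA has no 3'UTR: count 0, density 0
  b <- prof[prof$transcript_id == "txB", ]
  expect_identical(b$count, 0L)
  expect_identical(b$density, 0)
  # density * length / 1000 = count for every row
  expect_equal(prof$density * prof$utr3_length / 1000, as.numeric(prof$count))
  expect_error(profile_utrs(ann, seqs["txA"]), "missing from the sequence")
})

test_that("duplicating a 3'UTR at least doubles motif counts", {
  ann <- toy_annotation()[1:5, ]
  seqs <- toy_sequences()["txA"]
  ann2 <- ann
  ann2$end[5] <- 2100L  # 3'UTR now 900-2100: original UTR duplicated
  utr <- substr(seqs, 901, 1500)
  seqs2 <- c(txA = paste0(substr(seqs, 1, 1500), utr))
  c1 <- profile_utrs(ann, seqs, c(u = "TGCA"))$count
  c2 <- profile_utrs(ann2, seqs2, c(u = "TGCA"))$count
  expect_gte(c2, 2L * c1)
  expect_lte(c2, 2L * c1 + 3L)  # at most k-1 junction-spanning extras
})

test_that("welch_t_test matches its closed form and is antisymmetric", {
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  w <- welch_t_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(w$statistic, -1.7320508, tolerance = 1e-6)
  expect_equal(w$df, 4.411765, tolerance = 1e-6)
  ws <- welch_t_test(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(ws$statistic, -w$statistic)
  expect_equal(ws$p_value, w$p_value)
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("welch_t_test agrees with the reference implementation", {
  set.seed(99)
  for (i in 1:200) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    w <- welch_t_test(x, y)
    r <- t.test(x, y)
    expect_equal(w$statistic, unname(r$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(r$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, r$p.value, tolerance = 1e-10)
  }
})

test_that("compare_bound_unbound detects planted poly-U enrichment", {
  cfg <- sim_config(n_transcripts = 200, fraction_lincRNA = 0,
                    fraction_mir_targets = 0, target_overlap_fraction = 0,
                    fraction_rbp_targets = 0.5, n_reads = 0, rng_seed = 17)
  tr <- simulate_transcriptome(cfg)
  tt <- tr$truth$transcripts
  tg <- data.frame(transcript_id = tt$transcript_id, bound = tt$is_rbp_target,
                   n_peaks = as.integer(tt$is_rbp_target),
                   total_unique_CEs = 0L, utr3_length = tt$utr3_length)
  prof <- profile_utrs(tr$annotation, tr$sequences, c(polyU = "UUUUUUU"))
  cmp <- compare_bound_unbound(prof, tg, "polyU")
  expect_gt(cmp$density$mean_bound, cmp$density$mean_unbound)
  expect_lt(cmp$density$p_value, 0.01)
  expect_gt(cmp$count$mean_bound, cmp$count$mean_unbound)
  expect_error(compare_bound_unbound(prof, tg, "nope"), "not present")
})

test_that("identical groups give t = 0", {
  prof <- data.frame(transcript_id = sprintf("t%d", 1:8),
                     utr3_length = 1000L, kmer = "polyU",
                     count = rep(c(1L, 2L, 3L, 4L), 2),
                     density = rep(c(1, 2, 3, 4), 2))
  tg <- data.frame(transcript_id = sprintf("t%d", 1:8),
                   bound = rep(c(TRUE, FALSE), each = 4),
                   n_peaks = 0L, total_unique_CEs = 0L, utr3_length = 1000L)
  cmp <- compare_bound_unbound(prof, tg, "polyU")
  expect_equal(cmp$count$statistic, 0)
  expect_equal(cmp$density$p_value, 1)
})

test_that("hypergeometric overlap enrichment is exact", {
  res <- overlap_enrichment(sprintf("g%d", 1:5), sprintf("g%d", 2:5), 10)
  expect_identical(res$overlap, 4L)
  expect_equal(res$expected, 2)
  expect_equal(res$fold, 2)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # B subset of A covering the whole universe -> certain event
  res2 <- overlap_enrichment(sprintf("g%d", 1:10), sprintf("g%d", 1:4), 10)
  expect_equal(res2$p_value, 1)
  # disjoint sets
  res3 <- overlap_enrichment(c("a", "b"), c("c", "d"), 10)
  expect_identical(res3$overlap, 0L)
  expect_equal(res3$fold, 0)
  expect_lte(res3$p_value, 1)
  expect_error(overlap_enrichment(letters[1:5], letters[6:10], 8), "universe")
})

test_that("positional profile recovers planted U runs and one-hot singletons", {
  seqs <- c(t1 = paste0(strrep("A", 50), strrep("T", 11), strrep("C", 50)))
  ce <- ce_row("t1", 55, 10)  # center of the U run
  mat <- positional_profile(ce, seqs, flank = 5L)
  expect_equal(dim(mat), c(4L, 11L))
  expect_true(all(abs(colSums(mat) - 1) < 1e-9))
  expect_true(all(mat["U", ] == 1))
  # single event gives one-hot columns
  m2 <- positional_profile(ce_row("t1", 30, 1), seqs, flank = 3L)
  expect_true(all(m2 %in% c(0, 1)))
  expect_true(all(m2["A", ] == 1))
  expect_error(positional_profile(ce_row("t1", 1, 1), seqs, flank = 5L),
               "in-range")
})

test_that("uniform background gives a flat positional profile", {
  set.seed(4)
  seqs <- c(t1 = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                       collapse = ""))
  ce <- ce_row("t1", sample(100:19900, 10000, replace = TRUE), 1)
  mat <- positional_profile(ce, seqs, flank = 10L)
  expect_true(all(abs(mat - 0.25) < 0.02))
})

test_that("seed proximity distances and extreme cases behave", {
  ann <- toy_annotation()[1:5, ]
  # single transcript, one CE at 3'UTR start, one seed site at [910, 917)
  sites <- data.frame(transcript_id = "txA", start = 910L, end = 917L)
  ce <- ce_row("txA", 900)
  res <- seed_proximity_bias(ce, sites, ann, n_perm = 200L, seed = 1L)
  expect_identical(res$median_abs_distance, 10)
  expect_identical(res$n_events, 1L)
  # CEs exactly at the seed sites -> minimal attainable p
  ce2 <- ce_row("txA", 910)
  res2 <- seed_proximity_bias(ce2, sites, ann, n_perm = 200L, seed = 1L)
  expect_identical(res2$median_abs_distance, 0)
  expect_lte(res2$p_value, 5 / 201)
  expect_error(seed_proximity_bias(ce_row("nope", 5), sites, ann),
               "no transcripts share")
})

test_that("proximity p-values are roughly uniform under a uniform null", {
  ann <- toy_annotation()[1:5, ]
  set.seed(6)
  ps <- replicate(100, {
    sites <- data.frame(transcript_id = "txA",
                        start = sort(sample(900:1480, 3)), end = 0L)
    sites$end <- sites$start + 7L
    ce <- ce_row("txA", sample(900:1499, 20), 1)
    seed_proximity_bias(ce, sites, ann, n_perm = 99L,
                        seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps <= 0.2), 0.08)
  expect_lt(mean(ps <= 0.2), 0.35)
})

test_that("the bundled miRNA panel loads and yields valid seed sites", {
  panel <- mirna_panel()
  expect_identical(nrow(panel), 10L)
  expect_true(all(nchar(panel$mature_seq) >= 8))
  sites <- vapply(panel$mature_seq, seed_site_7merA1, character(1))
  expect_true(all(nchar(sites) == 7))
  expect_identical(unname(sites[panel$name == "miR-128-3p"]), "ACUGUGA")
})
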