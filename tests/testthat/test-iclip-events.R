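test_that("demultiplex splits reads by exact sample code and extracts UMIs", {
  spec <- barcode_spec(3L, 4L, 2L)
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    seq = c(paste0("AAA", "ACGT", "CC", "GATTACA"),   # sample s1
            paste0("TTT", "GGGG", "AA", "GATTACA"),   # unknown code
            paste0("CCC", "ACGT", "GG", "TTTTAAA")),  # sample s1
    stringsAsFactors = FALSE
  )
  dm <- demultiplex(reads, spec, c(s1 = "ACGT"))
  expect_identical(dm$summary, c(s1 = 2L, undetermined = 1L))
  expect_identical(dm$reads$umi, c("AAACC", "CCCGG"))
  expect_identical(nchar(dm$reads$umi), c(5L, 5L))
  expect_identical(dm$reads$insert, c("GATTACA", "TTTTAAA"))
})

test_that("demultiplex rejects duplicate sample codes", {
  expect_error(demultiplex(data.frame(read_id = "r", seq = "AAAACGTCCAAA"),
                           barcode_spec(), c(a = "ACGT", b = "ACGT")),
               "share a barcode")
})

test_that("all reads from a configured sample are assigned", {
  tr <- simulate_transcriptome(small_sim(seed = 31))
  rd <- simulate_iclip_reads(tr)
  dm <- demultiplex(rd$reads, barcode_spec(), c(s1 = tr$config$sample_code))
  expect_identical(unname(dm$summary["s1"]), nrow(rd$reads))
  expect_identical(unname(dm$summary["undetermined"]), 0L)
})

test_that("exact mapping places unique substrings and drops multimappers", {
  seqs <- c(t1 = paste(rep("ACGTG", 60), collapse = ""),
            t2 = paste(rep("TTGCA", 60), collapse = ""))
  # unique 20-mer from t1 at 0-based position 100
  ins <- substr(seqs["t1"], 101, 130)
  reads <- data.frame(read_id = "r1", sample = "s1", umi = "AAAAA",
                      insert = unname(ins), stringsAsFactors = FALSE)
  mp <- map_reads_exact(reads, seqs)
  # the repeat structure makes this 30-mer occur at several positions -> in
  # this fixture the insert is a multimapper within t1
  expect_identical(unname(mp$summary["multimapped"]), 1L)

  set.seed(9)
  uniq_seqs <- c(u1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                            collapse = ""),
                 u2 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                            collapse = ""))
  ins2 <- substr(uniq_seqs["u1"], 101, 130)
  reads2 <- data.frame(read_id = "r2", sample = "s1", umi = "AAAAA",
                       insert = unname(ins2), stringsAsFactors = FALSE)
  mp2 <- map_reads_exact(reads2, uniq_seqs)
  expect_identical(mp2$placements$transcript_id, "u1")
  expect_identical(mp2$placements$start, 100L)
  expect_identical(mp2$placements$end, 130L)
})

test_that("mapping an empty transcript database errors", {
  expect_error(map_reads_exact(data.frame(insert = "ACGT"), character(0)),
               "empty transcript database")
})

test_that("error-free synthetic reads map completely (minus multimappers)", {
  tr <- simulate_transcriptome(small_sim(seed = 31))
  rd <- simulate_iclip_reads(tr)
  dm <- demultiplex(rd$reads, barcode_spec(), c(s1 = tr$config$sample_code))
  mp <- map_reads_exact(dm$reads, tr$sequences)
  expect_identical(unname(mp$summary["unmapped"]), 0L)
  expect_identical(unname(mp$summary["mapped"] + mp$summary["multimapped"]),
                   nrow(rd$reads))
})

test_that("crosslink calling collapses PCR duplicates by UMI", {
  pl <- data.frame(
    read_id = sprintf("r%d", 1:5), sample = "s1",
    umi = c("AAACG", "AAACG", "CCGTA", "GGGGG", "GGGGG"),
    transcript_id = "t1", start = c(50L, 50L, 50L, 51L, 51L),
    end = 80L, strand = "+", stringsAsFactors = FALSE
  )
  ce <- call_crosslink_events(pl)
  expect_identical(nrow(ce), 2L)
  expect_identical(ce$position, c(49L, 50L))
  # three reads at start 50 with umis {AAACG, AAACG, CCGTA} -> 2 molecules
  expect_identical(ce$unique_count, c(2L, 1L))
})

test_that("reads at transcript start are dropped with a warning", {
  pl <- data.frame(read_id = c("r1", "r2"), sample = "s1",
                   umi = c("AAAAA", "CCCCC"), transcript_id = "t1",
                   start = c(0L, 10L), end = c(30L, 40L), strand = "+",
                   stringsAsFactors = FALSE)
  expect_warning(ce <- call_crosslink_events(pl), "position")
  expect_identical(nrow(ce), 1L)
  expect_identical(ce$position, 9L)
  expect_identical(attr(ce, "n_dropped_start"), 1L)
})

test_that("dedup counts equal a brute-force distinct-set oracle", {
  set.seed(42)
  n <- 50000
  pl <- data.frame(
    read_id = sprintf("r%d", seq_len(n)), sample = sample(c("a", "b"), n, TRUE),
    umi = paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                 sample(c("A", "C", "G", "T"), n, TRUE),
                 sample(c("A", "C", "G", "T"), n, TRUE)),
    transcript_id = sample(sprintf("t%d", 1:20), n, TRUE),
    start = sample.int(200, n, TRUE), strand = "+",
    stringsAsFactors = FALSE
  )
  ce <- suppressWarnings(call_crosslink_events(pl))
  # oracle: independent split/unique computation
  keep <- pl[pl$start > 0L, ]
  grp <- paste(keep$transcript_id, keep$start - 1L, keep$sample)
  oracle <- vapply(split(keep$umi, grp), function(u) length(unique(u)),
                   integer(1))
  got <- ce$unique_count
  names(got) <- paste(ce$transcript_id, ce$position, ce$sample)
  expect_identical(got[names(oracle)], oracle)
  expect_identical(sum(got), sum(oracle))
})

test_that("dedup is idempotent and bounded by read count", {
  tr <- simulate_transcriptome(small_sim(seed = 31))
  rd <- simulate_iclip_reads(tr)
  dm <- demultiplex(rd$reads, barcode_spec(), c(s1 = tr$config$sample_code))
  mp <- map_reads_exact(dm$reads, tr$sequences)
  ce <- suppressWarnings(call_crosslink_events(mp$placements))
  expect_lte(sum(ce$unique_count), nrow(mp$placements))
  # idempotence: one read per unique molecule reproduces the same table
  pl <- mp$placements
  uniq <- pl[!duplicated(paste(pl$transcript_id, pl$start - 1L, pl$sample,
                               pl$umi)), ]
  ce2 <- suppressWarnings(call_crosslink_events(uniq))
  attr(ce, "n_dropped_start") <- NULL
  attr(ce2, "n_dropped_start") <- NULL
  expect_identical(ce, ce2)
})

test_that("called crosslink positions match the generator's truth exactly", {
  tr <- simulate_transcriptome(small_sim(seed = 31))
  rd <- simulate_iclip_reads(tr)
  dm <- demultiplex(rd$reads, barcode_spec(), c(s1 = tr$config$sample_code))
  mp <- map_reads_exact(dm$reads, tr$sequences)
  ce <- suppressWarnings(call_crosslink_events(mp$placements))
  called <- paste(ce$transcript_id, ce$position)
  truth <- paste(rd$true_ce$transcript_id, rd$true_ce$start)
  expect_true(all(called %in% truth))
  # multimapped/dropped molecules are the only truth positions not recovered
  expect_gt(mean(truth %in% called), 0.98)
})
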