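pair_tbl <- function(seq1, qual1 = strrep("G", nchar(seq1)),
                     seq2 = seq1, qual2 = strrep("G", nchar(seq2))) {
  tibble::tibble(id = paste0("r", seq_along(seq1)),
                 seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2)
}

test_that("adapter trimming removes the longest qualifying suffix", {
  ad <- "TGGAATTCTCGGGTGCCAAGG"
  full <- paste0("ACGTACGTAC", ad)
  p <- trim_adapters(pair_tbl(full), ad, ad, min_overlap = 4)
  expect_equal(p$seq1, "ACGTACGTAC")
  expect_equal(nchar(p$qual1), 10L) # quality truncated in lock-step
  expect_true(p$trimmed1)

  none <- trim_adapters(pair_tbl("ACGTACGTACGT"), ad, ad, 4)
  expect_equal(none$seq1, "ACGTACGTACGT")
  expect_false(none$trimmed1)

  partial <- trim_adapters(pair_tbl(paste0("AAAACCCC", substr(ad, 1, 6))),
                           ad, ad, 4, 0)
  expect_equal(partial$seq1, "AAAACCCC")
})

test_that("adapter trimming matches the exhaustive overlap oracle", {
  set.seed(21)
  ad <- "GATCGTCGGACTGTAGAACTCTGAAC"
  reads <- vapply(1:50, function(i) {
    core <- random_seq(sample(5:30, 1))
    if (runif(1) < 0.7) paste0(core, substr(ad, 1, sample(1:20, 1))) else core
  }, character(1))
  got <- trim_adapters(pair_tbl(reads), ad, ad, 4, 0.1)$seq1
  want <- vapply(reads, oracle_trim, character(1), adapter = ad,
                 min_overlap = 4, max_mm_frac = 0.1, USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("UMI extraction splits the read-1 head", {
  x <- extract_umi(pair_tbl(paste0("ACGTACGTA", strrep("T", 20))),
                   umi_len = 9, end_len = 14)
  expect_equal(x$umi, "ACGTACGTA")
  expect_equal(x$seq1, strrep("T", 20))
  expect_equal(nchar(x$qual1), 20L)
  expect_false(x$too_short)

  off <- extract_umi(pair_tbl(strrep("A", 20)), umi_len = 0, end_len = 14)
  expect_equal(off$umi, "")
  expect_equal(off$seq1, strrep("A", 20))

  short <- extract_umi(pair_tbl(strrep("A", 10)), umi_len = 9, end_len = 14)
  expect_true(short$too_short)
})

test_that("channel barcodes resolve by IUPAC degenerate match", {
  tail_ <- strrep("C", 20)
  x <- extract_channel(pair_tbl("AAAA", seq2 = paste0("AAGTC", tail_)))
  expect_equal(x$channel, "modified") # A,A,G are R; T,C are Y
  expect_equal(x$seq2, tail_)
  y <- extract_channel(pair_tbl("AAAA", seq2 = paste0("TCTAG", tail_)))
  expect_equal(y$channel, "untreated") # T,C,T are Y; A,G are R
  z <- extract_channel(pair_tbl("AAAA", seq2 = paste0("AAGTG", tail_)))
  expect_equal(z$channel, "unassigned") # final G is not Y
})

test_that("zero-error simulated pairs demultiplex to their true bins exactly", {
  sim <- make_toy_sim(reads_per_length = 30, p_mod = rep(0, 60), p_bg = 0,
                      seq_error = 0, seed = 5)
  idx <- build_end_index(sim$targets)
  dx <- demultiplex(sim$pairs, idx)
  expect_equal(nrow(dx$rejects), 0L)
  expect_true(all(dx$records$match_class == "native"))

  truth_bins <- dplyr::count(sim$truth$reads, channel, length_n)
  got_bins <- dplyr::count(dx$records, channel, length_n)
  expect_equal(
    dplyr::arrange(got_bins, channel, length_n),
    dplyr::arrange(truth_bins, channel, length_n))
})

test_that("a substitution inside the end window is recovered as that length", {
  sim <- make_toy_sim(reads_per_length = 2, p_mod = rep(0, 60), p_bg = 0,
                      seq_error = 0, seed = 5)
  idx <- build_end_index(sim$targets)
  pairs <- sim$pairs[1, ]
  # corrupt position 3 of the end window (after the 9-nt UMI)
  pos <- 9L + 3L
  cur <- substr(pairs$seq1, pos, pos)
  substr(pairs$seq1, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  dx <- demultiplex(pairs, idx)
  truth <- sim$truth$reads[sim$truth$reads$id == pairs$id, ]
  if (nrow(dx$records) == 1L) {
    expect_equal(dx$records$length_n, truth$length_n)
    expect_equal(dx$records$match_class, "substitution")
  } else {
    # the corrupted key collided across lengths; it must be flagged ambiguous
    expect_equal(dx$rejects$reason, "ambiguous")
  }
})

test_that("demultiplexing conserves reads and is deterministic", {
  sim <- make_toy_sim(reads_per_length = 60, seq_error = 0.005, seed = 12)
  idx <- build_end_index(sim$targets)
  dx1 <- demultiplex(sim$pairs, idx)
  dx2 <- demultiplex(sim$pairs, idx)
  expect_identical(dx1$records, dx2$records)
  expect_identical(dx1$stats, dx2$stats)

  s <- function(metric) dx1$stats$count[dx1$stats$metric == metric]
  expect_equal(s("assigned") + s("rejected"), s("total"))
  expect_equal(s("too_short") + s("unassigned_channel") + s("ambiguous") +
                 s("unmatched"), s("rejected"))
  expect_equal(s("class_native") + s("class_substitution") +
                 s("class_insertion") + s("class_deletion"), s("assigned"))
})

test_that("FASTQ writing and reading round-trip, including gzip", {
  sim <- make_toy_sim(reads_per_length = 5, seed = 9)
  dir <- withr::local_tempdir()
  r1 <- file.path(dir, "t_R1.fastq.gz"); r2 <- file.path(dir, "t_R2.fastq.gz")
  write_fastq(sim$pairs$id, sim$pairs$seq1, sim$pairs$qual1, r1)
  write_fastq(sim$pairs$id, sim$pairs$seq2, sim$pairs$qual2, r2)
  back <- read_fastq_pair(r1, r2)
  expect_equal(as.data.frame(back), as.data.frame(sim$pairs))
})

test_that("per-bin FASTQ output carries the UMI in the read id", {
  sim <- make_toy_sim(reads_per_length = 4, p_mod = rep(0, 60), p_bg = 0,
                      seq_error = 0, seed = 2)
  idx <- build_end_index(sim$targets)
  dx <- demultiplex(sim$pairs, idx)
  dir <- withr::local_tempdir()
  manifest <- write_demux_bins(dx$records, dir)
  expect_true(all(file.exists(manifest$r1)))
  one <- read_fastq_pair(manifest$r1[1], manifest$r2[1])
  expect_true(all(grepl("_UMI:[ACGT]{9}$", one$id)))
})

test_that("optional UMI deduplication collapses exact duplicates per bin", {
  sim <- make_toy_sim(reads_per_length = 10, p_mod = rep(0, 60), p_bg = 0,
                      seq_error = 0, seed = 3)
  idx <- build_end_index(sim$targets)
  pairs <- dplyr::bind_rows(sim$pairs, sim$pairs[1, ] |>
                              dplyr::mutate(id = "dup_read"))
  dx <- demultiplex(pairs, idx, demux_config(dedup_umi = TRUE))
  expect_equal(dx$stats$count[dx$stats$metric == "umi_collapsed"], 1L)
})
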