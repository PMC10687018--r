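hi <- function(n) strrep(intToUtf8(38 + 33), n) # Phred 38
make_aln <- function(ops, tpos, rpos, insert, target) {
  structure(list(score = NA_real_,
                 ops = tibble::tibble(op = ops, tpos = tpos, rpos = rpos),
                 insert = insert, target = target, discarded = FALSE),
            class = "pairwise_alignment")
}

test_that("pair merging reconstructs the insert and resolves disagreements", {
  set.seed(30)
  insert <- random_seq(20) # aperiodic, so the true overlap is unambiguous
  s5 <- substr(insert, 1, 15)               # read 2 remainder
  s3 <- substr(insert, 6, 20)               # 3' piece, as read 1 = its revcomp
  r1 <- revcomp(s3)
  m <- merge_pair(r1, hi(15), s5, hi(15), min_overlap = 5)
  expect_true(m$merged)
  expect_equal(m$seq, insert)
  expect_equal(nchar(m$qual), 20L)

  # disagreement: quality 40 beats quality 10, merged quality is the difference
  s3_mut <- s3
  alt <- setdiff(BASES, substr(s3, 5, 5))[1]
  substr(s3_mut, 5, 5) <- alt # overlap position, disagrees with the 5' piece
  q40 <- strrep(intToUtf8(40 + 33), 15)
  q10 <- strrep(intToUtf8(10 + 33), 15)
  m2 <- merge_pair(revcomp(s3_mut), stringi::stri_reverse(q10), s5, q40,
                   min_overlap = 5)
  pos <- 10L # position 5 of the 3' piece = insert position 10
  expect_equal(substr(m2$seq, pos, pos), substr(insert, pos, pos))
  expect_equal(utf8ToInt(substr(m2$qual, pos, pos)) - 33L, 30L)

  none <- merge_pair(revcomp(strrep("A", 12)), hi(12), strrep("C", 12), hi(12),
                     min_overlap = 5)
  expect_false(none$merged)
})

test_that("merge overlap selection matches the exhaustive offset oracle", {
  set.seed(31)
  for (i in 1:50) {
    L <- sample(30:60, 1)
    insert <- random_seq(L)
    n5 <- sample(20:28, 1); n3 <- sample(20:28, 1)
    s5 <- substr(insert, 1, n5)
    s3 <- substr(insert, L - n3 + 1, L)
    # sprinkle a mismatch sometimes
    if (runif(1) < 0.5) {
      p <- sample(n3, 1)
      substr(s3, p, p) <- sample(BASES, 1)
    }
    want_o <- oracle_merge_overlap(s5, s3, 8, 0.1)
    m <- merge_pair(revcomp(s3), hi(n3), s5, hi(n5), min_overlap = 8)
    if (want_o == 0) {
      expect_false(m$merged)
    } else {
      expect_true(m$merged)
      expect_equal(nchar(m$seq), n5 + n3 - want_o)
    }
  }
})

test_that("alignment handles identity, substitutions and 3' overhangs", {
  target <- paste0("atgc", random_seq(40))
  insert <- toupper(target)
  a <- align_to_target(insert, target)
  expect_true(all(a$ops$op == "match"))
  expect_equal(a$score, 2 * nchar(insert))
  expect_false(a$discarded)

  sub <- insert
  substr(sub, 20, 20) <- setdiff(BASES, substr(insert, 20, 20))[1]
  b <- align_to_target(sub, target)
  expect_equal(sum(b$ops$op == "mismatch"), 1L)
  expect_equal(b$ops$tpos[b$ops$op == "mismatch"], 20L)

  # read from transcript n+1 against target n: 1-nt 3' overhang, no indels
  longer <- paste0(insert, "G")
  c_ <- align_to_target(longer, target)
  expect_false(any(c_$ops$op %in% c("insertion", "deletion")))
  expect_equal(c_$t_end, nchar(target))
  expect_equal(c_$r_end, nchar(longer) - 1L) # last read base is overhang
  expect_equal(c_$score, oracle_align_score(longer, toupper(target)))

  junk <- strrep("A", 30)
  set.seed(5)
  d <- align_to_target(junk, paste0("gc", random_seq(38)))
  expect_true(d$discarded) # below the score floor
})

test_that("mutation calling applies the quality gate", {
  target <- random_seq(60)
  insert <- target
  substr(insert, 40, 40) <- setdiff(BASES, substr(target, 40, 40))[1]
  aln <- align_to_target(insert, target)

  good <- call_mutations(aln, hi(60), min_qual = 25)
  expect_equal(good$events, 40L)
  expect_true(40L %in% good$depth)

  q <- hi(60)
  substr(q, 40, 40) <- intToUtf8(20 + 33) # Phred 20 < 25
  bad <- call_mutations(aln, q, min_qual = 25)
  expect_equal(length(bad$events), 0L)
  expect_false(40L %in% bad$depth) # excluded from that read's depth too
  expect_true(39L %in% bad$depth)
})

test_that("homopolymer indels give one event regardless of gap placement", {
  target <- paste0("CCGG", strrep("A", 6), "TTCC")    # homopolymer at 5..10
  insert <- paste0("CCGG", strrep("A", 4), "TTCC")    # 2-nt deletion
  via_aligner <- call_mutations(align_to_target(insert, target), hi(12))
  expect_equal(length(via_aligner$events), 1L)

  # every equivalent placement of the 2-column gap must call the same event
  events <- lapply(5:9, function(a) {
    b <- a + 1L
    diag_before <- seq_len(a - 1L)
    diag_after <- seq.int(b + 1L, 14L)
    ops <- c(rep("match", length(diag_before)), rep("deletion", 2L),
             rep("match", length(diag_after)))
    tpos <- c(diag_before, a, b, diag_after)
    rpos <- c(diag_before, a - 1L, a - 1L, diag_after - 2L)
    aln <- make_aln(ops, tpos, rpos, insert, target)
    call_mutations(aln, hi(12))$events
  })
  expect_equal(length(unique(events)), 1L)
  expect_equal(events[[1]], via_aligner$events)
})

test_that("insertions are gated on inserted-base quality", {
  target <- random_seq(30)
  insert <- paste0(substr(target, 1, 12), "G", substr(target, 13, 30))
  aln <- align_to_target(insert, target)
  expect_equal(sum(aln$ops$op == "insertion"), 1L)
  ok <- call_mutations(aln, hi(31))
  expect_equal(length(ok$events), 1L)
  q <- hi(31)
  rpos_ins <- aln$ops$rpos[aln$ops$op == "insertion"]
  substr(q, rpos_ins, rpos_ins) <- intToUtf8(10 + 33)
  low <- call_mutations(aln, q)
  expect_equal(length(low$events), 0L)
})

test_that("a null bin yields zero events at full depth", {
  sim <- make_toy_sim(reads_per_length = 100, p_mod = rep(0, 60), p_bg = 0,
                      seq_error = 0, seed = 4, min_len = 45, max_len = 47)
  idx <- build_end_index(sim$targets)
  dx <- demultiplex(sim$pairs, idx)
  bin <- dx$records |>
    dplyr::filter(channel == "modified", length_n == 46L)
  tab <- profile_bin(bin, sim$targets$full_rna[sim$targets$length_n == 46L])
  expect_true(all(tab$events == 0L))
  expect_true(all(tab$depth == nrow(bin)))

  expect_warning(
    empty <- profile_bin(bin[0, ], sim$targets$full_rna[1]), "empty")
  expect_true(all(empty$depth == 0L))
})

test_that("recovered rates honour the binomial sampling bound", {
  set.seed(42)
  tseq <- random_seq(80)
  designated <- seq(3, 57, by = 3) # spaced beyond the collapsing window
  p_mod <- rep(0, 80); p_mod[designated] <- 0.05
  cfg <- sim_config(tseq, min_len = 61, max_len = 80,
                    reads_per_length = 2000, p_mod = p_mod, p_bg = 0,
                    seq_error = 0)
  sim <- simulate_library(cfg, seed = 1)
  idx <- build_end_index(sim$targets)
  dx <- demultiplex(sim$pairs, idx)
  counts <- profile_run(dx$records, sim$targets, profile_config())
  ll <- nchar(cfg$leader)
  cells <- counts |>
    dplyr::filter(channel == "modified",
                  (position - ll) %in% designated, depth > 0) |>
    dplyr::mutate(rate = events / depth)
  expect_gt(nrow(cells), 300)
  bound <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(mean(abs(cells$rate - 0.05) <= bound), 0.99)
  # depth at the 3' terminus counts only reads covering it
  term <- counts |>
    dplyr::filter(channel == "modified", position == ll + length_n)
  expect_true(all(term$depth > 0))
})

test_that("reactivity is the background-subtracted rate with depth masking", {
  tab <- function(depth, events) {
    tibble::tibble(position = 1:4, nt = c("a", "t", "A", "C"),
                   depth = depth, events = events)
  }
  mod <- tab(c(1000L, 1000L, 1000L, 499L), c(0L, 0L, 50L, 20L))
  unt <- tab(c(1000L, 1000L, 1000L, 1000L), c(0L, 0L, 20L, 10L))
  pr <- compute_reactivity(mod, unt, min_depth = 500, leader_len = 2)
  expect_equal(nrow(pr), 2L) # leader positions never reported
  expect_equal(pr$reactivity[1], 0.05 - 0.02)
  expect_equal(pr$mask, c("ok", "low_depth"))
  expect_true(is.na(pr$reactivity[2])) # modified depth 499 < 500

  neg <- compute_reactivity(
    tab(rep(1000L, 4), c(0L, 0L, 20L, 0L)),
    tab(rep(1000L, 4), c(0L, 0L, 50L, 0L)),
    min_depth = 500, leader_len = 2)
  expect_equal(neg$reactivity[1], -0.03) # negative values preserved

  expect_error(compute_reactivity(mod[1:3, ], unt, 500, 2), "mismatched")
})
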