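test_that("matrix assembly is triangular and honours exclusions", {
  set.seed(101)
  prof <- make_random_profiles(21:30)
  m <- assemble_matrix(prof, excluded_lengths = 25:26)
  expect_s3_class(m, "cotrans_matrix")
  expect_equal(length(m$lengths), 8L)
  expect_false(any(m$lengths %in% 25:26))

  # row n = 23 has defined cells only for j <= 23
  r23 <- m$layers$reactivity[match(23L, m$lengths), ]
  expect_true(all(is.na(r23[24:30])))

  # triangularity across every layer and row
  for (ly in names(m$layers)) {
    for (i in seq_along(m$lengths)) {
      n <- m$lengths[i]
      beyond <- m$positions > n
      expect_true(all(is.na(m$layers[[ly]][i, beyond])))
    }
  }
  # masked positions carry no reactivity
  masked <- prof[prof$mask != "ok" & prof$length_n %in% m$lengths, ]
  idx <- cbind(match(masked$length_n, m$lengths), masked$position)
  expect_true(all(is.na(m$layers$reactivity[idx])))

  expect_error(assemble_matrix(dplyr::bind_rows(prof, prof[1, ])), "duplicate")
  expect_error(assemble_matrix(prof, excluded_lengths = 50), "excluded")
})

test_that("matrix CSV layers round-trip exactly", {
  set.seed(102)
  prof <- make_random_profiles(10:18)
  m <- assemble_matrix(prof, excluded_lengths = 13L)
  dir <- withr::local_tempdir()
  paths <- write_cotrans_csv(m, dir, prefix = "toy")
  expect_true(all(file.exists(paths)))
  for (ly in c("reactivity", "untreated_rate", "modified_rate", "depth")) {
    back <- read_cotrans_layer(file.path(dir, sprintf("toy_%s.csv", ly)))
    want <- m$layers[[ly]]
    dimnames(back) <- NULL; dimnames(want) <- NULL
    expect_equal(back, want)
  }
  # undefined cells are empty fields, not sentinel numbers
  line2 <- readLines(paths[["reactivity"]])[2]
  expect_match(line2, ",$")
})

test_that("replicate correlation reproduces hand-computed Pearson r", {
  prof <- function(vals) {
    tibble::tibble(length_n = 3L, position = 1:3, nt = "A",
                   mod_depth = 1000L, mod_events = 0L,
                   unt_depth = 1000L, unt_events = 0L,
                   mod_rate = 0, unt_rate = 0,
                   reactivity = vals, mask = "ok")
  }
  A <- assemble_matrix(prof(c(0, 1, 2)))
  B <- assemble_matrix(prof(c(0, 1, 4)))
  rep_ <- replicate_correlation(A, B)
  expect_equal(rep_$r, 0.960769, tolerance = 1e-5)
  expect_equal(rep_$n_used, 3L)

  self <- replicate_correlation(A, A)
  expect_equal(self$r, 1)
})

test_that("masking rules conserve candidate cells and cross-mask", {
  set.seed(103)
  for (trial in 1:5) {
    pa <- make_random_profiles(12:20, mask_frac = 0.2)
    pb <- make_random_profiles(12:20, mask_frac = 0.2)
    A <- assemble_matrix(pa); B <- assemble_matrix(pb)
    rep_ <- replicate_correlation(A, B)
    expect_equal(rep_$n_used + sum(rep_$excluded), rep_$n_candidates)
    expect_equal(rep_$n_candidates, sum(12:20)) # all triangular cells
    # agreement with the from-scratch Pearson formula
    expect_equal(rep_$r, oracle_pearson(rep_$pairs$value_a, rep_$pairs$value_b),
                 tolerance = 1e-12)
  }

  # a cell masked in A only is excluded from both and counted as cross-masked
  pa <- make_random_profiles(5:8, mask_frac = 0)
  pb <- pa
  pa$mask[pa$length_n == 6 & pa$position == 2] <- "low_depth"
  pa$reactivity[pa$length_n == 6 & pa$position == 2] <- NA
  repx <- replicate_correlation(assemble_matrix(pa), assemble_matrix(pb))
  expect_equal(unname(repx$excluded["cross_masked"]), 1L)

  # a zero at a 3'-terminal position drops the pair
  pz <- make_random_profiles(5:8, mask_frac = 0)
  pz2 <- pz
  pz$reactivity[pz$length_n == 7 & pz$position == 7] <- 0
  repz <- replicate_correlation(assemble_matrix(pz), assemble_matrix(pz2))
  expect_equal(unname(repz$excluded["zero_at_3prime"]), 1L)
})

test_that("stats::cor agrees with the two-pass Pearson oracle", {
  set.seed(104)
  for (i in 1:100) {
    x <- rnorm(sample(5:50, 1)); y <- rnorm(length(x))
    expect_equal(cor(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("neighbor correlation uses common positions and skips excluded bands", {
  # identical neighbor profiles on common positions give r = 1 on both layers
  set.seed(105)
  base_vals <- runif(30); base_bg <- runif(30, 0, 0.02)
  prof <- dplyr::bind_rows(lapply(25:30, function(n) {
    tibble::tibble(length_n = n, position = seq_len(n), nt = "A",
                   mod_depth = 1000L, mod_events = 0L, unt_depth = 1000L,
                   unt_events = 0L, mod_rate = base_vals[seq_len(n)],
                   unt_rate = base_bg[seq_len(n)],
                   reactivity = base_vals[seq_len(n)], mask = "ok")
  }))
  m <- assemble_matrix(prof)
  nc <- neighbor_correlation(m)
  expect_equal(nrow(nc), 5L)
  expect_true(all(abs(nc$r_reactivity - 1) < 1e-12))
  expect_true(all(abs(nc$r_background - 1) < 1e-12))
  expect_equal(nc$n_common, 25:29) # 3'-most position of the longer omitted

  # pairs spanning an excluded band are absent
  prof2 <- make_random_profiles(120:130)
  m2 <- assemble_matrix(prof2, excluded_lengths = 125:130)
  nc2 <- neighbor_correlation(m2)
  expect_false(any(nc2$n == 124L))
  expect_true(all(nc2$n %in% 120:123))

  # fewer than 3 common defined positions flags NA
  tiny <- make_random_profiles(2:4, mask_frac = 0)
  m3 <- assemble_matrix(tiny)
  nc3 <- neighbor_correlation(m3)
  expect_true(is.na(nc3$r_reactivity[nc3$n == 2])) # only 2 common positions
})

test_that("added independent noise attenuates neighbor correlation", {
  set.seed(106)
  truth <- runif(40)
  mk <- function(noise_sd) {
    prof <- dplyr::bind_rows(lapply(30:40, function(n) {
      tibble::tibble(length_n = n, position = seq_len(n), nt = "A",
                     mod_depth = 1000L, mod_events = 0L, unt_depth = 1000L,
                     unt_events = 0L, mod_rate = 0, unt_rate = 0,
                     reactivity = truth[seq_len(n)] +
                       rnorm(n, sd = noise_sd), mask = "ok")
    }))
    assemble_matrix(prof)
  }
  clean <- neighbor_correlation(mk(0))
  noisy <- neighbor_correlation(mk(0.3))
  expect_true(all(clean$r_reactivity >= noisy$r_reactivity))
})

test_that("tidy and glance methods expose matrices and reports as tibbles", {
  set.seed(107)
  prof <- make_random_profiles(8:12)
  m <- assemble_matrix(prof)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("length_n", "position", "reactivity", "depth") %in%
                    names(td)))
  expect_equal(nrow(td), length(m$lengths) * length(m$positions))

  rep_ <- replicate_correlation(m, m)
  gl <- glance(rep_)
  expect_s3_class(gl, "tbl_df")
  expect_equal(gl$r, 1)
  expect_s3_class(tidy(rep_), "tbl_df")
})

test_that("heatmap and QC plots build deterministically", {
  set.seed(108)
  prof <- make_random_profiles(8:30)
  m <- assemble_matrix(prof)
  p1 <- autoplot(m)
  p2 <- autoplot(m)
  expect_s3_class(p1, "ggplot")
  b1 <- ggplot2::ggplot_build(p1)$data
  b2 <- ggplot2::ggplot_build(p2)$data
  expect_identical(b1, b2) # deterministic for fixed input and scale
  expect_equal(length(unique(b1[[1]]$y)), length(m$lengths)) # one band per row

  empty <- structure(list(layers = list(), lengths = integer(0),
                          positions = integer(0), excluded = integer(0)),
                     class = "cotrans_matrix")
  expect_error(autoplot(empty), "empty")

  path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(m, path)
  expect_true(file.size(path) > 0)

  rep_ <- replicate_correlation(m, m)
  expect_s3_class(plot_replicate_hexbin(rep_), "ggplot")
  expect_s3_class(plot_neighbor_violin(neighbor_correlation(m)), "ggplot")
})
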