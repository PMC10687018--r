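# Independent reference implementations used to check the package's fast
# paths, plus small fixture builders. These deliberately use different
# algorithms (exhaustive enumeration, textbook formulas) from the code they
# verify.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# ---- Pearson r, from-scratch two-pass formula -------------------------------
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ---- exhaustive overlap-alignment score (score only) ------------------------
# Same scoring model as the package aligner (gap of length k costs
# go + k * ge), written as an independent dense DP over all three states.
oracle_align_score <- function(read, target, match = 2, mismatch = -3,
                               go = 5, ge = 2) {
  r <- strsplit(read, "")[[1]]; t <- strsplit(target, "")[[1]]
  m <- length(r); n <- length(t)
  M <- matrix(-Inf, m + 1, n + 1); X <- M; Y <- M
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (r[i - 1] == t[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - ge)
      Y[i, j] <- max(M[i - 1, j] - go - ge, Y[i - 1, j] - ge)
    }
  }
  max(M[m + 1, ], X[m + 1, ], Y[m + 1, ], M[, n + 1], X[, n + 1], Y[, n + 1])
}

# ---- brute-force edit-distance-1 end-index ----------------------------------
# Enumerates EVERY string of length k-1, k, k+1 over ACGT and assigns it by
# Levenshtein distance to the native end k-mers, independently of how the
# package constructs its variant table.
all_strings <- function(len) {
  if (len == 0L) return("")
  do.call(paste0, expand.grid(rep(list(BASES), len),
                              stringsAsFactors = FALSE))
}

oracle_end_index <- function(natives, lengths, end_len) {
  stopifnot(!anyDuplicated(natives))
  cands <- unlist(lapply((end_len - 1L):(end_len + 1L), all_strings))
  d <- utils::adist(cands, natives) # Levenshtein distance matrix
  entries <- list(); ambiguous <- character(0)
  for (i in seq_along(cands)) {
    s <- cands[i]
    exact <- which(d[i, ] == 0L)
    if (length(exact) == 1L) {
      entries[[length(entries) + 1L]] <-
        data.frame(key = s, length_n = lengths[exact], match_class = "native")
      next
    }
    close1 <- which(d[i, ] == 1L)
    if (length(close1) == 1L) {
      cls <- switch(as.character(nchar(s) - end_len),
                    "-1" = "deletion", "0" = "substitution", "1" = "insertion")
      entries[[length(entries) + 1L]] <-
        data.frame(key = s, length_n = lengths[close1], match_class = cls)
    } else if (length(close1) > 1L) {
      ambiguous <- c(ambiguous, s)
    }
  }
  list(entries = do.call(rbind, entries), ambiguous = ambiguous)
}

# ---- brute-force suffix/prefix adapter trimming -----------------------------
oracle_trim <- function(seq, adapter, min_overlap, max_mm_frac) {
  m <- nchar(seq)
  for (k in seq(min(m, nchar(adapter)), min_overlap)) {
    if (k < min_overlap) break
    suf <- strsplit(substr(seq, m - k + 1L, m), "")[[1]]
    pre <- strsplit(substr(adapter, 1L, k), "")[[1]]
    if (sum(suf != pre) <= floor(max_mm_frac * k)) {
      return(substr(seq, 1L, m - k))
    }
  }
  seq
}

# ---- brute-force pair merging over all offsets ------------------------------
# Returns the chosen overlap length (0 = unmergeable) by scanning every
# offset and applying the stated selection rule.
oracle_merge_overlap <- function(s5, s3, min_overlap, max_mm_frac) {
  n5 <- nchar(s5); n3 <- nchar(s3)
  best <- c(matches = -1, olap = 0, L = 0)
  for (o in seq(min_overlap, min(n5, n3))) {
    if (o < min_overlap) next
    a <- strsplit(substr(s5, n5 - o + 1L, n5), "")[[1]]
    b <- strsplit(substr(s3, 1L, o), "")[[1]]
    mm <- sum(a != b); mat <- o - mm
    if (mm / o > max_mm_frac) next
    L <- n5 + n3 - o
    if (mat > best["matches"] ||
        (mat == best["matches"] &&
         (o > best["olap"] || (o == best["olap"] && L < best["L"])))) {
      best <- c(matches = mat, olap = o, L = L)
    }
  }
  unname(best["olap"])
}

# ---- random reactivity profiles for matrix fixtures -------------------------
make_random_profiles <- function(lengths, mask_frac = 0.1) {
  do.call(rbind, lapply(lengths, function(n) {
    pos <- seq_len(n)
    mask <- ifelse(runif(n) < mask_frac, "low_depth", "ok")
    data.frame(length_n = n, position = pos,
               nt = sample(BASES, n, replace = TRUE),
               mod_depth = 1000L, mod_events = rbinom(n, 1000L, 0.05),
               unt_depth = 1000L, unt_events = rbinom(n, 1000L, 0.01),
               mod_rate = NA_real_, unt_rate = NA_real_,
               reactivity = NA_real_, mask = mask)
  })) |>
    dplyr::mutate(mod_rate = mod_events / mod_depth,
                  unt_rate = unt_events / unt_depth,
                  reactivity = ifelse(mask == "ok", mod_rate - unt_rate,
                                      NA_real_)) |>
    tibble::as_tibble()
}

# A small simulated run shared by several tests.
make_toy_sim <- function(target_len = 60, min_len = 40, max_len = 50,
                         reads_per_length = 150, seed = 7, seq_seed = 42, ...) {
  set.seed(seq_seed)
  tseq <- random_seq(target_len)
  cfg <- sim_config(tseq, min_len = min_len, max_len = max_len,
                    reads_per_length = reads_per_length, ...)
  simulate_library(cfg, seed = seed)
}
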