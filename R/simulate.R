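#' Simulation configuration
#'
#' Describes a synthetic variable-length cotranscriptional probing library
#' with known ground truth. The library architecture mirrors the real assay:
#' read 1 carries a 9-nt UMI followed by the reverse complement of the RNA 3'
#' end; read 2 carries a 5-nt degenerate channel barcode (`RRRYY` modified /
#' `YYYRR` untreated) followed by the leader and the transcript 5' end;
#' chemical adducts are encoded as cDNA mutations; the transcript-length
#' distribution carries roadblock-enriched and non-enriched (zero-weight)
#' bands.
#'
#' @param target_seq,leader Construct sequences (leader defaults to the two
#'   initiating nucleotides plus a 14-nt 5' structure cassette).
#' @param min_len,max_len Transcript length range.
#' @param reads_per_length Reads per (channel, length) at weight 1.
#' @param excluded_lengths Non-enriched lengths (weight forced to 0).
#' @param length_weights Optional per-length read-count weights (named by
#'   length or a vector over `min_len:max_len`); default 1.
#' @param p_mod Per-target-position adduct probability in the modified
#'   channel; default marks every third position as reactive at
#'   `p_bg + reactive_delta`.
#' @param p_bg Background probability, shared by both channels (scalar or
#'   per-position).
#' @param reactive_delta Reactivity increment used by the default `p_mod`.
#' @param encode_mix Fractions (substitution, insertion, deletion) by which an
#'   adduct is encoded; adduct-to-mutation encoding is certain (one adduct,
#'   one event). Substitutions are the default because they map to a single
#'   position; indel encoding is exercised by dedicated tests.
#' @param seq_error Independent per-base sequencing error rate on both reads.
#' @param read_len Read length (both mates).
#' @param umi_len,barcode_len,patterns,adapter1,adapter2 Library structure;
#'   must match the demultiplexing configuration.
#' @param qual_hi,qual_lo,frac_lo Quality model: constant Phred `qual_hi`
#'   with a fraction `frac_lo` of Phred `qual_lo` bases to exercise the
#'   quality gate.
#' @param name Run name used in read ids.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(target_seq, leader = "atGGCCTTCGGGCCAA",
                       min_len, max_len,
                       reads_per_length = 500L,
                       excluded_lengths = integer(0),
                       length_weights = NULL,
                       p_mod = NULL, p_bg = 0.01, reactive_delta = 0.04,
                       encode_mix = c(substitution = 1, insertion = 0,
                                      deletion = 0),
                       seq_error = 0.001, read_len = 150L,
                       umi_len = 9L, barcode_len = 5L,
                       patterns = c(modified = "RRRYY", untreated = "YYYRR"),
                       adapter1 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter2 = "GATCGTCGGACTGTAGAACTCTGAAC",
                       qual_hi = 38L, qual_lo = 15L, frac_lo = 0,
                       name = "sim") {
  target_seq <- toupper(normalize_seq(target_seq, "target_seq"))
  leader <- tolower(normalize_seq(leader, "leader"))
  L <- nchar(target_seq)
  if (min_len < 1L || min_len > max_len || max_len > L) {
    abort("transcript length range inconsistent with target_seq")
  }
  if (length(p_bg) == 1L) p_bg <- rep(p_bg, L)
  if (is.null(p_mod)) {
    p_mod <- p_bg
    reactive <- seq(3L, L, by = 3L)
    p_mod[reactive] <- p_bg[reactive] + reactive_delta
  }
  stopifnot(length(p_mod) == L, length(p_bg) == L)
  if (any(p_mod < 0 | p_mod > 1 | p_bg < 0 | p_bg > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (any(p_mod < p_bg)) abort("p_mod must be >= p_bg elementwise")
  lens <- seq.int(min_len, max_len)
  if (is.null(length_weights)) {
    w <- rep(1, length(lens))
  } else if (!is.null(names(length_weights))) {
    w <- rep(1, length(lens))
    w[match(as.integer(names(length_weights)), lens)] <- length_weights
  } else {
    stopifnot(length(length_weights) == length(lens))
    w <- length_weights
  }
  if (any(w < 0)) abort("length weights must be >= 0")
  w[lens %in% as.integer(excluded_lengths)] <- 0
  mix <- encode_mix / sum(encode_mix)
  structure(list(
    target_seq = target_seq, leader = leader,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    reads_per_length = reads_per_length,
    excluded_lengths = as.integer(excluded_lengths),
    length_weights = setNames(w, lens),
    p_mod = p_mod, p_bg = p_bg, encode_mix = mix,
    seq_error = seq_error, read_len = as.integer(read_len),
    umi_len = as.integer(umi_len), barcode_len = as.integer(barcode_len),
    patterns = patterns, adapter1 = adapter1, adapter2 = adapter2,
    qual_hi = as.integer(qual_hi), qual_lo = as.integer(qual_lo),
    frac_lo = frac_lo, name = name
  ), class = "sim_config")
}

# Substitute random different bases at (row, col) index pairs of a char matrix.
substitute_bases <- function(mat, idx) {
  if (nrow(idx) == 0L) return(mat)
  cur <- mat[idx]
  mat[idx] <- ALT_BASES[cbind(match(cur, DNA_BASES),
                              sample.int(3L, nrow(idx), replace = TRUE))]
  mat
}

# Apply independent per-base substitution errors at rate e to each string.
apply_seq_errors <- function(seqs, e) {
  if (e <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, e)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- ALT_BASES[cbind(match(ch[pos], DNA_BASES),
                               sample.int(3L, n_err[i], replace = TRUE))]
    # non-ACGT characters (none expected) would yield NA; guard:
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Quality strings: constant qual_hi with a frac_lo fraction of qual_lo bases.
make_quals <- function(lens, qual_hi, qual_lo, frac_lo) {
  q <- strrep(intToUtf8(qual_hi + 33L), lens)
  if (frac_lo > 0) {
    n_lo <- rbinom(length(lens), lens, frac_lo)
    hit <- which(n_lo > 0L)
    lo <- intToUtf8(qual_lo + 33L)
    for (i in hit) {
      pos <- sample.int(lens[i], n_lo[i])
      ch <- strsplit(q[i], "")[[1]]
      ch[pos] <- lo
      q[i] <- paste(ch, collapse = "")
    }
  }
  q
}

#' Simulate a cotranscriptional probing library with ground truth
#'
#' For each (channel, length, read): adducts are drawn per position (`p_mod`
#' or `p_bg` on target-region positions, `p_bg` on the leader for both
#' channels), each adduct is encoded as one mutation event per the encoding
#' mix, independent sequencing errors are added to both mates, and the pair is
#' emitted as read 1 = UMI + reverse complement of the mutated molecule and
#' read 2 = a concrete barcode drawn from the channel's degenerate pattern +
#' the mutated molecule from its 5' end, both padded with adapter and
#' truncated to the read length.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; fixes the full output.
#' @return Object of class `cotrans_sim`: `pairs` (tibble `id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`), `truth` (`reads`: per-read channel, true
#'   length, UMI and encoded event positions in full-RNA coordinates;
#'   `rates`: per (channel, length, position) expected event probability),
#'   `targets`, and `config`.
#' @export
simulate_library <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  targets <- build_intermediate_targets(config$target_seq, config$leader,
                                        config$min_len, config$max_len)
  ll <- nchar(config$leader)
  lens <- targets$length_n
  channels <- c("modified", "untreated")

  # leader positions carry the background rate in both channels
  p_leader <- rep(mean(config$p_bg), ll)
  p_full <- list(modified = c(p_leader, config$p_mod),
                 untreated = c(p_leader, config$p_bg))

  mix <- config$encode_mix
  types <- c("substitution", "insertion", "deletion")

  all_pairs <- vector("list", 2L * length(lens))
  all_truth <- vector("list", 2L * length(lens))
  k <- 0L
  for (ch in channels) {
    for (n in lens) {
      k <- k + 1L
      w <- config$length_weights[[as.character(n)]]
      n_reads <- as.integer(round(config$reads_per_length * w))
      if (n_reads == 0L) next
      full <- toupper(targets$full_rna[targets$length_n == n])
      L <- nchar(full)
      p <- p_full[[ch]][seq_len(L)]
      base <- strsplit(full, "")[[1]]
      mat <- matrix(rep(base, each = n_reads), nrow = n_reads)
      adduct <- matrix(runif(n_reads * L) < rep(p, each = n_reads),
                       nrow = n_reads)
      hits <- which(adduct, arr.ind = TRUE)
      type <- if (nrow(hits) > 0L) {
        sample(types, nrow(hits), replace = TRUE, prob = mix)
      } else character(0)

      sub_idx <- hits[type == "substitution", , drop = FALSE]
      mat <- substitute_bases(mat, sub_idx)
      mols <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))

      # indel encodings are applied per read, 3' to 5' to keep coordinates
      indel_rows <- unique(hits[type != "substitution", "row"])
      for (r in indel_rows) {
        sel <- which(hits[, "row"] == r & type != "substitution")
        sel <- sel[order(hits[sel, "col"], decreasing = TRUE)]
        s <- mols[r]
        for (q in sel) {
          pos <- hits[q, "col"]
          if (type[q] == "deletion") {
            s <- paste0(str_sub(s, 1L, pos - 1L), str_sub(s, pos + 1L))
          } else {
            s <- paste0(str_sub(s, 1L, pos),
                        sample(DNA_BASES, 1L),
                        str_sub(s, pos + 1L))
          }
        }
        mols[r] <- s
      }

      umi <- random_dna(n_reads, config$umi_len)
      barcode <- sample_iupac(config$patterns[[ch]], n_reads)
      r1 <- str_sub(paste0(umi, revcomp(mols), config$adapter1),
                    1L, config$read_len)
      r2 <- str_sub(paste0(barcode, mols, config$adapter2),
                    1L, config$read_len)
      r1 <- apply_seq_errors(r1, config$seq_error)
      r2 <- apply_seq_errors(r2, config$seq_error)

      ids <- sprintf("%s_%s_%d_%06d", config$name, ch, n, seq_len(n_reads))
      ev <- rep("", n_reads)
      if (nrow(hits) > 0L) {
        agg <- tapply(hits[, "col"], hits[, "row"],
                      function(x) paste(sort(x), collapse = ","))
        ev[as.integer(names(agg))] <- unname(agg)
      }
      all_pairs[[k]] <- tibble(
        id = ids, seq1 = r1,
        qual1 = make_quals(nchar(r1), config$qual_hi, config$qual_lo,
                           config$frac_lo),
        seq2 = r2,
        qual2 = make_quals(nchar(r2), config$qual_hi, config$qual_lo,
                           config$frac_lo))
      all_truth[[k]] <- tibble(id = ids, channel = ch, length_n = n,
                               umi = umi, event_positions = ev)
    }
  }

  rates <- list_rbind(map(channels, function(ch) {
    list_rbind(map(lens, function(n) {
      tibble(channel = ch, length_n = n, position = seq_len(ll + n),
             p_event = p_full[[ch]][seq_len(ll + n)])
    }))
  }))

  structure(list(
    pairs = list_rbind(all_pairs),
    truth = list(reads = list_rbind(all_truth), rates = rates),
    targets = targets, config = config
  ), class = "cotrans_sim")
}

#' Write a simulated library to FASTQ and truth files
#'
#' Emits gzipped R1/R2 FASTQ, per-read and per-position truth TSVs, and a
#' plain-text echo of the configuration for provenance.
#'
#' @param sim A [simulate_library()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_sim_fastq <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- sim$config$name
  r1 <- file.path(dir, paste0(nm, "_R1.fastq.gz"))
  r2 <- file.path(dir, paste0(nm, "_R2.fastq.gz"))
  write_fastq(sim$pairs$id, sim$pairs$seq1, sim$pairs$qual1, r1)
  write_fastq(sim$pairs$id, sim$pairs$seq2, sim$pairs$qual2, r2)
  tr <- file.path(dir, paste0(nm, "_truth_reads.tsv"))
  tp <- file.path(dir, paste0(nm, "_truth_rates.tsv"))
  readr::write_tsv(sim$truth$reads, tr)
  readr::write_tsv(sim$truth$rates, tp)
  cfg <- file.path(dir, paste0(nm, "_config.toml"))
  flat <- sim$config[!vapply(sim$config, is.null, logical(1))]
  writeLines(vapply(names(flat), function(k) {
    v <- flat[[k]]
    val <- if (is.character(v)) {
      paste0("[", paste(sprintf('"%s"', v), collapse = ", "), "]")
    } else {
      paste0("[", paste(format(v, digits = 12), collapse = ", "), "]")
    }
    if (length(v) == 1L) {
      val <- if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 12)
    }
    sprintf("%s = %s", k, val)
  }, character(1)), cfg)
  invisible(c(r1 = r1, r2 = r2, truth_reads = tr, truth_rates = tp,
              config = cfg))
}

#' Generate native or randomized 3' end test queries
#'
#' Native mode emits each native end k-mer `per_length` times; randomized mode
#' emits queries mutated by exactly one random substitution, insertion or
#' deletion, labelled with the true length and the applied edit.
#'
#' @param index An [build_end_index()] object.
#' @param mode `"native"` or `"randomized"`.
#' @param per_length Queries per transcript length.
#' @param seed Optional seed.
#' @return Tibble `query`, `true_length`, `edit` (`native` or the edit class),
#'   `edit_pos`.
#' @export
make_end_test_reads <- function(index, mode = c("native", "randomized"),
                                per_length = 1L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  natives <- index$entries |> filter(.data$match_class == "native")
  out <- natives[rep(seq_len(nrow(natives)), each = per_length), ]
  query <- out$key
  edit <- rep("native", length(query))
  edit_pos <- rep(NA_integer_, length(query))
  if (mode == "randomized") {
    k <- nchar(query)
    edit <- sample(c("substitution", "insertion", "deletion"),
                   length(query), replace = TRUE)
    edit_pos <- integer(length(query))
    for (i in seq_along(query)) {
      if (edit[i] == "substitution") {
        pos <- sample.int(k[i], 1L)
        cur <- str_sub(query[i], pos, pos)
        str_sub(query[i], pos, pos) <- sample(setdiff(DNA_BASES, cur), 1L)
      } else if (edit[i] == "deletion") {
        pos <- sample.int(k[i], 1L)
        query[i] <- paste0(str_sub(query[i], 1L, pos - 1L),
                           str_sub(query[i], pos + 1L))
      } else {
        pos <- sample.int(k[i] + 1L, 1L) - 1L  # gap index 0..k
        query[i] <- paste0(str_sub(query[i], 1L, pos),
                           sample(DNA_BASES, 1L),
                           str_sub(query[i], pos + 1L))
      }
      edit_pos[i] <- pos
    }
  }
  tibble(query = query, true_length = out$length_n, edit = edit,
         edit_pos = edit_pos)
}

#' Compare pipeline output against simulation truth
#'
#' @param sim A [simulate_library()] result.
#' @param demux A [demultiplex()] result for `sim$pairs`.
#' @param counts Optional count tables from [profile_run()] for rate
#'   recovery assessment.
#' @param tolerances List with `min_accuracy` and `max_rate_rmse`.
#' @return Object of class `truth_report`: overall and per-(channel, length)
#'   demultiplexing accuracy, per-position rate bias/RMSE (when `counts` is
#'   given), and pass/fail flags.
#' @export
truth_compare <- function(sim, demux, counts = NULL,
                          tolerances = list(min_accuracy = 0.99,
                                            max_rate_rmse = 0.02)) {
  truth <- sim$truth$reads
  rec <- demux$records
  if (!all(rec$id %in% truth$id)) {
    abort("demultiplexed records contain ids absent from the simulation truth")
  }
  joined <- truth |>
    left_join(rec |> select("id", assigned_channel = "channel",
                            assigned_length = "length_n"),
              by = "id") |>
    mutate(correct = !is.na(.data$assigned_length) &
             .data$assigned_channel == .data$channel &
             .data$assigned_length == .data$length_n)
  accuracy <- mean(joined$correct)
  by_bin <- joined |>
    group_by(.data$channel, .data$length_n) |>
    summarise(n = n(), accuracy = mean(.data$correct), .groups = "drop")

  rate_summary <- NULL
  if (!is.null(counts)) {
    est <- counts |>
      mutate(rate = ifelse(.data$depth > 0, .data$events / .data$depth,
                           NA_real_)) |>
      inner_join(sim$truth$rates,
                 by = c("channel", "length_n", "position")) |>
      filter(!is.na(.data$rate))
    rate_summary <- est |>
      group_by(.data$channel) |>
      summarise(n_positions = n(),
                bias = mean(.data$rate - .data$p_event),
                rmse = sqrt(mean((.data$rate - .data$p_event)^2)),
                .groups = "drop")
  }
  pass <- tibble(
    check = c("demux_accuracy",
              if (!is.null(rate_summary)) "rate_rmse"),
    pass = c(accuracy >= tolerances$min_accuracy,
             if (!is.null(rate_summary))
               all(rate_summary$rmse <= tolerances$max_rate_rmse))
  )
  structure(list(accuracy = accuracy, by_bin = by_bin,
                 rate_summary = rate_summary, pass = pass,
                 tolerances = tolerances),
            class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat(sprintf("<truth_report> demux accuracy %.4f over %d bins\n",
              x$accuracy, nrow(x$by_bin)))
  if (!is.null(x$rate_summary)) {
    for (i in seq_len(nrow(x$rate_summary))) {
      cat(sprintf("  %s: rate bias %+.5f, RMSE %.5f (%d positions)\n",
                  x$rate_summary$channel[i], x$rate_summary$bias[i],
                  x$rate_summary$rmse[i], x$rate_summary$n_positions[i]))
    }
  }
  cat(sprintf("  checks passed: %d/%d\n", sum(x$pass$pass), nrow(x$pass)))
  invisible(x)
}
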