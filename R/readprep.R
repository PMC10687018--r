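#' Read a paired-end FASTQ library into a tibble
#'
#' @param r1,r2 Paths to the read-1 and read-2 FASTQ files (plain or gzip).
#' @return Tibble with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  rd <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    tibble(id = sub("\\s.*$", "", names(x)),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  a <- rd(r1); b <- rd(r2)
  if (nrow(a) != nrow(b) || any(a$id != b$id)) {
    abort("read 1 and read 2 files are not paired (id mismatch)")
  }
  tibble(id = a$id, seq1 = a$seq, qual1 = a$qual, seq2 = b$seq, qual2 = b$qual)
}

#' Write sequences and qualities to a FASTQ file
#'
#' @param id,seq,qual Character vectors of equal length.
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(setNames(seq, id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplexing configuration
#'
#' Defaults follow the library architecture: a 9-nt unique molecular
#' identifier at the head of read 1, a 5-nt degenerate channel barcode at the
#' head of read 2 (`RRRYY` = chemically modified, `YYYRR` = untreated,
#' complementary at every position so exact matching cannot cross-talk), and a
#' 14-nt 3' end window for transcript-length inference.
#'
#' @param umi_len UMI length at the head of read 1 (0 disables extraction).
#' @param barcode_len Channel barcode length at the head of read 2.
#' @param end_len 3' end window length; must match the index.
#' @param adapter1,adapter2 Adapter sequences clipped from the 3' ends of
#'   reads 1 and 2.
#' @param trim_min_overlap,trim_max_mismatch_frac Adapter-match thresholds.
#' @param patterns Named IUPAC barcode patterns; names are channel labels.
#' @param dedup_umi Collapse exact duplicate UMIs within each
#'   (channel, length) bin (off by default; UMIs are recorded regardless).
#' @return A list of class `demux_config`.
#' @export
demux_config <- function(umi_len = 9L, barcode_len = 5L, end_len = 14L,
                         adapter1 = "TGGAATTCTCGGGTGCCAAGG",
                         adapter2 = "GATCGTCGGACTGTAGAACTCTGAAC",
                         trim_min_overlap = 4L, trim_max_mismatch_frac = 0.2,
                         patterns = c(modified = "RRRYY", untreated = "YYYRR"),
                         dedup_umi = FALSE) {
  structure(list(umi_len = as.integer(umi_len),
                 barcode_len = as.integer(barcode_len),
                 end_len = as.integer(end_len),
                 adapter1 = adapter1, adapter2 = adapter2,
                 trim_min_overlap = as.integer(trim_min_overlap),
                 trim_max_mismatch_frac = trim_max_mismatch_frac,
                 patterns = patterns, dedup_umi = dedup_umi),
            class = "demux_config")
}

#' Trim 3' adapters from read pairs
#'
#' Removes from each read the longest suffix that matches a prefix of its
#' adapter with at least `min_overlap` bases and a mismatch fraction at most
#' `max_mismatch_frac`; qualities are truncated in lock-step. Reads without a
#' qualifying match pass through unchanged.
#'
#' @param pairs Tibble as returned by [read_fastq_pair()].
#' @param adapter1,adapter2 Adapter sequences for reads 1 and 2.
#' @param min_overlap Minimum suffix/prefix overlap.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the overlap.
#' @return `pairs` with trimmed `seq*`/`qual*` and logical columns `trimmed1`,
#'   `trimmed2`.
#' @export
trim_adapters <- function(pairs, adapter1, adapter2, min_overlap = 4L,
                          max_mismatch_frac = 0.2) {
  stopifnot(nzchar(adapter1), nzchar(adapter2),
            max_mismatch_frac >= 0, max_mismatch_frac < 0.5)
  k1 <- .cpp_trim_adapter(pairs$seq1, adapter1, min_overlap, max_mismatch_frac)
  k2 <- .cpp_trim_adapter(pairs$seq2, adapter2, min_overlap, max_mismatch_frac)
  pairs |>
    mutate(trimmed1 = k1 < str_length(.data$seq1),
           trimmed2 = k2 < str_length(.data$seq2),
           seq1 = str_sub(.data$seq1, 1L, k1),
           qual1 = str_sub(.data$qual1, 1L, k1),
           seq2 = str_sub(.data$seq2, 1L, k2),
           qual2 = str_sub(.data$qual2, 1L, k2))
}

#' Extract the unique molecular identifier from read 1
#'
#' @param pairs Tibble with `seq1`/`qual1` columns.
#' @param umi_len UMI length (0 disables; `umi` becomes `""`).
#' @param end_len End-window length used downstream; reads shorter than
#'   `umi_len + end_len` are flagged `too_short`.
#' @return `pairs` with new columns `umi` and `too_short`, and the UMI removed
#'   from `seq1`/`qual1`.
#' @export
extract_umi <- function(pairs, umi_len = 9L, end_len = 14L) {
  too_short <- str_length(pairs$seq1) < umi_len + end_len
  pairs |>
    mutate(umi = str_sub(.data$seq1, 1L, umi_len),
           seq1 = str_sub(.data$seq1, umi_len + 1L),
           qual1 = str_sub(.data$qual1, umi_len + 1L),
           too_short = too_short)
}

#' Extract the chemical-probing channel barcode from read 2
#'
#' The first `barcode_len` bases of read 2 are matched against the degenerate
#' IUPAC patterns; a head matching exactly one pattern assigns that channel,
#' anything else is `unassigned`.
#'
#' @param pairs Tibble with `seq2`/`qual2` columns.
#' @param barcode_len Barcode length.
#' @param patterns Named character vector of IUPAC patterns.
#' @return `pairs` with new column `channel` and the barcode removed from
#'   `seq2`/`qual2`.
#' @export
extract_channel <- function(pairs, barcode_len = 5L,
                            patterns = c(modified = "RRRYY",
                                         untreated = "YYYRR")) {
  head_ <- str_sub(pairs$seq2, 1L, barcode_len)
  hits <- matrix(vapply(patterns, function(p) iupac_match(head_, p),
                        logical(nrow(pairs))),
                 nrow = nrow(pairs),
                 dimnames = list(NULL, names(patterns)))
  n_hit <- rowSums(hits)
  channel <- rep("unassigned", nrow(pairs))
  for (ch in names(patterns)) {
    channel[n_hit == 1L & hits[, ch]] <- ch
  }
  channel[str_length(head_) < barcode_len] <- "unassigned"
  pairs |>
    mutate(channel = channel,
           seq2 = str_sub(.data$seq2, barcode_len + 1L),
           qual2 = str_sub(.data$qual2, barcode_len + 1L))
}

#' Demultiplex read pairs by channel and transcript length
#'
#' Runs the full pre-processing cascade per pair: adapter trimming, UMI
#' extraction (read 1), channel-barcode extraction (read 2), then transcript
#' length classification by probing the head of the read-1 remainder against
#' the 3' end index at the native window size first, then the deletion
#' (`end_len - 1`) and insertion (`end_len + 1`) window sizes — the
#' parsimonious call wins. Reads failing any gate are routed to the reject
#' stream with a reason; no quality-based rejection happens here (quality is
#' applied at mutation counting).
#'
#' @param pairs Tibble from [read_fastq_pair()] (or a simulated library).
#' @param index An [build_end_index()] object with `read1` orientation.
#' @param config A [demux_config()].
#' @return List with `records` (assigned reads: `id`, `umi`, `channel`,
#'   `length_n`, `match_class`, trimmed payload `seq1`/`qual1`/`seq2`/`qual2`),
#'   `rejects` (with `reason`), and `stats` (tibble `metric`, `count`).
#' @export
demultiplex <- function(pairs, index, config = demux_config()) {
  stopifnot(inherits(index, "end_target_index"))
  if (index$orientation != "read1") {
    abort("demultiplex() requires an index built with orientation = 'read1'")
  }
  if (config$end_len != index$end_len) {
    abort("config end_len does not match the index")
  }
  total <- nrow(pairs)
  pairs <- trim_adapters(pairs, config$adapter1, config$adapter2,
                         config$trim_min_overlap, config$trim_max_mismatch_frac)
  n_trimmed <- sum(pairs$trimmed1 | pairs$trimmed2)
  pairs <- extract_umi(pairs, config$umi_len, config$end_len)
  pairs <- extract_channel(pairs, config$barcode_len, config$patterns)

  el <- index$end_len
  match_class <- rep("unmatched", nrow(pairs))
  length_n <- rep(NA_integer_, nrow(pairs))
  todo <- !pairs$too_short
  for (w in c(el, el - 1L, el + 1L)) {       # native, deletion, insertion
    if (!any(todo)) break
    ok <- todo & str_length(pairs$seq1) >= w
    if (!any(ok)) next
    res <- classify_end(str_sub(pairs$seq1[ok], 1L, w), index)
    hit <- res$match_class != "unmatched"
    idx <- which(ok)[hit]
    match_class[idx] <- res$match_class[hit]
    length_n[idx] <- res$length_n[hit]
    todo[idx] <- FALSE
  }

  reason <- rep(NA_character_, nrow(pairs))
  reason[match_class == "unmatched"] <- "unmatched"
  reason[match_class == "ambiguous"] <- "ambiguous"
  reason[pairs$channel == "unassigned"] <- "unassigned_channel"
  reason[pairs$too_short] <- "too_short"

  out <- pairs |>
    mutate(length_n = length_n, match_class = match_class, reason = reason) |>
    select("id", "umi", "channel", "length_n", "match_class", "reason",
           "seq1", "qual1", "seq2", "qual2")
  records <- out |> filter(is.na(.data$reason)) |> select(-"reason")
  rejects <- out |> filter(!is.na(.data$reason))

  n_collapsed <- 0L
  if (isTRUE(config$dedup_umi)) {
    before <- nrow(records)
    records <- records |>
      distinct(.data$channel, .data$length_n, .data$umi, .keep_all = TRUE)
    n_collapsed <- before - nrow(records)
  }

  cls <- c("native", "substitution", "insertion", "deletion")
  stats <- tibble(
    metric = c("total", "adapter_trimmed",
               paste0("channel_", names(config$patterns)),
               paste0("class_", cls),
               "too_short", "unassigned_channel", "ambiguous", "unmatched",
               "rejected", "assigned", "umi_collapsed"),
    count = unname(c(total, n_trimmed,
                     vapply(names(config$patterns),
                            function(ch) sum(records$channel == ch),
                            integer(1)),
                     vapply(cls, function(cl) sum(records$match_class == cl),
                            integer(1)),
                     sum(rejects$reason == "too_short"),
                     sum(rejects$reason == "unassigned_channel"),
                     sum(rejects$reason == "ambiguous"),
                     sum(rejects$reason == "unmatched"),
                     nrow(rejects), nrow(records), n_collapsed))
  )
  list(records = records, rejects = rejects, stats = stats)
}

#' Write demultiplexed bins as per-bin FASTQ files
#'
#' Files are named `<channel>_<n>nt_R1.fastq.gz` / `_R2.fastq.gz`; the UMI is
#' moved into the read id after a `_UMI:` tag.
#'
#' @param records Assigned records from [demultiplex()].
#' @param dir Output directory.
#' @return Invisibly, a tibble of (channel, length_n, r1, r2) paths.
#' @export
write_demux_bins <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bins <- records |>
    mutate(id = paste0(.data$id, "_UMI:", .data$umi)) |>
    group_by(.data$channel, .data$length_n)
  keys <- bins |> group_keys()
  paths <- bins |>
    group_map(function(df, key) {
      stem <- sprintf("%s_%dnt", key$channel, key$length_n)
      r1 <- file.path(dir, paste0(stem, "_R1.fastq.gz"))
      r2 <- file.path(dir, paste0(stem, "_R2.fastq.gz"))
      write_fastq(df$id, df$seq1, df$qual1, r1)
      write_fastq(df$id, df$seq2, df$qual2, r2)
      tibble(r1 = r1, r2 = r2)
    }) |>
    list_rbind()
  invisible(bind_cols(keys, paths))
}
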