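#' Alignment scoring parameters
#'
#' Semi-global alignment with free end gaps on the read, so that a read pooled
#' from a neighboring transcript length is absorbed as a 1-nt terminal
#' overhang rather than a spurious indel. A gap of length k costs
#' `gap_open + k * gap_ext`. Alignments scoring below
#' `score_floor_frac * match * min(read length, target length)` are discarded
#' as unalignable (and counted).
#'
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (penalties
#'   negative).
#' @param score_floor_frac Fraction of the maximum attainable score required
#'   to keep a read.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_ext = -2, score_floor_frac = 0.5) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, score_floor_frac = score_floor_frac),
            class = "align_params")
}

#' Mutation-profiling configuration
#'
#' The three external-tool thresholds are preserved as defaults: a minimum
#' effective depth of 500 for reporting reactivity, no quality-based pair
#' rejection before counting, and a Phred 25 floor for counting a base call.
#'
#' @param min_qual Minimum Phred score for a base call to contribute to depth
#'   or events.
#' @param merge_gap Mutated alignment columns separated by fewer than this
#'   many matching columns collapse into one event at the 3'-most position.
#' @param min_depth Minimum per-channel effective depth for a reactivity value.
#' @param merge_min_overlap,merge_max_mismatch_frac Read-pair merging
#'   thresholds.
#' @param align An [align_params()] object.
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(min_qual = 25L, merge_gap = 2L, min_depth = 500L,
                           merge_min_overlap = 10L,
                           merge_max_mismatch_frac = 0.1,
                           align = align_params()) {
  structure(list(min_qual = as.integer(min_qual),
                 merge_gap = as.integer(merge_gap),
                 min_depth = as.integer(min_depth),
                 merge_min_overlap = as.integer(merge_min_overlap),
                 merge_max_mismatch_frac = merge_max_mismatch_frac,
                 align = align),
            class = "profile_config")
}

#' Merge a read pair into a single insert
#'
#' Read 1 is reverse-complemented into RNA sense (the 3' piece) and overlapped
#' with read 2 (the 5' piece). Among overlaps of at least `min_overlap` bases
#' with mismatch fraction at most `max_mismatch_frac`, the one with the most
#' matching bases wins (ties to the longer overlap, then the shorter insert).
#' At agreeing positions the merged quality is the maximum; at disagreements
#' the higher-quality base wins with quality equal to the difference.
#'
#' @param seq1,qual1 Read-1 remainder (UMI removed) and qualities.
#' @param seq2,qual2 Read-2 remainder (barcode removed) and qualities.
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return List with `merged` (logical), `seq`, `qual`; when unmergeable,
#'   `seq`/`qual` are empty and the caller falls back to read 1 alone.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                       max_mismatch_frac = 0.1) {
  .cpp_merge_pair(seq2, qual2, revcomp(seq1), stringi::stri_reverse(qual1),
                  as.integer(min_overlap), max_mismatch_frac)
}

#' Align an insert to an intermediate-transcript target
#'
#' @param insert Insert sequence (RNA sense, DNA alphabet).
#' @param target Full target sequence (`full_rna`; case ignored).
#' @param params An [align_params()] object.
#' @return List of class `pairwise_alignment`: `score`, `ops` tibble
#'   (`op` in match/mismatch/insertion/deletion, `tpos`, `rpos`, 1-based;
#'   gap rows carry the left-neighbour coordinate of the non-consumed
#'   sequence), spans `t_start`/`t_end`/`r_start`/`r_end`, and `discarded`
#'   (TRUE when the score is below the floor).
#' @export
align_to_target <- function(insert, target, params = align_params()) {
  target <- toupper(target)
  a <- .cpp_align(toupper(insert), target, params$match, params$mismatch,
                  abs(params$gap_open), abs(params$gap_ext))
  floor_ <- params$score_floor_frac * params$match *
    min(nchar(insert), nchar(target))
  op_labels <- c("match", "mismatch", "insertion", "deletion")
  structure(
    list(score = a$score,
         ops = tibble(op = op_labels[a$ops + 1L], tpos = a$tpos,
                      rpos = a$rpos),
         t_start = a$t_start, t_end = a$t_end,
         r_start = a$r_start, r_end = a$r_end,
         insert = toupper(insert), target = target,
         discarded = a$score < floor_ || length(a$ops) == 0L),
    class = "pairwise_alignment"
  )
}

#' Call quality-filtered mutation events from an alignment
#'
#' Mismatches below `min_qual` are ignored and excluded from that read's
#' depth; indels are left-aligned within homopolymers; mutated columns
#' separated by fewer than `merge_gap` matching columns collapse into one
#' event assigned to the 3'-most mutated target position; end-gap overhangs
#' never produce events.
#'
#' @param aln A [align_to_target()] result.
#' @param qual Phred+33 quality string of the insert.
#' @param min_qual Quality floor for counting.
#' @param merge_gap Event-collapsing window.
#' @return List with `events` (target positions of collapsed events) and
#'   `depth` (target positions at which this read contributes depth).
#' @export
call_mutations <- function(aln, qual, min_qual = 25L, merge_gap = 2L) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  op_codes <- c(match = 0L, mismatch = 1L, insertion = 2L, deletion = 3L)
  .cpp_call_mutations(op_codes[aln$ops$op], aln$ops$tpos, aln$ops$rpos,
                      aln$insert, qual, aln$target,
                      as.integer(min_qual), as.integer(merge_gap))
}

#' Profile one (channel, length) bin
#'
#' Merges each pair, aligns the insert, applies the score floor and quality
#' filters, and accumulates per-position effective depth and collapsed
#' mutation events over the bin's coordinates.
#'
#' Alignment context: by default reads are aligned against `context` rather
#' than the bin's own (truncated) target. Every intermediate transcript is a
#' prefix of the same construct, and aligning against the longest available
#' sequence makes each read's mutation calls independent of which bin it is
#' counted into — a mutation near the RNA 3' end that is ambiguous between a
#' mismatch and a homopolymer indel would otherwise be resolved differently
#' against targets truncated at different lengths. Counting is restricted to
#' positions within the bin's target, so the 3'-terminal position of length n
#' still receives depth only from reads covering it.
#'
#' @param records Demultiplexed records for one bin (may be empty).
#' @param target Full target sequence (`full_rna`) for the bin's length;
#'   defines the counting coordinates.
#' @param config A [profile_config()].
#' @param context Alignment reference; defaults to `target`. Pass the
#'   longest transcript's `full_rna` (as [profile_run()] does) for
#'   bin-independent calls.
#' @param caps Optional per-read counting limit in full-RNA coordinates
#'   (default: the bin target's length). In smoothed bins each read is capped
#'   at the 3' end of its own assigned transcript, so it never contributes
#'   depth beyond the length it is believed to have.
#' @return Tibble `position`, `nt`, `depth`, `events` over the full RNA
#'   coordinates of the bin, with bin accounting in attribute `bin_stats`.
#' @export
profile_bin <- function(records, target, config = profile_config(),
                        context = NULL, caps = NULL) {
  target_u <- toupper(target)
  n <- nchar(target_u)
  nt <- strsplit(target_u, "")[[1]]
  context_u <- if (is.null(context)) target_u else toupper(context)
  if (substr(context_u, 1L, n) != target_u) {
    abort("alignment context must extend the bin's target")
  }
  if (nrow(records) == 0L) {
    warn("empty bin: returning a table of zeros")
    out <- tibble(position = seq_len(n), nt = nt, depth = 0L, events = 0L)
    attr(out, "bin_stats") <- tibble(n_reads = 0L, n_merged = 0L,
                                     n_unmerged = 0L, n_discarded = 0L)
    return(out)
  }
  p <- config$align
  if (is.null(caps)) caps <- n
  res <- .cpp_profile_bin(
    toupper(records$seq2), records$qual2,
    revcomp(toupper(records$seq1)), stringi::stri_reverse(records$qual1),
    context_u, as.integer(caps),
    config$merge_min_overlap, config$merge_max_mismatch_frac,
    p$match, p$mismatch, abs(p$gap_open), abs(p$gap_ext),
    p$score_floor_frac, config$min_qual, config$merge_gap)
  out <- tibble(position = seq_len(n), nt = nt,
                depth = res$depth[seq_len(n)], events = res$events[seq_len(n)])
  attr(out, "bin_stats") <- tibble(n_reads = res$n_reads,
                                   n_merged = res$n_merged,
                                   n_unmerged = res$n_unmerged,
                                   n_discarded = res$n_discarded)
  out
}

#' Profile all demultiplexed bins of a run
#'
#' @param records Assigned records from [demultiplex()]; if `plan` is given
#'   they are first pooled with [pool_reads()] and each pooled bin is aligned
#'   against the target of its window centre.
#' @param targets Targets tibble from [build_intermediate_targets()].
#' @param config A [profile_config()].
#' @param plan Optional [make_plan()] tibble for neighboring-transcript
#'   smoothing at read level.
#' @return Tibble `channel`, `length_n`, `position`, `nt`, `depth`, `events`
#'   covering every (channel, target length) bin, empty bins included.
#' @export
profile_run <- function(records, targets, config = profile_config(),
                        plan = NULL) {
  leader_len <- nchar(targets$full_rna[1]) - targets$length_n[1]
  if (!is.null(plan)) {
    records <- pool_reads(records, plan) |>
      rename(source_n = "length_n", length_n = "pooled_n")
  } else {
    records <- records |> mutate(source_n = .data$length_n)
  }
  channels <- c("modified", "untreated")
  context <- targets$full_rna[which.max(targets$length_n)]
  grid <- expand.grid(channel = channels, length_n = targets$length_n,
                      stringsAsFactors = FALSE)
  list_rbind(map(seq_len(nrow(grid)), function(i) {
    ch <- grid$channel[i]; n <- grid$length_n[i]
    bin <- records |> filter(.data$channel == ch, .data$length_n == n)
    tgt <- targets$full_rna[targets$length_n == n]
    tab <- suppressWarnings(profile_bin(bin, tgt, config, context = context,
                                        caps = leader_len + bin$source_n))
    bind_cols(tibble(channel = ch, length_n = n), tab)
  }))
}

#' Compute a background-subtracted reactivity profile
#'
#' Per target-region position (leader excluded): the mutation rate is
#' events / depth in each channel and reactivity is the modified rate minus
#' the untreated rate — a raw background-subtracted mutation rate, with no
#' SHAPE-style normalization. Positions where either channel is below
#' `min_depth` are masked `low_depth` and carry no reactivity.
#'
#' @param mod,unt Count tables (tibbles `position`, `nt`, `depth`, `events`)
#'   for the modified and untreated channels of one length.
#' @param min_depth Minimum per-channel effective depth.
#' @param leader_len Leader length in nt; leader positions are dropped.
#' @return Tibble `position` (target-region, 1-based), `nt`, `mod_depth`,
#'   `mod_events`, `unt_depth`, `unt_events`, `mod_rate`, `unt_rate`,
#'   `reactivity`, `mask` (`ok` or `low_depth`).
#' @export
compute_reactivity <- function(mod, unt, min_depth = 500L, leader_len) {
  if (nrow(mod) != nrow(unt) || any(mod$position != unt$position)) {
    abort("modified and untreated tables have mismatched coordinates")
  }
  out <- tibble(
    position = mod$position - leader_len,
    nt = mod$nt,
    mod_depth = mod$depth, mod_events = mod$events,
    unt_depth = unt$depth, unt_events = unt$events
  ) |>
    filter(.data$position >= 1L) |>
    mutate(
      mod_rate = ifelse(.data$mod_depth > 0, .data$mod_events / .data$mod_depth,
                        NA_real_),
      unt_rate = ifelse(.data$unt_depth > 0, .data$unt_events / .data$unt_depth,
                        NA_real_),
      mask = ifelse(.data$mod_depth >= min_depth & .data$unt_depth >= min_depth,
                    "ok", "low_depth"),
      reactivity = ifelse(.data$mask == "ok",
                          .data$mod_rate - .data$unt_rate, NA_real_)
    )
  out
}

#' Reactivity profiles for every length of a run
#'
#' @param counts Count tables from [profile_run()] or [pool_counts()].
#' @param min_depth Minimum per-channel effective depth.
#' @param leader_len Leader length in nt.
#' @return Tibble of per-length reactivity profiles with a `length_n` column.
#' @export
reactivity_run <- function(counts, min_depth = 500L, leader_len) {
  lens <- sort(unique(counts$length_n))
  list_rbind(map(lens, function(n) {
    mod <- counts |> filter(.data$channel == "modified", .data$length_n == n) |>
      arrange(.data$position)
    unt <- counts |> filter(.data$channel == "untreated", .data$length_n == n) |>
      arrange(.data$position)
    bind_cols(tibble(length_n = n),
              compute_reactivity(mod, unt, min_depth, leader_len))
  }))
}

#' Write a per-length reactivity profile as TSV
#'
#' @param profile One length's rows from [reactivity_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(
    profile |> select("position", "nt", "mod_depth", "mod_events",
                      "unt_depth", "unt_events", "reactivity", "mask"),
    path)
  invisible(path)
}
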