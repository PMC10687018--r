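#' Neighboring-transcript smoothing plan
#'
#' Neighboring transcripts tend to have similar reactivity patterns and
#' background mutation rates, so pooling reads from lengths n-1, n and n+1
#' boosts the effective sequencing depth of each length while preserving
#' length-dependent reactivity trends. Interior lengths pool
#' `[n - 1, n, n + 1]`; the minimum length pools `[min, min + 1]` and the
#' maximum `[max - 1, max]`.
#'
#' @param min_len,max_len Transcript length bounds, `min_len < max_len`.
#' @return Tibble with `n` and a list-column `sources` of source lengths.
#' @export
make_plan <- function(min_len, max_len) {
  if (min_len >= max_len) abort("min_len must be < max_len")
  n <- seq.int(min_len, max_len)
  tibble(
    n = as.integer(n),
    sources = map(n, function(k) {
      as.integer(intersect((k - 1L):(k + 1L), n))
    })
  )
}

#' Pool read bins across neighboring transcript lengths
#'
#' Each smoothed bin `(channel, n)` is the concatenation of the source bins in
#' plan order; both channels are pooled with the same plan. The input records
#' are not modified.
#'
#' @param records Assigned demultiplexed records (with `length_n`).
#' @param plan A [make_plan()] tibble.
#' @return Records replicated into their smoothing windows, with the target
#'   bin in column `pooled_n` (the original `length_n` is retained).
#' @export
pool_reads <- function(records, plan) {
  miss <- setdiff(unique(records$length_n), plan$n)
  if (length(miss) > 0L) {
    abort(sprintf("plan does not cover lengths: %s", paste(miss, collapse = ", ")))
  }
  long <- plan |> unnest("sources") |> rename(pooled_n = "n")
  empty <- setdiff(plan$n, records$length_n)
  if (length(empty) > 0L) {
    warn(sprintf("empty source bins treated as empty: %s",
                 paste(empty, collapse = ", ")))
  }
  inner_join(long, records, by = c(sources = "length_n"),
             relationship = "many-to-many") |>
    rename(length_n = "sources")
}

#' Pool mutation-count tables across neighboring transcript lengths
#'
#' The fast path equivalent to read-level pooling: per-position depth and
#' mutation events are summed over the source lengths of each smoothing
#' window, restricted to the positions covered by the pooled length's own
#' transcript (a source one nucleotide longer contributes nothing at its
#' 3'-terminal position).
#'
#' @param counts Count tables from [profile_run()]: tibble with `channel`,
#'   `length_n`, `position`, `nt`, `depth`, `events`.
#' @param plan A [make_plan()] tibble.
#' @param leader_len Leader length in nt (positions are on the full RNA).
#' @return Pooled count tables keyed by `channel`, `length_n` (the window
#'   centre) with summed `depth` and `events`.
#' @export
pool_counts <- function(counts, plan, leader_len) {
  long <- plan |> unnest("sources") |> rename(pooled_n = "n")
  pooled <- inner_join(long, counts, by = c(sources = "length_n"),
                       relationship = "many-to-many") |>
    filter(.data$position <= leader_len + .data$pooled_n) |>
    group_by(.data$channel, length_n = .data$pooled_n, .data$position,
             .data$nt) |>
    summarise(depth = sum(.data$depth), events = sum(.data$events),
              .groups = "drop") |>
    arrange(.data$channel, .data$length_n, .data$position)
  if (anyDuplicated(pooled[c("channel", "length_n", "position")]) > 0L) {
    abort("coordinate mismatch: source tables disagree on the nucleotide at a position")
  }
  pooled
}
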