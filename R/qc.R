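#' Replicate correlation with masking rules
#'
#' Candidate cells are every in-range cell `(n, j <= n)` of the shared grid.
#' A pair is excluded when (i) it is the row's 3'-terminal position
#' (`j == n`) and either replicate's reactivity is exactly zero — terminal
#' zeros indicate absence of signal rather than structure; (ii) the cell is
#' defined in only one replicate, in which case the other is masked too
#' (cross-masking); or (iii) the cell is undefined in both. Pearson's r is
#' computed on the survivors.
#'
#' @param A,B `cotrans_matrix` objects sharing lengths, positions and
#'   exclusions.
#' @param layer Layer to correlate (default `reactivity`).
#' @return Object of class `correlation_report`: `pairs` tibble
#'   (`length_n`, `position`, `value_a`, `value_b`), `r`, `n_used`,
#'   `excluded` (named counts), `n_candidates`.
#' @export
replicate_correlation <- function(A, B, layer = "reactivity") {
  stopifnot(inherits(A, "cotrans_matrix"), inherits(B, "cotrans_matrix"))
  if (!identical(A$lengths, B$lengths) || !identical(A$positions, B$positions) ||
      !identical(A$excluded, B$excluded)) {
    abort("replicate matrices have mismatched shape or exclusions")
  }
  ma <- A$layers[[layer]]; mb <- B$layers[[layer]]
  grid <- tibble(
    length_n = rep(A$lengths, times = ncol(ma)),
    position = rep(A$positions, each = nrow(ma)),
    value_a = as.vector(ma),
    value_b = as.vector(mb)
  ) |>
    filter(.data$position <= .data$length_n)

  def_a <- !is.na(grid$value_a)
  def_b <- !is.na(grid$value_b)
  terminal_zero <- def_a & def_b & grid$position == grid$length_n &
    (grid$value_a == 0 | grid$value_b == 0)
  cross_masked <- xor(def_a, def_b)
  undefined_both <- !def_a & !def_b
  used <- def_a & def_b & !terminal_zero

  pairs <- grid[used, ]
  r <- if (nrow(pairs) >= 2L) cor(pairs$value_a, pairs$value_b) else NA_real_
  structure(
    list(pairs = pairs, r = r, n_used = sum(used),
         excluded = c(zero_at_3prime = sum(terminal_zero),
                      cross_masked = sum(cross_masked),
                      undefined_both = sum(undefined_both)),
         n_candidates = nrow(grid), layer = layer),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> layer %s: r = %.4f over %d pairs\n",
              x$layer, x$r, x$n_used))
  cat(sprintf("  excluded: %s of %d candidate cells\n",
              paste(sprintf("%s %d", names(x$excluded), x$excluded),
                    collapse = ", "), x$n_candidates))
  invisible(x)
}

#' @method tidy correlation_report
#' @export
tidy.correlation_report <- function(x, ...) x$pairs

#' @method glance correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  tibble(r = x$r, n_used = x$n_used, n_candidates = x$n_candidates,
         zero_at_3prime = unname(x$excluded["zero_at_3prime"]),
         cross_masked = unname(x$excluded["cross_masked"]),
         undefined_both = unname(x$excluded["undefined_both"]))
}

#' Neighboring-transcript correlation
#'
#' For each retained adjacent length pair (n, n+1) — pairs spanning an
#' excluded band are skipped — Pearson's r over the common positions
#' `1..n` (the 3'-most nucleotide of the longer transcript is omitted),
#' separately for reactivity and for the untreated-channel (background)
#' mutation rate.
#'
#' @param m A `cotrans_matrix` with `reactivity` and `untreated_rate` layers.
#' @param min_pairs Minimum common defined positions for a correlation
#'   (pairs below this are flagged with `NA`).
#' @return Tibble `n`, `n_next`, `n_common`, `r_reactivity`, `r_background`.
#' @export
neighbor_correlation <- function(m, min_pairs = 3L) {
  stopifnot(inherits(m, "cotrans_matrix"))
  lens <- m$lengths
  adj <- lens[(lens + 1L) %in% lens]
  list_rbind(map(adj, function(n) {
    i <- match(n, lens); j <- match(n + 1L, lens)
    cols <- seq_len(n)  # omit the 3'-most position of the longer transcript
    one_layer <- function(layer) {
      a <- m$layers[[layer]][i, cols]
      b <- m$layers[[layer]][j, cols]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < min_pairs ||
          var(a[ok]) == 0 || var(b[ok]) == 0) { # r undefined, flag as NA
        return(list(r = NA_real_, n = sum(ok)))
      }
      list(r = cor(a[ok], b[ok]), n = sum(ok))
    }
    re <- one_layer("reactivity")
    bg <- one_layer("untreated_rate")
    tibble(n = n, n_next = n + 1L, n_common = re$n,
           r_reactivity = re$r, r_background = bg$r)
  }))
}
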