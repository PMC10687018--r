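#' Assemble per-length reactivity profiles into a cotranscriptional matrix
#'
#' Rows are transcript lengths (ascending, minus excluded non-enriched
#' lengths), columns are target-region positions `1..max(length)`. A cell
#' `(n, j)` is defined only when `j <= n`, `n` is retained, and the position
#' passed the depth mask; undefined cells are `NA`. Layers: `reactivity`,
#' `modified_rate`, `untreated_rate`, `mod_depth`, `unt_depth`, and `depth`
#' (the per-cell minimum of the two channel depths).
#'
#' @param profiles Tibble from [reactivity_run()] covering a contiguous length
#'   range.
#' @param excluded_lengths Integer vector of lengths that were not enriched by
#'   roadblocks and are excluded from the matrix and all analyses.
#' @return Object of class `cotrans_matrix`: list with `layers` (named list of
#'   numeric matrices), `lengths`, `positions`, `excluded`.
#' @export
assemble_matrix <- function(profiles, excluded_lengths = integer(0)) {
  lens <- sort(unique(profiles$length_n))
  if (length(lens) > 1L && !all(diff(lens) == 1L)) {
    abort("profiles must cover a contiguous length range")
  }
  if (anyDuplicated(profiles[c("length_n", "position")]) > 0L) {
    abort("duplicate lengths in profiles")
  }
  excluded_lengths <- as.integer(excluded_lengths)
  if (length(excluded_lengths) > 0L &&
      !all(excluded_lengths %in% lens)) {
    abort("excluded lengths outside the profile length range")
  }
  keep <- setdiff(lens, excluded_lengths)
  positions <- seq_len(max(lens))
  layer_cols <- c(reactivity = "reactivity", modified_rate = "mod_rate",
                  untreated_rate = "unt_rate", mod_depth = "mod_depth",
                  unt_depth = "unt_depth")
  shell <- matrix(NA_real_, nrow = length(keep), ncol = length(positions),
                  dimnames = list(keep, positions))
  kept <- profiles |> filter(.data$length_n %in% keep,
                             .data$position <= .data$length_n)
  ri <- match(kept$length_n, keep)
  ci <- kept$position
  layers <- lapply(layer_cols, function(col) {
    m <- shell
    v <- kept[[col]]
    if (col %in% c("reactivity", "mod_rate", "unt_rate")) {
      v[kept$mask != "ok"] <- NA_real_
    }
    m[cbind(ri, ci)] <- v
    m
  })
  layers$depth <- pmin(layers$mod_depth, layers$unt_depth)
  structure(list(layers = layers, lengths = keep, positions = positions,
                 excluded = sort(excluded_lengths)),
            class = "cotrans_matrix")
}

#' @export
print.cotrans_matrix <- function(x, ...) {
  cat(sprintf("<cotrans_matrix> %d lengths x %d positions (%d excluded lengths)\n",
              length(x$lengths), length(x$positions), length(x$excluded)))
  invisible(x)
}

#' Write / read cotranscriptional matrix layers as CSV
#'
#' One file per layer (`<prefix>_reactivity.csv`, `_untreated_rate.csv`,
#' `_modified_rate.csv`, `_depth.csv`): header row of positions, first column
#' the transcript length, undefined cells as empty fields (no sentinel values).
#'
#' @param m A `cotrans_matrix`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param layers Which layers to write.
#' @return Invisibly, the paths written.
#' @export
write_cotrans_csv <- function(m, dir, prefix = "cotrans",
                              layers = c("reactivity", "untreated_rate",
                                         "modified_rate", "depth")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(layers, function(ly) {
    path <- file.path(dir, sprintf("%s_%s.csv", prefix, ly))
    df <- as.data.frame(m$layers[[ly]])
    names(df) <- m$positions
    df <- cbind(transcript_length = m$lengths, df)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_cotrans_csv
#' @param path Path of one layer CSV written by [write_cotrans_csv()].
#' @return `read_cotrans_layer()` returns a numeric matrix with length
#'   rownames and position colnames.
#' @export
read_cotrans_layer <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_length
  m
}

#' @method tidy cotrans_matrix
#' @export
tidy.cotrans_matrix <- function(x, ...) {
  long <- list_rbind(map(names(x$layers), function(ly) {
    m <- x$layers[[ly]]
    tibble(layer = ly,
           length_n = rep(x$lengths, times = ncol(m)),
           position = rep(x$positions, each = nrow(m)),
           value = as.vector(m))
  }))
  tidyr::pivot_wider(long, names_from = "layer", values_from = "value") |>
    arrange(.data$length_n, .data$position)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
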