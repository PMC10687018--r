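#' Build intermediate-transcript targets
#'
#' A variable-length cotranscriptional probing experiment interrogates every
#' intermediate transcript of a target RNA: the nascent RNA of length `n` is
#' the constant 5' leader (structure cassette plus the two initiating
#' nucleotides, kept lowercase so that it is excluded from reactivity
#' reporting) followed by the first `n` nucleotides of the target sequence
#' (uppercase). Targets for successive lengths differ by exactly one 3'
#' nucleotide.
#'
#' @param target_seq Target RNA sequence (A/C/G/T/U; case ignored).
#' @param leader 5' leader sequence; stored lowercase.
#' @param min_len,max_len Transcript length bounds (in target-region
#'   nucleotides), `1 <= min_len <= max_len <= nchar(target_seq)`.
#' @return A tibble with one row per intermediate transcript: `length_n`,
#'   `leader`, `target_prefix`, `full_rna`.
#' @export
build_intermediate_targets <- function(target_seq, leader, min_len, max_len) {
  stopifnot(length(target_seq) == 1L, length(leader) == 1L)
  if (!nzchar(leader)) abort("leader must be non-empty")
  target_seq <- toupper(normalize_seq(target_seq, "target_seq"))
  leader <- tolower(normalize_seq(leader, "leader"))
  if (min_len < 1L || min_len > max_len || max_len > nchar(target_seq)) {
    abort(sprintf(
      "length bounds [%d, %d] outside 1..%d", min_len, max_len, nchar(target_seq)))
  }
  n <- seq.int(min_len, max_len)
  prefix <- str_sub(target_seq, 1L, n)
  tibble(
    length_n = as.integer(n),
    leader = leader,
    target_prefix = prefix,
    full_rna = paste0(leader, prefix)
  )
}

#' Write one FASTA file per intermediate transcript
#'
#' Record ids are `<name>_<n>nt`; sequences keep the lowercase leader /
#' uppercase target-prefix convention.
#'
#' @param targets Tibble from [build_intermediate_targets()].
#' @param dir Output directory (created if needed).
#' @param name Construct name used in record ids and file names.
#' @return Invisibly, the paths written.
#' @export
write_targets_fasta <- function(targets, dir, name = "target") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(targets)), function(i) {
    id <- sprintf("%s_%dnt", name, targets$length_n[i])
    path <- file.path(dir, paste0(id, ".fa"))
    x <- Biostrings::BStringSet(setNames(targets$full_rna[i], id))
    Biostrings::writeXStringSet(x, path)
    path
  }, character(1))
  invisible(paths)
}

# All distinct single-nucleotide substitution / deletion / insertion variants
# of one k-mer, excluding the k-mer itself.
end_variants <- function(kmer) {
  k <- nchar(kmer)
  chars <- strsplit(kmer, "")[[1]]
  subs <- unlist(lapply(seq_len(k), function(i) {
    alt <- setdiff(DNA_BASES, chars[i])
    vapply(alt, function(b) {
      paste0(str_sub(kmer, 1L, i - 1L), b, str_sub(kmer, i + 1L, k))
    }, character(1))
  }), use.names = FALSE)
  dels <- unique(vapply(seq_len(k), function(i) {
    paste0(str_sub(kmer, 1L, i - 1L), str_sub(kmer, i + 1L, k))
  }, character(1)))
  ins <- unique(unlist(lapply(0:k, function(i) {
    vapply(DNA_BASES, function(b) {
      paste0(str_sub(kmer, 1L, i), b, str_sub(kmer, i + 1L, k))
    }, character(1))
  }), use.names = FALSE))
  list(substitution = subs, deletion = dels, insertion = ins)
}

#' Build the 3' end target index
#'
#' Transcript identity is inferred from the RNA 3' end: for each intermediate
#' transcript the 3'-most `end_len` nucleotides of its full sequence (leader
#' included, so windows are always full length) form the native key, and all
#' distinct 1-nt substitution, insertion and deletion variants are indexed so
#' that a single sequencing error or encoded mutation in the end window does
#' not prevent length assignment.
#'
#' Collision policy: a native key always outranks variant keys of other
#' lengths; two identical native keys are a fatal target-design error. Within
#' the variant tier, a key claimed by more than one length is ambiguous and
#' reads matching it are discarded (and counted) rather than silently
#' misassigned. A key claimed by one length under several variant classes is
#' reported under the lexicographically first class.
#'
#' @param targets Tibble from [build_intermediate_targets()].
#' @param end_len End-window size in nt (default 14).
#' @param orientation `"read1"` (default) stores keys reverse-complemented so
#'   read-1 prefixes are looked up directly; `"rna"` stores RNA-sense keys.
#' @return An object of class `end_target_index`: list with `entries`
#'   (tibble `key`, `length_n`, `match_class`), `ambiguous_keys`, `end_len`,
#'   `orientation`.
#' @export
build_end_index <- function(targets, end_len = 14L,
                            orientation = c("read1", "rna")) {
  orientation <- match.arg(orientation)
  if (any(nchar(targets$full_rna) < end_len)) {
    abort("every target must be at least end_len nucleotides long")
  }
  full <- toupper(targets$full_rna)
  native_key <- str_sub(full, -end_len, -1L)
  dup <- duplicated(native_key) | duplicated(native_key, fromLast = TRUE)
  if (any(dup)) {
    abort(sprintf(
      "target-design error: lengths %s share identical native end k-mers",
      paste(targets$length_n[dup], collapse = ", ")))
  }

  natives <- tibble(key = native_key, length_n = targets$length_n,
                    match_class = "native")

  variants <- list_rbind(map(seq_len(nrow(targets)), function(i) {
    v <- end_variants(native_key[i])
    tibble(
      key = c(v$substitution, v$deletion, v$insertion),
      length_n = targets$length_n[i],
      match_class = rep(c("substitution", "deletion", "insertion"),
                        c(length(v$substitution), length(v$deletion),
                          length(v$insertion)))
    )
  }))

  # native keys outrank variants of any length
  variants <- variants[!(variants$key %in% natives$key), ]
  # one length claiming a key under several classes: keep the
  # lexicographically first class (deletion < insertion < substitution)
  variants <- variants |>
    arrange(.data$key, .data$length_n, .data$match_class) |>
    distinct(.data$key, .data$length_n, .keep_all = TRUE)
  # a key claimed by more than one length is ambiguous
  n_claims <- table(variants$key)
  ambiguous <- names(n_claims)[n_claims > 1L]
  variants <- variants[!(variants$key %in% ambiguous), ]

  entries <- bind_rows(natives, variants)
  if (orientation == "read1") {
    entries$key <- revcomp(entries$key)
    ambiguous <- revcomp(ambiguous)
  }
  structure(
    list(entries = entries, ambiguous_keys = ambiguous,
         end_len = as.integer(end_len), orientation = orientation,
         lengths = sort(targets$length_n)),
    class = "end_target_index"
  )
}

#' @export
print.end_target_index <- function(x, ...) {
  cat(sprintf(
    "<end_target_index> %d lengths (%d-%d), end_len %d, %s-sense keys\n",
    length(x$lengths), min(x$lengths), max(x$lengths), x$end_len,
    x$orientation))
  cat(sprintf("  %d keys (%d native), %d ambiguous\n", nrow(x$entries),
              sum(x$entries$match_class == "native"),
              length(x$ambiguous_keys)))
  invisible(x)
}

#' Classify a 3' end query against the end index
#'
#' @param query Character vector of k-mers in the index orientation; each must
#'   have `end_len - 1`, `end_len` or `end_len + 1` characters.
#' @param index An [build_end_index()] object.
#' @return Tibble with `query`, `length_n` (NA unless assigned) and
#'   `match_class` (`native`, `substitution`, `insertion`, `deletion`,
#'   `ambiguous` or `unmatched`).
#' @export
classify_end <- function(query, index) {
  stopifnot(inherits(index, "end_target_index"))
  lens <- nchar(query)
  if (any(!(lens %in% (index$end_len + c(-1L, 0L, 1L))))) {
    abort(sprintf("query length must be %d, %d or %d",
                  index$end_len - 1L, index$end_len, index$end_len + 1L))
  }
  query <- toupper(query)
  m <- match(query, index$entries$key)
  length_n <- index$entries$length_n[m]
  match_class <- index$entries$match_class[m]
  match_class[is.na(m)] <- "unmatched"
  amb <- query %in% index$ambiguous_keys
  match_class[amb] <- "ambiguous"
  length_n[amb] <- NA_integer_
  tibble(query = query, length_n = length_n, match_class = match_class)
}

#' Serialize / read an end index as TSV
#'
#' Plain TSV of (key, length, class) — ambiguous keys carry class
#' `ambiguous` and an empty length — preceded by one comment line recording
#' `end_len` and `orientation`.
#'
#' @param index An `end_target_index`.
#' @param path Output/input file path.
#' @return `write_end_index()` returns `path` invisibly; `read_end_index()`
#'   returns the reconstructed index.
#' @export
write_end_index <- function(index, path) {
  header <- sprintf("# end_len=%d orientation=%s", index$end_len,
                    index$orientation)
  tab <- bind_rows(
    index$entries,
    tibble(key = index$ambiguous_keys, length_n = NA_integer_,
           match_class = "ambiguous")
  )
  writeLines(c(header, "key\tlength\tclass",
               sprintf("%s\t%s\t%s", tab$key,
                       ifelse(is.na(tab$length_n), "", tab$length_n),
                       tab$match_class)), path)
  invisible(path)
}

#' @rdname write_end_index
#' @export
read_end_index <- function(path) {
  header <- readLines(path, n = 1L)
  end_len <- as.integer(sub(".*end_len=(\\d+).*", "\\1", header))
  orientation <- sub(".*orientation=(\\w+).*", "\\1", header)
  tab <- readr::read_tsv(path, skip = 1L, col_types = "cic",
                         col_names = TRUE, progress = FALSE)
  names(tab) <- c("key", "length_n", "match_class")
  amb <- tab$match_class == "ambiguous"
  entries <- as_tibble(tab[!amb, ])
  structure(
    list(entries = entries, ambiguous_keys = tab$key[amb],
         end_len = end_len, orientation = orientation,
         lengths = sort(unique(entries$length_n))),
    class = "end_target_index"
  )
}
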