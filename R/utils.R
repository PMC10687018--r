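# Small sequence utilities shared across the pipeline.

#' Reverse complement of DNA strings
#'
#' Case-preserving, vectorised reverse complement over the `ACGTN` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# Normalise a nucleotide string: U -> T, validate alphabet, preserve case.
normalize_seq <- function(x, what = "sequence") {
  x <- chartr("Uu", "Tt", x)
  bad <- grepl("[^ACGTacgt]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-nucleotide characters (alphabet is A/C/G/T/U)",
                  what))
  }
  x
}

# Convert integer Phred scores to a Phred+33 quality string of length n.
phred_string <- function(q, n) {
  strrep(intToUtf8(q + 33L), n)
}

# Match sequence heads against an IUPAC degenerate pattern, vectorised over x.
iupac_match <- function(x, pattern) {
  rx <- paste0("^", paste(vapply(strsplit(pattern, "")[[1]], function(b) {
    s <- IUPAC_SETS[[b]]
    if (is.null(s)) abort(sprintf("unknown IUPAC code '%s'", b))
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = ""))
  str_detect(x, rx)
}

# Draw one concrete sequence per row from an IUPAC degenerate pattern.
sample_iupac <- function(pattern, n) {
  sets <- lapply(strsplit(pattern, "")[[1]], function(b) IUPAC_SETS[[b]])
  cols <- vapply(sets, function(s) sample(s, n, replace = TRUE), character(n))
  if (n == 1L) paste(cols, collapse = "") else apply(cols, 1L, paste, collapse = "")
}

# Random DNA strings, vectorised.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
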