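# Shared alphabet constants (kept in one early-sourced file because several
# modules reference them at load time).

DNA_BASES <- c("A", "C", "G", "T")

# For each base (row), the three alternative bases.
ALT_BASES <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(DNA_BASES, NULL))

# IUPAC degenerate nucleotide codes used for channel barcodes.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
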