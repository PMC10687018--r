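---
title: "Methods: from cotranscriptional MaP reads to reactivity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cotranscriptional MaP reads to reactivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotransmap)
```

## The experiment this package models

A variable-length cotranscriptional probing experiment stalls RNA polymerase
across a DNA template using biotin–streptavidin roadblocks, so that every
intermediate transcript of a target RNA is displayed and chemically probed
— in a *modified* channel (reagent added) and an *untreated* channel
(background). Adduct positions are read out by mutational profiling (MaP):
error-prone reverse transcription converts each adduct into a cDNA mutation.
The sequencing library encodes, per read pair:

* **read 1**: a 9-nt unique molecular identifier (UMI), then the reverse
  complement of the RNA 3′ end (the cDNA is primed from a 3′ adapter);
* **read 2**: a 5-nt degenerate channel barcode — `RRRYY` for modified,
  `YYYRR` for untreated — then the 5′ structure-cassette leader and the
  transcript 5′ end.

The two barcode patterns are complementary at all five positions, so an
exact degenerate match can never assign both; any mismatch tolerance would
create cross-talk, which is why barcode matching here is exact.

The analysis output is the **cotranscriptional matrix**: rows are transcript
lengths $n$, columns nucleotide positions $j \le n$, and each defined cell is
the background-subtracted mutation rate

$$\mathrm{reactivity}(n, j) \;=\; \frac{m^{\mathrm{mod}}_{n,j}}{d^{\mathrm{mod}}_{n,j}} \;-\; \frac{m^{\mathrm{unt}}_{n,j}}{d^{\mathrm{unt}}_{n,j}},$$

with $m$ counted mutation events and $d$ effective depth. No SHAPE-style
normalization is applied: all values are raw background-subtracted rates, and
negative values are preserved. The constant 5′ leader (structure cassette
plus the two initiating nucleotides) is carried in lowercase in all target
sequences and is excluded from every reported profile.

## Transcript identity from the RNA 3′ end

Each intermediate transcript of length $n$ is the leader plus the first $n$
target nucleotides, so consecutive targets differ by one 3′ nucleotide and
the only sequence unique to a length is its 3′ end. `build_end_index()`
indexes, for every length, the 3′-most `end_len` nucleotides (default 14 nt;
windows are taken from the full RNA, so the leader pads short transcripts)
together with **all distinct 1-nt substitution, insertion and deletion
variants** — one MaP mutation or sequencing error inside the window must not
cost the read its length assignment.

Collision policy (the index is deterministic about ties):

* two identical **native** windows are a fatal target-design error — the
  construct cannot be demultiplexed at that `end_len`;
* a native key always outranks variant keys of other lengths;
* within the variant tier, a key claimed by more than one length is
  **ambiguous**; matching reads are rejected and counted, never silently
  assigned. Neighboring lengths *always* share one deletion and one
  insertion variant (delete the first base of window $n\!+\!1$ and you get
  the result of deleting the last base of window $n$), so a few percent of
  uniformly random 1-edit queries are intrinsically ambiguous — this is a
  property of the method, not of the implementation;
* a key claimed by one length under several classes is reported under the
  lexicographically first class (deletion < insertion < substitution). The
  original tooling does not document this tie; we pick a deterministic rule
  and label it a choice rather than guessing the original behaviour.

Index keys are stored reverse-complemented ("read-1 sense") so that read-1
prefixes are looked up directly. Demultiplexing probes the native window
size first, then the deletion (`end_len − 1`) and insertion (`end_len + 1`)
sizes — the parsimonious call wins.

**A selection bias worth knowing about.** A read whose end window carries an
adduct-encoded mutation has spent the one-edit tolerance; if a second edit
lands in the window the read becomes unassignable. Mutation rates inside the
3′-most `end_len` nucleotides of each length are therefore depressed by read
loss in a rate-dependent way (about 20% relative at a 5% event probability in
our simulations). This is inherent to demultiplexing on the mutation-bearing
3′ end; the package's recovery tests probe positions outside the
identification window so they measure the counter, not this selection.

## Read processing and mutation counting

Per read pair: 3′ adapters are clipped (longest read suffix matching an
adapter prefix, ≥ 4 nt overlap, ≤ 20% mismatches); the UMI and channel
barcode are removed; the pair is merged into one insert by scanning all
suffix–prefix overlaps (≥ 10 nt, ≤ 10% mismatches; most matching bases wins,
ties to the longer overlap). At merge disagreements the higher-quality base
is kept with quality equal to the difference, so a disagreement between
equal qualities yields quality 0 and is subsequently ignored by the
quality gate — deliberately: such positions carry no information. Pairs with
no qualifying overlap fall back to read 1 alone (the 3′ piece), flagged in
the bin statistics. No pair is rejected for low quality at this stage;
quality acts only at counting.

Inserts are aligned with a semi-global (free-end-gap) affine aligner
(match +2, mismatch −3, gap of length $k$ costs $5 + 2k$; alignments below
50% of the maximum attainable score are discarded and counted). Free end
gaps on both sequences mean a read pooled from a neighboring length is
absorbed as a 1-nt terminal overhang rather than a spurious indel, and
overhangs never produce events.

Mutation events are counted per the simplified MaP rules:

* base calls below Phred 25 are ignored — a low-quality mismatch neither
  produces an event nor contributes that position to the read's depth
  (numerator/denominator consistency);
* indels are left-aligned within homopolymers before calling, so every
  equivalent gap placement yields the same call;
* mutated alignment columns separated by fewer than `merge_gap = 2` matching
  columns collapse into **one** event assigned to the 3′-most mutated
  position — one adduct produces one RT signature, and the RT (copying
  3′→5′) meets the adduct at the 3′-most position first. A side effect is
  that two independent events within 2 nt of each other are counted once;
  at the event probabilities of these experiments this is a sub-SE
  correction, and it cancels between channels in the subtraction;
* deleted positions contribute depth when both flanking read bases pass the
  quality gate; an insertion is anchored at the first target position 3′ of
  the gap.

**Alignment context.** All reads of a run are aligned against the *longest*
transcript's sequence (every target is a prefix of it); counting is then
restricted to each bin's own coordinates, and each read's contribution is
additionally capped at the 3′ end of its assigned length. Two reasons. A
mutation near the RNA 3′ end that is ambiguous between a mismatch and a
homopolymer indel would otherwise be resolved differently against targets
truncated at different lengths, making calls depend on which smoothing bin a
read lands in; and a read assigned to length $n$ should never claim coverage
beyond position $n$, whatever its tail aligns to. With both rules, read-level
pooling followed by profiling and per-length profiling followed by count
pooling are *exactly* interchangeable — the same per-read calls are summed
either way — which the test suite asserts to floating-point identity,
indel encodings included.

The three external-tool thresholds are preserved as defaults: minimum
reporting depth 500 per channel, no quality-based pair rejection before
counting, and the Phred 25 counting floor. Test fixtures lower `min_depth`
explicitly where simulated depths are deliberately small; the threshold is a
reporting gate, not part of the estimator.

## Neighboring-transcript smoothing

Adapter ligation biases which transcript lengths are represented, and
neighboring transcripts have similar reactivity patterns and background
rates. `make_plan()` therefore maps every interior length to
$[n-1, n, n+1]$, the minimum to $[\min, \min+1]$ and the maximum to
$[\max-1, \max]$; both channels are pooled with the same plan.
`pool_reads()` concatenates the read bins (mirroring FASTQ-level smoothing);
`pool_counts()` sums per-position depth and events restricted to the pooled
length's coordinates — the fast path, exactly equivalent as described above.
Pooling roughly triples effective depth at interior lengths at the cost of
averaging over a 3-length window, which preserves folding transitions that
span several lengths but smears single-length events.

## Matrices and quality control

`assemble_matrix()` builds the triangular length × position layers
(reactivity, channel rates, depths); cells are undefined (`NA`, written as
*empty* CSV fields — sentinel values would corrupt correlations) wherever
$j > n$, the length is excluded as non-enriched (lengths without internal
roadblocks are excluded from the matrix and all analyses), or either
channel is below the depth threshold.

`replicate_correlation()` applies the masking rules before Pearson's $r$:
a cell undefined in one replicate is masked in both (cross-masking); a pair
at a row's 3′-terminal position is dropped when either value is exactly
zero — at the terminal nucleotide a zero indicates absence of signal rather
than structure. We interpret "RNA 3′ ends" as the single terminal position;
a wider terminal window is exposed via the code rather than claimed as the
original behaviour. The excluded-cell counts plus used pairs always equal
the candidate cells, which the tests assert. `neighbor_correlation()`
computes, for each retained adjacent pair $(n, n+1)$ — pairs spanning an
excluded band are skipped — $r$ over positions $1..n$ (the 3′-most
nucleotide of the longer transcript is omitted), separately for reactivity
and the untreated-channel (background) rate; pairs with fewer than 3 common
defined positions, or a zero-variance layer, are flagged `NA`.

## The simulator: what it emulates, and what it does not

`simulate_library()` generates the full library architecture with per-read
ground truth: per-position adduct draws ($p_{\mathrm{mod}}(j)$ in the
modified channel, shared background $p_{\mathrm{bg}}$ in both channels and on
the leader), certain adduct→mutation encoding with a configurable
substitution/insertion/deletion mix, independent per-base sequencing errors,
concrete barcodes drawn from the degenerate patterns, random UMIs, adapter
read-through, and a constant-quality model (Phred 38 with an optional
fraction of Phred 15 bases to exercise the quality gate). Defaults: 500
reads per (channel, length), background 1%, every third target position
reactive at 5% (i.e. a 4-point reactivity increment), sequencing error
$10^{-3}$ per base, 2 × 150 nt reads, substitution-only encoding. The
substitution default is deliberate: substitutions map an event to a single
position, which is what recovery against a positional truth requires; indel
encodings are simulated and tested where indel handling itself is under
test. Zero-weight length bands emulate the non-enriched gaps left where the
template carries no internal roadblocks.

Deliberately not modelled: polymerase mechanics and roadblock geometry
(abstracted into the length-weight vector), RNA folding and ligand response
(the true $p_{\mathrm{mod}}$ is position-only, identical across lengths —
so smoothing can only help in simulations, whereas real folding transitions
change reactivity between neighboring lengths), ligation sequence bias,
adapter dimers, UMI collisions from PCR duplication, and quality-score
correlation structure. Passing tests therefore demonstrate the pipeline's
correctness and statistical calibration, not that smoothing is harmless
around sharp folding transitions in real data.

UMIs are recorded in read ids and statistics; deduplication is off by
default (the upstream protocol does not prescribe it) with an optional
exact-UMI collapse per bin.

## Numerical and degenerate-input choices

* Alignment tie-breaks: diagonal over deletion over insertion during
  traceback, then homopolymer left-alignment, so calls are placement-
  invariant; score ties at the matrix border prefer the cell consuming more
  target, then more read.
* Gap cost convention: a gap of length $k$ costs $\mathrm{open} + k \cdot
  \mathrm{ext}$ ($5 + 2k$ at defaults).
* Empty bins profile to zero tables with a warning; empty matrices refuse to
  plot; `min = max` transcript ranges are the single-length mode of the
  assay and are supported everywhere except smoothing plans, which require
  at least two lengths.
* Reactivity at zero depth is `NA`, never 0; masks distinguish `low_depth`
  from defined zeros.

## Problem sizes in the test suite

The suite validates on deliberately small constructs (60–120 nt targets,
31–101 lengths, 50–5,000 read pairs per bin, ~10,000–50,000 pairs per
scenario), chosen so each property is measured at a depth where its expected
statistical fluctuation is well below the asserted tolerance — e.g.
reactivity recovery uses 5,000 reads per bin so that three pooled binomial
standard errors are ±0.010 around the true 0.040. The smoothing-benefit
check runs 20 independent replicate-pair simulations at 150 reads per bin,
where sampling noise dominates and pooling must raise replicate correlation
in at least 90% of trials.

## Known limitations

* The mutation counter is a simplified stand-in for a full MaP profiler:
  no multi-mutation deconvolution into co-occurring structural
  subpopulations, no per-read clustering, and a single collapsing rule in
  place of the external tool's undocumented mutation taxonomy. It is
  calibrated against the simulator's encoded event probabilities, not
  against the external tool's output.
* Rates in the 3′ identification window are depressed by the selection bias
  described above; interpret terminal-window reactivities with care.
* One construct per run: the index does not support multiple distinct
  target RNAs.
* Only ±1 smoothing windows are provided; wider or distance-weighted
  pooling is out of scope.
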