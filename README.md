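# cotransmap

Cotranscriptional RNA structure probing analysis by mutational profiling,
from raw paired-end reads to transcript-length × nucleotide-position
reactivity matrices.

## The problem

RNA folds while it is transcribed. Cotranscriptional chemical probing
experiments capture this by stalling RNA polymerase at every position of a
template, chemically probing the displayed nascent RNAs (with a SHAPE reagent
such as benzoyl cyanide, or with dimethyl sulfate), and reading out adduct
positions by mutational profiling (MaP): error-prone reverse transcription
encodes each adduct as a mutation in the cDNA. One sequencing library
therefore mixes *every intermediate transcript length* of the target in *two
chemical channels* (modified and untreated), and the analysis must:

1. infer each read's transcript length from the RNA 3′ end (a 14-nt k-mer
   with 1-edit tolerance) and its channel from a degenerate 5-nt barcode
   (`RRRYY` modified / `YYYRR` untreated),
2. count quality-filtered mutation events per nucleotide in each
   (channel, length) bin, and
3. report reactivity as the background-subtracted mutation rate

   reactivity(j) = m_mod(j) / d_mod(j) − m_unt(j) / d_unt(j)

   where m and d are mutation events and effective depth at position j —
   assembled into a triangular matrix over transcript lengths n (rows) and
   positions j ≤ n (columns).

Because 3′-adapter ligation biases transcript representation, the pipeline
supports **neighboring-transcript smoothing**: reads from lengths n−1, n,
n+1 are pooled into bin n (edges pool `[min, min+1]` and `[max−1, max]`),
boosting effective depth while preserving length-dependent reactivity
trends.

The package is aimed at groups running variable-length cotranscriptional
probing experiments (riboswitch folding pathways and similar systems) and at
method developers who need a fully simulatable, ground-truthed version of
such a pipeline.

## What is in the box

| Stage | Functions |
|---|---|
| Per-length targets + 3′ end index | `build_intermediate_targets()`, `build_end_index()`, `classify_end()` |
| Read pre-processing and demultiplexing | `trim_adapters()`, `extract_umi()`, `extract_channel()`, `demultiplex()` |
| Neighboring-transcript smoothing | `make_plan()`, `pool_reads()`, `pool_counts()` |
| Alignment + mutation counting | `merge_pair()`, `align_to_target()`, `call_mutations()`, `profile_run()` |
| Reactivity + matrices | `compute_reactivity()`, `reactivity_run()`, `assemble_matrix()`, `write_cotrans_csv()` |
| QC | `replicate_correlation()`, `neighbor_correlation()`, `autoplot()`, `plot_replicate_hexbin()`, `plot_neighbor_violin()` |
| Simulation with ground truth | `sim_config()`, `simulate_library()`, `make_end_test_reads()`, `truth_compare()` |

Everything takes and returns tibbles, so stages chain with the pipe; result
objects have `tidy()`, `glance()` and `autoplot()` methods. A thin
command-line wrapper for the file-facing stages is installed at
`system.file("scripts", "cotransmap", package = "cotransmap")`.

## Worked example

Simulate a full library for a 60-nt target (31 intermediate lengths, two
channels, 500 read pairs per bin), demultiplex it, apply smoothing, and build
the reactivity matrix:

```r
library(cotransmap)
library(dplyr)

set.seed(42)
target <- paste(sample(c("A","C","G","T"), 60, replace = TRUE), collapse = "")
cfg <- sim_config(target, min_len = 30, max_len = 60, reads_per_length = 500)
sim <- simulate_library(cfg, seed = 1)

index <- build_end_index(sim$targets)
index
#> <end_target_index> 31 lengths (30-60), end_len 14, read1-sense keys
#>   2968 keys (31 native), 60 ambiguous

dx <- demultiplex(sim$pairs, index)
dx$stats |> print(n = 5)
#> # A tibble: 15 × 2
#>   metric            count
#>   <chr>             <int>
#> 1 total             31000
#> 2 adapter_trimmed   31000
#> 3 channel_modified  14794
#> 4 channel_untreated 15302
#> 5 class_native      24257

counts   <- profile_run(dx$records, sim$targets, profile_config(min_depth = 300))
plan     <- make_plan(30, 60)
leader   <- nchar(cfg$leader)
smoothed <- pool_counts(counts, plan, leader_len = leader)
profiles <- reactivity_run(smoothed, min_depth = 300, leader_len = leader)

m <- assemble_matrix(profiles)
m
#> <cotrans_matrix> 31 lengths x 60 positions (0 excluded lengths)
autoplot(m)   # length x position reactivity heatmap

neighbor_correlation(m) |> head(3)
#> # A tibble: 3 × 5
#>       n n_next n_common r_reactivity r_background
#>   <int>  <int>    <int>        <dbl>        <dbl>
#> 1    30     31       30        0.985        0.855
#> 2    31     32       31        0.981        0.736
#> 3    32     33       32        0.982        0.688

truth_compare(sim, dx, counts)
#> <truth_report> demux accuracy 0.9707 over 62 bins
#>   modified: rate bias -0.00172, RMSE 0.00682 (1891 positions)
#>   untreated: rate bias -0.00051, RMSE 0.00449 (1891 positions)
```

Reading the numbers: of 31,000 simulated pairs, 97.1% return to their true
(channel, length) bin — the losses are reads whose end window carries more
than one mutation, which the 1-edit-tolerant index cannot place. Per-position
mutation rates are recovered to within binomial sampling error (RMSE ≈
`sqrt(p(1-p)/depth)`), and reactivity profiles of neighboring lengths
correlate strongly (r ≈ 0.98), which is what makes neighbor pooling sound.

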