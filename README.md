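# skimcnv

Deletion and duplication discovery in fast-neutron (FN) mutagenized
populations from two cheap genome-wide assays: very low coverage ("skim",
~1x) whole-genome sequencing counted in fixed 10 kb windows, and SNP-array
genotype calls whose null scores (`"---"`) mark missing sequence. It is
aimed at groups running large mutant collections in inbred crops, where the
question is "which lines carry a deletion over my gene, and how much of the
genome does the whole population delete?"

## The method

Per line, window read counts are median-normalized; per window, the
cross-line mean μ and SD σ classify each line's depth *x* into three
candidate classes:

* homozygous deletion: `x < μ − 3σ` (expected depth 0),
* hemizygous deletion: *x* closer to μ/2 than to μ, i.e. `x < 3μ/4`
  (expected depth 0.5),
* duplication: `x ≥ 2μ`.

Single flagged windows are mostly noise; deletions are *contiguous*. Under
the theory of runs, chance failures at per-interval rate *p* produce a
maximal run of exactly *n* failures at expected frequency

    F = p^n (1 − p)^2

so a run observed in *N* assayed intervals carries an expected chance count
`E = N·F`; runs with `E ≤ α` are accepted as events. The same machinery
scores runs of `"---"` genotype calls (at least 3 nulls, tolerating a single
valid interruption) in the array screen, after removing markers heterozygous
in every line. Population summaries collapse sibling calls by reciprocal
overlap, histogram the deletion size spectrum against a reciprocal (1/size)
reference curve, and project genome saturation: a population of *M* families
each deleting a fraction *f* of the genome hits a given locus with
probability `1 − (1 − f)^M`.

A synthetic-data generator (Poisson window counts over implanted truth sets
with shared lognormal mappability; marker matrices with null/heterozygous
mis-score noise) makes every stage testable without sequencing data.

## Worked example

Simulate a small population (8 lines, 20 Mb genome, one implanted event per
line), run the full pipeline, and look at the significant calls:

```r
library(skimcnv)
library(dplyr)

scan <- run_pipeline(list(
  genome = list(chrom_lengths = c(chr1 = 1.2e7, chr2 = 8e6),
                mappability_sd = 0.1),
  simulate = list(n_lines = 8, events_per_line = 1,
                  min_size = 1e5, max_size = 1e6, mean_depth = 67),
  saturation = list(n_population = 5000),
  seed = 21))

scan
#> CNV scan of 8 lines over 20.0 Mb
#>   deletions: 189 resolved (4 hom, 185 hemi); duplications: 3
#> Deletion spectrum: 9 calls -> 9 unique deletions; 2.2 Mb deleted (11.2% of 20.0 Mb)
#> Saturation model: 2.2 Mb deleted across 8 families (11.2% of a 20 Mb genome)
#>   per-family deleted fraction f = 0.014
#>   P(locus deleted in >=1 of 5000 families) = 1.0000 (100%)

tidy(scan) |> filter(E <= 0.05) |> select(line_id:kind, E)
#> # A tibble: 9 × 7
#>   line_id  chrom    start      end   size kind             E
#>   <chr>    <chr>    <dbl>    <dbl>  <dbl> <chr>        <dbl>
#> 1 line_001 chr1  11710000 11920000 210000 hom_del  3.00e- 36
#> 2 line_001 chr2   3690000  3700000  10000 hemi_del 5.55e-  3
#> 3 line_002 chr2   4490000  5190000 700000 hom_del  4.98e-124
#> 4 line_003 chr1  11360000 11630000 270000 hom_del  1.05e- 50
#> 5 line_004 chr2   3350000  3650000 300000 hemi_del 8.03e- 54
#> 6 line_005 chr1   7260000  7520000 260000 hemi_del 1.16e- 49
#> 7 line_005 chr2   3700000  3860000 160000 hemi_del 1.06e-  3
#> 8 line_006 chr1   6300000  6470000 170000 hom_del  3.70e- 29
#> 9 line_008 chr1   2110000  2270000 160000 hemi_del 1.58e- 33
```

All seven implanted deletions (`scan$truth`) are recovered with the right
zygosity and window-resolution breakpoints, and the implanted duplication
appears in `scan$duplications`. Rows 2 and 7 are instructive artifacts of the
small population: they sit under a *duplication carried by another line*,
whose doubled depth drags the 8-line window mean μ upward until normal-depth
lines drift below the `3μ/4` hemizygous threshold — with hundreds of lines,
as in a real screen, one variant line barely moves μ. `E` is the expected
number of equally long chance runs in that line; values around 10⁻³ are
borderline, values like 10⁻⁵⁰ are unambiguous events.

The headline population arithmetic:

```r
m <- saturation_model(deleted_bp = 734e6, genome_bp = 734e6 / 0.165,
                      n_families = 210, n_population = 5000)
m
#> Saturation model: 734.0 Mb deleted across 210 families (16.5% of a 4448 Mb genome)
#>   per-family deleted fraction f = 0.000786
#>   P(locus deleted in >=1 of 5000 families) = 0.9804 (98%)

detection_limit_bp(N = 4.45e5, p = 0.004, alpha = 0.05, window_size = 1e4)
#> [1] 30000
```

At realistic window counts and noise rates the smallest reliably detectable
deletion is three windows — 30 kb.

## Layout

* `R/genome.R`, `R/simulate.R` — window grid and the synthetic-data generator
* `R/depth.R` — track ingestion, normalization, cross-line window statistics
* `R/runs.R` — the runs-theory machinery (`run_frequency`, `expected_runs`,
  `min_significant_run`, `estimate_p`, `find_runs`)
* `R/caller.R` — flagging, calling, merging, unique-deletion spectrum,
  duplication spacing
* `R/axiom.R` — the array null-call screen
* `R/saturation.R`, `R/pipeline.R` — population arithmetic and `run_pipeline()`
* `vignettes/deletion-discovery.Rmd` — models, assumptions, design choices
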