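---
title: "Deletion discovery from skim sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion discovery from skim sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimcnv)
library(dplyr)
```

## The problem

Fast-neutron (FN) mutagenesis of an inbred plant line produces mostly large
genomic deletions — kilobases to megabases — together with occasional
duplications. A population of a few thousand mutagenized families is a
reverse-genetics resource only if one can say, line by line, *where* the
deletions are, and, population-wide, *how much* of the genome they cover.
Two cheap assays give that information at scale:

* **Skim sequencing**: ~1x whole-genome short reads per line, mapped to the
  progenitor assembly and counted in fixed 10 kb windows. A homozygous
  deletion shows near-zero depth, a hemizygous deletion roughly half depth,
  a duplication roughly double.
* **SNP-array genotyping**: a marker falling inside a homozygous deletion
  returns a null score (`"---"`, no signal in either channel) — but so does a
  technical failure, so single nulls are uninformative.

At 1x coverage single windows are noisy and single markers unreliable; what
separates deletions from noise in both assays is *contiguity*.

## The statistical core: theory of runs

Assume per-interval detection failures (windows flagged by chance, markers
mis-assayed) occur independently at rate $p$. The expected frequency of a
maximal run of exactly $n$ consecutive failures is approximated by

$$F = p^n (1 - p)^2,$$

the two boundary factors being the non-failures that terminate the run. In a
track of $N$ assayed intervals the expected number of such chance runs is
$E = N F$. A run is accepted as a real event at level $\alpha$ when
$E \le \alpha$; we report $E$ itself rather than a p-value, so "significant
at 0.05 but not at 0.01" reads directly as expected chance counts.

Two consequences drive the whole design:

* **Detection limit.** The smallest significant run length at
  $N = 4.45\times10^5$ windows, $p = 0.004$, $\alpha = 0.05$ is $n = 3$,
  i.e. 30 kb at 10 kb windows (`detection_limit_bp()`); smaller deletions
  cannot be distinguished from noise at this coverage.
* **Noise-rate estimation.** $p$ is estimated per line and per flag mode as
  the fraction of flagged intervals *outside accepted runs* (flags inside an
  event are evidence of the event, not the noise channel). The pipeline makes
  one re-estimation pass after provisional calling; iterating further changes
  nothing materially because accepted runs occupy a tiny genome fraction.

### Runs with interruptions

Real marker runs in the study data were accepted "even when interrupted by a
single valid call", because a mis-clustered genotype can break an otherwise
contiguous null run. `find_runs()` therefore bridges internal gaps of at most
`gap_tolerance` (default 1) unflagged intervals. Masked intervals are
transparent — neither flag nor gap.

Two refinements temper what the tolerance would otherwise cost:

* Runs are *scored* by their flagged count $n$ only; interruptions are
  reported but buy no significance.
* Each run also carries a trimmed **core**: leading or trailing flagged
  segments no longer than the tolerance (a single stray flag attached to the
  body across a bridged gap is more often chance than event) are excluded
  from the core extremes. Calls keep the full flagged extremes as their span;
  the resolved-deletion table uses core breakpoints. In simulation this
  removes the ~3%-per-event breakpoint stretching that stray flags otherwise
  cause, at the price of mis-trimming a genuine single-window tail roughly
  0.2% of the time per side.

## Depth model and flagging rules

Counts are normalized per line by the line's **median** window count
(robust to the line's own large deletions; a mean normalizer would be shifted
by exactly the events we are looking for). Cross-line per-window statistics
$\mu_i$ (mean) and $\sigma_i$ (SD, $n-1$ convention) then classify each
window of each line:

| mode | rule | expected depth |
|---|---|---|
| homozygous deletion | $x < \mu - 3\sigma$ | 0 |
| hemizygous deletion | $|x - \mu/2| < |x - \mu|$, i.e. $x < 3\mu/4$ (strict) | 0.5 |
| duplication | $x \ge 2\mu$ (boundary inclusive) | $\ge 2$ |

A tie at $x = 3\mu/4$ is *not* flagged — "closer to half" is read strictly.
Windows with $\mu_i$ below 0.1 are masked as unmappable, and partial terminal
windows are masked by default because their reduced width mimics low depth.

### Zygosity resolution

The three rules are deliberately not mutually exclusive: a zero-depth window
satisfies the hemizygous rule too, and when many lines carry deletions at a
locus the inflated $\sigma_i$ can push $\mu - 3\sigma$ below zero and blind
the homozygous rule entirely. The hemizygous rule, which does not involve
$\sigma$, is therefore the reliable *union* deletion track, while depth level
distinguishes zygosity. `resolve_deletions()` clusters a line's overlapping
deletion calls of both modes, takes the span from the strongest
hemizygous-mode call, and assigns the final zygosity from the median
normalized depth over that span (cutoff 0.25, the midpoint of the expected
levels 0 and 0.5). Both raw tracks remain available — a long hemizygous span
containing distinct homozygous sub-calls, which the study observed, is
visible through `hom_within_hemi()`.

### Merging and population summaries

Same-line, same-mode calls within 200 kb merge into one candidate event with
component structure preserved and $E$ equal to the minimum over components
(the strongest component carries the evidence). The pipeline gates merging on
significance at the loosest $\alpha$ — without the gate, isolated chance
flags near a real event get absorbed and stretch its span.

Across lines, `unique_deletions()` collapses calls with reciprocal overlap
$\ge$ 50% (sibling lineages of one family carry the same event), reports the
size histogram in 10 kb classes against a least-squares reciprocal curve
$c/\text{size}$, the union of deleted bp, and the genome fraction.
`duplication_spacing()` reports gaps between consecutive duplication calls
and what merging at several gap distances would do to the call count —
tight spacing is the signature of one fragmented event, not many independent
ones.

## The array screen

`call_axiom()` removes *fixed heterozygotes* (markers heterozygous in every
line of an inbred population mark probe/template mismatch, not real
heterozygosity), then finds per-line runs of `"---"` with at least
`min_run = 3` nulls, tolerating one valid interruption, merging candidates
within 5 markers (marker distance, not bp, because marker density varies).
Hemizygous deletions are invisible to this assay — one intact homologue still
yields signal — so only null runs are interpreted. Interrupting calls are
classified for reliability: heterozygous in the affected line only
(`line_specific_het` — residual signal from a deleted marker is typically
mis-clustered as heterozygous), differing from the modal call of the other
lines (`inconsistent`), otherwise `valid`; a candidate whose interruptions
are all unreliable is flagged likely contiguous. Isolated single nulls are
kept as low-confidence annotations, never as calls.

## Saturation arithmetic

With total unique deleted length $D$ in a screened sample of $k$ families on
a genome of $G$ bp, the per-family deleted fraction is $f = D/(Gk)$, and
under independent uniform placement the chance that a given locus is deleted
in at least one of $M$ families is $P = 1 - (1-f)^M$. With $D$ = 734 Mb
representing 16.5% of the genome, $k = 210$ and $M = 5000$, $P$ rounds to
98%. The published summary quotes "15%" of the genome alongside the 98%
figure, but only the 16.5% figure reproduces 98% under this model (15% gives
~96.7%); `saturation_model()` takes the inputs explicitly so either can be
computed. The independence and uniformity assumptions are idealizations —
deletions of essential regions are censored by viability, and sibling
lineages share events — so the projection is an upper-bound-flavoured
estimate, which is why `print()` states the assumption.

## The synthetic-data generator

Every caller above is tested against `implant_events()` +
`simulate_depth()` + `simulate_marker_calls()`, which emulate the study's
data-generating process:

* window counts are Poisson with rate
  $\lambda \cdot m_i \cdot f_{ij} \cdot w_i/w$, where $\lambda$ is the
  expected reads per full window at copy number 2 (default 67, a ~1x short
  read run at 10 kb windows), $m_i$ a mean-1 lognormal mappability factor
  shared by all lines (systematic window-to-window variation), and $f_{ij}$
  the effective copy factor — 0 / 0.5 / 2 inside events, blended
  proportionally in partially overlapped windows;
* event sizes follow a truncated reciprocal law (density $\propto 1/s$,
  the published size spectrum's shape), positions are uniform,
  within-line overlaps are rejected and redrawn;
* marker matrices score hom-deleted markers `"---"` with certainty, intact
  markers `"---"` at rate $\varepsilon_{null}$ and mis-heterozygous at rate
  $\varepsilon_{het}$ (defaults 0.005 each — placeholders calibrated to be in
  the regime where the runs model is informative, not estimates of the
  study's own error rates, which are not published), plus a configurable
  fixed-heterozygote fraction (default 0.02, of the order of the study's
  1,623 / 71,562).

What the generator does **not** model: read-level artefacts (FASTQ,
mapping ambiguity), GC bias beyond the lognormal factor, physical
re-insertion of duplicated sequence (duplications are depth-only), and
mis-assembly of the reference. Passing recovery tests therefore demonstrate
the statistical machinery, not robustness to alignment pathology.

## Test problem sizes and seeds

Recovery is exercised on a 20-line, 200 Mb population at $\lambda = 67$ with
four implanted deletions per line on the reciprocal law over [30 kb, 3 Mb]
and mappability SD 0.15 — large enough that ~80 events with sizes down to
the detection limit are scored, small enough to run comfortably in a test
suite. Calibration of the runs model uses five replicate $10^6$-interval
Bernoulli tracks per noise rate. All randomness flows from one integer seed
per simulation; stage sub-seeds are derived deterministically, so every
result in the suite is reproducible byte for byte.

```{r example}
scan <- run_pipeline(list(
  genome = list(chrom_lengths = c(chr1 = 1.2e7, chr2 = 8e6),
                mappability_sd = 0.1),
  simulate = list(n_lines = 8, events_per_line = 1,
                  min_size = 1e5, max_size = 1e6, mean_depth = 67),
  saturation = list(n_population = 5000),
  seed = 21))
glance(scan)
tidy(scan) |> filter(E <= 0.05)
```

## Known limitations

* Breakpoints are window-resolution; sub-window events appear only as the
  single-window depth-dip diagnostic `subwindow_deletion_bp()`.
* With few lines (< ~10) the cross-line $\sigma$ is noisy and the homozygous
  rule loses power; the hemizygous union track plus depth resolution degrades
  more gracefully.
* $E = N F$ is an expectation over exact-length contiguous runs; with a gap
  tolerance the chance of *clustered* flag patterns is somewhat higher than
  $F$ suggests, so $E$ is mildly anti-conservative for interrupted runs.
  At the default parameters the measured false significant call rate stays
  below $\alpha$ per line.
* The saturation projection inherits the independence/uniformity idealization
  discussed above.
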