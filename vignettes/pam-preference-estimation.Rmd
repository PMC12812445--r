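---
title: "Estimating Cas nuclease PAM preferences from genomic repeat protospacers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Cas nuclease PAM preferences from genomic repeat protospacers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomepam)
```

## The assay this package models

A CRISPR-Cas nuclease cleaves a DNA target only when the protospacer is
flanked by a functional protospacer-adjacent motif (PAM) — 3' of the spacer
for type II enzymes (SpCas9, SaCas9), 5' for type V (Cas12a). Classical PAM
screens synthesize randomized libraries; the approach implemented here
instead exploits the genome itself. Certain repeat 20-mers (segments of Alu
elements) occur thousands of times with essentially random 10-nt flanks, so
a single guide RNA targeting such a repeat turns every copy into one well of
a natural PAM library, read out in situ by capturing cleaved loci
(GUIDE-seq-style dsODN tagging). Only copies whose flank happens to carry a
functional PAM are cut; the flank composition of the captured loci, compared
against the flank composition of all candidate loci, is the PAM preference.

The package covers the computational side end to end:

* **Repeat selection** — `count_kmers()` (double-strand k-mer census),
  `filter_candidates()` (5'-G start, no AAA/TTT/CCC/GGG triple, occurrence
  threshold), `extract_flanks()` / `flank_diversity()` (flank PFMs and mean
  Shannon entropy), `mismatch_neighborhood()` (off-target capacity by exact
  Hamming distance).
* **Target matching** — `find_genomic_targets()` enumerates every genomic
  window within a mismatch budget (default 6 substitutions, no bulges) on
  both strands, flanks unconstrained; `assign_integrations()` maps
  integration positions to the nearest template.
* **PAM estimation** — `weighted_pfm()`, `pcv_table()`, `heatmap_matrix()`,
  `wobble_comparison()`, and the seed-extension motif table
  (`seed_extend()`), wrapped by the `genomepam()` fit.
* **Comparative metrics** — `enzyme_summary()`, `activity_specificity()`,
  `downsample_curve()`, `window_profile()` / `profile_ratio()`.
* **Synthetic data** — `sim_config()` / `sim_truth()` / `sim_genome()` /
  `sim_capture()` generate planted-truth experiments for validation.

## Conventions

Coordinates are 0-based half-open everywhere. Genomes are over
A/C/G/T/N; any scanned window containing N is skipped outright — it neither
counts as an occurrence nor as a mismatch, so N never inflates a background.
The k-mer census counts a k-mer as `fwd(w) + fwd(revcomp(w))`: a protospacer
target exists independently on each strand, so a palindromic k-mer at one
locus counts twice; overlapping occurrences all count. Flanks are always
reported in protospacer orientation (for a minus-strand hit the 3' flank is
the reverse complement of the genomic bases 5' of the hit interval). PAM
positions are numbered 1..10 outward from the spacer for 3' PAMs and -10..-1
for 5' PAMs, with -1 adjacent to the spacer. Degenerate IUPAC bases in
extended spacers (e.g. a 5' Y) match their allowed set at zero mismatch
cost.

## The PCV statistic

For a PAM sequence $p$ of length $L$,

$$\mathrm{PCV}(p) = \frac{\text{fraction of } p \text{ among captured PAM
windows (read-weighted)}}{\text{fraction of } p \text{ among the background
PAM windows}},$$

and the relative PCV is $\log_2 \mathrm{PCV}$ normalized so the top PAM is
0. The background population is the PAM flank set of *all candidate genomic
targets of the spacer* (the mismatch-budget template set), not genome-wide
L-mer frequencies: that population is what the capture can actually draw
from, so the ratio isolates cleavage preference from target-set composition.
Passing a whole-genome L-mer multiset as `background_pams` gives the
genome-wide variant if wanted. Captured fractions are read-weighted by
default (`weight_mode = "sites"` is available for sensitivity analysis; the
two agree when all read counts are equal). A PAM captured zero times has
relative PCV $-\infty$ (rendered as missing in the heat map); a PAM absent
from the background has *undefined* PCV — flagged, never infinite — and no
pseudocounts are applied by default.

Structural invariants, asserted in the test suite on every simulated run:
captured and background fractions each sum to 1; the background-weighted
mean of PCV is 1; the maximum relative PCV is 0; PCV is invariant to uniform
scaling of read counts.

## The seed-extension motif table

The motif table turns the same data into an explicit, significance-annotated
PAM call:

1. **Seed.** For each PAM position, the four single-base motifs form one
   window. Each motif's *edited value* blends its site evidence and read
   evidence (below); the window's 2×4 contingency table — rounded edited
   values against the motifs' background target counts — is tested with
   Pearson's chi-square. The position with the smallest p-value seeds the
   motif; within the window the motif with the highest percent of background
   targets edited is recorded.
2. **Extend.** The current motif grows by one base toward the 5' end or the
   3' end; each available side contributes a four-motif window, the more
   significant side wins, and its best motif becomes the current motif.
3. **Repeat** until both ends of the 10-position window are reached; every
   step is recorded (the full trace is always available).
4. **Report.** The retained list keeps steps that pass the significance
   floor and whose percent-edited strictly increases step over step.

The *edited value* of a motif is its captured-site count plus its summed
read counts linearly scaled into the site-count range, with the blend then
normalized so that the largest value equals the largest site count in the
window. The normalization matters: it keeps the statistic on the site-count
scale, so a motif whose reads are simply proportional to its sites
contributes its site count, and only a genuine read excess or deficit moves
the value. Without it the value would double the count scale and the
chi-square would be systematically anti-conservative — significance would
appear under a PAM-less (uniform) capture, which we verified does not happen
under the implemented form.

The chi-square places the background target counts themselves in the second
row of the table. Because the edited sites are a subset of those targets,
the test is conservative under no enrichment — the desired behavior for a
reporting tool: a retained motif reflects a real compositional shift of the
edited set away from the candidate-target background. Edited values are
rounded to integers before testing (the test needs counts); significance
comparisons across windows use p-values, not raw statistics, because
degrees of freedom can differ after zero-column drops.

Design choices that were genuinely open, and how they were fixed:

* **Significance floor.** No threshold is stated for "significant" in the
  original procedure. The default here is α = 0.01, Bonferroni-corrected by
  the number of candidate motifs per round (40 in the seed round, 8 per
  extension round). The full trace is emitted regardless, so any other
  gating can be applied post hoc.
* **Ties.** A p-value tie between windows is broken by the higher best-motif
  percent-edited, then in favor of the 3' side; within a window, by higher
  edited value, then lexicographic motif. Ties are resolved
  deterministically so the procedure is a pure function of its inputs.
* **Background per motif** is the number of candidate target templates whose
  PAM flank matches the motif, matching the "percent of genomic targets
  edited" reading of the table. Edited sites include both perfect-match and
  mismatch sites by default (`perfect_only = FALSE`).
* **One-base growth only**: extensions add a single contiguous base per
  round; gapped or disjunctive motifs are out of scope.

## The synthetic-data generator

`sim_truth()` draws planted targets under the study conditions the package
is validated against: i.i.d. uniform ACGT flanks (the repeat-selection
filters exist precisely to make real flanks look like this); mismatch
targets carry 1–6 substitutions with counts weighted toward few mismatches
(probabilities 0.40/0.25/0.15/0.10/0.06/0.04) and positions biased 4:1
toward spacer positions 8–11, where mismatches concentrate in real capture
data. `sim_capture()` gives each target an activity from an IUPAC PAM model
(most specific matching pattern wins), multiplied by a per-mismatch penalty
of 0.3; active targets are detected with probability `capture_rate` (default
0.9), and detected sites draw zero-truncated negative-binomial reads with
mean `activity × mean_depth` (default depth 100) and size 2 — read counts in
real capture data span orders of magnitude, so Poisson would be far too
tame. `sim_genome()` embeds the planted cassettes in an i.i.d. random
background at one target per equal-width slot (guaranteed non-overlap), and
`find_genomic_targets()` provably recovers exactly the planted set at
`max_mm = 0`.

What the generator does *not* emulate: chromatin accessibility structure,
PCR/UMI artifacts, locus-specific capture bias, assembly gaps, and repeat
clustering. Passing tests therefore demonstrate the correctness of the
estimators under clean sampling assumptions, not robustness to every
real-data pathology.

Problem sizes used in validation: parameter-recovery runs plant enough
perfect targets that roughly 500 edited sites are expected under the planted
model (9,000 targets for a 2-defined-base PAM at 1/16 match probability,
36,000 for 4-defined-base PAMs at 1/64); these runs use the planted-target
table directly as the background template set, which coincides with the
scanned template set on a clean genome. The recovery criterion — the final
retained motif occupies exactly the planted defined positions, with bases
inside the planted degenerate sets, and a PAM-less model retains nothing —
is asserted over 20 seeded runs per model in the test suite and the
acceptance script. End-to-end runs through genome embedding, scanning, and
integration-event assignment use ~1,500 targets in a ~550 kb genome.

## Numerical details

* Percentages are rounded half away from zero to one decimal
  (`percent_edited(1103, 1681)` prints 65.6), matching how such tables are
  conventionally printed; R's default round-half-even would differ at
  exact .05 boundaries.
* `edited_value()` with all-zero read counts warns and degrades to site
  counts (scale factor 0).
* Chi-square windows drop motifs whose column totals are zero (they carry
  no information and would zero an expected cell); if fewer than two motifs
  survive, the p-value is undefined and the step cannot be retained.
* Downsampling draws reads without replacement from the site-by-read-count
  multiset — one random permutation per replicate, with per-depth counts as
  prefix sums, so each depth is exactly multivariate hypergeometric and
  depths are nested within a replicate.
* All randomness flows from explicit integer seeds; per-replicate streams
  are derived arithmetically and stay below 2^31.

## Worked example

```{r example}
cfg <- sim_config(seed = 7, n_perfect_targets = 1500,
                  n_mismatch_targets = 400)
truth <- sim_truth(cfg)
sites <- sim_capture(truth, cfg)
fit <- genomepam(sites, sim_templates(truth))
fit
summary(fit)
```

```{r plot, fig.width = 8, fig.height = 4}
plot(fit)
```

The demo pipeline (`run_demo()`) additionally embeds the targets in a
genome, rediscovers them by scanning, and assigns derived integration
events before fitting, exercising the full matching path.

## Known limitations

* Substitution-only matching: spacer-target bulges are not modeled.
* The motif table reports a single best motif per step; degenerate PAMs
  (e.g. an R position) surface as one concrete base in the headline motif,
  with the sibling bases visible in the per-step window sub-table.
* The chi-square on edited values is a pragmatic enrichment screen, not a
  calibrated sampling model of capture; its conservative construction makes
  false retention unlikely but p-values should be read as ranks, not
  frequentist error rates.
* Full-genome repeat censuses at k = 20 are feasible but memory-hungry in
  this pure-R implementation; dedicated k-mer counters remain the right
  tool at that scale, with `count_kmers()` serving as their desk-scale,
  oracle-verified counterpart.
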