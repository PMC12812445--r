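# genomepam

Characterization of CRISPR-Cas PAM preferences from genomic repeat
protospacers.

## The problem

Every Cas nuclease requires a protospacer-adjacent motif (PAM) next to its
DNA target — NGG at the 3' side for SpCas9, NNGRRT for SaCas9, a 5' T-rich
motif for Cas12a-family enzymes — and determining the PAM of a new or
engineered nuclease is the first step in making it usable. Instead of a
synthetic randomized library, this package models an assay that uses the
genome itself as the library: certain repeat 20-mers (e.g. the Alu-derived
`GTGAGCCACTGTGCCTGGCC`) occur thousands of times with near-random 10-nt
flanks, so one guide RNA targeting the repeat probes thousands of candidate
PAMs at once, and genome-wide capture of cleaved loci (GUIDE-seq-style)
reads out which flanks were functional.

The package is aimed at computational biologists analyzing such capture
experiments — or designing new ones — and provides the full path: repeat
selection, candidate-target enumeration, site matching, PAM statistics,
motif reporting, cross-enzyme comparison, and a planted-truth simulator.

## The statistics at the core

For a PAM sequence *p* of length *L*, the **PAM cleavage value** is

    PCV(p) = captured fraction of p (read-weighted) / background fraction of p

over the PAM windows of all candidate genomic targets of the spacer, with
**relative PCV** = log2 PCV normalized so the top PAM is 0.

The **seed-extension motif table** finds the most significantly enriched
single base across the PAM window (chi-square of *edited values* — site
counts blended with range-scaled read counts — against background target
counts), then extends the motif one base at a time toward the 5' or 3' end,
keeping the more significant side each round and retaining the steps whose
percent of background targets edited strictly increases and passes a
Bonferroni-corrected significance floor.

## Worked example

Simulate a capture experiment with a planted 3' NGG PAM, then fit:

```r
library(genomepam)

cfg   <- sim_config(seed = 7, n_perfect_targets = 1500, n_mismatch_targets = 400)
truth <- sim_truth(cfg)
sites <- sim_capture(truth, cfg)      # a cleavage-site table
fit   <- genomepam(sites, sim_templates(truth))
fit
#> PAM preference fit (three_prime PAM)
#>   112 sites (92 perfect / 20 mismatch), 7,867 reads, 1900 background targets
#>   Top motif: GG at position(s) 2,3 (87.5% of 128 targets edited, p = 6.04e-45)
summary(fit)
#> ...
#> Retained seed-extension motifs:
#>  step_index motif positions edited_sites total_sites percent_edited  p_value
#>           1     G         2          112         492           22.8 1.23e-59
#>           2    GG       2,3          112         128           87.5 6.04e-45
```

Of 1,900 candidate targets, 112 were captured; all captured flanks carry GG
at PAM positions 2–3, so the single-base seed lands on G (112 of 492
G-carrying targets edited, 22.8%), the extension to GG concentrates the
signal (87.5% of the 128 GG targets edited), and no third base improves the
percentage — the planted NGG is recovered exactly. `plot(fit)` draws the
read-weighted base-preference profile and the 16×16 relative-PCV heat map;
`coef(fit)` returns the relative PCVs.

Real data enters through `read_site_table()` (a 10-column TSV of matched
cleavage sites) or through `find_genomic_targets()` +
`assign_integrations()` from a genome FASTA and integration positions. A
command-line wrapper with subcommands (`simulate`, `match`, `pam`, `table`,
`compare`, `downsample`, `windows`, `demo`, ...) is installed at
`inst/cli/genomepam.R`.

## Package layout

- `R/io.R` — genome FASTA and site-table IO
- `R/repeats.R` — k-mer census, candidate filters, flanks, Hamming neighborhood
- `R/matching.R` — candidate-target enumeration and event assignment
- `R/pam_stats.R` — weighted PFMs, PCV, heat map, wobble comparison
- `R/table.R` — edited value, window chi-square, seed extension
- `R/comparative.R` — on/off ratios, downsampling, window profiles
- `R/simulate.R` — planted-truth generator
- `R/genomepam.R` — the `genomepam()` fit and its S3 methods
- `vignettes/pam-preference-estimation.Rmd` — the methods vignette
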