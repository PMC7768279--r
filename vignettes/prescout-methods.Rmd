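---
title: "Methods and design of the prescout pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the prescout pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prescout)
```

prescout implements a desk-scale epigenomic screen for putative regulatory
elements (pREs) that are differentially active between two purified cell
populations — the motivating case is GABAergic cortical interneurons (CINs)
sorted against the remaining cortical cells — together with the downstream
computations used to validate such elements: replicate-consistency modelling,
multi-evidence candidate ranking, motif and region–gene term enrichment,
ChIP-qPCR fold-change arithmetic, and current-clamp electrophysiology with a
rule-based fast-spiking classifier.  This vignette records the models, the
parameter choices, and the places where the design was genuinely open.

## Coverage model and peak calling

Coverage is represented as fixed-width bins of fragment counts per
chromosome (`coverage_track()`).  The simulator (`gen_coverage()`) draws
fragment *starts* per bin from a Poisson law — background rate 5 fragments
per 50 bp bin by default — and lays each fragment forward over a 200 bp
extension, so a bin's coverage is the running sum of starts over the
extension window.  Planted regions multiply the start rate by a fold
(default 10) in the condition(s) they belong to.  This is deliberately the
simplest generative model consistent with the Poisson inference downstream;
it has no fragment-length variability, no GC or mappability bias, and no
chromatin structure, so passing tests demonstrate correctness of the
inference, not robustness to real-data artifacts.

`call_peaks()` is a clean-room, simplified broad-mark caller, not a port of
any published tool.  Per bin, the expected count is a depth-scaled local
control mean — the maximum of the control bin, a 1 kb window mean, and the
genome-wide control mean — a reduced form of the local-bias correction the
standard callers apply.  P-values are upper-tail Poisson probabilities,
adjusted by Benjamini–Hochberg across all genome bins (one genome-wide FDR,
not per chromosome).  Peak cores require `q <= 0.01` and are extended
through contiguous bins with `q` below the broad (linking) cutoff, also
0.01 by default.

Because fragments are laid forward from their start, an enriched coverage
run overhangs the underlying fragment-start region at its trailing edge by
exactly the extension length.  The caller deconvolves this by trimming
emitted regions by `fragment_extension` at the 3' edge (never below one
bin).  Without this correction every called region would carry a systematic
200 bp overhang — about 13% of a 1.5 kb planted region — which is exactly
the kind of avoidable boundary error the trimming removes.

`classify_differential()` compares two conditions per bin after scaling
counts to the smaller library, using the signed log10 likelihood ratio of a
two-rate model (each rate floored at a pseudocount of 1) against the
common-rate model `m = (k1 + k2)/2`.  Runs of same-sign bins with
`|LLR10| >= 3` and at least 150 bp long become condition-enriched regions;
the LLR cutoff of 3 is exposed in `peak_call_config()` because only the
150 bp minimum length is a fixed workflow constant — the cutoff itself is
the documented default of the standard differential tool.  "Common" regions
are delimited by calling each condition against a shared input and
intersecting, minus the differential regions; when no input is supplied a
flat pseudo-input at the median depth-scaled bin rate stands in.

## Replicate consistency (IDR)

Replicate peak scores are modelled with the two-component Gaussian copula
mixture: an irreproducible component (independent standard bivariate
normal) and a reproducible component `N(mu, sigma^2, rho)` with weight
`pi`.  Starting values are `(mu, sigma, rho, pi) = (2.6, 1.3, 0.8, 0.7)`,
the convention for log10 fold-change peak scores, and they are treated as
EM starting values, not fixed parameters.

The estimator is rank-based: scores enter only through their empirical
quantiles `(rank - 0.5)/n`.  We fit by expectation conditional
maximisation: pseudo-values are obtained by inverting the mixture-implied
marginal CDF `G(z) = pi N(mu, sigma) + (1 - pi) N(0, 1)` at the empirical
quantiles and are refreshed after every few EM passes.  A simpler one-shot
rank-normal transform (mapping ranks through the standard normal quantile)
was evaluated first and rejected: forcing an N(0,1) margin contradicts the
mixture's own marginal, and in simulation it collapses the fit (estimated
`pi` near 1 at truth 0.7).  With the ECM, recovery on 2,000 simulated pairs
at truth `(pi, rho) = (0.7, 0.8)` is within 0.03 and 0.02 respectively.
The log-likelihood is monotone within each EM pass (asserted in tests at
tolerance 1e-8); it may fluctuate slightly across pseudo-value refreshes,
which is why convergence is judged on the relative change between
refreshes (tolerance 1e-6, cap 500 iterations, non-convergence flagged).

The local idr of a pair is the posterior probability of the irreproducible
component; the global IDR is the running mean of local idr over pairs
sorted by increasing local idr.  Following the workflow this package
mirrors, IDR is a replicate-quality diagnostic: high-confidence sets come
from replicate intersection, and `idr_threshold()` is provided but optional.

## High-confidence sets and candidate ranking

Within each differential class, peaks separated by 500 bp or less are
merged within each replicate first, and the two replicates are then
intersected at base level (`hc_peaks()`); the order is fixed because
merging can create intersection across the ragged boundaries of broad
peaks, and a test pins that behaviour.  The merge is applied uniformly to
every set entering HC construction; applying it only to the differential
sets is the plausible alternative reading, and would only narrow the common
class.  Since merging within a class can re-create overlap across classes,
disjointness is restored afterwards with priority to the enriched classes
over common; overlap between the two enriched classes (only possible
through merging) is dropped from both sides.

Candidates are annotated by overlap (at least one shared base, half-open
BED semantics) with each TF-binding set, their union and intersection,
conserved elements, and per-cell-type accessibility sets, plus the nearest
gene by TSS distance with alphabetical tie-breaking.  The ranking is a
deterministic lexicographic sort — TF intersection, TF count, conservation,
selective accessibility, peak score, then coordinate — standing in for what
is, in practice, a manual screen of browser tracks; it exists to make the
pipeline's output reproducible and testable, not to claim an optimal
prioritisation.

On the default synthetic design (two 1 Mb chromosomes, 50 bp bins, 20 + 20
condition-specific and 40 shared regions of 1.5 kb at fold 10, two
replicates at depth factors 1 and 0.8), the end-to-end HC enriched class
achieves base-level sensitivity ≥ 0.85 and precision ≥ 0.90; the acceptance
script recomputes both from scratch.

## Motif and region–gene enrichment

`scan_motif()` scans both strands; N never matches.  Consensus motifs use
IUPAC codes; PWM motifs score log2 odds against a uniform background with a
hit threshold expressed as a fraction (default 0.8) of the maximum
achievable score.  Fold enrichment is exactly the percentage of target
sequences with a hit divided by the percentage of background sequences with
a hit, with an upper-tail binomial p-value at the background rate; a zero
background rate is floored at `0.5 / n_background` and the fold reported as
infinite.  The reference motif software uses a ZOOPS binomial on a matched
background; the binomial stand-in here keeps the published fold formula
exact while simplifying the null.

Region–gene association uses the basal-plus-extension rule: each gene gets
a basal domain of 5 kb upstream / 1 kb downstream of its TSS
(strand-aware), extended on each side to the nearest other gene's basal
domain edge, at most 1 Mb from the TSS, never truncating its own basal
domain.  The nearest obstruction is computed over all genes, not just the
TSS-adjacent one, which matters when close TSSs have overlapping basal
domains.  Curated-domain exceptions of the reference tool are not
implemented.  Term enrichment combines a region-level binomial test
(success probability = fraction of the genome covered by the term's
domains) and a gene-level hypergeometric test; a term is significant when
both BH FDRs are below 0.05 and region fold enrichment exceeds 2.

Genomic context annotation classifies the peak midpoint with precedence
promoter-TSS > 5'UTR > exon > intron > TTS > intergenic; the promoter
window is −1 kb..+100 bp of the TSS and the TTS window −100 bp..+1 kb,
both configurable.  Gene-body bases without exon annotation count as
intron.

## Electrophysiology

Sweep sets are families of 800 ms current steps (−50..+20 pA in 10 pA
steps for passive properties, 25–500 pA in 25 pA steps for firing).  The
feature definitions are: resting potential = mean of the 50 ms pre-stimulus
baseline of the zero-current sweep; input resistance = OLS slope of
steady-state voltage deflection (last 100 ms of the step) against current
over spike-free subthreshold sweeps, in megaohms; rheobase = smallest
current eliciting a spike; firing frequency = spikes per second over the
step; AP analysis on the *first* spike of the sweep 50 pA above rheobase
(or the nearest larger step), the conventional choice where "single AP
properties" leaves it open.

Threshold is the voltage at the maximum of the third time-derivative
within the 2 ms before the AP peak.  Raw finite differences make this
definition numerically fragile, so derivatives come from Savitzky–Golay
polynomial filters (order 4): a 0.5 ms window for smoothing and first
derivative, and a wider 1.0 ms window for the third derivative, whose
noise amplification grows steeply with derivative order.  Amplitude and
half-width are measured on the raw trace (peak minus threshold; time
between linearly interpolated crossings of threshold + amplitude/2 — at
10–50 kHz, sample-snapped widths are too coarse against a 0.5 ms
criterion); the fAHP trough is read from the smoothed trace between the
peak and the next spike's onset or 10 ms, whichever comes first.  Spike
detection requires an upward crossing of −20 mV at ≥ 10 mV/ms followed by
a peak above 0 mV, with a 1 ms refractory rule.

A cell is fast-spiking when at least three of four hold (strict
inequalities): half-width < 0.5 ms, maximal firing > 50 Hz, fAHP > 15 mV,
SFA < 2, where SFA is the last-to-first inter-spike-interval ratio of the
maximum-firing sweep ("maximal firing" is the mean rate over the step,
consistent with counting APs per second; an instantaneous-rate definition
is the noted alternative).  When SFA is undefined (fewer than three
spikes) the cell is classified on the remaining three criteria and must
satisfy all three — a conservative fallback that is a package decision,
not a published rule.

The synthetic cells (`gen_ephys_cell()`) are template-based rather than
conductance-based, precisely so that every feature has an exact programmed
truth: subthreshold sweeps follow the RC step response, spikes are
piecewise waveforms with programmed threshold, amplitude, half-width and
fAHP (the rising half-width contributes `hw/2`, the fall is scaled so the
descending half-amplitude crossing contributes the other half), spike
times follow a deterministic adapting schedule (each ISI stretched by the
adaptation factor), and each spike is preceded by a 6 ms depolarising
approach ramp so the third-derivative threshold estimator faces a
realistic slow-then-fast onset.  Gaussian noise (0.2 mV SD, a typical
good whole-cell recording) is added everywhere.  The FS preset (0.30 ms,
~124 Hz max, 20 mV fAHP, SFA 1) satisfies all four criteria with margin;
the RS preset (0.80 ms, ~41 Hz, 8 mV, SFA ~3.4) satisfies none; per-cell
jitter stays within class-safe bounds.  A conductance-based generator
would exercise the estimators against more realistic waveforms but has no
exact truth; it is the natural extension point.

## Statistics

`fisher_exact_2x2()` enumerates the hypergeometric support and sums point
probabilities no greater than the observed one (the point-probability
two-sided convention, with a 1e-7 relative tolerance against float ties) —
this convention reproduces the printed p = 0.0414 for the 11/2 vs 5/7
fast-spiking contingency and matches `stats::fisher.test`, which serves as
a cross-check in the tests, never as the implementation.  Zero-variance
inputs to the t tests return flagged degenerate results rather than
infinities; a constant vector equal to the null mean gives t = 0, p = 1.
One-way ANOVA uses `aov` with Tukey HSD (Tukey–Kramer for unequal n), with
the all-constant case reported as F = 0.  ΔΔCt follows
`ΔCt = Ct(target) − Ct(control region)`, `ΔΔCt = ΔCt(ChIP) − ΔCt(input)`,
fold `2^(−ΔΔCt)`, and the reported value is the log2 ratio of the two
samples' folds, so swapping samples negates it exactly.

## Reproducibility and problem sizes

Every generator is a pure function of its parameters and a seed (the RNG
state is saved and restored), and `run_pipeline()` is deterministic given
its config and seed, which a byte-identity test pins.  The default
problem sizes — 2 Mb toy genome at 50 bp bins, 2,000 IDR pairs, 500 + 500
motif sequences, a 200-cell electrophysiology bank at 50 kHz — were chosen
as the smallest designs at which the acceptance properties (parameter
recovery within ±0.05, feature recovery within ±1 mV / ±2 mV / ±0.05 ms /
±2 mV, ≥95% classification accuracy) are comfortably identifiable rather
than borderline.  The genome-scale counts of a real screen (tens of
thousands of peaks) are out of scope by design: they require the original
sequencing data, and nothing at desk scale stands in for them.

```{r example, eval = FALSE}
# A complete synthetic run
cfg <- run_config(outdir = "prescout_demo", seed = 1)
summary <- run_pipeline(cfg)
pipeline_report("prescout_demo")
```
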