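---
title: "Differential protein abundance from fragment-ion total ion counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential protein abundance from fragment-ion total ion counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticdiff)
library(dplyr)
```

## The quantitation model

ticdiff implements a label-free quantitation and differential-abundance
workflow for shotgun proteomics of two strains — in the motivating
application, wild-type *Neurospora crassa* against its VDAC-less
(mitochondrial porin deletion, ΔPor-1) mutant. The abundance measure is the
protein **total ion count (TIC)**: for protein $i$ in run $s$,

$$\mathrm{TIC}_{is} = \sum_{p \in \mathrm{PSMs}(i,s)} I_p,$$

the sum over all accepted peptide-spectrum matches of the summed MS/MS
fragment-ion intensities $I_p$. TIC is a *relative* measure within a run:
no cross-run normalisation is applied at rollup, because both differential
statistics centre their difference populations, which cancels any global
run offset exactly (this invariance is tested). All downstream work uses
$\log_2 \mathrm{TIC}$.

PSMs enter the rollup only if they pass the identification filters: an
expectation score $\log_{10}(e) < -1.5$ (strict inequality), at most one
missed tryptic cleavage, and precursor charge 2–4. A protein–run cell with
no accepted PSM is *undetected*: its log2 value is missing, never imputed
and never treated as $-\infty$. Quantitative testing uses only proteins
detected in the runs the test needs.

A deliberate simplification: each PSM counts toward the single protein it
is assigned to in the input. There is no razor-peptide logic or protein
inference; the upstream identification engine is expected to have resolved
ambiguity.

### Detection status

Each protein gets one of four statuses — `both-strains`, `mutant-only`,
`wild-type-only`, `undetected` — using "detected in ≥1 run of the strain"
semantics; `mutant-only` proteins (no wild-type signal at all) are read as
candidate overexpression beyond the comparison's dynamic range and
reported separately rather than given a statistic. A separate
`quantifiable` flag gates the differential test: *strict* (default for
replicated designs) requires detection in every run, *lenient* (default
for single-run designs) in ≥1 run per strain. The two pieces of
information are kept apart because a protein detected in, say, one of two
wild-type runs and both mutant runs is genuinely "seen in both strains"
yet cannot enter a statistic that needs all four values.

## The differential statistics

**Single-replicate z-score rule** (one run per strain). For proteins
detected in both runs, $d_i = \log_2\mathrm{TIC}_{i,\mathrm{mut}} -
\log_2\mathrm{TIC}_{i,\mathrm{wt}}$. The population of $d_i$ is
standardised to mean 0, SD 1 (sample SD, $n-1$), and a protein is flagged
when $|z_i| > 1.96$ — the central 95% band of the empirical difference
population. Mean-centring (not median) is used. There is no
multiple-testing correction: the procedure is a screen whose false-positive
rate under a null Gaussian population is the advertised 5%, which the test
suite and the acceptance script verify by simulation.

**Two-replicate signal-to-noise (Wstat) rule** (two runs per strain). Four
difference populations are formed per protein: within-strain replicate
differences $R_0$ (wild type), $R_1$ (mutant) — pure noise — and
between-strain differences $Z_0, Z_1$ paired by replicate index. Each
population is centred to across-protein mean 0. The noise scale is the
sample SD of the pooled centred $\{R_0, R_1\}$ values, and

$$\mathrm{S/N}_i = \frac{|z_{0i}^c + z_{1i}^c|}{\mathrm{noise}}, \qquad
\widehat{\Delta}_i = \frac{z_{0i}^c + z_{1i}^c}{2}.$$

A protein is called differential when $\mathrm{S/N}_i \ge 2.8$ **and**
$|\widehat{\Delta}_i| \ge 1$ (at least two-fold), both inclusive. The 2.8
cut-off is calibrated: with i.i.d. Gaussian replicate noise $\sigma$,
$\mathrm{Var}(Z_0 + Z_1) = 4\sigma^2$ while the pooled within-strain noise
SD estimates $\sqrt{2}\sigma$, so the null S/N is distributed as
$\sqrt{2}\,|N(0,1)|$ and $P(\mathrm{S/N} \ge 2.8) = 2(1 -
\Phi(2.8/\sqrt{2})) \approx 0.048 < 0.05$. The exact published form of the
statistic lives in prior literature; this package fixes the formula above
because it uses exactly the four named populations and reproduces that
calibration analytically — the choice is pinned by tests, not folklore.

Design notes, each genuinely open and decided here once:

* **Pooled noise.** $R_0$ and $R_1$ are pooled into a single SD rather
  than per-strain SDs; with only two replicates per strain, halving the
  degrees of freedom per strain costs more than strain-specific scales
  buy.
* **Centring per population, then pooling.** Each of the four populations
  is centred on its own mean before the pooled SD is taken; whether the
  original procedure centred before or after pooling is unknowable from
  the description, and the difference is second-order (the two centred
  within-strain populations have mean 0 either way).
* **Pairing.** $Z_0$ pairs mutant rep 1 with wild-type rep 1 by default.
  A `crossed` option exists, but because $z_0 + z_1$ contains every
  between-strain difference exactly once under either pairing, S/N, the
  effect estimate and the flags are provably identical — only the
  reported $z_0/z_1$ columns change. The option is kept for transparency,
  with that invariance tested.
* **Inclusive cut-offs** ($\ge 2.8$, $\ge 1$): "cut-off" language without
  stated strictness is read inclusively, and exact boundary cases
  (a protein at exactly two-fold) are retained.
* **Degenerate inputs.** Fewer than 3 quantifiable proteins, or a zero
  noise SD (all replicate values identical), abort with a statistical
  error rather than returning infinities.

## Set analysis

Compartment annotation is multi-label intersection counting against
user-supplied accession lists. Venn decomposition of 2–3 sets returns the
disjoint regions with members (region counts sum to the union — a tested
invariant). The package ships, as plain-text fixtures, the two stress
overlap panels from the motivating study: 29 mutant-elevated proteins
shared with an ER-unfolded-protein-response signature and 12 shared with a
menadione oxidative-stress signature, 8 proteins common to all three
conditions — `stress_overlap_panels()` loads them and
`scripts/acceptance.R` recomputes the 29/12/8 arithmetic from the files.

Category enrichment is a hypergeometric upper tail $P(X \ge k)$ with
parameters (universe $N$, category $K$, query $n$), Benjamini–Hochberg
adjusted across categories. The original analysis used a web
categorisation service; the hypergeometric test is the generic,
reproducible replacement and is labelled as an addition — the published
overlaps were raw counts with no significance test. The default universe
is the proteins detected in both strains.

## Assay arithmetic

`laurdan_ratio()` (F440/F490 fluidity ratio, lower = more fluid),
`acyl_percentages()` (GC peak areas to percentages, C17:1 internal
standard excluded from the total), `sterol_normalized()` /
`ergosterol_relative()` (ergosterol vs 5α-cholestanol, reference = 100%),
`catalase_units()` (1 U = 1 µmol H₂O₂/min, per mg protein) and
`ros_relative()` (DCF fluorescence per mg protein, % of reference) are
exact closed-form arithmetic; each ratio is invariant under common
rescaling of its numerator/denominator pair, verified against independent
recomputation at 1e-12 relative tolerance. Replicates are aggregated
ratio-first (each Laurdan curve is ratioed, then averaged), and
`assay_compare()` defaults to the pooled-variance t-test with Welch as the
switch. Peak detection and spectral correction are out of scope — areas
and intensities are inputs.

## The synthetic-data generator

`simulate_psm_data()` defines the study conditions every statistical claim
in this package is tested under. Per protein $i$: baseline $b_i \sim
N(\mu_0, \tau)$ on the log2 scale (log-normal TIC); with probability
$\pi_{DE}$ a strain effect of $\pm\delta$ (equal sign probability) added
to mutant runs; per-cell noise $N(0, \sigma_{rep})$. The cell's TIC is
split across a protein's peptides (a uniform-random count in a configured
range) by symmetric Dirichlet(1) weights — lossless under rollup, which is
tested to 1e-9, while giving realistically unequal peptide intensities.
Dropout removes whole protein–run cells with probability
$\Phi(\Phi^{-1}(\text{rate}) - s\,(b_i-\mu_0)/\tau)$, a probit link
(slope $s = 1$ by default) that concentrates missingness in the
low-abundance tail, mimicking detection limits.

Defaults — 1000 proteins, 2–10 peptides each, $\mu_0 = 10$, $\tau = 2$,
$\sigma_{rep} = 0.3$, $\pi_{DE} = 0.1$, $\delta = 2$, dropout 0.1 —
emulate a two-fold-and-up sparse perturbation in a ~1000-protein
comparison, the regime of the motivating S100 dataset. What the generator
does **not** emulate: retention-time structure, identification errors,
shared peptides, intensity-dependent variance, or the real dataset's
abundance distribution. Passing recovery tests therefore demonstrates the
statistics behave as designed under their own assumptions, not that those
assumptions hold for any particular instrument.

`null_calibration()` is the no-effect special case used for
false-positive-rate checks: all cells i.i.d. $N(\mu_0, \sigma_{rep})$,
fold-change filter off. Both statistics are scale-free
($\sigma_{rep}$ cancels), which is tested exactly.

## Problem sizes and determinism

The validation suites use 10,000 null proteins for the z-score calibration
(Monte-Carlo SE ≈ 0.2 percentage points), 100,000 for the S/N calibration
(SE ≈ 0.07 points), and 1500–2000 proteins for recovery/power studies —
sizes at which binomial error is far inside the asserted bands while a
full run stays in seconds. All random work flows through an explicit
integer seed and restores the caller's RNG state; identical configuration
and seed give byte-identical PSM tables and result files (no timestamps in
output headers), which is asserted down to the raw bytes.

## Known limitations

* Two strains, one or two replicates: the S/N procedure is not
  generalised past the designs it was defined for.
* No protein inference, no normalisation beyond centring, no moderated
  variance estimators — deliberate fidelity to the original procedure
  rather than a general-purpose limma competitor.
* Accession matching is exact and case-sensitive; no mapping across
  genome-annotation versions.
* The MGF reader handles the common dialect (BEGIN/END IONS, TITLE,
  PEPMASS, CHARGE, RTINSECONDS) only.

## A worked run

```{r example}
sim <- simulate_psm_data(n_proteins = 500, seed = 1)
report <- run_pipeline(sim$psms, sim$design,
                       signatures = stress_overlap_panels())
report
glance(report$diff)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(report$diff)
```
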