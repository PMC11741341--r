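---
title: "Methods: from TMT reporter ions to a calibrated secretome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from TMT reporter ions to a calibrated secretome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomics)
```

## The experiment this package models

An ER-targeted promiscuous biotin ligase (BirA\*) expressed in a tissue
of interest biotinylates proteins passing through the secretory
pathway. Biotinylated proteins captured from the circulation are
quantified by TMTpro multiplexing: each sample receives an isobaric tag
and contributes one reporter-ion channel to a single MS run. The
default design is a 12-plex with four conditions — a driver-only
control (`Ctrl`), ligase only (`BirA`), and ligase plus one of two
oncogenic drivers (`RasBirA`, `YkiBirA`) — with three replicates each.
The goal is a list of proteins enriched in the tumor-bearing samples
over the control: the candidate tumor secretome.

## Quantification model

**Impurity correction.** TMT tags carry isotopic impurities, so a
fraction of channel *j*'s true signal is read in neighbouring channels.
We encode this as a column-stochastic mixing matrix $M$ (column $j$ =
fate of channel $j$'s signal) and recover true signals per protein by
solving the linear system $M x = y$ with a general dense solver.
Determinant-based elimination (Cramer's rule, as vendor software
describes its correction) is algebraically identical for nonsingular
$M$; a factorization-based solve is numerically preferable and is what
`correct_impurities()` uses. Matrices with exact condition number
$\ge 10^8$ are rejected. Small negative solutions — noise pushing a
near-zero channel below zero — are clamped to 0 and flagged rather than
treated as errors; proteins with missing channels pass through
uncorrected and are flagged, since the system is underdetermined for
them.

**Filtering.** Downstream statistics use proteins with
`n_unique_peptides >= 2` and no missing channel. Completeness is
required *before* ratio computation so ratios are never formed from
imputed or partial rows.

**Ratios and normalization.** For protein $g$ and non-reference channel
$s$, the log2 ratio is $\log_2 I_{gs} - \overline{\log_2 I_{gc}}$
averaged over reference channels $c$ — the geometric-mean reference
intensity. The mean (default) versus median of reference-channel log2
intensities is exposed as `ref_summary`, since either convention is
defensible; with three reference replicates they differ negligibly.
Replicates are not paired across conditions. `median_normalize()`
subtracts each sample column's median, centring the aggregate ratio
distribution at 0 (idempotent; per-sample medians are 0 to within
1e-9).

**Moderated t.** For a contrast between conditions $a$ and $b$,
$\mathrm{logFC}_g = \bar{x}_{ga} - \bar{x}_{gb}$, with pooled variance
$s_g^2$ on $d_g = n_a + n_b - 2$ df. The empirical-Bayes prior
$(d_0, s_0^2)$ is estimated by the moment method: with
$z_g = \log s_g^2$, the identities
$E[z_g] = \log s_0^2 + \psi(d_g/2) - \log(d_g/2) - \psi(d_0/2) +
\log(d_0/2)$ and
$\mathrm{Var}[z_g] = \psi'(d_g/2) + \psi'(d_0/2)$ are solved for
$d_0$ by inverting the trigamma function with Newton iterations to a
relative tolerance of 1e-8. The posterior variance is
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and
$t_g = \mathrm{logFC}_g / (\tilde{s}_g \sqrt{1/n_a + 1/n_b})$ is
referred to a Student $t$ on $d_0 + d_g$ df, two-sided. Limits behave
as expected and are unit-tested: $d_0 = 0$ reproduces the ordinary
pooled t exactly; $d_0 = \infty$ (any estimate above $10^6$ is treated
as infinite, for numerical safety) uses the common variance $s_0^2$
with a normal reference distribution. When the simulated variances are
genuinely homoscedastic the moment estimator correctly drives
$d_0 \to \infty$; on heteroscedastic data it agrees with the
corresponding estimator in `limma` to at least six decimals (checked in
the test suite). Direction is two-sided here because enrichment
direction is enforced separately by the ratio threshold.

Contrasts against the reference condition are run **two-sample** on
per-channel median-centred log2 intensities rather than one-sample on
ratios. A one-sample t on ratios shares the reference-channel mean
across a protein's replicates: the shared term cancels from the sample
variance but not from the variance of the mean, so the test is
anti-conservative. The two-sample form on log2 data has no such
coupling; the ratio-table route still supports both modes for
standalone use. Proteins with fewer than two observed replicates in a
group are reported untested (`NA`) and excluded from the BH adjustment;
the BH step itself excludes missing p-values from the number of tests
and preserves input order.

## FPR threshold calibration

P-value cutoffs alone do not separate "statistically nonzero" from
"biologically secreted": ratio compression and shared background mean
an enrichment-ratio threshold is also needed, and its natural scale
differs per contrast. Following the control-gene approach, the
threshold is calibrated from annotated secreted genes (positive
controls, expected enriched) and annotated transcription factors
(negative controls, expected absent from circulation):

$$\mathrm{FPR}(t) = \frac{n_{NC}(\mathrm{logFC} \ge t)}
{n_{NC}(\mathrm{logFC} \ge t) + n_{PC}(\mathrm{logFC} \ge t)},$$

defined as 0 when no control lies at or above $t$. The empirical curve
only changes at observed control ratios, so the sweep over those values
(plus $-\infty$) is exact. The calibrated threshold is the *smallest
candidate whose entire suffix stays at or below the target* (10%
default): this guards against non-monotone empirical curves and is
deterministic. It is deliberately conservative — the returned value is
an observed control ratio, so when controls separate cleanly the
threshold sits at the first "clean" positive-control value rather than
inside the gap below it. Calibration is per contrast. A protein in
both control lists is ambiguous: it is labeled `none` and counted, so
it can neither inflate nor deflate the rate. Hits then require both
`p_adj < alpha` *and* `logFC >= threshold` (enrichment direction only;
depleted proteins are never hits), ordered by logFC descending with
identifier as the tie-break.

## Over-representation analysis

Gene-set enrichment among hits is the upper-tail hypergeometric test
$P(X \ge k)$ with universe $N$ = all proteins quantified after
filtering (the detected proteome is the sampling frame), set size $K$
after intersection with the universe, draws $n$ = hit-list size,
overlap $k$; BH across tested sets. Sets with fewer than 2 in-universe
genes are skipped and reported. This is the core test behind web-based
enrichment services, but exact p-values naturally differ from any
particular service's output because universes and annotation versions
differ. GMT input: a line needs at least a name and description field
(fewer is a parse error with its line number); a set with no genes is
dropped with a warning count; duplicate genes within a set count once.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the pipeline
must handle, with known truth so sensitivity, precision, and realized
FPR are measurable:

* log2 true intensity = protein baseline $\mathcal{N}(20, 2)$ +
  condition effect + cell noise $\mathcal{N}(0, \sigma)$ — the standard
  log-normal MS intensity model;
* a fraction `frac_enriched` of proteins (default 0.1) carries an
  additive `effect_size_log2` (default 2) in every non-reference
  condition; enrichment is treated as a protein property (secreted or
  not), so both tumor conditions share the enriched set;
* enriched proteins are drawn preferentially from the positive
  controls — 80% of PCs are truly enriched when the budget allows —
  and never from negative controls, mirroring the assumption that
  secreted annotations concentrate among true positives; with
  `frac_enriched = 0` nothing is enriched, including PCs;
* true intensities are mixed by a tridiagonal impurity matrix
  (`impurity_offdiag`, default 0.03 per adjacent channel — the scale of
  typical TMTpro adjacent-channel impurities); cells are then set
  missing uniformly at random (`missing_rate`, default 0);
* unique-peptide counts are uniform on `min_peptides_range` (default
  1–12), so the peptide filter is exercised at defaults.

Defaults (2000 proteins, 200 PC / 200 NC, noise sd 0.3) are chosen as
a realistic desk-scale stand-in for a hemolymph TMT experiment, sized
so the whole test suite runs in seconds. What the generator does *not*
model: peptide/spectrum-level variation and roll-up, intensity-dependent
variance trends, informative (intensity-dependent) missingness,
retention-time or fractionation structure, and batch effects across
plexes. Passing tests therefore demonstrate correctness of the
computations and calibration *under exchangeable log-normal noise*, not
robustness to every pathology of real MS data.

## Numerical and degenerate-input choices

* Impurity solve: LU-based `solve()`, exact-condition-number guard at
  1e8; clamp-and-flag for negative solutions.
* Trigamma inversion: Newton with asymptotic starts, tolerance 1e-8;
  prior df capped at 1e6 before being treated as infinite.
* Zero variance in every tested protein is a degenerate-fit error;
  isolated zero variances are shrunk like any other.
* Zero or missing intensities at ratio computation raise an error
  naming the protein and channel (the completeness filter normally
  prevents this).
* Ties in hit ordering break by protein identifier ascending, making
  outputs bitwise reproducible.
* qPCR: technical replicates are averaged on the dCt scale before the
  ΔΔCt difference; amplification efficiency is fixed at 2.

## Scale of the shipped checks

The test suite simulates experiments of 300–2000 proteins and verifies,
among other properties: impurity round-trips on 100 random mixing
matrices to 1e-9 relative error; type-I calibration on 10 null
simulations of 2000 proteins (raw positive fraction near 5%, under one
BH discovery per run on average); FPR recovery within 5 percentage
points of the 10% target over 10 simulations with 200 + 200 controls;
exact agreement of the threshold sweep with an exhaustive oracle; and
exact hypergeometric p-values against full draw enumeration for all
universes up to size 12. `scripts/acceptance.R` reruns the pipeline at
the 2000-protein defaults and reports the quantities it computes.

## Known limitations

* The reference condition for ratios defaults to the driver-only
  control but is configurable; comparisons against the ligase-only
  condition are equally supported and give different hit counts — the
  choice is biological, not statistical.
* The moderated model is a single two-group contrast; multi-factor
  designs, covariates, and intensity-trend priors are out of scope.
* Calibration quality degrades with few controls: with $n_{NC}$
  negative controls the empirical FPR moves in steps of order
  $1/n_{NC}$ near the threshold.
* ORA ignores annotation hierarchy and set overlap; ranked
  (KS-style) enrichment is not implemented.
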