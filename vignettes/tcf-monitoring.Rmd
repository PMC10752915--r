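---
title: "Quantifying tumor cell fraction in pLGG cultures by droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor cell fraction in pLGG cultures by droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plggtcf)
```

## The problem

Pediatric low-grade gliomas (pLGG), and pilocytic astrocytoma (PA) in
particular, are hard to grow in vitro: the MAPK-driven tumor cells enter
oncogene-induced senescence, and primary cultures are mixtures of tumor
cells and non-tumor microenvironmental cells that compete for the dish.
Establishing a patient-derived line (for example with inducible SV40 large
T antigen to bypass senescence) therefore needs close quality control: at
every passage one wants to know which fraction of the culture is still
tumor. Droplet digital PCR (ddPCR) against a tumor-specific DNA alteration
answers that with minimal gDNA input. This package implements the full
computational chain: droplet counts → concentrations → tumor cell fraction
(TCF) → longitudinal trajectory classification → cohort statistics, plus a
droplet-level simulator for testing every stage without access to raw plate
data.

## Measurement model

A ddPCR reaction is partitioned into $N$ droplets (typically ~20,000) of
volume $v$. With target concentration $c$ (copies/µl), the copies per
droplet are Poisson with mean $\lambda = c\,v$, so the probability that a
droplet is positive is $1 - e^{-\lambda}$ and, from $k$ positive droplets,

$$\hat\lambda = -\ln\!\left(1 - \frac{k}{N}\right), \qquad
  \hat c = \hat\lambda / v.$$

A fully positive well ($k = N$) carries no upper bound on $c$;
`estimate_lambda()` raises a saturation error rather than silently
correcting, because saturation usually means the sample was loaded too
concentrated and the well should be re-run. The droplet volume default is
`DEFAULT_DROPLET_VOLUME_UL` = 0.00085 µl (0.85 nl), the partition volume of
the instrument family these duplex assays were designed for; it is an
argument everywhere it matters.

Uncertainty is attached by a parametric bootstrap: positives are resampled
as $k^\ast \sim \mathrm{Binomial}(N, k/N)$, the estimator re-applied, and
empirical quantiles taken (default 2000 replicates, seed required). The
same machinery serves concentrations and TCFs, which is why a bootstrap was
preferred over a per-quantity delta method. In bootstrap resamples only, a
draw of $k^\ast = N$ is replaced by $N - 0.5$ so the quantiles remain
finite; the point estimate is never corrected.

## The two TCF estimators

**Duplication assay.** Tumor cells carrying the 7q34 tandem duplication
(the lesion underlying the KIAA1549:BRAF fusion) have 3 copies of BRAF exon
14 against 2 copies of the exon 3 reference; normal cells have 2 of each.
A mixture with tumor fraction $f$ has mean exon-14 copy number
$\mathrm{CN} = 2 + f$, estimated from the duplex as

$$\widehat{\mathrm{CN}} = 2\,\frac{c_{14}}{c_{3}}, \qquad
  \widehat{f} = \widehat{\mathrm{CN}} - 2 .$$

**Mutation assay.** BRAF V600E is assumed heterozygous and the locus
diploid: a tumor cell contributes 1 mutant + 1 wild-type allele, a normal
cell 2 wild-type. The mutant/wild-type concentration ratio at tumor
fraction $f$ is $r = f/(2-f)$, inverted as

$$\widehat{f} = \frac{2r}{1+r}, \qquad r = \frac{c_{\mathrm{MUT}}}{c_{\mathrm{WT}}}.$$

Both estimators clamp to $[0, 1]$ and set `clamped = TRUE` when the raw
value fell outside — noise can push a nearly-pure sample past the
boundary, and clamping with a flag keeps such wells analyzable but
auditable. An $r > 1$ additionally signals a violation of the
heterozygosity assumption. TCF values are fractions; `tcf_percent()` is the
(guarded) ×100 conversion used for reporting.

### Precision: the two assays are not equal

The partition-counting variance of $\hat\lambda$ is approximately
$(e^\lambda - 1)/N$. Propagated through the estimators at $N = 20{,}000$
droplets and a typical gDNA load (the reference channel near the
precision-optimal occupancy $\lambda \approx 1.4$), a single well gives a
TCF standard deviation of roughly 0.006 for the mutation assay but 0.03
for the duplication assay — discriminating copy number 2.5 from 2.55 is
intrinsically much harder than discriminating allele ratios. A single
20,000-droplet well therefore recovers TCF to ±0.05 (95% of runs) for the
mutation duplex, while the duplication duplex needs the usual remedy of
merging replicate wells (`merge_wells()`; four wells suffice). The test
suite checks exactly this, and users tracking duplication-positive samples
should plan plate layouts accordingly.

## Longitudinal monitoring and outcome calls

Cultures are followed per sample and medium arm (every sample is split
into astrocyte basal medium, ABM, and neural stem cell medium, NSM) at up
to four stages: `P0` (initial dissociated suspension, before the media
split), `P1` (after about one week), `TRANSDUCED` (first passage after
successful SV40-TAg infection) and `FINAL` (latest measurement).
`build_trajectory()` derives the swimmer-plot milestone chain — viable at
p1 → transduced → line established — which is monotone by construction.

Monitored cultures end in one of two states: tumor cells take over (TCF →
100%) or microenvironmental cells outgrow them (TCF → 0%).
`classify_outcome()` calls `ESTABLISHED` when the FINAL TCF is at or above
0.95 and `FAILED` at or below 0.05; the bands (rather than exact 1 and 0)
absorb measurement noise at the absorbing states and are configurable.
Everything between is `INDETERMINATE` — deliberately so, since a culture
at 50% has simply not finished competing. Untransduced cultures senesce
and are never classified as established; classification requires the
transduction milestone. The call depends only on the FINAL TCF, never on
intermediate dips, which is also a tested invariant.

`relative_change()` is defined as $(f_{p1} - f_{p0})/f_{p0}$ — change as a
fraction of baseline. A difference-based or log-ratio definition would
also have been defensible; the ratio form was chosen because it is the
most common reading of "relative change" and satisfies the exact identity
`relative_change(f, f (1 + x)) = x`, which the tests pin down. It is
undefined at a baseline of zero and errors there.

## Cohort statistics

The inferential layer wraps the stats package behind a uniform, validated
surface: Welch's unpaired $t$ test (the unequal-variance variant is the
default unpaired test of the wrapped package, and the safer choice when
group variances are unknown), classical one-way ANOVA with Tukey's HSD
(studentized-range adjusted pairwise $p$ values), Pearson correlation with
the $t$-transform test, and the five-number boxplot summary. Quantiles use
linear interpolation between order statistics (quantile type 7), stated
here once and fixed for reproducibility. Each wrapper is cross-checked in
the tests against hand-computed sums of squares and closed-form formulas
pushed through the corresponding distribution functions. No multiplicity
correction is applied beyond Tukey's.

## The synthetic world

The generator exists so that every pipeline stage can be tested from
droplet level up without any study data. It states a world; it does not
estimate one.

* **Mixtures.** `mixture_concentrations()` converts a true TCF into exact
  per-channel concentrations from the per-cell stoichiometry above —
  exon14/exon3 $= (2+f)/2$, MUT/WT $= f/(2-f)$ — at a default load of 800
  genome-equivalents/µl, which puts the reference channel near the
  precision-optimal droplet occupancy.
* **Wells.** `simulate_well()` draws positives as
  $\mathrm{Binomial}(N, 1 - e^{-cv})$ per channel — exactly the
  measurement model the estimators invert, so estimator bias would surface
  immediately.
* **Trajectories.** Growth competition is a discrete replicator map
  $f' = f w_T / (f w_T + (1-f) w_E)$ with per-passage fitness multipliers
  for tumor ($w_T$) and microenvironment ($w_E$). This is the simplest
  dynamic whose long-run behavior matches monitored cultures: every
  trajectory is absorbed at 0 or 1 unless $w_T = w_E$ exactly. Transduction
  multiplies $w_T$ by a boost factor from the transduction passage onward.
* **Cohorts.** `simulate_cohort()` draws ages from a truncated normal
  (mean 7.9, SD 5.4 years, truncated to 0–18), initial TCF from a
  truncated normal (mean 0.55, SD 0.23, truncated to the observed p0 range
  0.20–0.95), and alterations at frequencies 11:3:4
  (fusion : V600E : other). Tumor fitness declines linearly with age
  ($w_T = 1.2 - 0.06 \cdot \mathrm{age}$, floored at 0.6, against
  $w_E = 1$; boost 1.2), so younger samples are likelier to establish —
  the direction, not the magnitude, is the modeled claim. Workflow
  attrition follows the observed rates (17/18 viable at p1, 10/17
  transduced in ABM, none in NSM). No growth rates of this kind are
  published; the fitness numbers are tuning choices of the generator and
  all of them are overridable.

All randomness flows from a single seed through generator splitting
(`sample.int` under the parent seed yields one child seed per subtask), so
cohort-level runs are bit-reproducible regardless of how many wells they
contain.

What a green test on this world establishes: the estimators invert the
measurement model they assume, intervals are calibrated under binomial
partition noise, and the classification logic is consistent. What it does
not establish: anything about real droplet chemistry (rain, partial
inhibition, cross-talk between channels), non-droplet sources of TCF error
(sampling of the dish, subclonality, aneuploidy beyond the modeled loci),
or the biological accuracy of the replicator dynamics.

## Numerical and degenerate-input choices

* `-log1p(-k/N)` rather than `-log(1 - k/N)` for numerical accuracy at
  small positive fractions.
* $k = 0$ yields concentration 0 with a degenerate `[0, 0]` interval; the
  point mass is reported rather than a rule-of-three upper bound to keep
  the estimator/interval pair internally consistent.
* Bootstrap resamples with a zero reference channel carry no TCF
  information and are dropped from the quantile computation (they can only
  occur at extremely low reference loads).
* A mutant-free, wild-type-free well (`0, 0`) returns TCF 0; mutant signal
  without any wild-type raises an error, as it contradicts the
  heterozygous model rather than representing an extreme of it.
* Cohort tables are validated at parse time with errors naming the
  offending column or sample, and all sentinel and alteration strings are
  normalized on ingestion so downstream code never string-matches.

## Known limitations

* The duplication-assay precision floor discussed above: single-well TCF
  at $N = 20{,}000$ has SD ≈ 0.03 under ideal conditions.
* TCF from the duplication duplex assumes exactly one extra exon-14 copy
  per tumor cell; higher-order amplification or fusion variants without an
  exon-14 gain (for example PRKAR2B:BRAF) are outside the model, which is
  why such samples are counted as non-trackable.
* The mutation estimator assumes VAF is unaffected by copy-number change
  at the locus; no adjustment is attempted.
* The replicator map has no carrying capacity, senescence clock or
  transduction-efficiency structure — it reproduces the observed
  dichotomous endpoints, nothing mechanistic.
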