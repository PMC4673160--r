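---
title: "Isoform-group deconvolution from exon-level signals: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-group deconvolution from exon-level signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opnsplice)
```

## The measurement model

Exon-level expression platforms summarize probes into one value per probe
set, and each probe set interrogates one exon. Because every isoform that
retains an exon contributes its transcripts to that exon's signal, the
natural model on the linear scale is

$$ S_e \;=\; \sum_i M_{ie}\, a_i \;+\; \text{noise}, $$

where $M_{ie} \in \{0,1\}$ is the exon–isoform incidence matrix and $a_i
\ge 0$ the per-sample isoform abundances. Observed values are log2; all
additive arithmetic in this package therefore happens after linearizing
($2^{x}$). Whether a historical analysis subtracted log2 or linear values
is often unstated; linear is the physically coherent choice (transcript
counts add), and it is what `subtraction_estimates()` and
`lsq_estimates()` use. A log2-domain variant was considered and rejected as
a default because subtraction of log signals has no interpretation as an
abundance.

For the five-isoform osteopontin (*SPP1*/OPN) model shipped as
`spp1_gene()` — OPNa full; OPNb lacking exon 6; OPNc lacking exon 5; OPN4
lacking exons 4–6; OPN5 alone containing exon 4 — the incidence matrix has
the frequency vector (5, 5, 5, 1, 3, 3, 5, 5) over exons 1–8: exons 1, 2,
3, 7, 8 are *common* (every isoform), exon 4 is *private* to OPN5, and
exons 5 and 6 split the isoforms into complementary halves.

## Identifiability

Individual isoform abundances are usually not recoverable from exon
signals. Each *distinct* observed membership pattern contributes one
linear equation, so the estimable quantities are exactly the linear
functionals in the row space of that design. `identifiable_groups()`
computes this space by Gauss–Jordan reduction, rescales each basis row to
smallest integer coefficients, orders rows by first nonzero isoform, and
labels any 0/1 row as a "+"-joined *identifiable group*. The null space
(by SVD, tolerance scaled to machine precision) states precisely which
abundance combinations the data cannot distinguish.

Two consequences matter in practice:

* With no exon 6 probe set — the situation on a widely used exon array —
  the estimable groups are OPN5, OPNa+OPNb and OPNc+OPN4, and nothing
  finer. Any per-isoform claim from such data would be an artifact.
* Even with all 8 exons observed the design has rank 4 for 5 isoforms; the
  null space is spanned by (+1, −1, −1, +1, 0) over (OPNa, OPNb, OPNc,
  OPN4, OPN5). Full identifiability of this gene requires junction-level
  or isoform-specific measurements, not more exon probes.

Exons with identical membership columns are merged into one design
equation and their signals averaged — they carry the same information, and
keeping them separate would only re-weight noise.

## Estimators

**Total proxy.** Any common exon measures total gene output.
`select_total_proxy()` scores each common-exon probe set by the
cross-sample SD of its log2 signal after centering every sample at the
median of all common-exon probe sets. Median centering removes the
(large) sample-level expression differences so the score isolates
probe-level inconsistency. The `k = 3` lowest-scoring probe sets are kept
(ties broken by input order, making selection deterministic) and averaged
on the linear scale. `k = 3` mirrors the array analysis this generalizes;
raising `k` trades robustness against individual probe quality for noise
averaging.

**Subtraction.** When the observed exon patterns form a nested chain
(exon 4 carriers ⊂ exon 5 carriers ⊂ all isoforms, as here), groups follow
by successive subtraction: OPN5 = S₄, OPNa+OPNb = S₅ − S₄, OPNc+OPN4 =
S_total − S₅. Negative values — expected at low abundance under noise —
are clipped to 0 and *flagged*, never silently altered: abundances are
physical quantities, and the flags preserve diagnostics such as the
clipped fraction, which tends to 0 as noise does.

**Non-negative least squares.** `lsq_estimates()` generalizes to
non-nested designs: per sample it solves NNLS for abundances after
collapsing indistinguishable isoform classes (identical design columns)
into single unknowns, then evaluates the estimable functionals on the fit.
Estimable functionals depend only on fitted signals, so their values are
well defined despite the rank deficiency. On noise-free triangular
designs the two estimators agree to better than 1e-9 relative and both
reproduce the true group sums — an invariant the test suite enforces.

## qPCR quantification

`ddct_fold_change()` implements 2^−ΔΔCt with a reference index equal to
the arithmetic mean of the reference-gene Ct values (*GAPDH*, *ACTB*,
*RPLP0* by default) — the Ct-domain equivalent of a geometric mean of
linear quantities, which is how multi-gene normalization factors are
conventionally combined. The combination rule for the three-gene index is
not dictated by the source analysis; the arithmetic-mean-of-Ct reading was
chosen and is stated here explicitly. Amplification efficiency is fixed at
2.0 per cycle. Replicates are averaged per (sample, assay); pairs
spreading more than 1.0 cycle (configurable) are flagged, not dropped.
By construction the geometric mean fold over the calibrator set is exactly
1, and adding a constant to every assay's Ct in a sample leaves its fold
unchanged.

The overexpression caller uses threshold $T = 2m + s$ — twice the mean of
the Normal + Barrett's reference folds plus one sample SD ($n-1$
denominator) — with a *strict* inequality at the boundary. The phrase
"2-fold plus one standard deviation" admits a second reading (fold > 2 and
fold > m + s); it is available via `rule = "both"`, but $2m + s$ is the
default because it reduces to the plain 2-fold rule when the reference
group is noiseless. Stage-wise class comparisons use Welch t-tests on
log2 folds (folds are approximately log-normal; the log symmetrizes), with
degenerate classes (< 2 samples) summarized but excluded from testing.
Copy-number ratios from single-tube co-amplification use gain/loss bounds
1.5 / 0.67; these bounds are reporting conveniences, configurable, not
biological claims.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis
assumes, and only that:

* **Co-overexpression mechanism**: one shared per-sample log-normal factor
  (log2 SD `sample_factor_sd = 1.0`) multiplies all isoforms. This is the
  simplest mechanism that makes every isoform group correlate with total
  expression within a cohort, which is the phenomenon the deconvolution
  is meant to exhibit.
* **Tumor shift**: per-class additive log2 shifts of the total, default 0
  for Normal and Barrett's (BE), +0.5 for dysplasia, +3 (8-fold) for all
  EAC stages. The 8-fold value is the configured effect size used by the
  caller-sensitivity checks.
* **Splice proportions**: per-sample Dirichlet draws with concentrations
  (48, 48, 16, 8, 8) for (OPNa, OPNb, OPNc, OPN4, OPN5). The *ratios*
  6:6:2:1:1 encode the qualitative observations that OPNc is clearly
  scarcer than OPNa/OPNb and that OPNb exceeds or trails OPNa in
  individual tumors. The concentration *scale* (×8) was set so splice
  proportions are moderately stable across samples (per-isoform CV roughly
  30–45%): with much looser proportions the minor-isoform groups decouple
  from total expression, contradicting the co-overexpression the cohorts
  being emulated actually show. Both numbers are reconstructions, not
  measured values, and are tunable.
* **Probe signals**: log2 of the incidence-weighted abundance sum plus
  N(0, `probe_noise_sd = 0.1`) per probe set; 4 probe sets per common
  exon, 1 elsewhere, mimicking common-exon redundancy on exon arrays.
* **Ct tables**: Ct = `ct_intercept` − log2(quantity) + N(0,
  `ct_noise_sd = 0.2`) per replicate (duplicates by default), reference
  genes at constant quantity.

All randomness flows through one seed (`withr::with_seed`), leaving the
global RNG untouched; identical configurations produce byte-identical
outputs.

What the generator deliberately does **not** emulate: array hybridization
physics, probe-sequence effects, batch structure, RNA degradation,
cross-hybridization, or any correlation between splice proportions and
histology class. Passing tests therefore demonstrate the *statistical
machinery* — identifiability, estimator correctness, calling rules — not
robustness to real-array artifacts.

## Problem sizes and numerical choices

Simulation-based checks use cohorts of about 200 samples (29 per class
over the seven histology classes) and sweep 20 seeds where a property is
distributional; these sizes echo the array cohorts this style of analysis
is applied to (~120 tumors) while keeping the suite quick. Rank and
null-space decisions use SVD with a tolerance scaled to the largest
singular value and machine epsilon; integer rescaling of functionals
searches multipliers up to 64 and falls back to the raw real vector beyond
that. Degenerate inputs are first-class: empty isoform lists, unknown
exons, non-positive Ct values, zero-variance groups (correlation reported
as not computable, never 0), and all-zero expression (all groups 0, no
clipping flags) are each handled and tested.

## Known limitations

* **Remainder groups are the noisiest.** A group obtained as the
  difference of two large signals (here OPNc+OPN4 = S_total − S₅, about
  19% of the total) inherits the *absolute* noise of both, roughly a
  five-fold relative amplification at these proportions. At probe noise
  0.1 its cohort recovery correlation sits near 0.85–0.93 across seeds,
  versus > 0.99 for OPN5 and OPNa+OPNb; improving it requires more probe
  sets on the discriminating exons or lower probe noise, not a different
  estimator (NNLS gives the same floor). Interpret remainder-group values
  accordingly.
* Exon ordinals, not genomic coordinates, define exon identity; annotation
  input must use a consistent numbering (GTF input assigns ordinals by
  strand-aware genomic order).
* The amplicon ladder in `spp1_gene()` places the primer anchors in exons
  3 and 7 with exon lengths chosen to reproduce the observed 253/211/172
  bp products for OPNa/b/c; the actual primer positions of the original
  assay were not published, so OPN4/OPN5 product sizes (130/337 bp) are a
  model prediction, not an observed gel.
* No multiple-testing correction is applied to group correlations (three
  groups; the analogous cohort analysis reported uncorrected values); the
  p-values are conventional t-transform values and should be treated as
  descriptive.
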