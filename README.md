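# opnsplice

Osteopontin (*SPP1*/OPN) is expressed as five splice isoforms — OPNa (the
full transcript), OPNb (lacking exon 6), OPNc (lacking exon 5), OPN4
(lacking exons 4–6) and OPN5 (the only isoform containing exon 4) — and all
five are co-overexpressed in esophageal adenocarcinoma (EAC) relative to
normal esophagus and Barrett's metaplasia. Demonstrating this from exon
array data is not trivial: exon-level probe sets measure *sums* of isoform
abundances (every isoform containing the probed exon contributes), and
arrays may lack probe sets for discriminating exons entirely, so individual
isoforms are often not identifiable. `opnsplice` implements the analysis
that handles this correctly, for anyone quantifying splice-isoform groups
from exon-level signals or qRT-PCR in tumor cohorts.

## What the package computes

**Exon–isoform incidence and identifiability.** For a gene model with
isoforms \(i\) and exons \(e\), the binary incidence matrix \(M_{ie}\)
records exon membership. An exon-level signal is
\(S_e = \sum_i M_{ie}\, a_i\) with \(a_i \ge 0\) the isoform abundances.
Each *distinct* observed membership pattern contributes one linear
equation; the row space of this design is the space of estimable linear
functionals of \((a_i)\), computed by Gauss–Jordan reduction and reported
as "+"-joined isoform groups whenever a basis functional has 0/1
coefficients. For the five-isoform *SPP1* model with no exon 6 probe set
(the situation on the ST 2.1 exon array), the identifiable groups are
exactly **OPN5**, **OPNa+OPNb** and **OPNc+OPN4**; with all 8 exons
observed the design has rank 4 and a one-dimensional null space spanned by
(OPNa: +1, OPNb: −1, OPNc: −1, OPN4: +1, OPN5: 0).

**Group deconvolution.** Total OPN expression is proxied by the mean
(linear scale) of the `k = 3` common-exon probe sets with the smallest
cross-sample deviation after per-sample median centering. Group abundances
then follow by successive subtraction on the linear scale —
OPN5 = S₄, OPNa+OPNb = S₅ − S₄, OPNc+OPN4 = S_total − S₅ — with negative
estimates clipped to zero and flagged. A non-negative least-squares
estimator (`lsq_estimates()`) generalizes the subtraction scheme to
arbitrary designs and agrees with it to numerical precision on noise-free
data. Pearson correlations of each group against the total quantify
cohort-level co-overexpression.

**qRT-PCR quantification.** Fold changes use 2^−ΔΔCt with a three-gene
reference index (arithmetic mean of *GAPDH*, *ACTB*, *RPLP0* Ct values);
tumors are called overexpressing when fold > 2·m + s, with m, s the mean
and SD of the Normal + Barrett's reference folds; matched-pair copy-number
ratios come from single-tube co-amplification arithmetic
2^−[(ΔCt_tumor) − (ΔCt_normal)]. Per-isoform RT-PCR amplicon lengths are
predicted from the exon structure (OPNa/b/c ladder 253/211/172 bp).

**Synthetic cohorts.** A seeded generator produces labeled cohorts with a
shared per-sample log-normal factor (the co-overexpression mechanism), an
8-fold mean EAC shift, Dirichlet splice proportions (OPNa ≈ OPNb > OPNc >
OPN4 ≈ OPN5), exon-level probe signals with log2 noise, and Ct tables — so
the whole pipeline is testable with no external data.

## Worked example

```r
library(opnsplice)

gene <- spp1_gene()
M <- build_incidence(gene$exons, gene$isoforms)
M
#> Exon-isoform incidence matrix (5 isoforms x 8 exons)
#>           exon1 exon2 exon3 exon4 exon5 exon6 exon7 exon8
#> OPNa          1     1     1     0     1     1     1     1
#> OPNb          1     1     1     0     1     0     1     1
#> OPNc          1     1     1     0     0     1     1     1
#> OPN4          1     1     1     0     0     0     1     1
#> OPN5          1     1     1     1     1     1     1     1
#> frequency     5     5     5     1     3     3     5     5

predict_amplicons(M, gene$primers)
#> OPNa OPNb OPNc OPN4 OPN5
#>  253  211  172  130  337

identifiable_groups(M, observed_exons = c(1, 2, 3, 4, 5, 7, 8))
#> Identifiability from exons {1, 2, 3, 4, 5, 7, 8}
#>   design rank: 3 of 5 isoforms
#>   estimable functionals: OPNa+OPNb; OPNc+OPN4; OPN5
#>   fully identifiable: FALSE

cfg <- sim_config(n_per_class = 29, seed = 1)
cohort <- simulate_cohort(cfg)
X <- simulate_exon_signals(cohort$truth, M, cfg,
                           observed_exons = c(1, 2, 3, 4, 5, 7, 8))
proxy <- select_total_proxy(X, M, k = 3)
est <- subtraction_estimates(proxy, X, M, c(1, 2, 3, 4, 5, 7, 8))
correlate_groups(est, proxy)
#>   group_label pearson_r       p_value   n computable
#> 1        OPN5 0.9254677  1.120961e-86 203       TRUE
#> 2   OPNa+OPNb 0.9952692 1.711297e-205 203       TRUE
#> 3   OPNc+OPN4 0.9095822  1.343851e-78 203       TRUE
```

The incidence matrix encodes which exon signals inform which isoforms; the
frequency row shows that exons 1, 2, 3, 7, 8 are common to all five
isoforms (total-expression candidates), exon 4 is private to OPN5, and exon
5 separates OPNa/OPNb/OPN5 from OPNc/OPN4. The amplicon vector is the
single-tube RT-PCR ladder a primer pair anchored in exons 3 and 7 would
produce. The correlation table is the cohort-level co-overexpression
result: every identifiable isoform group tracks total OPN expression
(r ≈ 0.91–0.995 on this seeded cohort of 203 samples).

The same analysis runs end to end from a YAML configuration
(`inst/extdata/pipeline-config.yaml`) via `run_pipeline()`, or from the
shell via the thin CLI in `inst/cli/opnsplice`
(`simulate | incidence | deconvolve | qpcr | report` subcommands).

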