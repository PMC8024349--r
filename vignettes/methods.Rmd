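---
title: "Models and methods behind milkqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind milkqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`milkqtl` implements the analysis chain used in dairy-cattle quantitative
genetics to go from repeated test-day phenotypes (for example milk mineral
concentrations predicted from mid-infrared spectra) to regulatory variant
candidates: variance components, yield deviations, a mixed-linear-model
GWAS against imputed sequence dosages, QTL delineation, variant
annotation, PWM-based regulatory-SNP calling, tissue-specificity scoring,
and two-locus interaction tests. Because commercial test-day datasets are
restricted, the package ships a synthetic-data generator with known ground
truth; every statistical guarantee the package makes is demonstrated on
that generator.

## The repeatability animal model

For a pair of traits the records follow

\[
\mathbf{y} = \mathbf{X\beta} + \mathbf{Za} + \mathbf{Wp} + \mathbf{e},
\]

with fixed effects \(\beta\) (herd x test-day combination, lactation
stage, season of calving), additive genetic effects
\(\mathbf{a} \sim N(0, \mathbf{A} \otimes \mathbf{G}_0)\) where
\(\mathbf{A}\) is the pedigree numerator relationship matrix, permanent
environmental effects \(\mathbf{p} \sim N(0, \mathbf{I} \otimes
\mathbf{P}_0)\) capturing the repeated records of each cow, and residuals
\(\mathbf{e} \sim N(0, \mathbf{I} \otimes \mathbf{R}_0)\). The 2x2
matrices \(\mathbf{G}_0, \mathbf{P}_0, \mathbf{R}_0\) give per-trait
heritabilities \(h^2_i = g_{ii}/(g_{ii}+p_{ii}+r_{ii})\) and the genetic
correlation \(r_g = g_{12}/\sqrt{g_{11}g_{22}}\).

**Estimation.** `fit_bivariate_reml()` maximizes the exact restricted
likelihood through the sparse mixed-model equations:
\(-2\,l_R = \log|\mathbf{R}| + \log|\mathbf{G}| + \log|\mathbf{C}| +
\mathbf{y}'\mathbf{Py}\) up to a constant, with \(\mathbf{A}^{-1}\) built
directly from the pedigree by Henderson's rules (inbreeding from the
Meuwissen-Luo algorithm). The nine covariance parameters are
parameterized by Cholesky factors, which enforces positive
semi-definiteness without constraints, and optimized by quasi-Newton
(L-BFGS-B) from moment-based starting values (within-cow covariance for
\(\mathbf{R}_0\), a split of the between-cow covariance for
\(\mathbf{G}_0\) and \(\mathbf{P}_0\)). We chose direct maximization over
classical average-information updates because one code path handles
interior and boundary solutions alike; diagonal parameters are bounded
below at \(10^{-8}\times\) the phenotypic variance, and estimates at that
bound raise the `boundary` flag. Convergence is declared at a relative
restricted-log-likelihood change of \(10^{-6}\). The average-information
matrix is still computed at the optimum — from working vectors requiring
only solves against the factored coefficient matrix — and its inverse
gives delta-method standard errors for \(h^2\) and \(r_g\). The sparse
pattern of the coefficient matrix is assembled once and only its values
are refreshed across likelihood evaluations, so a 3000-cow, 24,000-record
bivariate fit takes about half a minute on one core.

**Yield deviations.** The GWAS response is the average of a cow's records
adjusted for non-genetic effects. Which effects count as "non-genetic" is
genuinely ambiguous for the permanent-environment BLUP, so
`compute_yield_deviations()` exposes `subtract_pe`: the default (TRUE)
subtracts both fixed-effect estimates and the PE BLUP, retaining the
additive signal. Note a consequence we quantified on synthetic data: the
PE term absorbs the within-family part of any single-QTL signal, so
planted-QTL effects reach the GWAS attenuated by roughly one third at 8
records per cow. Cows with fewer than `min_records` (default 3) records
are dropped and counted.

## Mixed-linear-model association

Per variant \(v\), `mlma_scan()` fits
\(\mathbf{yd} = \mathbf{1}m + \mathbf{x}_v b_v + \mathbf{u} +
\boldsymbol\varepsilon\) with
\(\mathbf{u} \sim N(0, \mathbf{G}\sigma^2_u)\), where \(\mathbf{G}\) is
the VanRaden method-1 genomic relationship matrix and the variance
components come from the null model (`fit_null()`, REML via a single
eigendecomposition of \(\mathbf{G}\) and a 1-D profile likelihood in the
variance ratio) and are then held fixed. Dosages are used as imputed
expectations in \([0,2]\), never hard-called. Estimation is generalized
least squares in the GRM eigenbasis (O(n) per variant after one rotation
of the dosage matrix); the association test is \(t = b_v/\mathrm{SE}\)
against a standard-normal reference by default (an exact t reference is
available via `df` for small simulations). The scan matches a dense
\(\mathbf{V}^{-1}\) solve to \(10^{-8}\) and holds its nominal type-I
error on permuted phenotypes.

On the GRM subset: the study design this package emulates computes the
polygenic covariance from a dense high-density panel while testing
sequence variants. At desk scale our "chip" subset is only ~10% of a few
thousand simulated variants, which controls family structure poorly and
produces spurious singleton regions; `compute_grm(subset = "all")` is the
faithful miniature of a dense HD panel and is what the pipeline tests
use. Leave-one-chromosome-out is deliberately not implemented, mirroring
the practice of building the GRM from an array panel distinct from the
tested sequence variants; proximal contamination is therefore possible
for variants on the array, and is documented rather than corrected.

## QTL delineation

Variants are retained when imputation \(R^2 \ge 0.20\) and
\(\mathrm{MAF} \ge 0.005\) (inclusive bounds). The genome-wide threshold
is Bonferroni: \(-\log_{10}(\alpha/n_\mathrm{tests})\), which for 12.9
million tests at \(\alpha = 0.05\) is 8.4 (nominal \(4\times10^{-9}\)).
Significant variants are chained into regions per chromosome by single
linkage with a strict 2-Mbp gap rule; whether the rule chains pairwise or
from region extremes is unstated in the source literature, and we chose
single linkage as the more conservative (region-growing) reading.

The confidence interval of a region spans the member variants in the
"upper third of the QTL peak". We read peak height on the
\(-\log_{10}P\) scale measured from the significance threshold \(T\) to
the maximum \(M\): the CI keeps variants scoring at least
\(T + \tfrac{2}{3}(M - T)\). The threshold-relative reading keeps CIs
well defined when \(M\) barely clears \(T\); the from-zero alternative
(\(\ge \tfrac{2}{3}M\)) sits behind `from = "zero"`. Ties for the top
variant break by higher imputation \(R^2\), then lower position.

Conditional analysis (`conditional_scan()`) refits the scan with the lead
variant as a fixed covariate, skipping variants with dosage
\(r^2 \ge 0.9\) against the lead; a region is rejected when no tested
member stays genome-wide significant. With near-perfect LD twins the
"causal" and "shadow" labels are statistically exchangeable — the twin
holding the lead survives, the other is rejected — which is exactly the
behaviour conditional analysis is meant to have.

Per-QTL variance explained is \(100 \cdot 2p(1-p)b^2/\sigma^2_g\) with
\(p\) the ALT frequency, \(b\) the estimated effect and \(\sigma^2_g\)
the null-model additive variance of the yield deviations; no LD
correction is applied when summing across QTL.

## Variant annotation

`classify_variant()` classifies each variant against every overlapping
transcript with precedence coding > splice > UTR > intron >
upstream/downstream, using GenomicRanges for overlap and Biostrings for
codon translation on the correct strand. Definitions follow VEP
conventions where the category vocabulary leaves them open: 5-kb
upstream/downstream windows (strand-aware), splice_acceptor = the last 2
intronic bases before an exon in transcription direction, splice_region
= 1-3 exonic or 3-8 intronic bases from a junction (donor bases 1-2 are
reported as splice_region because the vocabulary has no donor class).
Non-coding biotypes (lncRNA, miRNA, snRNA, scaRNA, tRNA) label their
exonic variants. Length-changing CDS variants are frameshift when the
length difference is not a multiple of 3. The classifier is tested for
100% agreement against an independently written brute-force
interval-and-codon oracle on simulated gene models.

## Regulatory prioritization

**PWM scoring.** Count matrices become log2-odds scores with a total
pseudocount of 0.8 split by background frequency (the common JASPAR-tool
convention; the source databases publish no single scheme).
`scan_pwm()` maximizes over all offsets and both strands with a
deterministic tie rule. Site significance uses the per-PWM null
distribution of single-window scores under the background model —
computed exactly for motifs up to 12 bp by convolving per-position score
distributions (equivalent to enumerating all \(4^L\) windows), by Monte
Carlo above that. A variant's TFBS verdict compares the best window score
of each allele to the site threshold `p_site` (default 0.05): loss =
reference significant, alternate not; gain = the reverse. One caveat
found while testing: for sharp consensus motifs a single substitution
rarely moves a site across the 0.05 line (a 7/8 match is still far into
the null tail), so loss/gain calling is most informative at stricter
`p_site`; the parameter is exposed for that reason.

**Tissue specificity.** For gene expression (scaled log2 FPKM-like
values) the model is \(\mathbf{ye} = \mathbf{1}me + \mathbf{x}_t b_t +
\mathbf{zc} + \mathbf{ee}\), fitted by OLS on the tested tissue's samples
(coded +1) together with samples outside the tissue's biological category
(coded -1); same-category other tissues are excluded, and age, sex and
study are covariates (dropped with a warning when collinear). A gene is
overexpressed when \(t = b_t/\mathrm{SE} > 0\) and \(P_t < 10^{-4}\) (the
positive-sign requirement makes "overexpressed" one-directional, which
the threshold alone would not). Tissue-specific genes are the top 10% by
t-statistic; the set size uses floor(0.10 n) — the convention that
reproduces both published counts we can check (203 genes -> 20, 160 TFs
-> 16) — with ceiling available behind a flag. rSNPs whose TF and target
gene are both tissue-specific are intersected by
`rsnp_specific_pairs()`; the TF-to-target map is positional (nearest
transcript with an upstream call), a documented stand-in for an unstated
mapping.

## Two-locus interaction

`interaction_test()` fits yd ~ genotype1 * genotype2 + (1 | sire) by REML
(lme4), with hard genotype calls obtained from dosages by rounding after
discarding dosages in (0.2, 0.8) or (1.2, 1.8). Main effects and the
interaction are Wald chi-square tests on coefficient blocks; empty cells
drop their contrasts. With no sire grouping the fit reduces exactly to
the two-way ANOVA. Under a purely additive simulated architecture the
interaction test holds its nominal type-I error (checked at
\(\alpha = 0.01\) over 500 simulations).

## The synthetic-data generator

`simulate_study()` emulates the structure of a large test-day study at
desk scale. Choices and what they do and do not capture:

* **Pedigree**: founder sires and dams, then 3 generations of cows
  drawing a sire from a shared pool (half-sib families dominate, low
  inbreeding). Real pedigrees are deeper and inbred; the tabular-method
  and Henderson-rule code paths handle inbreeding regardless.
* **Dosages**: variants sit in LD blocks (default 100 kb); each block
  carries one founder locus transmitted by Mendelian gene dropping, and
  every variant in a block is a per-haplotype 1%-flip-noise copy of it.
  This produces controllable within-block \(r^2\) (median > 0.9
  adjacent) and independent blocks — sufficient to exercise all
  \(r^2\)-based logic, but it is not a coalescent and has no recombination
  gradient. Imputation \(R^2\) is assigned (Beta(2,1), mean 2/3, matching
  the sequence-imputation scale reported for such data), with a 10% chip
  subset at \(R^2 = 1\); the imputation process itself is out of scope.
* **Phenotypes**: per-trait phenotypic variance 1; additive variance =
  the heritability target (defaults 0.33-0.57, the milk-mineral scale);
  permanent environment 15%; genetic correlations from a fixed PSD matrix
  spanning -0.25 to 0.60; herd x test-day, lactation-stage and
  season-of-calving fixed effects; at least 7 records per cow by default.
  Planted QTL are added on top of the polygenic term and excluded from
  its bookkeeping, so realized heritability slightly exceeds the target
  when QTL are planted. QTL effect sizes are normal with configurable SD,
  or sized to a requested fraction of additive variance
  (`qtl_var_frac`); the recovery tests plant 5 QTL at 15% each — the
  study conditions we chose so that signals survive the yield-deviation
  attenuation described above.
* **Gene models**: 2-4-exon protein-coding genes (valid ATG..stop CDS,
  no internal stops, GT..AG introns) plus single-exon non-coding
  biotypes, written consistently into random background chromosomes on
  both strands.
* **Expression atlas**: 12 tissues in 4 categories, 6 samples each, with
  two designated overexpressed genes per tissue shifted by +3 residual
  SD, and age/sex/study covariates.
* **PWMs**: count matrices with consensus columns (94/100) and a few
  degenerate columns, lengths 6-12 by default, serialized as JASPAR text.

Every generator is bit-reproducible from `seed`; module sub-seeds are
derived arithmetically so the streams are independent.

Passing tests on these data show that the estimators are correct and
calibrated under the stated models; they do not show robustness to
features real data have and the generator lacks: genotyping error,
selection, heterogeneous variance across herds, non-normal residuals,
lactation-curve trends, or realistic LD decay.

## Problem sizes used in the shipped checks

The recovery suites run at: 3000 cows x 8 records, 10 replicates for
variance components; 1000 cows x 10,000 null variants for scan
calibration; 1500 cows x 3000 variants x 10 seeds for the full QTL
pipeline; 500 simulations for interaction-test calibration. These sizes
were chosen as the smallest at which the sampling error of each check is
comfortably below the tolerance it asserts.
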