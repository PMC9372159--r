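---
title: "Models and methods behind clonehist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonehist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonehist)
```

clonehist implements the computational core of a multi-region,
laser-capture microdissection study design for germ cell tumours (GCTs):
hundreds of near-monoclonal microbiopsies per tumour, each yielding a
low-depth whole genome (roughly 15–48x) and/or a bulk-miniaturised
transcriptome, analysed against a matched normal and an unmatched panel of
normals. This vignette describes each model, its assumptions, the tunable
parameters and their defaults, and the design choices made where the
design was genuinely open.

## Variant rescue with a panel-based beta-binomial error model

Low-depth microbiopsies lose real mutations to hard filters. The package
rescues them in two steps. First, a multi-sample pileup across the
patient's biopsies removes sites with mean coverage <= 10x (probable
mapping artefacts; `pileup_rescue()`, boundary inclusive). Second, each
remaining (site, sample) pair is tested against a locus-specific error
rate learned from an unmatched panel of normal samples prepared on the
same platform (`fit_panel_error()`): the per-site mean error is the
pseudocount-regularised pooled alt fraction (pseudocounts 0.5/0.5 avoid
degenerate zero-error tails on clean panels), and a single global
overdispersion is fitted by the method of moments — per-site
overdispersion fits are unstable at panel depths (250 samples x ~30x for
substitutions, 100 for indels; a configuration knob, not two code paths).

`betabinom_rescue()` computes the one-sided upper-tail beta-binomial
probability P[X >= alt] and applies Benjamini–Hochberg correction with
presence called at adjusted p < 0.001. A tail probability replaces the
original Shearwater-style likelihood-ratio machinery because the published
procedure thresholds a corrected p-value, not a Bayes factor. Correction
pools across sites x samples within a patient by default; a `pool =
"sites"` switch corrects within samples, since the published description
does not fix this choice.

Sample eligibility throughout uses the average reads per chromosome copy,

  purity / (purity * ploidy + (1 - purity) * 2) * coverage,

with >= 5 required for clustering and >= 7 for copy-number gain timing.

## CCF clustering and the clone tree

`cluster_ccf()` fits a Dirichlet-process binomial mixture across a
patient's biopsies: mutation i in biopsy j contributes alt_ij ~
Binomial(total_ij, theta_kj * f_ij) where theta_kj is the cluster's cancer
cell fraction (CCF) and f_ij maps CCF to expected VAF through purity,
local total copy number and mutation multiplicity. Cluster CCFs live on a
discrete grid over [0, 1.25] (step 0.025) so a fully clonal cluster is
interior to the support; assignments are resampled by a collapsed
Chinese-restaurant sweep and cluster CCFs from their grid posterior. The
concentration parameter defaults to 1.0. Joint n-dimensional clustering
replaces the original triplet-wise combination of sample subsets, which
was a scalability workaround rather than a statistical requirement.
Defaults of 1000 sweeps with 200 burn-in match the multidimensional
setting; 3000/1000 suit designs with five or fewer biopsies. The point
clustering is the recorded partition closest to the posterior mean
co-clustering matrix (maximum posterior similarity), ties broken by the
smaller cluster count — the summarisation of posterior samples into
reported clusters is not fixed by the published procedure, so this
standard choice is stated explicitly. Only autosomal substitutions enter
clustering.

Clusters under 1% of the patient's substitutions or under 20 substitutions
are removed (`filter_clusters()`). `build_tree()` designates as trunk the
cluster present (CCF strictly > 0.1) in every biopsy with maximal mean
CCF, and nests every other cluster under its smallest-CCF dominator by the
pigeonhole principle, with a per-biopsy tolerance of 0.05. Parents are
restricted to clusters ranked strictly higher by total CCF, which
guarantees an acyclic tree even when sibling clusters tie. "Small clusters
violating the remainder of the tree" have no quantitative published rule;
the package flags clusters whose pigeonhole residual exceeds 0.1 while
holding under 5% of the trunk's mutations. In GCNIS-bearing patients,
clusters shared between in-situ and invasive biopsies are folded into the
trunk.

The trunk proportion is trunk / (trunk + mean tip distance), where each
branch tip contributes its full mutation distance back to the trunk —
internal branches shared by several tips are deliberately double-counted,
once per tip, normalising all subclonal branches equally
(`trunk_proportion()`).

## Timing whole-genome duplication in mutation time

On a duplicated allele, mutations acquired before the gain sit on both
derivative copies (multiplicity 2); later mutations sit on one copy.
For the timeable states 2+0, 2+1 and 2+2 the gain time is

  t = 2 n2 / (2 n2 + n1)   (2+0, 2+2),
  t = 3 n2 / (2 n2 + n1)   (2+1),

truncated to [0, 1], with a 95% percentile interval over 200 multinomial
bootstrap resamples (the published procedure fixes the >= 0.5 CI-width
exclusion but not the CI construction). Counts may be fractional.

`assign_multiplicity()` gives the hard maximum-likelihood multiplicity
(ties to 1). `time_segments()` however defaults to
`multiplicity_posterior()`, which fits each segment's multiplicity-2
mixture weight by maximum likelihood and sums per-mutation posterior
probabilities into soft counts. The reason is bias: at ~30x a depth-limited
hard classifier misassigns a few percent of the abundant multiplicity-1
mutations, which swamps the small true multiplicity-2 count whenever the
duplication was early — precisely the regime of interest in postpubertal
GCTs. The soft count is approximately unbiased there and agrees with hard
counts when the classes are well separated. Hard counting remains
available via `method = "hard"`.

The copy-number-adjusted pre-duplication burden inflates the raw
multiplicity-2 count by the fraction of eligible-segment substitutions on
2+1/2+0 segments, compensating the pre-duplication mutations on minor
alleles that cannot be observed there, and is extrapolated genome-wide by
covered length (default genome length 2,875,001,522 autosomal bases,
GRCh37). Whole-genome duplication is called when subclonality-weighted
ploidy >= 2.9 − 2 x (weighted homozygous fraction), boundary inclusive.
Burdens convert to primordial germ cell divisions by dividing by twice the
published 0.5–0.7 substitutions per haploid genome per division (midpoint
0.6 for the point estimate, rounded for reporting; both mean and median
are worth reporting across tumours since the published summary does not
say which it is). The burden-vs-age trend is fitted as y = a + b exp(c *
age) by profiling c (linear in a, b for fixed c) over a log-spaced grid
refined by golden-section search — deterministic, no starting values
needed. Chronological (CpG-clock) dating is deliberately out of scope:
GCT hypomethylation makes the CpG mutation rate non-clock-like.

Focal drivers: amplifications are segments < 1 Mb reaching 5 total copies
(ploidy < 2.7) or 9 (ploidy >= 2.7); deletions share the size/ploidy
cut-offs with total copy number 0 or below ploidy − 2.7; 1–10 Mb segments
meeting the copy threshold are reported as a separate "gain" tier.

## Histology-versus-clone concordance and the variance test

The genetic score of a biopsy pair is the substitutions in clusters
present in both (CCF > 0.1) over the mean of the two total burdens; the
transcriptomic score is the Pearson correlation of log2(TPM + 1) over
protein-coding genes outside the haemoglobin/immunoglobulin/cycling/
housekeeping exclusion sets. The +1 pseudocount makes the log defined at
zero while preserving monotonicity. `label_swap_test()` permutes the
intra/inter labels over pairwise comparisons (not over samples — a
sample-relabelling variant exists for sensitivity analysis) with statistic
median(intra) − median(inter); sampled mode uses the add-one convention
p = (1 + exceedances)/(n_perm + 1) with ties counted as exceedances
(conservative), and designs whose label assignments number at most
`n_perm` are enumerated exhaustively with p = (1 + alternatives >=
observed)/#assignments — a 4-genome, two-histology design yields exactly
15 assignments. The chromothripsis variance test compares the variance of
a focal tumour's intra-histology correlations against variances of random
same-size subsets of the correlations pooled across tumours; large
variance indicates transcriptional heterogeneity.

## Expression dosage analysis

Libraries expressing fewer than 1000 genes at >= 5 reads are removed
(strict boundary). TPM columns sum to 1e6 by construction. The
differential-expression routine is a deliberately self-contained Welch
test on log2(TPM + 1) with BH correction and a blocked variant (unweighted
mean of per-histology fold-changes; tests on within-histology-centred
values): the package's contribution is the permutation and rolling
machinery around the DE table, and any externally computed table with
`gene`/`log2fc` columns can be supplied instead. Rolling fold-change
tracks average 50 consecutive genes ranked by start coordinate (gene rank,
not base pairs, is the support). Cytoband enrichment is a rank-sum
comparison per band (>= 5 genes) against all other genes. The dosage test
draws `n_draws = 100,000` random gene sets, sized to the retained target
set, without replacement (a with-replacement flag exists; the published
description does not say) from genes on segments within ±0.5 of the
sample's ploidy, and reports the one-sided add-one p for the target's mean
log2 fold-change. Genes filtered from the DE table are excluded from
target and pool alike, and the pool is used exactly as supplied — removing
target genes from a legitimately overlapping pool breaks exchangeability
under the null. Gene-to-band and gene-to-segment assignment uses the gene
start coordinate (deterministic and strand-free).

## Mutational signatures

Spectra use the fixed 96-channel pyrimidine-centred order (C>A, C>G, C>T,
T>A, T>C, T>G blocks; flanks alphabetical), with purine-centred mutations
reverse-complemented. Per-patient spectra count each unique substitution
once across the patient's biopsies to avoid double-counting shared
truncal mutations. `em_attribution()` fits a multinomial mixture against a
reference catalogue by EM from a uniform deterministic start (tolerance
1e-8 on exposures; the log-likelihood is non-decreasing by construction
and asserted in tests). Effectively collinear catalogue columns (cosine >
0.999) are flagged: their summed exposure is identifiable, the split is
not. De novo extraction is out of scope; a small synthetic catalogue
(including an A[C>G]G-peaked component mimicking the young-onset yolk sac
signature) ships for tests, and real catalogues load from TSV.

## The synthetic cohort and what it does (not) show

`simulate_cohort()` emulates the study conditions: near-monoclonal
microbiopsies (major clone CCF 0.96), very early WGD by default
(mutation time 0.02; ~0.5 emulates the prepubertal late-duplication
regime), one clonal copy-number segment per autosome arm drawn from
{2+2, 2+1, 2+0, 3+2} with the 12p arm forced to a gained state, ~1,400
truncal substitutions (0.49/Mb over the autosomes), depth 30x, purity
0.95, a trunk holding >= 50% of mutations (default expectation 75%) over
a random rooted subclone tree whose tips define biopsy patches,
clock-dominated signature mixtures with a small A[C>G]G component,
histology expression programs (400 genes at ±1.5 log2) with
negative-binomial dispersion 0.2 (typical for bulk-miniaturised
libraries) and a doubled 12p dosage effect. Pre-duplication mutations on
the lost allele of 2+0 segments are recorded in the ground truth but
invisible in the read counts, exactly the censoring the adjusted burden
corrects. The simulator has no spatial geometry (biopsies are draws from
clone-labelled patches), no read-level artefacts, no structural variants
and no germline contamination structure, so green tests demonstrate
correctness of the estimators under the generative model, not robustness
to alignment artefacts or copy-number miscalls on real data.

Problem sizes in the shipped tests were chosen to exercise the estimators
at study-realistic scale while keeping the suite quick: 50 seeded cohorts
for burden recovery (timing pools truncal reads across the tumour's four
microbiopsies — shared truncal mutations are the multi-region design's
own leverage), 600 null tumours per calibration check, 10,000 sites for
the false-call bound, and 5,000-mutation spectra for signature recovery.

## Numerical choices and degenerate inputs

Boundary readings are documented where the published wording is
ambiguous: pileup removal is inclusive at mean 10x; ambiguous-read
exclusion requires strictly more ambiguous than alt reads; cluster
presence is strictly above CCF 0.1; library QC removes strictly fewer
than 1000 features; the WGD rule is inclusive at equality. Empty inputs
return empty, typed results (no mutations -> no clusters; empty pileup ->
empty site set); zero callable length yields a missing burden; a
zero-total spectrum and zero vectors in cosine similarity are rejected;
forests (no cluster present everywhere) carry a diagnostic and refuse a
trunk proportion. All samplers accept a seed and restore the caller's RNG
state; the pipeline derives per-stage seeds from one master seed by
hashing stage names, so stages are individually reproducible and reruns
are byte-identical.
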