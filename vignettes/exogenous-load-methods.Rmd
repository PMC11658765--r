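---
title: "Quantifying pest load from non-target reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pest load from non-target reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exoload)
```

This vignette documents the statistical machinery of `exoload`: what each
stage assumes, which tunable parameters matter, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open. It states no empirical result that the test suite
does not itself compute.

## 1. Read classification

A read **pair** is the unit of classification throughout. Given a host
alignment and one alignment per candidate pest genome (all SAM; secondary
`0x100` and supplementary `0x800` records are dropped first):

* **exogenous** — both mates unmapped in the host alignment (the pair-level
  reading of "SAM flag 12"); these are candidate pest/microbe DNA.
* **ambiguous** — at least one mate host-mapped *and* the pair has a primary
  pest alignment with MAPQ ≥ `mapq_min` (default 20). These arise from
  genomic regions conserved across taxa (rRNA arrays, organellar fragments,
  low-complexity repeats).
* **target** — both mates host-mapped, not ambiguous.
* **other** — exactly one mate host-mapped, not ambiguous. Half-mapped pairs
  are deliberately excluded from both exogenous counting and the variant
  blacklist: they carry one host-supported mate, so deleting them would
  bias coverage, while counting them as exogenous would double-book pairs.

The four classes partition the pair universe exactly; `classify_sample`
errors if a pest alignment contains read ids absent from the host alignment.

Why ambiguous removal matters: a contaminant read that maps into a conserved
host region deposits non-reference bases there. Samples with more
contamination get more such reads, so a naive variant caller manufactures
genotypes that *are* the contamination level — and any downstream scan finds
a spectacular association between those fake genotypes and the contamination
phenotype. Acceptance test A7 reproduces exactly this failure mode with the
naive pileup genotyper (`naive_pileup_genotypes`) and shows that
`blacklist_ambiguous` eliminates it: after cleanup the positions carry no
alternate-allele evidence at all.

Exogenous pairs are counted per pest taxon only when they have a primary
pest alignment at MAPQ ≥ 20; duplicate pairs (identical reference, position
and flag signature for both mates) collapse to one by default,
approximating upstream duplicate marking without BAM tags.

## 2. Competitive species assignment

Marker sequences from the candidate species are aligned (externally, or with
the toy built-in `align_candidates` for near-identical markers) and reduced
to a **SNP-only pseudo-reference**: every alignment column containing a gap
in any candidate is deleted. Diagnostic columns are positions where at least
two candidates differ (indexed 1-based within the pseudo-reference).

`assign_reads` is a deliberately naive, fully auditable mapper: exact k-mer
seeds (default `seed_k = 25`) at non-overlapping offsets, both strands,
ungapped full-length extension, score = matches − mismatches with a mismatch
budget of `max_mismatch_rate × read length` (default 5%). A read is assigned
only to a **strictly** best candidate; ties and misses are unassigned. This
is the conservative reading of "unique mappings only": a read from a region
identical across candidates cannot vote. Proportions are reported over
assigned reads only.

Design notes: seeding by non-overlapping k-mers tolerates up to
⌊L/k⌋ − 1 errors before a read can lose all seeds; at the default read
lengths (≥ 100 bp) and error rates this is not limiting. The assigner is
O(reads × candidates) and intended for marker-scale references (mitochondria,
ITS), not genomes.

## 3. Load normalisation and phenotype characterisation

Counts depend on sequencing depth, so the phenotype is the residual of

> log(count + 1) = α + β·log(deduplicated reads) + r

fit by OLS. Residuals are exactly orthogonal to the depth covariate and sum
to zero; if counts are exactly proportional to depth all residuals vanish
(both are tested). The log(+1) guards the zero counts that dominate
low-infestation samples.

Population differences use one-way fixed-effects ANOVA
(R² = SS_between/SS_total, F test). Two-group contrasts use Welch's t with
Satterthwaite degrees of freedom, with explicit degenerate conventions
(all-identical groups → t = 0, p = 1; zero variance with separated means →
p = 0).

### SNP-based heritability

The variance model is r = μ + g + ε with g ~ N(0, σ²g·K) and
ε ~ N(0, σ²e·I), K scaled to mean diagonal 1. After eigendecomposing
K = U·D·Uᵀ once, the restricted likelihood is profiled over
λ = σ²g/σ²e on log10 λ ∈ [−5, 5] (1-D optimisation; the GLS weights are
1/(λd_i + 1) in the rotated basis). Then h² = λ̂/(λ̂ + 1).

* **Confidence interval**: profile-likelihood inversion at the χ²₁ 0.95
  cutoff, clipped to [0, 1]. The upstream package used in the original
  analysis does not print its interval construction; this choice is
  self-contained and testable (coverage is asserted ≥ 80% nominal on
  simulations).
* **Boundaries**: estimates at the λ grid edge are flagged (`boundary`)
  rather than silently clipped. A *flat* profile (e.g. K = I, where σ²g and
  σ²e are unidentifiable) resolves to λ = 0 by an explicit tie-break: no
  relatedness signal is reported as no genetic variance.
* **Covariates**: intercept-only, matching the depth-corrected phenotype
  whose construction already removed the only stated covariate.

## 4. Mixed-model association

`fit_null_lmm` estimates λ̂₀ once under the null; `lmm_scan` then Wald-tests
each predictor column, either reusing λ̂₀ (`mode = "p3d"`, the default;
population-parameters-previously-determined) or re-optimising λ per
predictor (`mode = "exact"`). The two agree within 10% relative on p > 0.01
for informative fixtures (a tested, documented approximation property —
agreement is asymptotic, and small weakly-identified fixtures can disagree
more). With K = I the scan reduces exactly to OLS (tested to 1e−6
relative). EWA uses methylation fractions as predictors unchanged.

Constant predictors return p = NA with a reason code rather than an error:
in a scan of thousands of sites, a few degenerate columns should not abort
the run.

Significance thresholds follow the unlinked-variant convention: Bonferroni
α/n over the LD-pruned variant count, plus the fixed suggestive line
p = 1e−5. LD pruning runs in 50-variant windows sliding by 5 within
chromosomes, removing the lower-MAF member of the currently worst pair with
r² > 0.8 (tie → larger position); the retained set is verified by an
exhaustive within-window scan in the tests. Kinship defaults to the IBS
matrix on the full MAF-filtered set, `K_ij = mean((2 − |g_i − g_j|)/2)`,
with a `method = "grm"` flag for the centred/standardised alternative
(appropriate when the generative model is causal-variant-based, because IBS
is an affine — not proportional — transform of allelic correlation, which
mis-scales h² in that setting).

## 5. Candidate enrichment and the rotation null

At each −log10(p) threshold t (0.5 steps): s(t) significant variants, a(t)
of them within 20 kb of an a priori candidate gene;
E(t) = [a/s]/[A/S] with A, S the totals. The FDR upper bound among
significant candidates assumes every non-candidate hit is null and candidate
nulls occur at the non-candidate rate:
FDR ≤ [(s−a)·A/(S−A)]/a, clipped to 1.

The permutation null **rotates the candidate flags** circularly within each
chromosome by independent uniform offsets while p-values stay fixed in
genomic order. Rotating both tracks by a common offset would be the
identity, so the published phrasing is implemented as relative rotation;
this preserves the local autocorrelation of both tracks, which ordinary
permutation would destroy. Empirical p = (1 + #{null ≥ observed})/(n_perm+1);
the observed statistic is reproduced exactly by a zero offset, and the
empirical p is uniform under independence (both tested).

## 6. Methylation: filtering, DMRs, EWA

`filter_union` keeps cytosines covered ≥ 4× in ≥ 95% of samples with a
methylation difference ≥ 5% from the site median in ≥ 2 samples — the
standard informativeness filter before association.

The DMR caller substitutes the external WGBS pipeline with a transparent
seed–merge–test procedure under the same printed constraints (4× coverage,
per-context processing, extreme-group design, FDR < 20%):

1. a site is usable if ≥ 80% of each group is covered ≥ `min_cov` (an
   invented but necessary rule — group means must be well defined; skipped
   regions are counted);
2. seed sites have |mean_high − mean_low| ≥ `seed_diff` (0.1);
3. seeds ≤ `max_gap` (300 bp) apart merge; regions need ≥ `min_sites` (5);
4. per-sample region means are compared by Mann–Whitney U, BH-corrected
   within context, reported at q < 0.2 with direction (hyper/hypo w.r.t. the
   high-load group).

`max_gap` and `min_sites` are conventional WGBS-scale defaults, exposed as
arguments. Exact replication of the external caller is a non-goal; the
equivalence of its q-values with BH over these regions is assumed, not
established.

EWA then restricts the filtered matrix to sites inside DMRs of the matching
context and uses 0.05/n_DMRs as the Bonferroni threshold — cytosines within
one DMR are treated as mutually correlated, so the DMR is the testing unit.

## 7. The synthetic world

The generators emulate the statistical structure the analysis assumes — not
sequencing realism. All are pure functions of (parameters, seed).

* **Genomes**: random host contig; each pest carries a copy of one central
  host block mutated at rate `divergence`. The block is the source of
  ambiguity; its coordinates and divergent sites are truth.
* **Alignments**: pairs are emitted directly as SAM records (re-implementing
  an aligner is out of scope — classification operates on mapping
  behaviour). Host-only pairs are drawn *outside* the conserved block so
  truth labels stay exact; consequently pileup coverage inside the block
  comes only from contamination, a documented simplification that sharpens
  the A7 demonstration. Ambiguous pairs are pest-derived block reads mapped
  in both alignments, with count `round(ambiguous_fraction × pest count)` —
  contamination-correlated, as in the motivating failure mode.
* **Genotypes**: Balding–Nichols (ancestral frequencies uniform on
  `maf_range`, population frequencies Beta with concentration (1−F)/F,
  binomial dosages). Optional **founder lineages**
  (`n_founders_per_pop`, `founder_copy_rate`) give each population a few
  near-identical descent groups. This emulates selfing-species collections,
  where repeated lineages make kinship informative; without it, a panel of
  mutually unrelated samples at desk scale (n ≈ 300, 2,000 markers) leaves
  the REML variance ratio so weakly identified that heritability recovery is
  structurally impossible — the estimator, not the criterion, is the
  binding constraint. The heritability acceptance world is 10 populations ×
  3 founders at 98% copy rate, F_ST 0.35.
* **Loads**: liability l = g + u_pop + e with Var(g) = h², Var(u) =
  `pop_effect_sd`², residual topping up to 1. g comes from causal variants
  (default) or from the IBS kinship as an exactly h²-calibrated polygenic
  background (`genetic_model = "kinship"`); the latter is used for
  estimator-recovery tests because it is correctly specified for the IBS
  estimator. The draw is scaled theoretically (marginal variance h²·K_ii) —
  rescaling by the empirical SD would inflate the genetic variance whenever
  K has shared structure. The liability maps to a pest fraction via a
  bounded softplus link (default) or an `exp` link
  (f ∝ exp(0.5·l), capped), under which log-count phenotypes carry exactly
  the liability-scale h²; heritability tests use `exp` for that reason.
  Depths are log-normal (default mean 2×10⁵), counts Poisson(f·d) with a
  negative-binomial toggle.
* **Methylation**: context-specific Beta baselines (CG 0.70, CHG 0.30,
  CHH 0.08 — the canonical plant ordering), negative-binomial coverage
  (mean 15), binomial sampling of observed fractions, and spiked intervals
  where methylation shifts by `dmr_effect × standardised(load)`; negative
  effects are infestation-linked hypomethylation.

What a green test does **not** establish: realism of per-sample exogenous
fractions (unknown; defaults chosen for test power), sequencing error and
indel behaviour (not simulated), correctness on real aligner output with
soft-clips and tags (only minimal fields are parsed), or equivalence with
the external DMR caller.

## 8. Numerical choices and edge cases

* One internal coordinate convention: 0-based half-open intervals; SAM/VCF
  positions stay 1-based and convert at the parse boundary only.
* Missing dosages are mean-imputed per variant for kinship and LD only;
  association drops missing phenotypes listwise (imputation of genotypes
  for association is upstream's job).
* REML search bounds log10 λ ∈ [−5, 5]; optimizer tolerance 1e−7; PSD
  tolerance 1e−6 relative to the largest eigenvalue; negative eigenvalues
  within tolerance are clipped to zero.
* Welch df is floored at 1; Mann–Whitney uses the normal approximation
  (exact p is ill-defined with ties in methylation fractions).
* LD-pruning tie-break (equal MAF): remove the variant at the larger
  position — deterministic and reproducible.
* The pipeline derives per-stage seeds by stable string hashing of stage
  names from one global seed, so inserting a stage never shifts another
  stage's stream; all artifacts are MD5-manifested and reruns reproduce the
  hashes.

## 9. Known limitations

* The LMM uses a single random effect; dominance, epistasis and multiple
  variance components are out of scope.
* The Wald test is slightly anti-conservative at small n compared to LRT;
  the calibration test bounds the family-level behaviour (type-I error in
  [0.035, 0.065] under the structured null) but individual small fixtures
  can deviate.
* The naive species assigner is marker-scale; genome-scale competitive
  mapping should use a real aligner and feed the SAM in.
* `align_candidates` handles only deletion-free merges relative to the first
  sequence; real marker MSAs should come from a dedicated aligner.
* Heritability CIs are profile-based and can be wide at desk scale; the
  simulation evidence (coverage ≥ 80%) documents behaviour, it is not a
  distributional proof.
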