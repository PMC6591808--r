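---
title: "Master-regulator analysis of transcriptional networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master-regulator analysis of transcriptional networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonmra)
```

## The problem

Tumor subtypes defined by distinct genetic lesions (for example SDH-complex
loss, VHL loss, or an oncogenic translocation in a neuroendocrine tumor
family) show broad, coordinated transcriptional dysregulation that no single
downstream pathway explains. Master-regulator (MR) analysis asks which
transcription factors (TFs) are positioned to *drive* such a signature: a TF
is nominated when the set of genes it regulates — its **regulon**, inferred
from co-expression across a large tumor cohort — is statistically enriched
in the subtype's differential-expression signature. `regulonmra` implements
this entire workflow as composable, pipeable functions, together with a
synthetic cohort generator that plants a known regulatory network and known
perturbed MRs so every stage can be benchmarked against ground truth.

## Models and procedures

### Differential-expression signatures

`differential_signature()` contrasts two sample groups on log2 expression.
The effect size is the raw mean difference (log2 fold-change); the p-value
comes from a two-sided two-sample t statistic, either Welch
(`moderation = "none"`, the default) or a single-parameter moderated test
(`moderation = "shrink"`) that pools per-gene variances toward the
across-gene mean with prior weight `d0` (default 4). The moderated mode is
a deliberately simple stand-in for full empirical-Bayes machinery: it
stabilizes small-sample variances without introducing dependencies whose
internals the tests could not verify analytically. Adjusted p-values are
Benjamini–Hochberg throughout the package. A gene is in the signature when
|log2FC| exceeds `lfc_threshold` (default 1.5; 2.0 is the conventional
stricter choice for clean cell-line contrasts) and adjusted p < `alpha`
(default 0.05). A "one subtype versus everything else" contrast is written
`group_b = "rest"`; there is no separate code path. Genes with zero variance
and zero difference in both groups are assigned p = 1, and a floor of 1e-12
on the squared standard error protects degenerate inputs.

### Network inference

`infer_network()` scores every TF–gene pair by **mutual information** (MI),
estimated by the plug-in formula on equal-frequency bins of the
rank-transformed profiles with `floor(sqrt(n))` bins. This estimator was
chosen over kernel or adaptive-partitioning alternatives because it admits
an exact oracle: on any hand-built joint table the estimate must equal the
plug-in formula to machine precision, which the test suite enforces. MI of
a constant profile is defined as 0.

The retention threshold is a permutation null: MI between each TF and
sample-permuted target profiles, pooled over `n_permutations` rounds
(default 10), at the `1 - alpha_perm` quantile (default 0.01). The **mode
of regulation** (+1 activating / −1 repressing) is the sign of the Spearman
correlation, with ties mapped to +1.

`apply_dpi()` implements data-processing-inequality pruning: in every
triangle of retained edges, an edge is marked when its MI falls below
`min(other two) × (1 − tolerance)`, and all marked edges are removed
*simultaneously* after the full scan. Simultaneous removal makes the result
independent of scan order; sequential implementations can differ on
ties/chains, which is why exact edge-set equality with other software is
not claimed. Tolerance 0 is the stringent setting; 0.05 trades stringency
for sensitivity, and the edge set at tolerance 0 is provably contained in
the edge set at any larger tolerance (property-tested).

### Master-regulator nomination

`run_mra()` tests each regulon's overlap with the DE set by the one-sided
hypergeometric upper tail over the universe of network-scored genes, with
BH adjustment across TFs. The **attributable fraction** is the share of the
(universe-intersected) DE set inside the regulon; `cumulative_attribution()`
takes the *union* of the top-k regulons so shared targets are not double
counted — the curve is non-decreasing and bounded by 1. Ranking ties on p
are broken by larger regulon, then TF id, so reports are deterministic.
Whether a TF's own expression row should count toward its attributable
fraction is ambiguous; targets-only is implemented, consistent with the
regulon definition.

### Gene-set overlap significance

`overlap_significance()` draws `n_sims` pairs of uniform random subsets of
the stated sizes and records their intersections. Drawing two independent
uniform subsets and intersecting is distributionally identical to a single
hypergeometric draw, so the simulation uses `rhyper` for speed; the tests
verify the mean against the closed form K·n/N. Both an empirical p-value
(floored at 1/(n_sims+1)) and a Poisson-tail p fitted by the simulated mean
are reported: the Poisson value extrapolates resolution far beyond the
simulation count, as needed when true overlaps are dozens of standard
deviations beyond chance, and is labeled as an extrapolation. By direct
computation the Poisson tail stays within one order of magnitude of the
exact hypergeometric tail out to roughly three times the expected overlap;
beyond that it is visibly over-dispersed (sampling without replacement has
lighter tails), which is why the tests pin the agreement range explicitly.

### TF activity profiles

`infer_activity()` z-scores each gene against a reference (cohort mean/SD
by default, or an explicit reference sample set such as normal specimens)
and scores TF t in sample s as

  A_ts = Σ_{g ∈ regulon(t)} mode(t,g) · z_gs / sqrt(|regulon(t)|).

This signed-z-sum is linear, admits exact unit tests, and approximates
rank-based enrichment activity scores well in the additive-signal regime;
the interface (network in, TF × sample matrix out) leaves room for a
heavier enrichment-based scorer. TFs with fewer than `min_regulon` scored
targets are excluded and listed — never silently zero. Differential
activity between groups (`differential_activity()`) reports mean
differences in activity units with Wilcoxon rank-sum p-values; activities
can be negative, so fold-change-style ratios of activities are not
meaningful and are deliberately not reported.

Sample clustering is average-linkage agglomerative: on 1 − Pearson distance
over activity profiles (`cluster_samples_by_activity()`), or on the
expression submatrix of one regulon (`cluster_samples_by_regulon_expression()`),
where the default distance is Euclidean — a perturbed regulator shifts its
regulon's mean level, and a shift-sensitive distance is what separates
perturbed from control samples when only one regulon is in view.

### Regulon topology and synergy

`regulon_overlap_matrix()` scores pairwise regulon overlap by Jaccard
(overlap coefficient behind a flag), and `cluster_subnetworks()` cuts the
average-linkage tree on 1 − overlap into k subnetworks (default k = 3,
matching the two strong plus one weaker co-regulated blocks typical of
tumor cohorts). `synergy_analysis()` classifies each partner of a focal TF
by comparing the mean signature log2FC of the shared targets (mS) against
the full-regulon means (mA, mB) with a margin δ (default 0.2 log2 units,
minimum 5 shared targets): shared targets pushed below both regulons and
below zero are **synergistic repression**; pushed above both and above zero,
**synergistic activation**; a partner whose regulon is up while the shared
subset sits near baseline is **attenuation**. The margins make the calls
mutually exclusive by construction (property-tested on random mean
triples). The margin-based rule is a transparent surrogate for a visual
three-column comparison; no distributional test is claimed.

### Motif-based network validation

An inferred regulon is validated by asking whether its targets' promoters
carry the TF's binding motif closer to the TSS than chance. `pwm_scan()`
scores both strands by log-odds against a uniform 0.25 background with
pseudocount 1e-3; a window matches when it reaches `threshold_frac` (default
0.8) of the maximum achievable score. The fraction-of-maximum rule is
scramble-invariant: the same rule applies to every scrambled motif, so the
null is not biased by threshold re-calibration. Windows overlapping N are
skipped; scanning is case-insensitive; forward/reverse hits at the same
window are deduplicated to the higher-scoring strand (verified against a
brute-force scanner).

`nearest_match_fraction()` takes, per target, the distance from the nearest
match midpoint to the TSS inside a window (default 50 kbp centered on the
TSS) and reports the fraction of matched genes whose nearest match lies
within a proximal cutoff (default 2.5 kbp). Genes without any match are
excluded from the denominator (the alternative — counting them as
non-proximal — is exposed by simply treating the reported `n_no_match`).
`scrambled_motif_test()` repeats the computation for (default) 200
column-order permutations of the PWM — scrambling preserves the column
multiset and hence total information content — and reports the empirical
p-value (#{f_scr ≥ f_obs}+1)/(n+1). A scramble with no matches contributes
fraction 0; if the *observed* motif matches nothing the fraction is
undefined, the result is flagged, and p = 1 (no evidence).

### Cross-cohort and cross-species conservation

`regulon_fold_change()` averages a signature's log2FC over each regulon
(regulons entirely outside the signature are flagged absent, not zero).
`cross_cohort_validation()` correlates these per-MR means between a
discovery signature and an independent validation signature (Pearson and
Spearman); `conserved_mrs()` maps MR lists across species through a strict
one-to-one ortholog map (TFs without orthologs are dropped and counted),
intersects them, and tests the intersection against random TF sets of the
same sizes — jointly redrawn for three or more lists.
`concordance_classification()` calls a conserved MR sign-concordant when
the product of its two regulon means is strictly positive; a zero or
missing mean is flagged, not concordant. The TF universe for the null
defaults to the shared orthologous universe, the conservative choice when
the species' TF catalogs differ.

### Orchestration

`run_pipeline()` executes signature → network (per DPI tolerance) → MRA →
topology → activity → optional motif validation → optional cross-cohort
validation from one YAML (or list) config, writing each stage's TSVs before
the next begins, a timestamped log with record counts at every filter, a
resolved-config snapshot, and a manifest of md5 content hashes. One master
seed is expanded into per-stage seeds by a fixed affine map, so stages can
be re-run in isolation and whole runs are bit-reproducible (asserted by
manifest equality in the tests). Validation failures (missing path, alpha
outside (0,1], DPI tolerance outside [0,1)) abort before any stage runs.

## The synthetic cohort generator

`generate_truth()` plants a signed, weighted TF → target network with block
structure: TFs and targets are partitioned into blocks (default 3) and each
TF draws most of its regulon (default 70%) from its own block's pool,
producing the co-regulated subnetworks that regulon-overlap clustering
should find. Modes are −1 with probability 0.25; weights are
Uniform(1.0, 1.3); each subtype gets a disjoint set of 5 perturbed TFs
whose latent activity shifts by δ (default 3 log2-activity units).

`generate_cohort()` realizes expression: per sample, TF activity
a_t ~ Normal(μ, 1) with μ = δ for perturbed TFs in that sample's subtype;
target expression is the signed weighted sum of its regulators' activities
plus Normal(0, `noise_sd`) noise; TF expression is its own activity plus
half-noise — the noisy-readout assumption that makes the network
recoverable from expression at all. Everything is shifted +8 onto a
positive log2 scale.

Default sizes are 60 TFs, 600 targets, 120 network-inference samples and
20 + 10 signature samples — minutes-scale runtimes while leaving enough
power for the recovery properties below. Three generator constants were
calibrated once so that the default conditions actually realize the
recoverability the benchmarks assume, and are not revisited per test:
`noise_sd = 0.4`, regulon sizes 8–20, and a per-target in-degree cap of 2.
The in-degree cap matters because every additional regulator adds one unit
of activity-driven variance to a target; uncapped in-degree produces a tail
of high-variance targets whose TF–target correlations fall below the MI
permutation threshold and whose Welch standard errors swamp a 3-log2-unit
shift at n = 20 vs 10. Low regulatory in-degree is also what post-pruning
inferred networks look like. Under these defaults: median per-TF edge
recall ≈ 0.93 and precision ≈ 0.68 at 120 samples, signature sensitivity
≈ 0.96 at δ = 3, and as δ → 0 every detection statistic collapses to its
null calibration (the effect-size dial is exercised in the tests at
δ ∈ {0, 3}).

`generate_paired_cohorts()` produces an independent discovery
(tumor-vs-normal) and validation (tumor-vs-tumor) pair on one truth;
`generate_cross_species()` re-labels the universe into a second namespace,
conserves a configurable fraction of perturbed TFs (same sign), covers a
configurable fraction of genes with a one-to-one ortholog map, and draws an
independent cohort. `generate_promoters()` emits uniform-composition
promoter windows (TSS at center) with exact consensus instances of a TF's
motif planted near the TSSs of true targets at a configurable rate; decoys
are never planted. The bundled `make_test_pwm()` builds sharp PWMs (16
columns, consensus probability 0.97) for which the 80%-of-maximum threshold
admits only exact-consensus windows, keeping the background match rate over
50-kbp windows near 1e-3 per scramble — small enough that the planted
fixture's empirical p reaches its 1/(n+1) floor in almost every seed.

What the generator does **not** emulate: count-level sequencing noise
(negative binomial reads), probe effects, batch structure, copy-number
confounding, correlated TF activities, or chained (TF → TF → target)
regulation. Passing tests therefore demonstrate correctness of the
algorithms under an additive log-scale model with independent regulators,
not robustness to the full messiness of real cohorts.

## Numerical choices and degenerate inputs

- Equal-frequency binning breaks rank ties by original order, making MI
  deterministic; constant vectors short-circuit to MI = 0.
- The variance floor in signatures (1e-12), the SD floor in z-scoring
  (1e-8), and the p = 1 rule for exactly degenerate genes are all tested.
- BH adjustment is the standard step-up with monotonicity enforcement,
  capped at 1.
- Empirical p-values always use the (r+1)/(n+1) estimator — no zero
  p-values.
- Hierarchical clustering is average linkage by default everywhere;
  cluster labels come from `stats::cutree`, so partitions are deterministic
  given the input matrix and invariant to input order.
- Ortholog maps must be one-to-one; many-to-many relations are rejected
  rather than silently resolved.

## Known limitations

- The moderated t mode is a one-parameter shrinkage, not a full
  empirical-Bayes fit; analyses sensitive to the exact moderation (e.g.
  reproducing published DE gene counts) will differ.
- MRA uses the hypergeometric overlap test, not a mode-aware two-tailed
  enrichment statistic; shadow/synergy-corrected MR p-values are out of
  scope.
- The activity score is a signed z-sum, not a three-tailed rank-enrichment
  statistic; activities are comparable within a cohort/reference, not
  across differently normalized datasets.
- Exact edge-set equality with other DPI implementations is not guaranteed
  (removal-order semantics differ); the simultaneous-removal rule here is
  the one with an order-independent specification.
- Promoter windows must be supplied (or simulated); the package does not
  extract sequence from a reference genome.
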