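---
title: "Collapsed rare-variant mQTL mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsed rare-variant mQTL mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvmqtl)
```

## The problem

Single-variant methylation QTL (mQTL) scans miss regulatory signals that are
spread across several low-frequency (MAF ≤ 5%) or rare (MAF ≤ 1%) variants,
none of which reaches significance alone. `rvmqtl` maps such signals by
collapsing the variants that fall inside CpG-island-anchored regions and
testing the set jointly against the methylation level of nearby (cis) or
distant (trans) CpG probes. Because variants within one region can push
methylation in opposite directions, the joint test is a variance-component
(kernel) score test rather than a signed burden sum: a burden statistic
cancels under mixed effect signs, the kernel statistic does not (this is
asserted by a paired test in the suite).

## The model and the test

For a probe's (rank-normalized) methylation $y_i$, covariates $X_i$ and the
dosages $G_{i1},\dots,G_{ip}$ of the $p$ variants collapsed into a region,

$$y_i = \alpha_0 + \alpha' X_i + \beta' G_i + \epsilon_i,$$

and the region effect is tested as $H_0: \beta = 0$ by treating the
$\beta_j$ as random with mean zero and variance $w_j^2 \tau$. The score
statistic is

$$Q = \frac{r' K r}{2\hat\sigma^2}, \qquad K = G\,\mathrm{diag}(w_j^2)\,G',$$

where $r$ are the residuals of the covariate-only least-squares fit and
$\hat\sigma^2 = \mathrm{RSS}/(n-\mathrm{rank})$. Weights follow the Beta
density evaluated at each variant's sample MAF, $w_j = f(\mathrm{MAF}_j;
a_1, a_2)$, with the canonical defaults $a_1 = 1$, $a_2 = 25$ that upweight
rarer variants; both shapes are arguments everywhere they appear. Genotype
columns are mean-centered before the kernel is formed (a no-op for the
statistic when an intercept is in the null model, asserted by test) and MAF
is always recomputed from the analyzed sample's dosages with minor-allele
folding, so weights are invariant to allele-coding flips $g \mapsto 2-g$.

Under $H_0$, $Q \sim \sum_i \lambda_i \chi^2_{1}$ where $\lambda_i$ are the
eigenvalues of the covariate-projected weighted kernel divided by two; the
residual-variance estimate normalizes the statistic, not the spectrum, so
the pair $(Q, \lambda)$ yields the correct null law. Eigenvalues below
$10^{-10}\lambda_{\max}$ are dropped; rank-deficient kernels (e.g. variants
in perfect LD) are handled without special cases.

### Tail probabilities

`quadform_pvalue()` computes $P(\sum_i \lambda_i \chi^2_1 \ge Q)$ by

1. an exact chi-square tail when all eigenvalues are equal (the one- and
   two-variant unit-weight cases reduce to this; the one-variant limit
   equals the single-variant score test to machine precision);
2. numerical inversion of the characteristic function (Imhof-type
   integration, `stats::integrate` on $[0,\infty)$) accepted only when the
   integrator converges with an absolute error below
   $\max(10^{-6}, 10^{-3}p)$ and the result lies in $(10^{-10}, 1]$;
3. otherwise a moment-matched noncentral chi-square approximation fitted to
   the first four cumulants, evaluated with `log.p = TRUE` so that the
   extreme tails an mQTL scan produces (observed p-values reach $10^{-20}$
   and beyond) stay finite, ordered, and monotone in $Q$.

The method actually used is recorded in every result (`exact_quadform` or
`moment_matched`), and p-values are floored at `p_floor` ($10^{-300}$ by
default). A residual-permutation oracle (`permutation_pvalue()`) provides an
assumption-free cross-check.

### Known accuracy limits

The analytic null law is asymptotic. Two finite-sample effects matter:

* With very rare variants and small $n$ the score contributions are sums
  over few carriers, and the mixture-of-chi-squares tail can deviate from
  the exact (permutation) law; the package implements no small-sample
  variance/kurtosis adjustment. At the scales used here (n = 800, MAF 1-5%)
  the type-I error at $\alpha = 0.05$ is nominal within binomial error over
  2,000 replicates.
* Even for common variants, the exact permutation law conditions on the
  realized residual vector's empirical moments while the analytic law does
  not. At $n = 200$ this produces relative deviations of a few percent in
  the p-value — visible once the permutation p is estimated with $10^5$ or
  more permutations, and irreducible for any p computed from $(Q, \lambda)$
  alone, since two traits with the same $(Q, \lambda)$ can have different
  exact permutation p-values. The suite checks agreement at a tolerance
  that floors the permutation Monte-Carlo band at 0.02 on the $\log_{10}$
  scale.

## Regions, tiers, and test pairs

CpG islands arrive as BED intervals (0-based half-open, the package's
internal convention; VCF positions are converted at the boundary). Three
nested tiers expand each island symmetrically: the island itself, island +
2 kb shores, island + 4 kb shores-and-shelves, with starts clamped at zero.
A region is eligible at a MAF cutoff (5% or 1%) when at least two passing
variants fall inside the expanded interval — with one variant there is
nothing to collapse. Tier bookkeeping is incremental: an island is counted
at the narrowest tier at which it first becomes eligible, matching the
"a further N regions" style of reporting. Variant sets nest across tiers
and MAF cutoffs by construction (property-tested).

A region-probe pair is cis when the probe lies within 1 Mb of the expanded
region's nearest edge, inclusive at exactly 1 Mb; everything else — same
chromosome beyond the window, or any other chromosome — is trans, so cis
and trans partition the full grid exactly. Genome-scale trans counting is
done arithmetically (`trans_pair_count()`, exact in doubles far beyond
genome scale) rather than by materializing billions of pairs.

Islands with a previously reported single-variant mQTL within 5 kb (the
default `exclusion_pad`; 1 kb is a supported alternative reading of the
rule) are routed to the conditional analysis instead of the novel scan.

## Preprocessing

Variant QC keeps a variant when HWE $p > 5\times10^{-7}$, MAF $\le$ 5%, and
imputation info $> 0.8$ (missing info scores pass, for hard-called data).
Methylation is rank-inverse-normalized per probe with the rankit offset
$c = 0.5$ and average ranks for ties — the transform is the standard
outlier-taming step and makes the Gaussian error model defensible — and
covariates are handled either by pre-residualizing each probe or by keeping
them in the test's null model. The two paths give *identical* p-values when
the same covariate set is present in the null model (residuals are a
projection fixed point; asserted by test); the pipeline default keeps
covariates in the null model, which is also what makes per-probe null-model
caching exact. The analysis sample is the intersection of genotype,
methylation, and covariate ids in genotype order, and missing dosages are
mean-imputed per variant.

## Scan orchestration

`run_scan()` fits one null model per probe and reuses it across all regions
paired with that probe — the null model does not involve the region, so the
cached and refitted p-values are identical (tested at $10^{-12}$ relative).
Rows are emitted in deterministic (region, probe) order regardless of input
order. The significance rule is strict: a pair passes when
$p < 10^{-14}$ by default, a deliberately conservative genome-scale
correction; fixture-scale analyses pass a permissive threshold instead.
Hits get single-variant follow-up: each region variant is regressed on the
probe individually, and the `drivers` flag is raised when any single
variant alone reaches the scan threshold — the operational version of
"one variant is independently responsible". Hits can be re-evaluated in
further datasets (other time points, replication cohorts) using only the
variants each dataset has; nothing is imputed across datasets, and pairs
with fewer than two available variants are marked untestable.

## Conditional analysis

For regions near a known single-variant mQTL, the package estimates
two-locus LD between each region variant and the index SNP and removes
variants with $D' \ge 0.8$ (inclusive), because a rare variant on the index
haplotype would merely re-detect the known signal; $r^2$ is unsuitable here
since its attainable range collapses when a rare variant is compared with a
common SNP. $D'$ comes from a two-locus EM on unphased hard calls (50
iterations or $\Delta < 10^{-8}$; only the double heterozygote is
phase-ambiguous), with fractional dosages rounded for the EM and a
composite covariance estimator as the recorded fallback. $D'$ is symmetric
and invariant to allele recoding (property-tested), and the EM tracks the
phased-haplotype truth of the simulator within 0.02.

Regions still eligible after pruning (≥ 2 variants) are re-tested with the
index dosages appended to the covariates; when several index SNPs tag one
locus, pruning uses the maximum $D'$ over indices and the second
conditioning pass uses all of them. The same mechanism conditions a hit on
a variant overlapping the probe sequence, reporting
$\log_{10} p_{\mathrm{cond}} - \log_{10} p_{\mathrm{uncond}}$ as the
attenuation measure.

## Stability diagnostics

Leave-one-out first LD-prunes the region greedily in position order
(dropping the later variant of any pair with $r^2 \ge 0.8$; deterministic
and idempotent), then re-runs the kernel test with each remaining variant
removed in turn next to the all-variant reference. A genuinely joint
signal keeps every removal's $-\log_{10} p$ close to the reference; a
collapse on one removal exposes a single driver or an outlier carrier.
Carrier summaries back the box-plot inspection: per variant, five-number
summaries of methylation among carriers (dosage ≥ 0.5, the natural rule
for fractional dosages) and non-carriers, flagging carriers beyond
1.5 × IQR of the full-sample quartiles — the full sample is the reference
because carrier groups of rare variants are too small to define their own
robust fences.

## The synthetic-data generator

`simulate_mqtl_data()` produces a coupled fixture — dosage VCF, island BED,
probe manifest, methylation matrix, covariates, known-mQTL list, and a JSON
ground-truth record — with the statistical structure the analysis assumes:

* **Geometry.** Islands of 0.5-3 kb separated by 60-120 kb gaps (keeping
  shelf-expanded regions disjoint) on one chromosome; one probe near each
  island midpoint within ±100 kb; extra probes placed > 1 Mb beyond the
  last island so trans classification is exercised.
* **Genotypes.** A latent-haplotype block model: variants in a block carry
  their minor allele only on copies of a shared latent haplotype (thinned
  to each variant's target MAF), giving positive within-block LD with
  known phased truth — which is exactly what the conditional module needs
  for high-$D'$ cases — while blocks stay independent. Monomorphic draws
  are resampled; a variant whose expected minor-allele count is below one
  is an error, not a silent fix. Defaults: 800 samples (the scale of one
  cohort time point), MAF 1-5% (the low-frequency tier after QC), blocks
  of 2.
* **Methylation.** Generated exactly from the linear model above with
  Gaussian noise (unit SD by default — the analysis operates on the
  normalized scale), a binary batch covariate plus standard-normal
  covariates with fixed coefficients, and per-probe effect scenarios:
  `null`, `collapsed` (mixed-sign effects of ±0.7 on up to four variants),
  `single_variant` (one effect of 2.5), `single_plus_collapsed`,
  `tagged_only` (rare alleles placed on the index haplotype, $D' = 1$ by
  construction, with the effect on the index SNP only), and
  `probe_overlap`. The collapsed amplitude 0.7 is chosen so the scenario
  means what it claims at the default scale: the joint signal passes
  fixture-scale thresholds comfortably while no single variant — even with
  its LD partner's help — approaches the $10^{-14}$ driver rule; the
  single-variant amplitude 2.5 puts its driver far beyond that rule. The
  common index SNP defaults to MAF 0.2 with effect 1.2, a textbook strong
  single-variant mQTL.
* **Determinism.** A fixed config (including its seed) reproduces the
  fixture byte-for-byte on disk.

What the generator does **not** emulate: realistic human LD maps and
recombination structure (block LD is a modeling choice), 450k probe
chemistry and beta-value distributions (simulation is on the
post-normalization analysis scale), cell-type composition signals, and
population stratification. Passing tests therefore demonstrate the
statistical machinery under the stated generative model, not robustness to
every artifact of real array data.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to make each property
measurable with comfortable margins: 2,000 replicates at n = 800 for null
calibration; 50 instances at n = 200 with up to $10^5$ permutations for
the oracle comparison; 18-island fixtures at n = 500 (a few hundred
region-probe pairs) for planted-effect recovery; n = 600 for conditional
and leave-one-out constructions. The scan engine itself streams pair by
pair with per-probe caching and does not materialize trans pair lists, so
the same code paths scale to genome-wide use.

## Known limitations

* Quantitative traits only; no binary-trait (logistic) version, no
  SKAT-O-style adaptive combination, and no family/kinship adjustment.
* No small-sample moment adjustment for the analytic tail (see accuracy
  limits above); for very small n the permutation p-value is the safer
  instrument and is built in.
* The greedy $r^2$ pruning is a deterministic stand-in for external
  windowed pruning tools and is not claimed to match any specific tool
  invocation.
* Trans scans default to the island + shore tier, the tier that carries
  most cis signal, as a computational economy; it is a config switch, not
  a constraint.
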