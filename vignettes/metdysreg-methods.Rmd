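---
title: "Methods behind metdysreg: scoring metabolic dysregulation and recurrence kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind metdysreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metdysreg)
```

`metdysreg` quantifies how strongly folate, one-carbon and polyamine
metabolism are rewired in tumors, and connects that dysregulation to disease
recurrence in two settings: biochemical recurrence in patients, and
regrowth of castration-recurrent xenografts under dietary folate
manipulation. This vignette documents the models, the parameters that
matter, the numerical conventions, and the places where a design choice was
genuinely open.

## Differential expression and the moderated t

Counts are assumed to be bulk RNA-seq-style gene counts from paired (or at
least condition-labelled) tumor and normal samples. Normalization is the
trimmed mean of M-values: pairwise log-ratios against a reference sample
(the one whose library-size-scaled upper quartile is closest to the cohort
mean) are doubly trimmed — 30% on the M (log-ratio) scale, 5% on the A
(average-abundance) scale — and combined with inverse asymptotic-variance
weights. Factors are rescaled to geometric mean one, so they modify, not
replace, library sizes. Expression is then transformed to
`log2((count + 0.5) / (effective library size + 1) * 1e6)`; the 0.5 prior
count keeps zeros finite and its effect fades as counts grow.

The per-gene tumor-minus-normal contrast is tested with an empirical-Bayes
moderated t. Residual variances are modelled as scaled-F around a prior
variance `s0²` with `d0` prior degrees of freedom; both are estimated by
moment matching on `log s²` using the digamma/trigamma relations, with the
trigamma inverted by Newton iteration. When the trigamma moment equation
has no positive solution, the excess dispersion of the observed variances
is zero or negative and `d0` is set to `+Inf` (complete shrinkage) — the
documented limiting case, reported in the fitted object. Setting `d0 = 0`
disables shrinkage and reproduces the ordinary two-sample t exactly, which
the tests exploit as a limiting-case oracle; the default estimate is
cross-checked in the suite against an independent established
implementation to 1e-10.

Numerical conventions: genes with zero counts in every sample are dropped
before fitting and reported; zero residual variances are floored at 1e-10
before shrinkage so the statistic stays defined. Pairing is supported
(within-pair differences, `n−1` df) but the default is the two-group fit:
the cohorts this mirrors do not state which was used, and two-group is the
weaker assumption. An optional `weights = "trend"` mode fits a lowess of
per-gene `sqrt(residual sd)` against mean log-CPM and uses inverse
fourth-power fitted values as per-gene precision weights, scaling the
variances before shrinkage; the default stays unweighted because it is
simple and exactly testable.

## Gene, pathway and patient scores

The signed gene score is the pi-value construction
`s_g = log2FC_g × (−log10 padj_g)`: zero under the null (either factor
vanishes), sign-carrying, and monotone in both inputs. The wording that
motivated it ("scaling the adjusted p value and correcting for fold
change") admits alternatives, so the formula is deliberately a small,
documented function; `padj` is floored at 1e-300 to keep the logarithm
finite. The pathway score is `Σ s_g / √n` over the `n` pathway genes
actually present in the score table — absent genes shrink `n` rather than
entering as zeros, which would bias small pathways toward the null. The
√n divisor makes the *signed* total's sampling dispersion independent of
pathway size for exchangeable gene scores (the classical CLT scaling), and
that is the property the test suite checks; for absolute scores it is a
size normalization, not a size-invariance guarantee. Whether "n" should be
genes or patients is described inconsistently in the motivating analyses;
gene count is used here because patient count never enters the per-gene
statistics.

Per-patient scores standardize tumor expression against the normal samples
of the same cohort on the log-CPM scale (`z = (x − mean_N) / sd_N`, sample
sd; genes constant across normals are dropped and reported) and aggregate
as `Σ|z|/√n`, mirroring the cohort-level absolute score. A signed variant
is exposed. Quartile cut points are type-7 (linear-interpolation)
percentiles at 25/50/75%, with ties at a cut point going to the lower
quartile in stable input order; all-equal scores collapse to Q1 with a
warning. Kaplan–Meier estimation and the two-group log-rank test are
delegated to the `survival` package behind thin wrappers that enforce
administrative censoring at exactly 5 years (an event at exactly 5.0 years
counts as an event). Only Q1 versus Q4 is tested, but all four curves are
returned, since the intermediate quartiles are descriptively useful.

## The variable-position methylation caller

Input is an already-normalized CpG × sample beta matrix with diet-group
labels; probe filtering, within-array normalization and batch correction
are upstream by declaration. For each non-control group, per-animal deltas
are taken against the arithmetic mean of the control animals, and a CpG is
called hypermethylated when strictly more than 0.30 is seen in at least 2
animals (hypomethylated symmetrically). The 30% is an *absolute* beta
difference — beta is already a percentage-scale quantity — not a relative
change; both the strict inequality and the absolute reading follow the
definition the caller encodes. A CpG can in principle satisfy both
directions (with ≥ 2 supporters each way among 4 animals); such calls are
emitted in both directions and flagged rather than silently resolved.

Called CpGs map to genes with set semantics (a gene hit by several CpGs
counts once; unannotated CpGs are tallied separately). Overlap of gene
lists is tested with the exact upper-tail hypergeometric probability;
over-representation against a GMT collection is the same test per set with
BH adjustment across sets. This is an over-representation analysis of an
unranked list, chosen deliberately over a running-sum enrichment statistic
because the input is a gene *set*, not a ranked profile. The universe size
is a required, reported parameter (defaulting, where an annotation is
supplied, to its number of annotated genes): the correct universe is
genuinely unknowable from the data, so acceptance-style checks report the
conclusion across universes from 5,000 to 30,000. The overlap network
connects top sets by the overlap coefficient `|A∩B| / min(|A|, |B|)`
(1 for nested sets, by design) with a default edge cutoff of 0.25.

## Xenograft recurrence kinetics

Caliper volume is `length² × width × 0.5234` mm³ — intentionally
asymmetric in its arguments. Event classification evaluates threshold
crossings at measurement days only, with strict inequalities and no
interpolation, matching how such data are recorded: initial response
(< 300 mm³, the starting volume at androgen withdrawal), regression
(< 150 mm³), complete regression (< 100 mm³), and recurrence (first
volume > 500 mm³ *after* the regression day — growth without prior
regression is "non_regressed", not recurrence). Final status takes
precedence recurrent ≻ complete regression ≻ stable disease, with the
complete-vs-stable distinction made on the final measured volume: a
transient dip below 100 mm³ followed by regrowth to ≤ 500 mm³ ends as
stable disease. The source descriptions do not resolve that corner; the
final-volume rule is the documented choice. Interval summaries report, at
every 28-day endpoint out to 50 weeks, the fraction recurrent (absorbing
once the recurrence day passes), completely regressed (last measured
volume < 100 mm³) or stable; censored animals leave the denominator after
their censoring day and are excluded from contingency tables entirely.

Fisher's exact test is the exact conditional two-sided test (tables no
more probable than the observed one, with the customary 1e-7 relative tie
tolerance), implemented as a direct hypergeometric tail sum and verified
against exhaustive enumeration; the reported odds ratio is the sample
`ad/bc`. Welch's t and the two-tailed Pearson test wrap the standard
`stats` implementations.

## What the generators emulate — and what they do not

The synthetic module exists so that every downstream stage can be tested
against known truth; its defaults encode the study conditions the package
targets.

**Expression** (`expr_sim_config`): gene baselines are log-normal
(`sdlog = 1`), counts negative-binomial with a shared dispersion (default
0.1, a typical bulk value), and library sizes uniform over 500–1500
expected counts per gene — the deep-coverage regime of consortium RNA-seq,
where the log-CPM normal approximation underlying the moderated t is
comfortable. Planted effects multiply tumor means by `2^lfc` with
`|lfc| = effect_scale` and random sign; `round(effect_frac × size)`
members of each pathway are perturbed, and a gene claimed twice keeps its
first effect. Not emulated: within-pair correlation, batch structure,
GC/length biases, composition shifts large enough to stress TMM. Passing
recovery tests therefore demonstrates correctness of the statistics, not
robustness to those artifacts.

**Survival** (`surv_sim_config`): event times are exponential with hazard
`h0 · exp(β(score − mean))` (default `h0 = 0.1`/year, a plausible
biochemical-recurrence rate), censoring exponential with mean 10 years,
administrative horizon 5 years. Proportional hazards holds exactly by
construction, so log-rank power results are upper bounds for messier
real-world hazards.

**Methylome** (`meth_sim_config`): one control plus two diet groups, 4
animals each; baselines uniform in (0.1, 0.9); planted events shift
exactly `n_supporting_animals` randomly chosen animals by ±`delta_beta`.
Baselines of planted CpGs are drawn inside the range where the stated
shift fits in (0, 1); clipping remains the fallback for infeasible deltas
and is recorded in the truth table. Noise is Gaussian on the logit scale
(default sd 0.05) and back-transformed, keeping betas in (0, 1) with
realistic heteroscedasticity. Not emulated: probe-type effects, spatially
correlated CpGs, biological between-animal variation beyond logit noise.

**Trajectories** (`traj_sim_config`): 40 animals per arm start at 300 mm³
at androgen withdrawal, decay exponentially with a one-week half-life
(volumes floored at 4 mm³, a ~2 mm nodule — the practical caliper
detection floor), and a per-arm fraction regrows exponentially
(`log(2)/10` per day) from a uniform onset in days 56–252, measured weekly
for 350 days with multiplicative log-normal noise (CV 0.1). Default
recurrence probabilities (0.70 control, 0.40 depleted and supplemented)
encode a strong diet contrast; no distributional details of real regrowth
were available, so these are free knobs chosen once for realism, not
estimates. The onset window and regrowth rate guarantee that every planted
recurrence crosses 500 mm³ within follow-up, which is what makes the
noiseless classifier-vs-truth agreement an exact check.

Every generator is driven by a single integer seed and is byte-identical
under repetition; truth tables fully describe the planted structure, and
recovery tests read generator outputs only.

## Problem sizes and statistical readings used in the checks

The heavier verification runs use desk-scale designs chosen to make the
Monte-Carlo answers stable: null calibration on 2000-gene, 50+50-sample
cohorts (20 seeds; the uniformity check is a per-cohort Kolmogorov–Smirnov
test in the suite, and a pooled KS across cohorts in the acceptance
script, the pooled form being the natural one-number summary when the
seed itself varies); FDR control with 10% of genes planted at |log2FC| = 2
on 30 pairs; ranking recovery with one cohort at effect scale 2.0 against
five at 0.2 (1000 genes, 20 pairs, 100 seeds); log-rank power at β = 1 and
size at β = 0 with 400 patients (200 and 1000 seeds); caller recovery on
1000 CpGs with 50 planted events (20 seeds); exhaustive enumeration of
exact tests up to margins/universe of 30.

## Known limitations

The package scores dysregulation; it does not model counts with NB GLMs,
adjust for covariates or batch, fit Cox models, or perform ranked-list
enrichment. The per-patient score formula and the gene-count reading of
the √n divisor are documented conventions, pluggable where alternatives
are defensible. Methylation inputs must arrive normalized; the caller's
2-of-4 support rule is a fixed-design heuristic, not an error-controlled
test, and its false-call behavior under noise far above the logit-0.1
regime is not characterized.
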