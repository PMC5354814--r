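---
title: "Methods: connectivity-based drug repurposing and preclinical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based drug repurposing and preclinical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsrepo)
library(dplyr)
```

`ewsrepo` implements a complete computational drug-repurposing pipeline of
the kind used to nominate existing drugs against Ewing sarcoma (EWS), a
pediatric bone and soft-tissue cancer driven by the EWS/FLI1 fusion
oncogene: in-silico connectivity screening of a drug perturbation
database against disease-derived gene signatures, high-throughput
viability screening with counter-screen filtering, median-effect
dose-response and Chou-Talalay synergy analysis, non-compartmental
pharmacokinetics of blood gold (for the repurposed gold complex
auranofin), and Kaplan-Meier comparison of xenograft survival arms.
Because the perturbation databases and raw screens behind such studies
are generally not redistributable, the package ships a seeded
synthetic-data generator that plants known ground truth in every input,
so each stage — and the pipeline end to end — is testable and
reproducible offline.

## Connectivity scoring

### The statistic

A query signature is a pair of disjoint gene sets: `up` (over-expressed
in the condition of interest) and `down` (under-expressed). A drug
*instance* is one perturbation experiment summarized as a full ranking
of the gene universe, rank 1 being the most up-regulated gene. For a
gene set of size $t$ occupying ascending positions $V(1) \le \dots \le
V(t)$ in a ranking of $n$ genes, the bidirectional Kolmogorov-Smirnov
enrichment is

$$a = \max_j\left(\frac{j}{t} - \frac{V(j)}{n}\right),\qquad
  b = \max_j\left(\frac{V(j)}{n} - \frac{j-1}{t}\right),$$

returning $a$ if $a \ge b$ and $-b$ otherwise. Values near $+1$ mean the
set crowds the top of the ranking, near $-1$ the bottom. (The two tails
are not perfectly symmetric: a set filling the top $t$ positions scores
$1 - t/n$ while one filling the bottom scores $-(1 - (t-1)/n)$, a
consequence of the $(j-1)/t$ term; the package pins this exact form and
its tests enumerate every position set for small $n$ against a direct
evaluation.)

The connectivity score of a signature against an instance combines the
two sets: $s = (\mathrm{ks}_{up} - \mathrm{ks}_{down})/2$, zeroed when
both enrichments share a sign (a drug cannot coherently move both sets
the same way). Thus $s = -1$ is perfect *reversal* — the signature's
up-genes at the bottom of the drug ranking and down-genes at the top —
and $s = +1$ perfect *mimicry*. Reversal of a disease signature is the
repurposing hypothesis; mimicry of a fusion-silencing (siRNA) signature
identifies drugs phenocopying loss of the oncogenic driver.

### Aggregation, significance, selection

Drugs usually own several instances; the drug-level score is the median
of its instance scores (a max-magnitude alternative is exposed via
`aggregate = "max"`). Significance comes from a permutation null that
preserves each instance's ranking structure: `n_perm` random signatures
of identical up/down sizes are scored against the very same instances
and aggregated identically; the two-tailed p-value on $|s|$ carries an
add-one pseudocount, so the smallest attainable p is $1/(n_{perm}+1)$
and the p-values are valid (super-uniform) by exchangeability.
Benjamini-Hochberg FDR is applied across drugs within each approach,
hits require FDR < 0.05, and each approach keeps its top 20 by score
with deterministic tie-breaking (p-value, then drug id). The default
`n_perm = 1000` makes the p-value floor about $10^{-3}$, small enough
for ten true hits among 200 drugs to clear BH at 0.05.

Three approaches are run against the same database: reversal of a
disease signature, mimicry of a fusion-silencing signature, and
reversal of a chemoresistance signature; their hit lists are merged
into one table of distinct drugs with per-approach membership and
instance multiplicity, minus a user-supplied exclusion list (the
analogue of removing already-prescribed agents or manual triage).

### Signature construction

The disease signature for an overlap-based query is the direction-wise
intersection of two independent signatures; genes with conflicting
directions are dropped and reported rather than resolved by magnitude —
the conservative reading of an "overlap". The chemoresistance signature
is derived from pre-treatment expression of chemotherapy responders
versus non-responders by a per-gene Wilcoxon rank-sum test (mid-ranks,
tie-corrected normal approximation, no continuity correction), BH
adjustment across genes, direction by the sign of the median difference
and truncation to the top genes by absolute effect. A rank-based test
was chosen because it is invariant under monotone transforms of the
expression scale, which the test suite verifies literally. Gene
identifiers match as exact strings after upper-casing; no alias or
ortholog resolution is attempted.

Replicate robustness: drugs whose instances disagree carry little
signal, so for every drug with at least 2 instances the median pairwise
Spearman correlation among its rankings is computed (Pearson on stored
ranks) and drugs below 0.3 are dropped entirely; single-instance drugs
cannot be assessed and are retained with a flag. The 0.3 default is a
package choice exposed in the API — removal of non-robust profiles is
standard in this lineage but no canonical threshold exists.

## High-throughput screen

Plate signals are normalized per plate to percent inhibition,
$100\,(1 - \text{signal}/\overline{\text{vehicle}})$, using each
plate's own vehicle-control mean (absorbing plate effects). Assay
quality is gated by the Z-prime factor
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ with sample SDs;
plates below 0.5 are excluded from hit calling. A compound is a hit
when it exceeds 50% inhibition at 1 umol/L — strictly greater, so 50.0
is not a hit — in at least one tumor line; compounds also active in any
non-tumorigenic control line are discarded as generally cytotoxic, and
a blacklist removes agents already prescribed for the disease.
Reported values like "< 50" are stored left-censored; the hit predicate
is simply false for them, which is exact whenever the threshold is at
or above the censor bound. The bundled 45-compound example table
satisfies the rule on every row, and its one blacklisted compound is
excluded from nomination.

## Dose-response and synergy

Single-agent potency uses the median-effect model
$f_a/f_u = (D/D_m)^m$, linearized as
$\mathrm{logit}(f_a) = m\log D - m\log D_m$ and fitted by ordinary
least squares; $D_m$ is the IC50 and $m$ the sigmoidicity. Points with
negative $f_a$ (growth stimulation) are excluded; responses exactly at
0 or 1 are offset by $\varepsilon = 0.01$ so the logit exists, while
interior values are used as observed — this keeps noiseless round
trips exact to numerical precision, which the tests assert at 1e-6.
Curves never reaching 50% effect are right-censored at the top dose
("> 50"), curves already past 50% at the lowest dose left-censored
("< 0.003"-style); censored fits carry no $D_m$. Replicate fits are
summarized as mean ± SD across at least three independent curves.

Two-drug 9x9 checkerboards (eight two-fold dilutions per drug plus the
zero row/column) are scored with the mutually exclusive Chou-Talalay
combination index at each interior cell:
$\mathrm{CI} = d_1/D_{x1} + d_2/D_{x2}$ with
$D_{xi} = D_{m,i}\,(f_a/(1-f_a))^{1/m_i}$ evaluated at the cell's
observed (replicate-mean) effect, single-agent parameters taken from
the zero row/column axes. Cells with negative inhibition or complete
effect are undefined, as is the whole matrix when either single-agent
fit is censored. Classification bands: CI < 0.5 strong synergy,
< 0.9 synergy, up to 1.1 additive, above antagonism. The reporting
convention leaves the region between 0.9 and 1 and the exact
boundaries open, so an explicit additive band [0.9, 1.1] is pinned and
configurable. Replicate-mean $f_a$ is used for CI (per-replicate
analysis is available by filtering before the call); the third
"mutually nonexclusive" product term is deliberately omitted, matching
the default CI reported by the standard software in this field.

## Pharmacokinetics

Auranofin is dosed as the parent complex but assayed as blood gold;
with gold at 196.97 g/mol and auranofin at 678.48 g/mol, gold is 29% of
auranofin by weight, a 12 mg/kg dose contains 3.48 mg/kg gold, and a
12.43 ug/mL gold concentration is 63.1 umol/L. Non-compartmental
analysis takes Cmax/Tmax as the observed maximum, AUC(0-t) by the
linear trapezoid (log-linear deliberately not used — the linear rule is
the simplest defensible reading of a non-parametric summary, and an
option would only matter in sparse tails), and the terminal
elimination constant from a log-linear regression over a terminal
window. The default window rule scans the last 3 to 6 positive
concentrations (excluding Tmax itself) and keeps the best adjusted
R-squared; `"last3"` is available. A non-positive terminal slope
refuses extrapolation and returns an AUC(0-t)-only result with a flag.
Then AUC(0-inf) = AUC(0-t) + C_last/Kel, T1/2 = ln2/Kel, and
Cl/F = dose/AUC(0-inf) (mL/hr/kg for a ug/kg dose and ug/mL
concentrations). Repeated dosing is summarized by pre-dose troughs at
each multiple of the dosing interval and the accumulation ratio
trough/C_single(tau); for a one-compartment drug this follows the
superposition partial sum, which approaches — but after five daily
doses remains about 3% below — the steady-state limit
$1/(1 - e^{-k_e\tau})$.

## Survival

Kaplan-Meier product-limit curves are computed per arm,
$\hat S(t) = \prod_{t_i \le t}(1 - d_i/n_i)$, and arms are compared
with the classical 1-df log-rank test over shared risk sets,
hypergeometric variance. Pairwise comparisons against the vehicle arm
are unadjusted by default (Holm available); animals sacrificed at a
humane endpoint count as events, censoring is reserved for study end.
The implementation is cross-checked against the survival package on
hundreds of simulated trials in the test suite.

## What the synthetic generator emulates — and what it does not

Every generator is a pure function of its configuration and seed;
identical seeds give bit-identical outputs.

* **Rank profiles** arise the way real connectivity databases do: a
  latent differential-expression vector, rank-transformed. Planted
  reversers shift signature up-genes down by `plant_effect` (default 3
  latent SD units) and down-genes up; mimics the opposite; background
  drugs carry their own random latent profile. All instances of a drug
  share the drug-level latent vector, perturbed per instance by
  `noise_sd` (default 0.25), so replicates are mutually consistent the
  way the robustness filter expects. Defaults of 2,000 genes and 200
  drugs with 1-5 instances each keep every simulation-backed check
  inside a couple of minutes while preserving the multi-instance
  structure that drug-level aggregation and multiplicity reporting
  exercise.
* **Responder matrices** are standard-normal expression with a planted
  set shifted by a configurable number of SDs in the non-responder
  group (default 2). Note a practical power fact the test suite
  encodes: with 10 samples per group, BH-gated Wilcoxon recovers only
  roughly 60% of genes planted at 2 SD; near-complete (>= 90%) recovery
  needs about 3 SD. Recovery assertions therefore run at 3 SD.
* **Plates** use multiplicative gaussian noise (CV-parameterized,
  default 5%, floored at zero signal) because luminescence noise scales
  with signal; 32 vehicle and 32 kill-control wells put the expected
  Z-prime comfortably above 0.5.
* **Dose matrices** plant an interaction by generating the interior
  effect as the solution of $d_1/D_{x1}(f_a) + d_2/D_{x2}(f_a) =
  \alpha$, so the downstream CI recovers $\alpha$ exactly at zero
  noise ($\alpha$ = 1 additive, 0.5 synergy, 2 antagonism).
* **PK profiles** follow one-compartment first-order absorption,
  $C(t) = \frac{D\,k_a}{V(k_a - k_e)}(e^{-k_e t} - e^{-k_a t})$, with
  defaults (ka 0.352/hr, ke 0.029/hr, V/F 223.8 mL/kg, dose 3480
  ug/kg) chosen so the default profile on the standard sampling grid
  (pre-dose through 48 hr) reproduces the blood-gold study conditions:
  peak ~12.4 ug/mL near 8 hr, terminal half-life ~24 hr, exposure ~540
  ug·hr/mL, Cl/F ~6.5 mL/hr/kg. The flip-flop case ka = ke is
  rejected.
* **Survival** arms are exponential with administrative censoring at
  day 60; defaults give a vehicle median of 12 days, hazard ratios of
  0.6 for single agents and 0.5 for the combination, 12 animals per
  arm — enough for the combination arm to reach significance in a
  typical draw, as in the worked example.

Deliberately **not** emulated: real perturbation-database content and
batch structure, inference procedures for reduced gene panels,
cross-platform identifier mapping, microarray preprocessing, plate
spatial artifacts (edge effects, drift), receptor-level synergy
mechanisms beyond scaled Loewe, multi-compartment or nonlinear PK, and
tumor-volume dynamics. Passing tests therefore demonstrate the
*analysis machinery* — recovery of planted truth, calibration of the
permutation null, exactness of the closed-form algebra — not fidelity
to any particular biological dataset.

## Numerical and degenerate-input choices

* Ties in latent vectors are broken randomly but under the seed;
  planted drugs at zero noise keep an infinitesimal (1e-9 SD)
  background latent so replicate rankings stay reproducible instead of
  devolving into mass ties.
* A gene set equal to the whole universe has enrichment 0 by
  convention; empty sets are errors; one-sided signatures score on the
  available side and are flagged.
* Permutation p-values use the add-one pseudocount throughout; BH may
  reorder p and FDR freely.
* The log-rank variance term is skipped when a risk set has a single
  subject (its hypergeometric variance is zero); identical arms give
  statistic 0 and p 1.
* `uniroot` on the scaled-Loewe equation runs at tolerance 1e-12 with
  a closed form shortcut when the two slopes are equal.

## Problem sizes used by the test and acceptance runs

Simulation-backed checks use a 400-gene, 24-drug study for unit tests
and the full default 2,000-gene, 200-drug study (noise 0,
n_perm = 1000) for planted-recovery and calibration checks, pooling
background drugs over three seeds for the type-I estimate; survival
cross-checks run 500 simulated 12-per-arm trials. The complete suite
runs in about a minute on one core.

## Known limitations

* The permutation null is shared across drugs within a run (the same
  random signatures score every instance), which is exactly the
  exchangeability the p-values need but makes drug-level p-values
  mutually dependent; calibration statements are therefore about the
  pooled rate.
* Censored screen entries ("< 50") only support threshold predicates
  at or above the censor bound.
* The resistance approach's signature is derived from data unrelated
  to the drug database in the synthetic bundle, so its hit list is
  typically empty there — by design, it exercises the empty-list path.
* CI values are undefined wherever single-agent fits censor or cells
  leave (0, 1); no imputation is attempted.
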