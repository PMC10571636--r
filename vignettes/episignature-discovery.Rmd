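---
title: "Methylation episignature discovery with episig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation episignature discovery with episig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Several rare neurodevelopmental disorders leave a reproducible genome-wide
DNA methylation pattern — an *episignature* — in peripheral blood that can
be read from Infinium-style beta-value arrays. Discovering such a pattern
from a small case series is a pipeline problem: quality-filter probes and
samples, select unaffected controls matched on the covariates that dominate
blood methylation (age, sex, array platform), test every probe for a
case-control shift while adjusting for blood cell composition, select a
compact probe panel, and confirm that the panel separates cases from
controls in unsupervised analyses before any claim is made. `episig`
implements that workflow end to end, together with a seeded simulator so
every stage can be validated without patient data, and a small clinical
penetrance summarizer for the accompanying cohort phenotype table.

## The model

Methylation at probe $g$ in sample $i$ is measured as a beta value
$\beta_{gi} \in [0,1]$ (fraction methylated). Statistics are computed on
the variance-stabilized M scale,

$$M = \log_2\!\frac{\beta + \varepsilon}{1 - \beta + \varepsilon},
\qquad \varepsilon = 0.01,$$

where the offset keeps $M$ finite at the boundaries without moving the
midpoint ($M(0.5) = 0$ for any $\varepsilon$). Effect sizes are reported on
the beta scale ($\Delta\beta$, mean case minus mean control), which is the
scale on which the conventional "minimum 5% methylation difference"
screening threshold lives.

Each probe is fit by ordinary least squares,

$$M_{gi} = \alpha_g + \gamma_g\,\text{case}_i +
  \sum_k \eta_{gk}\, c_{ik} + e_{gi},$$

with $c_{ik}$ the estimated blood-cell proportions (one reference type
dropped — proportions are compositional, so the full set is collinear with
the intercept). With only a dozen cases, per-probe variance estimates
$s_g^2$ are noisy; they are therefore shrunk toward a prior through the
standard empirical-Bayes moderated-t construction. Assuming
$s_g^2 \sim s_0^2 F(d_g, d_0)$, the prior $(d_0, s_0^2)$ is estimated by
matching the mean and variance of $\log s_g^2$ to their theoretical values
(a digamma/trigamma moment system; the trigamma inversion is solved by
bisection to a relative tolerance of $10^{-8}$). The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}$$

yields $\tilde t_g = \hat\gamma_g / (\sqrt{v_g}\,\tilde s_g)$ on
$d_g + d_0$ degrees of freedom (standard normal when $d_0 = \infty$, which
the estimator returns when the spread of $\log s_g^2$ does not exceed its
sampling-only expectation; $d_0 = 0$ recovers the ordinary t-test).
Two-sided p-values are Benjamini–Hochberg adjusted. The in-package
implementation is verified in the test suite against `limma`'s
independently to six significant figures.

## Probe selection and model selection

Candidate probes must pass, in order:

1. $|\Delta\beta| \ge$ `delta_min` (default 0.05);
2. direction-free ROC importance $\max(A, 1-A) \ge$ `auc_min`, where $A$
   is the Mann–Whitney AUC (ties counted half) — direction-free because
   the screen should keep both hypo- and hypermethylated probes, with the
   panel's direction summarized afterwards;
3. rank by p-value (ties by larger $|\Delta\beta|$, then probe id) and
   keep the first `top_n`;
4. greedy correlation pruning: walking that order, drop any probe whose
   absolute Pearson correlation with an already-kept probe exceeds
   `r_max`, computed across all training samples (cases plus matched
   controls).

Sequential filtering (rather than a weighted combination of the p-rank and
ROC criteria) was chosen as the simplest composition that makes each
threshold individually interpretable.

Parameter combinations are compared by a clustering-quality score. With
samples as beta vectors over the candidate panel,

$$\text{score} = \frac{\text{gap}}
 {\text{spread}_\text{case} + \text{spread}_\text{control} + 10^{-8}},$$

where the gap is the minimum Euclidean case-control distance and each
spread is the root-mean-square distance of a group's samples to its
centroid (zero for singletons). The score is symmetric in the labels,
invariant to translation and rotation in probe space, scales linearly with
the data, and is zero exactly when the groups touch. RMS-to-centroid was
preferred over per-coordinate standard deviations to give one scalar
dispersion per group in arbitrary dimension; the score is computed in probe
space rather than MDS space so that it does not depend on an embedding
dimension. A practical consequence of this ratio form is that it is nearly
invariant in panel size (gap and spreads both grow roughly as the square
root of the panel dimension), so when several panel depths separate the
groups cleanly it tends to pick the smallest, strongest panel: model
selection favors compactness over exhaustiveness.

The default grid spans `top_n` ∈ {100, 200, 300, 500, 1000}, `auc_min` ∈
{0.75, 0.85, 0.95}, `r_max` ∈ {0.7, 0.8, 0.9} with `delta_min` fixed at
0.05. Ties in score break deterministically: fewer probes, then the
lexicographically smaller parameter tuple.

Unsupervised confirmation uses agglomerative clustering with Ward linkage
on Euclidean distances (`ward.D2`) and classical Torgerson MDS to two
dimensions. Held-out samples (test individuals, lymphoblastoid replicates)
are projected by appending them to the training matrix over the panel's
probes, recomputing the dendrogram, and assigning each to the side of the
two-cluster cut whose training majority defines its label; distances to
the training case and control centroids are reported alongside as a
continuous diagnostic, because borderline samples can co-cluster
ambiguously. A cut side containing no training samples carries no vote and
falls back to the nearer centroid.

## Matching

Controls are matched exactly on sex and array type; within each exact
stratum each case, processed in sample-sheet order, greedily takes the
`ratio` controls nearest in age without replacement (ratio restricted to
the conventional 1:3–1:8 range). Age ties break by lexicographic sample
id, so matching is deterministic and needs no seed. Greedy
nearest-neighbour within exact strata was preferred over a propensity
model: with two categorical covariates and one continuous covariate it
realizes the same intent transparently and reproducibly.

## The simulator

`generate_dataset()` draws data with the structure the analysis assumes:

* **Baselines.** Per-probe baseline M-values from a three-component
  mixture, means $(-3, 0, +3)$, SDs $(0.9, 0.5, 0.9)$, weights
  $(0.4, 0.2, 0.4)$ — the canonical bimodal Infinium beta density with a
  modest intermediate fraction.
* **Signal.** `n_signature` probes receive a case effect drawn uniformly
  from `delta_range` (default 5–16% absolute beta difference), negative
  with probability `hypo_fraction` (default 1: a fully hypomethylated
  profile). Effects are injected on the beta scale, where the 5% screening
  floor lives, then clamped to $[0.01, 0.99]$; noise and covariates act on
  the M scale, where the linear model operates. Signature probes are drawn
  from clean autosomal probes with intermediate baselines
  ($\beta_0 \in [0.25, 0.75]$) so the configured effect is realizable
  without clamping, mirroring the intermediate methylation typical of
  differentially methylated positions.
* **Covariates.** Six blood cell types by default, proportions from a
  neutrophil-dominated Dirichlet (total concentration 40); per-probe,
  per-cell-type M-scale coefficients with SD `cell_effect_sd` act on
  centered proportions. Controls cycle over the cases copying sex and
  array type with jittered age, so exact-stratum matching is feasible by
  construction.
* **Replicates.** LB-line replicates copy their source individual's
  expected methylation (baseline, case effect, cell effects) and add
  technical noise only, at half the biological `noise_sd` — replicates
  must co-cluster with their source group.
* **Detection failures.** A fraction `frac_failed_detection` (default
  0.1%) of probe-sample measurements receives a high detection p-value;
  probe fractions `frac_xy`, `frac_cross_reactive`, `frac_snp` carry the
  standard exclusion attributes.
* **Determinism.** One global seed; each generation stage draws from its
  own deterministically derived substream, so adding draws to one stage
  never perturbs another.

Defaults (20,000 probes, 12 cases, 60 controls, 2 held-out test samples,
3 replicates, 200 signature probes, `noise_sd` 0.25) describe a small
rare-disorder discovery cohort and are the conditions under which the
package's acceptance checks run; they are desk-scale on one CPU.

What the simulator does **not** emulate: probe-type chemistry and raw
intensities, batch effects beyond cell composition, spatially correlated
probes (CpG islands), genotype-driven outlier probes, or age/sex effects
on methylation itself (age and sex enter only through matching). Passing
tests therefore demonstrate that the machinery is correct and well
calibrated under its stated model, not that real cohorts will separate as
cleanly.

## Numerical and policy choices

* Detection failure is $p > 0.01$ per measurement; a probe is dropped if
  it fails in *any* retained sample (the conservative convention), and
  samples are filtered before probes so bad samples cannot inflate probe
  failure fractions. A sample fails when strictly more than 5% of its
  probes fail.
* $\varepsilon = 0.01$ in the M transform; `m_to_beta()` is its exact
  inverse at the same $\varepsilon$.
* The score's $10^{-8}$ regularizer only guards singleton-group or
  zero-spread degeneracies.
* Correlation pruning treats a constant (zero-variance) probe as
  uncorrelated rather than undefined.
* Penetrance percentages round half away from zero to integers, which
  reproduces conventional clinical reporting (23/40 printing as 58%).
* Cross-reactive and SNP-overlap status are manifest columns supplied by
  the user or the simulator; the package does not compute them, as
  published exclusion lists are array- and version-specific.

## Limitations

* The clustering score's functional form is a declared convention — the
  minimum inter-group distance against the summed group dispersions —
  chosen for symmetry, scale behaviour and testability; other monotone
  combinations of the same two ingredients would rank parameter
  combinations slightly differently, in particular in how strongly they
  prefer compact panels (see above).
* Greedy matching is not globally optimal across cases; it is optimal per
  case and deterministic, which is what a reproducible discovery pipeline
  needs most.
* The pipeline stops at clustering-confirmed profiles; it deliberately
  does not train a supervised classifier on the selected panel, which
  requires larger cohorts and external validation.

## A compact run

```{r example}
library(episig)

run <- run_pipeline(pipeline_config(sim = sim_config(seed = 1), ratio = 5))
glance(run$profile)          # panel size, hypomethylated fraction, score
run$clustering$purity        # 2-cut purity of the training samples
tidy(run$projection)         # held-out assignments with centroid distances
autoplot(run$clustering)     # MDS of training samples
summarize_penetrance(generate_phenotype_fixture())
```
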