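---
title: "Methods: drug-response imputation, consensus nomination and causal biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-response imputation, consensus nomination and causal biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioscreen)
```

glioscreen implements an in-silico drug discovery pipeline for glioblastoma
(GBM): it transfers drug sensitivity measured in cancer cell-line screens
onto patient tumor transcriptomes, nominates drugs whose predicted
sensitivity is consistently higher in GBM than in non-tumor or low-grade
comparison groups, and then asks *which genes cause* the predicted response
of a nominated drug. Because the real inputs (public tumor cohorts and
cell-line screens) are large external downloads, the package carries a
synthetic-data generator with full causal ground truth; every claim the
package makes about its own statistics is checked against that truth.

## 1. The imputation model

For each drug $d$, the training data are the screened cell lines: a gene
expression matrix $X$ (lines $\times$ genes, log-scale) and a response
vector $y$ of dose–response AUC values (lower = more sensitive; on the
familiar 10–20 score scale). We fit ridge regression

$$\hat\beta = (X_s^\top X_s + \lambda I)^{-1} X_s^\top (y - \bar y),$$

where $X_s$ is the training design with genes centered and scaled to unit
variance, and the intercept is $\bar y$. Lines not screened for $d$ are
dropped, so adding unscreened lines never changes a drug's model (a tested
invariant). Genes vastly outnumber lines, which is exactly the regime where
the L2 penalty is the standard choice; the solution is computed from the
thin SVD of $X_s$, which also gives the exact leave-one-out (LOO) residuals
$e_i/(1-h_{ii})$ for *every* candidate $\lambda$ at no extra cost.

Tunable parameters:

* `lambda_mode = "loo"` (default): $\lambda$ minimizes the closed-form LOO
  mean squared error over a grid of $10^{-4}$–$10^{5}$ (unitless, on the
  standardized-gene scale). A `"fixed"` mode exists for tests and for users
  who want one penalty across drugs. No selection rule is canonical here;
  LOO was chosen because it is exact, deterministic and needs no extra
  split.
* `min_fraction = 0.40` in `filter_drugs()`: drugs screened in fewer than
  40% of lines are removed before fitting (strict `<`, so exactly 40% is
  retained) — sparsely screened drugs would otherwise train on small,
  unrepresentative line subsets.
* Zero-variance genes are dropped with a warning; drugs trained on fewer
  than 20 lines are flagged in the model-set metadata.

### Cross-platform harmonization

Tumor cohorts come from different platforms (microarray vs RNA-seq), whose
per-gene scales are monotone-but-nonlinear distortions of each other.
`harmonize_expression()` restricts train and test to their shared genes and
replaces each test gene's values by the training distribution's empirical
quantiles at the test ranks ($(r-\tfrac12)/m$, piecewise-linear quantile).
This removes any per-gene strictly monotone distortion exactly up to
interpolation (a tested round trip through the generator's distortion) and
is idempotent. It deliberately preserves only rank information — which is
all that the downstream Spearman and rank-sum statistics consume. It is a
rank-to-quantile mapping authored for this package, not a reimplementation
of any published integration tool.

## 2. Drug nomination

Per cohort ("dataset"), each drug's imputed AUC is compared between the GBM
group and the comparison group with the two-sided Wilcoxon rank-sum test
(exact null distribution when both groups have $\le 10$ tie-free values,
tie-corrected normal approximation with continuity correction otherwise),
p-values are Benjamini–Hochberg adjusted *across drugs within the dataset*,
and the effect size is the Hodges–Lehmann estimate (HLE): the median of all
pairwise GBM $-$ control differences, in AUC units. Negative HLE means GBM
is predicted more sensitive.

A drug is *selected* in a dataset when

1. $q \le$ `alpha` (default 0.05),
2. HLE $< 0$ (direction), and
3. its HLE lies in the most-negative `percentile` (default 0.5) fraction of
   the drugs passing 1–2, with an inclusive ceiling (a lone passing drug is
   selected; boundary ties are all included).

`consensus()` nominates a drug that is selected in at least `min_clinical`
(default 3) clinical datasets *and* in the avatar dataset; drugs passing the
clinical majority but failing the avatar check are reported separately.

Design choices that were genuinely open:

* *HLE sign convention*: GBM $-$ control, so "better for GBM" is negative.
* *BH family*: drugs within one dataset comparison.
* *Percentile family*: computed among drugs passing significance and
  direction (the default); `percentile_scope = "all_significant"` ranks by
  $|$HLE$|$ among all significant drugs instead, since the phrase "top
  percentile of significant drugs with the largest shift" admits both
  readings. Selection always requires a negative HLE.

## 3. Causal biomarker discovery

For one nominated drug, the question becomes: which genes *cause* its
(predicted) response? The pipeline is a Spearman pre-filter followed by
constraint-based Bayesian-network learning local to the response node.

**Pre-filter.** `scc_filter()` keeps genes with BH $q <$ 0.05 and $|r| \ge$
`r_min` (default 0.60) Spearman correlation with the response, reducing
tens of thousands of genes to tens–hundreds. This both bounds the cost of
the network stage and neutralizes the variable-order dependence that
constraint-based learners exhibit in very high dimensions (candidates are
additionally processed in a fixed order: descending $|r|$, ties by gene ID).

**Conditional-independence test.** The partial correlation
$\rho(x, y \mid Z)$ is the Pearson correlation of the residuals of $x$ and
$y$ after linear regression on $Z$ (equivalently, from the inverse
correlation matrix — the two routes agree to $10^{-8}$ in tests). The
Fisher-z statistic $T = \sqrt{n - |Z| - 3}\,\operatorname{atanh}(\rho)$ is
compared to the standard normal; its *sign* carries directionality:
positive against AUC means high expression tracks resistance.

**MMPC.** The parent–child (PC) set of the response — genes directly
connected to it in a Bayesian network — is found by the max–min heuristic:
the forward phase repeatedly adds the candidate with the largest
*minimum* association $|T|$ over all conditioning subsets (size $\le$
`max_k`, default 3) of the current PC set, while that minimum is significant
at `alpha` (default 0.05); the backward phase removes any member rendered
independent by some subset of the others. Each surviving gene is reported
with its weakest surviving test — the elimination semantics make that the
gene's evidence floor. `max_k = 3` is standard practice and bounds runtime;
`alpha` is the CI-test level, distinct from the pre-filter FDR.

**Orientation.** MMPC does not distinguish causes from effects, so
`orient_parents()` runs a PC-style skeleton search over the response, its PC
genes and their own PC sets, orients v-structures from recorded separating
sets (for $i - k - j$ with $i \not\sim j$ and $k \notin \mathrm{sep}(i,j)$,
orient $i \to k \leftarrow j$), and propagates orientations with the
standard acyclicity-preserving rules. *Parental* genes are PC members with
an edge oriented into the response. Orientations that the data cannot
determine are reported undirected, never forced — a single cause with no
collider context stays undirected by design.

## 4. The synthetic-data generator

`sim_config()` + `simulate_cell_line_panel()` + `simulate_patient_cohorts()`
emulate the statistical structure the pipeline assumes, with recorded truth:

* Gene expression is standard normal per gene (the real inputs are
  normalized, log-transformed and approximately Gaussian); genes are
  independent unless structured below.
* Each drug has `n_parents_per_drug` *parent* genes with signed weights
  (magnitude `effect_size`, signs alternating $+,-,+\dots$ so both
  directions exist at every seed); the raw response is their weighted sum
  plus $N(0,$ `noise_sd`$^2)$ noise, min–max rescaled per drug into the
  10–20 AUC band (affine, so ranks are unchanged). Screen entries are
  removed completely at random at `missing_fraction`.
* In patient cohorts, GBM samples have each parent gene's mean shifted by
  $-$`sensitivity_shift`$\cdot\operatorname{sign}(w)$, so GBM imputes as
  more sensitive. `n_sensitive_drugs` controls how many drugs are true
  hits; the rest are null.
* *Child* genes are generated as weight $\times$ the **observed** (noisy)
  response plus unit noise — they are downstream of the response
  (response → gene edges), so they correlate with it and remain dependent
  given the parents, which is what makes them genuine PC members. (Making
  children functions of the noise-free parent combination would instead
  render them conditionally independent of the response given the parents —
  siblings, not children — and no PC algorithm should recover them.)
* *Confounded* genes are weight $\times$ one shared parent plus unit noise:
  marginally correlated with the response, conditionally independent given
  that parent. They are the canonical trap for correlation-based biomarker
  calls.
* `apply_platform_effect()` applies per-gene strictly increasing signed
  cubics (random positive slopes, offsets) to emulate platform distortion;
  ranks are preserved exactly.
* `simulate_dose_response()` draws relative-ATP viability from a
  four-parameter logistic in log10-dose (nine doses log-spaced over
  0.015–100 nM, six replicates, default 5-point replicate noise; GBM EC50
  1 nM with 0.2 lognormal spread vs NPC 500 nM, i.e. resistant within the
  tested range) and records each sample's noise-free trapezoidal AUC.

What the generator does **not** emulate: gene–gene correlation blocks among
bystanders, probe/background artifacts, tumor purity, subtype structure,
informative missingness, and batch effects beyond the per-gene monotone
map. Passing tests therefore demonstrate the statistical machinery under
the model's assumptions, not performance on real cohorts.

All randomness derives from the single config seed through named
per-stage substreams, so identical configs reproduce byte-identical
artifacts and no stage's draws can reorder another's.

## 5. Dose–response AUC

`auc_trapezoid()` averages technical replicates per dose and integrates the
relative-ATP curve by the trapezoidal rule (via `pracma::trapz`). The
default axis is log10(dose): the nine-dose design spans nearly four decades,
and on a linear axis the top dose would contribute almost the entire
integral. A linear-axis option is exposed. No sigmoid is fitted — the
empirical curve is integrated directly, so the statistic makes no
monotonicity or asymptote assumptions.

## 6. The validation experiments

The package ships the simulation studies it is judged by
(`*_experiment()` functions; `scripts/acceptance.R` re-runs them and writes
the numbers as JSON). Problem sizes were chosen to finish in a few minutes
on one core while leaving clear margins:

* **Null calibration** — 200 truly null drugs (zero effect, zero shift),
  each evaluated on its own independently drawn 50 + 50 cohort after
  training on a 150-line panel; reports the fraction of BH $q \le 0.05$ and
  a Kolmogorov–Smirnov uniformity check of the raw p-values. Each drug gets
  its own cohort because a shared cohort leaves the 200 p-values marginally
  uniform but mutually correlated through the common expression draw, which
  over-disperses the KS statistic — a property of that single draw, not of
  the test being calibrated.
* **Nomination power** — 100 drugs with 20 true GBM-sensitive hits
  (`sensitivity_shift` 1 SD, `effect_size` 1, noise 0.5), an 887-line
  training panel (the scale of the large public screens; smaller panels
  leave enough spurious weight on the hit drugs' shifted parent genes to
  produce occasional false consensus calls), five clinical cohorts plus one
  avatar at 80 samples/group, 10 replicate seeds. The effect-size
  percentile cut is disabled (`percentile = 1`) in this experiment: with
  exactly the 20 engineered hits passing significance and direction, a
  top-50%-of-passing cut caps per-cohort selections at 10 drugs by
  arithmetic, so the experiment measures what the consensus machinery can
  recover; the 50% cut remains the package default for real screens, where
  it is a conservativeness filter over a much larger passing set.
* **Imputation fidelity** — the reference panel (500 lines, 210 genes) and
  200 held-out samples; Spearman correlation of imputed vs true AUC.
* **Causal recovery** — the reference causal configuration (3 parents, 3
  children, 4 confounded, 200 bystanders, 500 samples, 20 seeds): PC-set F1
  against parents ∪ children, and how often confounded genes survive. The
  pre-filter runs at `r_min = 0.30` here: with $k$ independent
  equal-weight parents, no parent's marginal correlation can exceed
  $1/\sqrt{k}$ ($\approx 0.577$ for $k=3$ before noise), so the 0.60
  default — appropriate for the single-dominant-biomarker regime — would
  exclude every parent of this generative model by construction. These
  recovery metrics are computed against the *generative* response: the
  imputed score is a deterministic function of expression and therefore has
  no downstream children in the graph-theoretic sense (a child of the
  observed response is conditionally independent of the *imputed* response
  given the parents). The end-to-end imputed path is exercised by the
  directionality experiment below and by the fidelity experiment above.
* **Orientation precision** — same configuration at 2000 samples, 8 seeds;
  precision of parental calls pooled over seeds (the alternating parent
  signs guarantee collider evidence).
* **Directionality** — full train → harmonize → impute → filter → MMPC →
  orient path on one 1000-sample cohort; a parent gene with positive weight
  on AUC must be reported parental with the label
  "high expression → resistance" (higher AUC = less sensitive), the logical
  form of a resistance-biomarker call.

## 7. Numerical notes and degenerate inputs

* Ridge: rank-revealing SVD with singular values below
  $\max(d)\cdot\epsilon\cdot\max(\dim)$ discarded; LOO leverages clipped
  away from 1; constant response gives exactly zero weights and the
  constant as intercept.
* `fisher_z_test()` reports $|\rho| = 1$ as a signed infinite statistic
  with $p = 0$ rather than erroring mid-search.
* Constant genes: undefined correlations are reported `NA` with a warning
  (filter), or dropped with a warning (ridge).
* Exact Wilcoxon mode falls back to the corrected normal approximation,
  with a warning, when ties make enumeration unavailable.
* `harmonize_expression()` uses type-5 empirical quantiles so that with
  equal sample counts and no ties the mapping reproduces training order
  statistics exactly.
* MMPC tie-breaks (equal worst-case p) follow the fixed candidate order,
  making results independent of input column order.

## 8. Known limitations

* The harmonization preserves ranks only; intensity-dependent variance
  differences between platforms are not modeled.
* Constraint-based discovery assumes faithfulness and no latent confounding
  of response and candidate genes; the generator's confounded genes have
  *observed* parents, by design. Latent-variable discovery is out of scope.
* Parental calls need collider evidence; a drug whose response has a single
  strong cause will be reported with an undirected edge, not a parental
  call.
* The imputed response is a linear function of expression, so "causal"
  findings against it are statements about the generative signal it proxies;
  the package quantifies that proxy's fidelity rather than assuming it.

## 9. A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(n_genes = 60, n_cell_lines = 120, n_drugs = 3,
                  n_parents_per_drug = 2, n_children_per_drug = 1,
                  n_confounded_per_drug = 1, n_gbm = 40, n_control = 40,
                  sensitivity_shift = 1.5, seed = 1)
res <- run_pipeline(cfg, out_dir = tempfile("glioscreen"), n_clinical = 3)
res$consensus
res$biomarker
```

Every table `run_pipeline()` writes is re-readable with the package's own
readers, and the log records the exact thresholds each stage applied.
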