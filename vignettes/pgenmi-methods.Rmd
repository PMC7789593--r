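---
title: "Evidence-weighted mixture modelling of differential expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-weighted mixture modelling of differential expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgenmi)
```

## The model

`pgenmi` models the vector of per-gene differential-expression (DE)
p-values as a two-component mixture governed by a latent per-gene indicator
$Z_g$:

$$\Pr(Z_g = 1) = \mathrm{logistic}\Big(w_0 + \sum_t \sum_m w_{tm}\, r_{gtm}\Big),
\qquad
P_g \sim \begin{cases}\mathrm{Unif}(0,1) & Z_g = 0\\ \mathrm{Beta}(\alpha, 1) & Z_g = 1\end{cases}$$

with $r_{gtm} \in \{0,1\}$ the cis-regulatory evidence that a binding site
of TF $t$, overlapping a dynamic epigenomic mark $m$, lies within distance
$d$ of gene $g$'s TSS. The $\mathrm{Beta}(\alpha,1)$ density
$\alpha p^{\alpha-1}$ with $\alpha < 1$ is the classical model for an
enrichment of small p-values; $\alpha = 1$ collapses to the uniform, making
the mixture unidentifiable, which is why we constrain $\alpha \in (0,1)$.
Genes are treated as independent and $Z_g$ is marginalized analytically —
the likelihood is a product of two-term sums, so no E-M or sampling is
needed. Training maximizes

$$\mathcal{L}(\theta) = \sum_g \log \Pr(P_g) - \lambda \sum_{t,m} w_{tm}^2 .$$

Only evidence weights are penalized: $w_0$ absorbs the baseline fraction of
DE genes without evidence, and $\alpha$ is a shape, not a coefficient, so
shrinking either toward zero would bias the model rather than regularize
it. For the factorized variant (`variant = "fw"`), which ties
$w_{tm} = w_t w_m$, the penalty is the natural analogue
$\lambda(\sum_t w_t^2 + \sum_m w_m^2)$.

Model quality is reported as the log-likelihood ratio (LLR) against an
evidence-free null (only $w_0$ and $\alpha$) fitted to the same genes. Both
log-likelihoods are the *unpenalized* values at the respective optima of
penalized training, so the LLR is comparable across $\lambda$.

Because p-values carry no sign, the analysis is run twice:
`transform_de_pvalues(de, "down")` replaces $p$ by $1-p$ for genes with
positive log fold change (so only downregulated genes keep small p-values)
and `"up"` mirrors it. Genes with fold change exactly 1 are left unchanged
in both modes, and genes missing a fold change or p-value are dropped with
a reported count — imputing a direction for them would fabricate signal.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `distance` | gene-window half-width (bp) | user-set; CV over {10 kb, 50 kb, 200 kb, 1 Mb} | spans promoter-proximal to long-range enhancer scales |
| `lambda` | L2 coefficient | 0.1; CV grid {0.01, 0.1, 1, 10} | one decade around unity covers under- to over-penalized fits |
| `alpha` init | beta shape start | 0.5 | midpoint of the identifiable range |
| `w0` init | intercept start | logit(0.1) | ~10% of genes DE a priori, a typical two-condition experiment |
| `restarts` | optimizer starts | 5 | first start deterministic at zero weights; jittered restarts guard against rare local optima |
| p-value floor | clamp for $p = 0$ | 1e-12 | upstream tools emit exact zeros; the floor keeps $\log p$ finite without affecting any realistic p-value |

## Numerical choices

* **Log-space likelihood.** `gene_log_density()` combines
  $\log(1-\pi_g)$ and $\log \pi_g + \log\alpha + (\alpha-1)\log p_g$ by
  log-sum-exp; nothing overflows even at $p = 10^{-12}$, $\alpha \to 0$, or
  logits of $\pm 700$.
* **Optimizer.** `stats::optim` L-BFGS-B with analytic gradients (the
  gradient of the marginal likelihood has the closed form
  $\partial \ell_g / \partial \mathrm{logit}_g = \Pr(Z_g{=}1 \mid p_g) - \pi_g$,
  verified against finite differences in the tests). A deterministic
  quasi-Newton method suits this smooth, low-dimensional objective better
  than stochastic gradient descent and makes fits reproducible bit-for-bit
  given the seed. `tol` maps to L-BFGS-B's `factr`.
* **Constraint handling.** $\alpha = \mathrm{logistic}(a_{\mathrm{raw}})$
  keeps the shape in $(0,1)$ without constrained optimization.
* **Ties.** Equal ΔLLR values are broken by TF name; equal signature scores
  by gene id. All stochastic operations take an explicit seed and echo it in
  their results.
* **Degenerate inputs.** All-identical p-values, all-zero evidence columns
  and $p = 1$ under $\alpha < 1$ are all legal and tested; non-convergence
  flags the result instead of raising.

## Evidence construction

Coordinates are 0-based half-open (BED) everywhere; overlap means at least
one shared base; interval joins use GenomicRanges internally. The gene
window is $[\mathrm{tss} - d, \mathrm{tss} + d)$, centred on the TSS with
strand used only to locate it — the data distinguish "near the start site"
far more sharply than upstream from downstream, and a symmetric window
avoids an arbitrary asymmetry parameter. A dynamic mark is a replicate-1
peak overlapping any replicate-2 peak of the same stage (reported with
replicate-1 coordinates — the simplest auditable choice) with **zero**
overlap against either replicate of the other stage. Accessibility has one
profile per stage, so its dynamic calls skip the replicate requirement.

Strategy column counts per TF: DiffMark 8 (4 marks × 2 directions),
DiffMarkAggr 2, PresMark 4, DiffAcc 2, PresAcc 1, TFBS-only 1.

When both directions of one mark fire for the same (gene, TF), only one may
survive: we keep the direction with the larger total overlap (in bp)
between the TF's binding sites and that direction's dynamic intervals,
clipped to the gene window, breaking ties toward the late stage. Overlap
length is the one quantity available to all strategies that tracks "size of
the change" without importing signal values the builder deliberately does
not read. Conflicts are counted and reported;
`resolve_conflicts = FALSE` exposes the raw bits, which are monotone in $d$
(the resolved bits can flip direction as the window grows, so monotonicity
is only guaranteed pre-resolution).

TF contribution scores (`tf_delta_llr()`) re-evaluate the likelihood with a
TF's columns zeroed at the *trained* weights, without refitting. Refitting
would let the remaining correlated columns absorb the ablated TF's signal
and is non-deterministic across optimizer seeds; the fixed-weight ablation
is cheap, deterministic, and is the default (`refit = TRUE` is available
for sensitivity analysis).

`posterior_odds()` evaluates
$\mathrm{POR}_g = \pi_g \alpha p_g^{\alpha-1} / (1-\pi_g)$ and `rpor()`
forms the ratio of two such evaluations (with and without one TF's evidence
for that gene). Algebraically the beta factor cancels, leaving
$\mathrm{RPOR} = \exp(\sum_k w_k r_{gk})$ over the TF's columns; the tests
use that identity as an independent oracle against the two-evaluation
implementation.

`hypergeometric_enrichment()` defaults to the standard inclusive upper tail
$P(X \ge k)$; `strict = TRUE` gives $P(X > k)$, which is what some
published overlap figures report — for the canonical regulon-overlap
configuration (sets of 500 and 1981 in a universe of 17,200, overlap 87)
the strict tail reproduces the published 3E−5 at one significant figure
while the inclusive tail is 5E−5.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws evidence bits i.i.d. Bernoulli per column,
computes the logistic prior, draws $Z_g$, and samples p-values from the
stated conditionals; it is the generative reading of the model, so
parameter-recovery tests are well-posed. Real evidence matrices violate the
independence assumption: binding sites co-localize, so columns are
positively correlated. The `correlated = TRUE` option adds a shared
per-gene openness factor (open genes receive bits at 1.8× the nominal rate,
closed at 0.2×, preserving the marginal) for robustness checks, but neither
option reproduces peak-length structure, chromosomal clustering, or the
heavy-tailed p-value dependence of real DE tables. Passing recovery tests
therefore demonstrates correctness of the estimator under the model, not
performance guarantees on real data.

`simulate_genomic_fixture()` builds a toy single-chromosome genome in which
every edge pattern of the builder occurs at least once: replicate-
inconsistent peaks, exactly-one-base cross-stage overlaps, binding sites at
both sides of the window boundary, an unequal-overlap direction conflict
and an exact tie. Its expected matrices come from an independent plain-loop
brute-force scan, so builder and oracle share no code.

## Evaluation machinery

Cross-validation supports the 80/20 hyperparameter scheme (every
(d, λ) pair scored on the test split) and the 72/18/10 strategy-comparison
scheme (validation picks the pair, test LLR recorded once per repeat,
enabling paired per-repeat comparisons between encodings; ties count for
neither side). Held-out LLR evaluates both the trained model and the
trained null on the held-out genes. The permutation null shuffles each
evidence column independently across genes — preserving column marginals
while destroying gene-evidence association — refits on the full gene set
with (d, λ) fixed at the observed-data optimum, and summarizes the observed
LLR as a z-score.

Jaccard similarity of two all-zero feature vectors is defined as 0 (it
cannot arise in the published setting; 0 is the conservative choice for a
similarity). The distinct-profile selection scores each foreign TF by its
maximum Jaccard against the reference panel and keeps scores strictly below
the cutoff (default 0.2).

## Problem sizes used in the test suite

The suite simulates its own data at sizes chosen to make each statistical
assertion sharp but quick: marginalization is checked on 10^4 random
instances; parameter recovery on 10 datasets of 50,000 genes × 160 columns
(weight correlation ≥ 0.8, sign agreement ≥ 0.9 for |w| ≥ 1, α within
±0.05); shuffled-null calibration on 20 replicates of 50 permutations at
1,000 genes × 8 columns (|z| < 3 in ≥ 95%); builder-vs-oracle equality on
12-gene fixtures for all six strategies; cross-validation comparisons at
4,000 genes over 10 repeats.

## Known limitations

* Evidence is binary; peak strength, summit distance and multiplicity are
  deliberately discarded, trading sensitivity for interpretability.
* One latent indicator per gene means the model explains *that* a gene's
  expression changed, not which TF changed it; TF attribution is post hoc
  via ΔLLR/RPOR and inherits their correlations.
* ΔLLR without refitting slightly overstates the contribution of TFs whose
  evidence correlates with others'.
* The L2 penalty is spherical; no sparsity is induced, so near-zero weights
  are shrunken but not selected away.
* No uncertainty is attached to weights, ΔLLR or RPOR; rankings come
  without confidence intervals.
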