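---
title: "Methods: linking cortical-thickness differences to regional gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking cortical-thickness differences to regional gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Longitudinal cohorts of mild cognitive impairment (MCI) contain two
kinds of patients: those who remain stable and those who convert to
Alzheimer's disease. Comparing their baseline structural MRI yields a
per-region difference in mean cortical thickness,
$\Delta CT_r = \overline{CT}^{(A)}_r - \overline{CT}^{(B)}_r$, over a
few hundred cortical parcels (group A stable, group B converting, so a
positive value means the cortex is thinner in converters). The
scientific question is which genes' regional expression patterns align
with this map. `plsct` answers it with a single-response partial least
squares regression (PLS1) of $\Delta CT$ on a region-by-gene expression
matrix, such as a donor atlas aggregated to the same parcellation, and
then asks three follow-up questions: is the leading component more
aligned with $\Delta CT$ than chance; which genes drive it; and how do
its regional scores and gene list distribute over cytoarchitectonic
classes and cell-type marker sets.

# The model and its stages

## Delta-CT and predictor preparation

`compute_delta_ct()` subtracts group means region by region. Exactly
two groups are supported; multi-group contrasts are rejected rather
than silently averaged. Expression columns are standardized to zero
mean and unit sample variance (denominator $n-1$) across regions by
`standardize_genes()` so that weights are comparable between genes;
zero-variance genes are dropped with a warning. `align_regions()`
joins the two data sets on the *sorted intersection* of region ids —
never on position — and refuses to proceed below 10 shared regions.

## PLS1

For centred $X$ ($R \times G$) and centred $y$, the first component
weight is the normalized covariance direction
$w_1 \propto X^\top y$; the score is $t_1 = X w_1$; $X$ is deflated by
the rank-one regression of $X$ on $t_1$ and the step repeats. For a
single response this NIPALS-style extraction needs no inner iteration,
scores are mutually orthogonal, and the closed form of $w_1$ provides
an exact independent oracle used by the test suite. Each score column
is sign-flipped so that $\mathrm{corr}(t_k, y) \ge 0$, fixing the
reflection ambiguity; "positive weight" therefore always means
"expression high where $y$ is high". The variance explained by
component $k$ is the incremental $R^2$ of $y$ on the first $k$
orthogonal scores, so the entries are non-negative and sum to at most
one. With all $\min(R-1, G)$ components the fitted values equal
ordinary least squares, a second independent oracle.

## Component count

`select_components_cv()` uses $k$-fold cross-validation over *regions*
(default 10 folds, up to 35 components) and returns the count with the
smallest mean out-of-fold squared error, breaking ties toward fewer
components. Two behaviours are worth knowing. First, the fold split is
a function of the seed only, so the selection is reproducible. Second,
when the response is very close to an exact linear function of the
expression columns (as in a nearly noiseless simulation), out-of-fold
error genuinely keeps decreasing with $k$ and the argmin sits at the
upper bound; a low-rank optimum appears only when the response carries
noise that extra components cannot predict. This is a property of
cross-validated PLS, not a defect, and the unit tests exercise the
low-rank case at a moderate noise level (subject noise 0.4 mm) where
the interior optimum is real.

## Permutation test of variance explained

The observed statistic is the fraction of $\mathrm{var}(y)$ explained
by one component. The null refits after permuting $y$ across regions
(10,000 permutations by default), and
$p = \big(1 + \#\{\text{null} \ge \text{observed}\}\big)/(n_{perm}+1)$,
so $p$ is never zero. For component 1 the statistic has a closed form
that is vectorized over permutations; higher components refit
explicitly. The null permutes region labels only — it does not
preserve the spatial autocorrelation of expression, so on smooth maps
this test is anti-conservative relative to a spin-style null; that is
a deliberate scope decision (no surface geometry is consumed anywhere)
and the reason the calibration tests use spatially unstructured nulls.

## Bootstrap gene z-scores

Gene significance uses a region bootstrap (default 1000 resamples):
refit on resampled regions, align each replicate's component to the
observed one, and standardize the observed weight by the per-gene
bootstrap standard deviation: $z_g = w_g / \widehat{se}_g$. Two
alignment details matter numerically:

* **sign**: each replicate is flipped to have positive inner product
  with the observed weight vector, preventing reflection artifacts
  from inflating the spread;
* **scale**: the spread is measured on the component's *covariance
  scale* (the weight vector times its pre-normalization norm
  $\lVert X^\top y\rVert$). Resampling with replacement inflates that
  norm (by roughly $\sqrt{2}$ under a null response), so re-normalizing
  every replicate to unit length would understate the per-gene spread
  and overdisperse $z$ under the null — enough to break false-discovery
  control. On the covariance scale the null $z$ distribution is close
  to standard normal.

Two-sided normal p-values are Benjamini–Hochberg adjusted across all
genes, and a gene is called significant only if it passes **both**
thresholds: $|z| > 1.96$ and $q < 0.05$. The positive and negative
significant lists are reported separately, ordered by $|z|$.

## Class profiling and gene-set tests

`regional_scores()` projects standardized expression on a weight
vector and centres the result; `class_enrichment()` compares each
cytoarchitectonic class's mean score with a null built by permuting
the region-to-class assignment. The p-value is two-sided on the
absolute class mean,
$p = (1 + \#\{|\text{null mean}| \ge |\text{observed mean}|\})/(n_{perm}+1)$,
which reaches the attainable floor $1/(n_{perm}+1)$ for a decisive
shift and exactly 1 for constant scores; direction ("over"/"under") is
taken relative to the null median. BH adjustment runs across classes.
The default map has seven classes (five cytoarchitectonic types plus
limbic and insular subtypes), but the class count is data-driven.

`overlap_test()` counts genes shared between a query list and each
marker set and compares against `n_perm` uniform draws of equally many
genes from the universe (one-sided, enrichment only); the exact
upper-tail hypergeometric probability is reported alongside, because
the resampling null *is* hypergeometric — the Monte-Carlo p converges
to it at rate $\sqrt{p(1-p)/n_{perm}}$. `ora()` is the purely exact
variant for annotation collections. The universe is the post-QC
expression matrix's gene set, not the genome: it is the frame the
permutation actually samples from.

# The synthetic generator

The generator exists because no public data pairing is shipped: it
plants a known linear signal so that every downstream stage can be
validated against ground truth.

* Expression: each gene is an independent stationary AR(1) process
  over the fixed region ordering (default $\rho = 0.3$, unit marginal
  variance). This mimics the smoothness of cortical expression maps
  well enough to stress the permutation machinery, without any surface
  geometry.
* Cohort: `n_causal` genes (default 50 of 2000) receive
  $\mathcal{N}(0,1)$ weights; the planted map $d$ is the standardized
  projection of expression on those weights; group B is thinned by
  $\text{effect} \times 0.1\,\text{mm} \times d_r$ (0.1 mm per unit
  pattern is a typical cortical-thickness effect magnitude) on top of
  i.i.d. subject noise (default 0.1 mm); group sizes default to
  100 + 40. The defaults give an unambiguous component-1 detection
  while remaining at desk scale (308 regions).
* Annotations: seven marker sets of 100 genes; the first contains half
  causal genes, the rest draw from non-causal genes; plus a balanced
  seven-class region partition.

What the generator does **not** emulate: donor-level microarray noise,
cortical geometry and its spatially correlated measurement error,
site/scanner effects, and correlated gene modules (genes are
independent given the region ordering). Passing tests therefore
demonstrate algorithmic correctness and statistical calibration on
spatially unstructured nulls — not robustness to the full messiness of
imaging-transcriptomic data.

A consequence worth stating: with $\mathcal{N}(0,1)$ causal weights,
a causal gene's correlation with the planted map scales like
$|w_g|/\sqrt{n_{causal}}$ against a sampling error of $1/\sqrt{R}$,
so at the default dimensions a sizeable fraction of causal genes are
*informationally undetectable* — any ranking, including one built from
the true noiseless map, tops out near AUROC 0.75 for causal-gene
retrieval. The significant-list *precision* stays high (the genes that
are called are overwhelmingly causal); the *recall*-side ceiling is a
property of the planted design, not of the estimator.

# Numerical choices

* Seeds: every public function taking `seed` derives independent
  sub-stream seeds per stage and restores the caller's RNG state;
  identical configuration and seed give byte-identical artifacts.
* Permutation p-values use exact `>=` comparisons and add-one
  smoothing everywhere; add-one keeps them in
  $[1/(n_{perm}+1),\, 1]$.
* Standardization uses sample variance ($n-1$); constant columns are
  dropped, not imputed.
* Degenerate bootstrap resamples (constant response) are redrawn and
  counted; rank-deficient resamples fall back to the observed weights
  and are counted the same way.
* CV ties break to fewer components (`which.min` on the error curve).
* Test and acceptance runs use reduced resampling (`profile = "test"`:
  1000 permutations, 200 bootstraps) and the problem sizes quoted in
  the test files (for example 1000 replicate null datasets of
  50 regions x 200 genes for calibration, 10 replicate studies at the
  full default 308 x 2000 for recovery); the full profile
  (10000 / 1000) is the default for analyses.

# Known limitations

* Two-group contrasts only; no covariate adjustment of thickness.
* The permutation null ignores spatial autocorrelation (no spin test);
  on strongly autocorrelated maps component significance is
  optimistic.
* Component 2 and beyond are fitted and testable but no downstream
  interpretation is built for them.
* The over-representation test is set-based only (no ontology
  structure, no inter-gene correlation correction).
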