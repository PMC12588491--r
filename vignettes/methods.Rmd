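---
title: "Generative modeling of heterogeneous multi-source health tables: models, assumptions, and design choices"
author: "HetTabGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative modeling of heterogeneous multi-source health tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Health data about a population is typically scattered across several
tables -- a clinical study, an insurance claims extract, intervention
trials -- that measure mostly disjoint sets of attributes on mostly
disjoint sets of subjects.  HetTabGen builds a single generative model of
the joint distribution over the union of attributes from such tables.  The
key obstacle is that no record observes all attributes: each source
contributes a block of columns, and everything outside a record's block is
structurally missing.  The key opportunity is that a small set of *common
attributes* (age, sex, body measurements) appears in every source.

Two variables X and Y that never co-occur in one record can still be
related statistically through common variables Z:

$$P(Y \mid X) = \int P(Y \mid Z, X)\, P(Z \mid X)\, dZ
            = \int P(Y \mid Z)\, P(Z \mid X)\, dZ,$$

where the second equality assumes conditional independence of Y and X
given Z.  This *statistical linkage* needs no shared subjects and no
identifiers; it is the assumption under which row-wise concatenation of
sources into one sparse table is a sensible training set.  The assumption
is untestable from the concatenated data itself and can fail: if X and Y
are dependent beyond what Z carries, the model cannot know.

## Typed attributes

Every attribute is declared in a schema with one of five types, each with
a parametric output distribution:

| type                  | distribution | output parameters            |
|-----------------------|--------------|------------------------------|
| `real`                | Gaussian     | mean, SD                     |
| `positive`            | log-normal   | mean, SD of the log value    |
| `count`               | Poisson      | rate $\lambda$               |
| `categorical`         | multinomial  | level probabilities          |
| `ordered_categorical` | multinomial  | level probabilities (ordered levels) |

Real attributes are standardized to zero mean and unit SD; positive
attributes are standardized on the log scale; counts are modeled on their
natural scale (the likelihood is Poisson in the raw count) with a fixed
`log1p` location/scale transform used only for input embedding; level
types are embedded through learned per-level vectors.  Standardizers are
fitted on the training split only and stored in the corpus and in every
checkpoint.  The unbiased (n − 1) SD estimator is used throughout.
Zero-variance attributes have their SD floored (default 1e-6) with a
warning.  The Jacobian of the log transform for positive attributes is a
per-record constant and is omitted from the reported loss; reported losses
for positive attributes are therefore Gaussian NLLs on the standardized
log scale.

Ordered categorical attributes are decoded with a plain softmax head; the
ordering is used in evaluation, not in the likelihood.  A cumulative-link
head would be the natural refinement but adds little at the cohort sizes
this package targets.

## Architecture

A record is a *set* of typed tokens, one per observed attribute; missing
attributes produce no token.  Each token is the sum of a learned
attribute-identity embedding and a learned value embedding (a linear map
of the standardized scalar, or a level embedding).  There are no
positional encodings -- attribute identity plays that role -- so every
operation is invariant to token order.

* **Encoder.** Pre-layer-norm attention blocks in which *only observed
  tokens act as keys*: missing attributes contribute nothing to the
  encoding of the observed ones.  A record with no observed attribute
  skips attention entirely.
* **Latent assembly.** The full-width latent sequence combines the
  transformed observed latents with a learnable per-attribute *default
  token* for each missing attribute.
* **Decoder.** Attention blocks in which every position (observed or
  missing) queries the observed latents, followed by per-attribute typed
  heads that emit the distribution parameters above.  With an empty input
  the decode is driven entirely by default tokens and yields the model's
  unconditional estimate.

### Iterative decoding with imputed-value feedback

A single decode pass is trained only on conditioning patterns that occur
under masked training.  When X and Y live in different sources, the
pattern "X observed, predict Y" never occurs, and we found experimentally
that a single pass does not reliably compose $P(Z|X)$ and $P(Y|Z)$ -- the
alignment between the internal representation of an encoded X token and
the decoder pathway trained on Z tokens is not identifiable from the
masked-modeling objective alone at realistic cohort sizes.

The default architecture (`networkConfig(passes = 2)`) therefore decodes
twice.  Pass 1 is the network above.  Pass 2 re-runs it after substituting,
for every *helper* attribute -- missing but not itself being queried -- an
*imputed value token*: the ordinary value embedding evaluated at the
pass-1 estimate (predicted mean for numeric attributes,
probability-weighted level embeddings for level types).  Because an
imputed token has byte-for-byte the same form as an observed-value token,
the conditionals learned on observed tokens transfer verbatim, and the
two-pass decode computes a plug-in form of the marginalization identity:
impute Z from X, then read Y from the imputed Z.

Two details are essential:

* **Leave-target-out.**  A queried attribute never sees its own pass-1
  estimate.  Feeding it back would let training collapse into copying the
  first-pass output, which is catastrophic exactly in the cross-source
  case where the first pass is unreliable.  During training the
  reconstruction targets are the left-out set; at inference the requested
  targets are.
* **Untrained attributes stay inert.**  The model records which
  attributes it has seen during training (`trainedAttributes`); an
  attribute added to the schema but never trained never feeds back a
  token, and (because pass-1 decoding attends only over observed tokens)
  has exactly zero influence on other attributes' outputs.

The plug-in feedback uses the conditional mean rather than a draw, so the
second pass slightly understates the extra uncertainty that latent-Z
variability contributes to cross-source conditionals; the conditional
*mean* is unaffected, which is what the linkage recovery checks measure.

Defaults are desk-scale: 32-dimensional embeddings, one encoder and one
decoder block, 4 heads, feed-forward width 64.  Published models of this
family vary parameter counts over two orders of magnitude; size is
configuration, not substance.

## Training

Training is masked modeling: within each record, every observed cell is
independently selected as a reconstruction target with probability
`maskRate` (default 0.5; at least one target per record is enforced, and a
length-2 `maskRate` range draws a per-record rate for broader
conditioning-size coverage -- an option we do not use by default, as the
fixed rate performed better on this package's own generation tasks).
Targets are hidden from the input; structurally missing cells are never
targets.  The loss is the mean per-target typed negative log-likelihood,
averaged per target (not per record) so that densely observed records do
not dominate; with two-pass decoding both passes are supervised with equal
weight.

The schedule has two stages: the model is first trained on each source
separately (one shared network, sequential passes over the sources), then
fine-tuned on the combined corpus.  The optimizer is Adam with cosine
decay to 5% of the peak rate, global gradient-norm clipping (5), and
decoupled weight decay (1e-3) on weight matrices and embeddings only.
Training refuses any corpus containing records flagged as holdout.

Stage-1 source order, epochs per stage, and the use of one shared network
across sources are not externally prescribed; the package fixes them as
configuration (`trainingConfig`), with sources visited in corpus order.

## The cohort simulator and its oracle

Every quantitative claim in the test suite is checked against simulated
cohorts with known ground truth.  Subjects draw a latent
$z \sim N(0, I_k)$; each attribute applies its link to a linear score
$w^\top z + b$ plus Gaussian noise: identity (real), exponential
(positive), Poisson with log link (count), thresholds on a noisy index
(ordered), softmax over per-level scores (categorical).  Source blocks and
per-attribute MCAR missingness are applied afterwards, emulating the
block-missing structure of concatenated multi-source data.  The dominant
missingness in that setting is structural (whole blocks), which the
concatenation step produces; the MCAR component models within-block
gaps.

The paired oracle evaluates true conditionals: exactly for all-real
queries (jointly Gaussian), otherwise by self-normalized importance
sampling over the latent with closed-form per-type conditional likelihoods
(Gauss-Hermite quadrature absorbs score noise for counts), reporting a
Monte-Carlo standard error and refusing queries whose effective sample
size collapses.  A separate discrete X→Z→Y chain oracle, exact by
enumeration over its eight outcomes, pins the marginalization identity
itself (e.g. P(Z=1|X=1)=0.8, P(Y=1|Z=1)=0.9, P(Y=1|Z=0)=0.2 gives
P(Y=1|X=1)=0.76).

The simulator reproduces the *structural* properties of multi-source
health data -- mixed types, block missingness, common linking attributes,
latent dependence -- not the clinical marginals of any real cohort.
Passing tests therefore demonstrate that the machinery recovers known
joint structure under its own assumptions (linear latent factors,
MCAR-within-block missingness); they do not certify performance on real
data, where missingness can be informative and dependence non-linear in
ways the latent-factor family only partially spans (the test suite does
include one deliberately non-linear cohort, $y = x^2 + \varepsilon$).

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` use fixed desk-scale conditions,
chosen once as representative rather than tuned: linkage sources of 2,500
records each with loading 0.85 on a shared factor; a bivariate Gaussian
cohort of 4,000 records with correlation 0.8; a 12-attribute two-source
cohort of 2,000 records per source with 5% within-block missingness and a
10% sex-by-age-decade stratified holdout; a 10-attribute regression cohort
of 3,000 records with 3,000 synthetic records for the machine-learning
efficiency comparison (mirroring the published protocol's use of a
synthetic sample comparable to or larger than the original, with
gradient-boosted trees as the fixed regressor and an R² readout on a real
held-out quarter).  Network sizes are the defaults above; training runs
20-80 epochs depending on the cohort.

## Evaluation framework

* **Imputation error.**  For each target attribute, holdout records with
  the target observed are imputed from the top-10 predictors ranked by the
  model itself (mean NLL reduction when a single candidate is observed),
  using the *mode* of the estimated distribution as the point estimate:
  the de-standardized mean for real, $\exp(\mu - \sigma^2)$ for positive,
  $\lfloor \lambda \rfloor$ for count, the argmax level otherwise.
  Numeric errors are |imputed − true| divided by the training-set SD on
  the natural scale; level types report accuracy macro-averaged over the
  levels present.  Mean imputation (real, positive) and mode imputation
  (count, categorical, ordered) provide the baselines.
* **Univariate fidelity.**  Overlap area of normalized histograms over
  shared bin edges (Freedman-Diaconis bins by default; levels as bins for
  level types): $\sum_i \min(p_i, q_i) \in [0, 1]$.
* **Bivariate fidelity.**  For pre-selected pairs (X, Y), X is split into
  equal-frequency bins (bins under 20 records are excluded); within each
  bin the reference Y values are compared, via the overlap above, with
  model draws of Y conditioned on the bin median of X; the pair metric is
  the bin-weighted mean.  This detects non-linear structure a covariance
  summary misses.
* **Scenario checks.**  Personas (named observed-value maps) are imputed
  and expected inequalities between modes are verified, reporting both
  direction and magnitude.
* **External concordance.**  The model-sample mean is treated as a sample
  mean and scored as $z = (\bar{x} - \mu_{ext}) / \sigma_{ext}$ against a
  user-supplied external summary; distributional similarity is the
  closed-form overlap area of the two fitted normal densities (computed
  from the density intersection points; verified against numerical
  integration).  The external SD (not the standard error) is the
  denominator, matching the scale on which such comparisons are reported.
* **Machine-learning efficiency.**  The same gradient-boosted-tree
  regressor (xgboost, single-threaded for exact reproducibility) is
  fitted on real training rows, on synthetic rows only, and on their
  union, and all three are scored by R² on a held-out real test split.

## Numerical choices and degenerate inputs

Likelihood heads clamp log-SD to [−6, 6] and log-rate to [−15, 15];
probability vectors are exact softmax outputs and sum to one within
1e-6.  Poisson modes tie-break upward (an integer rate is its own mode);
categorical argmax ties resolve to the lowest level index.  Empty records
are valid at inference (unconditional estimates) and skipped with a log
entry during training.  Up-sampling in record adjustment is uniform with
replacement; down-sampling is without replacement; neither fabricates
values.  Sequential generation draws one seeded random attribute order per
call and applies it to all records, which vectorizes the pass over
records; order effects average out over draws and the documented
dependency checks (pairwise correlation recovery, marginal overlap) are
insensitive to this choice.  What-if output always carries an explicit
disclaimer that the contrast is associative, not causal.

## Known limitations

* Statistical linkage inherits the conditional-independence assumption;
  violations are invisible to the model and to the holdout benchmark.
* The two-pass feedback uses plug-in conditional means; cross-source
  conditional *variances* are mildly understated.
* The simulator's ground truth is a linear latent-factor family; real
  cohorts with informative missingness or heavy-tailed marginals are
  outside what the included checks certify.
* Ordered categories are modeled without a cumulative link, which wastes
  ordering information in the likelihood.
* The attribute screen's nominal-pair association (Cramér's V on
  quartile-discretized partners) is a pragmatic stand-in for a dedicated
  mixed-type correlation coefficient.
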