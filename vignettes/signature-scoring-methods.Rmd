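---
title: "Single-sample signature scoring: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample signature scoring: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscore)
```

## The problem

A gene signature condenses a transcriptomic phenotype — immune infiltration,
proliferation, stromal content, metastatic risk — into a set of genes,
sometimes directional (up/down lists) and sometimes with fitted per-gene
coefficients. Scoring a signature *per sample* turns a genes × samples
expression matrix into one number per sample per signature, a major
dimensionality reduction that makes downstream visualization and modelling
tractable. `sigscore` implements the common scoring procedures behind one
tidy interface: every scorer takes the expression data first and returns a
tibble with one row per sample.

All methods assume the input is **already normalized**, on a roughly
continuous log-like scale (log-intensities or log-counts). No normalization,
batch correction or identifier conversion is attempted; gene symbols are
matched case-sensitively after whitespace trimming, on the assumption that
both the matrix and the signatures use official HUGO symbols.

## Input validation

`as_expr_matrix()` establishes the invariants every engine relies on: unique
gene symbols, unique sample identifiers, finite values.

* Rows containing any missing or non-finite value are **dropped** (with a
  message). Imputation is out of scope: the rank-based methods would be
  distorted by imputed values in ways that are hard to reason about.
* Duplicate gene symbols are collapsed by keeping the row with the **highest
  mean expression** — the common probe-collapse convention. A mean-aggregate
  alternative was rejected because averaging rows changes within-sample rank
  semantics, while keeping one observed row does not.
* Validation is idempotent and order-preserving, so validated matrices can be
  passed around freely.

## The three enrichment engines

### Combined z-score

Each gene is standardized across the cohort with the sample standard
deviation (divisor *n* − 1); sample *j* scores set *S* as
$\sum_{g \in S} z_{gj} / \sqrt{|S|}$. Under an independence null each score
is approximately standard normal, which is what makes the $\sqrt{|S|}$
scaling natural. Two numerical choices matter:

* **Zero-variance genes** (constant housekeeping rows, all-zero features)
  get $z = 0$ with a warning rather than erroring, so one flat row cannot
  kill a cohort run.
* The score is cohort-dependent: adding samples changes per-gene means and
  standard deviations, hence all scores. It is, however, invariant to adding
  a constant to the whole matrix.

### ssGSEA

Within each sample, genes are ranked ascending (1 = lowest of *N*) and
walked in decreasing-rank order. The in-set empirical CDF accumulates weight
$r_g^\alpha$ normalized by the total in-set weight; the out-set CDF is
uniform over the $N - |S|$ non-members. The enrichment score is the sum of
the difference over all *N* walk positions. Parameters:

* `alpha` (default **0.25**): the rank-weighting exponent. 0 weights all set
  genes equally; larger values emphasize extreme-rank genes. Ranks (1..N)
  are used as weights rather than expression values, the standard
  single-sample variant, which makes the raw score invariant under any
  strictly monotone per-sample transform.
* `norm` (default **raw**): `"separate"` divides each signature's column by
  its own score range, `"all"` by the global range across every requested
  signature. Either makes scores depend on the cohort *and* on which other
  signatures were requested in the same call — documented loudly, and the
  reason raw is the default. A zero range (degenerate cohort) is an error
  naming the offending signature rather than a silent division by zero.
* `tie_rule` (default **average**): average ranks keep the rank-sum
  invariant $\sum r = N(N+1)/2$; `min`/`max` are offered for compatibility
  studies. With tied weights the walk order among tied genes follows row
  order, which only matters for tied data.

A set covering *every* gene of the matrix leaves no out-set and is an error;
a set with no genes present yields an explicit `NA` column with a warning —
never a silent zero.

### singscore

The up-score is the mean rank of the up genes, rescaled onto [0, 1] by its
attainable extremes $r_{min} = (n+1)/2$ and $r_{max} = (2N-n+1)/2$. Down
sets are scored identically on reversed ranks $N + 1 - r$, and a
bidirectional total is the sum of the two. `center = TRUE` (default, the
cited procedure's default) shifts each directional score by −0.5 so that
"no enrichment" sits at zero. Undirected sets are treated as up sets by
default (`undirected = "raw_rank"`); the `"abs_median_centered"` option
instead ranks $|x - \mathrm{median}(x)|$ within the sample, rewarding genes
extreme in either direction. A set spanning all genes makes
$r_{max} = r_{min}$ and is an error.

### Original-method archetypes

Most published recipes reduce to one of two archetypes, which
`score_original()` evaluates: the arithmetic **mean** of signature-gene
expression, or a **weighted sum** $\sum_g c_g x_{gj}$ against published
coefficients. Weighted signatures must carry a coefficient for every gene;
terms whose gene is absent from the matrix are dropped with a warning
(coverage auditing is `check_sig()`'s job, scoring does not duplicate it).

## Dispatch

`sig_score()` routes: registry keyword selections default to each
signature's original procedure (signatures flagged for dedicated scorers are
excluded with a pointer); `method = "zscore" / "ssgsea" / "singscore"`
forces one engine for everything selected; custom gene-set lists default to
**raw ssGSEA** and reject `method = "original"`, since no original recipe
exists for an arbitrary user set. Dispatch adds nothing numerically — it is
tested to agree exactly with calling the engines directly.

## Dedicated scorers

**ESTIMATE-style** (`score_estimate()`): immune and stromal sets scored with
raw ssGSEA at α = 0.25; their sum is the combined score; purity is
$\cos(a + b \cdot \mathrm{estimate})$ with the published coefficients
$(a, b) = (0.6049872018, 0.0001467884)$ shipped as an editable config file
with its source DOI. The cosine is only monotone decreasing while its
argument stays in $[0, \pi]$; samples outside that branch get `NA` purity
with a warning, and values are clamped to [0, 1].

**CINSARC-style** (`classify_cinsarc()`): genes standardized across the
cohort, then each sample is classified by leave-one-out nearest centroid —
the held-out sample is removed from its own class's centroid — with
Euclidean distance in the standardized space (1 − Pearson correlation
available via `metric`). C1 is the strictly-closer-to-no-metastasis call;
ties go to C2, the conservative high-risk call. Standardization is computed
once on the full cohort by default; `restandardize = TRUE` redoes it within
every fold. The global default is simpler and keeps the fold geometry
comparable across samples; the flag exists because the choice is genuinely
open.

**Immunophenoscore-style** (`score_ips()`): per-gene cohort z-scores, marker
scores as the mean z of the marker's genes, category scores (MHC, EC, SC,
CP) as the weighted mean of marker scores. With signed weights a plain
$\sum w s / \sum w$ is ill-defined (the denominator can vanish), so the
category score is $\sum w s / \sum |w|$ — negative-weight suppressor and
checkpoint markers pull the category down, and the magnitude stays on the
marker-score scale. The aggregate `az` is the sum of the four categories;
`ips` is 0 for `az` ≤ 0 and otherwise `min(10, round(az * 10/3))`, rounding
half away from zero (the rounding convention is not fixed by the cited
procedure's description, so it is pinned and documented here).

### Bundled reference tables

The purity coefficients are the published values. The 141-gene
immune/stromal lists, the 67-gene sarcoma signature and the immunophenogram
marker memberships are **not** bundled verbatim: transcribing them reliably
is an implementer task against the cited sources, and mis-transcription
would be worse than absence. The shipped files are synthetic demonstration
stand-ins — named and described as such — with the same structure and
biological intent, and every scorer accepts user-supplied gene lists or
marker tables so the published tables drop in unchanged.

## Parallelism

`workers > 1` forks the per-sample loop with `parallel::mclapply`. Chunks
are contiguous sample blocks reassembled in order, and no scoring path uses
random numbers, so results are bit-identical for any worker count — the
tests assert `identical()`, not near-equality.

## The synthetic cohort generators

`simulate_spike_cohort()` draws i.i.d. Gaussian baseline expression
(mean 6, sd 1 — a log2-like scale typical of normalized arrays) and shifts
the designated set genes upward by `effect_size` sd units in a spiked sample
group. `simulate_two_classes()` separates two Gaussian clusters by `delta`
sd per gene. All randomness flows from the `seed` argument through a local
RNG that leaves the caller's state untouched; identical seeds give
bit-identical cohorts.

These generators emulate exactly what the engines assume — continuous,
roughly symmetric, independent normalized expression — and deliberately not
what real data adds on top: gene–gene correlation, heavy tails,
count-scale mean–variance coupling, batch structure. Passing tests
therefore demonstrate correctness of the *statistics* (oracle agreement,
closed forms, invariances, signal recovery under the stated model), not
robustness to real-data pathologies. Default validation sizes (cohorts of
100–2000 genes, 20–50 samples, 20–200 random oracle instances) were chosen
as the smallest scales at which the properties under test are
non-trivially exercised.

## Known limitations

* No permutation-based p-values for enrichment scores, and no
  Kolmogorov-style kernel method: the three engines here are alternatives
  to, not a superset of, that family.
* Keyword matching is substring-based and case-insensitive (an exact-match
  flag exists); with a large registry, short keywords may over-match.
* The combined z-score and the IPS z-step are cohort-dependent by
  construction; single-sample use requires a reference cohort.
* Scores from `norm = "separate"`/`"all"` ssGSEA are not comparable across
  cohorts or across differently composed signature requests.
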