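---
title: "Ranking chemical health hazards with the Mahalanobis–Taguchi System"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking chemical health hazards with the Mahalanobis–Taguchi System}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtshazard)
```

## The model

The Mahalanobis–Taguchi System (MTS) measures how abnormal an item is
relative to a reference group of normal items, the *unit space* (or
Mahalanobis space). Applied to chemical screening, "normal" means
*low-hazard*: every chemical poses some hazard, so hazard must be judged
relatively, as distance from the least hazardous chemicals rather than
against an absolute standard.

Each chemical is described by ten GHS health-hazard endpoints. Ordered
categories are quantified as points:

| Category | 1 | 2 | 3 | 4 | 5 | Not Classified | Classification Not Possible | Not Applicable |
|---|---|---|---|---|---|---|---|---|
| Score | 100 | 50 | 100/3 | 25 | 20 | 10 | 30 | 1 |

Category *n* scores 100/*n*, so severity decays harmonically. Not
Classified (positive evidence of no hazard) sits below Category 5.
Classification Not Possible — no data, which is *not* evidence of safety —
is deliberately placed near Category 3: scoring missing data near
Category 2 would overweight ignorance, scoring it near Not Classified would
equate ignorance with demonstrated safety. All eight scores are
user-overridable through `quantification_scheme()`, because the final
ranking is sensitive to this choice (see Limitations).

The unit space is built from chemicals with zero Category 1, zero
Category 2 classifications and a quantified total of at most 280 points
(`selection_criteria()`; both the ceiling and its inclusivity are
arguments — one source prints the criterion as "< 280", the accompanying
prose as "280 or less", and we default to the inclusive reading). From the
members' score vectors we take per-endpoint means $\bar x_i$ and standard
deviations $s_i$ (with the $n-1$ divisor) and the sample correlation matrix
$R$. A chemical with scores $x$ is then ranked by the scaled Mahalanobis
distance

$$\mathrm{MD}(x) \;=\; \frac{1}{k}\, z^\top R^{-1} z,
\qquad z_i = \frac{x_i - \bar x_i}{s_i},$$

over the $k$ non-degenerate endpoints. This is the canonical Taguchi form;
dividing by $k$ makes distances comparable across variable counts and gives
the exact closed form that the mean MD over the fitting members equals
$(n-1)/n$ — a property the test suite asserts to $10^{-8}$, and a useful
health check on any fitted reference. The scaling is switchable
(`scale_by_k = FALSE`) since conventions differ between software packages;
with correlation-based standardization the unscaled form equals the classic
covariance-based Mahalanobis distance.

### Assumptions

The distance treats the unit-space members as draws from a common
multivariate distribution summarized by its first two moments. The score
scale is ordinal-made-numeric: MD inherits whatever distortions the
quantification imposes. The correlation matrix is estimated, not assumed
known, hence the requirement of at least $k + 2$ members (fewer guarantees
a singular matrix, and `select_normal_group()` refuses to proceed).

## Numerical choices

* **Singularity.** If the smallest eigenvalue of $R$ falls below
  $10^{-10}$ times the largest, the Moore–Penrose pseudoinverse replaces
  the plain inverse. Endpoints with zero variance among members are
  excluded from $z$ and $k$ entirely (with a warning) rather than
  epsilon-inflated, because inflation silently distorts every distance.
* **Aggregation order.** The three inhalation routes merge to the *most
  conservative* value. The conservativeness order is defined as descending
  quantification score — Category 1 > 2 > 3 > Classification Not Possible
  > Category 4 > 5 > Not Classified > Not Applicable — so the order where
  missing information ranks among the numbered categories follows directly
  from the 30-point choice above, and a user who overrides the scheme gets
  a consistently re-ordered merge.
* **Missing cells** in input CSVs become Classification Not Possible with
  a warning, matching the semantics of "insufficient information".
  Sub-categories 1A/1B (mutagenicity, carcinogenicity, reproductive
  toxicity) normalize to Category 1, which is how the GHS treats their
  severity and the only Category-1 score the quantification defines.
* **Ties in ranking** use competition ranks (equal MD, equal rank, next
  rank skipped): reproducible and conventional.
* **Determinism.** Nothing in the scoring path is randomized; results are
  reproducible given the same input content regardless of row order.

## Grading

Distances are partitioned into $k = 4$ ordered grades (grade 4 = most
hazardous) by four class-interval methods. Throughout, intervals are
half-open $[\mathrm{low}, \mathrm{high})$ with the final class closed, and
a value exactly on a break goes to the upper class.

* `classify_equal_interval()`: breaks at $\min + i(\max-\min)/k$.
* `classify_quantile()`: class occupancies as equal as possible. Cut
  candidates are type-1 (inverse empirical CDF) quantiles at $i/k$; each
  break is then placed at the smallest data value *strictly above* its
  quantile. This keeps the global boundary rule, balances classes exactly
  on tie-free data, and never splits tied values across classes. With
  $k = 4$ this is quartile classification.
* `classify_jenks()`: exact Fisher–Jenks dynamic program minimizing the
  total within-class sum of squared deviations from class means, run on
  weighted unique values (ties are atomic). The test suite verifies
  optimality against exhaustive enumeration.
* `classify_geometric_interval()`: the method name circulates in GIS
  practice without a canonical definition, so we implement the
  transparent multiplicative rule — breaks at
  $\min \cdot (\max/\min)^{i/k}$, i.e. log-equal spacing — with a shift by
  $1 - \min$ when the minimum is non-positive. This suits the strongly
  right-skewed MD distributions the pipeline produces. It is an
  approximation to any particular GIS product's variant; the strategy is
  isolated in one function and easily swapped.

Equal-interval, quantile and Jenks grades are invariant under positive
affine transforms of the scores; geometric intervals are not (they are
scale- but not shift-invariant), which is inherent to the method.

## Agreement and validation

External CRS scores are opaque numeric columns — this package never
recomputes other methods' scores. Raw-score agreement uses Pearson
correlation with a two-sided $t$ test ($n-2$ df, no multiple-testing
correction). Grade agreement uses Cohen's kappa in the disagreement-weight
form
$$\kappa_w = 1 - \frac{\sum w_{ij} o_{ij}}{\sum w_{ij} e_{ij}},
\qquad w_{ij} = \left(\frac{|i-j|}{k-1}\right)^p,$$
with $p = 1$ (linear), $p = 2$ (quadratic), or 0/1 off-diagonal weights
(unweighted); one code path covers all three. Weighted kappa often grows
with the weighting degree on near-monotone disagreement patterns, but this
is a tendency, not a theorem, and the tests treat it accordingly.

Validation against a regulatory list reports the fraction of regulated
chemicals reaching grades 3–4 (true positives) and of non-regulated
chemicals doing so (false positives). Group summaries use Student-$t$
confidence intervals because regulatory categories can be tiny (three to
five chemicals), where normal quantiles would be misleadingly narrow;
singleton groups report a mean with an explicitly undefined interval.

## The synthetic generator

`simulate_ghs()` draws a zero-mean Gaussian latent severity vector per
chemical with a target correlation matrix (Cholesky factorization, checked
for positive semi-definiteness), discretizes each endpoint through
ascending thresholds into exactly the categories defined for that endpoint,
then independently masks cells to Classification Not Possible (default
probability 0.15, mimicking the pervasive data gaps of curated GHS tables)
or Not Applicable (0.05). Planted hazards are forced to Category 1 on six
to eight randomly chosen endpoints.

Default marginal thresholds put roughly 5% of background cells in
Categories 1–2, which leaves a usable low-hazard normal group after
selection; the default latent correlations mirror the strong empirical
endpoint associations of real GHS data (skin/eye 0.70, oral/dermal 0.60,
the two STOT endpoints 0.53, weaker links among acute routes and CMR
endpoints).

What the generator deliberately does *not* emulate: real category
*marginals* per endpoint (real tables are far more Classification Not
Possible-heavy and endpoint-specific), non-Gaussian dependence (tail
dependence between severe classifications), and the fact that real
missingness is informative rather than independent. Passing pipeline tests
on synthetic data therefore demonstrates the *mechanics* — selection,
estimation, distance, grading, agreement — not that the ranking is valid
for any particular real inventory. Two masking-related consequences are
worth knowing: independent masking attenuates between-endpoint score
correlations (a latent correlation of 0.8 between skin and eye irritation
survives discretization well above 0.4 with masking off, and is attenuated
further once masking is added), and masking has two opposing effects on the normal group — it
inflates totals (Classification Not Possible is 30 points vs 10 for Not
Classified), shrinking the group once totals approach the 280-point
ceiling, but it also hides Category 1/2 classifications, which grows the
group at low masking rates.

Problem sizes in the test suite were chosen to exercise each property at
the smallest scale where it is statistically unambiguous: closed-form and
oracle checks run on instances of dimension ≤ 3, distributional properties
of the generator at n = 5000, replicate-based separation checks at 20–25
seeds of a few hundred chemicals, and the end-to-end run at n = 3000 with
10 planted hazards.

## Known limitations

* The ranking depends on the quantification. Changing the Classification
  Not Possible score in particular reshuffles chemicals with sparse data;
  every constant is overridable precisely so such sensitivity analyses are
  one config edit.
* MD magnitudes are not comparable across different unit spaces: the unit
  space defines the scale. Compare rankings, not raw distances, between
  datasets.
* Variable selection (orthogonal arrays, signal-to-noise ratios — the
  second half of the classic MTS workflow) is out of scope; all ten
  endpoints always contribute.
* The geometric-interval rule is one defensible reading of an
  under-specified method name; grade boundaries from other software will
  differ.
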