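---
title: "Methods: haplotype diversity, probabilistic identification and spatial structure of barcode reference libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, probabilistic identification and spatial structure of barcode reference libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelib)
```

`barcodelib` implements the analytical pipeline used to audit large,
taxonomically curated COI barcode reference libraries: how much haplotype
diversity the library has captured, how reliably it identifies specimens,
how mitochondrial diversity is structured in space, and which taxa deserve
taxonomic attention. Every stage can be exercised on seeded synthetic
libraries, so the whole pipeline is testable without any external data.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic data can and cannot show.

## The reference library

A library is a set of specimens, each carrying an aligned COI barcode in a
fixed `L = 658`-column frame over the alphabet A/C/G/T/N/-, a 4-level
taxonomy path (family, subfamily, genus, species; species may be empty for
specimens identified only to genus), and decimal-degree coordinates.
Sequences enter the library only with at least 600 unambiguous (A/C/G/T)
positions; we interpret the inclusion rule this way, rather than as raw
length, so that N-padded records cannot qualify. The alphabet is
deliberately restricted: how ambiguity codes beyond N should be treated is
genuinely open, and we chose not to guess — inputs carrying IUPAC
ambiguity codes must be recoded to N upstream.

Sequences are assumed pre-aligned (trimmed barcodes in a common frame); no
aligner is bundled because none of the downstream statistics require one.

## Haplotype diversity and sampling completeness

Within a species, two sequences share a haplotype when they agree at every
position where both are unambiguous, and haplotypes are the transitive
closure of that relation. The closure means an N-rich sequence can merge
two otherwise distinct haplotypes; this matches common barcode practice
but is not the only defensible convention, so a strict mode (exact
full-frame equality, `strict = TRUE`) is available and used nowhere by
default.

Expected richness in a subsample of `m` specimens uses the analytic
hypergeometric form
$$S(m) = \sum_i \left[1 - \binom{n - x_i}{m}\Big/\binom{n}{m}\right],$$
the asymptote is the bias-corrected Chao1 estimator
$$\hat S = S_{obs} + \frac{n-1}{n}\frac{f_1(f_1-1)}{2(f_2+1)},$$
and extrapolation beyond `n` follows the matching sampling-theory curve
with $\hat f_0 = \hat S - S_{obs}$. Completeness is $S_{obs}/\hat S$,
summarised over species with at least six specimens. The bias-corrected
Chao1 form is the default of the standard
rarefaction/extrapolation framework; it is defined (and equal to
$S_{obs}$) even when no doubletons exist.

Octave profiles bin haplotype abundances into the eight log2 classes 1,
2–3, 4–7, …, 128–255. Abundances of 256 or more are clamped into the top
class with a warning instead of opening a ninth class: the profile is a
fixed-width summary and real libraries rarely exceed the top class.

## Distance audits

All distances are uncorrected p-distances with pairwise deletion: sites
where either sequence is ambiguous are dropped, and a pair is valid only
when at least 300 sites (half the barcode; configurable) remain. On the
658-site frame, 4 substitutions correspond to p = 0.61%, the
nearest-neighbour threshold used by the audit flags. Per species we report
mean and maximum intraspecific distance and the nearest-neighbour
distance (minimum over all cross-species pairs; ties list every
neighbour). Audit flags are strict inequalities: deep split when
`max_intra > 2.5%`, low divergence when `0 < nn_dist < 0.61%`, shared
when `nn_dist = 0`.

Barcode-sharing cases are the connected components of the species graph
whose edges are zero-distance cross-species pairs; component sizes give
the pairs/triplets/... accounting. Whether a case is operational
(unresolved taxonomy) or biological (introgression) is an expert
annotation the user supplies, never inferred.

The full pairwise matrix is computed by base-indicator cross-products
(five matrix products), not per-pair loops; results are identical to the
per-pair definition, which the tests verify.

## Probabilistic identification

The classifier walks the taxonomy root → family → subfamily → genus →
species. At each node the probability mass is split over candidate
children by a multinomial regression on two predictors per child: the
minimum and the average p-distance from the query to the child's
reference sequences, standardised to zero mean and unit variance over the
training predictors of that level. One weight vector
$(\beta_0, \beta_{min}, \beta_{avg})$ is shared across all nodes of a
level — a taxon-generic model that stays identifiable at modest library
sizes. There is no "unknown species" slack class: the taxonomy is closed.
Because the average distance enters alongside the minimum, the classifier
is sensitive to haplotype frequency: a species whose references are
mostly far from the query scores worse than one merely touched by a
single shared haplotype, which is what keeps rare introgression from
collapsing identification.

Training maximises, by MCMC, the posterior of each level's weights over
leave-one-out records: every reference sequence, at every level of its
true path, with itself removed from all reference sets. Priors are
zero-mean Gaussians with sd 100 — effectively flat against standardised
predictors. Records whose true child has no remaining references
(singleton species) contribute a fixed log-likelihood floor of −30 so
they cannot dominate training; their count is reported.

Each level runs one random-walk Metropolis chain: 1000 adaptation
iterations in which the proposal scale follows a Robbins–Monro update
$s \leftarrow s\,\exp\{\gamma_t(\text{acc}_t - 0.44)\}$ toward the 0.44
target acceptance, then 1000 iterations with the proposal frozen. We use
a polynomially decaying gain $\gamma_t = t^{-0.6}$ rather than $1/t$: the
harmonic gain freezes the scale within a few dozen iterations, before a
badly initialised scale can recover, while $t^{-0.6}$ still satisfies the
usual diminishing-adaptation conditions. The point estimate is the
maximum-a-posteriori sample of the fixed-proposal half; MAP ties keep the
first sample reached, and the top species in reports breaks probability
ties lexicographically. Classification is exhaustive over all branches —
no beam pruning — so path probabilities are exact under the model, sum to
one at every node with candidates, and decay monotonically along paths.
Under leave-one-out, a singleton species is unreachable and its correct
probability is exactly zero, which is how such species appear in
real-library audits as well.

## Spatial structure

Belts are an overlapping sliding window: centers every 0.5°, each belt
collecting specimens within ±1° (closed boundary). Within a belt, a
species with at least six specimens is scored twice: (i) its
rarefaction–extrapolation curve evaluated at its maximum belt sample size
across all belts, and (ii) the analytic expected rarefied richness at its
minimum qualifying belt sample size. For (ii) we deliberately use the
expectation rather than one random subsample — it equals the mean of the
draw-based procedure, is deterministic, and removes one seed from the
pipeline. Belt summaries average over species; belts with no qualifying
species are dropped, which is why the realised belt count is smaller than
the nominal grid.

The trend model is an additive mixed model: richness against a penalized
spline of the belt center (basis dimension 10, shrunk when fewer belts
are available), the mean conspecific great-circle distance (haversine,
sphere radius 6371 km) as a parametric covariate, a species random
intercept, and a continuous-AR1 (exponential) residual correlation along
the axis. The response can alternatively be per-belt means
(`per_belt = TRUE`); per species-belt records with a random intercept is
the default because it uses the data at their native resolution. The
exponential correlation is a choice — the requirement is only that
spatial autocorrelation be controlled — and the distance covariate is the
guard against mistaking sampling spread for diversity. Visual trend
inspection uses loess with span 0.4 (tricube-weighted local quadratics,
exact "direct" surface) and a ±1.96 SE band.

Spatial thinning (`spatial_subsample`) caps specimens per cell of a
configurable grid (defaults: 1° cells, cap 10) with a seeded draw; the
exact cell size and cap behind "homogeneous subsampling" of real
libraries is rarely stated, so both are parameters rather than constants.

## Comparative analysis

The comparative module asks whether range size explains haplotype
richness beyond sampling effort. Observed and estimated richness, range
size and specimen count all enter log-transformed. The model is GLS with
residual covariance $\sigma^2 V_\lambda$, where $V$ is the Brownian
covariance of the species tree and $V_\lambda$ multiplies off-diagonals
by Pagel's $\lambda \in [0,1]$. $\lambda$ is profiled on a 101-point grid
with golden-section refinement — deterministic and robust for a
one-dimensional, often flat likelihood. At $\hat\lambda$: coefficients by
GLS, standard errors from $RSS/(n-k)$, two-sided t tests on $n-k$
degrees of freedom. Because R² conventions differ under GLS, both the
whitened-scale R² (against the GLS intercept-only model) and the raw-scale
R² are reported, labelled. AICc counts the coefficients plus $\sigma^2$
and $\lambda$; model comparisons flag a difference only above 2 AICc
units (strictly), and AICc is reported as `NA` when `n ≤ k + 1` leaves
the correction undefined. With $\lambda = 0$ the fit reduces exactly to
(variance-weighted) OLS, which the tests assert to 1e-8, and the
implementation is cross-checked against an independent GLS/corPagel fit.

## The synthetic-data generator

`generate_dataset()` emulates the statistical shape of a curated
continental library, with every draw determined by one seed:

* **Taxonomy and tree** — a balanced 4-level taxonomy (defaults
  3 × 2 × 3 × 3 = 54 species) and the matching ultrametric cladogram with
  unit branch per rank. The tree carries only the covariance structure
  PGLS needs; it is not a coalescent simulation.
* **Sequences** — one random ancestral barcode per genus; each congeneric
  species mutates its own private block of `species_divergence = 10`
  sites, so congeners differ by at least 20 substitutions (~3%) and
  different genera by far more. Haplotype `k` of a species adds one
  private substitution plus `floor((k-1)/4)` shared "depth" substitutions,
  so rare haplotypes sit further from the core; this yields mean
  intraspecific distances near 0.5% and maxima above 2.5% only in
  haplotype-rich species. Substitutions are uniform (Jukes–Cantor-like),
  with no indels, because p-distance analyses ignore them.
* **Abundances** — haplotype `k` is sampled with geometric weight
  `shape^(k-1)`. The defaults `shape = 0.9`, mean true richness
  `30 · range^0.125` (log-normal spread 0.5), were fixed once so the
  generated cohorts show the two abundance features real libraries show
  together: the singleton octave is modal, and mean sampling completeness
  sits well below one (≈0.76–0.80 at the default effort). A steeper
  geometric law cannot do this: it is scale-free across log2 octaves
  (about one haplotype per octave), so singletons stop dominating. The
  geometric law was chosen for its one-parameter tractability; its rare
  tail is still shorter than the near-log-series tail of real COI data,
  so synthetic completeness is higher than the ~62% real libraries
  report. Passing tests therefore validate the estimators, not that
  number.
* **Effort and geography** — range sizes are log-uniform over 10–10⁴
  occupied cells; specimen counts follow `1.7 · range^0.5` with
  log-normal effort noise (sd 0.4), giving ≈48 specimens per species on
  average and keeping effort correlated with, but not determined by,
  range — without the noise the two predictors of the comparative module
  would be exactly collinear. Each species occupies a latitudinal
  interval whose width grows with range.
* **Gradient** — with a configured gradient (default peak 42.5°, sd 5,
  base 0.2), the number of haplotypes locally available at latitude x
  scales with a Gaussian bump, so belt analyses see richer southern
  assemblages. The acceptance cohorts sharpen this to sd 2.5 over a
  35–50° extent with 21 species × 100 specimens — the smallest
  configuration at which overlapping belts reliably hold six specimens
  per species.
* **Introgression** — a configured pair plants `n` exact copies of the
  donor's most common haplotype into the recipient (and pins one donor
  specimen to it, so the shared barcode exists on both sides).

What the generator does **not** model: demography and coalescence,
recombination, selection (including endosymbiont sweeps), alignment
error, geographic clines within species other than the richness gradient,
and the long abundance tail noted above. Results on synthetic data
validate the estimators and the pipeline's wiring under known truth; they
do not reproduce the real library's headline values.

## Problem sizes and determinism

The shipped analyses and tests run at desk scale, chosen as the smallest
cohorts with comfortable statistical margins: the default 54-species
library (~2600–3900 specimens) for diversity/distance/identification
stages; 32 species × 20 specimens for classifier validation; 21 species
× 100 specimens × 20 seeds for gradient recovery; n = 200 tips × 20
seeds for coefficient recovery in PGLS. All randomness flows from
explicit integer seeds; rerunning any stage with the same seed reproduces
its outputs byte for byte.

## Known limitations

* Completeness estimates inherit Chao1's lower-bound character: with
  long-tailed abundance distributions the true haplotype count is
  underestimated, so "completeness" is an optimistic fraction.
* The transitive-closure haplotype rule can chain distinct haplotypes
  through low-quality sequences; use strict mode when data quality is
  poor.
* One weight vector per level assumes distance predictors behave
  comparably across taxa of a rank; strongly heterogeneous rates would
  argue for per-node weights, at the cost of identifiability.
* The expected-value standardisation of belt richness (method ii) is not
  exactly invariant to total sample size at fixed composition — the
  hypergeometric expectation approaches its multinomial limit as samples
  grow, and the tests check that convergence rather than strict
  invariance.
* The form of the additive trend model (which correlation structure,
  which response resolution) is a modelling choice; both response modes
  are exposed, and conclusions should be checked under both.
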