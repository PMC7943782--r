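# barcodelib

Auditing tools for curated DNA-barcode (COI) reference libraries of the
kind assembled for continental faunas — thousands of specimens, hundreds
of species, a 4-level taxonomy. Given aligned barcodes, specimen
metadata, a species phylogeny and range sizes, the package answers four
questions such libraries raise:

1. **How much haplotype diversity has been captured?** Sequences are
   collapsed into haplotypes per species; expected richness under
   subsampling is the analytic hypergeometric rarefaction
   *S(m) = Σᵢ [1 − C(n−xᵢ, m)/C(n, m)]*, the asymptote is bias-corrected
   Chao1 *Ŝ = S_obs + ((n−1)/n) · f₁(f₁−1)/(2(f₂+1))*, and sampling
   completeness is S_obs/Ŝ. Octave profiles bin haplotype abundances into
   the eight log₂ classes 1, 2–3, …, 128–255.
2. **How reliably does the library identify specimens?** A hierarchical
   probabilistic classifier walks the taxonomy root → family → subfamily
   → genus → species; each node splits its probability over candidate
   children by multinomial regression on the minimum and average
   p-distance from the query to each child's references (standardised;
   one shared weight vector per level). Weights are trained by adaptive
   random-walk Metropolis (target acceptance 0.44; 1000 adaptation + 1000
   fixed iterations; zero-mean Gaussian priors, sd 100) and evaluated by
   leave-one-out classification of every reference barcode.
3. **How is mitochondrial diversity structured in space?** Overlapping
   0.5°-spaced belts (±1°) score each adequately sampled species'
   standardised haplotype richness; belt trends are fitted with an
   additive mixed model (penalized spline over the axis, conspecific
   great-circle distance as covariate, continuous-AR1 residuals) and
   inspected with loess (span 0.4).
4. **Which taxa need taxonomic attention?** Uncorrected p-distances with
   pairwise deletion drive nearest-neighbour summaries, barcode-sharing
   detection (connected components of zero-distance cross-species links)
   and audit flags: deep splits (max intraspecific > 2.5%), low
   divergence (nearest neighbour < 0.61%, i.e. 4 substitutions on the
   658-site frame), and sharing (distance 0). A phylogenetic GLS with
   Pagel's λ relates log haplotype richness to log range size and log
   specimen count, with AICc model comparison.

A seeded synthetic-library generator (`generate_dataset()`) reproduces
the statistical shape of such datasets — skewed, singleton-dominated
haplotype abundances, effort tied to range size, a latitudinal richness
gradient, occasional cross-species barcode sharing, and a matching
ultrametric tree — so the full pipeline runs and is tested without any
external downloads. See the methods vignette
(`vignettes/barcode-library-methods.Rmd`) for models, parameters and
limitations.

## Worked example

The `analysis/` directory is a numbered pipeline over a synthetic
54-species library (~3900 specimens) written to `results/`:

```sh
Rscript analysis/01_simulate.R   # library + tree + ranges -> results/data/
Rscript analysis/02_diversity.R
Rscript analysis/03_distances.R
Rscript analysis/04_protax.R
Rscript analysis/05_spatial.R
Rscript analysis/06_pgls.R
```

Stage 2 reports how much of each species' estimated haplotype diversity
the library holds:

```
53 of 54 species have >= 6 specimens and enter the completeness cohort
mean sampling completeness: 80.6%
96% of species have more than half their estimated haplotype diversity sampled
modal octave class: 1 (mean share 38.9%)
```

— most haplotypes are seen once (modal octave class 1), and roughly a
fifth of the estimated diversity remains unsampled at ~70 specimens per
species. Stage 3 finds exactly the two planted barcode-sharing pairs:

```
mean intraspecific p-distance: 0.51%
2 species flagged for deep splits (> 2.5%), 0 for low divergence ...
2 barcode-sharing case(s) involving 4 species (2 -> 2 by component size)
```

Stage 4 trains the classifier and evaluates every barcode leave-one-out:

```
specimen-weighted mean probability of correct identification: 99.7%
96% of (non-singleton) species identified with mean probability above 95%
```

Only the sharing species fall below certainty — identification is
near-dichotomous in nearest-neighbour distance. Stage 5 recovers the
configured 42.5° richness peak from the belt analysis
(`loess-smoothed richness peaks at 43.2 degrees N`, smooth term
p ≈ 0), and stage 6 prints the Table-style PGLS coefficients, e.g. for
estimated richness `range 0.103 ± 0.047 (t = 2.19, p = 0.033)` with the
full model beating the best univariate model by 2.4 AICc units.

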