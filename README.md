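# nichebreadth

Tools for linking the **dietary niche breadth** of insectivorous predators
(measured from DNA-metabarcoding diet profiles) to features of their
**spatial distribution** (derived from habitat-suitability rasters).

The package targets a recurring question in trophic ecology: does a broader
diet go with a larger — or a more evenly exploitable — geographic
distribution? Its users are ecologists with (i) replicated OTU read-count
tables from faecal metabarcoding, (ii) prey phylogenies with posterior
uncertainty, and (iii) per-species habitat-suitability maps from
distribution models.

## What it computes

**Dietary breadth** is measured with Hill numbers of a species' pooled diet
profile `p`:

- `dR` — richness: the neutral Hill number of order *q* = 0,
  `⁰D = S_obs`;
- `dRE` — richness + evenness: order *q* = 1,
  `¹D = exp(−Σᵢ pᵢ ln pᵢ)`;
- `dRER` — richness + evenness + regularity: the *phylogenetic* Hill number
  of order 1 on the prey tree,
  `¹PD = exp(−Σ_{i∈B} (Lᵢ/T̄) aᵢ ln aᵢ)`, with branch lengths `Lᵢ`,
  branch abundances `aᵢ` and mean depth `T̄ = Σ Lᵢ aᵢ`, evaluated once per
  posterior tree draw so that phylogenetic uncertainty propagates into a
  mean ± SE;
- Levins' index (`1/Σ pᵢ²` = order-2 Hill number) for comparability with
  the older literature, and trait-axis breadths (hunting/habitat/roosting)
  as exponential Shannon diversities.

**Diversity partitioning**: multiplicative alpha (individuals), beta,
gamma (species) decomposition with equal weights, and the Jaccard-type
turnover `(1 − 1/β)/(1 − 1/N)` quantifying how much of the species diet
arises from differences among individuals.

**Spatial metrics** from suitability rasters: potential range size (cells
strictly above the species' minimum suitability) and distribution
homogeneity, the Hill evenness factor `¹D/⁰D` of the normalised
cell-suitability distribution (1 when all suitable cells are equal,
towards 0 as suitability concentrates).

**Association stage**: ordinary linear models for single-value-per-species
metrics, and random-intercept linear mixed models (REML, likelihood-ratio
p values, marginal/conditional R²) wherever dRER's tree draws introduce
pseudoreplication; the two primer datasets are averaged per metric
(draw-wise for dRER) before the contrast battery.

**Quality control** of raw replicated count tables follows the standard
sequence-reliability rules: batch-scoped removal of OTUs found in
extraction/library blanks, a 2-of-3 PCR replicate concordance filter,
replicate collapse, a 5000-read minimum depth filter, and a 0.02 %
within-sample relative-abundance filter, with rarefaction curves and a
curvature (saturation) index as diagnostics.

A fully seeded **synthetic-data generator** (`sim_config()`,
`simulate_assemblage()`) emulates the whole study design — 7 species,
triplicate PCRs, two primers, posterior-like tree sets, planted
contaminants and a tunable coupling between true dRER and raster
homogeneity — so every stage is testable with known ground truth.

## Worked example

```r
library(nichebreadth)

cfg <- sim_config(seed = 42, n_species = 7, n_individuals = 10,
                  n_otus = 400, n_trees = 20, depth_mean = 15000,
                  raster_dim = c(30, 30))
sim <- simulate_assemblage(cfg)     # counts, trees, rasters, traits, truth
run <- run_pipeline(sim)            # QC -> diversity -> partition -> spatial -> models

run$records$metrics[, c("species", "dR", "dRE", "dRER", "turnover", "homogeneity")]
#>   species   dR   dRE  dRER turnover homogeneity
#> 1    SP01 16.0  7.06  5.22    0.248     0.00931
#> 2    SP02 26.5 10.07  6.15    0.194     0.05836
#> 3    SP03 30.0 16.00  6.97    0.255     0.20143
#> 4    SP04 35.0 22.52  8.93    0.274     0.83309
#> 5    SP05 42.0 27.81  9.58    0.258     0.81603
#> 6    SP06 47.0 33.01 10.91    0.276     0.96976
#> 7    SP07 52.0 36.38  7.76    0.269     0.56303
```

Species are generated with graded richness/evenness/regularity, and their
raster unevenness is coupled to true dRER (`coupling_slope = 0.8` by
default), which the fitted contrasts recover:

```r
run$contrasts
#> Association battery:
#>   dR_vs_homogeneity                  LM F =   7.943  p = 0.03718 *
#>   dRER_vs_homogeneity                LMM t =   8.439  p = 1.261e-05 *
#>   alpha_vs_dRER                      LM F =   8.523  p = 0.03304 *
#>   turnover_vs_dRER                   LM F =   3.307  p = 0.1287
#>   ...
```

The `dRER_vs_homogeneity` line is the headline association: broader,
phylogenetically more even diets go with more homogeneous potential
distributions. Single Hill computations are one-liners:

```r
p <- c(OTU_1 = 0.6, OTU_2 = 0.3, OTU_3 = 0.1)
hill_number(p, 0)    # 3         (dR)
hill_number(p, 1)    # 2.454556  (dRE)
levins_index(p)      # 2.173913  (= Hill q = 2)
evenness_factor(p)   # 0.8181852 (q=1 / q=0)
```

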