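---
title: "Dietary niche breadth and distribution homogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary niche breadth and distribution homogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichebreadth)
```

This vignette documents the models the package implements, the knobs that
matter, the numerical choices made where conventions diverge, and what the
synthetic-data generator does and does not emulate.

## The scientific setting

Classical tests of the niche-breadth/range-size hypothesis relied on
coarse metrics on both sides: prey counted from morphological scat
analysis, and range size from expert maps. DNA metabarcoding of faecal
samples resolves thousands of prey taxa per predator population, and
species distribution models resolve *how* suitability is spread over a
range, not just how large the range is. The package operationalises both
sides — dietary breadth as Hill numbers of diet profiles, spatial
structure as Hill numbers of suitability rasters — and fits the
associations between them.

## Hill numbers and the breadth metrics

For a relative-abundance (or relative-incidence) profile $p$ over OTUs,
the Hill number of order $q$ is

$$^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
  ^1D = \exp\Big(-\sum_i p_i \ln p_i\Big),$$

the effective number of equally abundant OTUs. The $q \to 1$ limit is
handled analytically, never by numerical limit; profiles that are exactly
uniform on their support short-circuit to the support size so that the
"uniform $\Rightarrow S$, at every order" identity holds to the last bit.

The three dietary-breadth metrics are `dR` $=\,^0D$, `dRE` $=\,^1D$, and
`dRER`, the phylogenetic Hill number of order 1. With $B$ the branch set
of the prey tree pruned to the profile's support, $L_i$ the branch
lengths, $a_i$ the total abundance of leaves descending branch $i$ and
$\bar T = \sum_i L_i a_i$ the abundance-weighted mean depth,

$$^qPD = \Big[\sum_{i \in B} \frac{L_i}{\bar T}\, a_i^q\Big]^{1/(1-q)},$$

the mean-phylogenetic-diversity formulation of the phylogenetic Hill
family. Normalising by $\bar T$ makes the value invariant to rescaling all
branch lengths, and pruning before computing $\bar T$ means the quantity
describes the *consumed* assemblage, not the reference tree. On a star
tree with equal branch lengths $^qPD$ collapses to $^qD$; both properties
are enforced by test.

Phylogenetic uncertainty is propagated by evaluating $^1PD$ once per tree
in a posterior-like tree set (50 draws by default) and reporting the mean
and the standard error across draws ($\mathrm{sd}/\sqrt{N}$). With
identical trees the dispersion is exactly zero.

**Pooling individuals.** A species profile is, by default, the
equal-weight arithmetic mean of the individuals' renormalised profiles.
Read-pooling (summing counts) would let deeply sequenced individuals
dominate; it remains available via `pool = "reads"` since both
conventions circulate. Incidence profiles are presence vectors normalised
to sum one, which makes incidence mode a valid input to every Hill
computation rather than a separate code path.

## Partitioning and turnover

Species diversity is decomposed multiplicatively with equal subsystem
weights $w_j = 1/N$: gamma is the Hill number of the pooled profile,
alpha the equal-weight Hill alpha (for $q = 1$, the exponential of the
mean Shannon entropy), and $\beta = \gamma/\alpha \in [1, N]$. Turnover
is reported on the Jaccard-type normalisation

$$T_J = \frac{1 - 1/\beta}{1 - 1/N},$$

which is 0 when all individuals eat the same diet and 1 when their diets
are disjoint; the endpoint behaviour (rather than the Sørensen-type
$(\beta-1)/(N-1)$ alternative) is pinned by test. Unequal weights are
rejected at the interface: silently admitting them would detach beta from
the turnover formula's $[0,1]$ guarantee. The partition order defaults to
$q = 1$, matching dRE/dRER; the choice is exposed as an argument since no
single convention dominates.

## Quality control of replicated count tables

The chain is: **blank removal → replicate concordance → collapse →
depth filter → relative-abundance filter**, each step logged with its
parameters in a provenance record.

- *Blank removal* is batch-scoped: an OTU detected in an extraction or
  library blank is zeroed in all samples of that processing batch only.
  PCR blanks are reported but not used for removal — they sit downstream
  of the contamination sources the rule addresses; treating them as
  removal blanks would delete genuine diet carried over as droplet
  contamination at the PCR stage.
- *Replicate concordance* keeps an OTU in a sample only if detected in at
  least 2 of the 3 PCR replicates; blanks are exempt (their content feeds
  the previous rule). Running concordance before or after blank removal
  gives the same final table because blank removal zeroes whole
  OTU-by-batch blocks; the order above is fixed and audited so provenance
  is unambiguous.
- *Collapse* sums replicates (not averages), so the depth threshold keeps
  its literal read-count meaning.
- Boundary semantics are strict on the removal side: a sample with
  exactly 5000 reads is kept, an OTU at exactly 0.02 % of its sample is
  kept. The relative-abundance comparison is a single pass against the
  pre-filter totals; re-normalising between removals would make the
  result order-dependent within the step.
- The *curvature index* summarises a rarefaction curve as the area under
  the curve over the area of its enclosing rectangle (depth range ×
  maximum richness): 1 for a saturated flat curve, 0.5 for a straight
  line through the origin. There is no universal formula for this
  diagnostic; this AUC ratio is the package's documented choice. Samples
  below a configurable threshold (default 0.9) are *flagged*, never
  dropped — the hard rule remains the depth filter. Rarefaction
  expectations are analytic (hypergeometric), cross-checked in the tests
  against brute-force resampling and `vegan::rarefy`.

## Spatial metrics

Potential range size counts raster cells with suitability strictly above
the species' minimum-suitability floor `s_min`. Distribution homogeneity
restricts to the same cells, normalises suitabilities to
$p_c = s_c/\sum s_c$, and takes the evenness factor $^1D/^0D$. Gating
both metrics with the same `s_min` makes the $q=0$ point of the spatial
breadth profile coincide with potential range size. `s_min` is a
per-species input (distribution models estimate it in different ways);
when absent it falls back to the smallest positive suitability present.
Cells are counted, not area-weighted — for wide-latitude unprojected
grids this conflates count with area, which is flagged here for
geographic use. Raster I/O supports the plain-text ESRI ASCII grid
dialect with exact round-tripping.

## Association models

Metrics with one value per species are related by ordinary least squares
(`fit_lm`), reporting the slope, $F_{(1, n-2)}$, $r^2$ and $p$. dRER
carries one value per posterior tree, so its associations use a
random-intercept linear mixed model. One orientation note: the
species-level covariate (e.g. homogeneity) is constant within species,
so the identifiable model places the tree draws on the *response* side,

$$\mathrm{dRER}_{sj} = \beta_0 + \beta_1 x_s + u_s + \varepsilon_{sj},
  \quad u_s \sim \mathcal N(0, \sigma_u^2),$$

fitted by REML. Putting the draws on the predictor side instead would
leave $\beta_1$ confounded with $u_s$ (the response would be constant
within species). Reported: the fixed-effect $t$ with $n_\mathrm{species}
- 2$ df; a $p$ value from the likelihood-ratio test of the full against
the intercept-only model, both refitted by maximum likelihood (mixed-model
$p$ values admit several conventions; the LR test is the one implemented,
and is recorded in the output); and variance-partition
$R^2$s, $R^2_m = \sigma_f^2/(\sigma_f^2+\sigma_u^2+\sigma_e^2)$ and
$R^2_c = (\sigma_f^2+\sigma_u^2)/(\cdot)$, so $R^2_c \ge R^2_m$ always.
A singular fit (random-intercept variance at zero) falls back to OLS on
the species means with a warning; in the balanced case the LMM slope
equals that OLS slope anyway. Two primer datasets are averaged per metric
before modelling, draw-wise for dRER (draw $k$ with draw $k$) so the
dispersion across draws survives averaging. The contrast battery applies
no multiple-testing correction and uses the conventional $p = 0.05$
threshold.

## The synthetic-data generator

`simulate_assemblage()` produces every input with known truth. Defaults
mirror the targeted study design: 7 species, ~50 individuals each,
triplicate PCRs under two primers, a 2000-OTU universe, 50 perturbed
trees, one 50×50 raster per species. Structure:

- **Prey tree**: random pure-birth tree; the tree set multiplies branch
  lengths by lognormal(0, sd) factors with fixed topology. This emulates
  the branch-length component of posterior uncertainty — the part that
  drives dRER dispersion — cheaply and with a stable leaf set; it does
  not emulate topological uncertainty.
- **Diets**: each species draws a prey pool (uniformly over leaves, or
  concentrated near a seed leaf as the clustering strength `lambda_phylo`
  grows — lower regularity), a base profile from a symmetric Dirichlet
  (concentration = evenness), and individuals as gamma-perturbed copies
  with shape $(1-\tau)/\tau$: $\tau = 0$ gives identical individuals
  (beta exactly 1), $\tau \to 1$ nearly disjoint diets. Richness,
  evenness and regularity are graded across species by default.
- **Reads**: multinomial draws at negative-binomial depths (mean 20 000,
  chosen so that the 0.02 % filter corresponds to ~4 reads, as in deeply
  sequenced studies), per-replicate amplification dropout, lognormal
  per-OTU primer bias, planted contaminants present in each batch's
  extraction/library blanks *and* its samples across all replicates (so
  only the blank rule can remove them), single-replicate artifact OTUs,
  trace OTUs below the abundance threshold, and a small fraction of
  under-sequenced samples.
- **Rasters**: lognormal suitabilities rescaled into (0, 1], a
  per-species habitat fraction setting the potential range, and log
  unevenness coupled linearly (slope `coupling_slope`, default 0.8, plus
  noise) to the species' standardised true dRER. The coupling is imposed
  on the *generating parameter*, not on realised homogeneity, so realised
  values inherit sampling noise — the honest analogue of an observational
  design.

What the generator does **not** emulate: sequence-level errors and
chimeras, PCR amplification bias beyond a static per-OTU factor,
topological tree uncertainty, spatially autocorrelated suitability, and
real taxonomic structure. Passing tests therefore demonstrate that the
*estimators and filters* behave as specified under the assumed generative
model, not that any field dataset satisfies that model.

## Problem sizes and numerical choices

The test suite exercises the end-to-end dissociation property (planted
dRER–homogeneity coupling detected, uncoupled dR–homogeneity not) on
100 assemblages of 50 species, 4 individuals each, 500 OTUs, 5 trees and
mean depth 12 000 — sizes chosen as the smallest at which the
species-level regression is comfortably powered and the small-sample
noise of 7-species assemblages no longer dominates. In that
configuration prey-pool size and Dirichlet concentration are held
constant across species, and only the phylogenetic clustering gradient
drives dRER, so neutral richness stays uncoupled from the rasters by
construction. Mixed-model calibration is checked over 200 simulated fits
of 30 species × 8 draws with variance components 0.5/0.5, comparing the
recovered slope against the ±2 SE band implied by the known components.

Degenerate inputs are handled explicitly: empty profiles, all-nodata
rasters, no cells above `s_min`, trees with zero mean depth, missing
leaves (error lists them), single-individual species (no partition),
sub-3-species record sets (contrast battery refuses), and singular mixed
fits (documented fallback). Beta is clamped into $[1, N]$ against
floating-point excursions at the endpoints; the clamp is within $10^{-9}$
tolerance of the exact value.

## Known limitations

- Blank-based removal deletes whole OTU–batch blocks; a contaminant that
  is also genuine diet in the same batch is lost (conservative by
  design).
- Distribution homogeneity inherits raster resolution: resampling a map
  changes $^0D$ faster than $^1D$, so only same-resolution comparisons
  are meaningful.
- The LMM degrees of freedom ($n_\mathrm{species} - 2$) are a convention,
  not a Satterthwaite approximation.
- With only 7 species, species-level regressions have little power and
  the type-I behaviour of the whole battery is weak; the package's own
  power analyses run at 50 species for that reason.
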