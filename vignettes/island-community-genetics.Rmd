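---
title: "Methods: community structure and mitochondrial differentiation of island faunas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community structure and mitochondrial differentiation of island faunas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islecomm)
```

`islecomm` joins two traditions that are usually kept apart: the
community-ecology analysis of which species occur on which islands, and the
population-genetic analysis of how each species' mitochondrial variation is
distributed among those islands and their source areas. This vignette
documents the statistical machinery, the defaults and their rationale, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the methods literature is silent.

## Nestedness and its null models

The degree to which depauperate island faunas are subsets of richer ones is
measured with NODF (nestedness based on overlap and decreasing fill). For a
presence–absence matrix, every pair of rows contributes
`100 * shared / fill_smaller` when the two fills differ strictly, and 0
when they are equal; likewise for column pairs; NODF is the mean over all
pairs, 0–100. The strict decreasing-fill requirement follows the canonical
definition: a pair of equally rich islands carries no evidence of
nestedness, however similar their faunas. `pack_matrix()` sorts rows and
columns by decreasing marginal totals (ties broken by label so packing is
reproducible), but the NODF value itself is permutation-invariant because
each pair is oriented by its own fills.

Observed NODF only becomes interpretable against a null ensemble, and the
verdict is notoriously null-model dependent, so three classical
randomizations are provided:

* **EE** (equiprobable–equiprobable): the observed number of presences is
  scattered uniformly over the cells. Preserves only total fill; the most
  liberal null.
* **CE** (proportional): each cell is Bernoulli with probability
  `(r_i/C + c_j/R)/2`, the mean of its row and column fill proportions.
  Preserves marginals in expectation only.
* **FF** (fixed–fixed): both marginals preserved exactly, sampled with the
  curveball trade algorithm. Each trade picks two rows and re-deals a random
  subset of their non-shared presences; the chain's stationary distribution
  is uniform over all matrices with the observed marginals. Between retained
  samples we apply `5 * fill` trades after a `10 * fill` burn-in — a
  standard mixing heuristic, exposed as the `trades` argument. The test
  suite verifies uniformity directly against the fully enumerated
  fixed-marginal state space of a 4×4 matrix (12 states, 10,000 draws,
  3-sd bands).

`nodf_test()` reports the null mean and SD, `z = (obs − mean)/sd`, an
add-one two-sided empirical p, and conventional significance stars on |z|
(1.96/2.58/3.29). A significantly *negative* z under FF (an "anti-nested"
pattern) indicates more species turnover than expected even after fixing
richness and occupancy — chequered distributions.

The default of 999 null matrices mirrors standard practice; calibration
tests in the suite use 199–299 nulls, which is ample to estimate a z-score
while keeping the 100-replicate Monte-Carlo experiments fast.

## Beta-diversity partition

For each island pair with `a` shared and `b`, `c` unique species:
`βsor = (b+c)/(2a+b+c)` (Sørensen), `βsim = min(b,c)/(a+min(b,c))`
(Simpson, the turnover component) and `βnes = βsor − βsim` (the
nestedness-resultant component). The summary statistic is the **mean of the
per-pair ratios** `βnes/βsor`; the alternative convention (ratio of the
mean components) is computed alongside and written to every report, since
the two can differ appreciably and published values do not always state
which was used. Pairs with identical faunas (`βsor = 0`) and pairs
involving an empty island are excluded from the mean.

## Species units from COI p-distances

The uncorrected p-distance between two aligned sequences is the proportion
of differing sites among comparable sites; sites with `N` or a gap in
either sequence are excluded pair by pair (pairwise deletion — standard
barcode practice, maximizing usable sites). Other IUPAC ambiguity codes are
mapped to `N` on input. Sequences are assumed pre-aligned and equal-length;
pairs of unequal length get an undefined distance, which never links.

Units are single-linkage clusters: connected components of the graph
linking specimens at p-distance strictly below 3%. Single linkage (rather
than complete linkage) is deliberate — barcode clusters routinely chain
through intermediate haplotypes, and a units definition phrased as "groups
of individuals" below a threshold is a connected-components definition.
The threshold is strict (`<`, not `≤`) and configurable. Unit labels derive
from the lexicographically smallest member species label, with an index for
species that split into several units.

Nominal species counts and analysis-unit counts need not coincide (units
can merge described species or split deep intraspecific lineages), so
downstream community analyses accept an explicit species list rather than
deriving one from the clustering.

## Distance-based differentiation: Ht, Hs, Dst, Gst

For each unit: `Ht` is the mean p-distance over all unordered specimen
pairs; `Hs` is the **unweighted** mean across areas of the within-area mean
p-distances — equal area weights match the classical Nei formulation, and
the alternative (weighting by sample size) would let heavily sampled areas
dominate a quantity meant to describe areas, not specimens. Areas with a
single specimen contribute to Ht but are excluded from Hs (within-area
diversity is undefined at n = 1).

`Dst = Ht − Hs` measures among-area differentiation in p-distance units.
Unbalanced sampling can make the raw difference negative; such values are
clamped to zero (the conventional treatment of this small-sample bias), and
both the raw and clamped values are retained, with clamps counted.
`Gst = Dst/Ht` standardizes to [0, 1]; monomorphic units (`Ht = 0`) get
Gst = 0 by convention.

Pairwise-area Gst restricts the Nei decomposition to the two areas —
`Dst_ij = Ht_ij − Hs_ij` with `Ht_ij` over the pooled pair and `Hs_ij` the
unweighted mean of the two within-area means — but standardizes by the
**species-wide** Ht, so that the pairwise values of one species are
comparable across pairs: they express which fraction of that species' total
diversity separates each particular pair of areas. Cells need at least two
specimens per area.

Averaging each cell over the species with a defined value gives the mean
Gst matrix; per-area mean Dst averages unit Dst over the units sampled in
the area. An 80% sequencing-coverage filter (strictly greater than) can
drop areas whose fauna is too incompletely sequenced for these averages to
be meaningful.

## Ordination and the RGB map

The mean Gst matrix is ordinated by classical scaling (PCoA): double-centre
`−D²/2`, eigendecompose, keep the axes with positive eigenvalues. Missing
cells (area pairs with no contributing species) are imputed with the grand
mean of the available dissimilarities before scaling — a neutral choice
that pulls unknown pairs toward the average rather than toward either
extreme; the number of imputations is reported. No Cailliez/Lingoes
correction is applied; negative-eigenvalue axes are dropped, the simplest
defensible treatment for a matrix that is an average of bounded indices
rather than a metric.

The configuration is then aligned to the areas' geographic coordinates by
least-squares Procrustes (translation, rotation/reflection, uniform
scaling — `vegan::procrustes`), and projected into RGB: axis 1 min–max
scaled to red, axis 2 to green, blue set to `255 − round((r+g)/2)`. Two
axes are used by default. The channel assignment is a convention —
any orthogonal axis-to-channel map conveys the same structure — and the
property that matters (colour distance increases with configuration
distance) is what the tests check. A constant axis maps to mid-channel 128.

## Occupancy versus differentiation

Spearman rank correlation (average ranks for ties) tests whether
differentiation declines with dispersal or with island occupancy. For
n ≤ 9 the two-sided p-value is exact, by full enumeration of the n!
permutations; above that, the usual t-approximation on n − 2 degrees of
freedom is used.

The quadrant test asks whether the joint distribution of occupancy and
differentiation is structured: species are classed widespread/rare at half
the **maximum** occupancy and low/high at half the maximum `√Dst` (the
square root de-skews Dst), giving four quadrants (WL, WH, RL, RH). Species
exactly on a boundary go to the lower category — a documented, configurable
tie rule. Null replicates independently permute the occupancy and `√Dst`
vectors across species, which breaks their association while preserving
both marginal distributions exactly; an alternative null that resamples
uniformly within the observed ranges is available via `null = "resample"`.
For each quadrant, `q` is the fraction of null replicates with a strictly
smaller count, plus half the ties; `q < 0.05` marks a significantly empty
quadrant and `q > 0.95` a significantly full one. Note that the permutation
null conditions on the observed marginals: in the degenerate case where
every species falls on one side of both splits, the null counts are
invariant and `q` is exactly 0.5 — no verdict is possible, by design.

Per-island analyses restrict the species set to each island's fauna but
reuse the **global** split thresholds, so "widespread" and "diversified"
mean the same thing on every island; islands with fewer than four species
are skipped. Each island's null stream is derived from the island's species
subset, so islands with identical faunas give identical results.

## Richness models, lmg, and glacial colonizers

Richness is modelled as a Gaussian linear model of `log10(richness)` —
the response is log-transformed, so a log-link count GLM would
double-transform — on up to seven predictors: MT (°C), AP (mm),
`log10(IA)` (km²), EL (m), `log10(IS)` (km; a +1 offset when any island
has IS = 0), `log10(SR)` and PC (0/1). Model selection is bidirectional
stepwise search from the full model minimizing the Gaussian profile AIC
`n·ln(RSS/n) + 2k`; the search is deterministic and the selected model's
AIC never exceeds the full model's.

Relative importance uses the lmg decomposition: a predictor's share is its
average incremental R² over all orderings of model entry, computed over
predictor subsets with combinatorial weights (equivalent to, and tested
against, direct enumeration of orderings). Shares always sum to the model
R²; enumeration is limited to 8 predictors (`2^8` subset fits).

The glacial-colonizer estimate compares, for each island with a Pleistocene
land connection, its residual under the contemporary-only model (Res.1)
with its residual under the model including the connection factor (Res.2).
Residuals are back-transformed to the species-count scale
(`observed − 10^fitted`) — the difference `Res.1 − Res.2` is then a number
of species, the natural unit for "how many glacial colonizers persisted".
The estimator deserves one caveat, which the tests quantify: when a real
connection effect exists, the contemporary-only model absorbs part of it
into its intercept (roughly the effect times the proportion of connected
islands), so the difference under-estimates the planted effect unless
connected islands are few. With a single connected island among 40 the
planted effect is recovered within 10%; and when no effect is planted the
differences for unconnected islands are centred on zero.

## The synthetic-data generators

The generators produce data whose structure is known exactly, so that every
stage has a parameter-recovery test.

* `simulate_incidence()` interpolates between a nested regime — presence
  probability `plogis(alpha_s + beta_i)` with a species propensity gradient
  `alpha` and an island suitability gradient `beta`, both linear on the
  logit scale over ±`gradient_strength` — and a turnover regime assigning
  disjoint species blocks to island groups round-robin (which guarantees
  non-nested structure without tuning). `nestedness_weight` sets the mix.
  The default `gradient_strength = 4` produces moderately nested matrices
  of the kind real archipelagos yield; at 10 the draws are nearly
  deterministic and mean NODF of an 11 × 27 matrix at weight 1 is ≈ 86 —
  the "strong gradient" regime used by the recovery tests. At weight 0 with
  two blocks the expected NODF is exactly 0.
* `simulate_sequences()` gives each species a random 658-bp base haplotype
  (the COI barcode length) and a second lineage at
  `round(658 · lineage_divergence)` fixed differences; lineages are placed
  either disjointly across the two halves of the area set (`chequered`,
  emulating mutual exclusion) or mixed; each specimen then receives
  `Poisson(within_lineage_theta)` private mutations. With chequered
  placement and `theta = 0`, Hs is exactly 0 and Gst exactly 1 — the sharp
  end-member the popgen tests pin down. Defaults (4 areas × 4 specimens,
  divergence 0.04, theta 0.5) give two well-separated lineages per species
  with realistic within-lineage scatter.
* `simulate_covariates()` draws island area log-uniform on 1–1000 km²,
  elevation uniform on 50–1500 m, isolation log-uniform on 1–200 km, source
  richness uniform on 50–250 species and a 0.3-probability Pleistocene
  connection, then computes `log10(richness)` from a known coefficient
  vector plus Gaussian noise (`noise_sd`, default 0.05 — comparable to the
  residual scatter of real island species–area regressions). Temperature
  and precipitation are generated as decoys with zero true effect, so
  selection procedures can be scored. Default coefficients
  (0.25 on log-area, 2·10⁻⁴ per m elevation, −0.15 on log-isolation, 0.4 on
  log-source-richness, 0.15 for a connection) are of the magnitude island
  biogeographic studies report, and give every predictor a detectable but
  not overwhelming signal at 40 islands.

One master seed drives per-species/per-stage sub-streams, so enlarging a
simulation does not perturb the draws of existing species.

What the generators do **not** emulate: coalescent genealogies (lineages
are fixed-difference clouds, not gene trees), recombination, selection,
migration, spatial autocorrelation among islands, observation error in the
incidence matrix, and correlated covariates (predictors are drawn
independently, which makes variance partitioning *easier* than in real
archipelagos where area, elevation and isolation co-vary). Passing recovery
tests therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to these violations.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on synthetic data at
deliberately modest sizes, chosen to exercise every code path while keeping
a full run in the minutes range: 11 × 27 incidence matrices (community
tests), 100-seed Monte-Carlo experiments with 199–299 null matrices
(calibration), 10,000 curveball draws on a 4×4 state space (uniformity),
40-island covariate tables (recovery), and a few hundred specimens per
sequence experiment. Exact comparisons use tolerance 1e-10 to 1e-12;
Monte-Carlo assertions use 3-sd binomial bands.

Degenerate inputs are handled explicitly rather than by accident: units
with fewer than two specimens are skipped and logged; a unit whose every
area has a single specimen has undefined Hs and is skipped; an all-zero
simulated incidence matrix is resampled up to 100 times; a null ensemble
with zero SD yields a missing z; constant ordination axes map to
mid-channel grey; boundary species in the quadrant test go to the lower
category; `IS = 0` islands get a +1 offset inside the log.

## Known limitations

* The p-distance matrix is computed in R with pairwise loops — fine for
  the ~1000-specimen scale it targets, not for tens of thousands.
* Pairwise Gst requires two specimens per area per species; sparse sampling
  leaves missing cells that are imputed (and counted) before ordination.
* The quadrant test's split-at-half-maximum rule makes its categories
  sensitive to single extreme species; the randomization inherits that
  sensitivity, which is the method's own property, not softened here.
* Stepwise AIC retains a null predictor with non-trivial probability
  (~0.16 each); selection results should be read with the lmg shares, not
  as a hypothesis test.
* No model-corrected distances (K2P etc.), AMOVA/Φst, haplotype-network
  drawing or map rendering; those sit outside the package's scope.
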