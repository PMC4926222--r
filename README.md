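# islecomm

Integrated community-ecology and mitochondrial-differentiation analysis of
island faunas.

Insular communities are shaped jointly by contemporary ecology (area,
isolation, climate, the richness of the nearest source) and by history
(Pleistocene land bridges, lineage-level colonization). `islecomm` implements
a complete pipeline that analyses an archipelago from both sides at once:

* **Community structure** — NODF nestedness of an islands × species
  presence–absence matrix tested against three classical null models
  (equiprobable **EE**, proportional **CE**, fixed-marginal **FF** via the
  curveball trade algorithm), a widespread/rare split at half the island
  count, and pairwise Sørensen beta diversity partitioned into turnover
  (Simpson) and nestedness-resultant components.
* **Species units** — specimens clustered into analysis units by
  single-linkage chains of uncorrected COI p-distances below 3%, the barcode
  threshold that separates most Lepidoptera sister species.
* **Population differentiation** — per unit, the distance-based Nei-style
  decomposition: total diversity Ht (mean pairwise p-distance over all
  specimens), within-area diversity Hs (unweighted mean of within-area mean
  p-distances), among-area differentiation `Dst = Ht − Hs` (negative values
  clamped to 0), and its standardized fraction `Gst = Dst / Ht ∈ [0, 1]`;
  pairwise-area Gst uses the two-area Nei decomposition standardized by the
  species-wide Ht. Per-cell averages across species give a mean area × area
  Gst matrix and per-area mean Dst.
* **Ordination** — principal coordinates analysis of the mean Gst matrix,
  Procrustes alignment of the configuration onto geographic coordinates, and
  an RGB projection in which colour resemblance tracks genetic resemblance.
* **Occupancy vs differentiation** — Spearman rank tests, and a
  four-quadrant randomization test: species classed widespread/rare at half
  the maximum occupancy and low/high at half the maximum √Dst, with 999
  permutation nulls deciding which quadrants are significantly empty
  (q < 0.05) or full (q > 0.95).
* **Richness models** — Gaussian GLMs of log10 richness on temperature,
  precipitation, log-area, elevation, log-isolation, log-source-richness and
  a Pleistocene-connection factor; bidirectional AIC stepwise selection;
  `lmg` hierarchical variance partitioning (average incremental R² over all
  predictor orderings); and the residual-difference estimate of
  glacial-maximum colonizers (residual without the connection term minus
  residual with it, on the species-count scale).
* **Synthetic data** — generators for incidence matrices with a tunable
  nestedness-vs-turnover balance, multi-lineage haplotype sets with
  controlled inter-area divergence (including chequered, i.e. mutually
  exclusive, lineage placement), and covariate tables drawn from a known
  linear model — so every stage has a parameter-recovery test with no
  external data.

## Worked example

```r
library(islecomm)

cfg <- sim_config(seed = 11)
m <- simulate_incidence(cfg)          # 11 islands x 27 species
nodf_test(m, "EE", n_null = 999, seed = 12)
#> NODF = 62.977 vs EE null (n = 999): mean = 51.077, z = 4.551***, p = 0.0010
nodf_test(m, "FF", n_null = 999, seed = 13)
#> NODF = 62.977 vs FF null (n = 999): mean = 62.975, z = 0.002, p = 0.9990
```

The community is significantly nested relative to the equiprobable null
(observed NODF far above the null mean, z ≈ 4.6), but indistinguishable from
chance once row and column totals are fixed — the classic signature of
nestedness driven by richness and occupancy gradients.

```r
seqs <- simulate_sequences(sim_config(seed = 11, n_species = 6,
                                      lineage_divergence = 0.01,
                                      within_lineage_theta = 0.5))
st <- diff_stats(seqs)
round(t(sapply(st, function(s) c(Ht = s$ht, Hs = s$hs,
                                 Dst = s$dst, Gst = s$gst))), 4)
#>           Ht     Hs    Dst    Gst
#> sp_01 0.0064 0.0008 0.0057 0.8819
#> sp_02 0.0066 0.0009 0.0057 0.8566
#> ...
mean_gst_matrix(st)$mean_gst
#>         area_01 area_02 area_03 area_04
#> area_01      NA   0.000   0.878   0.878
#> area_02   0.000      NA   0.878   0.878
#> area_03   0.878   0.878      NA   0.000
#> area_04   0.878   0.878   0.000      NA
```

Each species carries two lineages ~1% apart, fixed on opposite halves of the
area set (chequered placement), so most of the total diversity lies between
areas: Gst per species is near 1, and the mean Gst matrix separates the two
area groups (cross-group differentiation ≈ 0.88, within-group ≈ 0).

The whole analysis can also be orchestrated from one configuration:

```r
cfg <- run_config(incidence = "incidence.csv", fasta = "sequences.fa",
                  covariates = "covariates.csv", out_dir = "out",
                  seed = 1, n_null = 999)
run_all(cfg)   # writes CSV artifacts + out/report.json
```

or from the shell via the thin front end in `exec/`:

```sh
islecomm simulate --seed 1 --out-dir fixtures/
islecomm run --config run.yaml
```

Input conventions: FASTA headers are `specimenID|speciesLabel|areaLabel`;
the incidence matrix is a CSV with island labels in the first column and 0/1
species columns; covariates are a CSV with columns `island, MT, AP, IA, EL,
IS, SR, PC, richness` (PC coded 0/1).

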