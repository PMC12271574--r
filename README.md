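# plumedpr

Analysis of the bacterial **diversity–productivity relationship (DPR)**
along estuarine-plume salinity gradients, for microbial ecologists working
with 16S ASV tables, a rooted phylogeny and per-sample productivity
measurements (bacterial production from ³H-leucine incorporation, bacterial
abundance from flow cytometry).

The core question: as a river plume freshens and fertilizes coastal water,
does heterotrophic productivity follow *species* diversity or
*phylogenetic* diversity — and is the coupling driven by complementarity
(co-occurring lineages spanning more of the tree) or by selection
(productive, phylogenetically dispersed copiotroph clades taking over)?

## What it computes

* **Preprocessing** — 16S copy-number correction (half-up rounding),
  seeded rarefaction to the minimum depth, relative abundances; water-mass
  classification (plume < 33 PSU, mixed 33–33.75, open-sea > 33.75);
  leucine → carbon production (0.35 kg C mol⁻¹; 1 pmol l⁻¹ h⁻¹ =
  0.0084 mg C m⁻³ d⁻¹) and cell-specific production sBP = BP/BA.
* **Diversity** — richness, Shannon (nats), abundance-weighted mean
  pairwise phylogenetic distance

  MPD = Σᵢ Σⱼ≠ᵢ wᵢwⱼdᵢⱼ / Σᵢ Σⱼ≠ᵢ wᵢwⱼ,

  and its standardized effect size SES_MPD = (MPD − mean MPD_null) /
  sd(MPD_null) under an independent-swap null (999 abundance-carrying
  checkerboard randomizations preserving sample richness and taxon
  occurrence frequency; C++ kernel).
* **Niches** — abundance-weighted mean salinity (the taxon's salinity
  optimum) and mean sBP; plume/mixed/open-sea indicator classification;
  Levins (or Pianka/Schoener) niche overlap; salinity-niche differences.
* **Co-occurrence** — SparCC compositionality-robust correlations
  (Dirichlet resampling, log-ratio variation matrix, sparsity-approximated
  basis variances, strong-pair exclusion), permutation-bootstrap
  pseudo-p-values with the add-one rule, a meta-network thresholded at
  p < .01 and |r| ≥ 0.75, per-sample subnetworks with topology (size,
  connectivity, mean degree, clustering, greedy modularity), cohesion
  (abundance-weighted mean positive/negative connectedness) and a
  complementarity proxy (total branch length of the subtree spanned by
  significantly co-occurring taxa).
* **Phylogenetic bins** — maximal clades with within-clade cophenetic
  distance ≤ 0.1; per-bin mean phylogenetic distance, abundance ×
  (BP, BA, sBP) Pearson correlations, mean niche overlap/difference.
* **Statistics** — Kruskal–Wallis with BH-corrected pairwise rank-sum
  follow-ups and compact letter displays; hierarchical partitioning of
  diversity on indicator groups (independent effects summing exactly to
  the full-model R²).
* **Synthetic data** — a seeded generator (Yule tree, copiotroph/oligotroph
  guilds with salinity optima, coupled BP/BA/sBP) with full ground truth,
  used by the test suite for parameter-recovery and direction checks.

Everything tabular goes in and comes out as tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` ggplot builders.
Community matrices and trees use the field's native containers (numeric
matrix, `ape::phylo`).

## Worked example

```r
library(plumedpr)

ds <- simulate_dataset(
  sim_config(n_taxa = 60, n_samples = 30, depth_meanlog = log(2000)),
  seed = 1
)
cfg <- run_config(ds$counts, ds$tree, ds$samples, ds$copy_numbers,
                  seed = 1, n_null = 199, n_boot = 100, n_inner = 10)
bundle <- run_pipeline(cfg)

dplyr::select(head(bundle$diversity, 4),
              sample_id, richness, shannon, mpd, ses_mpd, water_mass, bp)
#>   sample_id richness shannon   mpd ses_mpd water_mass    bp
#> 1 S001            54    2.62 0.501  -2.24  mixed      3.04
#> 2 S002            21    2.67 0.771  -0.393 plume      1.47
#> 3 S003            53    2.79 0.621  -1.86  mixed      2.39
#> 4 S004            49    2.68 0.555  -3.39  scs        0.839
```

Sample S002 sits in the plume (salinity 29): few taxa (richness 21) but a
*high* weighted MPD (0.77) — its abundance is spread over distantly related
copiotroph clades — and the least negative SES_MPD. The offshore sample
S004 has more taxa but a tight dominant clade, hence low MPD.

Group tests reproduce the designed contrast (letters: groups sharing a
letter are not significantly different at BH-adjusted p ≥ 0.05):

```r
dplyr::filter(bundle$tests, variable %in% c("bp", "mpd", "richness"))
#>   variable     H  p_value group   mean     sd letter
#> 1 bp        9.77 7.55e-3  plume  2.56  1.36   a
#> 2 bp        9.77 7.55e-3  mixed  2.17  0.742  a
#> 3 bp        9.77 7.55e-3  scs    1.23  0.467  b
#> 4 richness 13.1  1.41e-3  plume 34.6  14.6    a
#> 5 richness 13.1  1.41e-3  mixed 55.8   2.12   b
#> 6 richness 13.1  1.41e-3  scs   52.5   2.80   c
#> 7 mpd      21.5  2.11e-5  plume  0.718 0.0468 a
#> 8 mpd      21.5  2.11e-5  mixed  0.598 0.0516 b
#> 9 mpd      21.5  2.11e-5  scs    0.539 0.0355 c
```

Production and phylogenetic diversity are highest in the plume while
richness is lowest there — the decoupling of taxonomic from phylogenetic
DPR. The sample-level coupling is positive:

```r
with(bundle$diversity, pearson_test(mpd, bp))
#>       r p_value     n
#> 1 0.383  0.0365    30
glance(bundle$meta)
#>   n_taxa n_edges n_positive n_negative r_cut p_cut
#> 1     60     126        122          4  0.75  0.01
```

`plot_water_mass_boxes()`, `plot_dpr()`, `plot_bin_niche()` and
`autoplot()` on the network/SES objects draw the standard figures.

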