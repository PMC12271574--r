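---
title: "Methods: phylogenetic diversity, productivity and co-occurrence along a plume salinity gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic diversity, productivity and co-occurrence along a plume salinity gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumedpr)
```

# The scientific problem

Estuarine plumes inject nutrients and labile organic matter into coastal
seas. Heterotrophic bacterioplankton respond quickly, and the question this
package addresses is how their *diversity–productivity relationship* (DPR)
behaves across the resulting salinity gradient: does productivity track
species diversity (richness, Shannon), or phylogenetic diversity (how
evolutionarily spread out the abundant taxa are)? Under phylogenetic niche
conservatism, close relatives share traits, so a community of distantly
related taxa is more likely to contain functionally distinct — and possibly
highly productive — lineages. Two mechanisms are distinguished: a
*complementarity effect* (diverse assemblages cooperate and partition
resources; proxied here by the phylogenetic breadth of significantly
co-occurring taxa) and a *selection effect* (diversity raises the chance of
including high-productivity taxa; visible as productive, phylogenetically
dispersed clades dominating low-salinity communities).

The package implements the full analysis chain for an ASV table, a rooted
phylogeny, and per-sample environmental/productivity metadata, plus a
synthetic-data generator with known ground truth so every stage can be
validated without field data.

# Water masses and productivity units

Samples are classified by practical salinity: **plume** (< 33), **mixed**
(33–33.75, boundaries inclusive) and **SCS** (open South China Sea water,
> 33.75). The boundary values fall in the mixed class because the outer
classes are defined by strict inequalities.

Bacterial production (BP) is derived from ³H-leucine incorporation with the
empirical conversion factor 0.35 kg C (mol leucine)⁻¹ and a linear 24 h
day, giving 1 pmol l⁻¹ h⁻¹ = 0.0084 mg C m⁻³ d⁻¹. No isotope-dilution
correction is applied. Cell-specific production is sBP = BP/BA expressed in
fg C cell⁻¹ d⁻¹ (BA in cells ml⁻¹); `validate_sample_table()` enforces
consistency of the three columns to 10⁻⁶ relative.

# Preprocessing

The pipeline order is: 16S rRNA operon copy-number correction (divide reads
by the taxon's copy number, round half-up so the table stays integral;
missing copy numbers default to 1 with a warning), then rarefaction of every
sample to the minimum sample total (a single without-replacement draw per
sample, all governed by one seed), then relative abundances. Rounding is
half-up rather than R's banker's rounding so the correction is
deterministic and integral. The input table is assumed to already exclude
non-heterotrophic reads (chloroplasts, mitochondria, archaea,
cyanobacteria); upstream read processing is out of scope.

# Diversity

Richness counts positive entries; Shannon uses natural logarithms (nats),
the common ecology default. Phylogenetic diversity uses the
abundance-weighted mean pairwise distance over taxa present in a sample,

$$\mathrm{MPD} = \frac{\sum_i \sum_{j \ne i} w_i w_j d_{ij}}
                     {\sum_i \sum_{j \ne i} w_i w_j},$$

with $d_{ij}$ the cophenetic (tip-to-tip) distance. The implementation is
vectorized (`W D W'` with diagonal cancellation) and is tested to 10⁻¹²
against an explicit double-loop oracle. Note that some reference
implementations (e.g. picante) keep the $i = j$ pairs in the denominator;
the two conventions differ by the factor $1 - \sum w_i^2 / (\sum w_i)^2$
and the test suite reconciles them exactly.

The null model is the independent swap: 2×2 submatrices with occupancy
pattern `[[+,0],[0,+]]` have their nonzero entries (abundances, not just
presences) moved to the opposite diagonal. This preserves per-sample
richness and per-taxon occurrence frequency exactly, so

$$\mathrm{SES}_{\mathrm{MPD}} =
  \frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
       {\mathrm{sd}(\mathrm{MPD}_{null})}$$

is independent of richness. Positive values mean co-occurring taxa are more
phylogenetically distant than chance. Numerical choices: 999 null
replicates by default (conventional for SES metrics), 1000 successful
swaps per replicate, each replicate seeded independently from the master
seed (so replicates are exchangeable and reproducible), and the sample
(n−1) standard deviation. Abundances are carried through the swaps so the
weighted MPD genuinely varies under the null. A null standard deviation
below 10⁻¹² (e.g. a matrix admitting no swaps) yields a missing SES with a
warning rather than an infinite value. The swap kernel is in C++ (Rcpp), as
the field's packages do, with an attempt cap so a swap-free matrix returns
unchanged. On data generated by the null process itself the mean SES over
50 samples is within ±0.15 of zero at 999 replicates — a calibration the
test suite checks.

# Niches

A taxon's salinity niche is its abundance-weighted mean sample salinity
(`awm_strategy()`); the same construction with sBP gives a relative
productivity score. Indicator taxa are classified by applying the
water-mass thresholds to the niche value. Niche overlap defaults to Levins'
index on sample-normalized abundance profiles,

$$O_{ij} = \frac{\sum_h p_{ih} p_{jh}}{\sum_h p_{ih}^2},$$

which is asymmetric; the pairwise summary averages the two directions.
Pianka and Schoener indices are selectable alternatives — the choice of
index is genuinely open and is recorded in the run manifest. Niche
difference is the absolute difference of salinity niches (a pseudometric,
in PSU). All pairwise quantities are computed from the rarefied table,
matching the pipeline order; taxa with zero total abundance are excluded
rather than imputed.

# Co-occurrence network

Compositional count data induce spurious negative correlations between
relative abundances, so correlations are estimated with the SparCC
approach: per resample, posterior fractions are drawn from a row-wise
Dirichlet (pseudocount 1); the log-ratio variation matrix
$t_{ij} = \mathrm{var}\log(x_i/x_j)$ is formed; basis variances solve the
sparsity-approximation linear system; correlations follow from
$r_{ij} = (\omega_i^2 + \omega_j^2 - t_{ij}) / (2\omega_i\omega_j)$,
clipped to [−1, 1]; and the most strongly correlated pairs (|r| above 0.1)
are excluded from the system one at a time (up to 10 iterations) so they do
not bias the basis variances. The final matrix averages 20 Dirichlet
resamples. All of these internals are configurable; the defaults follow the
published algorithm's conventions. At least 4 taxa and 4 samples are
required or the basis-variance system is underdetermined.

Significance uses bootstrap pseudo-p-values: each of 100 bootstraps
permutes every taxon's counts across samples independently and recomputes
SparCC; the two-sided add-one formula
$p = (1 + \#\{|r^{boot}| \ge |r^{obs}|\}) / (n_{boot} + 1)$ never returns
0 and makes the conventional $p < .01$ cut attainable at 100 bootstraps
($1/101 \approx 0.0099$). The meta-network keeps edges with $p < .01$ and
$|r| \ge 0.75$, signed by the correlation.

Per-sample subnetworks are induced by presence. Topology metrics are
computed on the unsigned simple graph: size, connectivity (edges), mean
degree $2E/N$, clustering coefficient (average local; nodes of degree < 2
contribute 0), and modularity of the deterministic greedy agglomerative
partition (stochastic community detection would break bit-reproducibility).
Cohesion weights each taxon's abundance by its mean positive (or negative)
meta-network correlation: positive cohesion $= \sum_i a_i \bar r_i^+$, and
the reported ratio is |negative|/positive cohesion (undefined, with a
warning, when positive cohesion is zero). The complementarity proxy is the
total branch length of the minimal subtree spanning the taxa that
participate in at least one significant co-occurrence (degree ≥ 1;
including all present nodes is a config alternative), excluding the stem
above their most recent common ancestor; it is computed by a linear-time
edge-marking traversal and tested against a brute-force union of
tip-to-tip paths.

# Phylogenetic bins

Bins are the maximal clades whose maximum within-clade cophenetic distance
does not exceed 0.1 tree distance units, found root-to-tip; tips in no
qualifying multi-tip clade become singletons. This clade-based reading of
"binning at a fixed branch length" (the convention of the community
assembly literature); a tip-depth cut is the obvious alternative and was
not taken because it does not guarantee the within-bin distance cap that
the per-bin statistics rely on. Bin ids follow traversal order for
determinism, and no minimum bin size is imposed. Per bin, the mean member
relative abundance per sample is correlated (Pearson, as is standard for
these per-bin panels) against BP, BA and sBP, and pairwise niche overlap
and difference are averaged over member pairs (missing for singletons).

# Group statistics

Water-mass comparisons use the Kruskal–Wallis test (tie-corrected) with
pairwise rank-sum follow-ups corrected by Benjamini–Hochberg, summarized as
a compact letter display (groups sharing a letter are not significantly
different at adjusted p ≥ 0.05). The pairwise procedure behind published
group letters is typically unstated; pairwise Wilcoxon rank-sum with BH is
the choice here and is recorded. Hierarchical partitioning decomposes the
least-squares full-model R² of a diversity metric on predictor groups
(here: summed relative abundance of plume/mixed/SCS indicator taxa) into
independent effects by averaging incremental R² over all group orderings;
plain (not adjusted) R² is used so the effects sum *exactly* to the
full-model R², an identity the tests assert at 10⁻¹⁰. Subset enumeration
caps at 10 groups (2¹⁰ model fits).

# The synthetic study design

`simulate_dataset()` draws, from one master seed: a pure-birth (Yule) tree
rescaled to root-to-tip depth 0.5 (pairwise distances ≤ 1, so the 0.1 bin
width is meaningful); guild-structured traits; and a community matrix plus
metadata. Defaults define the study conditions:

* 72 samples stratified over salinity 28–34.5 PSU (≈ 40% plume, 25% mixed,
  35% SCS — at least 10 samples per class), three depth layers with
  plume-biased surface sampling.
* 300 taxa; 35% copiotrophs assigned to at least 4 deep, mutually disjoint
  clades (so plume communities are phylogenetically dispersed), the rest
  oligotrophs. One oligotroph clade — chosen as the shallowest clade holding
  5–15% of tips — is the *dominant streamlined ecotype* (SAR11-like): its
  base abundance is rescaled to 65% of the oligotroph guild total
  (conserving the guild total), its salinity optima sit tightly at the
  guild mean, and its internal branches are compressed (×0.3).
* Salinity optima: copiotrophs 30.5 ± 0.6 PSU, oligotrophs 34.1 ± 0.35 PSU,
  plus a Brownian component diffused along the tree (weight 0.5 PSU per
  standardized trait unit) so optima carry phylogenetic signal beyond the
  guild structure. Gaussian niche breadths: 1.2 PSU (copiotrophs, bloom
  specialists of the fresher plume) and 1.0 PSU (oligotrophs).
* Per-cell productivity traits are log-normal with copiotroph mean 6 and
  oligotroph mean 2 fg C cell⁻¹ d⁻¹ (the 3× contrast of fast- vs
  slow-growing ecotypes; magnitudes in the observed sBP range). Community
  sBP is the abundance-weighted mean trait times log-normal noise
  (sd(log) = 0.3); BA scales with expected community size around
  5×10⁵ cells ml⁻¹; BP = sBP × BA, so the three columns are exactly
  consistent. HNA/LNA counts mirror the copiotroph/oligotroph mass split.
* Copiotroph pendant branches are elongated by +0.035 distance units and
  the dominant clade's internal branches compressed, so within-bin
  phylogenetic distance is linked to the productive guild — the designed
  bin-level pattern (internally diverse bins correlate positively with
  productivity).
* Sequencing depths are log-normal (median 8000, sd(log) 0.3) so
  rarefaction is a real step; reads are multiplied by per-taxon 16S copy
  numbers (copiotrophs 3–8, oligotrophs 1–2) so copy-number correction is a
  real step that exactly inverts the inflation.

What the generator emulates: the qualitative gradient structure — higher
BP/BA/sBP and phylogenetic diversity with copiotroph dominance in the
plume; higher richness with a dominant tight oligotroph clade offshore;
salinity-niche indicator structure; and the within-bin
distance–productivity link. What it does not emulate: the field study's
absolute values for network topology and complementarity (those depend on
unpublished upstream read processing), taxonomic composition, temperature/
chlorophyll covariation beyond simple monotone trends, or spatial/depth
autocorrelation. Passing tests therefore demonstrate correctness of the
algorithms and recovery of designed effects, not field realism of every
summary statistic.

Typical problem sizes used in the test suite are scaled down (30–50
samples, 40–150 taxa, 49–999 null replicates depending on what the test
probes); the acceptance script runs the full default design with 999 null
replicates and 100 bootstraps.

# Degenerate inputs and numerical conventions

* Fewer than 2 present taxa: MPD (and SES) are missing with a warning.
* Null sd < 10⁻¹²: SES missing with a warning.
* Zero positive cohesion: ratio missing with a warning.
* Fewer than 2 connected taxa: complementarity 0.
* Empty subgraph: all topology metrics 0 with a warning.
* All-tied group values: H = 0, p = 1, a single shared letter.
* Collinear predictors: `lm.fit` drops columns with a warning; the R² sum
  identity still holds.
* Correlations are clipped to [−1, 1]; basis variances floored at 10⁻¹⁰.
* Ties in greedy modularity and bin traversal are broken by node/tree
  order, never randomly.

# Reproducibility

Every stochastic stage (rarefaction, null replicates, Dirichlet resamples,
bootstraps, the generator) derives its stream from one master seed;
`run_pipeline()` is bit-reproducible for a fixed configuration and writes a
YAML manifest with inputs, parameters, package versions and collected
warnings. The expensive SparCC + bootstrap stage is cached keyed on a
content hash of the rarefied table and parameters, so re-runs with
unchanged upstream inputs reuse it.

# Known limitations

* SparCC assumes sparse true correlation structure; in the strongly
  niche-structured synthetic communities many true correlations are
  non-zero, so the meta-network is denser than typical field networks and
  subnetwork size approaches sample richness.
* The complementarity proxy inherits the branch-length scale of the input
  tree; comparisons are only meaningful within one tree.
* Bootstrap p-values are granular (multiples of 1/(n_boot+1)); at 100
  bootstraps the only value below .01 is 1/101.
* The independent swap preserves occupancy margins but not column
  abundance totals; this is the standard formulation and is what makes
  SES_MPD richness-independent.
* Hierarchical partitioning enumerates 2^k subsets; it is intended for a
  handful of predictor groups, not high-dimensional variable selection.
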