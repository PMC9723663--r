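# roseonet

Linking a reference-defined bacterial guild — the marine Roseobacter
group (MRG) — to DMSP-producing phytoplankton in 16S/18S rRNA amplicon
time series.

Marine Roseobacters are copiotrophic bacteria whose blooms often track
phytoplankton that synthesise dimethylsulfoniopropionate (DMSP), a key
organosulfur currency of the surface ocean. Testing that association in
situ means working with two ASV count tables (16S for bacteria, 18S for
eukaryotic phototrophs) sampled monthly at multiple oceanographic sites,
and asking three questions: *who is in the guild*, *who makes DMSP*, and
*do they co-occur in space and season*. `roseonet` implements that
analysis end to end, for microbial ecologists who have amplicon
time-series data (or want to study the method's behaviour on synthetic
communities with known ground truth).

## What it computes

| Stage | Method | Key rule |
|---|---|---|
| Guild screen | global-alignment identity of 16S ASVs vs a dereplicated guild reference library | member iff identity ≥ 0.89 (inclusive) |
| Trait placement | Jukes–Cantor ML placement of 18S ASVs on a trait-labelled reference phylogeny | producer iff cumulative like-weight ratio ≥ 0.90; HiDP/LoDP split at 50 mM intracellular DMSP by genus |
| Seasonality | Bray–Curtis time-lag pools + Mantel correlogram | seasonal iff Kruskal–Wallis q < 0.05 and same-season pairs more similar |
| Co-occurrence | MICe/TICe (equicharacteristic-matrix estimators, `B(n) = n^0.6`) + Spearman rho | edge significant iff TICe > 0 and MICe ≥ 0.178; strong iff also rho > 0.6 |

The MICe/TICe engine is implemented in C++ and verified against
exhaustive partition enumeration; the placement engine is verified
against direct ancestral-state summation; ANOSIM p-values are exact
(full label enumeration) on small designs. The statistic for a pair
`(x, y)` is the maximal normalised mutual information

    MICe = max over grids (k x l), k*l <= n^0.6, of I(x, y; G) / log min(k, l)

with one axis mass-equipartitioned and the other optimised by dynamic
programming; TICe sums the same matrix.

## Worked example

Simulate three sites x 36 months with a latitudinal seasonality gradient
and sparse guild-to-HiDP couplings (0.8) against a 0.3 background, then
run seasonality and the network:

```r
library(roseonet)

cls   <- producer_class_layout(30, trait_fraction = 0.6, hidp_fraction = 0.45)
guild <- rep(c(TRUE, FALSE), each = 20)
cfg   <- simulation_config(n_bact_asvs = 40, n_phyto_asvs = 30,
                           trait_fraction = 0.6, hidp_fraction = 0.45,
                           guild_fraction = 0.5, seed = 42)
cfg$coupling_matrix <- guild_class_coupling(guild, cls, 0.8, 0.3, seed = 42)
sim <- generate_time_series(cfg)

seas <- site_seasonality(sim$bact, sim$metadata, analysis_config(top_k = 20))
edges <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                       sim$truth$producer_class)
gsum <- guild_mean_comparison(edges)
```

Output (abridged):

```
site01: seasonal=FALSE (H=0.0, q=1)          # amplitude 0  (tropical end)
site02: seasonal=FALSE (H=2.6, q=0.316)      # amplitude 0.75
site03: seasonal=TRUE  (H=81.5, q=5.16e-19)  # amplitude 1.5 (temperate end)

   guild class mean_rho sd_rho n_edges
1    MRG  HiDP    0.215 0.1390      91
2    MRG  LoDP    0.182 0.1203      52
6 nonMRG  LoDP    0.169 0.1125      72
...
top cell: MRG:HiDP   omnibus: KW_H p = 1.69e-06
```

The temperate site is flagged seasonal while the flat site is not, and
the guild-by-class comparison puts the planted MRG:HiDP cell on top: mean
Spearman rho over significant positive edges is highest where the strong
couplings were planted, and the Levene-gated omnibus test (here the
Kruskal–Wallis branch) confirms the cells differ.

`run_pipeline(pipeline_config(...), out_dir)` chains all stages —
simulate, screen, classify, seasonality, statistics, network, report —
writing TSV/FASTA/Newick/GraphML artifacts plus a JSON report; reruns
with the same configuration and seed are byte-identical. A thin CLI
wrapper lives in `inst/scripts/roseonet-cli.R`.

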