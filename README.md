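# follinet

Network-theoretic analysis of **in vitro folliculogenesis (ivF)
signaling**, for reproductive biologists and systems biologists who work
with literature-curated interaction databases.

The ivF literature across mammalian models can be curated into a table of
directed molecular interactions — *source molecule, interaction, target
molecule/event, species, PMID* — and analysed as a directed signaling
network. `follinet` implements that analysis as a reusable, tested
pipeline:

* **Database handling** — read/validate the five-column table, collapse
  duplicates, report species incidence, build a simple directed graph
  (parallel edges merged, self-loops dropped), export SIF / GraphML /
  edge lists.
* **Topology** — node/link/component counts, mean local clustering,
  characteristic path length, mean neighbors, and log–log OLS power-law
  fits of the degree distributions (slope Γ, R, R²) — the scale-free
  diagnosis.
* **Controllers** — hubs by the degree rule γ > μ + σ (population σ over
  all nodes); bottlenecks by the shortest-path-tree score
  BN(v) = Σₛ pₛ(v), where pₛ(v) = 1 iff more than |V(Tₛ)|/4 tree paths
  rooted at s meet at v; and their intersection **hub.BN**, the
  network's controllers.
* **Stratification** — each node's in/out degree ratio
  DR_io = 100·γ_IN/(γ_IN+γ_OUT) bands the network into input
  ([0,36)), processing ([36,68)) and output ([68,100]) layers.
* **Attack experiments** — iterative targeted removal of the most
  connected nodes (default 2.5% per cycle, two cycles) versus a matched
  random control, with giant-component tracking and collapse detection.
* **KDE subpopulations** — 1D/2D Gaussian kernel density estimation with
  prominence-merged mode detection, subpopulation assignment and
  isolated-point flagging (e.g. hub.BN in the degree × BN-score plane).
* **Synthetic databases** — a layered preferential-attachment generator
  that emulates the curated table's statistical structure (scale-free
  degrees, curated species incidence, planted input/processing/output
  layers), so the full pipeline is testable end to end.

## Worked example

```r
library(follinet)

# a curated-scale synthetic database: 641 nodes, 2086 links,
# curated mammal-model incidence
gen <- synthetic_database(synthetic_spec(seed = 11))
net <- build_network(gen$db)
topology_summary(net)
#> Network topology
#>   Number of nodes:                641
#>   Number of links:                2086
#>   Number of connected components: 1
#>   Clustering coefficient:         0.054
#>   Char. path length:              3.302
#>   Avg. number of neighbors:       6.509
#>   In degree : Gamma = -1.562, R = -0.948, R^2 = 0.899
#>   Out degree: Gamma = -1.714, R = -0.935, R^2 = 0.874
```

One weakly connected component and high-R² power-law degree fits: a
scale-free network with a hyperconnected minority. Who controls it?

```r
find_controllers(net)
#> Controllers of a 641-node network
#>   hubs:        56 (8.7%)  [degree > mu + sigma = 6.51 + 8.56 = 15.07]
#>   bottlenecks: 56 (top-56 by BN score)
#>   hub.BN:      45; controller union 10.5% of the network
```

A few percent of nodes are hubs (the curated reference reports 38/641 =
5.9% hubs and a 7.2% controller union). Removing them is what hurts:

```r
tgt <- targeted_attack(net, fraction = 0.025, cycles = 2)
rnd <- random_attack(net, n_per_cycle = lengths(tgt$removed), cycles = 2, seed = 7)
c(targeted = tail(tgt$giant_fraction, 1), random = tail(rnd$giant_fraction, 1))
#> targeted   random
#>    0.800    0.942
```

Two cycles of targeted 2.5% hub removal cost the giant component five
times as much as the same number of random deletions — the scale-free
robust-yet-fragile signature.

```r
st <- stratify_network(net, find_controllers(net))
st$composition
#>             controller_class
#> layer        hub  BN hub.BN other
#>   input        3   5     12   252
#>   processing   3   5     18   134
#>   output       5   1     15   188
```

The DR_io bands recover the planted signal flow: 88% of the generator's
ground-truth input-layer nodes land in the input stratum.

## The analysis workflow

Numbered drivers under `analysis/` run the full study over a generated
curated-scale database and write their tables under `results/`:

```sh
Rscript analysis/01_build_database.R     # database + species incidence
Rscript analysis/02_network_topology.R   # topology summary, SIF export
Rscript analysis/03_controllers.R        # centralities, hubs/BN/hub.BN
Rscript analysis/04_stratification.R     # DR_io layers x controller classes
Rscript analysis/05_attack_experiment.R  # targeted vs random, 20 replicates
Rscript analysis/06_subpopulations.R     # 1D and 2D KDE of the controllers
Rscript analysis/07_full_pipeline.R      # all of the above behind one config
```

`run_pipeline()` (script 07) executes every stage behind a single seeded
config and writes a manifest with per-file MD5 hashes; reruns with the
same config are byte-identical.

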