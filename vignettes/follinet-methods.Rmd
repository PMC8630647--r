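---
title: "Network-theoretic analysis of in vitro folliculogenesis signaling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-theoretic analysis of in vitro folliculogenesis signaling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follinet)
```

## The problem

In vitro folliculogenesis (ivF) — growing ovarian follicles and maturing
oocytes in culture — is documented by a large, scattered literature across
mammalian models. One productive way to organize that evidence is to curate
every reported molecular interaction into a table (source molecule,
interaction, target molecule/event, species, PMID) and analyse the result
as a directed signaling network: molecules and follicular events are nodes,
curated interactions are directed links. The questions the network answers
are structural: which few molecules control the system (hubs,
bottlenecks), how does signal flow from systemic hormones down to
follicular outcomes (layer stratification), and how fragile is the system
to losing its controllers (attack experiments)?

`follinet` implements that analysis pipeline end to end, together with a
synthetic-database generator that emulates the statistical structure of
such a curated table, so every stage is fully testable without the
curated file, which has no public accession.

## The network substrate

`build_network()` turns the record table into a *simple* directed graph:

* one edge per distinct ordered (source, target) pair — parallel records
  merge their interaction labels, species and PMIDs onto the edge. A
  simple graph is required for normalized betweenness, and it is what a
  single reported link count refers to;
* self-loops are dropped (path-based metrics and local clustering are
  undefined on them);
* node identity is the canonicalized name string (whitespace-trimmed and
  collapsed, case preserved). No synonym resolution is attempted: merging
  curated names is curation, not computation.

Distance-based measures (components, characteristic path length, neighbor
counts, clustering, closeness, betweenness, bottleneck trees) default to
the **undirected projection** of the graph. A curated signaling network of
this kind is reported as one connected component with well-defined
closeness for every node, which is only consistent with undirected
distances — a strictly layered directed graph would have unreachable pairs
everywhere. Degree-based measures (the hub rule, DR_io, attack targeting)
always respect direction. Directed variants of the distance-based
measures are available behind `mode = "out"` / `directed_distances =
TRUE` for sensitivity analysis.

## Topology

`topology_summary()` reports node/link counts, weak components, mean local
clustering (nodes with fewer than two neighbors contribute 0 and stay in
the denominator — one convention has to be fixed, and this one keeps the
mean over *all* nodes), characteristic path length over connected pairs,
mean distinct-neighbor count, and power-law fits of both degree
distributions.

`powerlaw_fit()` is ordinary least squares on the log–log
degree-frequency table (degree 0 dropped), the convention of Cytoscape's
Network Analyzer — the tool this analysis style comes from — rather than a
maximum-likelihood tail fit. The slope is the exponent $\Gamma$, and $R^2$
of the fit doubles as the "still scale-free?" diagnostic during attack
experiments. Distributions with fewer than three distinct positive
degrees are reported as unfittable (`NA` in summaries, an error when
called directly).

## Controllers

**Hubs** are nodes whose total degree $\gamma = \gamma_{IN} +
\gamma_{OUT}$ strictly exceeds $\mu + \sigma$, with $\mu$ and $\sigma$
the mean and *population* (divide-by-$n$) standard deviation over all
nodes. The population form is the convention in descriptive network
statistics; at several hundred nodes the difference from the sample form
is negligible, but it is fixed and documented so results are exactly
reproducible.

**Bottlenecks** use the shortest-path-tree score
$BN(v) = \sum_{s} p_s(v)$: for each root $s$ one shortest-path tree
$T_s$ is built, and $p_s(v) = 1$ iff more than $|V(T_s)|/4$ of the tree
paths from $s$ meet at $v$. Two conventions had to be fixed:

* *Tree choice.* Shortest-path trees are not unique. The parent of $v$ is
  defined as the lexicographically smallest neighbor of $v$ one
  breadth-first layer closer to the root. This rule is deterministic and
  declarative — it does not depend on traversal-queue mechanics — which
  makes it easy to verify independently; the package also exposes
  `neighbor_order = "revlex"` so the sensitivity of scores to the tree
  choice can be measured (scores may differ; both are well defined).
* *"Meet at $v$".* A path counts as meeting every vertex it passes
  through **including its endpoint** (`count_endpoint = TRUE`), which
  makes the count for $v$ exactly the size of the subtree rooted at $v$ —
  the published subtree-size implementation of this score. The strict
  interior reading is available via `count_endpoint = FALSE`. Under the
  default, each endpoint of a single-edge graph scores $BN = 1$ (subtree
  size 1 exceeds $|V(T_s)|/4 = 1/2$ from the opposite root); this was
  settled by an explicit tree-materializing oracle, not by hand.

The bottleneck *set* is the top-$k$ by score, with $k$ defaulting to the
hub count (the tool asks its user for a top-$N$; matching the hub count
reproduces the convention under which hub and bottleneck sets have equal
size). Ties at the cutoff break by higher total degree, then name.
**hub.BN** — the intersection — are the controllers; the union's share of
the network is the controller percentage.

## Layer stratification

DR_io maps each node's link balance to $[0, 100]$. The printed form of
the ratio ($\gamma_{IN}/\gamma_{OUT} \times 100$) is unbounded and cannot
be banded into 0–100 intervals, so the package uses the only reading
consistent with the published bands: the **in-fraction**

$$DR_{io} = 100\cdot\frac{\gamma_{IN}}{\gamma_{IN} + \gamma_{OUT}},$$

which sends pure sources (hormone-like inputs) to 0 and pure sinks
(terminal follicular events) to 100. The integer bands 0–35 / 36–67 /
68–100 generalize to half-open real intervals $[0,36)$, $[36,68)$,
$[68,100]$ — DR_io is generally non-integer and the boundary treatment
has to be declared. Note the bands are asymmetric by construction (the
input band is 36 units wide, the output band 33), so reversing every edge
mirrors DR_io exactly ($dr \mapsto 100 - dr$) but swaps layer labels only
outside the narrow mismatch zones $[32,36)$ and $(64,68]$. Isolated
nodes (no links) have undefined DR_io and are excluded, with a count.

## Attack experiment

`targeted_attack()` removes, per cycle, the $\lceil f \cdot n \rceil$
highest-total-degree survivors ($f = 0.025$, 2 cycles by default; ties by
higher BN score, then name) and re-examines the topology after each
cycle. The per-cycle removal count is a fraction of *current nodes*: at
curated scale that is ~16 nodes per cycle, the only reading under which
two cycles remove enough material to threaten the network (2.5% of the
~38 hubs would remove a single node). `random_attack()` removes the same
per-cycle counts uniformly at random (mandatory seed) — the matched
control that isolates the effect of targeting.

`detect_collapse()` declares collapse when the giant weak component falls
below 50% of the original node count, or when the total-degree
distribution stops supporting a power law ($R^2 < 0.5$, or unfittable
when it was fittable before the attack). Both thresholds are declared
package definitions — the qualitative claim they quantify is "the
topology was destroyed" — and both are arguments.

A limitation worth stating plainly: on synthetic scale-free networks of
the emulated density (641 nodes, 2086 links, mean degree ~6.5), two or
three cycles of 2.5% targeted removal *damage* the giant component
markedly relative to the random control (the paired comparison is the
tested, reproducible form of the fragility claim) but do **not** drive it
below 50%: no graph of that density loses half its giant component to a
≤7.5% node removal. The boolean collapse verdict therefore stays `FALSE`
on the synthetic networks even where a curated network with a more
star-like periphery might genuinely shatter.

## KDE subpopulations

`kde_estimate()` is a product Gaussian kernel on a regular grid (≥128
points per axis, padded 3 bandwidths beyond the data range). Bandwidths
default to Silverman's rule per dimension,
$h_j = 0.9\,\min(s_j, IQR_j/1.34)\, n^{-1/(d+4)}$, floored at
$10^{-6}$ of the range for degenerate dimensions. Per-dimension
bandwidths make the estimate adapt to each axis' scale, so axes with
incommensurate units (node degree vs. BN score) are weighted as they
would be after z-standardization while all coordinates stay on their
original scale.

`find_subpopulations()` segments the density surface into basins of
steepest ascent (a descending sweep over grid cells; each cell joins the
basin of its highest neighbor, which is exactly the basin structure of
discrete gradient ascent). Three declared rules keep the segmentation
honest about sampling noise:

* *Prominence.* Two adjacent basins remain distinct only if the saddle
  between them dips below `merge_ratio` (default 0.5) of the lower peak;
  otherwise the shallower mode is a bump on its neighbor and merges.
  Without this, Silverman-bandwidth KDE of a few dozen points routinely
  splits one Gaussian cluster into noise bumps.
* *Isolation.* The low-density level is `density_quantile` (default 5%)
  of the peak density; points whose own density falls below it are
  isolated, and modes below it are discarded.
* *Group size.* A basin holding fewer than `min_members` (default 2)
  points is not a population — its points are reclassified as isolated.
  This matches the analysis' own semantics, where single detached
  controllers are reported as "isolated nodes", distinct from
  subpopulations. (If *every* basin is a singleton — e.g. two lone,
  well-separated points — they are kept, since there is no larger
  population to be detached from.)

The pipeline applies the 1D path to hub clustering coefficients (is the
hub population homogeneous?) and the 2D path to hub.BN in the degree ×
BN-score plane (do the top controllers split into groups, and which sit
isolated at extreme values?).

## The synthetic database generator

`generate_layered_scalefree()` grows a graph by preferential attachment
(attachment probability $\propto$ degree$^{\alpha}$, $\alpha = 1$ by
default — the scale-free regime), with defaults mirroring the curated
database it stands in for: 641 nodes, 2086 links, species annotations
drawn from the curated literature's mammal-model incidence (Rodent
39.17%, Ovine 17.2%, Bovine 13.7%, …), and three ground-truth signal
layers drawn per node (input 0.30 / processing 0.25 / output 0.45 —
qualitative proportions with a large output stratum, exposed as config).

Two generator choices deserve explanation:

* *Per-node link counts are geometric*, with mean set by the edge budget
  (~3.3), not constant. A constant-$m$ growth process gives every node
  minimum degree 3; curated literature networks instead have a
  degree-1-dominated periphery (most molecules appear in one curated
  interaction), and the geometric draw reproduces that shape while
  landing exactly on the target edge count.
* *Directions follow layers.* Each node has a layer-dependent emission
  propensity (input 0.9, processing 0.5, output 0.1); an edge between
  $u$ and $v$ points $u \to v$ with probability
  $p_u(1-p_v) / [p_u(1-p_v) + p_v(1-p_u)]$. Input-layer nodes therefore
  emit, and output-layer nodes receive, the large majority of their
  links, giving the DR_io stratification a planted truth to recover.
  This direction structure is an artifact invention — the real curated
  network has it only implicitly.

What the generator does *not* emulate: curated name vocabularies (nodes
are opaque labels), the local clustering created by co-citation of
related molecules (synthetic clustering ≈ 0.05 vs. the curated ~0.08),
the longer curated path lengths (~5.7 vs. ~3.3 here — preferential
attachment builds shortcuts curation does not), and freely diffusible
molecules (H₂O, CO₂), which curation removes and the generator never
creates. Tests passing on synthetic data therefore validate the
*machinery* (metrics, selection rules, experiment bookkeeping) and the
recoverability of planted structure; they do not certify the curated
network's specific metric values.

## Determinism and numerics

* Every stochastic stage takes an explicit seed; the pipeline fans one
  root seed out to stages by fixed offsets. Same config, same bytes: the
  manifest's per-file MD5 hashes are reproducible.
* Numbers in TSV/JSON outputs are written at 6 significant digits.
* BFS-tree parent selection, bottleneck tie-breaks (score, then degree,
  then name) and attack tie-breaks (degree, then BN score, then name)
  are all total orders, so no output depends on hash or insertion order.
* Problem sizes used by the test-suite simulations — 200 random oracle
  graphs at $n \le 10$, 20-seed replicates at 300–641 nodes for
  stratification and attack, 60 planted-cluster KDE runs — were chosen
  as the smallest sizes at which the tested properties are
  non-degenerate and stable.

## Known limitations

* The hub threshold $\mu + \sigma$ is scale-sensitive: adding isolated
  nodes lowers both $\mu$ and $\sigma$ and can admit new hubs; the
  package recomputes rather than asserts monotonicity.
* BN scores depend on the (declared) tree rule; CytoHubba-style tools do
  not publish theirs, so cross-tool score identity is not guaranteed —
  rankings are typically stable, exact scores need not be.
* The OLS log–log power-law fit is a tool convention, not a rigorous
  tail estimator; its $\Gamma$ should be compared only with values
  produced the same way.
* The boolean collapse verdict on dense synthetic networks is
  conservative (see the attack section); the paired targeted-vs-random
  comparison is the robust form of the fragility result.
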