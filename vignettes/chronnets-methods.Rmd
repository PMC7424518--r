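---
title: "Chronological networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronological networks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronnets)
```

## The model

A chronnet is a graph representation of an event stream
$X = \{e_1, \dots, e_T\}$, each event $e_a = (l_a, t_a)$ a located,
timestamped point. Space is divided into grid cells; cells with events are
nodes. A directed link $(v_i, v_j)$ is added for every ordered event pair
$(e_a, e_{a+g})$ with lag $1 \le g \le h$ whose events fall in cells $i$
and $j$ (and, when a cutoff $d_{\max}$ is set, whose spatial distance is
$\le d_{\max}$). The weight $w_{ij}$ counts such pairs; $i = j$ gives
self-loops counting consecutive events inside a cell. All analyses default
to the undirected aggregation $w_{ij} + w_{ji}$, window $h = 1$, and no
distance cutoff — the simplest configuration, and the one all of the
package's validated behavior is stated for. The construction is a single
pass over the sorted events, so cost is linear in $T$ at fixed $h$.

The modelling assumption worth stating explicitly: *temporal adjacency is
evidence of association*. A single consecutive pair is weak evidence —
hence weak links, and the pruning step ($w \le \tau$ removed) that keeps
only recurrent patterns. Pruning is optional and data-dependent: densities
fall quickly even for small $\tau$, and too large a $\tau$ disconnects the
graph, so the package reports isolated-node counts and computes path
statistics on the largest component with an explicit coverage figure.

### Parallel events

Real streams contain same-timestamp events. The package groups events by
*successive distinct timestamps present in the data* and links every cell
with an event in one group to every **different** cell in the next group
(one weight unit per cell pair per group pair). Two deliberate readings are
embedded here:

* **Lag over groups, not raw clock values.** If a time step has no events,
  the chain does not break; when all timestamps are distinct the rule
  reduces exactly to the consecutive-pair rule. This keeps one code path
  and one semantics for both regimes.
* **Same-cell pairs across parallel groups are excluded** (the combination
  rule is over different cells); under the plain consecutive rule
  (singleton groups) a same-cell pair is a legitimate self-loop. The flag
  `parallel_self_loops = TRUE` restores self-loop counting across parallel
  groups for users who want uniform loop semantics.

Events are deduplicated to cells within a group: links count *node*
combinations, so a cell firing twice in one step contributes once to each
cross link. With a distance cutoff active, the first event of a cell in a
group serves as its representative position; for singleton groups (the
only case exercised quantitatively) this is exact.

### Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `h` | max sequence lag linked | 1 | window mode links all lags `1..h`; `mode = "exact"` links only lag `h` |
| `d_max` | max distance for a link | none | units of the coordinates (planar) or km (lonlat/haversine) |
| `tau` | prune links with weight ≤ τ | 0 | nodes are kept when isolated |
| `delta_t` | snapshot window length | none | windows anchored at the first timestamp; `delta_t` ≥ span gives the single static network |
| grid `nx, ny` | spatial resolution | user's choice | no general rule exists: finer grids give larger, sparser networks; the package never guesses silently |
| `delta` | label-smoothing radius | 1 | odd; see below |

## Measures

Degree $k_i$ counts distinct co-active neighbour cells (self-loops
excluded); strength $s_i = \sum_j w_{ij}$ sums incident weights and — since
the sum runs over $j = i$ — includes self-loop weight once by default
(`self_loops = FALSE` to exclude). The resulting identities, tested
exactly, are $\sum_i k_i = 2|E|$ and
$\sum_i s_i = 2\sum_{i<j} w_{ij} + \sum_i w_{ii}$.

Path-based measures use unweighted hop counts by default (a hop is one
consecutive-event step), computed on the largest connected component.
Weighted closeness maps weight to distance as $1/w$: recurrent links are
short temporal distances, so cells with strong links score high. Global
transitivity is the standard triple-closure fraction with self-loops
ignored.

Tail fitting: the discrete power-law exponent is the Clauset-style MLE
with the lower cutoff chosen by KS minimisation (igraph's `plfit`); the
log-normal alternative is fitted to the *same* tail by left-truncated MLE,
and `tail_fit_comparison()` reports both KS distances. The comparison
deliberately stops short of declaring scale-freeness — a KS-optimal cutoff
deep in a tail leaves few points, where several families fit; with a
user-pinned cutoff (`k_min = 1`) the comparison spans the whole
distribution and discriminates sharply. This is why the package reports
the comparison rather than a verdict.

## Event clustering, smoothing, change points

Communities of the weighted chronnet (fast-greedy agglomerative modularity
with a full dendrogram, or seeded label propagation with restarts) are
groups of cells active in the same periods. Each event inherits its cell's
community, giving the label sequence $C = \{c_1, \dots, c_T\}$; a change
point is any $t$ with $c_t \ne c_{t-1}$.

The correction function $f(C, \delta)$ replaces $c_t$ iff the window
$\{c_{t-\delta}, \dots, c_{t-1}, c_{t+1}, \dots, c_{t+\delta}\}$ (odd
$\delta$, center excluded) holds exactly one unique value. Design choices
that the definition leaves open:

* **Simultaneous application** from the original sequence — the result
  cannot depend on sweep order.
* **Boundaries untouched**: positions without a full window are left as
  is; a conservative choice that never manufactures labels near the edges.
* **Default $\delta = 1$**, the smallest odd radius. It corrects exactly
  the isolated mislabels (one event stranded between two agreeing
  neighbours) while minimising the chance that two nearby mislabels sit in
  each other's windows and block correction — with wider windows that
  blocking becomes more likely, not less, because the rule demands
  unanimity. Genuine regime changes are safe under any $\delta$: their
  windows are mixed.

Fast-greedy ties in modularity are broken toward the *coarsest* partition
so that, e.g., a uniform complete graph is reported as one community
rather than an arbitrary split of equal modularity. Label propagation is
order-dependent, so it is seeded and restarted (default 10), reporting the
run with maximal modularity.

## The synthetic generator

`generate_from_matrix()` realises the emission model: at each step
$t = 1..T$ every cell fires independently with probability $P_{ij}$, and a
fired cell emits one event uniformly inside itself (sub-cell placement is
not part of the model; uniform is the least-informative choice). The
scenario builders compose this into the study conditions:

* `four_period_scenario()` — four equal intervals, activity concentrated
  on successive quadrants of a 20×20 grid at `p_in = 0.02` per cell-step,
  background `p_out = 1e-5` elsewhere, `T = 12000`. The in/background
  probabilities are fixed in the defaults so the experiment is
  reproducible; they are the package's concrete reading of "arbitrarily
  chosen so as to create four temporal clusters plus a few outliers", and
  all are overridable.
* `alternating_gaussians()` — bursts of events from isotropic Gaussians
  ($\sigma = 100$ in a $[0,1000]^2$ domain against a 10×10 grid) cycling
  through 2 or 3 centers; 40 bursts; 25,000 events per burst by default
  (reduced sizes are used in the test suite). Center layouts place
  adjacent centers $\ge 8\sigma$ apart: with closer centers the planted
  clusters genuinely overlap — events land in cells dominated by a
  neighbouring cluster — and the planted labels stop being clean ground
  truth. The overlap regime is reachable by passing custom centers.
* `sample_trajectory()` — Lorenz ($\sigma = 10$, $\beta = 8/3$,
  $\rho = 28$; $x,y$ projection; horizon 200, step 0.01) and Rössler
  ($a = b = 0.2$, $c = 5.7$; $x,z$; horizon 1000, step 0.02) integrated
  with fixed-step RK4 after a 10-time-unit transient from $(1,1,1)$ /
  $(1,1,0)$; the attractor shape is insensitive to the initial point once
  the transient is discarded. Note that step-halving agreement is only
  meaningful over short horizons: chaotic error growth amplifies any
  integration difference exponentially, so the convergence check in the
  tests uses a 2-time-unit horizon.

All generators are seed-deterministic, and scenario builders return their
planted labels so downstream recovery can be scored exactly (ARI).

### What the generator does and does not emulate

It reproduces the statistical skeleton the analyses rely on: per-cell
emission rates of a chosen family (uniform/power-law/exponential),
regime changes in space and time, sparse outliers, deterministic
trajectories. It does **not** emulate measurement artefacts of real data —
duplicate detections from overlapping sensor swaths, spatially correlated
false alarms, varying detection confidence, seasonal drift within a
regime. Passing the recovery tests therefore demonstrates that the method
does what it claims under its own model assumptions, not that any
particular real data set satisfies those assumptions.

## Numerical and interface choices

* **Gridding**: 0-based row-major cell ids; half-open cells with a closed
  top edge per axis, so assignment is total on the bounding box. Grid
  refinement by integer factors preserves coarse ids under integer
  division (tested).
* **Hexagonal global grids**: the package owns only the closed forms —
  $10a^r + 2$ cells for an aperture-$a$ icosahedral hexagonal system at
  resolution $r$, and mean cell area as surface/count (authalic Earth
  area 5.10072×10⁸ km²). Geometry (which hexagon contains a point) is
  delegated to external tools via `load_cell_assignment()`; this keeps the
  package free of geodesic polygon code while remaining grid-agnostic.
* **Timestamps** are an ordered numeric key (integer steps, epoch seconds,
  or parsed ISO dates); only order and differences are used.
* **Bad records** in event files are collected into a line-numbered report
  attached to the returned table; parsing continues. Large raw files
  routinely contain sporadic malformed rows, and silent dropping hides
  data-quality problems.
* **Fire records**: confidence filtering is strict (`> 75`), all type
  codes are kept by default so static sources (volcanoes, gas flares)
  remain visible to outlier detection. Whether multi-satellite records
  should be merged before gridding is left to the data as distributed —
  records are used as provided.
* **Problem sizes in the test suite** are the package's own choices for a
  fast, deterministic suite: 10 seeds at the full `T = 12000` four-period
  setting; Gaussian scenarios at 40×2,500 events; estimator-recovery
  checks at $n = 10^4$; brute-force construction oracles at $T \le 200$;
  exhaustive path/centrality oracles at $n \le 50$.
* **Assumption for the fire study configuration**: global path length and
  transitivity figures are computed on the pruned ($\tau = 2$) network's
  largest component; the checked-in `fire_pipeline.yaml` records this
  together with the other settings (top 20% strongest links and top-1%
  degree outliers removed before community detection).

## Known limitations

* The parallel-event combination rule weights cell pairs, not event
  pairs; heavily parallel streams with within-step multiplicities are
  summarised more coarsely than a per-event rule would.
* `d_max` with parallel groups uses representative event positions (exact
  only for singleton groups).
* Community methods are modularity-based and inherit its resolution
  limit; very small regimes may merge into larger communities.
* The label-correction rule fixes isolated mislabels only; bursts of
  consecutive mislabels (e.g. from genuinely overlapping clusters) are
  left, by design — they are signal about cluster overlap, not noise.
* Snapshot layers are independent static chronnets; cross-layer analytics
  (temporal-network measures) are out of scope.
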