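# smallworldnet

Graph-theoretic small-world analysis of functional brain connectivity, for
researchers who start from regional BOLD time series (e.g. 90 AAL-atlas
regions) and want to know whether — and at which correlation thresholds —
the resulting binary networks are organized as small worlds, and whether two
groups or conditions differ.

## What it computes

From a region × time matrix per subject:

1. **Connectivity** — zero-phase Butterworth band-pass (0.01–0.08 Hz),
   optional nuisance regression, Pearson correlation matrix with zeroed
   diagonal, and binarization: an edge joins regions *i* ≠ *j* when
   |r<sub>ij</sub>| ≥ T, swept over T = 0.225, 0.250, …, 0.550. The lower end
   of the grid respects the connectivity bound K<sub>net</sub> ≥ 2 ln N ≈ 9
   for N = 90.
2. **Indicators** — for each binary network the six standard measures, each
   the node mean over all N nodes: clustering coefficient C<sub>net</sub>
   (C<sub>i</sub> = 2t<sub>i</sub>/(K<sub>i</sub>(K<sub>i</sub>−1))), average
   path length L<sub>net</sub>, global efficiency E<sub>glob</sub>
   (mean of (1/(N−1)) Σ 1/d<sub>ij</sub>), local efficiency E<sub>loc</sub>
   (efficiency of each node's neighbour-induced subgraph), and mean degree
   K<sub>net</sub>.
3. **Null models** — 100 degree-matched random networks per graph via
   Markov-chain double-edge swaps (10 successful swaps per edge;
   conflicting proposals aborted), giving C<sub>random</sub> and
   L<sub>random</sub> and the small-world indices
   γ = C<sub>net</sub>/C<sub>random</sub>,
   λ = L<sub>net</sub>/L<sub>random</sub>, σ = γ/λ; σ > 1 is the
   small-world signature.
4. **Statistics** — per threshold and indicator: Box-Cox transform toward
   normality (pooled ML λ), two-sample t-test, Bonferroni correction across
   the 14-threshold family, reported as mean ± SD curves plus a comparison
   table.

A synthetic-data module generates multi-subject, block-modular ROI series
(90 regions × 150 volumes at TR = 2 s, 11 subjects/group by default) with a
controllable between-group density effect, so the whole pipeline runs and is
tested without any imaging data. See
`vignettes/smallworld-pipeline.Rmd` for the methods account.

## Worked example

```r
library(smallworldnet)

ws <- generate_benchmark_graph("watts_strogatz", n = 90, k = 10, p = 0.1,
                               seed = 20260928)
m <- network_metrics(ws)
ens <- ensemble_summary(ws, n_random = 100, target_swaps_per_edge = 10,
                        seed = 20260929)
small_world_index(m$C_net, ens$C_random, m$L_net, ens$L_random)
```

Running `Rscript analysis/05_smallworld_benchmarks.R` (the same computation
plus an Erdős–Rényi control) prints:

```
                        graph  C_net L_net C_random L_random gamma lambda sigma
1 watts_strogatz_n90_k10_p0.1 0.4974 2.631  0.09511    2.171 5.230 1.2121 4.315
2        erdos_renyi_n90_p0.2 0.2066 1.803  0.20536    1.805 1.006 0.9989 1.007
```

Read: the Watts–Strogatz graph keeps lattice-like clustering (γ ≈ 5.2) at
near-random path length (λ ≈ 1.2), hence σ ≈ 4.3 ≫ 1 — a small world. The
Erdős–Rényi control is statistically indistinguishable from its own
degree-matched nulls (σ ≈ 1).

The full pipeline is organised as numbered drivers under `analysis/`:
`01_simulate.R` (two synthetic groups, the "left" one with a +0.1
within-module correlation shift), `02_connectivity.R` (filtering +
correlation matrices), `03_threshold_sweep.R` (indicators and per-subject
null ensembles over the 14 thresholds), `04_group_comparison.R` (mean ± SD
curves; Box-Cox + t-test + Bonferroni per threshold), and
`05_smallworld_benchmarks.R`. Each stage writes tab-delimited tables and a
JSON manifest under `results/`. On the default synthetic dataset stage 04
prints:

```
K_net : significant at T = 0.425, 0.45, 0.475, 0.5, 0.525, 0.55
sigma : no Bonferroni-significant threshold
C_net : significant at T = 0.25, 0.275, 0.3, 0.325, 0.35, 0.375, 0.4, 0.425, 0.45, 0.475, 0.5, 0.525, 0.55
E_glob: no Bonferroni-significant threshold
```

i.e. the simulated +0.1 within-module correlation shift is detected as a
denser, more clustered "left" network at mid-to-high thresholds, while σ
does not separate the groups on this dataset.

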