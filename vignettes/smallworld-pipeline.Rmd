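---
title: "Small-world analysis of thresholded functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world analysis of thresholded functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A functional brain network is built from regional BOLD time series in four
steps. Each region's series is band-pass filtered (0.01–0.08 Hz by default,
the conventional slow-fluctuation band at TR = 2 s), nuisance signals are
regressed out, Pearson correlations are computed between every pair of
regions with the diagonal forced to zero, and the correlation matrix is
binarized: regions *i* ≠ *j* are joined by an (unweighted, undirected) edge
whenever |r~ij~| ≥ T. Because the network analysis is binary, the sign of a
strong correlation is deliberately discarded; a strongly anti-correlated
pair is still a connection.

No single threshold T is privileged, so everything downstream is swept over
a grid — 0.225 to 0.550 in steps of 0.025 (14 values) by default. The lower
end of that range is tied to the heuristic connectivity bound K~net~ ≥
2 ln N (≈ 9 for N = 90 regions): below it a sparse random graph is no
longer almost surely connected, and sweep rows whose mean degree falls under
the bound carry a `below_bound` flag.

For each binarized network six indicators are computed, each a node-level
quantity averaged over all N nodes:

* degree K~i~ and its mean K~net~ (density);
* clustering coefficient C~i~ = 2t~i~ / (K~i~(K~i~−1)), with t~i~ the edge
  count among node *i*'s neighbours, and its mean C~net~ (cliquishness);
* average shortest path L~i~ (mean over partners reachable from *i*) and its
  mean L~net~;
* nodal efficiency E~g,i~ = (1/(N−1)) Σ~j≠i~ 1/d~ij~ and its mean E~glob~
  (with 1/∞ := 0 for unreachable pairs);
* local efficiency E~loc,i~, the mean inverse distance *within the subgraph
  induced by node i's neighbours* (not within the full graph), and its mean
  E~loc~.

Small-worldness is judged against degree-matched random graphs: 100
independent randomizations of each network by the double-edge-swap Markov
chain (pick two edges at random, cross their endpoints, abort if a self-loop
or duplicate would arise), run to 10 successful swaps per edge. With
C~random~ and L~random~ the ensemble means,

γ = C~net~ / C~random~, λ = L~net~ / L~random~, σ = γ / λ,

and σ > 1 is the small-world signature: lattice-like clustering at
random-graph path lengths.

Group comparison runs per threshold and per indicator: a Box-Cox transform
toward normality, a pooled two-sample t-test, and Bonferroni correction with
the threshold grid as the family (m = 14 by default; metrics are corrected
separately, mirroring per-panel starring of threshold curves).

## What the synthetic generator emulates — and what it does not

The pipeline ships a generator in place of non-deposited fMRI recordings.
Each subject is an independent draw from a multivariate normal with unit
variances and a block-modular correlation matrix: `within_r` (default 0.5)
inside each of `n_modules` (default 6) contiguous modules, `between_r`
(default 0.1) across modules. Default dimensions mirror a single-site task
study: 90 regions, 150 retained volumes at TR = 2 s (155 acquired in 310 s,
first 5 dropped), 11 subjects per group. Group B's within-module correlation
is shifted additively by `group_effect`; a positive shift makes its
thresholded networks denser, reproducing the direction of a
left-versus-right-hand density difference. An additive shift was chosen over
a multiplicative one because it keeps the effect size in correlation units —
the same units as the threshold grid — and cannot change sign.

The generator targets second-order statistics only, because the pipeline
consumes nothing else: there is no hemodynamic response model, no spatial
structure, no scanner drift, no motion, and subjects within a group are
exchangeable. Temporal autocorrelation is off by default; when enabled, one
AR(1) coefficient is applied identically to every region (innovations
rescaled to unit marginal variance), which leaves the lag-0 cross-correlation
targets exact — the property the construction was chosen for. Consequently,
passing tests show that the *graph-theoretic and statistical machinery* is
correct and calibrated for data whose correlation structure is as specified;
they do not validate the preprocessing choices against physiological noise,
motion artefacts, or spatially autocorrelated parcellations in real
recordings. Module count 6 (≈ 15 regions each) is a plausibility choice, not
an empirical estimate: it gives non-trivial clustering at the 90-node scale.

The six-module default with `within_r = 0.5`–0.7 produces binarized networks
that are themselves small-world against their rewired nulls (σ > 1 at
mid-range thresholds), so the full pipeline can be exercised end to end on
synthetic input.

## Numerical and design choices

* **Filter.** The band-pass family is not dictated by the model; a zero-phase
  forward-backward Butterworth of order 4 is used, standard resting-state
  practice. Zero-phase matters because a phase shift would decorrelate
  series relative to one another. Each series is demeaned before filtering —
  DC is outside the band by construction, and removing it first keeps the
  forward-backward pass free of large edge transients. Series must be
  comfortably longer than the filter warm-up (a few dozen samples); shorter
  input is a hard error rather than a silent artefact.
* **Tie rule.** An edge is kept at exact equality |r| = T ("less than the
  threshold" is what removes a connection).
* **Disconnected graphs.** The path-length formula is undefined for
  unreachable pairs. L~i~ therefore averages over reachable partners only; a
  node with none has undefined L~i~ and is excluded from L~net~; the
  `connected` flag and the K~net~ < 2 ln N flag surface the affected rows so
  they can be masked rather than silently mixed in. Efficiencies use
  1/∞ = 0 and need no masking. Degree-0/1 nodes have C~i~ = 0 and
  E~loc,i~ = 0 by convention (their denominators vanish).
* **Rewiring pairing.** When two edges (i₁,j₁), (i₂,j₂) are selected, there
  are two degree-preserving crossed pairings. The chain proposes both with
  equal probability: fixing one pairing relative to a canonical edge
  orientation makes the chain irreversible, and measurably biases it — the
  clustering of rewired dense random graphs collapses to roughly a third of
  the degree-matched expectation. With random pairing the package's nulls
  agree with igraph's independent rewiring implementation.
* **Null ensembles.** 100 networks per ensemble, 10 successful swaps per
  edge, attempt cap 100× the target, all configurable. Each null runs on its
  own sub-seed drawn once up front, so ensembles are reproducible and the
  per-null chains independent. Ensembles are built per subject per threshold
  (required for subject-level σ statistics); a graph that admits no
  successful swap (e.g. a triangle) triggers an explicit rigidity warning
  and is returned unchanged.
* **Box-Cox lambda scope.** λ is estimated by profile maximum likelihood
  (via `MASS::boxcox`) from the two groups *pooled*, then applied to both.
  Estimating λ separately per group looks natural but puts the two samples
  on different transformed scales; in null simulations that inflated the
  per-threshold false-positive rate from the nominal 0.05 to about 0.7. The
  per-group variant is kept as `lambda_scope = "per_group"` for auditing,
  with the λ values recorded per threshold either way. Non-positive samples
  are shifted by −min + ε before transforming, and the shift is recorded.
* **t-test.** Pooled-variance two-sample t with df = n₁+n₂−2 (Welch variant
  by flag). Two identical constant samples give t = 0, p = 1; unequal-mean
  zero-variance samples are flagged as degenerate rather than silently
  producing NaN.
* **Bonferroni family.** The threshold grid for one metric (m = 14 by
  default). Correcting across metrics as well would be stricter; the
  per-metric family matches the way threshold curves are starred one panel
  at a time.
* **Shortest paths.** Iterated boolean adjacency products: distance k is the
  first power with a nonzero walk count. At N ≤ a few hundred this is faster
  in R than per-node search loops and exact by construction; it is verified
  against a Floyd–Warshall oracle in the tests.

## Problem sizes used in the test suite

Oracle-equivalence tests run 100 random graphs of up to 12 nodes against
brute-force enumeration, exact to 1e−12. The asymptotic ring-lattice
clustering check runs at n = 500, k = 10 (tolerance 1e−3). The small-world
signature check uses the full 100-network ensembles at n = 90. Statistical
calibration runs 200 two-group datasets at the study scale (11 subjects per
group, 90 regions, 150 timepoints) under the null and 200 under a +0.1
within-module effect, on a reduced grid of three thresholds
{0.325, 0.425, 0.525} and the density metric K~net~ (which needs no null
ensembles); the type-I rate is tested with the replicate as the independent
unit, and detection power must reach 80%. The analysis scripts use
n_random = 20 as a desk profile for the per-subject sweep and note that 100
is the full ensemble size.

## Known limitations

* Correlation-level synthesis only: no validation against hemodynamics,
  motion, or atlas geometry; real-data preprocessing (image realignment,
  normalization, ROI extraction) is upstream of this package entirely.
* Binary, undirected networks only — no weighted variants, no partial
  correlation, no Fisher z step.
* The σ index inherits the known sensitivity of C~random~/L~random~ to the
  null ensemble; only degree-matched rewiring nulls are provided (no
  latticization-based ω-type indices).
* The two-sample t-test treats groups as independent samples; for paired
  designs (the same subjects under two conditions) it is conservative in the
  wrong way, and a paired alternative should be preferred — it is not
  implemented here because the group-level interface deliberately mirrors
  the two-sample design.

## A minimal end-to-end run

```{r example}
library(smallworldnet)

cfg <- simulation_config(n_subjects = 11, group_effect = 0.1, seed = 1)
ds <- generate_two_group_dataset(cfg, labels = c("right", "left"))
groups <- lapply(ds, function(set) lapply(set$subjects, correlation_matrix))

sw <- run_sweep(groups, threshold_grid(),
                null_config = list(n_random = 20, seed = 2))
curves <- group_curves(sw)
compare_groups(sw, metric = "K_net", groups = c("left", "right"))
```
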