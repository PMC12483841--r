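---
title: "Methods: minimum-set prioritization for sagebrush landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum-set prioritization for sagebrush landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The planning model

`sagescape` implements systematic conservation planning on raster
landscapes: given a pool of candidate 30 m cells (*planning units*), a
per-unit *cost* to be minimized, and per-unit *feature* values for a set of
focal species, the core problem is the **minimum-set** integer program

$$
\min_x \;\; \sum_i c_i x_i \;+\; b\Big[\sum_i p^*_i x_i \;-\;
2\sum_{(i,j)\in E} L_{ij}\, y_{ij}\Big]
\quad\text{s.t.}\quad
\sum_i f_{ki} x_i \ge t_k \;\;\forall k,\qquad
x_i = 1 \;\; (i \in \text{locked}),\qquad x \in \{0,1\}^n ,
$$

where $E$ is the rook adjacency of the unit grid, $L_{ij}$ the shared edge
length (one cell side), and
$p^*_i = (\text{shared perimeter}_i) + \phi \cdot (\text{study-edge
length}_i)$ with edge factor $\phi \in [0,1]$. The bracketed term is the
exposed boundary of the selected set, so a positive penalty $b$ rewards
clumping; the edge factor (default $\phi = 0.5$) halves the charge on
segments along the study-area boundary so peripheral units are not
over-penalized. The linking variables $y_{ij} \le x_i, x_j$ are continuous
in $[0,1]$; because their objective coefficients are non-positive they are
integral at any optimum, which keeps the model small. Targets are **hard
constraints**. The *gap* parameter (default 0.01) is the relative
optimality tolerance of the solver — the returned objective is certified to
be within that factor of the proven lower bound — not a tolerance on
targets. (Planning folklore sometimes glosses the gap as "allowed deviation
from targets"; the solver semantics used here follow the mathematical
programming convention of the tools this workflow descends from.)

Relative targets $t_k = \tau_k \sum_i f_{ki}$ (default $\tau = 0.2$: hold
at least 20 % of every feature's study-wide total) are the standard mode; a
relative target against a zero-total feature is treated as vacuous
($t_k = 0$, with a warning) rather than infeasible, since $0.2 \times 0 =
0$. Absolute targets are used by the uncertainty sweep so that all
iterations chase the same frozen quantity.

## The solver

No external MILP library is required: the `milp` backend is a
branch-and-bound written for this problem class.

* **Lower bounds.** At a node with units fixed in ($F_1$) or out ($F_0$),
  each unit's boundary earn-back is credited optimistically against every
  neighbour not excluded, giving separable coefficients
  $\tilde a_i = c_i + b\,p^*_i - b L \,\#\{j \sim i : j \notin F_0\} \ge
  c_i$. The remaining covering LP over free units is bounded by its
  Lagrangian dual, maximized by exact cyclic coordinate ascent (each
  coordinate is a 1-D piecewise-linear concave maximization solved at its
  breakpoints). Any dual point yields a valid bound, so the ascent need not
  converge; the root uses 40 sweeps (it anchors the reported gap), deeper
  nodes 8.
* **Incumbents.** LP-support rounding plus a cost-effectiveness greedy
  (gain per cost against residual targets), redundancy pruning, and — when
  $b > 0$ — a deterministic single-flip descent on the exact objective.
* **Termination.** Best-first search stops when the tree is exhausted
  (status `optimal`), the relative gap reaches `gap` (`within_gap`), or a
  node/wall-clock budget is hit (`feasible`, reporting the honestly
  achieved gap). Budgets default to 200 000 nodes below 500 units, 1 000
  below 2 000, 50 above, with a 20 s wall clock per solve; desk-scale
  catalog problems typically return within seconds. Leaf nodes evaluate
  the boundary term exactly, so with `gap = 0` the search is exact — the
  test suite verifies objective agreement with exhaustive enumeration to
  1e-9 across a randomized battery.
* **Other backends.** `exhaustive` enumerates up to 22 units with a
  deterministic tie-break (lexicographically smallest selected set),
  serving as the oracle; `greedy` returns a feasible solution quickly. All
  backends agree on feasibility and name violated features when targets
  are unreachable.

With strong boundary penalties on large pools the optimistic edge credit
makes the bound loose, and gaps of order $b \times$ (internal exposed
boundary) may remain unproven within budget; the solution is still
feasible and the gap is reported rather than hidden.

# Layers and transforms

* **Degraded cells**: change from historic cover ($\Delta_h$) and from
  ecological-potential cover ($\Delta_p$) is computed per cell; a cell is
  degraded when either change exceeds its study-wide mean by two standard
  deviations, or both sit in their one-to-two-SD bands. Change is signed
  (gains are negative losses) and statistics are taken over all non-nodata
  cells, since the classification is about departure from the typical
  change. If both change fields are constant the classification errors out.
* **Intact cells**: not degraded, current cover $\ge 15\,\%$ (inclusive —
  the conventional minimum for sage-grouse use), not nodata.
* **Cost transposition** $v' = -v + v_{\max} + 1$ turns "more is better"
  surfaces (connectivity, future cover, soil moisture) into minimizable
  costs with minimum exactly 1; $v_{\max}$ is taken over the candidate
  pool only, because values outside the pool never enter the objective.
* **Positive shift** $v' = v + |v_{\min}| + 1$ repairs signed layers
  (connectivity loss). It is applied verbatim even to all-positive inputs —
  reproducibility of the stated rule beats cleverness.
* **Utility (uncertainty) transforms**: $c' = c + w \cdot \mathrm{CV}$,
  $f' = \max(0, f - w \cdot \mathrm{CV})$; $w = 0$ is the identity.
* **Ecological potential**: degraded cells are assigned the mean of a
  feature over *intact* cells of their management cluster; clusters with
  no intact cells leave their degraded cells undefined (excluded from that
  feature's totals), never zero.
* Feature layers are linearly rescaled to $[0,1]$ study-wide before
  optimization; a constant layer maps to zeros (usable, no division by
  zero). CV is sd/mean with non-positive means yielding nodata.

# Circuit-theory connectivity

Movement potential is modeled as current through a resistor network:
cells are nodes, rook neighbours are resistors with conductance equal to
the mean of the two cells' conductances (percent sagebrush cover by
default), and zero-conductance cells are removed from the network. For
each source visited by the moving window, one ampere is injected and all
other sources inside the window are grounded; the Kirchhoff system is
solved by sparse Cholesky on the source's connected component, and
per-cell throughflow (half the summed absolute edge currents plus half the
injection/extraction at focal nodes) is accumulated over windows. Windows
are truncated at the study edge — no data exists outside. A window whose
source reaches no ground carries zero current (logged, not fatal).

Sources are cover-based (cells at or above 15 % cover, matching the intact
definition) or point-based (leks, equal source strength by default). The
lek variant follows the point run with a focal mean over the window
radius, which is this package's reading of "mean value over the moving
window" for that product — the one place the upstream parameterization is
genuinely underdetermined — and then zeroes a 1 km protection buffer
around each lek. The loss layer subtracts two identically configured runs
and clamps gains to zero, because apparent gains can be artifacts of
current redirection.

The `stride` parameter thins visited window centers for desk-scale
tractability; `stride = 1` is the dense scheme, and the cumulative map is
invariant to visiting order at any stride. The synthetic-bundle default
(radius 900 m, stride 5 on a 3 km landscape) keeps the same
window-to-landscape proportion as a 30 km window on a regional study area.

# The problem catalog

Nine frozen configurations mirror the standard analysis battery:
protection over intact habitat with uniform cost (1a), transposed
sagebrush connectivity (1b), transposed future cover (1c), or untransposed
soil moisture with optional future-cover masks at 5/10/15 % (1d, where an
aggressive mask may legally empty the pool — reported as infeasible, not
an error); restoration over degraded habitat using ecological-potential
features and transposed soil moisture with intact cells locked in (2a) and
its uncertainty variant (2b); and the conservation-design set restricted
to core/growth areas (3a protection by transposed lek connectivity; 3b
resilience and 3c connectivity-loss restoration, both locking in 3a's
selection so restoration clusters on the protected core — their pools are
the degraded-within-design cells plus 3a's sites so the lock is
satisfiable). Boundary penalties default to 1e-5 (a nominal
anti-fragmentation device, an ordinary `b`, not a special mode) for 1a/1d,
0.1 for 2a, 2.5/1.5 for 3b/3c, none elsewhere. Problem 1d uses soil
moisture *untransposed*: minimizing it deliberately steers protection to
low-moisture, low-resilience sites.

Restoration-gain features are zero on locked-in intact units, so capture
proportions measure restoration gain over degraded cells only. The
cluster-mean abundance layer (already cluster-constant) enters restoration
problems directly, without the zonal imputation step.

## Uncertainty sweep and sensitivity classes

The sweep freezes absolute targets from the unpenalized layers, then
re-solves at penalty weights $w = 0.0, 0.1, \dots, 0.8$ (nine iterations)
with no boundary penalty and no locked-in units — both would confound the
between-weight comparison. Features without a CV layer are excluded.
Because $f' \le f$, any feasible iteration's selection also meets the
frozen targets on the original features; this dominance is asserted at run
time. Selection counts over feasible iterations classify units as low
($\ge 7$), medium (4–6), or high (1–3) sensitivity; never-selected units
form their own class because the classification compares selected sites
only. Infeasible iterations are flagged and excluded from counts.

## Boundary-penalty calibration

The upstream calibration criterion ("aligned with problem objectives") is
judgment-based; this package substitutes a declared rule: sweep candidate
penalties, report cost inflation over the $b = 0$ optimum, clump count,
and exposed boundary, and return the largest candidate whose pure-cost
inflation stays within a stated tolerance (default 10 %). The report is
returned so a user can overrule the rule with eyes open.

# The synthetic landscape generator

Real inputs for this workflow (remote-sensed cover series, modeled species
densities, restricted lek locations) are large or unavailable, so the
package ships a seeded generator whose defaults *are* the study
conditions used by the tests and the acceptance script: a 100 × 100 grid
of 30 m cells; spatially autocorrelated cover fields built by Gaussian
smoothing of white noise (scale 4 cells), historic mean ≈ 30 % cover;
ecological potential = historic plus a small positive offset; patchy
degradation over 20 % of cells at ≈ 15 percentage points depth; future
cover attenuated by a smooth west–east trend so the 5/10/15 % thresholds
cut the map nontrivially. Six focal species emulate the field's data
contrast: gamma-sampled densities (non-negative, right-skewed) with
increasing, decreasing (an open-shrubland analogue), and hump-shaped cover
responses; beta-sampled probabilities with mass near 1 (left-skewed); one
probability layer deliberately carries no CV surface and is therefore
excluded from the uncertainty sweep; and a cluster-constant abundance
layer stands in for lek-trend estimates aggregated to management
clusters. Cluster zones are edge-snapped rectangular tiles; conservation
areas are random rectangles covering ≈ 35 % of the grid; leks are sampled
with probability proportional to squared cover, so their mean underlying
cover exceeds the grid mean.

What the generator does *not* emulate: anisotropic terrain-driven cover
structure, temporal autocorrelation beyond the single degradation event,
spatially correlated observation error between species, and the sheer
scale of regional rasters. Green tests on these bundles therefore
demonstrate the machinery — classification, connectivity, optimization,
reporting — under controlled conditions with known structure, not the
reproduction of any region-specific result.

# Numerical choices

* Cell membership in polygons and buffers is by cell-center containment —
  unambiguous and cheap. Zone tile boundaries are snapped to cell edges so
  no center is ambiguous.
* Feasibility comparisons use a 1e-9 absolute slack; exhaustive ties are
  broken toward the lexicographically smallest selected set; ties under
  transposition remain ties (tie-breaking is the optimizer's concern).
* Focal means and field smoothing run through FFT convolution
  (zero-padded, edge-renormalized); "zero" in smoothed maps therefore
  carries ~1e-13 numerical noise, and tests compare against tolerances,
  not exact zeros. Unsmoothed current maps are exactly zero off-network.
* Rasters are written with 17 significant digits so write–read round-trips
  are bit-exact; raster alignment (shape, cell size, origin) is enforced,
  never repaired — reprojection and resampling are out of scope.
* Per-solve problem sizes in the shipped tests (up to ~8 600 units, six
  features) were chosen so the full battery runs comfortably on one CPU;
  they are desk-scale choices, not algorithmic limits.

# Known limitations

* Proven optimality gaps degrade with strong boundary penalties on large
  pools (see above); statuses are honest about it.
* The lek-connectivity focal-mean interpretation and the
  boundary-calibration rule are declared substitutes for underdetermined
  upstream details.
* Only binary decisions, minimum-set objectives, and linear boundary
  penalties are supported — no maximum-utility objectives,
  irreplaceability scores, or nonlinear connectivity terms inside the
  program.
* Single coordinate system, single-band rasters; the toolkit assumes
  pre-aligned inputs.
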