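---
title: "Methods: coupled LULC accounting, ESV valuation and grey scenario optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled LULC accounting, ESV valuation and grey scenario optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyplus)
```

# What the package models

`greyplus` implements a coupled analysis chain for land systems in
data-scarce basins: (1) land-use/land-cover (LULC) change accounting between
categorical raster epochs; (2) ecosystem-service valuation (ESV) by the
equivalent-factor method with a dynamic standard equivalent and regional
corrections; (3) optimization of the future land-use *structure* (the
six-class area vector) by a grey multi-objective linear program (GMOP)
supported by GM(1,1) grey forecasting; and (4) allocation of the optimized
structure back onto the map by a simplified patch-generating cellular
automaton with learned transition suitability, validated by standard
land-change metrics.

Throughout, the six classes follow the conventional coding
`1` cultivated, `2` forest, `3` grassland, `4` water, `5` construction,
`6` unused.

# The synthetic study system

Real basin-scale inputs (multi-epoch classified rasters, 18 driving-factor
layers, yearbook series) are proprietary or bulky, so the package carries a
first-class generator whose ground truth is known exactly:

* **Land-use pair.** The initial epoch assigns classes along the level sets
  of a smooth random field (a sum of random sinusoids), which gives
  spatially contiguous class regions while keeping cell counts *exactly* at
  the configured proportions. The second epoch applies a row-stochastic
  transition kernel patch-wise: per origin class, the number of converted
  cells equals the kernel row times the class count (largest-remainder
  rounding), and converted cells are grown as contiguous patches by
  4-neighbour dilation from random seeds. Patch-wise (rather than
  i.i.d. cell-wise) seeding was chosen deliberately: the allocation stage is
  a patch-based model, and it should face spatially structured change.
* **Driving factors.** A linked factor is standard normal noise shifted by
  `slope` on exactly the cells undergoing its transition. Under this
  equal-variance Gaussian construction the class-conditional probability is
  *exactly* logistic in the factor with logit slope `slope`, so the expected
  separability is known in closed form (held-out AUC
  `pnorm(slope / sqrt(2))`, about 0.983 at the default slope 3). Unlinked
  layers are pure noise and the link table ships with the stack for oracle
  tests.
* **Socioeconomic series.** Exponential trends `v0 (1+g)^t` with
  multiplicative log-normal noise — the functional family in which the
  GM(1,1) grey model is exact, so forecast bias can be tested going to zero
  with the noise. Default levels and growth rates are set to magnitudes
  typical of an arid inland basin over 1990–2020 (population ~3.5e5 growing
  1.3 %/yr, per-capita GDP growing ~8 %/yr, Engel coefficients drifting down
  ~1 %/yr, grain yields ~2 %/yr); they are study conditions, not tuning
  knobs.

What the generator does *not* emulate: real geography (climate gradients,
terrain-driven anisotropy), classification error, or temporal
autocorrelation beyond two epochs. Passing tests therefore demonstrate
correctness of the mechanics and recoverability of planted signal, not
predictive skill on any real basin.

A single integer seed threads through every stochastic operation;
regeneration with the same seed is bit-identical.

# Accounting

Per-class areas and composition shares come from cell counts times the cell
area, with nodata excluded from every denominator. The **single land-use
dynamic degree** is the standard annualized relative rate

$$K = \frac{U_b - U_a}{U_a} \cdot \frac{1}{T} \cdot 100\ \ [\%/\mathrm{yr}],$$

undefined for a zero start area (an error, not a sentinel). Internal values
keep full precision; rounding to 2 decimals happens only in reporting
functions. Inter-epoch change is a plain cross-tabulation; its
row-normalized form drives the Markov projection `areas' = areas P^n` used
for the business-as-usual scenario. The calibration interval for the Markov
step defaults to the most recent epoch pair and is configurable.

# Valuation

The equivalent-factor method prices each class by
$VC_i = Q \cdot PI \cdot E_a \sum_f EC_f(i)$ and aggregates
$ESV = \sum_i A_i \, VC_i$.

* **Equivalent tables.** Two vintages of the standard Chinese unit-area
  equivalent tables are bundled as CSV: the 2003 nine-function table and the
  2015 eleven-function revision (adding water supply and nutrient cycle
  maintenance). Construction land is zero by definition in both. The
  conventional policy — 2003 table for epochs before 2020, 2015 table from
  2020 on — is encoded in `equivalent_version_for()` but overridable.
* **Standard equivalent** $E_a$: one seventh of the mean grain output value
  per hectare (price × yield / 7), the Xie convention. For the four
  reference years 1990/2000/2010/2020 the published constants
  2006/2043/2107/2181 yuan/hm² ship as authoritative values; the formula
  path serves synthetic or user data.
* **Biomass correction** $Q = (NPP_i/NPP_j + FVC_i/FVC_j)/2$ (region over
  nation). If FVC is unavailable it can be derived from NDVI by the
  dimidiate pixel model with 5th/95th percentile endpoints
  (`fvc_from_ndvi()`).
* **Social correction** $PI = A \cdot W$ with payment ability
  $A = GDP_i/GDP_j$ and willingness-to-pay $W = L_i/L_j$, where
  $L = 1/(1+e^{-(1/E_n - 3)})$ maps the Engel coefficient to a development
  stage in (0, 1).

The three factors compose **multiplicatively** onto the table. The
composition point is genuinely open in the source methodology; it is
isolated in `corrected_coefficients()` so an additive or partial variant is
a one-line change. With $Q = PI = 1$ and a packaged $E_a$ the valuation
reduces exactly to the unscaled table — a tested identity.

Value maps use Jenks natural breaks (exact Fisher dynamic programming, ties
to the lower class, upper-inclusive bounds). On large rasters the break
search runs on a deterministic sorted thinning of up to 4000 cells — the
classification itself is applied to every cell — and the dynamic program is
checked against exhaustive partition search on small inputs. Fewer distinct
values than classes is an error.

# Grey forecasting and the optimizer

**GM(1,1).** Fitting is the textbook construction: first-order accumulated
generating operation, least squares on
$x^{(0)}(k) + a z^{(1)}(k) = b$. Prediction, however, iterates the fitted
*difference equation* forward, $x^{(0)}(k) = (b - a x^{(1)}(k-1))/(1+a/2)$,
instead of evaluating the continuous response
$(x^{(0)}(1)-b/a)e^{-ak}+b/a$. The discrete form was chosen because it is
exact on noiseless geometric series (the continuous response carries an
$e^{-a}$-versus-ratio discretization bias of order $a^3$ per step) and
because the $a \to 0$ constant-series limit needs no special-casing. Both
properties are tested.

**The program.** Decision variables are the six class areas (continuous
hm²; at basin scale integerality is irrelevant and the reported optima are
vertices anyway). Three linear objectives — economic benefit, ESV and
ecological capacity (the latter net of a 12 % biodiversity set-aside) — are
maximized subject to: a total-area equality; a population-capacity row
$a_{21}(x_1+x_2+x_3) + a_{22} x_5 \le P$ whose two coefficients are *grey*
(interval-valued); a food-security floor on cultivated land derived from
per-capita demand, yield, cropping ratio and multiple-cropping index; a
green-equivalent forest-cover floor ($0.46 x_1 + x_2 + 0.49 x_3$ at least
20 % of the basin); and per-class box bounds. The published constants for
all of these ship as defaults of `constraint_set()`. The population row
applies to $x_1+x_2+x_3$ exactly as printed.

Design choices that the source methodology leaves open:

* **Grey resolution.** A whitening weight $\lambda \in [0,1]$ maps each
  interval to $lower + \lambda(upper-lower)$; default $\lambda = 0.5$, with
  a mandatory sensitivity sweep at $\lambda \in \{0, 0.5, 1\}$
  (`grey_sensitivity()`). Infeasible grey corners are *reported*: with the
  published constants the $\lambda = 1$ corner is provably infeasible
  (the total-area equality forces
  $x_1+x_2+x_3 \ge 3{,}542{,}897 - x_5$, so the row's minimum exceeds
  $P$), which the sweep surfaces rather than hides.
* **Scalarization.** Multi-objective modes use a weighted sum of min–max
  normalized objectives (each normalized by its own feasible range found by
  two auxiliary LP solves), equal weights by default, making the composite
  invariant to objective scale and to weight rescaling. A lexicographic
  mode is available behind `scenario_spec(method =)`.
* **Scenarios.** `red` maximizes the economic objective, `elp` the two
  ecological ones, `eeb` all three; `bau` bypasses the LP entirely and is
  the Markov projection.

The solver is the simplex method (`boot::simplex`) on a tableau rescaled to
order one (areas of ~10⁶ against a 10⁻¹⁰ pivot tolerance are otherwise
ill-conditioned). Its optima are verified in the test suite against an
independent brute-force enumeration of basic feasible solutions and against
rejection-sampled feasible points.

For synthetic basins `constraint_set_from_areas()` builds an analogous
constraint set from the observed and Markov-projected areas: boxes bracket
the two with a ±20 % band, the population cap gets 5 % head-room above the
upper grey corner so every whitening stays feasible, and the food
parameters are calibrated so the cultivated floor sits at half the current
cultivated area.

# Spatial allocation

This is a behavioural re-implementation of the patch-generating CA family
(expansion-sample learning plus multi-type random patch seeds with
decreasing thresholds), desk-scale, not a parity port of any released tool.

* **LEAS.** For each growing class, positives are cells that newly became
  the class between the calibration epochs; negatives are a sample of
  unchanged cells. A probability random forest (default, `ranger`) or a
  logistic regression is fitted on min–max normalized factors and scored
  over the whole grid, giving a suitability surface in [0, 1]. At least 30
  positives are required; the learner contract is calibration-based (tested
  AUC behaviour), not implementation-based.
* **CA.** Each round, growing classes convert candidate cells of permitted,
  currently-surplus donor classes. A candidate's score is suitability ×
  weighted 3×3 neighbourhood share of the growing class, so growth hugs
  existing patch edges; cells away from any edge can enter as random patch
  seeds once their suitability clears a per-class threshold that decays by
  δ = 0.9 whenever the class cannot meet demand. Edge neighbourhoods are
  truncated, never wrapped. Demands arrive in hm² and are converted to
  whole cells by largest remainder; iteration stops when every class is
  within tolerance (default 0.1 % of the grid) or at the iteration cap.
  Conversion only relabels cells, so total area is conserved exactly, and
  candidates are drawn only from permitted donors, so a forbidden
  transition is structurally impossible (both are tested exhaustively).
* **Validation.** Overall accuracy and the kappa coefficient come from the
  cell-level confusion matrix; the figure of merit restricts attention to
  cells where change was observed or simulated:
  $FOM = B/(A+B+C+D)$ with hits $B$, misses $A$, wrong-class hits $C$ and
  false alarms $D$. Identical maps score 1/1/1; simulating pure persistence
  against observed change scores FOM 0.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages (synthesis → accounting → valuation →
optimization → allocation → validation → reporting), persists CSV/JSON
artifacts on request and stamps every bundle with the seed and a
configuration hash. All randomness derives from the one seed; two runs of
the same configuration are bit-identical, which the suite asserts.

The default test and example problem sizes — grids between 90×90 and
500×500, 11-year series, 100 random LP instances against the vertex oracle
— were chosen so the full suite exercises every mechanism at sampling
errors (≈3/√N) small enough to be meaningful while remaining desk-scale.

# Known limitations

* Raster I/O is plain-text ESRI ASCII grid; the containers are matrices
  with minimal geometry metadata, not a full geospatial stack (no CRS
  interpretation, no reprojection, no block processing for very large
  rasters).
* The bundled equivalent tables are the standard national ones; regional
  per-function recalibrations beyond the Q/PI/Ea corrections are out of
  scope, so absolute ESV totals for any real basin depend on inputs the
  user must supply.
* The CA is deliberately simplified (uniform neighbourhood weights by
  default, one seeding mechanism); it aims at the mechanism family's
  qualitative behaviour — demand satisfaction, permission safety,
  edge-hugging growth, reproducibility — not at replicating any specific
  released simulator's maps.
* The grey program treats only the two published population-row
  coefficients as intervals; extending greyness to other rows is possible
  through the same whitening interface but not implemented.

# Worked example

```{r example, eval = FALSE}
K <- diag(6)
K[3, 1] <- 0.06; K[3, 5] <- 0.01; K[3, 3] <- 0.93   # grassland loss
K[6, 3] <- 0.05; K[6, 1] <- 0.02; K[6, 6] <- 0.93   # unused reclaimed
K[2, 3] <- 0.03; K[2, 2] <- 0.97
K[4, 6] <- 0.02; K[4, 4] <- 0.98

cfg <- synthetic_config(120, 120, transition_kernel = K, cell_area = 100,
                        years = 2010:2020, seed = 42)
bundle <- run_pipeline(pipeline_config(cfg, seed = 42))
bundle$dynamics                    # per-class dynamic degrees
bundle$scenario_comparison$esv     # scenario ESV changes
bundle$validation                  # kappa / OA / FOM of the replay
```
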