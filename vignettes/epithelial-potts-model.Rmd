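---
title: "Modelling epithelial layer morphogenesis with a Cellular Potts Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling epithelial layer morphogenesis with a Cellular Potts Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(epipotts)
```

## The model

`epipotts` simulates a cross-section of epithelial cells proliferating on a
substrate with a two-dimensional Cellular Potts Model (CPM). The lattice is
a rectangle in the x–z plane (x along the substrate, z perpendicular, z = 0
at the bottom); every site carries one label — medium (0), frozen substrate
(−1), frozen boundary wall (−2), or a positive cell id — and a cell is the
set of sites sharing its id. Configurations are weighted by the energy

$$E \;=\; \lambda_{area} \sum_\sigma (A_\sigma - A_0)^2
      \;+\; \lambda_{cont} \sum_\sigma L_\sigma^2
      \;+\; \sum_{\langle i,j\rangle} J(\sigma_i, \sigma_j)\,
            (1 - \delta_{\sigma_i \sigma_j}),$$

with $A_\sigma$ the pixel count of cell $\sigma$, $L_\sigma$ its
boundary-link count, and $J$ the contact energy per unordered neighbour
pair: $\lambda_{adh}^{cc} \le 0$ between unlike cells,
$\lambda_{adh}^{cs} \le 0$ between a cell and the substrate, and zero when
either site is medium or wall. The first term penalises deviations from the
target area $A_0$ (compressibility), the second models cortical actomyosin
contractility as a spring of zero rest length on the cell perimeter, and
the third makes intercellular and cell–substrate contact energetically
favourable. Dynamics are elementary steps: a random site, a random face
neighbour, and a copy of the source label onto the target accepted with the
Metropolis probability ($1$ for $\Delta E \le 0$, $e^{-\Delta E/T}$
otherwise). One Monte Carlo step (MCS) — the model's time unit — is one
attempt per lattice site.

Cells whose area has reached $A_0$ divide once per MCS with probability

$$P_{div} = P_{max}\,\frac{n_s^k}{\,n_s^k + (\gamma\sqrt{A_0})^k\,},$$

a Hill function of the cell's substrate-adhesion pixel count $n_s$ (pixels
with a face-adjacent substrate pixel). Detached cells never divide. The
mitotic plane passes through the centroid with a normal set by the
orientation policy: `vertical` (normal $(1,0)$; daughters side by side),
`horizontal` (normal $(0,1)$; daughters stacked), `random` (uniform angle),
or `major_axis` (normal along the principal axis of the pixel covariance,
so daughters separate along the cell's long axis — the long-axis rule).
Daughters inherit roughly $A_0/2$ each and regrow through the ordinary
Potts dynamics.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `A0` | 225 px | target area (15 × 15 initial cell) |
| `T` | 50 | Potts temperature (energy scale of acceptance) |
| `gamma`, `k` | 2, 10 | Hill half-saturation $\gamma\sqrt{A_0} = 30$ px, steepness |
| `P_max` | 0.1 /MCS | maximal division probability |
| `lambda_area` | 1 | compressibility (energy / px² deviation²) |
| `lambda_cont` | 3 | cortical contractility (energy / link²) |
| `lambda_adh_cc`, `lambda_adh_cs` | −150, −300 | contact energies per link (≤ 0) |
| lattice | 480 × 195 | production domain; substrate 450 × 3 px |

The adhesion ratio $\alpha = \lambda_{adh}^{cs}/\lambda_{adh}^{cc}$ is the
control parameter of the collective phase diagrams; sweeps expose it as a
derived axis. The mechanical defaults sit mid-diagram (cuboidal monolayer
territory); single runs almost always override them.

Two neighbourhood conventions matter and are configurable:

* `perimeter_order = 1` (default): $L_\sigma$ counts von Neumann links to
  unlike labels, which makes a lattice rectangle's count exactly
  $2l + 2h$ — the analytic rectangle model below is then the literal
  continuum limit of the lattice term.
* `contact_order = 2` (default): the $J$ sum runs over the Moore
  neighbourhood, the common practice of lattice tissue simulators. Under
  order-1 contact the substrate gain per spread column is three times
  weaker; at the parameter values the phase diagrams are mapped over, a single
  cell then never spreads enough to reach $A_0$, proliferation stays
  blocked everywhere, and no monolayer can form — so order 2 is not a
  cosmetic choice but the convention under which the collective phase
  diagram exists at these parameter scales.

## Numerical design

**Incremental energies.** The Monte Carlo kernel (C++) evaluates
$\Delta E$ of a proposed copy in O(1): only the two affected cells' area
and perimeter terms and the contact links incident on the target site
change. A cell shrinking to zero pixels loses its area and perimeter terms
outright (cell death by shrinkage is allowed; fragmentation is also
allowed, as in the plain CPM — no connectivity constraint). The test suite
certifies the incremental path against full recomputation, exactly for
integer parameters and to 1e−9 relative for floats, and checks that
accumulated deltas reproduce the endpoint energy along simulated paths.

**Random numbers.** All stochastic operations draw from R's global RNG;
`params$seed` seeds the whole run, every artifact records it, and per-run
sweep seeds derive deterministically from the base seed and run index
(kept below $2^{31}$). Identical parameters and seed give bit-identical
trajectories.

**Proposal bookkeeping.** Degenerate picks (same label on both sites, or a
frozen wall/substrate site as source or target) consume an attempt, so one
MCS is always exactly width × height attempts (other CPM codes differ on
whether no-ops consume an attempt; counting them only rescales time).

**Steady state.** The model has no intrinsic stopping point, so runs end
when no division occurred over a sliding window (default 500 MCS) *and*
the mean total energy drifted by less than `steady_tol` (default 1e−3
relative) between the two window halves. Drift, not peak-to-peak range, is
compared because thermal fluctuation at T = 50 never vanishes. For
collective-structure experiments we lengthen the window to 1500 MCS:
near self-arrest the division probability of border cells falls to
~10⁻³/MCS and inter-division gaps routinely exceed 500 MCS, which would
otherwise stop runs mid-growth.

**Division geometry.** Pixels are assigned to daughters by the sign of the
distance from the pixel centre to the division plane. Tie pixels (exactly
on the plane) go as a block to the side with the smaller strict count
(negative side on equality), keeping daughters balanced: a 15 × 15 mother
split vertically yields areas 120 and 105. The fresh id goes to the side
with larger mean x (then larger mean z). A partition that would leave a
side empty aborts the division without changing the state. Under
`major_axis`, a cell with isotropic second moments (eigenvalue gap below
1e−9 relative) falls back to a random angle.

## The analytic rectangle

For a single rectangular cell of length $l$ and height $h$ the energy
reduces to the closed form

$$E(l, h) = \lambda_{area}(l h - A_0)^2 + \lambda_{cont}(2l + 2h)^2 +
\lambda_{adh}^{cs}\, l,$$

whose stationary conditions are solved numerically by multi-start
L-BFGS-B from the best points of a coarse grid over
$(0, 4\sqrt{A_0}]^2$, with the analytic gradient. When
$\lambda_{adh}^{cs} = 0$ the energy is symmetric in $(l, h)$ and for fixed
$lh$ the perimeter term is minimised on the diagonal, so the search runs
in one dimension and returns $l^* = h^*$ exactly. The landscape has
near-flat valleys (especially at small $\lambda_{area}$); along a valley
the energy, not the coordinate, is the meaningful certificate, so the
brute-force certification asserts that the optimizer never loses to an
exhaustive 0.01-step grid and that its grid-rounded point is within one
grid step of the grid minimum *in energy*. Minimisers within 0.1% of the
search-box boundary are flagged.

```{r rect}
eq <- rect_equilibrium(cpm_params(lambda_area = 1, lambda_cont = 3,
                                  lambda_adh_cs = -300))
tidy(eq)
```

## What the simulations emulate — and what they do not

A run starts from one 15 × 15 cell on the substrate and, depending on the
mechanics and the division orientation, produces one of three structure
classes: a **non-confluent** cluster (proliferation blocked by strong
contractility and weak substrate adhesion), a self-arresting confluent
**monolayer** of squamous, cuboidal or columnar cells (crowding shrinks
area and $n_s$ until $P_{div}$ collapses), or a **multilayer** that keeps
dividing while extruding cells out of the basal layer. `classify_trajectory()`
makes this call deterministically from the morphology time series:
coverage of the substrate top row, suprabasal counts, the division log,
and the mean height/width aspect ratio with a configurable cuboidal band
(±0.25 by default; the squamous/cuboidal/columnar categories have no
canonical quantitative boundaries, so the band is a package choice). "Confluent" accepts window-mean coverage ≥ 0.95
because thermal fluctuations transiently open single-pixel gaps above the
substrate even in a closed layer. A multilayer growing slower than 20% of
the sweep's fastest is refined to `multilayer_slow`; an arrested state
that still holds suprabasal cells is reported as `multilayer_slow` too
(a stalled multilayer, not a monolayer).

The desk-scale preset (`cpm_params_reduced()`: 240 × 100 lattice, 220 px
substrate, 10,000 MCS) is used throughout the tests and the reproduction
script; per-cell shape metrics are local and insensitive to domain width,
but absolute cell counts, waiting times to confluence, and any quantity
tied to the domain scale are not comparable to full-scale (480 × 195,
longer-budget) runs. The model deliberately omits cell death,
differentiation, and any cytoskeletal term: in the
strong-adhesion/low-contractility corner it therefore produces unrealistic
thin elongated shapes that a real cytoskeleton would prevent, and
multilayer height grows without the homeostatic turnover of real
epithelia. Passing tests certify the model's internal mechanics and its
qualitative phase structure, not quantitative agreement with real tissue.

The height-comparison experiments (interior basal-cell height between
$\alpha = 2$ and $\alpha = 20$) exclude the two edge cells of the layer,
which abut bare substrate and are systematically flatter, and average over
the steady window across ≥5 seeds. Under this package's conventions the
directional effect reproduces robustly — lowering lateral cell–cell
adhesion flattens cells — but its magnitude depends strongly on the
contact-neighbourhood bookkeeping, over which CPM implementations differ:
at the mid-diagram parameter point we measure a factor of about 1.15 at
desk scale, while the squamous- and columnar-corner factors are close to
1.1. We document the conventions used rather than tuning them toward any
particular factor.

## A short run

```{r run, eval = FALSE}
p <- cpm_params_reduced(lambda_area = 1, lambda_cont = 7,
                        lambda_adh_cs = -700, lambda_adh_cc = -350,
                        division_mode = "vertical", seed = 101,
                        steady_window = 1500)
traj <- run_simulation(p)
glance(traj)          # one-row summary with the structure label
autoplot(traj)        # basal / suprabasal counts over time
autoplot(traj$final_state)

sweep <- run_sweep(sweep_spec(
  list(lambda_cont = c(1, 7), lambda_adh_cs = c(-100, -700), alpha = c(2, 20)),
  replicates = 3, base_seed = 1,
  base_params = cpm_params_reduced(steady_window = 1500)))
plot_phase_diagram(sweep)
```

## Known limitations

* The stationary distribution of the CPM chain is not exactly Boltzmann:
  the proposal scheme is asymmetric wherever a compartment has no medium
  neighbour (a fully enclosed pixel cannot be retracted by medium). The
  dynamics tests therefore validate occupancy against the exactly
  enumerated transition matrix of a small toy chain rather than against a
  naive Boltzmann ratio.
* Quantitative phase-boundary positions shift with the neighbourhood
  orders; only the qualitative corner assignments are asserted.
* The steady-state detector is a heuristic; multilayers never satisfy it
  and always run to their MCS budget.
* Snapshots store the full label matrix as plain text — fine at desk
  scale, verbose for long production runs (use `snapshot_every` and
  `keep_snapshots = FALSE`).
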