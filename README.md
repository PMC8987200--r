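# epipotts

A two-dimensional Cellular Potts Model (CPM) of epithelial cells
proliferating on a substrate, for studying how cell mechanics and the
orientation of cell division shape single-cell morphology and the
transition between non-confluent clusters, confluent monolayers, and
multilayered structures.

The package is aimed at computational tissue-morphogenesis work: it
simulates a cross-section of an epithelium (x along the substrate, z
perpendicular), sweeps mechanical parameter grids into phase diagrams, and
classifies the resulting collective structures.

## The model

Every lattice site carries one label — medium, frozen substrate, frozen
boundary wall, or a cell id — and configurations evolve by Metropolis
pixel copies under the energy

```
E = λ_area Σ_σ (A_σ − A0)²  +  λ_cont Σ_σ L_σ²  +  Σ_<i,j> J(σ_i, σ_j) (1 − δ_ij)
```

with `A_σ` the cell's area, `L_σ` its boundary-link count, and `J` the
contact energy per neighbour pair (`λ_adh^cc ≤ 0` cell–cell, `λ_adh^cs ≤ 0`
cell–substrate, 0 against medium or wall). A copy is accepted with
probability 1 if it lowers `E` and `exp(−ΔE/T)` otherwise; one Monte Carlo
step (MCS) is one attempt per lattice site. A cell whose area has reached
the target `A0` divides per MCS with the Hill probability

```
P_div = P_max · n_s^k / (n_s^k + (γ√A0)^k)
```

of its substrate-adhesion pixel count `n_s` (detached cells never divide),
along a plane whose normal is vertical `(1,0)`, horizontal `(0,1)`, random,
or aligned with the cell's major axis. A closed-form companion model — a
single rectangular cell with `E(l,h) = λ_area(lh−A0)² + λ_cont(2l+2h)² +
λ_adh^cs·l` — gives the analytic equilibrium aspect ratio and area
(`rect_equilibrium()`, `analytic_phase_surface()`).

## A worked example

```r
library(epipotts)

p <- cpm_params_reduced(              # 240 x 100 desk-scale preset
  lambda_area = 1, lambda_cont = 7,
  lambda_adh_cs = -700, lambda_adh_cc = -350,   # alpha = 2
  division_mode = "vertical", seed = 101, steady_window = 1500)
traj <- run_simulation(p)
glance(traj)
```

```
#> # A tibble: 1 × 14
#>   label    coverage mean_aspect suprabasal_max suprabasal_trend divisions_ceased
#>   <chr>       <dbl>       <dbl>          <int>            <dbl> <lgl>
#> 1 monolay…    0.995       0.602              0                0 TRUE
#>   growth_rate n_cells n_basal n_suprabasal n_divisions completed_mcs steady_mcs
#>         <dbl>   <int>   <int>        <int>       <int>         <int>      <int>
#> 1           0      15      15            0          14          4062       4062
#> # i 1 more variable: seed <int>
```

The single starting cell divided 14 times along the substrate until the
layer became confluent (window-mean coverage 0.995 — thermal fluctuations
keep transient single-pixel gaps open), at which point crowding cut the
cells' area and adhesion sites and proliferation self-arrested at
MCS 4062 (`divisions_ceased`, `steady_mcs`): a monolayer of 15 flat cells
(mean height/width aspect 0.60, hence `monolayer_squamous`). `tidy(traj)` returns the per-snapshot
morphology table, `autoplot(traj)` the basal/suprabasal time series, and
`autoplot(traj$final_state)` the configuration itself.

Phase diagrams come from seeded sweeps:

```r
master <- run_sweep(sweep_spec(
  list(lambda_cont = c(1, 3, 5, 7), lambda_adh_cs = -c(100, 300, 500, 700),
       alpha = c(2, 20)),
  replicates = 3, base_seed = 1,
  base_params = cpm_params_reduced(steady_window = 1500),
  out_root = "sweep_out"))
plot_phase_diagram(master)
```

A thin CLI wrapping the same functions ships at `inst/cli/epipotts`
(verbs: `simulate`, `sweep`, `analyze`, `rect`, `fixtures`).

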