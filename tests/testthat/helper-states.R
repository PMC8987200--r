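# Shared helpers: randomized toy lattices and independent oracles.

# A randomized 20x20 toy state: wall ring, a substrate strip, and the
# interior filled with random labels from {medium, cells 1..4}, so states
# contain fragmented cells, cell-cell, cell-substrate and cell-medium
# interfaces.  Caches come from the full recount.
random_toy_state <- function(seed, params = NULL) {
  set.seed(seed)
  if (is.null(params)) {
    params <- cpm_params(
      lattice_width = 20, lattice_height = 20, substrate_width = 10,
      substrate_thickness = 2, A0 = sample(5:40, 1),
      lambda_area = sample(0:5, 1), lambda_cont = sample(0:4, 1),
      lambda_adh_cc = -sample(0:6, 1), lambda_adh_cs = -sample(0:6, 1),
      division_mode = "disabled", max_mcs = 0)
  }
  st <- initialize_simulation(params)
  labels <- st$labels
  free <- which(labels == CPM_MEDIUM | labels >= 1L)
  labels[free] <- sample(0:4, length(free), replace = TRUE)
  epipotts:::new_cpm_state(labels, params)
}

# draw a valid proposal (face-adjacent, differing labels, neither frozen);
# returns 0-based c(source, target) sites
random_proposal <- function(state) {
  labels <- state$labels
  W <- nrow(labels); H <- ncol(labels)
  repeat {
    idx <- sample(W * H, 1)
    li <- labels[idx]
    if (li %in% c(CPM_SUBSTRATE, CPM_WALL)) next
    xi <- (idx - 1L) %% W; zi <- (idx - 1L) %/% W
    o <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample(4, 1), ]
    xj <- xi + o[1]; zj <- zi + o[2]
    lj <- labels[xj + 1L, zj + 1L]
    if (lj %in% c(CPM_SUBSTRATE, CPM_WALL) || lj == li) next
    return(list(source = c(xi, zi), target = c(xj, zj)))
  }
}

# independent oracle: full-recompute energy difference of applying the copy
full_recompute_delta <- function(state, source, target) {
  after <- state
  after$labels <- state$labels + 0L
  after$labels[target[1] + 1L, target[2] + 1L] <-
    state$labels[source[1] + 1L, source[2] + 1L]
  after <- recount_cell_statistics(after)
  total_energy(after)$total - total_energy(state)$total
}

# a state holding one 30-wide x 8-tall cell (area 240 >= A0, n_s = 30):
# sits exactly at the Hill half-saturation point of the default parameters
half_saturation_state <- function(...) {
  epipotts:::build_fixture_state(
    40L, 16L, substrate_width = 36L, substrate_thickness = 2L,
    cells = list(`1` = epipotts:::rect_pixels(4:33, 3:10)),
    params_args = list(A0 = 225, division_mode = "vertical", ...))
}

expect_caches_match_recount <- function(state) {
  rc <- recount_cell_statistics(state)
  expect_identical(state$area, rc$area)
  expect_identical(state$boundary, rc$boundary)
  expect_identical(state$ns, rc$ns)
  expect_identical(state$sumx, rc$sumx)
  expect_identical(state$sumz, rc$sumz)
}
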