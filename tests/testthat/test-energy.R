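test_that("total energy reproduces hand-derived configurations", {
  # isolated 15x15 cell, order-1 perimeter L = 60, J = 0 everywhere
  p <- cpm_params(lattice_width = 60, lattice_height = 40,
                  substrate_width = 50, lambda_area = 1, lambda_cont = 3,
                  lambda_adh_cc = 0, lambda_adh_cs = 0)
  e <- total_energy(initialize_simulation(p))
  expect_equal(e$area_term, 0)
  expect_equal(e$contractility_term, 3 * 60^2)
  expect_equal(e$adhesion_term, 0)
  expect_equal(e$total, 10800)
  expect_equal(e$total, e$area_term + e$contractility_term + e$adhesion_term)

  # empty lattice: all sums empty
  empty <- epipotts:::build_fixture_state(10L, 8L, 6L, 2L, cells = list())
  expect_equal(total_energy(empty)$total, 0)

  # two face-adjacent 1-pixel cells on a 6x6 toy grid, order-1 everywhere:
  # E = 0 + (16 + 16) - 2
  toy <- epipotts:::build_fixture_state(
    6L, 6L, substrate_width = 2L, substrate_thickness = 1L,
    cells = list(`1` = cbind(2L, 3L), `2` = cbind(3L, 3L)),
    params_args = list(A0 = 1, lambda_area = 1, lambda_cont = 1,
                       lambda_adh_cc = -2, lambda_adh_cs = 0,
                       contact_order = 1, perimeter_order = 1))
  e2 <- total_energy(toy)
  expect_equal(e2$area_term, 0)
  expect_equal(e2$contractility_term, 32)
  expect_equal(e2$adhesion_term, -2)
  expect_equal(e2$total, 30)
})

test_that("adhesion term agrees with an explicit pairwise enumeration", {
  # independent oracle: loop over every site and offset, count each
  # unordered unlike pair once
  brute_adhesion <- function(state) {
    labels <- state$labels
    W <- nrow(labels); H <- ncol(labels)
    p <- state$params
    offs <- list(c(1, 0), c(0, 1))
    if (p$contact_order >= 2) offs <- c(offs, list(c(1, 1), c(1, -1)))
    sub <- cpm_compartments()["substrate"]
    tot <- 0
    for (x in 0:(W - 1)) for (z in 0:(H - 1)) for (o in offs) {
      xn <- x + o[1]; zn <- z + o[2]
      if (xn < 0 || xn >= W || zn < 0 || zn >= H) next
      u <- labels[x + 1, z + 1]; v <- labels[xn + 1, zn + 1]
      if (u == v) next
      if (u >= 1 && v >= 1) tot <- tot + p$lambda_adh_cc
      else if ((u >= 1 && v == sub) || (v >= 1 && u == sub))
        tot <- tot + p$lambda_adh_cs
    }
    tot
  }
  for (seed in c(4, 5)) {
    st <- random_toy_state(seed)
    expect_equal(total_energy(st)$adhesion_term, brute_adhesion(st))
    st$params$contact_order <- 1L
    expect_equal(total_energy(st)$adhesion_term, brute_adhesion(st))
  }
})

test_that("incremental delta equals the full-recompute difference", {
  # integer-valued parameters: exact equality
  for (seed in 11:14) {
    st <- random_toy_state(seed)
    for (i in 1:60) {
      pr <- random_proposal(st)
      expect_identical(delta_energy(st, pr$source, pr$target),
                       full_recompute_delta(st, pr$source, pr$target))
    }
  }
  # float parameters: 1e-9 relative
  p <- cpm_params(lattice_width = 20, lattice_height = 20,
                  substrate_width = 10, substrate_thickness = 2,
                  A0 = 17.3, lambda_area = 0.731, lambda_cont = 2.19,
                  lambda_adh_cc = -3.7, lambda_adh_cs = -1.13,
                  division_mode = "disabled")
  st <- random_toy_state(15, params = p)
  for (i in 1:200) {
    pr <- random_proposal(st)
    d1 <- delta_energy(st, pr$source, pr$target)
    d2 <- full_recompute_delta(st, pr$source, pr$target)
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("delta is antisymmetric under move reversal", {
  st <- random_toy_state(21)
  set.seed(1)
  for (i in 1:50) {
    pr <- random_proposal(st)
    fwd <- delta_energy(st, pr$source, pr$target)
    after <- st
    after$labels <- st$labels + 0L
    after$labels[pr$target[1] + 1, pr$target[2] + 1] <-
      st$labels[pr$source[1] + 1, pr$source[2] + 1]
    after <- recount_cell_statistics(after)
    # reverse: any neighbour of the target that still holds the old label
    # can copy it back; use the original target value from st
    old <- st$labels[pr$target[1] + 1, pr$target[2] + 1]
    rev <- epipotts:::cpm_delta_site(
      after$labels, after$area, after$boundary,
      pr$target[1], pr$target[2], old,
      st$params$lambda_area, st$params$lambda_cont,
      st$params$lambda_adh_cc, st$params$lambda_adh_cs,
      st$params$A0, st$params$perimeter_order, st$params$contact_order)
    expect_identical(rev, -fwd)
  }
})

test_that("killing a 1-pixel cell removes its area and perimeter terms", {
  st <- epipotts:::build_fixture_state(
    8L, 8L, substrate_width = 4L, substrate_thickness = 1L,
    cells = list(`1` = cbind(3L, 2L)),
    params_args = list(A0 = 9, lambda_area = 2, lambda_cont = 3,
                       lambda_adh_cc = -1, lambda_adh_cs = -4))
  # medium at (3, 3) expands down onto the cell's only pixel
  d <- delta_energy(st, c(3, 3), c(3, 2))
  expect_identical(d, full_recompute_delta(st, c(3, 3), c(3, 2)))
  # by hand: lose 2*(1-9)^2 and 3*4^2, lose the substrate contacts of the
  # pixel (face + two diagonals under order-2 contact: 3 * -4)
  expect_equal(d, -2 * 64 - 3 * 16 + 12)
})

test_that("zero adhesion decouples cells into isolated single-cell energies", {
  st <- generate_fixture("two-layer-6-cell")
  st$params$lambda_adh_cc <- 0
  st$params$lambda_adh_cs <- 0
  e_all <- total_energy(st)$total
  iso_sum <- 0
  for (id in 1:6) {
    solo <- st
    solo$labels <- st$labels + 0L
    solo$labels[solo$labels >= 1L & solo$labels != id] <- 0L  # medium
    solo <- recount_cell_statistics(solo)
    iso_sum <- iso_sum + total_energy(solo)$total
  }
  expect_equal(e_all, iso_sum)
})

test_that("energy is a state function along a simulated path", {
  # accumulated kernel deltas must match the recomputed endpoint energy
  p <- cpm_params(lattice_width = 30, lattice_height = 24,
                  substrate_width = 20, A0 = 25, lambda_area = 2,
                  lambda_cont = 1, lambda_adh_cc = -40, lambda_adh_cs = -80,
                  division_mode = "disabled", max_mcs = 200, seed = 5)
  st <- initialize_simulation(p)
  e0 <- total_energy(st)$total
  acc <- 0
  set.seed(p$seed)
  for (i in 1:200) {
    r <- run_mcs(st)
    st <- r$state
    acc <- acc + r$stats$delta_e
  }
  e1 <- total_energy(st)$total
  expect_equal(e0 + acc, e1, tolerance = 1e-9)
})

test_that("contract violations are rejected", {
  st <- generate_fixture("single-cell")
  expect_error(delta_energy(st, c(2, 2), c(4, 2)), class = "cpm_contract_error")
  expect_error(delta_energy(st, c(2, 10), c(2, 11)), class = "cpm_contract_error")
  # substrate as target
  top <- epipotts:::substrate_top(st$params)
  expect_error(delta_energy(st, c(30, top + 1), c(30, top)),
               class = "cpm_contract_error")
})
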