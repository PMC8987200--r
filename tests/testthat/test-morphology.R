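test_that("snapshot metrics recover constructed geometries", {
  init <- measure_snapshot(generate_fixture("single-cell"))
  expect_equal(init$n_cells, 1L)
  expect_equal(init$n_basal, 1L)
  expect_equal(init$mean_height, 15)
  expect_equal(init$mean_width, 15)
  expect_equal(init$mean_aspect, 1)

  two <- measure_snapshot(generate_fixture("two-layer-6-cell"))
  expect_equal(two$n_basal + two$n_suprabasal, two$n_cells)
  expect_equal(c(two$n_basal, two$n_suprabasal), c(4L, 2L))

  L <- measure_snapshot(generate_fixture("L-shaped-cell"))
  expect_equal(L$mean_height, 7)   # bounding extent of rows 3..9
})

test_that("basal/suprabasal partition holds along a simulated trajectory", {
  p <- cpm_params(lattice_width = 60, lattice_height = 50,
                  substrate_width = 50, A0 = 100, lambda_area = 30,
                  lambda_cont = 1, lambda_adh_cs = -400,
                  lambda_adh_cc = -200, division_mode = "major_axis",
                  max_mcs = 400, seed = 8, snapshot_every = 50)
  traj <- run_simulation(p)
  expect_true(all(traj$reports$n_basal + traj$reports$n_suprabasal ==
                    traj$reports$n_cells))
  expect_true(all(traj$reports$coverage >= 0 & traj$reports$coverage <= 1))
})

test_that("classification maps synthetic trajectories to their categories", {
  snap <- function(mcs, cov, asp, nsup, ncell) {
    tibble::tibble(mcs = mcs, n_cells = ncell, n_basal = ncell - nsup,
                   n_suprabasal = nsup, coverage = cov, mean_aspect = asp)
  }
  # confluent, arrested, flat cells -> squamous monolayer
  mono <- dplyr::bind_rows(lapply(seq(0, 2000, 100), function(m)
    snap(m, ifelse(m < 500, m / 500, 1), 0.6, 0, 10)))
  expect_equal(classify_trajectory(mono)$label, "monolayer_squamous")
  # same but tall cells -> columnar; mid band -> cuboidal
  col <- dplyr::mutate(mono, mean_aspect = 1.6)
  expect_equal(classify_trajectory(col)$label, "monolayer_columnar")
  cub <- dplyr::mutate(mono, mean_aspect = 1.1)
  expect_equal(classify_trajectory(cub)$label, "monolayer_cuboidal")
  # widening the cuboidal band reclassifies only into the adjacent class
  wide <- classification_thresholds(aspect_delta = 0.7)
  expect_equal(classify_trajectory(col, thresholds = wide)$label,
               "monolayer_cuboidal")

  # arrested without coverage -> non-confluent
  nc <- dplyr::bind_rows(lapply(seq(0, 2000, 100), function(m)
    snap(m, 0.1, 0.95, 0, 1)))
  expect_equal(classify_trajectory(nc)$label, "non_confluent")

  # growing suprabasal population with ongoing division -> multilayer
  ml <- dplyr::bind_rows(lapply(seq(0, 2000, 100), function(m)
    snap(m, min(1, m / 300), 1.2, m %/% 200, 5 + m %/% 100)))
  ev <- tibble::tibble(mcs = seq(100, 2000, 100))
  expect_equal(classify_trajectory(ml, events = ev)$label, "multilayer")
  # ... and slow against a much faster reference rate
  slow <- classification_thresholds(reference_rate = 1)
  expect_equal(classify_trajectory(ml, events = ev, thresholds = slow)$label,
               "multilayer_slow")

  # degenerate inputs are inconclusive
  expect_equal(classify_trajectory(snap(0, 0, NA, 0, 0))$label, "inconclusive")
  empty <- dplyr::bind_rows(lapply(seq(0, 2000, 100), function(m)
    snap(m, 0, NA_real_, 0, 0)))
  expect_equal(classify_trajectory(empty)$label, "inconclusive")

  # determinism: identical inputs, identical labels
  expect_identical(classify_trajectory(ml, events = ev),
                   classify_trajectory(ml, events = ev))
})

test_that("basal dynamics tabulates the division log per snapshot", {
  p <- cpm_params(lattice_width = 60, lattice_height = 40,
                  substrate_width = 50, A0 = 64, lambda_area = 40,
                  lambda_cont = 1, lambda_adh_cs = -300,
                  lambda_adh_cc = -150, division_mode = "vertical",
                  max_mcs = 300, seed = 4, snapshot_every = 50)
  traj <- run_simulation(p)
  bd <- basal_dynamics(traj)
  expect_equal(bd$mcs, sort(unique(traj$cells$mcs)))
  expect_true(all(bd$n_basal + bd$n_suprabasal > 0))
  # dividing-cell adhesion counts come straight from the event log
  for (i in seq_len(nrow(bd))) {
    expect_equal(bd$dividing_ns[[i]],
                 traj$events$mother_ns[traj$events$mcs == bd$mcs[i]])
  }

  # zero-length trajectory -> empty table
  t0 <- run_simulation(update_params(p, max_mcs = 0, division_mode = "disabled"))
  t0$cells <- t0$cells[0, ]
  expect_equal(nrow(basal_dynamics(t0)), 0)
})

test_that("steady height averages interior basal cells only", {
  # six identical 10 x 20 cells in a row: height 20 regardless of edges
  cells <- stats::setNames(lapply(0:5, function(i)
    epipotts:::rect_pixels((2 + 10 * i):(11 + 10 * i), 3:22)), 1:6)
  st <- epipotts:::build_fixture_state(64L, 30L, substrate_width = 62L,
                                       substrate_thickness = 2L, cells = cells,
                                       params_args = list(A0 = 200))
  traj <- structure(list(params = st$params,
                         cells = dplyr::mutate(cell_table(st), mcs = 0L),
                         events = epipotts:::empty_events(),
                         reports = measure_snapshot(st),
                         steady_mcs = 0L, completed_mcs = 0L),
                    class = "cpm_trajectory")
  expect_equal(mean_steady_cell_height(traj, window = 100), 20)

  # make the two edge cells taller: interior mean must not move
  st2 <- st
  st2$labels[2:11 + 1, 23:25 + 1] <- 1L     # left edge cell now 23 tall
  st2$labels[52:61 + 1, 23:25 + 1] <- 6L    # right edge cell too
  st2 <- recount_cell_statistics(st2)
  traj$cells <- dplyr::mutate(cell_table(st2), mcs = 0L)
  expect_equal(mean_steady_cell_height(traj, window = 100), 20)

  # still-dividing trajectories refuse a steady measurement
  traj$completed_mcs <- 1000L
  traj$cells$mcs <- 1000L
  traj$events <- tibble::tibble(mcs = 950L)
  traj$steady_mcs <- NA_integer_
  expect_error(mean_steady_cell_height(traj, window = 100),
               class = "cpm_no_steady_window")
})

test_that("replicate seeds give mutually consistent steady heights", {
  h <- purrr::map_dbl(c(31, 32), function(s) {
    p <- cpm_params(lattice_width = 100, lattice_height = 60,
                    substrate_width = 80, lambda_area = 1, lambda_cont = 7,
                    lambda_adh_cs = -700, lambda_adh_cc = -350,
                    division_mode = "vertical", max_mcs = 4000, seed = s,
                    steady_window = 800)
    mean_steady_cell_height(run_simulation(p, keep_snapshots = FALSE),
                            require_steady = FALSE)
  })
  expect_lt(abs(h[1] - h[2]), 3)  # pixel-scale replicate agreement
})
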