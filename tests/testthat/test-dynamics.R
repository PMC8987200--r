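test_that("acceptance follows the Metropolis rule exactly at the boundary", {
  expect_equal(acceptance_probability(c(-5, 0), T = 50), c(1, 1))
  expect_equal(acceptance_probability(50, T = 50), exp(-1))
  expect_equal(acceptance_probability(c(5, 25, 50, 100, 250), T = 50),
               exp(-c(0.1, 0.5, 1, 2, 5)))
  set.seed(1)
  expect_true(all(metropolis_accept(rep(-3, 100), T = 50)))
})

test_that("one MCS performs exactly width x height attempts", {
  st <- initialize_simulation(cpm_params(seed = 1))
  set.seed(1)
  r <- run_mcs(st)
  expect_equal(r$stats$attempted, 480 * 195)
  expect_equal(r$state$mcs, 1L)
  expect_true(r$stats$accepted <= r$stats$attempted)
  expect_true(all(unlist(r$stats[, c("accepted", "rejected_same_label",
                                     "rejected_frozen")]) >= 0))
  expect_lte(r$stats$accepted + r$stats$rejected_same_label +
               r$stats$rejected_frozen, r$stats$attempted)
})

test_that("frozen compartments are never overwritten and pixels conserved", {
  p <- cpm_params(lattice_width = 40, lattice_height = 30,
                  substrate_width = 30, A0 = 25, lambda_cont = 1,
                  lambda_adh_cs = -120, lambda_adh_cc = -60,
                  division_mode = "disabled", seed = 3)
  st <- initialize_simulation(p)
  wall0 <- st$labels == cpm_compartments()["wall"]
  sub0 <- st$labels == cpm_compartments()["substrate"]
  set.seed(3)
  for (i in 1:50) st <- run_mcs(st)$state
  expect_identical(st$labels == cpm_compartments()["wall"], wall0)
  expect_identical(st$labels == cpm_compartments()["substrate"], sub0)
  expect_equal(sum(table(st$labels)), 40L * 30L)
  expect_caches_match_recount(st)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- cpm_params(lattice_width = 40, lattice_height = 30,
                  substrate_width = 30, A0 = 25, lambda_adh_cs = -150,
                  lambda_adh_cc = -75, max_mcs = 60, seed = 17,
                  division_mode = "vertical", snapshot_every = 20)
  t1 <- run_simulation(p)
  t2 <- run_simulation(p)
  expect_identical(t1$final_state$labels, t2$final_state$labels)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_equal(t1$stats, t2$stats)
  expect_equal(t1$events, t2$events)
  t3 <- run_simulation(update_params(p, seed = 18))
  expect_false(identical(t1$final_state$labels, t3$final_state$labels))
})

test_that("a near-zero temperature freezes a cell pinned at its target area", {
  # all moves change the area term by at least lambda_area, so every
  # available move is uphill and the Boltzmann factor vanishes
  p <- cpm_params(lattice_width = 30, lattice_height = 30,
                  substrate_width = 20, A0 = 25, lambda_area = 1000,
                  lambda_cont = 0, lambda_adh_cc = 0, lambda_adh_cs = 0,
                  T = 1e-6, division_mode = "disabled", seed = 2)
  st <- initialize_simulation(p)
  before <- st$labels
  set.seed(2)
  r <- run_mcs(st)
  expect_equal(r$stats$accepted, 0)
  expect_identical(r$state$labels, before)
})

test_that("zero-length runs return the initial configuration", {
  p <- cpm_params(lattice_width = 40, lattice_height = 30,
                  substrate_width = 30, A0 = 25, max_mcs = 0, seed = 1)
  traj <- run_simulation(p)
  expect_equal(traj$completed_mcs, 0L)
  expect_identical(traj$final_state$labels,
                   initialize_simulation(p)$labels)
  expect_equal(nrow(traj$reports), 1L)
})

test_that("the R-level single attempt updates caches like the kernel", {
  st <- random_toy_state(31)
  set.seed(99)
  n_acc <- 0
  for (i in 1:400) {
    r <- attempt_copy(st)
    st <- r$state
    if (r$accepted) n_acc <- n_acc + 1
  }
  expect_gt(n_acc, 0)
  expect_caches_match_recount(st)
  expect_equal(sum(table(st$labels)), 400L)
})

test_that("long-run occupancy matches the exactly enumerated chain", {
  # 5x7 toy: substrate columns x=1..3 at z=1..3, six free sites (x=1..3,
  # z=4..5), one cell, A0=1, lambda_area=700, lambda_adh_cs=-750, T=50,
  # order-1 contact.  The chain over the 62 live, non-filling pixel
  # subsets is small enough to enumerate: build the exact transition
  # matrix from every (site, neighbour) proposal with Metropolis
  # acceptance on independently recomputed total energies, solve for the
  # stationary distribution, and compare the kernel's empirical occupancy.
  # (Death and complete filling are suppressed by factors below e^-15 and
  # are treated as rejections in the oracle.)
  site_id <- function(x, z) (z - 4L) * 3L + x
  mk <- function(occ) {
    px <- which(occ)
    x <- ((px - 1L) %% 3L) + 1L; z <- ((px - 1L) %/% 3L) + 4L
    epipotts:::build_fixture_state(
      5L, 7L, substrate_width = 3L, substrate_thickness = 3L,
      cells = if (length(px)) list(`1` = cbind(as.integer(x), as.integer(z)))
              else list(),
      params_args = list(A0 = 1, lambda_area = 700, lambda_cont = 0,
                         lambda_adh_cc = 0, lambda_adh_cs = -750,
                         contact_order = 1, perimeter_order = 1, T = 50))
  }
  nC <- 62L
  occs <- lapply(1:nC, function(k) as.logical(bitwAnd(k, 2^(0:5))))
  energies <- vapply(occs, function(o) total_energy(mk(o))$total, 0)
  N <- 5 * 7
  P <- matrix(0, nC, nC)
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (k in 1:nC) {
    labs <- mk(occs[[k]])$labels
    stay <- 1
    for (x in 0:4) for (z in 0:6) for (d in dirs) {
      li <- labs[x + 1, z + 1]
      if (li %in% c(-1L, -2L)) next
      xj <- x + d[1]; zj <- z + d[2]
      lj <- labs[xj + 1, zj + 1]
      if (lj %in% c(-1L, -2L) || lj == li) next
      occ2 <- occs[[k]]; occ2[site_id(xj, zj)] <- (li == 1L)
      k2 <- sum(occ2 * 2^(0:5))
      if (k2 == 0L || k2 == 63L) next
      de <- energies[k2] - energies[k]
      pr <- (1 / (N * 4)) * (if (de <= 0) 1 else exp(-de / 50))
      P[k, k2] <- P[k, k2] + pr
      stay <- stay - pr
    }
    P[k, k] <- P[k, k] + stay
  }
  ev <- eigen(t(P))
  pi_exact <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_exact <- pi_exact / sum(pi_exact)

  for (seed in 1:2) {
    st <- epipotts:::own_state(mk(c(FALSE, TRUE, rep(FALSE, 4))))
    p <- st$params
    set.seed(seed)
    counts <- numeric(nC)
    for (i in 1:30000) {
      epipotts:::cpm_run_steps(st$labels, st$area, st$boundary, st$ns,
                               st$sumx, st$sumz, st$subadj, N,
                               p$lambda_area, p$lambda_cont,
                               p$lambda_adh_cc, p$lambda_adh_cs,
                               p$A0, p$T, p$perimeter_order, p$contact_order)
      occ <- as.vector(st$labels[2:4, 5:6]) == 1L
      k <- sum(occ * 2^(0:5))
      if (k >= 1 && k <= 62) counts[k] <- counts[k] + 1
    }
    expect_lt(max(abs(counts / sum(counts) - pi_exact)), 0.04)
  }
})
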