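#' Metropolis acceptance rule
#'
#' Acceptance probability of an elementary step: 1 for `delta_e <= 0`,
#' `exp(-delta_e / T)` otherwise. `metropolis_accept()` draws the
#' corresponding Bernoulli decisions using R's RNG.
#'
#' @param delta_e Numeric vector of energy changes.
#' @param T Potts temperature.
#' @return `acceptance_probability()`: probabilities in \[0, 1\];
#'   `metropolis_accept()`: logical vector of accept decisions.
#' @export
#' @examples
#' acceptance_probability(c(-10, 0, 50), T = 50)
acceptance_probability <- function(delta_e, T) {
  stopifnot(T > 0)
  ifelse(delta_e <= 0, 1, exp(-delta_e / T))
}

#' @rdname acceptance_probability
#' @export
metropolis_accept <- function(delta_e, T) {
  runif(length(delta_e)) < acceptance_probability(delta_e, T)
}

# private copies of everything the kernel mutates in place
own_state <- function(state) {
  state$labels <- state$labels + 0L
  for (v in c("area", "boundary", "ns", "sumx", "sumz")) {
    state[[v]] <- state[[v]] + 0
  }
  state
}

# ensure cache vectors are plain doubles of capacity >= n ids
grow_caches <- function(state, nmax) {
  cur <- length(state$area)
  if (nmax > cur) {
    pad <- double(nmax - cur)
    for (v in c("area", "boundary", "ns", "sumx", "sumz")) {
      state[[v]] <- c(state[[v]], pad)
    }
  }
  state
}

#' One elementary copy attempt
#'
#' Picks a uniformly random site and a uniformly random face neighbour; if
#' either is frozen (wall or substrate) or both carry the same label the
#' attempt is counted but changes nothing; otherwise the source label is
#' copied onto the target with the Metropolis probability and all caches
#' are updated incrementally. This R-level path mirrors the compiled kernel
#' used by [run_mcs()] and exists for inspection and testing of single
#' steps.
#'
#' @param state A `cpm_state` with exact caches.
#' @param params Parameters; defaults to the state's own.
#' @return A list with `state`, logical `accepted`, the proposal `reason`
#'   (`"accepted"`, `"rejected_boltzmann"`, `"same_label"`, `"frozen"`),
#'   and `delta_e` (NA for degenerate picks).
#' @export
attempt_copy <- function(state, params = state$params) {
  stopifnot(inherits(state, "cpm_state"))
  labels <- state$labels
  W <- nrow(labels); H <- ncol(labels)
  idx <- floor(runif(1) * W * H) + 1
  li <- labels[idx]
  if (li %in% c(CPM_WALL, CPM_SUBSTRATE)) {
    return(list(state = state, accepted = FALSE, reason = "frozen",
                delta_e = NA_real_))
  }
  off <- neighbour_offsets(1L)[floor(runif(1) * 4) + 1, ]
  xi <- (idx - 1L) %% W; zi <- (idx - 1L) %/% W
  xj <- xi + off[[1L]]; zj <- zi + off[[2L]]
  lj <- labels[xj + 1L, zj + 1L]
  if (lj %in% c(CPM_WALL, CPM_SUBSTRATE)) {
    return(list(state = state, accepted = FALSE, reason = "frozen",
                delta_e = NA_real_))
  }
  if (lj == li) {
    return(list(state = state, accepted = FALSE, reason = "same_label",
                delta_e = NA_real_))
  }
  de <- cpm_delta_site(labels, state$area, state$boundary, xj, zj, li,
                       params$lambda_area, params$lambda_cont,
                       params$lambda_adh_cc, params$lambda_adh_cs,
                       params$A0, params$perimeter_order, params$contact_order)
  if (!metropolis_accept(de, params$T)) {
    return(list(state = state, accepted = FALSE,
                reason = "rejected_boltzmann", delta_e = de))
  }
  state <- own_state(state)
  state <- apply_copy(state, xj, zj, li, lj, params)
  list(state = state, accepted = TRUE, reason = "accepted", delta_e = de)
}

# incremental cache update mirroring the kernel's accept branch
apply_copy <- function(state, xj, zj, a, b, params) {
  off <- neighbour_offsets(params$perimeter_order)
  nb <- state$labels[cbind(xj + off[, 1L] + 1L, zj + off[, 2L] + 1L)]
  nP <- nrow(off)
  state$labels[xj + 1L, zj + 1L] <- a
  on_sub <- state$subadj[xj + 1L, zj + 1L]
  if (a >= 1L) {
    ka <- sum(nb == a)
    state$area[a] <- state$area[a] + 1
    state$boundary[a] <- state$boundary[a] + (nP - ka) - ka
    state$sumx[a] <- state$sumx[a] + xj
    state$sumz[a] <- state$sumz[a] + zj
    if (on_sub) state$ns[a] <- state$ns[a] + 1
  }
  if (b >= 1L) {
    kb <- sum(nb == b)
    state$area[b] <- state$area[b] - 1
    state$boundary[b] <- state$boundary[b] + kb - (nP - kb)
    state$sumx[b] <- state$sumx[b] - xj
    state$sumz[b] <- state$sumz[b] - zj
    if (on_sub) state$ns[b] <- state$ns[b] - 1
    if (state$area[b] <= 0) {
      state$area[b] <- 0; state$boundary[b] <- 0; state$ns[b] <- 0
      state$sumx[b] <- 0; state$sumz[b] <- 0
    }
  }
  state
}

#' Run one Monte Carlo step
#'
#' Executes exactly `lattice_width * lattice_height` elementary copy
#' attempts (the model's natural time unit) through the compiled kernel and
#' increments the MCS clock. Degenerate picks (same label, frozen
#' compartment) consume an attempt.
#'
#' @param state A `cpm_state` with exact caches.
#' @param params Parameters; defaults to the state's own.
#' @return A list with the updated `state` and `stats`, a one-row tibble
#'   with columns `mcs`, `attempted`, `accepted`, `rejected_same_label`,
#'   `rejected_frozen`, `acceptance_ratio`, `delta_e`.
#' @export
run_mcs <- function(state, params = state$params) {
  stopifnot(inherits(state, "cpm_state"))
  state <- own_state(state)
  W <- nrow(state$labels); H <- ncol(state$labels)
  res <- cpm_run_steps(state$labels, state$area, state$boundary, state$ns,
                       state$sumx, state$sumz, state$subadj, W * H,
                       params$lambda_area, params$lambda_cont,
                       params$lambda_adh_cc, params$lambda_adh_cs,
                       params$A0, params$T,
                       params$perimeter_order, params$contact_order)
  state$mcs <- state$mcs + 1L
  stats <- tibble::tibble(
    mcs = state$mcs,
    attempted = res$attempted,
    accepted = res$accepted,
    rejected_same_label = res$rejected_same_label,
    rejected_frozen = res$rejected_frozen,
    acceptance_ratio = res$accepted / res$attempted,
    delta_e = res$delta_e)
  list(state = state, stats = stats)
}

#' Run a full simulation
#'
#' Initializes the standard geometry, then alternates Monte Carlo steps
#' with (unless `division_mode == "disabled"`) one proliferation sweep per
#' MCS, until `max_mcs` or the steady-state criterion fires: no division
#' during the last `steady_window` MCS and a relative drift of the mean
#' total energy between the two halves of that window below `steady_tol`.
#' Snapshots (morphology report, per-cell table, and optionally the label
#' matrix) are taken every `snapshot_every` MCS and at the final step.
#'
#' @param params A [cpm_params()] object. `params$seed` seeds R's RNG for
#'   the whole run; pass `seed = NULL` to leave the RNG state untouched.
#' @param keep_snapshots Keep the label matrices of all snapshots (set
#'   `FALSE` in large sweeps to save memory; the final state is always
#'   kept).
#' @param verbose Print progress every 1000 MCS.
#' @return A `cpm_trajectory`: list with `params`, `reports` (per-snapshot
#'   morphology tibble), `cells` (long per-snapshot per-cell tibble),
#'   `events` (division log), `stats` (per-MCS dynamics tibble),
#'   `snapshots` (named list of label matrices), `final_state`,
#'   `steady_mcs` (NA when the budget ran out first), `completed_mcs`.
#' @export
#' @examples
#' p <- cpm_params(lattice_width = 60, lattice_height = 40,
#'                 substrate_width = 50, max_mcs = 20,
#'                 division_mode = "disabled", seed = 7)
#' traj <- run_simulation(p)
#' tidy(traj)
run_simulation <- function(params, keep_snapshots = TRUE, verbose = FALSE) {
  stopifnot(inherits(params, "cpm_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- own_state(initialize_simulation(params))
  W <- nrow(state$labels); H <- ncol(state$labels)
  n_attempts <- W * H

  energy <- total_energy(state, params)$total
  max_mcs <- params$max_mcs
  e_hist <- double(max_mcs)
  stat_cols <- c("attempted", "accepted", "rejected_same_label",
                 "rejected_frozen", "n_cells", "n_divisions")
  stats_m <- matrix(0, nrow = max_mcs, ncol = length(stat_cols),
                    dimnames = list(NULL, stat_cols))

  reports <- list(); cells_l <- list(); snaps <- list(); events <- list()
  take_snapshot <- function(mcs) {
    key <- as.character(mcs)
    reports[[key]] <<- measure_snapshot(state)
    ct <- cell_table(state)
    if (nrow(ct)) cells_l[[key]] <<- dplyr::mutate(ct, mcs = mcs, .before = 1)
    if (keep_snapshots) snaps[[key]] <<- state$labels + 0L
  }
  take_snapshot(0L)

  last_div <- 0L
  steady_mcs <- NA_integer_
  w <- params$steady_window
  mcs <- 0L

  while (mcs < max_mcs) {
    mcs <- mcs + 1L
    res <- cpm_run_steps(state$labels, state$area, state$boundary, state$ns,
                         state$sumx, state$sumz, state$subadj, n_attempts,
                         params$lambda_area, params$lambda_cont,
                         params$lambda_adh_cc, params$lambda_adh_cs,
                         params$A0, params$T,
                         params$perimeter_order, params$contact_order)
    state$mcs <- mcs
    energy <- energy + res$delta_e

    ndiv <- 0L
    if (params$division_mode != "disabled") {
      sw <- proliferation_sweep(state, params)
      state <- sw$state
      ndiv <- nrow(sw$events)
      if (ndiv > 0L) {
        events[[length(events) + 1L]] <- sw$events
        last_div <- mcs
        # divisions change the energy outside the kernel's accumulator
        energy <- total_energy(state, params)$total
      }
    }

    e_hist[mcs] <- energy
    stats_m[mcs, ] <- c(res$attempted, res$accepted, res$rejected_same_label,
                        res$rejected_frozen, length(live_cells(state)), ndiv)

    if (mcs %% params$snapshot_every == 0L) take_snapshot(mcs)
    if (verbose && mcs %% 1000L == 0L) {
      message(sprintf("mcs %d: %d cells, E = %.4g", mcs,
                      length(live_cells(state)), energy))
    }

    if (mcs >= w && (mcs - last_div) >= w) {
      seg <- e_hist[(mcs - w + 1L):mcs]
      half <- w %/% 2L
      m1 <- mean(seg[seq_len(half)])
      m2 <- mean(seg[(half + 1L):w])
      if (abs(m2 - m1) <= params$steady_tol * max(abs(m1), 1e-12)) {
        steady_mcs <- mcs
        break
      }
    }
  }

  if (mcs %% params$snapshot_every != 0L || mcs == 0L) take_snapshot(mcs)

  done <- mcs
  stats <- tibble::as_tibble(as.data.frame(stats_m[seq_len(done), , drop = FALSE]))
  stats <- dplyr::mutate(stats,
                         mcs = seq_len(done),
                         energy = e_hist[seq_len(done)],
                         acceptance_ratio = .data$accepted / .data$attempted,
                         .before = 1)

  structure(list(
    params = params,
    reports = dplyr::bind_rows(reports),
    cells = dplyr::bind_rows(cells_l),
    events = if (length(events)) dplyr::bind_rows(events) else empty_events(),
    stats = stats,
    snapshots = snaps,
    final_state = state,
    steady_mcs = steady_mcs,
    completed_mcs = mcs
  ), class = "cpm_trajectory")
}

#' @export
print.cpm_trajectory <- function(x, ...) {
  fin <- x$reports[nrow(x$reports), ]
  cat(sprintf("<cpm_trajectory> %d MCS (%s), %d cells (%d basal / %d suprabasal), %d divisions\n",
              x$completed_mcs,
              if (is.na(x$steady_mcs)) "budget exhausted"
              else sprintf("steady at %d", x$steady_mcs),
              fin$n_cells, fin$n_basal, fin$n_suprabasal, nrow(x$events)))
  invisible(x)
}
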