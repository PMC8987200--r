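#' Morphology report of one snapshot
#'
#' Per-snapshot summary of the cell population: cell counts split into
#' basal (`ns > 0`, adhering to the substrate) and suprabasal (`ns == 0`),
#' substrate coverage (fraction of substrate-top pixels with a cell
#' directly above), means and SDs of per-cell area, height, width and
#' aspect ratio (height/width from bounding extents), the mean adhesion
#' count of basal cells, and the layer height (topmost cell pixel minus
#' substrate top).
#'
#' @param state A `cpm_state`.
#' @return A one-row tibble (a morphology report).
#' @export
#' @examples
#' measure_snapshot(generate_fixture("two-layer-6-cell"))
measure_snapshot <- function(state) {
  stopifnot(inherits(state, "cpm_state"))
  ct <- cell_table(state)
  p <- state$params
  span <- substrate_span(p)
  top_row <- state$labels[(span[1] + 1L):(span[2] + 1L), substrate_top(p) + 2L]
  coverage <- mean(top_row >= 1L)
  basal <- ct[ct$basal, ]
  tibble::tibble(
    mcs = state$mcs,
    n_cells = nrow(ct),
    n_basal = nrow(basal),
    n_suprabasal = nrow(ct) - nrow(basal),
    coverage = coverage,
    mean_area = mean(ct$area), sd_area = sd(ct$area),
    mean_height = mean(ct$height), sd_height = sd(ct$height),
    mean_width = mean(ct$width), sd_width = sd(ct$width),
    mean_aspect = mean(ct$aspect), sd_aspect = sd(ct$aspect),
    mean_ns_basal = mean(basal$ns),
    layer_height = if (nrow(ct)) max(ct$z_max) - substrate_top(p) else 0L)
}

#' Classification thresholds for collective structures
#'
#' @param aspect_delta Half-width of the cuboidal aspect-ratio band: mean
#'   aspect below `1 - aspect_delta` is squamous, above `1 + aspect_delta`
#'   columnar.
#' @param confluence_min Minimum window-mean coverage that counts as a
#'   confluent layer (thermal fluctuations transiently open single-pixel
#'   gaps above the substrate even in a closed layer, so full confluence
#'   reads slightly below 1).
#' @param suprabasal_tol Maximum suprabasal count (within the final window)
#'   still compatible with a monolayer.
#' @param slow_frac A multilayer whose total-cell growth rate is below this
#'   fraction of `reference_rate` is labelled `multilayer_slow`.
#' @param reference_rate Reference growth rate (cells per MCS) for the slow
#'   criterion, typically the fastest rate in a sweep; `NA` disables the
#'   slow label.
#' @param window_frac Fraction of the trajectory used as the final
#'   assessment window when no steady window was detected.
#' @return A named list of thresholds.
#' @export
classification_thresholds <- function(aspect_delta = 0.25,
                                      confluence_min = 0.95,
                                      suprabasal_tol = 0,
                                      slow_frac = 0.2,
                                      reference_rate = NA_real_,
                                      window_frac = 0.25) {
  list(aspect_delta = aspect_delta, confluence_min = confluence_min,
       suprabasal_tol = suprabasal_tol, slow_frac = slow_frac,
       reference_rate = reference_rate, window_frac = window_frac)
}

#' Classify a trajectory into a collective-structure category
#'
#' Deterministically maps the morphology time series of a run to one of the
#' structure types: `non_confluent` (divisions ceased without covering the
#' substrate), `monolayer_squamous` / `monolayer_cuboidal` /
#' `monolayer_columnar` (confluent, no persistent suprabasal cells,
#' divisions self-arrested; the shape class comes from the window-mean
#' aspect ratio), `multilayer` (persistently growing suprabasal
#' population), `multilayer_slow` (multilayer growing more slowly than
#' `slow_frac` times the reference rate, or stalled with suprabasal cells
#' present), or `inconclusive` (degenerate or too-short input). The label
#' is a pure function of the reports, events, and thresholds.
#'
#' @param x A `cpm_trajectory`, or a data frame of morphology reports (one
#'   row per snapshot, as returned by [measure_snapshot()]).
#' @param events Division-event tibble (needed for the data-frame method;
#'   `NULL` means no divisions).
#' @param thresholds See [classification_thresholds()].
#' @param ... Passed between methods.
#' @return A one-row tibble: `label` plus the decision metrics
#'   (`coverage`, `mean_aspect`, `suprabasal_max`, `suprabasal_trend`,
#'   `divisions_ceased`, `growth_rate`).
#' @export
classify_trajectory <- function(x, ...) UseMethod("classify_trajectory")

#' @rdname classify_trajectory
#' @export
classify_trajectory.cpm_trajectory <- function(x, thresholds = classification_thresholds(), ...) {
  classify_trajectory(x$reports, events = x$events, thresholds = thresholds,
                      steady_mcs = x$steady_mcs)
}

#' @rdname classify_trajectory
#' @param steady_mcs MCS at which the run reached steady state (NA if it
#'   did not); used only to prefer the steady window.
#' @export
classify_trajectory.data.frame <- function(x, events = NULL,
                                           thresholds = classification_thresholds(),
                                           steady_mcs = NA_integer_, ...) {
  th <- thresholds
  out <- function(label, cov = NA_real_, asp = NA_real_, smax = NA_real_,
                  strend = NA_real_, ceased = NA, rate = NA_real_) {
    tibble::tibble(label = label, coverage = cov, mean_aspect = asp,
                   suprabasal_max = smax, suprabasal_trend = strend,
                   divisions_ceased = ceased, growth_rate = rate)
  }
  if (is.null(events)) events <- empty_events()
  if (nrow(x) < 3L || all(x$n_cells == 0)) return(out("inconclusive"))

  end <- max(x$mcs)
  win_start <- if (!is.na(steady_mcs)) {
    max(0, end - diff(range(x$mcs)) * th$window_frac)
  } else {
    end - max(diff(range(x$mcs)) * th$window_frac, 1)
  }
  w <- x[x$mcs >= win_start, ]
  if (nrow(w) < 2L) return(out("inconclusive"))

  # a run that hit the steady criterion has, by construction, had no
  # division for a full steady window
  ceased <- !is.na(steady_mcs) || !any(events$mcs > win_start)
  cov <- mean(w$coverage)
  asp <- mean(w$mean_aspect, na.rm = TRUE)
  smax <- max(w$n_suprabasal)

  # growth statistics over the final third of the whole trajectory
  third <- x[x$mcs >= end - diff(range(x$mcs)) / 3, ]
  rate <- if (nrow(third) >= 2L && diff(range(third$mcs)) > 0) {
    (third$n_cells[nrow(third)] - third$n_cells[1]) / diff(range(third$mcs))
  } else 0
  half <- x[x$mcs >= end - diff(range(x$mcs)) / 2, ]
  strend <- if (nrow(half) >= 2L) {
    mean(half$n_suprabasal[half$mcs >= stats::median(half$mcs)]) -
      mean(half$n_suprabasal[half$mcs < stats::median(half$mcs)])
  } else 0

  if (ceased) {
    if (cov < th$confluence_min) {
      return(out("non_confluent", cov, asp, smax, strend, TRUE, rate))
    }
    if (smax <= th$suprabasal_tol) {
      shape <- if (asp < 1 - th$aspect_delta) "squamous"
               else if (asp > 1 + th$aspect_delta) "columnar"
               else "cuboidal"
      return(out(paste0("monolayer_", shape), cov, asp, smax, strend, TRUE, rate))
    }
    # arrested with suprabasal cells present: a stalled multilayer
    return(out("multilayer_slow", cov, asp, smax, strend, TRUE, rate))
  }

  persistent <- smax > th$suprabasal_tol && strend > 0 &&
    w$n_suprabasal[nrow(w)] > 0
  if (persistent) {
    slow <- is.finite(th$reference_rate) &&
      rate < th$slow_frac * th$reference_rate
    return(out(if (slow) "multilayer_slow" else "multilayer",
               cov, asp, smax, strend, FALSE, rate))
  }
  out("inconclusive", cov, asp, smax, strend, FALSE, rate)
}

#' Basal-cell dynamics time series
#'
#' Tabulates, per snapshot, the basal/suprabasal split, the mean and SD of
#' basal-cell area and substrate-adhesion count, and the adhesion counts of
#' the cells that divided at that MCS — the observables of the
#' basal-dynamics analysis.
#'
#' @param traj A `cpm_trajectory`.
#' @return A tibble with one row per snapshot; zero rows for an empty
#'   trajectory.
#' @export
basal_dynamics <- function(traj) {
  stopifnot(inherits(traj, "cpm_trajectory"))
  cells <- traj$cells
  if (is.null(cells) || !nrow(cells)) {
    return(tibble::tibble(mcs = integer(), n_basal = integer(),
                          n_suprabasal = integer(), mean_basal_area = double(),
                          sd_basal_area = double(), mean_basal_ns = double(),
                          sd_basal_ns = double(), dividing_ns = list()))
  }
  ev <- traj$events
  cells |>
    dplyr::group_by(.data$mcs) |>
    dplyr::summarise(
      n_basal = sum(.data$basal),
      n_suprabasal = sum(!.data$basal),
      mean_basal_area = mean(.data$area[.data$basal]),
      sd_basal_area = sd(.data$area[.data$basal]),
      mean_basal_ns = mean(.data$ns[.data$basal]),
      sd_basal_ns = sd(.data$ns[.data$basal]),
      .groups = "drop") |>
    dplyr::mutate(dividing_ns = purrr::map(.data$mcs, function(m) {
      ev$mother_ns[ev$mcs == m]
    }))
}

#' Mean steady-state basal-cell height
#'
#' Average, over the snapshots of the final window, of the per-snapshot
#' mean height of interior basal cells. The two edge cells of the layer
#' (smallest and largest basal centroid x) are excluded whenever at least
#' three basal cells are present: border cells abut bare substrate, spread
#' sideways, and are systematically flatter than layer-interior cells.
#'
#' @param traj A `cpm_trajectory`.
#' @param window Width of the assessment window in MCS; defaults to the
#'   run's `steady_window`.
#' @param require_steady Error when the run neither reached the steady
#'   criterion nor stopped dividing within the window (set `FALSE` to
#'   measure a still-evolving trajectory anyway).
#' @return Mean interior basal-cell height in pixels.
#' @export
mean_steady_cell_height <- function(traj, window = traj$params$steady_window,
                                    require_steady = TRUE) {
  stopifnot(inherits(traj, "cpm_trajectory"))
  end <- traj$completed_mcs
  start <- max(0, end - window)
  if (require_steady && is.na(traj$steady_mcs) &&
      any(traj$events$mcs > start)) {
    abort(sprintf(paste0("no steady window: divisions still occurring after ",
                         "MCS %d (last at %d); lengthen the run or pass ",
                         "require_steady = FALSE"),
                  start, max(traj$events$mcs)),
          class = "cpm_no_steady_window")
  }
  cells <- traj$cells[traj$cells$mcs >= start, ]
  if (!nrow(cells)) abort("no cells in the assessment window",
                          class = "cpm_no_steady_window")
  per_snap <- cells |>
    dplyr::filter(.data$basal) |>
    dplyr::group_by(.data$mcs) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) >= 3L) {
        edge <- c(which.min(df$centroid_x), which.max(df$centroid_x))
        df <- df[-edge, ]
      }
      mean(df$height)
    })
  mean(unlist(per_snap))
}
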