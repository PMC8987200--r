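empty_events <- function() {
  tibble::tibble(mcs = integer(), mother = integer(), daughter = integer(),
                 normal_x = double(), normal_z = double(),
                 mother_area = double(), mother_ns = double(),
                 area_kept = double(), area_new = double())
}

#' Division probability as a Hill function of substrate adhesion
#'
#' \deqn{P_{div} = P_{max} \, n_s^k / (n_s^k + (\gamma \sqrt{A_0})^k)}
#' with `n_s` the cell's substrate-adhesion pixel count. Cells with no
#' substrate contact never divide (`P_div = 0` at `n_s = 0`): proliferation
#' requires adhesion to the substrate. The half-saturation point is at
#' `n_s = gamma * sqrt(A0)` (30 adhesion pixels at the defaults), where the
#' probability equals `P_max / 2`. Eligibility (area at least `A0`) is
#' checked by the caller, [proliferation_sweep()].
#'
#' @param n_s Numeric vector of substrate-adhesion pixel counts.
#' @param params A [cpm_params()] object.
#' @return Probabilities in `[0, P_max]`, vectorised over `n_s`.
#' @export
#' @examples
#' division_probability(c(0, 30, 60), cpm_params())
division_probability <- function(n_s, params) {
  stopifnot(inherits(params, "cpm_params"))
  half <- params$gamma * sqrt(params$A0)
  ifelse(n_s <= 0, 0, params$P_max / (1 + (half / n_s)^params$k))
}

#' Choose the division-plane normal for a cell
#'
#' Returns the unit normal of the mitotic plane under the configured
#' orientation policy. `"vertical"` gives `(1, 0)` (plane normal along x:
#' daughters placed side by side on the substrate); `"horizontal"` gives
#' `(0, 1)` (daughters stacked); `"random"` draws a uniform angle in
#' `[0, pi)`; `"major_axis"` aligns the normal with the principal
#' eigenvector of the cell's pixel-position covariance, so daughters
#' separate along the cell's long axis (a tall cell stacks its daughters).
#' A cell with isotropic second moments (eigenvalue gap below `1e-9`
#' relative) is degenerate under `"major_axis"` and falls back to a random
#' angle.
#'
#' @param state A `cpm_state`.
#' @param cell_id Id of a live cell.
#' @param mode One of `"vertical"`, `"horizontal"`, `"random"`,
#'   `"major_axis"`; defaults to the state's `division_mode`.
#' @return Unit numeric vector `c(n_x, n_z)`.
#' @export
choose_division_plane <- function(state, cell_id,
                                  mode = state$params$division_mode) {
  stopifnot(inherits(state, "cpm_state"))
  mode <- match.arg(mode, c("vertical", "horizontal", "random", "major_axis"))
  if (mode == "vertical") return(c(1, 0))
  if (mode == "horizontal") return(c(0, 1))
  if (mode == "random") {
    th <- runif(1) * pi
    return(c(cos(th), sin(th)))
  }
  idx <- which(state$labels == cell_id)
  if (!length(idx)) abort("cell not found", class = "cpm_contract_error")
  W <- nrow(state$labels)
  x <- (idx - 1L) %% W
  z <- (idx - 1L) %/% W
  cv <- stats::cov(cbind(x, z))
  if (any(!is.finite(cv))) cv <- matrix(0, 2, 2)  # single-pixel cell
  eg <- eigen(cv, symmetric = TRUE)
  gap <- eg$values[1] - eg$values[2]
  if (gap <= 1e-9 * max(eg$values[1], 1)) {
    th <- runif(1) * pi
    return(c(cos(th), sin(th)))
  }
  v <- eg$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Divide a cell along a plane through its centroid
#'
#' Partitions the mother's pixels by the signed distance of each pixel
#' centre to the plane through the mother's centroid with the given unit
#' normal. Pixels exactly on the plane are assigned as a block to the side
#' with the smaller strict-side count (negative side when equal), keeping
#' the daughter areas as balanced as possible (each about `A0/2` for an
#' `A0`-sized mother). The side with the larger mean x (then larger mean z)
#' becomes a fresh cell id; the other keeps the mother's id. Daughters then
#' regrow toward `A0` through the ordinary Potts dynamics — no growth is
#' performed here. A partition that would leave one side empty aborts the
#' division with no state change.
#'
#' @param state A `cpm_state`.
#' @param cell_id Id of a live cell with area at least 2.
#' @param normal Numeric `c(n_x, n_z)`, need not be normalised.
#' @return A list with the updated `state` and `event` (one-row tibble, or
#'   NULL when the division was aborted).
#' @export
divide_cell <- function(state, cell_id, normal) {
  stopifnot(inherits(state, "cpm_state"))
  idx <- which(state$labels == cell_id)
  if (length(idx) < 2L)
    abort("cell must have at least 2 pixels to divide",
          class = "cpm_contract_error")
  nrm <- normal / sqrt(sum(normal^2))
  W <- nrow(state$labels)
  x <- (idx - 1L) %% W
  z <- (idx - 1L) %/% W
  d <- (x - mean(x)) * nrm[1] + (z - mean(z)) * nrm[2]
  tol <- 1e-9
  pos <- d > tol
  neg <- d < -tol
  tie <- !pos & !neg
  if (any(tie)) {
    if (sum(pos) < sum(neg)) pos[tie] <- TRUE else neg[tie] <- TRUE
  }
  if (!any(pos) || !any(neg)) {
    return(list(state = state, event = NULL))  # degenerate split: abort
  }

  new_side <- if (mean(x[pos]) > mean(x[neg])) "pos"
              else if (mean(x[pos]) < mean(x[neg])) "neg"
              else if (mean(z[pos]) >= mean(z[neg])) "pos" else "neg"
  new_idx <- if (new_side == "pos") idx[pos] else idx[neg]

  new_id <- length(state$area) + 1L
  state <- grow_caches(state, new_id)
  mother_area <- state$area[cell_id]
  mother_ns <- state$ns[cell_id]
  state$labels[new_idx] <- new_id
  state <- recount_pair(state, cell_id, new_id)

  event <- tibble::tibble(
    mcs = state$mcs, mother = as.integer(cell_id),
    daughter = as.integer(new_id),
    normal_x = nrm[1], normal_z = nrm[2],
    mother_area = mother_area, mother_ns = mother_ns,
    area_kept = state$area[cell_id], area_new = state$area[new_id])
  list(state = state, event = event)
}

# local recount of the two daughters' caches; no other cell's statistics
# change because every mother-neighbour link stays an unlike-label link
recount_pair <- function(state, id1, id2) {
  W <- nrow(state$labels)
  off <- neighbour_offsets(state$params$perimeter_order)
  for (id in c(id1, id2)) {
    idx <- which(state$labels == id)
    x <- (idx - 1L) %% W
    z <- (idx - 1L) %/% W
    state$area[id] <- length(idx)
    state$sumx[id] <- sum(x)
    state$sumz[id] <- sum(z)
    state$ns[id] <- sum(state$subadj[idx])
    bnd <- 0L
    for (t in seq_len(nrow(off))) {
      nb <- state$labels[idx + off[t, 1L] + off[t, 2L] * W]
      bnd <- bnd + sum(nb != id)
    }
    state$boundary[id] <- bnd
  }
  state
}

#' Proliferation sweep: one division opportunity per cell per MCS
#'
#' Iterates the live cells in randomised order; every cell whose cached
#' area is at least `A0` divides with probability [division_probability()],
#' along the plane chosen by [choose_division_plane()]. Called once per MCS
#' after the Monte Carlo step; skipped entirely when
#' `division_mode == "disabled"`.
#'
#' @param state A `cpm_state` with exact caches.
#' @param params Parameters; defaults to the state's own.
#' @return A list with the updated `state` and `events` (tibble of division
#'   events, possibly empty).
#' @export
proliferation_sweep <- function(state, params = state$params) {
  stopifnot(inherits(state, "cpm_state"))
  if (params$division_mode == "disabled") {
    return(list(state = state, events = empty_events()))
  }
  ids <- live_cells(state)
  eligible <- ids[state$area[ids] >= params$A0]
  if (!length(eligible)) return(list(state = state, events = empty_events()))
  if (length(eligible) > 1L) eligible <- sample(eligible)
  events <- list()
  for (id in eligible) {
    p <- division_probability(state$ns[id], params)
    if (p <= 0 || runif(1) >= p) next
    nrm <- choose_division_plane(state, id, params$division_mode)
    res <- divide_cell(state, id, nrm)
    state <- res$state
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
  }
  list(state = state,
       events = if (length(events)) dplyr::bind_rows(events) else empty_events())
}
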