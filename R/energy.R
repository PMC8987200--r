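#' Total Potts energy of a configuration
#'
#' Evaluates the full energy functional by direct summation over the grid:
#' the compressibility term `lambda_area * sum((A - A0)^2)` over cells, the
#' contractility term `lambda_cont * sum(L^2)` with `L` the boundary-link
#' count under the configured perimeter neighbourhood, and the adhesion term
#' summing the contact energy `J` once per unordered neighbour pair of
#' unlike labels within the contact neighbourhood (`J = lambda_adh_cc` for
#' cell-cell, `lambda_adh_cs` for cell-substrate, 0 when either site is
#' medium or wall). Computed from the raw label matrix, independently of the
#' cached statistics.
#'
#' @param state A `cpm_state`.
#' @param params Parameters; defaults to the state's own.
#' @return An object of class `cpm_energy` with fields `area_term`,
#'   `contractility_term`, `adhesion_term`, `total`.
#' @export
#' @examples
#' st <- initialize_simulation(cpm_params_reduced())
#' total_energy(st)
total_energy <- function(state, params = state$params) {
  stopifnot(inherits(state, "cpm_state"))
  labels <- state$labels
  W <- nrow(labels); H <- ncol(labels)

  idx <- which(labels >= 1L)
  ids <- labels[idx]
  nmax <- if (length(ids)) max(ids) else 0L
  area <- tabulate(ids, nbins = nmax)
  live <- area > 0

  area_term <- params$lambda_area * sum((area[live] - params$A0)^2)

  bnd <- double(nmax)
  if (length(idx)) {
    off <- neighbour_offsets(params$perimeter_order)
    for (t in seq_len(nrow(off))) {
      nb <- labels[idx + off[t, 1L] + off[t, 2L] * W]
      bnd <- bnd + tabulate(ids[nb != ids], nbins = nmax)
    }
  }
  cont_term <- params$lambda_cont * sum(bnd[live]^2)

  # unordered pairs: offsets (1,0), (0,1) for order 1, plus the two
  # diagonals (1,1), (1,-1) for order 2
  pair_off <- list(c(1L, 0L), c(0L, 1L))
  if (params$contact_order >= 2L) {
    pair_off <- c(pair_off, list(c(1L, 1L), c(1L, -1L)))
  }
  adh <- 0
  for (o in pair_off) {
    xs <- seq_len(W - o[1L])
    zs <- if (o[2L] >= 0L) seq_len(H - o[2L]) else seq.int(1L - o[2L], H)
    u <- labels[xs, zs, drop = FALSE]
    v <- labels[xs + o[1L], zs + o[2L], drop = FALSE]
    cc <- sum(u >= 1L & v >= 1L & u != v)
    cs <- sum((u >= 1L & v == CPM_SUBSTRATE) | (u == CPM_SUBSTRATE & v >= 1L))
    adh <- adh + params$lambda_adh_cc * cc + params$lambda_adh_cs * cs
  }

  structure(list(area_term = area_term,
                 contractility_term = cont_term,
                 adhesion_term = adh,
                 total = area_term + cont_term + adh),
            class = "cpm_energy")
}

#' Incremental energy change of a proposed pixel copy
#'
#' Energy difference `E(after) - E(before)` for copying the label of
#' `source` onto `target`, computed in O(1) by touching only the terms of
#' the two affected cells and the contact links incident on the target
#' site. The state is not modified. Sites are 0-based `(x, z)` pairs; they
#' must be face-adjacent, carry different labels, and neither may be wall
#' or substrate.
#'
#' @param state A `cpm_state` with exact caches.
#' @param source,target Integer vectors `c(x, z)`, 0-based.
#' @param params Parameters; defaults to the state's own.
#' @return The scalar energy change.
#' @export
delta_energy <- function(state, source, target, params = state$params) {
  stopifnot(inherits(state, "cpm_state"))
  source <- as.integer(source); target <- as.integer(target)
  stopifnot(length(source) == 2L, length(target) == 2L)
  if (sum(abs(source - target)) != 1L)
    abort("`source` and `target` must be face-adjacent sites",
          class = "cpm_contract_error")
  a <- state$labels[source[1L] + 1L, source[2L] + 1L]
  b <- state$labels[target[1L] + 1L, target[2L] + 1L]
  if (a == b)
    abort("source and target carry the same label", class = "cpm_contract_error")
  if (a %in% c(CPM_WALL, CPM_SUBSTRATE) || b %in% c(CPM_WALL, CPM_SUBSTRATE))
    abort("wall and substrate are frozen compartments", class = "cpm_contract_error")
  cpm_delta_site(state$labels, state$area, state$boundary,
                 target[1L], target[2L], a,
                 params$lambda_area, params$lambda_cont,
                 params$lambda_adh_cc, params$lambda_adh_cs,
                 params$A0, params$perimeter_order, params$contact_order)
}

#' @export
print.cpm_energy <- function(x, ...) {
  cat(sprintf("<cpm_energy> total %g (area %g + contractility %g + adhesion %g)\n",
              x$total, x$area_term, x$contractility_term, x$adhesion_term))
  invisible(x)
}

#' @rdname total_energy
#' @param x A `cpm_energy` object.
#' @param ... Unused.
#' @method tidy cpm_energy
#' @export
tidy.cpm_energy <- function(x, ...) {
  tibble::tibble(term = c("area", "contractility", "adhesion", "total"),
                 energy = c(x$area_term, x$contractility_term,
                            x$adhesion_term, x$total))
}
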