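#' Energy of a single rectangular cell
#'
#' Closed-form energy of an idealised rectangular cell of length `l` and
#' height `h` on the substrate:
#' \deqn{E(l, h) = \lambda_{area} (l h - A_0)^2 + \lambda_{cont} (2l + 2h)^2
#'   + \lambda_{adh}^{cs} \, l.}
#' The perimeter `2l + 2h` matches the order-1 boundary-link count of a
#' lattice rectangle exactly, and the substrate term counts the `l` contact
#' links along the cell's base.
#'
#' @param l,h Cell length and height in pixels, positive; vectorised.
#' @param params A [cpm_params()] object (`lambda_area`, `lambda_cont`,
#'   `lambda_adh_cs`, `A0` are used).
#' @return Numeric vector of energies.
#' @export
#' @examples
#' rect_energy(15, 15, cpm_params(lambda_area = 1, lambda_cont = 3,
#'                                lambda_adh_cs = -100))
rect_energy <- function(l, h, params) {
  stopifnot(inherits(params, "cpm_params"))
  if (any(l <= 0) || any(h <= 0))
    abort("`l` and `h` must be positive", class = "cpm_domain_error")
  params$lambda_area * (l * h - params$A0)^2 +
    params$lambda_cont * (2 * l + 2 * h)^2 +
    params$lambda_adh_cs * l
}

#' Stationarity residuals of the rectangular-cell energy
#'
#' The two partial derivatives of [rect_energy()],
#' \deqn{\partial E/\partial l = 2\lambda_{area} h (l h - A_0)
#'   + 8\lambda_{cont}(l + h) + \lambda_{adh}^{cs},}
#' \deqn{\partial E/\partial h = 2\lambda_{area} l (l h - A_0)
#'   + 8\lambda_{cont}(l + h),}
#' both zero at a stationary point.
#'
#' @inheritParams rect_energy
#' @return A tibble with columns `dE_dl`, `dE_dh`, vectorised over `l`, `h`.
#' @export
rect_stationarity_residual <- function(l, h, params) {
  stopifnot(inherits(params, "cpm_params"))
  common <- 8 * params$lambda_cont * (l + h)
  tibble::tibble(
    dE_dl = 2 * params$lambda_area * h * (l * h - params$A0) + common +
      params$lambda_adh_cs,
    dE_dh = 2 * params$lambda_area * l * (l * h - params$A0) + common)
}

#' Mechanical equilibrium of the rectangular cell
#'
#' Global minimiser of [rect_energy()] over the box
#' `(0, box_max]^2` (default `box_max = 4 * sqrt(A0)`), found by
#' multi-start local descent from the best points of a coarse grid. When
#' `lambda_adh_cs = 0` the energy is symmetric in `l` and `h` and the
#' minimum lies on the diagonal, so the search is done in one dimension and
#' returns `l_star == h_star` exactly. A minimiser within `1e-3 * box_max`
#' of the box boundary is flagged.
#'
#' @param params A [cpm_params()] object.
#' @param box_max Upper edge of the search box in pixels.
#' @param coarse_n Coarse-grid resolution per axis.
#' @param n_starts Number of local descents started from the best coarse
#'   points.
#' @return An object of class `rect_equilibrium` with fields `l_star`,
#'   `h_star`, `aspect_ratio` (`h_star / l_star`), `area`, `energy`,
#'   `on_boundary`, `params`.
#' @export
#' @examples
#' rect_equilibrium(cpm_params(lambda_area = 1, lambda_cont = 3,
#'                             lambda_adh_cs = -300))
rect_equilibrium <- function(params, box_max = 4 * sqrt(params$A0),
                             coarse_n = 121, n_starts = 8) {
  stopifnot(inherits(params, "cpm_params"))
  if (params$lambda_area <= 0 && params$lambda_cont <= 0)
    abort("energy unbounded below: need lambda_area > 0 or lambda_cont > 0",
          class = "cpm_domain_error")
  lo <- 1e-8

  if (params$lambda_adh_cs == 0) {
    f1 <- function(s) rect_energy(s, s, params)
    opt <- stats::optimize(f1, lower = lo, upper = box_max, tol = 1e-10)
    ls <- opt$minimum
    return(new_rect_equilibrium(ls, ls, opt$objective, box_max, params))
  }

  g <- seq(box_max / coarse_n, box_max, length.out = coarse_n)
  egrid <- outer(g, g, function(l, h) rect_energy(l, h, params))
  ord <- order(egrid)[seq_len(n_starts)]
  starts <- cbind(g[(ord - 1L) %% coarse_n + 1L],
                  g[(ord - 1L) %/% coarse_n + 1L])

  fn <- function(p) rect_energy(p[1], p[2], params)
  gr <- function(p) {
    r <- rect_stationarity_residual(p[1], p[2], params)
    c(r$dE_dl, r$dE_dh)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- optim(starts[s, ], fn, gr, method = "L-BFGS-B",
               lower = c(lo, lo), upper = c(box_max, box_max),
               control = list(factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  new_rect_equilibrium(best$par[1], best$par[2], best$value, box_max, params)
}

new_rect_equilibrium <- function(l, h, e, box_max, params) {
  structure(list(
    l_star = l, h_star = h, aspect_ratio = h / l, area = l * h, energy = e,
    on_boundary = min(l, h) < 1e-3 * box_max ||
      max(l, h) > box_max * (1 - 1e-3),
    params = params), class = "rect_equilibrium")
}

#' @export
print.rect_equilibrium <- function(x, ...) {
  cat(sprintf("<rect_equilibrium> l* = %.3f, h* = %.3f (aspect %.3f, area %.1f), E = %.4g%s\n",
              x$l_star, x$h_star, x$aspect_ratio, x$area, x$energy,
              if (x$on_boundary) " [on search-box boundary]" else ""))
  invisible(x)
}

#' @rdname rect_equilibrium
#' @param x A `rect_equilibrium` object.
#' @param ... Unused.
#' @method tidy rect_equilibrium
#' @export
tidy.rect_equilibrium <- function(x, ...) {
  tibble::tibble(l_star = x$l_star, h_star = x$h_star,
                 aspect_ratio = x$aspect_ratio, area = x$area,
                 energy = x$energy, on_boundary = x$on_boundary)
}

#' @rdname rect_equilibrium
#' @method glance rect_equilibrium
#' @export
glance.rect_equilibrium <- function(x, ...) tidy(x)

#' Analytic single-cell phase surface
#'
#' Solves the rectangular-cell equilibrium for every row of a parameter
#' grid and returns the equilibrium aspect ratio and area per grid point —
#' the analytic counterpart of the simulated single-cell phase diagram.
#'
#' @param param_grid A data frame with any of the columns `lambda_area`,
#'   `lambda_cont`, `lambda_adh_cs`, `A0`; one equilibrium is computed per
#'   row (other parameters come from `base_params`).
#' @param base_params Baseline [cpm_params()] supplying unlisted fields.
#' @param ... Passed on to [rect_equilibrium()].
#' @return The grid with columns `l_star`, `h_star`, `aspect_ratio`,
#'   `area`, `energy`, `on_boundary` appended.
#' @export
#' @examples
#' grid <- tidyr::expand_grid(lambda_cont = c(1, 3), lambda_adh_cs = c(-100, -700))
#' analytic_phase_surface(grid)
analytic_phase_surface <- function(param_grid, base_params = cpm_params(), ...) {
  stopifnot(is.data.frame(param_grid))
  allowed <- c("lambda_area", "lambda_cont", "lambda_adh_cs", "A0")
  bad <- setdiff(names(param_grid), allowed)
  if (length(bad))
    abort(paste0("unsupported grid column(s): ", paste(bad, collapse = ", ")),
          class = "cpm_params_error")
  extra <- list(...)
  res <- purrr::pmap(param_grid, function(...) {
    p <- do.call(update_params, c(list(base_params), list(...)))
    tidy(do.call(rect_equilibrium, c(list(p), extra)))
  })
  dplyr::bind_cols(tibble::as_tibble(param_grid), dplyr::bind_rows(res))
}
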