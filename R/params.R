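#' Simulation parameters for the epithelial Potts model
#'
#' Bundles every mechanical, proliferation, geometry, and run-control
#' parameter of the model. The energy functional is
#' \deqn{E = \lambda_{area} \sum_\sigma (A_\sigma - A_0)^2
#'         + \lambda_{cont} \sum_\sigma L_\sigma^2
#'         + \sum_{\langle i,j \rangle} J(\sigma_i, \sigma_j)
#'           (1 - \delta_{\sigma_i \sigma_j}),}
#' where \eqn{J} equals `lambda_adh_cc` between unlike cells,
#' `lambda_adh_cs` between a cell and the substrate, and 0 when either site
#' is medium or wall. Both adhesion parameters must be non-positive (contact
#' is energetically favourable). A cell with area at least `A0` divides per
#' Monte Carlo step with probability
#' \deqn{P_{div} = P_{max} \, n_s^k / (n_s^k + (\gamma \sqrt{A_0})^k),}
#' a Hill function of its substrate-adhesion pixel count \eqn{n_s}.
#'
#' @param lambda_area Compressibility penalty (energy per squared
#'   pixel-area deviation), non-negative.
#' @param lambda_cont Cortical contractility penalty (energy per squared
#'   boundary-link count), non-negative.
#' @param lambda_adh_cc Cell-cell boundary energy per contact link,
#'   non-positive.
#' @param lambda_adh_cs Cell-substrate boundary energy per contact link,
#'   non-positive.
#' @param A0 Target cell area in pixels.
#' @param T Potts temperature (energy scale of the Metropolis rule).
#' @param gamma Hill half-saturation multiplier; the half-saturation point
#'   is `gamma * sqrt(A0)` adhesion pixels.
#' @param k Hill coefficient.
#' @param P_max Maximal division probability per MCS, in \[0, 1\].
#' @param lattice_width,lattice_height Lattice size in sites (x along the
#'   substrate, z perpendicular to it).
#' @param substrate_width Width of the frozen substrate strip in pixels;
#'   must fit inside the wall ring.
#' @param substrate_thickness Thickness of the substrate strip in pixels.
#' @param division_mode Orientation policy for the mitotic plane normal:
#'   `"vertical"` (normal (1,0): daughters side by side), `"horizontal"`
#'   (normal (0,1): daughters stacked), `"random"` (uniform angle),
#'   `"major_axis"` (normal along the principal axis of the cell's pixel
#'   covariance, so daughters separate along the major axis), or
#'   `"disabled"`.
#' @param contact_order Neighbourhood order of the adhesion sum: 1
#'   (von Neumann, 4 neighbours) or 2 (Moore, 8 neighbours).
#' @param perimeter_order Neighbourhood order of the boundary-link count
#'   \eqn{L_\sigma}; order 1 makes a rectangle's count exactly `2l + 2h`.
#' @param max_mcs Run length in Monte Carlo steps.
#' @param seed RNG seed recorded with every run.
#' @param snapshot_every Snapshot/measurement cadence in MCS.
#' @param steady_window,steady_tol Steady-state detection: the run stops
#'   early when no division occurred during the last `steady_window` MCS and
#'   the relative drift of the mean total energy between the two halves of
#'   that window is below `steady_tol`.
#'
#' @return An object of class `cpm_params` (a named list).
#' @seealso [cpm_params_reduced()] for the desk-scale preset,
#'   [initialize_simulation()], [run_simulation()].
#' @export
#' @examples
#' p <- cpm_params(lambda_cont = 3, lambda_adh_cs = -300)
#' adhesion_ratio(p)
cpm_params <- function(lambda_area = 1,
                       lambda_cont = 3,
                       lambda_adh_cc = -150,
                       lambda_adh_cs = -300,
                       A0 = 225,
                       T = 50,
                       gamma = 2,
                       k = 10,
                       P_max = 0.1,
                       lattice_width = 480,
                       lattice_height = 195,
                       substrate_width = 450,
                       substrate_thickness = 3,
                       division_mode = c("vertical", "horizontal", "random",
                                         "major_axis", "disabled"),
                       contact_order = 2,
                       perimeter_order = 1,
                       max_mcs = 50000,
                       seed = 1,
                       snapshot_every = 100,
                       steady_window = 500,
                       steady_tol = 1e-3) {
  division_mode <- match.arg(division_mode)
  p <- list(
    lambda_area = as.double(lambda_area),
    lambda_cont = as.double(lambda_cont),
    lambda_adh_cc = as.double(lambda_adh_cc),
    lambda_adh_cs = as.double(lambda_adh_cs),
    A0 = as.double(A0),
    T = as.double(T),
    gamma = as.double(gamma),
    k = as.double(k),
    P_max = as.double(P_max),
    lattice_width = as.integer(lattice_width),
    lattice_height = as.integer(lattice_height),
    substrate_width = as.integer(substrate_width),
    substrate_thickness = as.integer(substrate_thickness),
    division_mode = division_mode,
    contact_order = as.integer(contact_order),
    perimeter_order = as.integer(perimeter_order),
    max_mcs = as.integer(max_mcs),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    snapshot_every = as.integer(snapshot_every),
    steady_window = as.integer(steady_window),
    steady_tol = as.double(steady_tol)
  )
  class(p) <- "cpm_params"
  validate_cpm_params(p)
  p
}

validate_cpm_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(msg, class = "cpm_params_error")
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("lambda_area", "lambda_cont", "lambda_adh_cc", "lambda_adh_cs",
              "A0", "T", "gamma", "k", "P_max", "steady_tol")) {
    chk(num1(p[[f]]), paste0("`", f, "` must be a finite numeric scalar"))
  }
  chk(p$lambda_area >= 0, "`lambda_area` must be >= 0")
  chk(p$lambda_cont >= 0, "`lambda_cont` must be >= 0")
  chk(p$lambda_adh_cc <= 0, "`lambda_adh_cc` must be <= 0 (adhesion favours contact)")
  chk(p$lambda_adh_cs <= 0, "`lambda_adh_cs` must be <= 0 (adhesion favours contact)")
  chk(p$A0 > 0, "`A0` must be > 0")
  chk(p$T > 0, "`T` must be > 0")
  chk(p$gamma > 0, "`gamma` must be > 0")
  chk(p$k > 0, "`k` must be > 0")
  chk(p$P_max >= 0 && p$P_max <= 1, "`P_max` must lie in [0, 1]")
  chk(p$lattice_width >= 5 && p$lattice_height >= 5,
      "lattice must be at least 5 x 5 sites")
  chk(p$substrate_width >= 1, "`substrate_width` must be >= 1")
  chk(p$substrate_width <= p$lattice_width,
      "`substrate_width` must not exceed `lattice_width`")
  chk(p$substrate_thickness >= 1, "`substrate_thickness` must be >= 1")
  chk(p$contact_order %in% c(1L, 2L), "`contact_order` must be 1 or 2")
  chk(p$perimeter_order %in% c(1L, 2L), "`perimeter_order` must be 1 or 2")
  chk(p$max_mcs >= 0, "`max_mcs` must be >= 0")
  chk(p$snapshot_every >= 1, "`snapshot_every` must be >= 1")
  chk(p$steady_window >= 2, "`steady_window` must be >= 2")
  invisible(p)
}

#' Desk-scale parameter preset
#'
#' The reduced lattice used for fast phase-diagram probing: 240 x 100 sites
#' with a 220-pixel substrate and a 10,000-MCS budget. Shape metrics are
#' local, so a narrower domain leaves single-cell and per-cell monolayer
#' morphology essentially unchanged while cutting run time by roughly 4x
#' relative to the production 480 x 195 domain.
#'
#' @param ... Overrides passed on to [cpm_params()].
#' @return A `cpm_params` object.
#' @export
#' @examples
#' cpm_params_reduced(lambda_cont = 7, lambda_adh_cs = -700)$lattice_width
cpm_params_reduced <- function(...) {
  args <- modifyList(list(lattice_width = 240, lattice_height = 100,
                          substrate_width = 220, max_mcs = 10000),
                     list(...))
  do.call(cpm_params, args)
}

#' Adhesion ratio alpha
#'
#' The ratio `lambda_adh_cs / lambda_adh_cc` of substrate to cell-cell
#' adhesion strength, the control parameter of the collective phase
#' diagrams. Large alpha means relatively weak lateral cell-cell adhesion.
#'
#' @param params A `cpm_params` object.
#' @return A numeric scalar (`Inf` when `lambda_adh_cc` is 0).
#' @export
adhesion_ratio <- function(params) {
  stopifnot(inherits(params, "cpm_params"))
  if (params$lambda_adh_cc == 0) return(Inf)
  params$lambda_adh_cs / params$lambda_adh_cc
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A `cpm_params` object.
#' @param ... Named fields to replace.
#' @return A `cpm_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cpm_params"))
  new <- list(...)
  bad <- setdiff(names(new), names(unclass(params)))
  if (length(bad)) {
    abort(paste0("unknown parameter field(s): ", paste(bad, collapse = ", ")),
          class = "cpm_params_error")
  }
  do.call(cpm_params, modifyList(unclass(params), new))
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("<cpm_params>\n")
  cat(sprintf("  mechanics : lambda_area=%g lambda_cont=%g lambda_adh_cc=%g lambda_adh_cs=%g (alpha=%g)\n",
              x$lambda_area, x$lambda_cont, x$lambda_adh_cc, x$lambda_adh_cs,
              adhesion_ratio(x)))
  cat(sprintf("  potts     : A0=%g T=%g perimeter_order=%d contact_order=%d\n",
              x$A0, x$T, x$perimeter_order, x$contact_order))
  cat(sprintf("  division  : mode=%s gamma=%g k=%g P_max=%g\n",
              x$division_mode, x$gamma, x$k, x$P_max))
  cat(sprintf("  geometry  : %d x %d lattice, substrate %d x %d\n",
              x$lattice_width, x$lattice_height, x$substrate_width,
              x$substrate_thickness))
  cat(sprintf("  run       : max_mcs=%d seed=%s snapshot_every=%d steady (%d MCS, tol %g)\n",
              x$max_mcs, if (is.null(x$seed)) "NULL" else as.character(x$seed),
              x$snapshot_every, x$steady_window, x$steady_tol))
  invisible(x)
}
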