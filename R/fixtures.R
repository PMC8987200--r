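# Hand-constructed lattice states with known exact metrics, for unit tests
# and worked examples.  Each fixture is built in code, deterministically.

# assemble a state from explicit geometry; cells is a named list mapping
# id -> integer matrix of 0-based (x, z) pixel coordinates (one row each)
build_fixture_state <- function(W, H, substrate_width, substrate_thickness,
                                cells, params_args = list()) {
  labels <- matrix(CPM_MEDIUM, W, H)
  labels[c(1L, W), ] <- CPM_WALL
  labels[, c(1L, H)] <- CPM_WALL
  x0 <- (W - substrate_width) %/% 2L
  labels[(x0 + 1L):(x0 + substrate_width), 2L:(substrate_thickness + 1L)] <- CPM_SUBSTRATE
  for (id in names(cells)) {
    px <- cells[[id]]
    stopifnot(all(labels[cbind(px[, 1L] + 1L, px[, 2L] + 1L)] == CPM_MEDIUM))
    labels[cbind(px[, 1L] + 1L, px[, 2L] + 1L)] <- as.integer(id)
  }
  p <- do.call(cpm_params, modifyList(
    list(lattice_width = W, lattice_height = H,
         substrate_width = substrate_width,
         substrate_thickness = substrate_thickness,
         division_mode = "disabled", max_mcs = 0L),
    params_args))
  new_cpm_state(labels, p)
}

rect_pixels <- function(x_range, z_range) {
  as.matrix(expand.grid(x = x_range, z = z_range))
}

#' Deterministic test fixtures
#'
#' Small hand-constructed lattices with known exact metrics. The catalogue:
#' \describe{
#'   \item{`single-cell`}{The standard initial condition (one 15 x 15 cell
#'     on the substrate) on a 60 x 40 lattice.}
#'   \item{`domino`}{One 2-pixel horizontal cell on the substrate
#'     (area 2, `ns` 2).}
#'   \item{`two-layer-6-cell`}{Four basal cells in a row plus two
#'     suprabasal cells stacked on top: `(n_basal, n_suprabasal) = (4, 2)`.}
#'   \item{`L-shaped-cell`}{One L-shaped cell spanning rows 3-9: area 20,
#'     boundary-link count 24 (order 1), `ns` 5, height 7, width 5.}
#'   \item{`pre-confluent-monolayer`}{Three separated 8 x 10 cells on a
#'     40-pixel substrate: coverage 24/40.}
#' }
#'
#' @param name Fixture name from the catalogue above.
#' @return A `cpm_state` with exact caches.
#' @export
#' @examples
#' measure_snapshot(generate_fixture("pre-confluent-monolayer"))
generate_fixture <- function(name) {
  catalogue <- c("single-cell", "domino", "two-layer-6-cell",
                 "L-shaped-cell", "pre-confluent-monolayer")
  if (!is.character(name) || length(name) != 1L || !name %in% catalogue) {
    abort(paste0("unknown fixture; catalogue: ",
                 paste(catalogue, collapse = ", ")),
          class = "cpm_fixture_error")
  }
  switch(name,
    "single-cell" = initialize_simulation(
      cpm_params(lattice_width = 60, lattice_height = 40,
                 substrate_width = 50, division_mode = "disabled",
                 max_mcs = 0L)),
    "domino" = build_fixture_state(
      12L, 8L, substrate_width = 8L, substrate_thickness = 2L,
      cells = list(`1` = rect_pixels(5:6, 3L)),
      params_args = list(A0 = 4)),
    "two-layer-6-cell" = build_fixture_state(
      30L, 20L, substrate_width = 28L, substrate_thickness = 2L,
      cells = list(`1` = rect_pixels(2:6, 3:8),
                   `2` = rect_pixels(7:11, 3:8),
                   `3` = rect_pixels(12:16, 3:8),
                   `4` = rect_pixels(17:21, 3:8),
                   `5` = rect_pixels(4:8, 9:12),
                   `6` = rect_pixels(12:16, 9:12)),
      params_args = list(A0 = 30)),
    "L-shaped-cell" = build_fixture_state(
      14L, 14L, substrate_width = 10L, substrate_thickness = 2L,
      cells = list(`1` = rbind(rect_pixels(3:7, 3:4),
                               rect_pixels(3:4, 5:9))),
      params_args = list(A0 = 20)),
    "pre-confluent-monolayer" = build_fixture_state(
      46L, 20L, substrate_width = 40L, substrate_thickness = 2L,
      cells = list(`1` = rect_pixels(4:11, 3:12),
                   `2` = rect_pixels(18:25, 3:12),
                   `3` = rect_pixels(32:39, 3:12)),
      params_args = list(A0 = 80)))
}
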