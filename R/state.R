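#' Lattice state of the simulation
#'
#' A `cpm_state` holds the label grid together with per-cell cached
#' statistics. The grid is an integer matrix of dimension
#' `(lattice_width, lattice_height)`; element `[x + 1, z + 1]` is the label
#' of the 0-based site `(x, z)`, with `x` running along the substrate and
#' `z` perpendicular to it (`z = 0` at the bottom wall). Caches (`area`,
#' `boundary`, `ns`, `sumx`, `sumz`) are numeric vectors indexed by cell id
#' and are maintained incrementally by the dynamics; [recount_cell_statistics()]
#' rebuilds them from the raw grid and is the oracle the incremental
#' bookkeeping is tested against.
#'
#' @name cpm_state
NULL

new_cpm_state <- function(labels, params, mcs = 0L) {
  state <- structure(
    list(labels = labels,
         area = double(0), boundary = double(0), ns = double(0),
         sumx = double(0), sumz = double(0),
         subadj = substrate_adjacency(labels),
         mcs = as.integer(mcs),
         params = params),
    class = "cpm_state")
  recount_cell_statistics(state)
}

# Logical matrix: site has at least one face-adjacent substrate pixel.
# Static geometry because the substrate is frozen.
substrate_adjacency <- function(labels) {
  W <- nrow(labels); H <- ncol(labels)
  sub <- labels == CPM_SUBSTRATE
  sa <- matrix(FALSE, W, H)
  sa[1:(W - 1), ] <- sa[1:(W - 1), ] | sub[2:W, ]
  sa[2:W, ] <- sa[2:W, ] | sub[1:(W - 1), ]
  sa[, 1:(H - 1)] <- sa[, 1:(H - 1)] | sub[, 2:H]
  sa[, 2:H] <- sa[, 2:H] | sub[, 1:(H - 1)]
  sa
}

# Directed neighbour offsets; the first 4 are the von Neumann
# neighbourhood (order 1), all 8 the Moore neighbourhood (order 2).
neighbour_offsets <- function(order) {
  off <- cbind(dx = c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L),
               dz = c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L))
  off[seq_len(if (order >= 2) 8L else 4L), , drop = FALSE]
}

#' Initialize the standard simulation geometry
#'
#' Builds the lattice the model starts from: a one-site-thick frozen wall
#' ring on the border, a frozen substrate strip of `substrate_width` by
#' `substrate_thickness` pixels resting on the bottom wall and centred
#' horizontally, one square cell of side `round(sqrt(A0))` sitting on the
#' substrate and centred horizontally, and medium everywhere else.
#'
#' @param params A [cpm_params()] object.
#' @return A `cpm_state` with exact per-cell caches and `mcs = 0`.
#' @export
#' @examples
#' st <- initialize_simulation(cpm_params_reduced())
#' cell_table(st)
initialize_simulation <- function(params) {
  stopifnot(inherits(params, "cpm_params"))
  W <- params$lattice_width
  H <- params$lattice_height
  side <- as.integer(round(sqrt(params$A0)))
  thick <- params$substrate_thickness
  geom_err <- function(msg) abort(msg, class = "cpm_geometry_error")

  if (params$substrate_width > W - 2L)
    geom_err("substrate wider than the lattice interior")
  if (side > params$substrate_width)
    geom_err("initial cell wider than the substrate")
  if (thick + side + 2L > H)
    geom_err("lattice too short for substrate plus initial cell")

  labels <- matrix(CPM_MEDIUM, W, H)
  labels[c(1L, W), ] <- CPM_WALL
  labels[, c(1L, H)] <- CPM_WALL

  x0 <- (W - params$substrate_width) %/% 2L      # 0-based left edge
  labels[(x0 + 1L):(x0 + params$substrate_width), 2L:(thick + 1L)] <- CPM_SUBSTRATE

  cx0 <- (W - side) %/% 2L
  if (cx0 < x0 || cx0 + side > x0 + params$substrate_width)
    geom_err("initial cell does not fit on the substrate")
  z0 <- thick + 1L                               # 0-based first row above substrate
  labels[(cx0 + 1L):(cx0 + side), (z0 + 1L):(z0 + side)] <- 1L

  new_cpm_state(labels, params)
}

#' Recompute all per-cell statistics from the raw grid
#'
#' Full recount of every cached quantity (area, boundary-link count under
#' the configured perimeter neighbourhood, substrate-adhesion pixel count,
#' centroid coordinate sums) directly from the label matrix. This is the
#' oracle against which the incremental cache updates of the Monte Carlo
#' kernel are validated, and the repair path for externally edited grids.
#'
#' @param state A `cpm_state`.
#' @return The state with exact caches.
#' @export
recount_cell_statistics <- function(state) {
  stopifnot(inherits(state, "cpm_state"))
  labels <- state$labels
  W <- nrow(labels)
  idx <- which(labels >= 1L)
  ids <- labels[idx]
  nmax <- if (length(ids)) max(ids) else 0L

  area <- as.double(tabulate(ids, nbins = nmax))
  sumx <- double(nmax); sumz <- double(nmax)
  ns <- double(nmax); bnd <- double(nmax)

  if (length(idx)) {
    x <- (idx - 1L) %% W
    z <- (idx - 1L) %/% W
    sx <- rowsum(cbind(x, z), ids)
    rid <- as.integer(rownames(sx))
    sumx[rid] <- sx[, 1L]
    sumz[rid] <- sx[, 2L]

    sa <- substrate_adjacency(labels)
    ns <- as.double(tabulate(ids[sa[idx]], nbins = nmax))

    off <- neighbour_offsets(state$params$perimeter_order)
    for (t in seq_len(nrow(off))) {
      nb <- labels[idx + off[t, 1L] + off[t, 2L] * W]
      diff <- nb != ids
      bnd <- bnd + tabulate(ids[diff], nbins = nmax)
    }
  }

  state$area <- area
  state$boundary <- bnd
  state$ns <- ns
  state$sumx <- sumx
  state$sumz <- sumz
  state$subadj <- substrate_adjacency(labels)
  state
}

#' Per-cell record table
#'
#' One row per live cell: pixel area, boundary-link count, substrate
#' adhesion pixel count `ns`, centroid, bounding extents, and the derived
#' height, width, aspect ratio (`height / width`), and basal flag
#' (`ns > 0`). Coordinates are 0-based pixel indices.
#'
#' @param state A `cpm_state`.
#' @return A tibble with one row per cell.
#' @export
cell_table <- function(state) {
  stopifnot(inherits(state, "cpm_state"))
  labels <- state$labels
  W <- nrow(labels)
  idx <- which(labels >= 1L)
  if (!length(idx)) {
    return(tibble::tibble(
      id = integer(), area = double(), boundary = double(), ns = double(),
      centroid_x = double(), centroid_z = double(),
      x_min = integer(), x_max = integer(), z_min = integer(),
      z_max = integer(), width = integer(), height = integer(),
      aspect = double(), basal = logical()))
  }
  ids <- labels[idx]
  x <- (idx - 1L) %% W
  z <- (idx - 1L) %/% W
  live <- sort(unique(ids))
  f <- factor(ids, levels = live)
  xmin <- vapply(split(x, f), min, 0L)
  xmax <- vapply(split(x, f), max, 0L)
  zmin <- vapply(split(z, f), min, 0L)
  zmax <- vapply(split(z, f), max, 0L)
  tibble::tibble(
    id = live,
    area = state$area[live],
    boundary = state$boundary[live],
    ns = state$ns[live],
    centroid_x = state$sumx[live] / state$area[live],
    centroid_z = state$sumz[live] / state$area[live],
    x_min = unname(xmin), x_max = unname(xmax),
    z_min = unname(zmin), z_max = unname(zmax),
    width = unname(xmax - xmin + 1L),
    height = unname(zmax - zmin + 1L),
    aspect = unname((zmax - zmin + 1) / (xmax - xmin + 1)),
    basal = state$ns[live] > 0
  )
}

# ids of live cells
live_cells <- function(state) which(state$area > 0)

# 0-based z of the substrate's top row (substrate occupies z = 1 .. thickness)
substrate_top <- function(params) params$substrate_thickness

# 0-based x span of the substrate strip
substrate_span <- function(params) {
  x0 <- (params$lattice_width - params$substrate_width) %/% 2L
  c(x0, x0 + params$substrate_width - 1L)
}

#' @export
print.cpm_state <- function(x, ...) {
  n <- length(live_cells(x))
  cat(sprintf("<cpm_state> %d x %d lattice, %d cell%s, mcs %d\n",
              nrow(x$labels), ncol(x$labels), n, if (n == 1) "" else "s",
              x$mcs))
  invisible(x)
}
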