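#' Read and write snapshot files
#'
#' A snapshot is a plain-text file: a header of `# key: value` lines
#' recording the full parameter set, the MCS clock, and the package
#' version, followed by the integer label matrix, one lattice row per line,
#' top row first (so the file reads like the rendered configuration).
#' Reserved codes: medium 0, substrate -1, wall -2; cells are positive ids.
#'
#' @param state A `cpm_state`.
#' @param path File path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `cpm_state` with freshly recounted caches.
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "cpm_state"))
  p <- unclass(state$params)
  hdr <- c("# epipotts snapshot",
           paste0("# version: ", as.character(packageVersion("epipotts"))),
           paste0("# mcs: ", state$mcs),
           vapply(names(p), function(k) {
             paste0("# param ", k, ": ", as.character(p[[k]]))
           }, ""))
  H <- ncol(state$labels)
  rows <- vapply(H:1, function(z) {
    paste(state$labels[, z], collapse = " ")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr & nzchar(lines)]

  pm <- regmatches(hdr, regexec("^# param ([^:]+): (.*)$", hdr))
  pm <- pm[lengths(pm) == 3L]
  vals <- stats::setNames(lapply(pm, function(m) {
    v <- m[[3L]]
    if (m[[2L]] == "division_mode") v else as.numeric(v)
  }), vapply(pm, function(m) m[[2L]], ""))
  params <- do.call(cpm_params, vals)

  mcs_line <- grep("^# mcs: ", hdr, value = TRUE)
  mcs <- if (length(mcs_line)) as.integer(sub("^# mcs: ", "", mcs_line[1])) else 0L

  rows <- lapply(body, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
  H <- length(rows)
  W <- length(rows[[1L]])
  if (W != params$lattice_width || H != params$lattice_height)
    abort("snapshot body does not match the lattice size in its header",
          class = "cpm_io_error")
  labels <- matrix(CPM_MEDIUM, W, H)
  for (i in seq_len(H)) labels[, H - i + 1L] <- rows[[i]]
  st <- new_cpm_state(labels, params, mcs = mcs)
  st
}

#' Read and write flat configuration files
#'
#' The configuration format is a flat YAML document whose keys mirror the
#' [cpm_params()] field names exactly.
#'
#' @param params A `cpm_params` object.
#' @param path File path.
#' @return `write_cpm_config()` returns `path` invisibly;
#'   `read_cpm_config()` returns a validated `cpm_params`.
#' @export
write_cpm_config <- function(params, path) {
  stopifnot(inherits(params, "cpm_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_cpm_config
#' @export
read_cpm_config <- function(path) {
  do.call(cpm_params, yaml::read_yaml(path))
}

#' Render a snapshot to a PNG image
#'
#' One colour per compartment: medium black, substrate steel blue, wall
#' grey, cells cycled through a qualitative palette by id.
#'
#' @param state A `cpm_state`.
#' @param path Output PNG path.
#' @param scale Integer pixel-replication factor.
#' @return `path`, invisibly.
#' @export
export_snapshot_png <- function(state, path, scale = 2L) {
  if (!requireNamespace("png", quietly = TRUE))
    abort("the `png` package is required for image export")
  stopifnot(inherits(state, "cpm_state"))
  labels <- state$labels
  W <- nrow(labels); H <- ncol(labels)
  pal <- grDevices::hcl(h = seq(15, 375, length.out = 13)[-13],
                        l = 65, c = 100)
  col <- matrix("#000000", W, H)
  col[labels == CPM_WALL] <- "#555555"
  col[labels == CPM_SUBSTRATE] <- "#4682B4"
  cell_mask <- labels >= 1L
  col[cell_mask] <- pal[(labels[cell_mask] - 1L) %% length(pal) + 1L]
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) {
    img[, , ch] <- t(matrix(rgb[ch, ], W, H))[H:1, ]
  }
  if (scale > 1L) {
    img <- img[rep(seq_len(H), each = scale), rep(seq_len(W), each = scale), ,
               drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}
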