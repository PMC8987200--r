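#' Specify a parameter sweep
#'
#' A sweep runs one simulation per point of the cartesian product of the
#' axes, times `replicates`, with per-run seeds derived deterministically
#' from `base_seed` and the run index. Axis names must be [cpm_params()]
#' fields, except the derived axis `alpha` (the adhesion ratio), which sets
#' `lambda_adh_cc = lambda_adh_cs / alpha` after all other axes are
#' applied.
#'
#' @param axes Named list of value vectors, e.g.
#'   `list(lambda_cont = c(1, 3, 5, 7), lambda_adh_cs = -c(100, 300, 500, 700))`.
#' @param replicates Runs per grid point.
#' @param base_seed Base RNG seed for the whole sweep.
#' @param base_params Baseline parameters for fields not on an axis;
#'   defaults to the desk-scale preset.
#' @param out_root Output directory for per-run artifacts and the master
#'   table; `NULL` keeps everything in memory.
#' @param keep_snapshots Keep label matrices inside the returned
#'   trajectories' slots (memory-heavy; artifact files are unaffected).
#' @param thresholds Classification thresholds, see
#'   [classification_thresholds()].
#' @return A `sweep_spec` object.
#' @export
#' @examples
#' spec <- sweep_spec(list(lambda_cont = c(1, 7)), base_seed = 42,
#'                    base_params = cpm_params_reduced(max_mcs = 100))
sweep_spec <- function(axes, replicates = 1L, base_seed = 1L,
                       base_params = cpm_params_reduced(),
                       out_root = NULL, keep_snapshots = FALSE,
                       thresholds = classification_thresholds()) {
  stopifnot(is.list(axes), length(axes) > 0, !is.null(names(axes)),
            all(nzchar(names(axes))))
  ok <- c(names(unclass(base_params)), "alpha")
  bad <- setdiff(names(axes), ok)
  if (length(bad))
    abort(paste0("unknown sweep axis: ", paste(bad, collapse = ", ")),
          class = "cpm_params_error")
  grid <- tidyr::expand_grid(!!!axes, replicate = seq_len(replicates))
  structure(list(axes = axes, grid = grid, replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), base_params = base_params,
                 out_root = out_root, keep_snapshots = keep_snapshots,
                 thresholds = thresholds),
            class = "sweep_spec")
}

# deterministic per-run seed stream: Lehmer step on the base seed plus an
# index offset, kept inside the 32-bit signed range
per_run_seed <- function(base_seed, index) {
  m <- 2147483647
  s <- ((base_seed %% m) * 48271 + index * 69621) %% m
  as.integer(s + (s == 0))
}

# polynomial checksum of the serialized parameter set, for resumability checks
param_checksum <- function(params, seed) {
  p <- unclass(params)
  txt <- paste(names(p), vapply(p, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ";")
  txt <- paste0(txt, "|seed=", seed)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

run_params_for <- function(spec, row) {
  fields <- row[setdiff(names(row), c("replicate", "alpha"))]
  p <- do.call(update_params, c(list(spec$base_params), fields))
  if (!is.null(row$alpha)) {
    p <- update_params(p, lambda_adh_cc = p$lambda_adh_cs / row$alpha)
  }
  p
}

#' Run a parameter sweep
#'
#' Executes every scheduled run of a [sweep_spec()], classifies each
#' trajectory, and returns (and optionally writes) a master table with one
#' row per run. With `out_root` set, each run gets its own directory
#' containing a metadata file (parameters, seed, package version,
#' checksum), the morphology reports, the division log, and the final
#' snapshot; a rerun of the same spec skips runs whose checksum matches
#' (resumability), so interrupting and resuming yields the same master
#' table. Failures are isolated per run: a failing run is logged with
#' `label = "error"` and the sweep completes. After all runs, multilayer
#' labels are refined: a multilayer growing slower than
#' `thresholds$slow_frac` times the fastest multilayer growth rate in this
#' sweep becomes `multilayer_slow`.
#'
#' @param spec A `sweep_spec`.
#' @param verbose Print one line per run.
#' @return The master tibble: axes, replicate, seed, classification label
#'   and metrics, final cell counts, run length.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- spec$grid
  if (!is.null(spec$out_root)) {
    dir.create(spec$out_root, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- as.list(grid[i, ])
    seed <- per_run_seed(spec$base_seed, i)
    params <- update_params(run_params_for(spec, row), seed = seed)
    check <- param_checksum(params, seed)
    run_dir <- if (!is.null(spec$out_root)) {
      file.path(spec$out_root, sprintf("run_%04d", i))
    }

    if (!is.null(run_dir) && file.exists(file.path(run_dir, "result.csv")) &&
        file.exists(file.path(run_dir, "meta.yaml"))) {
      meta <- yaml::read_yaml(file.path(run_dir, "meta.yaml"))
      if (identical(meta$checksum, check)) {
        rows[[i]] <- tibble::as_tibble(read.csv(file.path(run_dir, "result.csv")))
        if (verbose) message(sprintf("run %d/%d: resumed", i, nrow(grid)))
        next
      }
    }

    res <- tryCatch({
      traj <- run_simulation(params, keep_snapshots = spec$keep_snapshots)
      cls <- classify_trajectory(traj, thresholds = spec$thresholds)
      fin <- traj$reports[nrow(traj$reports), ]
      out <- dplyr::bind_cols(
        tibble::as_tibble(row), tibble::tibble(seed = seed), cls,
        tibble::tibble(n_cells = fin$n_cells, n_basal = fin$n_basal,
                       n_suprabasal = fin$n_suprabasal,
                       completed_mcs = traj$completed_mcs,
                       steady_mcs = traj$steady_mcs))
      if (!is.null(run_dir)) {
        dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
        yaml::write_yaml(list(run = i, seed = seed, checksum = check,
                              version = as.character(packageVersion("epipotts")),
                              params = unclass(params)),
                         file.path(run_dir, "meta.yaml"))
        write.csv(traj$reports, file.path(run_dir, "reports.csv"),
                  row.names = FALSE)
        write.csv(traj$events, file.path(run_dir, "events.csv"),
                  row.names = FALSE)
        write_snapshot(traj$final_state, file.path(run_dir, "final.snapshot"))
        write.csv(out, file.path(run_dir, "result.csv"), row.names = FALSE)
      }
      out
    }, error = function(e) {
      warn(sprintf("run %d failed: %s", i, conditionMessage(e)))
      dplyr::bind_cols(tibble::as_tibble(row),
                       tibble::tibble(seed = seed, label = "error"))
    })
    rows[[i]] <- res
    if (verbose) {
      message(sprintf("run %d/%d: %s", i, nrow(grid),
                      res$label %||% "?"))
    }
  }

  master <- dplyr::bind_rows(rows)
  # sweep-relative refinement of slow-growing multilayers
  ml <- master$label %in% c("multilayer", "multilayer_slow")
  if (any(ml) && "growth_rate" %in% names(master)) {
    ref <- max(master$growth_rate[ml], na.rm = TRUE)
    if (is.finite(ref) && ref > 0) {
      slow <- ml & master$label == "multilayer" &
        master$growth_rate < spec$thresholds$slow_frac * ref
      master$label[slow] <- "multilayer_slow"
    }
  }
  if (!is.null(spec$out_root)) {
    write.csv(master, file.path(spec$out_root, "master.csv"),
              row.names = FALSE)
  }
  master
}

`%||%` <- function(a, b) if (is.null(a)) b else a
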