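# brute-force oracle: exhaustive 0.01-step grid search over the box
brute_rect_min <- function(params, step = 0.01, box = 4 * sqrt(params$A0)) {
  g <- seq(step, box, by = step)
  la <- params$lambda_area; lc <- params$lambda_cont
  lcs <- params$lambda_adh_cs; A0 <- params$A0
  best <- Inf; bl <- NA_real_; bh <- NA_real_
  for (l in g) {
    e <- la * (l * g - A0)^2 + lc * (2 * l + 2 * g)^2 + lcs * l
    i <- which.min(e)
    if (e[i] < best) { best <- e[i]; bl <- l; bh <- g[i] }
  }
  c(l = bl, h = bh, e = best)
}

# the optimizer must (a) never lose to the exhaustive grid and (b) round
# onto a grid point whose energy is within one grid step of the grid
# minimum (along the shallow valley directions of this landscape the
# energy, not the coordinate, is the sharp certificate)
expect_matches_brute <- function(params, step = 0.01) {
  r <- rect_equilibrium(params)
  b <- brute_rect_min(params, step = step)
  expect_lte(r$energy, b["e"] + 1e-9 * max(1, abs(b["e"])))
  snap <- function(v) max(step, round(v / step) * step)
  e_snap <- rect_energy(snap(r$l_star), snap(r$h_star), params)
  slack <- max(abs(rect_energy(b["l"] + c(step, -step, 0, 0),
                               b["h"] + c(0, 0, step, -step), params) - b["e"]))
  expect_lte(e_snap - b["e"], slack + 1e-9 * max(1, abs(b["e"])))
  expect_lt(abs(r$l_star - b["l"]), 0.25)   # same basin
  expect_lt(abs(r$h_star - b["h"]), 0.25)
  invisible(r)
}
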