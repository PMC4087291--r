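# shared fixtures: everything is generated in code, no stored data

fix_geom <- function() beam_geometry()

fix_params <- function(...) beam_model_params(...)

# hand-written depth-dose samples with a clear build-up and tail
fix_pdd <- function() {
  pdd_curve(c(0, 0.5, 1, 2, 3.25, 5, 10, 15, 20, 28),
            c(18, 60, 82, 96, 100, 95, 76, 61, 48, 34))
}

# symmetric flat-top profile samples at the reference depth
fix_profile <- function(ref_depth = 3.25) {
  pos <- seq(-8, 8, by = 0.5)
  val <- 100 / (1 + exp((abs(pos) - 5.16) / 0.35))
  profile_curve(pos, val, ref_depth = ref_depth)
}

# independent piecewise-linear interpolation (two-point formula), used as
# the brute-force oracle; deliberately loop-based and separate from the
# package's approx()-based path
oracle_interp <- function(xs, ys, x) {
  n <- length(xs)
  i <- findInterval(x, xs)
  if (i < 1L) return(NA_real_)
  if (i >= n) return(if (x == xs[n]) ys[n] else NA_real_)
  t <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  (1 - t) * ys[i] + t * ys[i + 1L]
}

oracle_pdd_eval <- function(curve, d) {
  xs <- curve$depth; ys <- curve$dose; n <- length(xs)
  if (d <= xs[1L]) return(ys[1L])
  if (d >= xs[n]) return(ys[n])
  oracle_interp(xs, ys, d)
}

oracle_profile_eval <- function(curve, x, h) {
  xs <- curve$position; ys <- curve$dose; n <- length(xs)
  if (x < xs[1L]) return(ys[1L] * max(0, 1 - (xs[1L] - x) / h))
  if (x > xs[n]) return(ys[n] * max(0, 1 - (x - xs[n]) / h))
  oracle_interp(xs, ys, x)
}

# closure experiment: reconstruct a ground-truth plane from its own curves
closure_setup <- function(pixel, nonsep = FALSE,
                          params = fix_params(), geom = fix_geom()) {
  grid <- symmetric_grid(pixel, halfwidth = 15, depth = 28, geom = geom)
  truth <- if (nonsep) nonseparable_truth(params, geom, grid)
           else separable_truth(params, geom, grid)
  curves <- sample_curves_from_truth(truth)
  recon <- reconstruct_plane(curves$pdd, curves$profile, geom, grid)
  masks <- region_masks(geom, curves$profile, grid)
  list(grid = grid, truth = truth, curves = curves, recon = recon,
       masks = masks,
       report = agreement(recon, truth, masks))
}
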