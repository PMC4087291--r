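erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' Analytic 18 MV beam model parameters
#'
#' Parameters of the analytic fixture standing in for measured or simulated
#' beam data. The depth dose follows a build-up times attenuation form
#' `PDD(d) ~ (1 - exp(-alpha d)) exp(-mu d)`; `alpha` is solved from `mu`
#' and the requested depth of maximum dose via
#' `d* = log(1 + alpha/mu) / alpha`. The lateral profile is an
#' error-function flat top whose penumbra width is `penumbra_sigma0`; the
#' non-separable ground truth additionally widens the penumbra with depth
#' (`penumbra_sigma0 + penumbra_growth * d`) and adds a small exponential
#' scatter tail outside the field.
#'
#' Defaults give a realistic 18 MV shape: tail slope `mu = 0.045` per cm,
#' maximum at 3.25 cm, 0.3 cm penumbra sigma growing at 0.04 cm per cm of
#' depth, and a 2% scatter tail with 5 cm decay length. These are cosmetic
#' modelling defaults, not measured beam constants.
#'
#' @param mu Linear attenuation coefficient for the PDD tail, 1/cm.
#' @param d_max_target Depth of maximum dose, cm.
#' @param penumbra_sigma0 Penumbra sigma at the surface, cm.
#' @param penumbra_growth Penumbra sigma growth, cm of sigma per cm depth
#'   (non-separable truth only).
#' @param tail_amplitude Scatter-tail amplitude just outside the field, in
#'   percent of the local central-axis dose (non-separable truth only;
#'   must be <= 3).
#' @param tail_decay Scatter-tail decay length, cm.
#' @return An object of class `beam_model_params` (includes the solved
#'   `alpha`).
#' @examples
#' prm <- beam_model_params()
#' log(1 + prm$alpha / prm$mu) / prm$alpha   # = 3.25
#' @export
beam_model_params <- function(mu = 0.045, d_max_target = 3.25,
                              penumbra_sigma0 = 0.3, penumbra_growth = 0.04,
                              tail_amplitude = 2, tail_decay = 5) {
  stopifnot(mu > 0, d_max_target > 0, penumbra_sigma0 > 0,
            penumbra_growth >= 0, tail_amplitude >= 0, tail_decay > 0)
  if (tail_amplitude > 3)
    stop("`tail_amplitude` must not exceed 3% of the local axis dose",
         call. = FALSE)
  f <- function(a) log(1 + a / mu) / a - d_max_target
  lohi <- c(mu * (1 + 1e-9), 1e3 * mu)
  if (f(lohi[1L]) * f(lohi[2L]) > 0)
    stop("no build-up rate alpha in (mu, 1000 mu) reaches the requested ",
         "d_max_target; adjust mu or d_max_target", call. = FALSE)
  alpha <- stats::uniroot(f, lohi, tol = 1e-12)$root
  structure(
    list(mu = mu, alpha = alpha, d_max_target = d_max_target,
         penumbra_sigma0 = penumbra_sigma0, penumbra_growth = penumbra_growth,
         tail_amplitude = tail_amplitude, tail_decay = tail_decay),
    class = "beam_model_params"
  )
}

# unnormalised analytic depth-dose form; vanishes at the surface
pdd_form <- function(params, d) {
  (1 - exp(-params$alpha * d)) * exp(-params$mu * d)
}

# flat-top profile form at penumbra sigma `sig`, field shoulder `a` (cm):
# difference of error functions, ~1 inside the field, 0 far outside
profile_form <- function(x, a, sig) {
  0.5 * (erf((a - x) / sig) + erf((a + x) / sig))
}

# half-field shoulder at depth dref: the surface field edge projected along
# its fan line
field_shoulder <- function(params, geom, dref) {
  fan_map(geom$field_size / 2, 0, dref, geom)
}

#' Synthetic central-axis depth-dose curve
#'
#' Evaluates the analytic build-up/attenuation depth-dose form on a depth
#' grid and returns it as a normalised [pdd_curve()] (maximum 100%). By
#' construction the continuous form peaks exactly at `d_max_target`.
#'
#' @param params [beam_model_params()].
#' @param depths Depth sample grid, cm.
#' @return A [pdd_curve()].
#' @export
synth_pdd <- function(params, depths = seq(0.05, 27.95, by = 0.1)) {
  stopifnot(inherits(params, "beam_model_params"))
  pdd_curve(depths, pdd_form(params, depths))
}

#' Synthetic off-axis profile at the reference depth
#'
#' An error-function flat top: `OAR(x) ~ erf((a - x)/sigma) + erf((a + x)/sigma)`
#' with the shoulder `a` at the fan-line projection of the surface field
#' edge to `ref_depth`, normalised to 100% on the axis.
#'
#' @param params [beam_model_params()].
#' @param geom [beam_geometry()].
#' @param positions Off-axis sample grid, cm.
#' @param ref_depth Depth of the profile, cm; defaults to the model's
#'   `d_max_target`.
#' @return A [profile_curve()].
#' @export
synth_profile <- function(params, geom, positions = seq(-15, 15, by = 0.1),
                          ref_depth = params$d_max_target) {
  stopifnot(inherits(params, "beam_model_params"),
            inherits(geom, "beam_geometry"))
  a <- field_shoulder(params, geom, ref_depth)
  profile_curve(positions,
                profile_form(positions, a, params$penumbra_sigma0),
                ref_depth = ref_depth)
}

#' Separable ground-truth dose plane
#'
#' Evaluates `PDD(d) * OAR(fan_map(x, d, d_ref)) / 100` analytically at
#' every pixel centre — a plane that lies exactly inside the model class of
#' [reconstruct_plane()], used as the closure oracle: reconstructing from
#' this plane's own axis PDD and reference-depth profile must reproduce it
#' up to pure interpolation error.
#'
#' @param params [beam_model_params()].
#' @param geom [beam_geometry()].
#' @param grid [grid_spec()].
#' @return A [dose_plane()].
#' @export
separable_truth <- function(params, geom, grid) {
  truth_plane(params, geom, grid, separable = TRUE)
}

#' Non-separable ground-truth dose plane
#'
#' Like [separable_truth()] but with physics the single-profile algorithm
#' can only approximate: the penumbra sigma widens with depth
#' (`sigma0 + growth * d`) and a small exponential scatter tail (at most 3%
#' of the local axis dose) is added outside the field, mimicking the extra
#' scattered radiation of a polyenergetic beam. With `penumbra_growth = 0`
#' and `tail_amplitude = 0` it reduces exactly to the separable plane.
#'
#' @inheritParams separable_truth
#' @return A [dose_plane()].
#' @export
nonseparable_truth <- function(params, geom, grid) {
  truth_plane(params, geom, grid, separable = FALSE)
}

truth_plane <- function(params, geom, grid, separable) {
  stopifnot(inherits(params, "beam_model_params"),
            inherits(geom, "beam_geometry"), inherits(grid, "grid_spec"))
  dref <- params$d_max_target
  a <- field_shoulder(params, geom, dref)
  dep <- grid_depths(grid)
  lat <- grid_lateral(grid)
  pddv <- pdd_form(params, dep)
  pddv <- pddv / max(pddv) * 100
  values <- matrix(0, grid$n_depth, grid$n_lateral)
  for (i in seq_along(dep)) {
    u <- fan_map(lat, dep[i], dref, geom)     # fan-line coordinate at d_ref
    sig <- if (separable) params$penumbra_sigma0
           else params$penumbra_sigma0 + params$penumbra_growth * dep[i]
    oar <- profile_form(u, a, sig) / profile_form(0, a, sig) * 100
    row <- pddv[i] * oar / 100
    if (!separable && params$tail_amplitude > 0) {
      out <- abs(u) > a
      row[out] <- row[out] + pddv[i] * params$tail_amplitude / 100 *
        exp(-(abs(u[out]) - a) / params$tail_decay)
    }
    values[i, ] <- row
  }
  dose_plane(values, grid)
}

#' Extract the algorithm's two input curves from a dose plane
#'
#' Mirrors how the reconstruction inputs are obtained from a scored 2-D
#' dose distribution: the column nearest the beam axis becomes the PDD
#' (renormalised to 100%), and the row at that PDD's depth of maximum
#' becomes the off-axis profile with `ref_depth` set accordingly. When no
#' column centre sits exactly on the axis (even column counts), the nearest
#' column is used, ties resolved to the positive side.
#'
#' @param dm A [dose_plane()].
#' @return A list with elements `pdd` ([pdd_curve()]) and `profile`
#'   ([profile_curve()]).
#' @export
sample_curves_from_truth <- function(dm) {
  stopifnot(inherits(dm, "dose_plane"))
  g <- plane_grid(dm)
  lat <- grid_lateral(g); dep <- grid_depths(g)
  m <- as.matrix(dm)
  j0 <- which.min(abs(lat) - 1e-12 * (lat > 0))  # tie -> positive side
  pdd <- pdd_curve(dep, m[, j0])
  i0 <- which.max(m[, j0])
  profile <- profile_curve(lat, m[i0, ], ref_depth = dep[i0])
  list(pdd = pdd, profile = profile)
}
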