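#' Workflow: generate synthetic beam data
#'
#' Generates the configured ground-truth plane on the scoring layout,
#' extracts the two algorithm inputs from it (axis PDD and reference-depth
#' profile) and writes `pdd.csv`, `profile.csv`, `truth.dat` plus a
#' `params.yaml` sidecar recording every parameter used. Fully
#' deterministic: rerunning with the same configuration yields
#' byte-identical files.
#'
#' @param cfg A [default_run_config()]-shaped configuration.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(cfg = default_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(cfg)
  grid <- config_scoring_grid(cfg)
  params <- config_params(cfg)
  truth <- switch(cfg$beam_model$truth,
                  separable = separable_truth(params, geom, grid),
                  nonseparable = nonseparable_truth(params, geom, grid),
                  stop("beam_model$truth must be 'separable' or 'nonseparable'",
                       call. = FALSE))
  curves <- sample_curves_from_truth(truth)
  paths <- list(pdd = file.path(out_dir, "pdd.csv"),
                profile = file.path(out_dir, "profile.csv"),
                truth = file.path(out_dir, "truth.dat"),
                sidecar = file.path(out_dir, "params.yaml"))
  write_curve(curves$pdd, paths$pdd)
  write_curve(curves$profile, paths$profile)
  write_dose_plane(truth, paths$truth)
  yaml::write_yaml(list(geometry = cfg$geometry, scoring = cfg$scoring,
                        beam_model = c(cfg$beam_model,
                                       alpha_per_cm = params$alpha),
                        seed = cfg$seed),
                   paths$sidecar)
  invisible(paths)
}

#' Workflow: reconstruct a dose plane from curve files
#'
#' Reads a PDD and a profile table, runs [reconstruct_plane()] on the
#' configured reconstruction grid and writes the matrix; optionally also
#' writes grayscale and colour PNG renderings.
#'
#' @inheritParams run_simulate
#' @param pdd_file,profile_file Curve files as written by [write_curve()].
#' @param out_matrix Output path for the plane.
#' @param gray_png,color_png Optional PNG output paths.
#' @param grid Optional [grid_spec()] overriding the configured
#'   reconstruction grid (e.g. `plane_grid()` of a reference plane, so the
#'   result can be compared pixel for pixel).
#' @return Invisibly, the reconstructed [dose_plane()].
#' @export
run_reconstruct <- function(cfg = default_run_config(), pdd_file, profile_file,
                            out_matrix, gray_png = NULL, color_png = NULL,
                            grid = NULL) {
  geom <- config_geometry(cfg)
  if (is.null(grid)) grid <- config_grid(cfg, geom)
  pdd <- read_curve(pdd_file, "pdd")
  profile <- read_curve(profile_file, "profile")
  plane <- reconstruct_plane(pdd, profile, geom, grid)
  write_dose_plane(plane, out_matrix)
  if (!is.null(gray_png)) write_gray_png(plane, gray_png)
  if (!is.null(color_png))
    write_color_png(render_color(plane, config_palette(cfg)), color_png)
  invisible(plane)
}

#' Workflow: render a stored dose plane to PNG
#'
#' @inheritParams run_simulate
#' @param matrix_file A plane written by [write_dose_plane()].
#' @param mode `"gray"` (continuous gray levels), `"bands"` (posterised
#'   decile bands, borders = isodose curves) or `"hsi"` (colour wash).
#' @param out_png Output PNG path.
#' @return Invisibly, the rendered plane tibble.
#' @export
run_render <- function(cfg = default_run_config(), matrix_file,
                       mode = c("gray", "bands", "hsi"), out_png) {
  mode <- match.arg(mode)
  plane <- read_dose_plane(matrix_file)
  out <- switch(mode,
    gray = {
      x <- to_gray(plane)
      write_gray_png(x, out_png)
      x
    },
    bands = {
      edges <- cfg$bands$edges_pct
      bm <- segment_bands(plane, edges)
      # each band displayed at the gray level of its upper edge; background black
      lut <- c(0, byte8(edges[-1] / 100 * 255))
      bm$gray <- lut[bm$band + 1L]
      write_gray_png(bm, out_png)
      bm
    },
    hsi = {
      x <- render_color(plane, config_palette(cfg))
      write_color_png(x, out_png)
      x
    })
  invisible(out)
}

#' Workflow: compare two stored dose planes
#'
#' Reads a reconstructed and a reference plane, classifies pixels with
#' [region_masks()] (field shape taken from the reference plane's own
#' reference-depth profile), prints the [agreement()] summary and checks it
#' against the configured in-field and penumbra bounds.
#'
#' @inheritParams run_simulate
#' @param recon_file,reference_file Planes written by [write_dose_plane()].
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a list with the `agreement_report` and a logical
#'   `passed`.
#' @export
run_validate <- function(cfg = default_run_config(), recon_file,
                         reference_file, quiet = FALSE) {
  geom <- config_geometry(cfg)
  recon <- read_dose_plane(recon_file)
  reference <- read_dose_plane(reference_file)
  profile <- sample_curves_from_truth(reference)$profile
  masks <- region_masks(geom, profile, plane_grid(recon))
  rep <- agreement(recon, reference, masks)
  bounds <- cfg$validation
  infield <- rep$by_region$max_dev[rep$by_region$region == "in_field"]
  penumb <- rep$by_region$max_dev[rep$by_region$region == "penumbra"]
  passed <- infield <= bounds$in_field_max_pct && penumb <= bounds$penumbra_max_pct
  if (!quiet) {
    print(rep)
    cat(sprintf("bounds: in-field <= %g, penumbra <= %g => %s\n",
                bounds$in_field_max_pct, bounds$penumbra_max_pct,
                if (passed) "PASS" else "FAIL"))
  }
  invisible(list(report = rep, passed = passed))
}
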