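#' Extract a lateral profile from a dose plane
#'
#' Returns the plane's row nearest the requested depth as a lateral curve,
#' the way individual depth profiles are pulled out of the matrix for
#' comparison figures. If the requested depth is more than half a pixel
#' away from the nearest row centre, a warning notes the snap.
#'
#' @param dm A [dose_plane()].
#' @param depth Requested depth, cm; must lie within the grid.
#' @return A `resampled_curve` tibble (`abscissa`, `dose`) with attribute
#'   `depth` giving the snapped row depth.
#' @export
extract_profile <- function(dm, depth) {
  stopifnot(inherits(dm, "dose_plane"))
  g <- plane_grid(dm)
  dep <- grid_depths(g)
  if (depth < min(dep) - g$pixel_spacing / 2 ||
      depth > max(dep) + g$pixel_spacing / 2)
    stop("`depth` lies outside the grid", call. = FALSE)
  i <- which.min(abs(dep - depth))
  if (abs(dep[i] - depth) > g$pixel_spacing / 2 + 1e-9)
    warning(sprintf("depth %.4g cm snapped to row at %.4g cm", depth, dep[i]),
            call. = FALSE)
  m <- as.matrix(dm)
  out <- tibble::tibble(abscissa = grid_lateral(g), dose = m[i, ])
  structure(out, start = g$lateral_origin, spacing = g$pixel_spacing,
            depth = dep[i], class = c("resampled_curve", class(out)))
}

#' In-field / penumbra / out-of-field region masks
#'
#' Classifies every pixel by its fan-mapped reference off-axis ratio
#' `r = OAR(fan_map(x, d, d_ref)) / 100`: in-field where `r >= 0.8`,
#' penumbra where `0.2 <= r < 0.8`, out-of-field where `r < 0.2` — the
#' standard dosimetric 80%/20% convention for the field edge. The three
#' regions are disjoint and cover the plane.
#'
#' @param geom [beam_geometry()].
#' @param profile The reference [profile_curve()] defining the field shape.
#' @param grid [grid_spec()].
#' @return A tibble of class `region_masks` with columns `lateral`, `depth`,
#'   `oar_ref` (the ratio `r`) and `region` (factor: `in_field`,
#'   `penumbra`, `out_of_field`), ordered like a [dose_plane()] on `grid`.
#' @export
region_masks <- function(geom, profile, grid) {
  stopifnot(inherits(geom, "beam_geometry"),
            inherits(profile, "profile_curve"), inherits(grid, "grid_spec"))
  lat <- grid_lateral(grid); dep <- grid_depths(grid)
  dref <- ref_depth(profile)
  xr <- outer(dep, lat, function(d, x) fan_map(x, d, dref, geom))
  r <- matrix(eval_profile(profile, as.vector(xr),
                           edge_decay = grid$pixel_spacing),
              nrow = grid$n_depth) / 100
  plane <- dose_plane(pmax(r, 0), grid)  # reuse the tidy pixel ordering
  out <- tibble::tibble(
    lateral = plane$lateral, depth = plane$depth, oar_ref = plane$dose,
    region = factor(
      ifelse(plane$dose >= 0.8, "in_field",
             ifelse(plane$dose >= 0.2, "penumbra", "out_of_field")),
      levels = c("in_field", "penumbra", "out_of_field"))
  )
  structure(out, grid = grid, class = c("region_masks", class(out)))
}

#' Agreement between two dose planes
#'
#' Pixelwise comparison of a reconstructed plane against a reference on the
#' same grid. Both planes are renormalised to 100% at their own maxima and
#' the deviation at each pixel is the absolute difference in percentage
#' points of that maximum (not a local percent ratio, which would blow up
#' at low doses). Deviations are aggregated per region (in-field, penumbra,
#' out-of-field) and per listed comparison depth; the metric is symmetric
#' in the two planes.
#'
#' @param recon,reference [dose_plane()]s on identical grids.
#' @param masks [region_masks()] on the same grid.
#' @param depths Depths (cm) for the per-depth deviation table; defaults to
#'   the standard comparison depths from the build-up region down to 25.25
#'   cm. Each snaps to the nearest grid row.
#' @return An object of class `agreement_report`: a list with tibbles
#'   `overall` (one row), `by_region` and `by_depth`.
#' @examples
#' geom <- beam_geometry(); prm <- beam_model_params()
#' grid <- symmetric_grid(0.5)
#' truth <- separable_truth(prm, geom, grid)
#' cur <- sample_curves_from_truth(truth)
#' rec <- reconstruct_plane(cur$pdd, cur$profile, geom, grid)
#' agreement(rec, truth, region_masks(geom, cur$profile, grid))
#' @export
agreement <- function(recon, reference, masks,
                      depths = c(0.75, 1.25, 1.75, 3.25, 4.75, 6.75, 9.25,
                                 15.25, 20.25, 25.25)) {
  stopifnot(inherits(recon, "dose_plane"), inherits(reference, "dose_plane"),
            inherits(masks, "region_masks"))
  ga <- plane_grid(recon); gb <- plane_grid(reference)
  gm <- attr(masks, "grid")
  if (!identical(unclass(ga)[c("pixel_spacing", "n_lateral", "n_depth",
                               "lateral_origin", "depth_origin")],
                 unclass(gb)[c("pixel_spacing", "n_lateral", "n_depth",
                               "lateral_origin", "depth_origin")]))
    stop("`recon` and `reference` must share the same grid", call. = FALSE)
  if (!all(gm$n_depth == ga$n_depth, gm$n_lateral == ga$n_lateral))
    stop("`masks` must be built on the same grid", call. = FALSE)
  a <- recon$dose / max(recon$dose) * 100
  b <- reference$dose / max(reference$dose) * 100
  dev <- abs(a - b)
  df <- tibble::tibble(lateral = recon$lateral, depth = recon$depth,
                       region = masks$region, dev = dev)
  by_region <- df |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     max_dev = max(.data$dev),
                     mean_dev = mean(.data$dev), .groups = "drop")
  dep <- grid_depths(ga)
  snapped <- vapply(depths, function(d) dep[which.min(abs(dep - d))], 0)
  by_depth <- df |>
    dplyr::filter(.data$depth %in% snapped) |>
    dplyr::group_by(depth = .data$depth, region = .data$region) |>
    dplyr::summarise(max_dev = max(.data$dev),
                     mean_dev = mean(.data$dev), .groups = "drop")
  overall <- tibble::tibble(max_dev = max(dev), mean_dev = mean(dev),
                            n = length(dev))
  structure(list(overall = overall, by_region = by_region,
                 by_depth = by_depth),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> deviations in percentage points of D_max\n")
  cat(sprintf("  overall: max %.4g, mean %.4g over %d pixels\n",
              x$overall$max_dev, x$overall$mean_dev, x$overall$n))
  for (k in seq_len(nrow(x$by_region)))
    cat(sprintf("  %-12s max %.4g  mean %.4g  (n = %d)\n",
                as.character(x$by_region$region[k]), x$by_region$max_dev[k],
                x$by_region$mean_dev[k], x$by_region$n[k]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an agreement report
#'
#' `tidy()` returns the per-region deviation summary (one row per region);
#' `glance()` returns a one-row summary with overall and per-region maxima.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$by_region

#' @rdname tidy.agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  wide <- stats::setNames(x$by_region$max_dev,
                          paste0(x$by_region$region, "_max"))
  dplyr::bind_cols(x$overall, tibble::as_tibble(as.list(wide)))
}

#' Plot per-depth agreement
#'
#' Maximum deviation at each listed comparison depth, split by region.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$by_depth,
                  ggplot2::aes(x = .data$depth, y = .data$max_dev,
                               colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "depth [cm]", y = "max |deviation| [% of D_max]",
                  colour = NULL)
}
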