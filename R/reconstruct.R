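#' Dose plane container
#'
#' A 2-D relative dose distribution on a [grid_spec()] lattice, stored in
#' long (tidy) form: one row per pixel with columns `lateral`, `depth` and
#' `dose` (percent of the plane's reference maximum). Rows are ordered by
#' depth, then lateral position, so [as.matrix()] recovers the
#' `n_depth x n_lateral` matrix (row index = depth increasing downward,
#' column index = lateral increasing left to right).
#'
#' @param values An `n_depth x n_lateral` numeric matrix of percent dose.
#' @param grid The [grid_spec()] the values live on.
#' @return A tibble of class `dose_plane` with attribute `grid`.
#' @export
dose_plane <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_depth, grid$n_lateral)))
    stop("`values` must be an n_depth x n_lateral matrix", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative", call. = FALSE)
  out <- tibble::tibble(
    lateral = rep(grid_lateral(grid), each = grid$n_depth),
    depth = rep(grid_depths(grid), times = grid$n_lateral),
    dose = as.vector(values)
  )
  out <- dplyr::arrange(out, .data$depth, .data$lateral)
  structure(out, grid = grid, class = c("dose_plane", class(out)))
}

#' @rdname dose_plane
#' @param x A `dose_plane`.
#' @param ... Unused.
#' @export
as.matrix.dose_plane <- function(x, ...) {
  g <- plane_grid(x)
  i <- match(x$depth, grid_depths(g))
  j <- match(x$lateral, grid_lateral(g))
  m <- matrix(NA_real_, g$n_depth, g$n_lateral)
  m[cbind(i, j)] <- x$dose
  m
}

#' @rdname dose_plane
#' @export
plane_grid <- function(x) {
  stopifnot(inherits(x, "dose_plane"))
  attr(x, "grid")
}

#' Reconstruct a 2-D dose plane from a PDD and one off-axis profile
#'
#' The core dosimetric algorithm. For every pixel centre `(x, d)` of the
#' grid the relative dose is the product of two linearly interpolated
#' factors, both in percent:
#'
#'   `PD(x, d) = PDD(d) * OAR(fan_map(x, d, d_ref)) / 100`
#'
#' where `PDD` is the central-axis depth-dose curve evaluated at the pixel's
#' vertical depth, and `OAR` is the single off-axis profile, looked up at
#' the lateral position where the pixel's fan line (the straight ray from
#' the source through the pixel) crosses the profile's reference depth. The
#' divergence of the beam is thus carried entirely by the fan-line rescaling
#' of off-axis positions.
#'
#' Outside its sampled range the PDD is clamped to its endpoint values; the
#' profile decays linearly to zero over one pixel spacing beyond its last
#' sample, so no dose is painted onto the phantom edge.
#'
#' @param pdd A [pdd_curve()].
#' @param profile A [profile_curve()] sampled at the depth of maximum dose.
#'   If its `ref_depth` differs from the PDD's `d_ref` by more than one
#'   pixel spacing, a warning is issued and the profile's `ref_depth` is
#'   used as the fan-mapping anchor.
#' @param geom A [beam_geometry()].
#' @param grid A [grid_spec()]; must lie inside the phantom.
#' @return A [dose_plane()].
#' @examples
#' geom <- beam_geometry()
#' prm <- beam_model_params()
#' pdd <- synth_pdd(prm, seq(0.05, 27.95, by = 0.1))
#' prof <- synth_profile(prm, geom, seq(-15, 15, by = 0.1))
#' plane <- reconstruct_plane(pdd, prof, geom, symmetric_grid(0.25))
#' max(plane$dose)
#' @export
reconstruct_plane <- function(pdd, profile, geom, grid) {
  stopifnot(inherits(pdd, "pdd_curve"), inherits(profile, "profile_curve"),
            inherits(geom, "beam_geometry"), inherits(grid, "grid_spec"))
  grid_spec(grid$pixel_spacing, grid$n_lateral, grid$n_depth,
            grid$lateral_origin, grid$depth_origin, geom = geom)
  dref <- ref_depth(profile)
  if (abs(dref - d_ref(pdd)) > grid$pixel_spacing + 1e-9)
    warning(sprintf(
      "profile ref_depth (%.4g cm) differs from PDD d_ref (%.4g cm); using ref_depth",
      dref, d_ref(pdd)), call. = FALSE)
  lat <- grid_lateral(grid)
  dep <- grid_depths(grid)
  pdd_k <- eval_pdd(pdd, dep)                       # one value per row
  # fan-map every pixel's lateral position to the reference depth, then look
  # the profile up there; vectorised over the full plane
  xr <- outer(dep, lat, function(d, x) fan_map(x, d, dref, geom))
  oar <- eval_profile(profile, as.vector(xr), edge_decay = grid$pixel_spacing)
  values <- matrix(oar, nrow = grid$n_depth) * pdd_k / 100
  eps <- 1e-6
  if (max(values) > 100 + eps)
    stop("reconstructed dose exceeds 100%: check curve normalisation",
         call. = FALSE)
  dose_plane(values, grid)
}

#' Relative dose at a single point
#'
#' Evaluates the reconstruction formula at one (or several) arbitrary
#' points, without building a full plane: the same product of interpolated
#' PDD and fan-mapped off-axis ratio as [reconstruct_plane()].
#'
#' @inheritParams reconstruct_plane
#' @param x Lateral position(s), cm.
#' @param d Depth(s), cm.
#' @param edge_decay Length over which the profile decays to zero beyond its
#'   last sample, cm. To reproduce a pixel of [reconstruct_plane()] exactly,
#'   pass that grid's `pixel_spacing` (the default only matters for queries
#'   beyond the profile's sampled support).
#' @return Dose in percent, vectorised over `x`/`d`.
#' @export
dose_at_point <- function(x, d, pdd, profile, geom,
                          edge_decay = stats::median(diff(profile$position))) {
  stopifnot(inherits(pdd, "pdd_curve"), inherits(profile, "profile_curve"),
            inherits(geom, "beam_geometry"))
  n <- max(length(x), length(d))
  x <- rep_len(x, n); d <- rep_len(d, n)
  xr <- fan_map(x, d, ref_depth(profile), geom)
  eval_pdd(pdd, d) * eval_profile(profile, xr, edge_decay) / 100
}

#' Read and write dose planes as delimited text
#'
#' A plane is stored as whitespace-delimited text with a three-line `#`
#' header (grid origin, spacing, dimensions) followed by one row of pixel
#' values per depth row. Values are written with 17 significant digits so a
#' write/read cycle is bit-exact.
#'
#' @param plane A [dose_plane()].
#' @param path File path.
#' @return `read_dose_plane()` returns a [dose_plane()]; `write_dose_plane()`
#'   returns `path` invisibly.
#' @export
write_dose_plane <- function(plane, path) {
  g <- plane_grid(plane)
  m <- as.matrix(plane)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# origin_cm: lateral %.17g depth %.17g",
            g$lateral_origin, g$depth_origin),
    sprintf("# pixel_spacing_cm: %.17g", g$pixel_spacing),
    sprintf("# dimensions: %d depth-rows %d lateral-cols",
            g$n_depth, g$n_lateral)
  ), con)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1:3]
  org <- as.numeric(strsplit(sub("^# origin_cm: lateral ", "", hdr[1L]),
                             " depth ", fixed = TRUE)[[1L]])
  spacing <- as.numeric(sub("^# pixel_spacing_cm: ", "", hdr[2L]))
  dims <- as.integer(regmatches(hdr[3L], gregexpr("[0-9]+", hdr[3L]))[[1L]])
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  g <- grid_spec(spacing, n_lateral = dims[2L], n_depth = dims[1L],
                 lateral_origin = org[1L], depth_origin = org[2L])
  dose_plane(m, g)
}

#' @export
print.dose_plane <- function(x, ...) {
  g <- plane_grid(x)
  cat(sprintf("<dose_plane> %d x %d pixels (%.4g cm), max %.4g%%\n",
              g$n_depth, g$n_lateral, g$pixel_spacing, max(x$dose)))
  NextMethod()
}
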