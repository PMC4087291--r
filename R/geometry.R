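#' Beam and phantom geometry
#'
#' Describes the treatment setup: a point photon source on the beam axis at
#' `ssd` centimetres above a water phantom, collimated to a square field of
#' side `field_size` defined at the phantom surface. Depth is measured
#' positive downward from the surface; lateral position is zero on the beam
#' central axis. All positions in this package refer to pixel/voxel centres.
#'
#' @param ssd Source-to-surface distance in cm. Default 100, the standard
#'   isocentric setup for a clinical linac.
#' @param field_size Side of the square field at the phantom surface, cm.
#' @param phantom_halfwidth Half the lateral extent of the water phantom, cm
#'   (default 25, i.e. a 50 cm wide tank).
#' @param phantom_depth Depth of the phantom, cm (default 30).
#' @return An object of class `beam_geometry`.
#' @examples
#' geom <- beam_geometry()
#' fan_map(5, 10, 3.25, geom)
#' @export
beam_geometry <- function(ssd = 100, field_size = 10,
                          phantom_halfwidth = 25, phantom_depth = 30) {
  stopifnot(is.numeric(ssd), length(ssd) == 1L,
            is.numeric(field_size), length(field_size) == 1L)
  if (!(ssd > 0)) stop("`ssd` must be positive", call. = FALSE)
  if (!(field_size > 0)) stop("`field_size` must be positive", call. = FALSE)
  if (!(phantom_halfwidth > 0) || !(phantom_depth > 0))
    stop("phantom dimensions must be positive", call. = FALSE)
  if (field_size > 2 * phantom_halfwidth)
    stop("`field_size` must fit inside the phantom", call. = FALSE)
  structure(
    list(ssd = ssd, field_size = field_size,
         phantom_halfwidth = phantom_halfwidth,
         phantom_depth = phantom_depth),
    class = "beam_geometry"
  )
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("<beam_geometry>\n")
  cat(sprintf("  SSD %.4g cm | field %.4g x %.4g cm at surface\n",
              x$ssd, x$field_size, x$field_size))
  cat(sprintf("  phantom %.4g cm wide x %.4g cm deep\n",
              2 * x$phantom_halfwidth, x$phantom_depth))
  invisible(x)
}

#' Rescale an off-axis position between depths along the diverging fan line
#'
#' A point at lateral position `x` and depth `d` lies on the straight line
#' (fan line) from the source through the phantom. This returns the lateral
#' position where that same line crosses the reference depth `d_ref`:
#' `x * (ssd + d_ref) / (ssd + d)`. The fan mapping is how a single profile
#' measured at the depth of maximum dose is reused at every other depth.
#'
#' @param x Lateral position(s), cm. Vectorised.
#' @param d Depth(s) of the point, cm (>= 0). Recycled against `x`.
#' @param d_ref Reference depth, cm (>= 0).
#' @param geom A [beam_geometry()].
#' @return Lateral position(s) at depth `d_ref`, cm.
#' @examples
#' geom <- beam_geometry(ssd = 100)
#' fan_map(5, 10, 3.25, geom)  # 5 * 103.25 / 110
#' @export
fan_map <- function(x, d, d_ref, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (any(d < 0) || any(d_ref < 0))
    stop("depths must be non-negative", call. = FALSE)
  if (any(geom$ssd + d <= 0))
    stop("ssd + d must be positive", call. = FALSE)
  x * (geom$ssd + d_ref) / (geom$ssd + d)
}

#' Pixel grid for a reconstructed dose plane
#'
#' Defines a regular 2-D grid of square pixels in the lateral/depth plane.
#' `lateral_origin` and `depth_origin` are the coordinates of the centre of
#' the first pixel; the beam axis is at lateral 0 and the phantom surface at
#' depth 0.
#'
#' @param pixel_spacing Pixel pitch in cm (same laterally and in depth).
#' @param n_lateral,n_depth Number of columns / rows (>= 2).
#' @param lateral_origin Lateral position of the first column centre, cm.
#' @param depth_origin Depth of the first row centre, cm.
#' @param geom Optional [beam_geometry()]; when given, all pixel centres are
#'   required to lie inside the phantom.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(pixel_spacing, n_lateral, n_depth,
                      lateral_origin, depth_origin, geom = NULL) {
  if (!(pixel_spacing > 0)) stop("`pixel_spacing` must be positive", call. = FALSE)
  n_lateral <- as.integer(n_lateral); n_depth <- as.integer(n_depth)
  if (n_lateral < 2L || n_depth < 2L)
    stop("grid must have at least 2 pixels in each direction", call. = FALSE)
  g <- structure(
    list(pixel_spacing = pixel_spacing,
         n_lateral = n_lateral, n_depth = n_depth,
         lateral_origin = lateral_origin, depth_origin = depth_origin),
    class = "grid_spec"
  )
  if (!is.null(geom)) {
    lat <- grid_lateral(g); dep <- grid_depths(g)
    eps <- 1e-9
    if (min(lat) < -geom$phantom_halfwidth - eps ||
        max(lat) > geom$phantom_halfwidth + eps ||
        min(dep) < -eps || max(dep) > geom$phantom_depth + eps)
      stop("grid extends beyond the phantom", call. = FALSE)
  }
  g
}

#' Symmetric reconstruction grid covering the beam
#'
#' Convenience constructor: a grid centred on the beam axis (so lateral 0 is
#' always a column centre) spanning `[-halfwidth, halfwidth]` laterally and
#' `[spacing/2, depth - spacing/2]` in depth.
#'
#' @param pixel_spacing Pixel pitch, cm.
#' @param halfwidth Lateral half-extent, cm (default 15).
#' @param depth Depth extent, cm (default 28).
#' @param geom Optional [beam_geometry()] for bounds checking.
#' @return A `grid_spec`.
#' @export
symmetric_grid <- function(pixel_spacing, halfwidth = 15, depth = 28,
                           geom = NULL) {
  n_half <- floor(halfwidth / pixel_spacing + 1e-9)
  n_lateral <- 2L * as.integer(n_half) + 1L
  n_depth <- as.integer(round(depth / pixel_spacing))
  grid_spec(pixel_spacing,
            n_lateral = n_lateral, n_depth = n_depth,
            lateral_origin = -n_half * pixel_spacing,
            depth_origin = pixel_spacing / 2,
            geom = geom)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
grid_lateral <- function(grid) {
  grid$lateral_origin + (seq_len(grid$n_lateral) - 1L) * grid$pixel_spacing
}

#' @rdname grid_spec
#' @export
grid_depths <- function(grid) {
  grid$depth_origin + (seq_len(grid$n_depth) - 1L) * grid$pixel_spacing
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels of %.4g cm\n",
              x$n_depth, x$n_lateral, x$pixel_spacing))
  cat(sprintf("  lateral %.4g .. %.4g cm | depth %.4g .. %.4g cm\n",
              min(grid_lateral(x)), max(grid_lateral(x)),
              min(grid_depths(x)), max(grid_depths(x))))
  invisible(x)
}

#' Voxel scoring grid of the reference simulation layout
#'
#' The layout on which the reference beam data are scored: cubic voxels of
#' `voxel_side` cm (0.5 cm, i.e. 0.125 cm^3) arranged in 56 depth rows with
#' centres from 0.25 to 27.75 cm and 60 lateral columns spanning 30 cm —
#' 3360 voxels in total, one lateral dose profile per depth row. Note the
#' lateral column count is even, so no column centre sits exactly on the
#' beam axis.
#'
#' @param voxel_side Voxel edge length, cm.
#' @param n_depth,n_lateral Row / column counts.
#' @return A `grid_spec` with additional class `scoring_grid` and a
#'   `voxel_side` field.
#' @examples
#' g <- scoring_grid()
#' g$n_depth * g$n_lateral   # 3360
#' @export
scoring_grid <- function(voxel_side = 0.5, n_depth = 56, n_lateral = 60) {
  g <- grid_spec(voxel_side, n_lateral = n_lateral, n_depth = n_depth,
                 lateral_origin = -(n_lateral - 1) / 2 * voxel_side,
                 depth_origin = voxel_side / 2)
  g$voxel_side <- voxel_side
  class(g) <- c("scoring_grid", class(g))
  g
}
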