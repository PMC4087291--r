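# round half away from zero, then clamp to 0..255 (8-bit channel rule)
byte8 <- function(x) {
  as.integer(pmin(255, pmax(0, floor(abs(x) + 0.5) * sign(x))))
}

#' Grayscale transform of a dose plane
#'
#' Maps relative dose to an 8-bit gray level, `round(dose/100 * 255)`
#' (half away from zero), replicated on the three RGB channels when an
#' image is written: 0% dose is black, 100% dose is 255, the maximum of
#' the gray scale.
#'
#' @param dm A [dose_plane()] with doses in `[0, 100]`.
#' @return The plane with an integer `gray` column added.
#' @examples
#' g <- scoring_grid()
#' plane <- separable_truth(beam_model_params(), beam_geometry(), g)
#' range(to_gray(plane)$gray)
#' @export
to_gray <- function(dm) {
  stopifnot(inherits(dm, "dose_plane"))
  if (max(dm$dose) > 100 + 1e-6)
    stop("doses above 100% cannot be rendered; renormalise first", call. = FALSE)
  dm$gray <- byte8(pmin(dm$dose, 100) / 100 * 255)
  dm
}

#' Segment a dose plane into isodose bands
#'
#' Partitions the plane into dose bands for banded (posterised) display:
#' with the default decile edges, doses in 1–10% form the first band,
#' 10–20% the second (upper edge inclusive), and so on up to 91–100%.
#' Pixels below the lowest edge are background (band 0). The borders
#' between bands are the isodose curves.
#'
#' @param dm A [dose_plane()].
#' @param edges Strictly increasing percent thresholds. The default
#'   `c(1, 10, 20, ..., 100)` yields ten bands.
#' @return The plane with an integer `band` column (0 = background), class
#'   `band_map`, and the edges stored as attribute `edges`.
#' @export
segment_bands <- function(dm, edges = c(1, seq(10, 100, by = 10))) {
  stopifnot(inherits(dm, "dose_plane"))
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("`edges` must be strictly increasing with at least two values",
         call. = FALSE)
  dose <- pmin(dm$dose, max(edges))  # tolerate the 1e-6 normalisation slack
  band <- as.integer(cut(dose, breaks = edges, right = TRUE,
                         include.lowest = TRUE))
  band[dm$dose < edges[1L]] <- 0L
  dm$band <- band
  attr(dm, "edges") <- edges
  class(dm) <- c("band_map", class(dm))
  dm
}

# band labels as an n_depth x n_lateral integer matrix
label_matrix <- function(bm) {
  g <- plane_grid(bm)
  i <- match(bm$depth, grid_depths(g))
  j <- match(bm$lateral, grid_lateral(g))
  m <- matrix(NA_integer_, g$n_depth, g$n_lateral)
  m[cbind(i, j)] <- bm$band
  m
}

#' Mark isodose contour pixels on a band map
#'
#' Flags every pixel whose 4-neighbourhood (up/down/left/right) contains a
#' different band label; those limiting lines between bands are the isodose
#' curves.
#'
#' @param bm A band map from [segment_bands()].
#' @return `bm` with a logical `contour` column added.
#' @export
band_contours <- function(bm) {
  stopifnot(inherits(bm, "band_map"))
  m <- label_matrix(bm)
  nr <- nrow(m); nc <- ncol(m)
  edge <- matrix(FALSE, nr, nc)
  edge[-nr, ] <- edge[-nr, ] | m[-nr, ] != m[-1, ]
  edge[-1, ]  <- edge[-1, ]  | m[-1, ]  != m[-nr, ]
  edge[, -nc] <- edge[, -nc] | m[, -nc] != m[, -1]
  edge[, -1]  <- edge[, -1]  | m[, -1]  != m[, -nc]
  g <- plane_grid(bm)
  i <- match(bm$depth, grid_depths(g))
  j <- match(bm$lateral, grid_lateral(g))
  bm$contour <- edge[cbind(i, j)]
  bm
}

#' RGB to HSI (triangle model)
#'
#' Converts unit-interval RGB to hue/saturation/intensity with the triangle
#' model's closed-form branch formulas: `I = (R+G+B)/3`, and branching on
#' the smallest channel (tested in the order blue, red, green, with
#' non-strict comparisons),
#' \itemize{
#'   \item B smallest: `H_raw = (G-B)/(3I-3B)`, `S = (I-B)/I`
#'   \item R smallest: `H_raw = (B-R)/(3I-3R) + 1`, `S = (I-R)/I`
#'   \item G smallest: `H_raw = (R-G)/(3I-3G) + 2`, `S = (I-G)/I`
#' }
#' The raw hue spans three sectors `[0, 3)` and is divided by 3 so the
#' stored hue lies in `[0, 1)`. Achromatic pixels (R = G = B) take
#' `S = 0, H = 0` by convention.
#'
#' @param r,g,b Channel values in `[0, 1]`. Vectorised.
#' @param as_printed Use `3I - 3R` in the green-smallest denominator (a
#'   published variant) instead of the pattern-consistent `3I - 3G`.
#'   Default `FALSE`.
#' @return A tibble with columns `h`, `s`, `i`.
#' @examples
#' rgb_to_hsi(1, 0.5, 0)   # h = 1/9, s = 1, i = 0.5
#' @export
rgb_to_hsi <- function(r, g, b, as_printed = FALSE) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(r, n); g <- rep_len(g, n); b <- rep_len(b, n)
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 1))
    stop("RGB channels must lie in [0, 1]", call. = FALSE)
  i <- (r + g + b) / 3
  h <- numeric(n); s <- numeric(n)
  achro <- r == g & g == b
  bb <- !achro & b <= r & b <= g
  rr <- !achro & !bb & r <= b & r <= g
  gg <- !achro & !bb & !rr
  h[bb] <- (g[bb] - b[bb]) / (3 * i[bb] - 3 * b[bb])
  s[bb] <- (i[bb] - b[bb]) / i[bb]
  h[rr] <- (b[rr] - r[rr]) / (3 * i[rr] - 3 * r[rr]) + 1
  s[rr] <- (i[rr] - r[rr]) / i[rr]
  gden <- if (as_printed) 3 * i[gg] - 3 * r[gg] else 3 * i[gg] - 3 * g[gg]
  h[gg] <- (r[gg] - g[gg]) / gden + 2
  s[gg] <- (i[gg] - g[gg]) / i[gg]
  h[achro] <- 0; s[achro] <- 0
  tibble::tibble(h = h / 3, s = s, i = i)
}

#' Triangle-model HSI back to RGB
#'
#' Closed-form inverse of [rgb_to_hsi()] (pattern-consistent branch form).
#' With sector `k = floor(3h)` and within-sector fraction `f = 3h - k`, the
#' smallest channel is `I(1-S)`, the next is offset by `3ISf`, and the third
#' follows from `R+G+B = 3I`.
#'
#' @param h Hue in `[0, 1)`; `s` saturation in `[0, 1]`; `i` intensity in
#'   `[0, 1]`.
#' @param s,i See `h`.
#' @return A tibble with columns `r`, `g`, `b` (not clamped; out-of-gamut
#'   `(h, s, i)` triples can yield channels above 1).
#' @export
hsi_to_rgb <- function(h, s, i) {
  n <- max(length(h), length(s), length(i))
  h <- rep_len(h, n); s <- rep_len(s, n); i <- rep_len(i, n)
  k <- pmin(2, pmax(0, floor(3 * h)))
  f <- 3 * h - k
  lo <- i * (1 - s)
  mid <- lo + 3 * i * s * f
  hi3 <- 3 * i
  r <- g <- b <- numeric(n)
  b[k == 0] <- lo[k == 0]; g[k == 0] <- mid[k == 0]
  r[k == 0] <- hi3[k == 0] - g[k == 0] - b[k == 0]
  r[k == 1] <- lo[k == 1]; b[k == 1] <- mid[k == 1]
  g[k == 1] <- hi3[k == 1] - r[k == 1] - b[k == 1]
  g[k == 2] <- lo[k == 2]; r[k == 2] <- mid[k == 2]
  b[k == 2] <- hi3[k == 2] - r[k == 2] - g[k == 2]
  zero <- s == 0
  r[zero] <- i[zero]; g[zero] <- i[zero]; b[zero] <- i[zero]
  tibble::tibble(r = r, g = g, b = b)
}

# opponent-axis matrix: intensity row plus two chromatic axes.
# A published variant prints this matrix without signs and reuses it for the
# inverse; the signed standard form is used here and inverted numerically.
hsi_opponent_matrix <- function() {
  rbind(c(1, 1, 1) / 3,
        c(-1, -1, 2) / sqrt(6),
        c(1, -1, 0) / sqrt(2))
}

#' Matrix-form RGB to HSI transform
#'
#' Applies a fixed 3x3 opponent-axis matrix to `(R, G, B)` giving the
#' intensity `I` and two chromatic coordinates `(V1, V2)`, then
#' `H = atan2(V1, V2)` and `S = sqrt(V1^2 + V2^2)`. Provided for
#' completeness as an alternative hue/saturation parameterisation; the
#' triangle-model [rgb_to_hsi()] is the rendering path used elsewhere in
#' this package.
#'
#' @inheritParams rgb_to_hsi
#' @return A tibble with columns `i`, `v1`, `v2`, `h` (radians), `s`.
#' @export
hsi_matrix_transform <- function(r, g, b) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(r, n); g <- rep_len(g, n); b <- rep_len(b, n)
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 1))
    stop("RGB channels must lie in [0, 1]", call. = FALSE)
  v <- hsi_opponent_matrix() %*% rbind(r, g, b)
  tibble::tibble(i = v[1, ], v1 = v[2, ], v2 = v[3, ],
                 h = atan2(v[2, ], v[3, ]),
                 s = sqrt(v[2, ]^2 + v[3, ]^2))
}

#' @rdname hsi_matrix_transform
#' @param i Intensity; `h` angle in radians; `s` chromatic radius — as
#'   returned by the forward transform.
#' @param h,s See `i`.
#' @export
hsi_matrix_inverse <- function(i, h, s) {
  n <- max(length(i), length(h), length(s))
  i <- rep_len(i, n); h <- rep_len(h, n); s <- rep_len(s, n)
  rgb <- solve(hsi_opponent_matrix()) %*% rbind(i, s * sin(h), s * cos(h))
  tibble::tibble(r = rgb[1, ], g = rgb[2, ], b = rgb[3, ])
}

#' Default isodose colour palette
#'
#' The conventional hot-to-cold dose wash: red-orange for the 80–100%
#' region of maximum intensity, yellow for 70–80%, green for 25–70% and
#' blue for 0–25%, with the displayed intensity scaling with dose inside
#' each band (so the green and blue bands run dark to light as dose rises).
#' Hues are triangle-model values in `[0, 1)`.
#'
#' @return A tibble with columns `lo`, `hi`, `name`, `hue`, `sat`.
#' @export
default_palette <- function() {
  tibble::tibble(
    lo = c(0, 25, 70, 80),
    hi = c(25, 70, 80, 100),
    name = c("blue", "green", "yellow", "red-orange"),
    hue = c(2 / 3, 1 / 3, 1 / 6, 1 / 18),
    sat = c(1, 1, 1, 1)
  )
}

#' Colour-render a dose plane via HSI
#'
#' Assigns each pixel the hue/saturation of its palette band (the lowest
#' band includes its lower edge; higher bands are lower-open, upper-closed,
#' so band boundaries coincide exactly with [segment_bands()] given the
#' same edges). The intensity scales linearly with dose within the band and
#' the HSI triple is converted back to RGB bytes through [hsi_to_rgb()],
#' rescaled so a 100% pixel reaches the brightest in-gamut shade of its
#' hue. Doses outside every band render black.
#'
#' @param dm A [dose_plane()].
#' @param palette A tibble like [default_palette()]: non-overlapping
#'   `lo`/`hi` dose ranges in percent plus `hue` and `sat`.
#' @return The plane with columns `band_name`, `h`, `s`, `i` and byte
#'   columns `R`, `G`, `B` added.
#' @export
render_color <- function(dm, palette = default_palette()) {
  stopifnot(inherits(dm, "dose_plane"),
            all(c("lo", "hi", "hue", "sat") %in% names(palette)))
  pal <- palette[order(palette$lo), , drop = FALSE]
  if (any(diff(pal$lo) <= 0) || any(pal$hi <= pal$lo) ||
      any(pal$lo[-1] < pal$hi[-nrow(pal)]))
    stop("palette dose ranges must be increasing and non-overlapping",
         call. = FALSE)
  dose <- dm$dose
  n <- length(dose)
  h <- numeric(n); s <- numeric(n); ii <- numeric(n)
  name <- rep(NA_character_, n)
  hit <- rep(FALSE, n)
  for (k in seq_len(nrow(pal))) {
    inband <- if (k == 1L) dose >= pal$lo[k] & dose <= pal$hi[k]
              else dose > pal$lo[k] & dose <= pal$hi[k]
    inband <- inband & !hit
    hit <- hit | inband
    h[inband] <- pal$hue[k]; s[inband] <- pal$sat[k]
    ii[inband] <- dose[inband] / 100
    name[inband] <- if ("name" %in% names(pal)) pal$name[k] else as.character(k)
  }
  base <- hsi_to_rgb(h, s, rep(1, n))     # channel pattern at unit intensity
  cmax <- pmax(base$r, base$g, base$b)
  scale <- ifelse(hit & cmax > 0, ii / cmax, 0)
  dm$band_name <- name
  dm$h <- ifelse(hit, h, 0); dm$s <- ifelse(hit, s, 0); dm$i <- ifelse(hit, ii, 0)
  dm$R <- byte8(base$r * scale * 255)
  dm$G <- byte8(base$g * scale * 255)
  dm$B <- byte8(base$b * scale * 255)
  dm
}

#' Write dose-plane renderings as PNG
#'
#' Images are written with the phantom surface (depth row 0) at the top and
#' the beam axis at the horizontal centre of a symmetric grid.
#'
#' @param x For `write_gray_png()`, a plane from [to_gray()] (or a bare
#'   [dose_plane()], converted on the fly); for `write_color_png()`, a
#'   plane from [render_color()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(x, path) {
  if (!"gray" %in% names(x)) x <- to_gray(x)
  g <- plane_grid(x)
  i <- match(x$depth, grid_depths(g)); j <- match(x$lateral, grid_lateral(g))
  m <- matrix(0, g$n_depth, g$n_lateral)
  m[cbind(i, j)] <- x$gray / 255
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
write_color_png <- function(x, path) {
  stopifnot(all(c("R", "G", "B") %in% names(x)))
  g <- plane_grid(x)
  i <- match(x$depth, grid_depths(g)); j <- match(x$lateral, grid_lateral(g))
  arr <- array(0, c(g$n_depth, g$n_lateral, 3))
  arr[cbind(i, j, 1L)] <- x$R / 255
  arr[cbind(i, j, 2L)] <- x$G / 255
  arr[cbind(i, j, 3L)] <- x$B / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Plot a dose plane
#'
#' Raster display of the dose distribution with depth increasing downward.
#' `mode = "bands"` posterises into the decile isodose bands of
#' [segment_bands()]; `mode = "contours"` overlays isodose lines at the
#' band edges.
#'
#' @param object A [dose_plane()].
#' @param mode `"dose"`, `"bands"` or `"contours"`.
#' @param edges Band edges for the banded/contour modes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_plane
#' @export
autoplot.dose_plane <- function(object, mode = c("dose", "bands", "contours"),
                                edges = c(1, seq(10, 100, by = 10)), ...) {
  mode <- match.arg(mode)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lateral, y = .data$depth))
  if (mode == "bands") {
    bm <- segment_bands(object, edges)
    p <- ggplot2::ggplot(bm, ggplot2::aes(x = .data$lateral, y = .data$depth)) +
      ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$band))) +
      ggplot2::scale_fill_viridis_d(name = "band")
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$dose)) +
      ggplot2::scale_fill_viridis_c(name = "dose [%]")
    if (mode == "contours")
      p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$dose),
                                     breaks = edges, colour = "white",
                                     linewidth = 0.3)
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "off-axis position [cm]", y = "depth [cm]")
}
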