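#' Percentage depth dose curve
#'
#' A sampled central-axis depth-dose curve. On construction the curve is
#' normalised so its maximum is exactly 100%, matching the convention that
#' all relative doses are expressed as a percentage of the dose at the depth
#' of maximum dose (d_ref). If several samples tie for the maximum, the
#' shallowest depth is taken as d_ref.
#'
#' @param depths Depths in cm, non-negative and strictly increasing, or a
#'   data frame with columns `depth` and `dose`.
#' @param values Dose values (any positive scale; normalised to max 100).
#' @return A tibble of class `pdd_curve` with columns `depth`, `dose` and an
#'   attribute `d_ref`.
#' @examples
#' pdd <- pdd_curve(c(0, 1, 3.25, 10, 20), c(20, 90, 100, 75, 48))
#' d_ref(pdd)
#' @export
pdd_curve <- function(depths, values = NULL) {
  if (is.data.frame(depths)) {
    df <- depths
    stopifnot(all(c("depth", "dose") %in% names(df)))
    depths <- df$depth; values <- df$dose
  }
  check_curve_samples(depths, values, "depth")
  if (any(depths < 0)) stop("depths must be non-negative", call. = FALSE)
  values <- values / max(values) * 100
  d_ref <- depths[which.max(values)]  # which.max takes the first (shallowest) tie
  out <- tibble::tibble(depth = as.numeric(depths), dose = as.numeric(values))
  structure(out, d_ref = d_ref, class = c("pdd_curve", class(out)))
}

#' Off-axis dose profile at a reference depth
#'
#' A lateral dose profile sampled at a stated reference depth, normalised so
#' the (linearly interpolated) value on the beam axis is exactly 100%.
#'
#' @param positions Off-axis positions in cm, strictly increasing and
#'   spanning the axis (negative and positive sides), or a data frame with
#'   columns `position` and `dose`.
#' @param values Dose values (normalised to 100 at position 0).
#' @param ref_depth Depth at which the profile was sampled, cm.
#' @return A tibble of class `profile_curve` with columns `position`, `dose`
#'   and an attribute `ref_depth`.
#' @export
profile_curve <- function(positions, values = NULL, ref_depth) {
  if (is.data.frame(positions)) {
    df <- positions
    stopifnot(all(c("position", "dose") %in% names(df)))
    positions <- df$position; values <- df$dose
  }
  check_curve_samples(positions, values, "position")
  if (min(positions) > 0 || max(positions) < 0)
    stop("profile positions must span the beam axis (position 0)", call. = FALSE)
  if (!is.numeric(ref_depth) || length(ref_depth) != 1L || ref_depth < 0)
    stop("`ref_depth` must be a single non-negative depth in cm", call. = FALSE)
  central <- stats::approx(positions, values, xout = 0)$y
  if (!is.finite(central) || central <= 0)
    stop("profile value on the axis must be positive", call. = FALSE)
  values <- values / central * 100
  out <- tibble::tibble(position = as.numeric(positions), dose = as.numeric(values))
  structure(out, ref_depth = as.numeric(ref_depth),
            class = c("profile_curve", class(out)))
}

check_curve_samples <- function(x, y, what) {
  if (length(x) < 2L)
    stop("a curve needs at least 2 samples", call. = FALSE)
  if (length(x) != length(y))
    stop(sprintf("`%s` and dose values must have the same length", what),
         call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("curve samples must be finite", call. = FALSE)
  if (any(diff(x) <= 0))
    stop(sprintf("`%s` values must be strictly increasing", what), call. = FALSE)
  if (any(y < 0)) stop("dose values must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' @rdname pdd_curve
#' @param curve A `pdd_curve`.
#' @export
d_ref <- function(curve) {
  stopifnot(inherits(curve, "pdd_curve"))
  attr(curve, "d_ref")
}

#' @rdname profile_curve
#' @param curve A `profile_curve`.
#' @export
ref_depth <- function(curve) {
  stopifnot(inherits(curve, "profile_curve"))
  attr(curve, "ref_depth")
}

# Piecewise-linear evaluation of a PDD at arbitrary depths.
# Outside the sampled range the value is clamped to the nearest endpoint
# sample (rule = 2): a query shallower than the first sample returns the
# first sample, deeper than the last returns the last.
eval_pdd <- function(curve, d) {
  stats::approx(curve$depth, curve$dose, xout = d, rule = 2)$y
}

# Piecewise-linear evaluation of a profile at arbitrary off-axis positions.
# Beyond the sampled support the dose decays linearly to zero over one
# `edge_decay` length (one pixel spacing in reconstruction), then is zero:
# a finite support prevents clamped shoulder values from painting dose onto
# the phantom edge.
eval_profile <- function(curve, x, edge_decay) {
  stopifnot(edge_decay > 0)
  p <- curve$position; v <- curve$dose
  y <- stats::approx(p, v, xout = x, rule = 2)$y
  lo <- p[1L]; hi <- p[length(p)]
  below <- x < lo
  above <- x > hi
  y[below] <- v[1L] * pmax(0, 1 - (lo - x[below]) / edge_decay)
  y[above] <- v[length(v)] * pmax(0, 1 - (x[above] - hi) / edge_decay)
  y
}

#' Resample a curve onto a regular pixel lattice
#'
#' Evaluates a curve by linear interpolation at `count` evenly spaced
#' points `start, start + spacing, ...` — the pixel-pitch resampling that
#' turns the voxel-sampled input curves into per-pixel values. Outside the
#' sampled range, a PDD is clamped to its endpoint values while a profile
#' decays linearly to zero over one `spacing` beyond its last sample.
#'
#' @param curve A [pdd_curve()] or [profile_curve()].
#' @param start Abscissa of the first output sample, cm.
#' @param spacing Output pitch, cm (> 0).
#' @param count Number of output samples (>= 2).
#' @return A tibble of class `resampled_curve` with columns `abscissa` and
#'   `dose`, and attributes `start` and `spacing`.
#' @export
resample_curve <- function(curve, start, spacing, count) {
  stopifnot(spacing > 0, count >= 2)
  xs <- start + (seq_len(count) - 1L) * spacing
  if (inherits(curve, "pdd_curve")) {
    ys <- eval_pdd(curve, xs)
  } else if (inherits(curve, "profile_curve")) {
    ys <- eval_profile(curve, xs, edge_decay = spacing)
  } else {
    stop("`curve` must be a pdd_curve or profile_curve", call. = FALSE)
  }
  out <- tibble::tibble(abscissa = xs, dose = ys)
  structure(out, start = start, spacing = spacing,
            class = c("resampled_curve", class(out)))
}

#' Read and write dose curves as delimited text
#'
#' Curves are stored as two-column whitespace- or comma-delimited text
#' (columns `abscissa_cm`, `dose_percent`), `#` marking comment lines. A
#' profile's reference depth is carried in a `# ref_depth_cm: <d>` comment
#' written by [write_curve()].
#'
#' @param path File path.
#' @param type `"pdd"` or `"profile"`. For `"profile"`, `ref_depth` is taken
#'   from the file's `ref_depth_cm` comment unless given explicitly.
#' @param ref_depth Reference depth override for profiles, cm.
#' @return A [pdd_curve()] or [profile_curve()].
#' @export
read_curve <- function(path, type = c("pdd", "profile"), ref_depth = NULL) {
  type <- match.arg(type)
  lines <- readLines(path, warn = FALSE)
  if (type == "profile" && is.null(ref_depth)) {
    m <- grep("^#\\s*ref_depth_cm:", lines, value = TRUE)
    if (length(m)) ref_depth <- as.numeric(sub("^#\\s*ref_depth_cm:\\s*", "", m[1L]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  body <- sub(",", " ", body, fixed = TRUE)
  has_header <- grepl("[A-Za-z]", body[1L])
  if (has_header) body <- body[-1L]
  dat <- utils::read.table(text = body, col.names = c("abscissa", "dose"))
  if (type == "pdd") {
    pdd_curve(dat$abscissa, dat$dose)
  } else {
    if (is.null(ref_depth))
      stop("profile file has no ref_depth_cm comment; pass `ref_depth`",
           call. = FALSE)
    profile_curve(dat$abscissa, dat$dose, ref_depth = ref_depth)
  }
}

#' @rdname read_curve
#' @param curve A `pdd_curve` or `profile_curve`.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(curve, "pdd_curve")) {
    writeLines(c("# central-axis percentage depth dose",
                 sprintf("# d_ref_cm: %.17g", d_ref(curve)),
                 "abscissa_cm dose_percent"), con)
    xs <- curve$depth
  } else if (inherits(curve, "profile_curve")) {
    writeLines(c("# off-axis dose profile (percent of central-axis dose)",
                 sprintf("# ref_depth_cm: %.17g", ref_depth(curve)),
                 "abscissa_cm dose_percent"), con)
    xs <- curve$position
  } else stop("`curve` must be a pdd_curve or profile_curve", call. = FALSE)
  writeLines(sprintf("%.17g %.17g", xs, curve$dose), con)
  invisible(path)
}
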