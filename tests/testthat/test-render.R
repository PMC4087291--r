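# a tiny plane holding prescribed dose values, for transform tests
value_plane <- function(values) {
  n <- length(values)
  nc <- max(2, ceiling(sqrt(n))); nr <- max(2, ceiling(n / nc))
  m <- matrix(0, nr, nc)
  m[seq_len(n)] <- values
  dose_plane(m, grid_spec(0.5, n_lateral = nc, n_depth = nr,
                          lateral_origin = 0, depth_origin = 0.25))
}

test_that("the gray transform is exact at the endpoints and monotone", {
  doses <- (0:1000) / 10
  g <- to_gray(value_plane(doses))
  lev <- g$gray[match(doses, g$dose)]
  expect_equal(lev[doses == 100], 255L)   # maximum dose -> top of the scale
  expect_equal(lev[doses == 0], 0L)
  expect_equal(lev[doses == 20], 51L)     # 0.2 * 255 exactly
  expect_true(all(diff(lev) >= 0))        # monotone non-decreasing
  expect_true(all(lev >= 0L & lev <= 255L))
  expect_error(to_gray(value_plane(c(0, 101))), "renormalise")
})

test_that("decile banding follows the half-open interval rule", {
  bm <- segment_bands(value_plane(c(0.5, 1, 5, 10, 10.5, 95, 100)))
  lab <- function(d) bm$band[match(d, bm$dose)]
  expect_equal(lab(5), 1L)       # 1-10% is the first band
  expect_equal(lab(95), 10L)     # 91-100% is the tenth
  expect_equal(lab(10), 1L)      # upper edge inclusive
  expect_equal(lab(10.5), 2L)
  expect_equal(lab(1), 1L)       # lowest edge inclusive
  expect_equal(lab(0.5), 0L)     # below 1%: background
  expect_error(segment_bands(value_plane(50), edges = c(10, 5)), "increasing")
})

test_that("band labels match an independent per-pixel threshold scan", {
  doses <- as.vector(outer(seq(0, 100, by = 2.5), c(0, 0.3, 0.7), `+`))
  doses <- doses[doses <= 100]
  edges <- c(1, seq(10, 100, by = 10))
  bm <- segment_bands(value_plane(doses))
  # oracle: explicit scan over edges, first band closed below
  oracle <- vapply(doses, function(d) {
    if (d < edges[1]) return(0L)
    for (k in seq_len(length(edges) - 1L)) {
      lo_ok <- if (k == 1L) d >= edges[k] else d > edges[k]
      if (lo_ok && d <= edges[k + 1L]) return(k)
    }
    stop("unreachable")
  }, 0L)
  expect_equal(bm$band[match(doses, bm$dose)], oracle)
  # partition conservation: background plus band counts covers every pixel
  expect_equal(sum(tabulate(bm$band + 1L, 11L)), nrow(bm))
})

test_that("contours appear exactly where 4-neighbour labels differ", {
  # uniform plane: no contours
  uni <- band_contours(segment_bands(value_plane(rep(50, 36))))
  expect_false(any(uni$contour))
  # two half-planes: one straight two-pixel-wide boundary (both sides marked)
  m <- matrix(c(rep(5, 12), rep(95, 12)), nrow = 4, byrow = FALSE)
  hp <- dose_plane(m, grid_spec(0.5, n_lateral = 6, n_depth = 4,
                                lateral_origin = 0, depth_origin = 0.25))
  hb <- band_contours(segment_bands(hp))
  cm <- matrix(FALSE, 4, 6)
  i <- match(hb$depth, grid_depths(plane_grid(hb)))
  j <- match(hb$lateral, grid_lateral(plane_grid(hb)))
  cm[cbind(i, j)] <- hb$contour
  expect_equal(which(apply(cm, 2, any)), c(3L, 4L))
  expect_true(all(cm[, 3:4]))
  # disk-shaped band: contour pixel count equals a brute neighbourhood scan
  n <- 21
  xy <- expand.grid(r = 1:n, c = 1:n)
  disk <- matrix(ifelse((xy$r - 11)^2 + (xy$c - 11)^2 <= 36, 80, 5), n, n)
  dp <- dose_plane(disk, grid_spec(0.5, n_lateral = n, n_depth = n,
                                   lateral_origin = -5, depth_origin = 0.25))
  db <- band_contours(segment_bands(dp))
  lab <- matrix(ifelse(disk > 70, 1L, 0L), n, n)
  brute <- 0L
  for (r in 1:n) for (c in 1:n) {
    nb <- c(if (r > 1) lab[r - 1, c], if (r < n) lab[r + 1, c],
            if (c > 1) lab[r, c - 1], if (c < n) lab[r, c + 1])
    if (any(nb != lab[r, c])) brute <- brute + 1L
  }
  expect_equal(sum(db$contour), brute)
})

test_that("triangle-model RGB -> HSI follows the branch formulas", {
  # achromatic: saturation 0, hue pinned to 0
  a <- rgb_to_hsi(0.5, 0.5, 0.5)
  expect_equal(c(a$h, a$s, a$i), c(0, 0, 0.5))
  # worked example: R=1, G=0.5, B=0 sits in the blue-smallest sector
  x <- rgb_to_hsi(1, 0.5, 0)
  expect_equal(x$i, 0.5)
  expect_equal(x$s, 1)
  expect_equal(x$h * 3, 1 / 3, tolerance = 1e-12)   # raw hue before /3
  expect_error(rgb_to_hsi(1.2, 0, 0), "\\[0, 1\\]")
  # printed-variant flag changes only the green-smallest branch
  y1 <- rgb_to_hsi(0.8, 0.1, 0.6)
  y2 <- rgb_to_hsi(0.8, 0.1, 0.6, as_printed = TRUE)
  expect_false(isTRUE(all.equal(y1$h, y2$h)))
  expect_equal(y1$s, y2$s)
})

test_that("RGB -> HSI -> RGB round-trips to 1e-10 on random in-gamut pixels", {
  set.seed(421)
  n <- 1000
  r <- runif(n); g <- runif(n); b <- runif(n)
  hsi <- rgb_to_hsi(r, g, b)
  back <- hsi_to_rgb(hsi$h, hsi$s, hsi$i)
  expect_lt(max(abs(back$r - r)), 1e-10)
  expect_lt(max(abs(back$g - g)), 1e-10)
  expect_lt(max(abs(back$b - b)), 1e-10)
})

test_that("the matrix-form transform is consistent and invertible", {
  gr <- hsi_matrix_transform(0.4, 0.4, 0.4)
  expect_equal(c(gr$v1, gr$v2, gr$s), c(0, 0, 0))   # opponent axes vanish
  set.seed(7)
  r <- runif(200); g <- runif(200); b <- runif(200)
  f <- hsi_matrix_transform(r, g, b)
  expect_equal(f$s, sqrt(f$v1^2 + f$v2^2), tolerance = 1e-12)
  back <- hsi_matrix_inverse(f$i, f$h, f$s)
  expect_lt(max(abs(back$r - r)), 1e-10)
  expect_lt(max(abs(back$g - g)), 1e-10)
  expect_lt(max(abs(back$b - b)), 1e-10)
})

test_that("colour rendering assigns palette bands like a threshold scan", {
  doses <- c(0, 5, 10, 24.9, 25, 25.1, 50, 70, 75, 80, 90, 100)
  rc <- render_color(value_plane(doses))
  got <- rc$band_name[match(doses, rc$dose)]
  oracle <- vapply(doses, function(d) {
    if (d <= 25) "blue" else if (d <= 70) "green"
    else if (d <= 80) "yellow" else "red-orange"
  }, "")
  expect_equal(got, oracle)
  # dose 90% renders in the red-orange hue range, dose 10% in blue
  expect_equal(rc$h[match(90, rc$dose)], 1 / 18)
  expect_equal(rc$h[match(10, rc$dose)], 2 / 3)
  # zero dose is black
  expect_equal(unlist(rc[match(0, rc$dose), c("R", "G", "B")],
                      use.names = FALSE), c(0L, 0L, 0L))
  bad <- default_palette(); bad$lo[2] <- 20
  expect_error(render_color(value_plane(50), bad), "non-overlapping")
})

test_that("palette band edges coincide with segment_bands given the same edges", {
  doses <- seq(0, 100, by = 0.25)
  edges <- c(1, seq(10, 100, by = 10))
  pal <- tibble::tibble(lo = head(edges, -1), hi = edges[-1],
                        name = as.character(1:10),
                        hue = seq(0, 0.9, by = 0.1), sat = 1)
  rc <- render_color(value_plane(doses), pal)
  bm <- segment_bands(value_plane(doses), edges)
  expect_equal(ifelse(is.na(rc$band_name), 0L, as.integer(rc$band_name)),
               bm$band)
})

test_that("PNG writers produce images matching the pixel tables", {
  skip_if_not_installed("png")
  geom <- fix_geom()
  plane <- reconstruct_plane(fix_pdd(), fix_profile(), geom,
                             symmetric_grid(0.5, halfwidth = 6, depth = 10,
                                            geom = geom))
  gpath <- withr::local_tempfile(fileext = ".png")
  write_gray_png(plane, gpath)
  img <- png::readPNG(gpath)
  expect_equal(dim(img), c(plane_grid(plane)$n_depth, plane_grid(plane)$n_lateral))
  expect_equal(max(round(img * 255)), 255)
  cpath <- withr::local_tempfile(fileext = ".png")
  write_color_png(render_color(plane), cpath)
  cimg <- png::readPNG(cpath)
  expect_equal(dim(cimg)[3], 3L)
})
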