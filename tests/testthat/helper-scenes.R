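# Shared fixtures: all synthetic, built in code at test time.

# positive-truncated normal draws within (lo, hi)
rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# exact disk rasterization used as the geometry oracle
raster_disk <- function(radius, pad = 3) {
  size <- 2L * ceiling(radius) + 2L * pad + 1L
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius^2)
}

# small rendered spheroid scene + its detected grid
small_spheroid_scene <- function(layout = "array150", rows = 3, cols = 4,
                                 diameters = NULL, day = 7, seed = 3,
                                 noise = TRUE) {
  sp <- if (noise) sceneSpec(layout, rows = rows, cols = cols, seed = seed)
        else sceneSpec(layout, rows = rows, cols = cols, seed = seed,
                       noise_sigma = 0, illumination_gradient = 0)
  n <- rows * cols
  if (is.null(diameters)) diameters <- rep(0.5 * sp@trap_diameter_um, n)
  sc <- sceneFromDiameters(sp, diameters, day = day)
  r <- renderScene(sc, day)
  list(spec = sp, scene = sc, render = r)
}

# segment one trap of a rendered scene against its detected grid
segment_trap <- function(img, grid, i, params = list(), day = 7) {
  tr <- traps(grid)
  half <- trapLattice(grid)$pitch_row_px / 2
  roi <- spheroidArray:::.roiAround(tr$center_row[i], tr$center_col[i],
                                    half, dim(img))
  d2 <- outer((seq_along(roi$rows) - roi$center[1])^2,
              (seq_along(roi$cols) - roi$center[2])^2, "+")
  interior <- d2 <= spheroidArray:::.trapInteriorRadius(tr$radius_px[i])^2
  list(mask = segmentSpheroid(img[roi$rows, roi$cols], interior,
                              trap_id = tr$trap_id[i], day = day,
                              offset = c(roi$rows[1], roi$cols[1]),
                              params = params),
       roi = roi)
}
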