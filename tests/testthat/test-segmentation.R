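test_that("preprocessing preserves constants, collapses color, removes impulses", {
  # constant image unchanged
  flat <- matrix(0.4, 60, 60)
  expect_equal(preprocessImage(flat), flat)

  # 3-channel input with equal channels matches the single-channel path
  col <- array(rep(flat, 3), c(60, 60, 3))
  expect_equal(preprocessImage(col), preprocessImage(flat))

  expect_error(preprocessImage(matrix(numeric(0), 0, 0)), "empty")

  # 2% salt-and-pepper on a binary disk scene: median filter restores
  # >= 99% of pixels
  clean <- 0.2 + 0.6 * !raster_disk(30, pad = 10)
  set.seed(4)
  noisy <- clean
  hit <- sample(length(noisy), round(0.02 * length(noisy)))
  noisy[hit] <- rep(c(0, 1), length.out = length(hit))
  restored <- preprocessImage(noisy, median_radius = 2)
  expect_gte(mean(abs(restored - clean) < 0.05), 0.99)
})

test_that("spheroids segment with high overlap and empty traps stay empty", {
  set.seed(11)
  d <- rtruncnorm(12, 75, 15, 30, 135)
  s <- small_spheroid_scene("array150", rows = 3, cols = 4, diameters = d)
  img <- preprocessImage(s$render$image)
  g <- detectTraps(img, 150, 1)
  dices <- vapply(seq_len(nTraps(g)), function(i) {
    st <- segment_trap(img, g, i)
    truth <- s$render$labels[st$roi$rows, st$roi$cols] > 0
    expect_true(st$mask@found)
    dice_overlap(st$mask@mask, truth)
  }, numeric(1))
  expect_gte(min(dices), 0.9)
  expect_gte(median(dices), 0.95)

  # determinism: identical inputs give identical masks
  m1 <- segment_trap(img, g, 1)$mask
  m2 <- segment_trap(img, g, 1)$mask
  expect_identical(m1@mask, m2@mask)

  # empty traps at default noise never produce a mask
  s0 <- small_spheroid_scene("array150", rows = 3, cols = 4,
                             diameters = rep(NA_real_, 12))
  img0 <- preprocessImage(s0$render$image)
  g0 <- detectTraps(img0, 150, 1)
  found <- vapply(seq_len(nTraps(g0)), function(i)
    segment_trap(img0, g0, i)$mask@found, logical(1))
  expect_true(all(!found))
})

test_that("mask pixels stay inside the trap region", {
  s <- small_spheroid_scene("array150", rows = 2, cols = 2,
                            diameters = rep(90, 4))
  img <- preprocessImage(s$render$image)
  g <- detectTraps(img, 150, 1)
  tr <- traps(g)
  for (i in seq_len(nrow(tr))) {
    half <- trapLattice(g)$pitch_row_px / 2
    roi <- spheroidArray:::.roiAround(tr$center_row[i], tr$center_col[i],
                                      half, dim(img))
    d2 <- outer((seq_along(roi$rows) - roi$center[1])^2,
                (seq_along(roi$cols) - roi$center[2])^2, "+")
    interior <- d2 <= spheroidArray:::.trapInteriorRadius(tr$radius_px[i])^2
    sm <- segmentSpheroid(img[roi$rows, roi$cols], interior)
    expect_true(all(!sm@mask | interior))
  }
})

test_that("the largest of several objects in a trap is retained", {
  # synthetic ROI: two dark disks on light background inside a trap disk
  roi <- matrix(0.85, 201, 201)
  big <- raster_disk(30); small <- raster_disk(10)
  roi[41:(40 + nrow(big)), 41:(40 + ncol(big))][big] <- 0.4
  roi[150:(149 + nrow(small)), 150:(149 + ncol(small))][small] <- 0.4
  trap <- outer(seq_len(201) - 101, seq_len(201) - 101,
                function(i, j) i^2 + j^2 <= 95^2)
  sm <- segmentSpheroid(roi, trap)
  expect_true(sm@found)
  expect_equal(sum(sm@mask), sum(big), tolerance = 0.05)
  expect_error(segmentSpheroid(roi, trap & FALSE), "empty trap mask")
})

test_that("day-0 cell counting is accurate for non-confluent droplets", {
  sp <- sceneSpec("array150", rows = 2, cols = 2, pitch_factor = 1.5, seed = 21)
  sc <- dropletScene(sp, rep(170, 4), c(12, 0, 25, 5))
  r <- renderScene(sc, 0)
  img <- preprocessImage(r$image)
  tt <- traps(sc)
  counts <- vapply(seq_len(4), function(i) {
    roi <- spheroidArray:::.roiAround(tt$center_row[i], tt$center_col[i],
                                      spheroidArray:::.pitchPx(sp) / 2, dim(img))
    mask <- r$labels[roi$rows, roi$cols] == tt$trap_id[i]
    if (!any(mask)) return(NA_integer_)
    as.integer(countCells(img[roi$rows, roi$cols], mask, 8))
  }, integer(1))
  expect_lte(abs(counts[1] - 12), 1)   # 12 rendered cells -> within +/- 1
  expect_lte(abs(counts[3] - 25), 2)
  expect_lte(abs(counts[4] - 5), 1)
  # an empty droplet has zero blobs
  sc0 <- dropletScene(sp, rep(170, 4), rep(0, 4))
  r0 <- renderScene(sc0, 0)
  img0 <- preprocessImage(r0$image)
  roi <- spheroidArray:::.roiAround(tt$center_row[1], tt$center_col[1],
                                    spheroidArray:::.pitchPx(sp) / 2, dim(img0))
  mask <- r0$labels[roi$rows, roi$cols] == tt$trap_id[1]
  expect_equal(as.integer(countCells(img0[roi$rows, roi$cols], mask, 8)), 0L)
  expect_error(countCells(img0, matrix(FALSE, 2, 2), 8), "empty")
})
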