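test_that("noise-free scenes are detected completely and accurately", {
  for (layout in c("array150", "array300")) {
    s <- small_spheroid_scene(layout, rows = 3, cols = 5,
                              diameters = rep(NA_real_, 15), day = 1,
                              noise = FALSE)
    g <- detectTraps(s$render$image, s$spec@trap_diameter_um,
                     s$spec@pixel_scale)
    expect_equal(nTraps(g), 15)                    # recall and precision 100%
    expect_equal(sum(traps(g)$provisional), 0)
    tt <- traps(s$scene)
    err <- vapply(seq_len(nrow(tt)), function(i)
      min(sqrt((traps(g)$center_row - tt$center_row[i])^2 +
               (traps(g)$center_col - tt$center_col[i])^2)), numeric(1))
    expect_lt(max(err), 2)                         # centers within 2 px
    # detected radius within 15% of nominal (also enforced by validity)
    expect_lt(abs(2 * traps(g)$radius_px[1] - s$spec@trap_diameter_um) /
                s$spec@trap_diameter_um, 0.15)
  }
})

test_that("detection tolerates default noise and occupied traps", {
  s <- small_spheroid_scene("array150", rows = 4, cols = 4,
                            diameters = rep(75, 16), noise = TRUE)
  g <- detectTraps(s$render$image, 150, 1)
  expect_equal(nTraps(g), 16)
  expect_gte(mean(!traps(g)$provisional), 0.99)    # recall >= 99%
})

test_that("structureless images raise the no-array error", {
  expect_error(detectTraps(matrix(0.5, 400, 400), 150, 1), "no array found")
  expect_error(detectTraps(matrix(runif(160000), 400, 400), 150, 1),
               "no array found")
  expect_error(detectTraps(array(0.5, c(10, 10, 3)), 150, 1), "single-channel")
  expect_error(detectTraps(matrix(0.5, 50, 50), 15, 1), "20 px")
})

test_that("trap masks are disjoint labeled disks of the right size", {
  s <- small_spheroid_scene("array150", rows = 3, cols = 4,
                            diameters = rep(NA_real_, 12), day = 1,
                            noise = FALSE)
  g <- detectTraps(s$render$image, 150, 1)
  lab <- buildTrapMasks(g)
  expect_identical(dim(lab), dim(s$render$image))
  expect_setequal(unique(lab[lab > 0]), traps(g)$trap_id)
  # rasterization oracle: disk pixel count within 1% of pi r^2
  r <- traps(g)$radius_px[1]
  a <- sum(lab == traps(g)$trap_id[1])
  expect_lt(abs(a - pi * r^2) / (pi * r^2), 0.01)

  # empty grid errors; overlapping disks are named
  g_empty <- g; g_empty@traps <- g_empty@traps[0, ]
  expect_error(buildTrapMasks(g_empty), "empty")
  g_bad <- g
  g_bad@traps$center_row[2] <- g_bad@traps$center_row[1] + 1
  g_bad@traps$center_col[2] <- g_bad@traps$center_col[1] + 1
  expect_error(buildTrapMasks(g_bad), "trap_ids 1/2")
})

test_that("day registration recovers rigid offsets and flags dropouts", {
  s <- small_spheroid_scene("array150", rows = 3, cols = 5,
                            diameters = rep(NA_real_, 15), day = 1,
                            noise = FALSE)
  g <- detectTraps(s$render$image, 150, 1)

  # self-registration is the identity with all traps matched to themselves
  reg <- registerDays(g, g)
  expect_equal(reg$rotation_deg, 0, tolerance = 1e-8)
  expect_equal(unname(reg$translation), c(0, 0), tolerance = 1e-8)
  expect_identical(reg$correspondence$trap_id_a, reg$correspondence$trap_id_b)

  # a known (5, -3) px shift is recovered within 0.5 px
  g2 <- g
  g2@traps$center_row <- g2@traps$center_row + 5
  g2@traps$center_col <- g2@traps$center_col - 3
  reg2 <- registerDays(g, g2)
  expect_lt(max(abs(reg2$translation - c(5, -3))), 0.5)

  # 5% dropout: the rest match, the missing are flagged NA
  drop <- c(3)
  g3 <- g; g3@traps <- g3@traps[-drop, ]
  reg3 <- registerDays(g, g3)
  expect_true(is.na(reg3$correspondence$trap_id_b[drop]))
  expect_equal(sum(!is.na(reg3$correspondence$trap_id_b)), nTraps(g) - 1)

  # different layouts are refused
  s300 <- small_spheroid_scene("array300", rows = 2, cols = 2,
                               diameters = rep(NA_real_, 4), day = 1,
                               noise = FALSE)
  g300 <- detectTraps(s300$render$image, 300, 1)
  expect_error(registerDays(g, g300), "layout")
})
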