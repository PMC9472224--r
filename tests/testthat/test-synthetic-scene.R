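test_that("Poisson encapsulation matches its closed-form occupancy", {
  # degenerate lambda: essentially no droplet is occupied
  counts0 <- simulateEncapsulation(loadingModel(1e-9), 1000, seed = 1)
  expect_true(all(counts0 == 0))

  # occupancy converges to 1 - exp(-lambda) within Monte-Carlo error
  for (lambda in c(0.5, 1, 2.3026)) {
    n <- 1e5
    counts <- simulateEncapsulation(loadingModel(lambda), n, seed = 42)
    p <- 1 - exp(-lambda)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(counts > 0) - p), 3 * se)
  }
})

test_that("encapsulation rejects invalid parameters", {
  expect_error(loadingModel(0), "positive")
  expect_error(loadingModel(-2), "positive")
  expect_error(simulateEncapsulation(loadingModel(1), 0), "positive")
})

test_that("a lambda tuned to the 300 um array spans 10-45 cells per droplet", {
  # the mid-range loading of the larger array: laden droplets mostly carry
  # 10-45 cells
  counts <- simulateEncapsulation(loadingModel(25), 2000, seed = 9)
  laden <- counts[counts > 0]
  expect_gte(mean(laden >= 10 & laden <= 45), 0.90)
})

test_that("growth is gated on the initial cell count", {
  gm <- growthModel(min_growth_count = 10, daily_rate_um_per_day = 6,
                    jitter_sigma_um = 0)
  tr <- simulateGrowth(c(5, 20, 0), gm, seed = 2)
  low <- tr$diameter_um[tr$cell_count == 5]
  high <- tr$diameter_um[tr$cell_count == 20]
  # below the gate: stagnant (identical expected diameter every day)
  expect_equal(diff(low), rep(0, 3))
  # above the gate: strictly increasing every day
  expect_true(all(diff(high) > 0))
  # no cells, no spheroid
  expect_true(all(is.na(tr$diameter_um[tr$cell_count == 0])))

  # zero rate, zero jitter: identity across days
  tr0 <- simulateGrowth(c(20), growthModel(daily_rate_um_per_day = 0,
                                           jitter_sigma_um = 0), seed = 1)
  expect_equal(length(unique(tr0$diameter_um)), 1L)

  expect_error(growthModel(days = numeric(0)), "non-empty")
})

test_that("rendering is deterministic and spheroids rasterize to their true area", {
  s <- small_spheroid_scene(diameters = c(100, rep(60, 11)), noise = TRUE)
  r1 <- renderScene(s$scene, 7)
  r2 <- renderScene(s$scene, 7)
  expect_identical(r1$image, r2$image)   # bit-identical under the same seed

  # mask-area oracle: each rendered disk within 1% of pi (d/2)^2
  for (id in traps(s$scene)$trap_id) {
    a <- sum(r1$labels == id)
    d <- groundTruth(s$scene)$diameter_um[id]
    expect_lt(abs(a - pi * (d / 2)^2) / (pi * (d / 2)^2), 0.01)
  }

  # every rendered label belongs to a real trap of the scene
  expect_true(all(unique(r1$labels[r1$labels > 0]) %in% traps(s$scene)$trap_id))
})

test_that("noise-free rendering leaves in-mask pixels at their set values", {
  s <- small_spheroid_scene(rows = 2, cols = 2, diameters = rep(80, 4),
                            noise = FALSE)
  r <- renderScene(s$scene, 7)
  sp <- s$spec
  rim_and_interior <- r$image[r$labels > 0]
  # every in-mask pixel is either the rim level or interior texture
  expect_true(all(rim_and_interior <= sp@background_level))
  expect_true(any(rim_and_interior == sp@rim_level))
  # background is exactly the background level
  bg <- r$image[r$labels == 0]
  expect_true(all(bg %in% c(sp@background_level, sp@trap_line_level)))
})

test_that("oversized spheroids are refused with the trap named", {
  sp <- sceneSpec("array150", rows = 2, cols = 2, noise_sigma = 0,
                  illumination_gradient = 0)
  sc <- sceneFromDiameters(sp, c(60, 200, 60, 60), day = 7)
  expect_error(renderScene(sc, 7), "trap 2")
})

test_that("fluorescence truth drives the rendered channels", {
  sp <- sceneSpec("array150", rows = 2, cols = 3, seed = 5, noise_sigma = 0,
                  illumination_gradient = 0)
  conds <- spheroidArray:::.defaultConditions()
  conds[["off"]] <- list(ki67 = 0, dead_fraction = 0, live_dead = FALSE)
  sc <- sceneFromDiameters(sp, rep(80, 6), day = 7, conditions = conds)

  # zero Ki-67: FITC indistinguishable from background
  f0 <- renderFluorescence(sc, "off", noise = FALSE)
  expect_equal(unique(as.vector(f0$channels$FITC)), 0.05)

  # drug-dose contrast: E2-only brighter than the 100 nM dose
  fe <- renderFluorescence(sc, "E2 only", noise = FALSE)
  fi <- renderFluorescence(sc, "100 nM ICI + E2", noise = FALSE)
  m <- fe$labels > 0
  expect_gt(mean(fe$channels$FITC[m]), mean(fi$channels$FITC[m]))

  # DAPI present wherever cells are
  expect_true(all(fe$channels$DAPI[m] > 0.05))

  # gain linearity: doubling the gain doubles signal above background
  f1 <- renderFluorescence(sc, "E2 only", noise = FALSE,
                           gains = list(FITC = 0.3, DAPI = 0.5, rhodamine = 0.5))
  f2 <- renderFluorescence(sc, "E2 only", noise = FALSE,
                           gains = list(FITC = 0.6, DAPI = 0.5, rhodamine = 0.5))
  expect_equal(f2$channels$FITC[m] - 0.05, 2 * (f1$channels$FITC[m] - 0.05),
               tolerance = 1e-12)

  expect_error(renderFluorescence(sc, "no such condition"), "unknown condition")
})
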