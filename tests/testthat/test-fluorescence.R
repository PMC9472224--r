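test_that("per-object intensity is the background-subtracted mask mean", {
  mask <- raster_disk(20, pad = 12)
  dims <- dim(mask)
  # uniform channel at background: exact cancellation
  expect_equal(perObjectIntensity(mask, matrix(0.2, dims[1], dims[2])), 0)

  # foreground at background + k recovers k exactly
  ch <- matrix(0.2, dims[1], dims[2]); ch[mask] <- 0.2 + 0.34
  expect_equal(perObjectIntensity(mask, ch), 0.34, tolerance = 1e-12)

  # with Gaussian noise: recovered within 2%
  set.seed(3)
  chn <- ch + rnorm(length(ch), 0, 0.05)
  expect_lt(abs(perObjectIntensity(mask, chn) - 0.34) / 0.34, 0.02)

  expect_error(perObjectIntensity(mask & FALSE, ch), "empty")
  expect_error(perObjectIntensity(mask, ch, background_annulus = mask),
               "overlaps")
})

test_that("Ki-67 normalization maps the reference group mean to one", {
  set.seed(5)
  rec <- data.frame(
    condition = rep(c("E2 only", "50 nM ICI + E2", "100 nM ICI + E2"), each = 8),
    FITC = c(rnorm(8, 0.54, 0.02), rnorm(8, 0.30, 0.02), rnorm(8, 0.05, 0.01)),
    DAPI = rnorm(24, 0.5, 0.02))
  out <- normalizeKi67(rec, "E2 only")
  means <- tapply(out$normalized_ki67, out$condition, mean)
  expect_equal(unname(means["E2 only"]), 1, tolerance = 1e-12)
  # dose-dependent ordering preserved after normalization
  expect_gt(means["E2 only"], means["50 nM ICI + E2"])
  expect_gt(means["50 nM ICI + E2"], means["100 nM ICI + E2"])

  # idempotence: renormalizing changes nothing
  out2 <- normalizeKi67(out, "E2 only")
  expect_equal(out2$normalized_ki67, out$normalized_ki67)

  # gain invariance: common gain on both channels cancels
  rec2 <- rec; rec2$FITC <- 3.7 * rec2$FITC; rec2$DAPI <- 3.7 * rec2$DAPI
  expect_equal(normalizeKi67(rec2, "E2 only")$normalized_ki67,
               out$normalized_ki67, tolerance = 1e-12)

  # all-zero FITC: everything normalizes to zero, without dividing by zero
  rec3 <- rec; rec3$FITC <- 0
  expect_true(all(normalizeKi67(rec3, "E2 only")$normalized_ki67 == 0))

  # zero DAPI records are flagged and excluded with a warning
  rec4 <- rec; rec4$DAPI[1] <- 0
  expect_warning(out4 <- normalizeKi67(rec4, "E2 only"), "flagged")
  expect_true(out4$flagged[1])
  expect_true(is.na(out4$normalized_ki67[1]))

  expect_error(normalizeKi67(rec[1:2, ], "E2 only"), ">= 3")
})

test_that("drug-condition ordering is recovered on rendered scenes", {
  hits <- 0
  for (s in 1:5) {
    sp <- sceneSpec("array150", rows = 2, cols = 3, seed = 100 + s)
    sc <- sceneFromDiameters(sp, rep(80, 6), day = 7)
    ids <- traps(sc)$trap_id
    rec <- do.call(rbind, lapply(
      c("E2 only", "50 nM ICI + E2", "100 nM ICI + E2", "no E2 control"),
      function(cond) {
        f <- renderFluorescence(sc, cond)
        data.frame(condition = cond,
                   FITC = vapply(ids, function(i)
                     perObjectIntensity(f$labels == i, f$channels$FITC),
                     numeric(1)),
                   DAPI = vapply(ids, function(i)
                     perObjectIntensity(f$labels == i, f$channels$DAPI),
                     numeric(1)))
      }))
    m <- tapply(normalizeKi67(rec, "E2 only")$normalized_ki67, rec$condition, mean)
    if (m["E2 only"] > m["50 nM ICI + E2"] &&
        m["50 nM ICI + E2"] > m["100 nM ICI + E2"] &&
        m["50 nM ICI + E2"] > m["no E2 control"]) hits <- hits + 1
  }
  expect_equal(hits, 5)
})

test_that("viability fractions follow the rendered live/dead split", {
  sp <- sceneSpec("array150", rows = 2, cols = 3, seed = 9)
  conds <- spheroidArray:::.defaultConditions()
  conds[["half-dead"]] <- list(ki67 = NA_real_, dead_fraction = 0.5,
                               live_dead = TRUE)
  sc <- sceneFromDiameters(sp, rep(90, 6), day = 7, conditions = conds)
  f <- renderFluorescence(sc, "half-dead")
  vf <- viabilityFractions(f$channels$FITC, f$channels$rhodamine, f$labels)
  expect_true(all(abs(vf$live_fraction - 0.5) <= 0.05))

  # flat dead channel: fully live; flat live channel: fully dead
  flat <- matrix(0.05, nrow(f$labels), ncol(f$labels))
  expect_true(all(viabilityFractions(f$channels$FITC, flat,
                                     f$labels)$live_fraction == 1))
  expect_true(all(viabilityFractions(flat, f$channels$rhodamine,
                                     f$labels)$live_fraction == 0))
  # no signal anywhere: flagged NA
  v0 <- viabilityFractions(flat, flat, f$labels)
  expect_true(all(v0$flagged))
  expect_true(all(is.na(v0$live_fraction)))
})
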