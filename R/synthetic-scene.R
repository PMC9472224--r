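#' Simulate Poisson droplet encapsulation
#'
#' Draws i.i.d. Poisson cell counts for `n_droplets` droplets under a
#' [loadingModel()]. The fraction of droplets with at least one cell
#' (occupancy) converges to `1 - exp(-lambda)`; a mean loading of
#' `lambda = 2.3026` therefore reproduces 90% occupancy.
#'
#' @param loading a [loadingModel()].
#' @param n_droplets number of droplets to simulate.
#' @param seed RNG seed.
#' @return integer vector of cell counts, length `n_droplets`.
#' @examples
#' counts <- simulateEncapsulation(loadingModel(2.3026), 1e4, seed = 1)
#' mean(counts > 0)   # ~0.90
#' @export
simulateEncapsulation <- function(loading, n_droplets, seed = 1L) {
  if (!inherits(loading, "LoadingModel"))
    stop("'loading' must be a loadingModel()", call. = FALSE)
  .assertPositiveScalar(n_droplets, "n_droplets")
  .withSeed(seed, rpois(as.integer(n_droplets), loading$lambda))
}

#' Simulate gated growth tracks
#'
#' Produces the true diameter day-series for each droplet's spheroid under
#' a [growthModel()]: tracks with `count >= min_growth_count` grow linearly,
#' occupied tracks below the gate stay at their initial diameter, and
#' droplets with zero cells form no spheroid (`NA` diameters). Gaussian
#' jitter is applied independently per day.
#'
#' @param cell_counts integer vector of initial cell counts (one track each).
#' @param model a [growthModel()].
#' @param seed RNG seed.
#' @return data.frame with columns `track`, `cell_count`, `day`,
#'   `diameter_um` (long format, one row per track per day).
#' @examples
#' simulateGrowth(c(5, 20), growthModel(jitter_sigma_um = 0), seed = 1)
#' @export
simulateGrowth <- function(cell_counts, model, seed = 1L) {
  if (!inherits(model, "GrowthModel"))
    stop("'model' must be a growthModel()", call. = FALSE)
  if (!length(model$days)) stop("'days' must be non-empty", call. = FALSE)
  if (any(cell_counts < 0)) stop("cell counts must be >= 0", call. = FALSE)
  n <- length(cell_counts)
  days <- model$days
  d0 <- model$initial_diameter_coef_um * cell_counts^(1 / 3)
  grow <- cell_counts >= model$min_growth_count
  .withSeed(seed, {
    out <- do.call(rbind, lapply(seq_along(days), function(k) {
      drift <- ifelse(grow, model$daily_rate_um_per_day * (days[k] - days[1]), 0)
      d <- d0 + drift + rnorm(n, 0, model$jitter_sigma_um)
      d[cell_counts == 0] <- NA_real_
      data.frame(track = seq_len(n), cell_count = cell_counts,
                 day = days[k], diameter_um = pmax(d, 0))
    }))
    out[order(out$track, out$day), , drop = FALSE]
  })
}

#' Scene constructors
#'
#' Three ways to build a [SyntheticScene]:
#' `simulateScene()` draws cell counts from a loading model and diameters
#' from a growth model (the full longitudinal experiment);
#' `sceneFromDiameters()` fixes the true spheroid diameter of every trap on
#' a single day (used to key a scene to a published size distribution);
#' `dropletScene()` builds a day-0 scene of freshly trapped droplets with
#' rendered individual cells.
#'
#' @param spec a [sceneSpec()].
#' @param loading a [loadingModel()].
#' @param growth a [growthModel()].
#' @param conditions named list of per-condition fluorescence truth; the
#'   default covers the estrogen/fulvestrant drug panel and a live/dead
#'   staining condition.
#' @param seed scene seed; defaults to the spec's seed.
#' @return a [SyntheticScene].
#' @examples
#' sp <- sceneSpec("array300", rows = 4, cols = 4)
#' sc <- simulateScene(sp, loadingModel(25), growthModel(), seed = 1)
#' nTraps(sc)
#' @export
simulateScene <- function(spec, loading, growth = growthModel(),
                          conditions = .defaultConditions(),
                          seed = spec@seed) {
  tab <- .trapCenterTable(spec)
  n <- nrow(tab)
  counts <- simulateEncapsulation(loading, n, seed = .subSeed(seed, 1))
  dl <- simulateGrowth(counts, growth, seed = .subSeed(seed, 2))
  dmax <- spec@trap_diameter_um * 0.95
  dl$diameter_um <- pmin(dl$diameter_um, dmax)
  tab$cell_count <- counts
  tab$droplet_diameter_um <- NA_real_
  new("SyntheticScene", spec = spec, traps = tab,
      diameters = data.frame(trap_id = dl$track, day = dl$day,
                             diameter_um = dl$diameter_um),
      days = growth$days, conditions = conditions, seed = as.integer(seed))
}

#' @rdname simulateScene
#' @param diameters_um per-trap true spheroid diameters (um); `NA` = empty
#'   trap. Recycled length must equal the trap count.
#' @param day the single imaging day the diameters refer to.
#' @export
sceneFromDiameters <- function(spec, diameters_um, day = 7,
                               conditions = .defaultConditions(),
                               seed = spec@seed) {
  tab <- .trapCenterTable(spec)
  if (length(diameters_um) != nrow(tab))
    stop(sprintf("need %d diameters, got %d", nrow(tab), length(diameters_um)),
         call. = FALSE)
  tab$cell_count <- NA_integer_
  tab$droplet_diameter_um <- NA_real_
  new("SyntheticScene", spec = spec, traps = tab,
      diameters = data.frame(trap_id = tab$trap_id, day = day,
                             diameter_um = diameters_um),
      days = day, conditions = conditions, seed = as.integer(seed))
}

#' @rdname simulateScene
#' @param droplet_diameters_um per-trap true droplet diameters (um).
#' @param cell_counts per-trap encapsulated cell counts.
#' @export
dropletScene <- function(spec, droplet_diameters_um, cell_counts,
                         seed = spec@seed) {
  tab <- .trapCenterTable(spec)
  n <- nrow(tab)
  if (length(droplet_diameters_um) != n || length(cell_counts) != n)
    stop(sprintf("need %d droplet diameters and cell counts", n), call. = FALSE)
  pmax_um <- (.pitchPx(spec) - 2) * spec@pixel_scale
  if (any(droplet_diameters_um > pmax_um, na.rm = TRUE))
    stop("droplet diameter exceeds the trap pitch; droplets would merge",
         call. = FALSE)
  tab$cell_count <- as.integer(cell_counts)
  tab$droplet_diameter_um <- droplet_diameters_um
  new("SyntheticScene", spec = spec, traps = tab,
      diameters = data.frame(trap_id = integer(0), day = numeric(0),
                             diameter_um = numeric(0)),
      days = 0, conditions = .defaultConditions(), seed = as.integer(seed))
}

# Paint `level` over `mask` pixels of the tile of `img` at roi.
.paintTile <- function(img, roi, mask, level) {
  tile <- img[roi$rows, roi$cols]
  tile[mask] <- level
  img[roi$rows, roi$cols] <- tile
  img
}

#' Render a brightfield scene image
#'
#' Draws one imaging day of a [SyntheticScene] as a grayscale intensity
#' matrix in `[0,1]`: trap walls as dark annuli, spheroids as dark-rimmed
#' granular disks centered in their traps (or, on day 0, droplets as
#' contrast disks containing individual dark cell blobs), then the linear
#' illumination gradient, additive Gaussian noise and optional
#' salt-and-pepper impulses, in that order. Rendering is deterministic in
#' the scene seed and day: identical calls give bit-identical images.
#'
#' @param scene a [SyntheticScene].
#' @param day which imaging day to render (must be in `scene@days`).
#' @param noise apply the spec's noise/gradient model (set `FALSE` for a
#'   clean render regardless of the spec).
#' @return list with `image` (numeric matrix, rows x cols), `labels`
#'   (integer matrix; ground-truth object mask labeled by trap_id) and
#'   `day`.
#' @examples
#' sp <- sceneSpec("array300", rows = 2, cols = 2, noise_sigma = 0,
#'                 illumination_gradient = 0)
#' sc <- sceneFromDiameters(sp, rep(100, 4), day = 7)
#' r <- renderScene(sc, 7)
#' range(r$image)
#' @export
renderScene <- function(scene, day = scene@days[1], noise = TRUE) {
  spec <- scene@spec
  if (!day %in% scene@days)
    stop(sprintf("day %g not in scene days (%s)", day,
                 paste(scene@days, collapse = ", ")), call. = FALSE)
  dim <- .imageDim(spec)
  rtrap <- .trapRadiusPx(spec)
  pitch <- .pitchPx(spec)
  droplet_day <- day == 0 && any(!is.na(scene@traps$droplet_diameter_um))
  dd <- if (droplet_day) NULL else
    scene@diameters[scene@diameters$day == day, , drop = FALSE]

  .withSeed(.subSeed(scene@seed, 1000 + round(100 * day)), {
    img <- matrix(spec@background_level, dim[1], dim[2])
    labels <- matrix(0L, dim[1], dim[2])
    h <- pitch / 2
    for (i in seq_len(nrow(scene@traps))) {
      tr <- scene@traps[i, ]
      roi <- .roiAround(tr$center_row, tr$center_col, h, dim)
      size_r <- length(roi$rows); size_c <- length(roi$cols)
      d2 <- outer((seq_len(size_r) - roi$center[1])^2,
                  (seq_len(size_c) - roi$center[2])^2, "+")
      wall <- .trapWall(rtrap)
      ring <- d2 <= (rtrap + wall / 2)^2 & d2 >= (rtrap - wall / 2)^2
      tile <- img[roi$rows, roi$cols]
      tile[ring] <- spec@trap_line_level

      if (droplet_day) {
        ddrop <- tr$droplet_diameter_um
        if (!is.na(ddrop) && ddrop > 0) {
          rd <- ddrop / spec@pixel_scale / 2
          disk <- d2 <= rd^2
          rim <- disk & d2 >= (rd - 3)^2
          tile[disk] <- spec@droplet_level
          tile[rim] <- spec@rim_level
          rcell <- spec@cell_radius_um / spec@pixel_scale
          if (tr$cell_count > 0) {
            pts <- .packPoints(tr$cell_count, max(rd - rcell - 4, 1), 2 * rcell + 1)
            if (nrow(pts) < tr$cell_count)
              warning(sprintf(
                "trap %d: droplet too small for %d cells; only %d rendered",
                tr$trap_id, tr$cell_count, nrow(pts)))
            for (k in seq_len(nrow(pts))) {
              cd2 <- outer((seq_len(size_r) - roi$center[1] - pts[k, 1])^2,
                           (seq_len(size_c) - roi$center[2] - pts[k, 2])^2, "+")
              tile[cd2 <= rcell^2] <- spec@cell_level
            }
          }
          lt <- labels[roi$rows, roi$cols]
          lt[disk] <- tr$trap_id
          labels[roi$rows, roi$cols] <- lt
        }
      } else {
        dsph <- dd$diameter_um[match(tr$trap_id, dd$trap_id)]
        if (length(dsph) == 1 && !is.na(dsph) && dsph > 0) {
          if (dsph > spec@trap_diameter_um)
            stop(sprintf("spheroid in trap %d (%.1f um) exceeds the trap diameter (%g um)",
                         tr$trap_id, dsph, spec@trap_diameter_um), call. = FALSE)
          rs <- dsph / spec@pixel_scale / 2
          disk <- d2 <= rs^2
          rimw <- max(2, 0.08 * rs)
          rim <- disk & d2 >= (rs - rimw)^2
          inner <- disk & !rim
          tex <- rnorm(sum(inner), spec@foreground_level, spec@texture_sigma)
          tile[inner] <- .clip01(tex)
          tile[rim] <- spec@rim_level
          lt <- labels[roi$rows, roi$cols]
          lt[disk] <- tr$trap_id
          labels[roi$rows, roi$cols] <- lt
        }
      }
      img[roi$rows, roi$cols] <- tile
    }

    if (noise) {
      if (spec@illumination_gradient != 0) {
        f <- 1 + spec@illumination_gradient * (seq_len(dim[2]) / dim[2] - 0.5)
        img <- img * rep(f, each = dim[1])
      }
      if (spec@noise_sigma > 0)
        img <- img + rnorm(length(img), 0, spec@noise_sigma)
      if (spec@salt_pepper_frac > 0) {
        nsp <- round(spec@salt_pepper_frac * length(img))
        if (nsp > 0) {
          at <- sample.int(length(img), nsp)
          img[at] <- rep(c(0, 1), length.out = nsp)
        }
      }
      img <- .clip01(img)
    }
    list(image = img, labels = labels, day = day)
  })
}

#' Render fluorescence channels for a condition
#'
#' Produces the FITC, DAPI and rhodamine channel images of a scene day
#' under one experimental condition. DAPI (nuclei) covers every spheroid;
#' for drug-panel conditions FITC carries a uniform Ki-67 signal whose
#' level above background is `gains$FITC * ki67_fraction`; for live/dead
#' conditions FITC marks live cells (calcein) and rhodamine marks the
#' cells flagged dead in the ground truth. Fluorescence is rendered with
#' flat illumination (epifluorescence flat-field) plus the spec's additive
#' noise.
#'
#' @param scene a [SyntheticScene].
#' @param condition a condition label present in `scene@conditions`.
#' @param day imaging day (defaults to the last).
#' @param gains named list of channel gains (signal above background at
#'   fraction 1).
#' @param background fluorescence background level.
#' @param noise apply the spec's additive noise.
#' @return list with `channels` (named list of FITC/DAPI/rhodamine
#'   matrices), `labels` (spheroid ground-truth label matrix), `truth`
#'   (per-trap data.frame of true levels: `ki67`, `dead_fraction`,
#'   `live_px`, `dead_px`), and `condition`.
#' @export
renderFluorescence <- function(scene, condition, day = max(scene@days),
                               gains = list(FITC = 0.6, DAPI = 0.5, rhodamine = 0.5),
                               background = 0.05, noise = TRUE) {
  spec <- scene@spec
  if (!condition %in% names(scene@conditions))
    stop(sprintf("unknown condition '%s'; scene defines: %s", condition,
                 paste(names(scene@conditions), collapse = ", ")), call. = FALSE)
  cond <- scene@conditions[[condition]]
  dim <- .imageDim(spec)
  pitch <- .pitchPx(spec)
  dd <- scene@diameters[scene@diameters$day == day, , drop = FALSE]
  live_dead <- isTRUE(cond$live_dead)

  .withSeed(.subSeed(scene@seed, 5000 + round(100 * day)), {
    fitc <- matrix(background, dim[1], dim[2])
    dapi <- matrix(background, dim[1], dim[2])
    rho  <- matrix(background, dim[1], dim[2])
    labels <- matrix(0L, dim[1], dim[2])
    truth <- scene@traps[, c("trap_id", "center_row", "center_col")]
    truth$ki67 <- if (live_dead) NA_real_ else cond$ki67
    truth$dead_fraction <- cond$dead_fraction
    truth$live_px <- 0L; truth$dead_px <- 0L
    h <- pitch / 2
    rcell <- spec@cell_radius_um / spec@pixel_scale

    for (i in seq_len(nrow(scene@traps))) {
      tr <- scene@traps[i, ]
      dsph <- dd$diameter_um[match(tr$trap_id, dd$trap_id)]
      if (!length(dsph) || is.na(dsph) || dsph <= 0) next
      rs <- dsph / spec@pixel_scale / 2
      roi <- .roiAround(tr$center_row, tr$center_col, h, dim)
      d2 <- outer((seq_len(length(roi$rows)) - roi$center[1])^2,
                  (seq_len(length(roi$cols)) - roi$center[2])^2, "+")
      disk <- d2 <= rs^2
      dt <- dapi[roi$rows, roi$cols]; dt[disk] <- background + gains$DAPI
      dapi[roi$rows, roi$cols] <- dt
      lt <- labels[roi$rows, roi$cols]; lt[disk] <- tr$trap_id
      labels[roi$rows, roi$cols] <- lt

      if (live_dead || cond$dead_fraction > 0) {
        n_cells <- max(1L, round(0.55 * (rs / rcell)^2))
        pts <- .packPoints(n_cells, max(rs - rcell, 1), 1.8 * rcell)
        n_dead <- round(cond$dead_fraction * nrow(pts))
        is_dead <- seq_len(nrow(pts)) %in%
          (if (n_dead > 0) sample.int(nrow(pts), n_dead) else integer(0))
        ft <- fitc[roi$rows, roi$cols]; rt <- rho[roi$rows, roi$cols]
        for (k in seq_len(nrow(pts))) {
          cd2 <- outer((seq_len(length(roi$rows)) - roi$center[1] - pts[k, 1])^2,
                       (seq_len(length(roi$cols)) - roi$center[2] - pts[k, 2])^2, "+")
          cdisk <- cd2 <= rcell^2
          if (is_dead[k]) {
            rt[cdisk] <- background + gains$rhodamine
            truth$dead_px[i] <- truth$dead_px[i] + sum(cdisk)
          } else if (live_dead) {
            ft[cdisk] <- background + gains$FITC
            truth$live_px[i] <- truth$live_px[i] + sum(cdisk)
          }
        }
        fitc[roi$rows, roi$cols] <- ft; rho[roi$rows, roi$cols] <- rt
      }
      if (!live_dead) {
        ft <- fitc[roi$rows, roi$cols]
        ft[disk] <- background + gains$FITC * cond$ki67
        fitc[roi$rows, roi$cols] <- ft
      }
    }

    chans <- list(FITC = fitc, DAPI = dapi, rhodamine = rho)
    if (noise && spec@noise_sigma > 0)
      chans <- lapply(chans, function(m)
        .clip01(m + rnorm(length(m), 0, spec@noise_sigma)))
    list(channels = chans, labels = labels, truth = truth, condition = condition)
  })
}
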