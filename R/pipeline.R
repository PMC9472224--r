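# Orchestration and file I/O: dataset writing for synthetic scenes, run
# configuration, and the end-to-end pipeline
# (detect -> segment -> measure -> link -> classify -> summarize
#  -> fluorescence -> stats).

.readImageMatrix <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img
}

.writeImage16 <- function(img, path) {
  EBImage::writeImage(EBImage::Image(.clip01(img)), path,
                      type = "tiff", bits.per.sample = 16L)
}

#' Write a synthetic scene to disk as a pipeline-ready dataset
#'
#' Renders and writes every imaging day as a 16-bit grayscale TIFF named
#' `{layout}_{day}_{channel}.tif` under `dir/images/`, optional
#' fluorescence channel sets for the given conditions, the ground truth as
#' CSV under `dir/truth/` (kept separate from pipeline inputs), the scene
#' parameters as YAML, and a ready-to-run pipeline `config.yaml`.
#'
#' @param scene a [SyntheticScene].
#' @param dir output directory (created if needed).
#' @param conditions character vector of condition labels to render as
#'   fluorescence channel sets (on the last day); `NULL` for none.
#' @return invisibly, the path to the written `config.yaml`.
#' @export
writeSceneDataset <- function(scene, dir, conditions = NULL) {
  spec <- scene@spec
  img_dir <- file.path(dir, "images")
  truth_dir <- file.path(dir, "truth")
  for (d in c(dir, img_dir, truth_dir))
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0)
    stop(sprintf("output directory '%s' is not writable", dir), call. = FALSE)

  images <- list()
  for (day in scene@days) {
    r <- renderScene(scene, day)
    fn <- sprintf("%s_%g_brightfield.tif", spec@layout_id, day)
    .writeImage16(r$image, file.path(img_dir, fn))
    images[[as.character(day)]] <- file.path("images", fn)
  }

  fluo_cfg <- NULL
  if (length(conditions)) {
    day <- max(scene@days)
    entries <- lapply(conditions, function(cond) {
      r <- renderFluorescence(scene, cond, day = day)
      slug <- gsub("[^A-Za-z0-9]+", "-", cond)
      files <- list()
      for (ch in names(r$channels)) {
        fn <- sprintf("%s_%g_%s_%s.tif", spec@layout_id, day, ch, slug)
        .writeImage16(r$channels[[ch]], file.path(img_dir, fn))
        files[[ch]] <- file.path("images", fn)
      }
      c(list(condition = cond,
             live_dead = isTRUE(scene@conditions[[cond]]$live_dead)), files)
    })
    fluo_cfg <- list(day = max(scene@days), conditions = entries)
  }

  truth <- merge(scene@traps, scene@diameters, by = "trap_id", all.x = TRUE)
  truth <- truth[order(truth$trap_id, truth$day), ]
  write.csv(truth, file.path(truth_dir, "ground_truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    layout_id = spec@layout_id, rows = spec@rows, cols = spec@cols,
    trap_diameter_um = spec@trap_diameter_um, pixel_scale = spec@pixel_scale,
    pitch_factor = spec@pitch_factor, noise_sigma = spec@noise_sigma,
    illumination_gradient = spec@illumination_gradient,
    cell_radius_um = spec@cell_radius_um,
    seed = scene@seed, days = as.list(scene@days)
  ), file.path(truth_dir, "scene.yaml"))

  cfg <- list(layout = spec@layout_id, pixel_scale = spec@pixel_scale,
              seed = scene@seed, alpha = 0.05, out_dir = "results",
              days = as.list(scene@days), images = images)
  if (!is.null(fluo_cfg)) cfg$fluorescence <- fluo_cfg
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}

#' Read the ground truth table of a written scene dataset
#'
#' @param dir dataset directory written by [writeSceneDataset()].
#' @return the ground-truth data.frame.
#' @export
readGroundTruth <- function(dir)
  read.csv(file.path(dir, "truth", "ground_truth.csv"))

#' Read and validate a pipeline run configuration
#'
#' Loads a YAML run configuration, resolves file paths relative to the
#' config's directory, and fails fast if any referenced image is missing.
#'
#' @param path path to `config.yaml`, or an equivalent named list.
#' @param base_dir directory against which relative paths resolve
#'   (defaults to the config file's directory).
#' @return validated config list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path, base_dir = NULL) {
  cfg <- if (is.character(path)) {
    if (is.null(base_dir)) base_dir <- dirname(path)
    yaml::read_yaml(path)
  } else path
  if (is.null(base_dir)) base_dir <- "."
  need <- c("layout", "pixel_scale", "days", "images")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(paste("config is missing fields:", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!cfg$layout %in% names(.LAYOUTS))
    stop(sprintf("unknown layout '%s'", cfg$layout), call. = FALSE)
  resolve <- function(f) if (grepl("^/", f)) f else file.path(base_dir, f)
  cfg$images <- lapply(cfg$images, resolve)
  for (d in cfg$days)
    if (is.null(cfg$images[[as.character(d)]]))
      stop(sprintf("no image configured for day %s", d), call. = FALSE)
  for (f in unlist(cfg$images))
    if (!file.exists(f)) stop(sprintf("image file missing: %s", f), call. = FALSE)
  if (!is.null(cfg$fluorescence)) {
    cfg$fluorescence$conditions <- lapply(cfg$fluorescence$conditions, function(e) {
      for (ch in intersect(c("FITC", "DAPI", "rhodamine"), names(e))) {
        e[[ch]] <- resolve(e[[ch]])
        if (!file.exists(e[[ch]]))
          stop(sprintf("fluorescence image missing: %s", e[[ch]]), call. = FALSE)
      }
      e
    })
  }
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$params)) cfg$params <- list()
  structure(cfg, class = c("RunConfig", "list"))
}

# Segment + measure every trap of one day's image against a reference
# grid. Spheroid mode thresholds within the trap interior (clear of the
# wall ring); droplet mode (day 0) searches the whole pitch cell, because
# droplets can slightly exceed the trap diameter, and suppresses the wall
# ring by morphological opening. Optionally counts day-0 cells per droplet.
.measureDay <- function(img, grid, day, pixel_scale, seg_params,
                        id_map = NULL, droplet_mode = FALSE,
                        count_cells = FALSE, cell_radius_px = 8) {
  tr <- traps(grid)
  half <- max(mean(c(grid@lattice$pitch_row_px, grid@lattice$pitch_col_px)) / 2,
              tr$radius_px[1] + 4)
  rows <- vector("list", nrow(tr))
  label_map <- if (isTRUE(attr(seg_params, "label_map")))
    matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(tr))) {
    roi <- .roiAround(tr$center_row[i], tr$center_col[i], half, dim(img))
    sub <- img[roi$rows, roi$cols]
    d2 <- outer((seq_along(roi$rows) - roi$center[1])^2,
                (seq_along(roi$cols) - roi$center[2])^2, "+")
    if (droplet_mode) {
      tmask <- d2 <= (half - 1)^2
      sp <- modifyList(list(open_radius = .trapWall(tr$radius_px[i])), seg_params)
    } else {
      tmask <- d2 <= .trapInteriorRadius(tr$radius_px[i])^2
      sp <- seg_params
    }
    id <- if (is.null(id_map)) tr$trap_id[i] else id_map[i]
    if (is.na(id)) next
    sm <- segmentSpheroid(sub, tmask, trap_id = id, day = day,
                          offset = c(roi$rows[1], roi$cols[1]),
                          params = sp)
    row <- measureMask(sm, pixel_scale = pixel_scale)
    row$provisional <- tr$provisional[i]
    if (count_cells)
      row$cell_count <- if (droplet_mode && sm@found)
        as.integer(countCells(sub, sm@mask, cell_radius_px)) else NA_integer_
    if (!is.null(label_map) && sm@found) {
      tile <- label_map[roi$rows, roi$cols]
      tile[sm@mask] <- as.integer(id)
      label_map[roi$rows, roi$cols] <- tile
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(label_map)) attr(out, "label_map") <- label_map
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stage order detect -> segment -> measure -> link ->
#' classify -> summarize, then fluorescence quantification and the ANOVA /
#' Fisher LSD reports when the config provides them. Later days are
#' registered onto the first day's trap grid so measurements share
#' reference trap ids. Writes tidy CSVs, a QC overlay, and a manifest to
#' `out_dir`; on a stage failure the partial outputs are preserved and the
#' manifest records the failing stage.
#'
#' @param config a config list or path (see [readRunConfig()]).
#' @param out_dir output directory; defaults to the config's `out_dir`.
#' @return invisibly, a list with the in-memory results (`grid`,
#'   `measurements`, `tracks`, `track_summary`, `distributions`,
#'   `day_anova`, `fluorescence`, `fluorescence_anova`, `manifest`).
#' @export
runPipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- "results"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_hash <- .paramHash(unclass(cfg))
  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("spheroidArray")),
                   stages = list())
  res <- list()
  nominal <- .LAYOUTS[[cfg$layout]]$trap_diameter_um
  seg_params <- if (!is.null(cfg$params$segment)) cfg$params$segment else list()
  alpha <- cfg$alpha

  finish <- function(status, stage = NULL, error = NULL) {
    manifest$completed <<- status
    if (!is.null(stage)) manifest$failed_stage <<- stage
    if (!is.null(error)) manifest$error <<- conditionMessage(error)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  stage <- "detect"
  out <- tryCatch({
    days <- as.numeric(unlist(cfg$days))
    imgs <- lapply(days, function(d)
      preprocessImage(.readImageMatrix(cfg$images[[as.character(d)]]),
                      median_radius = if (!is.null(cfg$params$median_radius))
                        cfg$params$median_radius else 2))
    names(imgs) <- as.character(days)
    grid <- detectTraps(imgs[[1]], nominal, cfg$pixel_scale)
    res$grid <- grid
    writeTrapGrid(grid, file.path(out_dir, "trap_grid.csv"))
    manifest$stages$detect <- sprintf("%d traps (%d provisional)",
                                      nTraps(grid), sum(traps(grid)$provisional))

    stage <- "segment/measure"
    meas <- list()
    for (k in seq_along(days)) {
      id_map <- NULL
      g_day <- grid
      if (k > 1) {
        g_day <- detectTraps(imgs[[k]], nominal, cfg$pixel_scale)
        reg <- registerDays(g_day, grid)
        id_map <- reg$correspondence$trap_id_b
      }
      sp_day <- seg_params
      if (isTRUE(cfg$params$write_masks)) attr(sp_day, "label_map") <- TRUE
      meas[[k]] <- .measureDay(
        imgs[[k]], g_day, days[k], cfg$pixel_scale, sp_day,
        id_map = id_map, droplet_mode = days[k] == 0,
        count_cells = isTRUE(cfg$params$count_cells),
        cell_radius_px = if (!is.null(cfg$params$cell_radius_um))
          cfg$params$cell_radius_um / cfg$pixel_scale else 8)
      lm_day <- attr(meas[[k]], "label_map")
      if (!is.null(lm_day)) {
        .writeImage16(lm_day / 65535,
                      file.path(out_dir, sprintf("masks_day%g.tif", days[k])))
        attr(meas[[k]], "label_map") <- NULL
      }
    }
    measurements <- do.call(rbind, meas)
    measurements$params_hash <- .paramHash(seg_params)
    res$measurements <- measurements
    write.csv(measurements, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    manifest$stages$measure <- sprintf("%d rows, %d found",
                                       nrow(measurements),
                                       sum(measurements$found))

    stage <- "link/classify"
    tracks <- linkTracks(measurements)
    summary_df <- classifyGrowth(tracks, alpha = alpha)
    res$tracks <- tracks; res$track_summary <- summary_df
    write.csv(tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
    write.csv(summary_df, file.path(out_dir, "track_summary.csv"),
              row.names = FALSE)
    manifest$stages$classify <- table(summary_df$label)

    stage <- "summarize"
    dists <- lapply(days, function(d)
      tryCatch(summarizeDistribution(tracks, d), error = function(e) NULL))
    dists <- Filter(Negate(is.null), dists)
    res$distributions <- dists
    if (length(dists))
      write.csv(do.call(rbind, lapply(dists, function(s)
        data.frame(day = s$day, mean_um = s$mean, sd_um = s$sd, n = s$n))),
        file.path(out_dir, "distributions.csv"), row.names = FALSE)
    if (length(days) >= 2) {
      g1 <- tracks$diameter_um[tracks$day == days[1]]
      g2 <- tracks$diameter_um[tracks$day == days[length(days)]]
      g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
      if (length(g1) > 1 && length(g2) > 1) {
        an <- fisherLSD(oneWayAnova(stats::setNames(list(g1, g2),
          paste0("day", days[c(1, length(days))]))))
        res$day_anova <- an
        write.csv(data.frame(F = an@F_statistic, df_between = an@df_between,
                             df_within = an@df_within, p = an@p_value,
                             label = labelSignificance(min(an@p_value, 1))),
                  file.path(out_dir, "day_anova.csv"), row.names = FALSE)
      }
    }

    if (!is.null(cfg$fluorescence)) {
      stage <- "fluorescence"
      fl <- .runFluorescence(cfg, imgs, grid, days, seg_params, out_dir)
      res$fluorescence <- fl$records
      res$fluorescence_anova <- fl$anova
      manifest$stages$fluorescence <- sprintf("%d records", nrow(fl$records))
    }

    stage <- "overlay"
    .writeOverlay(imgs[[1]], grid, file.path(out_dir, "qc_overlay.png"))
    finish(TRUE)
    res$manifest <- manifest
    res
  }, error = function(e) {
    finish(FALSE, stage = stage, error = e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}

# Fluorescence sub-pipeline: per-condition per-object intensities from the
# fluorescence day's brightfield masks, Ki-67 normalization, viability,
# and the condition ANOVA.
.runFluorescence <- function(cfg, imgs, grid, days, seg_params, out_dir) {
  fday <- if (!is.null(cfg$fluorescence$day)) cfg$fluorescence$day else max(days)
  bf <- imgs[[as.character(fday)]]
  tr <- traps(grid)
  half <- max(mean(c(grid@lattice$pitch_row_px, grid@lattice$pitch_col_px)) / 2,
              tr$radius_px[1] + 4)
  masks <- list()
  for (i in seq_len(nrow(tr))) {
    roi <- .roiAround(tr$center_row[i], tr$center_col[i], half, dim(bf))
    d2 <- outer((seq_along(roi$rows) - roi$center[1])^2,
                (seq_along(roi$cols) - roi$center[2])^2, "+")
    sm <- segmentSpheroid(bf[roi$rows, roi$cols],
                          d2 <= .trapInteriorRadius(tr$radius_px[i])^2,
                          trap_id = tr$trap_id[i], day = fday,
                          offset = c(roi$rows[1], roi$cols[1]),
                          params = seg_params)
    if (sm@found) masks[[as.character(tr$trap_id[i])]] <-
      list(mask = sm@mask, roi = roi)
  }
  rows <- list(); via_rows <- list()
  for (e in cfg$fluorescence$conditions) {
    chans <- lapply(intersect(c("FITC", "DAPI", "rhodamine"), names(e)),
                    function(ch) .readImageMatrix(e[[ch]]))
    names(chans) <- intersect(c("FITC", "DAPI", "rhodamine"), names(e))
    for (nm in names(masks)) {
      mk <- masks[[nm]]
      vals <- lapply(chans, function(ch)
        perObjectIntensity(mk$mask, ch[mk$roi$rows, mk$roi$cols]))
      rows[[length(rows) + 1L]] <- data.frame(
        trap_id = as.integer(nm), condition = e$condition,
        FITC = if (!is.null(vals$FITC)) vals$FITC else NA_real_,
        DAPI = if (!is.null(vals$DAPI)) vals$DAPI else NA_real_,
        rhodamine = if (!is.null(vals$rhodamine)) vals$rhodamine else NA_real_)
    }
    if (isTRUE(e$live_dead) && all(c("FITC", "rhodamine") %in% names(chans))) {
      lab <- matrix(0L, nrow(bf), ncol(bf))
      for (nm in names(masks)) {
        mk <- masks[[nm]]
        tile <- lab[mk$roi$rows, mk$roi$cols]
        tile[mk$mask] <- as.integer(nm)
        lab[mk$roi$rows, mk$roi$cols] <- tile
      }
      vf <- viabilityFractions(chans$FITC, chans$rhodamine, lab)
      vf$condition <- e$condition
      via_rows[[length(via_rows) + 1L]] <- vf
    }
  }
  records <- do.call(rbind, rows)
  anova_res <- NULL
  ref <- cfg$fluorescence$reference_condition
  ki <- records[!vapply(cfg$fluorescence$conditions, function(e)
    isTRUE(e$live_dead), logical(1))[match(records$condition,
      vapply(cfg$fluorescence$conditions, `[[`, character(1), "condition"))], ,
    drop = FALSE]
  if (!is.null(ref) && nrow(ki)) {
    records <- normalizeKi67(records, ref)
    ki <- records[records$condition %in% ki$condition & !records$flagged, ]
    if (length(unique(ki$condition)) >= 2) {
      groups <- split(ki$normalized_ki67, ki$condition)
      anova_res <- fisherLSD(oneWayAnova(groups))
      write.csv(anova_res@pairwise,
                file.path(out_dir, "fluorescence_pairwise.csv"),
                row.names = FALSE)
      write.csv(data.frame(F = anova_res@F_statistic,
                           df_between = anova_res@df_between,
                           df_within = anova_res@df_within,
                           p = anova_res@p_value),
                file.path(out_dir, "fluorescence_anova.csv"), row.names = FALSE)
    }
  }
  if (length(via_rows))
    write.csv(do.call(rbind, via_rows), file.path(out_dir, "viability.csv"),
              row.names = FALSE)
  write.csv(records, file.path(out_dir, "fluorescence.csv"), row.names = FALSE)
  list(records = records, anova = anova_res)
}

# Downsampled QC overlay: brightfield with detected trap circles.
.writeOverlay <- function(img, grid, path, max_px = 1500) {
  f <- max(1, ceiling(max(dim(img)) / max_px))
  small <- if (f > 1)
    EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                       w = floor(nrow(img) / f),
                                       h = floor(ncol(img) / f)))
  else img
  grDevices::png(path, width = ncol(small), height = nrow(small))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(c(1, ncol(small)), c(1, nrow(small)), type = "n",
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::rasterImage(grDevices::as.raster(.clip01(small)),
                        1, 1, ncol(small), nrow(small))
  tr <- traps(grid)
  th <- seq(0, 2 * pi, length.out = 33)
  for (i in seq_len(nrow(tr))) {
    graphics::lines(tr$center_col[i] / f + tr$radius_px[i] / f * cos(th),
                    nrow(small) - tr$center_row[i] / f +
                      tr$radius_px[i] / f * sin(th),
                    col = if (tr$provisional[i]) "orange" else "cyan")
  }
  invisible(path)
}
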