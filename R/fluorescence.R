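# Per-spheroid fluorescence quantification: background-subtracted channel
# intensities, Ki-67 normalization, and live/dead viability fractions.

# Background annulus `gap` px outside the mask, `width` px wide.
.backgroundAnnulus <- function(mask, gap = 3, width = 5) {
  inner <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask * 1), EBImage::makeBrush(2L * as.integer(gap) + 1L, "disc"))) > 0
  outer_ <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(mask * 1),
    EBImage::makeBrush(2L * as.integer(gap + width) + 1L, "disc"))) > 0
  outer_ & !inner
}

#' Background-subtracted mean intensity of one object
#'
#' Mean channel intensity over the object mask minus the median intensity
#' over a local background annulus (by default a 5 px ring starting 3 px
#' outside the mask), clipped at zero. The median background is robust to
#' neighboring objects and slow illumination changes.
#'
#' @param mask logical matrix: the object.
#' @param channel numeric matrix, same shape.
#' @param background_annulus optional logical matrix; must be disjoint
#'   from `mask`. Built automatically when `NULL`.
#' @param gap,width annulus geometry in px (used when building it).
#' @return non-negative scalar intensity.
#' @export
perObjectIntensity <- function(mask, channel, background_annulus = NULL,
                               gap = 3, width = 5) {
  if (!any(mask)) stop("empty object mask", call. = FALSE)
  if (!identical(dim(mask), dim(channel)))
    stop("'mask' and 'channel' dimensions differ", call. = FALSE)
  ann <- if (is.null(background_annulus)) .backgroundAnnulus(mask, gap, width)
         else background_annulus
  if (!any(ann)) stop("empty background annulus", call. = FALSE)
  if (any(ann & mask))
    stop("background annulus overlaps the object mask", call. = FALSE)
  max(mean(channel[mask]) - median(channel[ann]), 0)
}

#' Normalize per-spheroid Ki-67 signal to a reference condition
#'
#' Each spheroid's proliferation readout is its FITC/DAPI intensity ratio
#' (DAPI division controls for spheroid size and cellularity), rescaled so
#' the mean ratio of the reference condition equals 1. Spheroids with a
#' non-positive DAPI mean are flagged and excluded with a warning. The
#' operation is idempotent and invariant to a common gain applied to both
#' channels.
#'
#' @param records data.frame with columns `condition`, `FITC`, `DAPI`
#'   (background-subtracted means, e.g. from [perObjectIntensity()]).
#' @param reference_condition label of the reference (positive-control)
#'   group; needs at least 3 usable records.
#' @return `records` with columns `ki67_ratio`, `normalized_ki67` and
#'   `flagged` added; flagged rows carry `NA` values.
#' @export
normalizeKi67 <- function(records, reference_condition) {
  stopifnot(all(c("condition", "FITC", "DAPI") %in% names(records)))
  rec <- as.data.frame(records)
  rec$flagged <- !(is.finite(rec$DAPI) & rec$DAPI > 0)
  if (any(rec$flagged))
    warning(sprintf("%d record(s) with non-positive DAPI flagged and excluded",
                    sum(rec$flagged)))
  rec$ki67_ratio <- ifelse(rec$flagged, NA_real_, rec$FITC / rec$DAPI)
  ref <- rec$condition == reference_condition & !rec$flagged
  if (sum(ref) < 3)
    stop(sprintf("reference condition '%s' needs >= 3 usable records (has %d)",
                 reference_condition, sum(ref)), call. = FALSE)
  ref_mean <- mean(rec$ki67_ratio[ref])
  rec$normalized_ki67 <- if (ref_mean == 0) {
    ifelse(rec$flagged, NA_real_, 0)
  } else rec$ki67_ratio / ref_mean
  rec
}

# Does a channel carry real signal? Guards Otsu against splitting pure
# background noise into spurious positives.
.hasSignal <- function(channel, min_contrast = 0.1) {
  quantile(channel, 0.999, names = FALSE) - median(channel) > min_contrast
}

#' Live/dead viability fractions per spheroid
#'
#' For each spheroid mask, the live fraction is the live-stain-positive
#' pixel area divided by the total stain-positive area (live + dead)
#' within the mask. Positivity thresholds are per-channel Otsu over the
#' whole image; a channel whose intensity spread is below `min_contrast`
#' is treated as signal-free (no positives). Spheroids with no positive
#' pixels in either channel are flagged with `NA`.
#'
#' @param live_channel,dead_channel numeric matrices (e.g. calcein /
#'   ethidium homodimer).
#' @param masks integer label matrix (object id per pixel, 0 background)
#'   or a named list of logical masks.
#' @param min_contrast minimum channel intensity spread to attempt
#'   thresholding.
#' @return data.frame: `object`, `live_px`, `dead_px`, `live_fraction`,
#'   `flagged`.
#' @export
viabilityFractions <- function(live_channel, dead_channel, masks,
                               min_contrast = 0.1) {
  if (!identical(dim(live_channel), dim(dead_channel)))
    stop("channel dimensions differ", call. = FALSE)
  if (is.matrix(masks)) {
    ids <- sort(unique(masks[masks > 0]))
    masks <- lapply(ids, function(i) masks == i)
    names(masks) <- ids
  }
  # Otsu, floored at median + 5 MAD: with very sparse positives Otsu can
  # land inside the background noise, so positivity must also clear the
  # channel's noise floor
  posThr <- function(ch) {
    if (!.hasSignal(ch, min_contrast)) return(Inf)
    max(.otsuThreshold(as.vector(ch)),
        median(ch) + 5 * stats::mad(ch))
  }
  thr_l <- posThr(live_channel)
  thr_d <- posThr(dead_channel)
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    lp <- sum(live_channel > thr_l & m)
    dp <- sum(dead_channel > thr_d & m)
    data.frame(object = nm, live_px = lp, dead_px = dp,
               live_fraction = if (lp + dp > 0) lp / (lp + dp) else NA_real_,
               flagged = lp + dp == 0)
  })
  do.call(rbind, out)
}
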