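# Brightfield spheroid segmentation: grayscale conversion, denoising, and
# per-trap isolation of the spheroid, plus day-0 cell counting.

# Otsu threshold of a numeric vector (256-bin histogram on [0,1]).
.otsuThreshold <- function(x) {
  x <- x[is.finite(x)]
  EBImage::otsu(EBImage::Image(matrix(.clip01(x), ncol = 1)),
                range = c(0, 1), levels = 256)
}

#' Preprocess a brightfield image
#'
#' Collapses color to luminance (channel mean), applies an edge-preserving
#' median filter, and optionally flattens slow background variation by
#' subtracting a large-scale Gaussian blur (re-centered so the output stays
#' range-preserving in `[0,1]`).
#'
#' @param image numeric matrix, or rows x cols x 3 color array.
#' @param median_radius median filter radius in px (0 disables).
#' @param flatten_sigma SD (px) of the background blur; `NULL` disables
#'   flattening (the default: per-trap thresholding already defeats slow
#'   illumination gradients).
#' @return filtered numeric matrix in `[0,1]`.
#' @export
preprocessImage <- function(image, median_radius = 2, flatten_sigma = NULL) {
  if (is.null(dim(image)) || length(image) == 0)
    stop("empty image", call. = FALSE)
  if (length(dim(image)) == 3L) image <- rowMeans(image, dims = 2L)
  if (length(dim(image)) != 2L)
    stop("'image' must be 2-D grayscale or 3-channel color", call. = FALSE)
  img <- .clip01(image)
  if (median_radius > 0)
    img <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(img),
                                                    as.integer(median_radius)))
  if (!is.null(flatten_sigma)) {
    bg <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                            sigma = flatten_sigma))
    img <- .clip01(img - bg + mean(bg))
  }
  img
}

#' Segment the spheroid inside one trap
#'
#' Thresholds the trap interior (Otsu by default, computed over trap-disk
#' pixels only so the global illumination gradient cannot bias it; dark
#' pixels are foreground), applies morphological closing and hole filling,
#' and keeps the largest connected component. Components smaller than
#' `min_area_px`, or thresholds with too little foreground/background
#' contrast, yield `found = FALSE`.
#'
#' @param roi numeric matrix covering the trap plus margin (preprocessed).
#' @param trap_mask logical matrix, same shape as `roi`: the trap disk.
#' @param trap_id,day identifiers stamped into the result.
#' @param offset (row, col) of `roi`'s top-left pixel in the full image.
#' @param params list: `min_area_px` (default 50), `close_radius` (px,
#'   default 2), `threshold` (`"otsu"` or a numeric global threshold),
#'   `min_contrast` (minimum mean foreground/background separation,
#'   default 0.15), `open_radius` (px, default 0: morphological opening
#'   applied before closing; set to the trap wall thickness in droplet
#'   mode, where the search region must include the wall ring, so that
#'   the thin dark ring cannot masquerade as an object).
#' @return a [SpheroidMask].
#' @export
segmentSpheroid <- function(roi, trap_mask, trap_id = NA_integer_,
                            day = NA_real_, offset = c(1L, 1L),
                            params = list()) {
  if (!any(trap_mask)) stop("empty trap mask", call. = FALSE)
  if (!identical(dim(roi), dim(trap_mask)))
    stop("'roi' and 'trap_mask' dimensions differ", call. = FALSE)
  p <- modifyList(list(min_area_px = 50, close_radius = 2,
                       threshold = "otsu", min_contrast = 0.15,
                       open_radius = 0), params)
  empty <- function() new("SpheroidMask", trap_id = as.integer(trap_id),
                          day = as.numeric(day),
                          mask = matrix(FALSE, nrow(roi), ncol(roi)),
                          offset = as.integer(offset), found = FALSE)
  vals <- roi[trap_mask]
  thr <- if (identical(p$threshold, "otsu")) .otsuThreshold(vals) else p$threshold
  dark <- vals < thr
  if (!any(dark) || all(dark)) return(empty())
  if (mean(vals[!dark]) - mean(vals[dark]) < p$min_contrast) return(empty())
  fg <- roi < thr & trap_mask
  m <- EBImage::Image(fg * 1)
  if (p$open_radius > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * as.integer(p$open_radius) + 1L,
                                                "disc"))
  if (p$close_radius > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * as.integer(p$close_radius) + 1L,
                                                "disc"))
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  lab <- EBImage::imageData(lab)
  lab[!trap_mask] <- 0L   # containment: clip any closing spill to the trap
  if (max(lab) == 0) return(empty())
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  if (areas[big] < p$min_area_px) return(empty())
  mask <- lab == big
  # re-label in case clipping split the component; keep the largest piece
  lab2 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab2) > 1) {
    a2 <- tabulate(lab2[lab2 > 0])
    mask <- lab2 == which.max(a2)
    if (sum(mask) < p$min_area_px) return(empty())
  }
  new("SpheroidMask", trap_id = as.integer(trap_id), day = as.numeric(day),
      mask = mask, offset = as.integer(offset), found = TRUE)
}

#' Count cells in a day-0 droplet
#'
#' Scale-selective blob counting: the image is inverted, smoothed with a
#' Gaussian matched to the cell radius, and local maxima at least one cell
#' radius apart with sufficient prominence above the droplet's median level
#' are counted. The droplet mask is eroded by the cell radius plus rim
#' width so the droplet's own dark rim is never counted. Overlapping cells
#' merge into one blob, so tight clusters undercount; this is the expected
#' failure mode of day-0 counting.
#'
#' @param roi_day0 numeric matrix covering the droplet (preprocessed).
#' @param droplet_mask logical matrix: the droplet disk.
#' @param cell_radius_px expected cell radius in px.
#' @param params list: `min_prominence` (default 0.08), `rim_px` (default 3).
#' @return integer count, with peak coordinates in attribute `"peaks"`.
#' @export
countCells <- function(roi_day0, droplet_mask, cell_radius_px,
                       params = list()) {
  if (!any(droplet_mask)) stop("empty droplet mask", call. = FALSE)
  p <- modifyList(list(min_prominence = 0.08, rim_px = 3), params)
  erode_r <- as.integer(ceiling(cell_radius_px) + p$rim_px)
  core <- EBImage::imageData(EBImage::erode(
    EBImage::Image(droplet_mask * 1),
    EBImage::makeBrush(2L * erode_r + 1L, "disc"))) > 0
  if (!any(core)) return(structure(0L, peaks = matrix(numeric(0), 0, 3)))
  sig <- max(1, cell_radius_px / 2)
  ksize <- 2L * as.integer(ceiling(2.5 * sig)) + 1L
  kern <- EBImage::makeBrush(ksize, "gaussian", sigma = sig)
  sm <- EBImage::imageData(EBImage::filter2(EBImage::Image(-roi_day0), kern,
                                            boundary = "replicate"))
  baseline <- median(sm[core])
  sm_masked <- sm
  sm_masked[!core] <- -Inf
  peaks <- .localMaxima(sm_masked, min_dist = cell_radius_px,
                        threshold = baseline + p$min_prominence)
  structure(nrow(peaks), peaks = peaks)
}
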