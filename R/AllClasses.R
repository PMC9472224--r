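#' @import methods
#' @importFrom stats median mad rnorm rpois runif sd lm pf pt quantile anova
#'   aggregate coef dist resid vcov setNames
#' @importFrom utils read.csv write.csv combn head modifyList packageVersion
#' @importFrom graphics plot hist
NULL

.LAYOUTS <- list(
  array150 = list(rows = 33L, cols = 30L, trap_diameter_um = 150),
  array300 = list(rows = 30L, cols = 15L, trap_diameter_um = 300)
)

#' Scene specification for the synthetic trap-array generator
#'
#' A `SceneSpec` holds the geometry and photometry of one synthetic device
#' image: the trap lattice (layout, rows x cols, trap diameter, pitch), the
#' pixel calibration, the brightfield gray levels used to draw traps,
#' droplets, cells and spheroids, and the degradation model (additive
#' Gaussian noise, salt-and-pepper fraction, linear illumination gradient
#' across the image width).
#'
#' The two device layouts mirror the physical trapping arrays: `"array150"`
#' is a 990-trap device with 150 um traps (tiled 33 x 30 by default) and
#' `"array300"` a 450-trap device with 300 um traps (30 x 15). Smaller
#' custom tilings of either trap size are allowed via `rows`/`cols`.
#'
#' @slot layout_id `"array150"` or `"array300"`.
#' @slot rows,cols integer lattice tiling.
#' @slot trap_diameter_um nominal trap diameter (um).
#' @slot pixel_scale calibration in um per pixel.
#' @slot pitch_factor center-to-center trap spacing as a multiple of the
#'   trap diameter.
#' @slot background_level,foreground_level,rim_level,trap_line_level,droplet_level,cell_level
#'   gray levels in `[0,1]` used by the renderer (background; spheroid
#'   interior; spheroid dark rim; trap wall annulus; day-0 droplet interior;
#'   day-0 cell blobs).
#' @slot texture_sigma SD of the granular texture inside spheroids.
#' @slot noise_sigma SD of additive Gaussian pixel noise.
#' @slot salt_pepper_frac fraction of pixels replaced by 0/1 impulses.
#' @slot illumination_gradient fractional intensity slope across the image
#'   width (0 = flat illumination).
#' @slot cell_radius_um radius of one rendered cell.
#' @slot seed base seed for all stochastic rendering.
#' @name SceneSpec-class
#' @aliases SceneSpec
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  layout_id = "character",
  rows = "integer",
  cols = "integer",
  trap_diameter_um = "numeric",
  pixel_scale = "numeric",
  pitch_factor = "numeric",
  background_level = "numeric",
  foreground_level = "numeric",
  rim_level = "numeric",
  trap_line_level = "numeric",
  droplet_level = "numeric",
  cell_level = "numeric",
  texture_sigma = "numeric",
  noise_sigma = "numeric",
  salt_pepper_frac = "numeric",
  illumination_gradient = "numeric",
  cell_radius_um = "numeric",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (!object@layout_id %in% names(.LAYOUTS))
    msg <- c(msg, sprintf("unknown layout_id '%s'", object@layout_id))
  if (object@rows < 1L || object@cols < 1L)
    msg <- c(msg, "rows and cols must be positive")
  if (object@pixel_scale <= 0) msg <- c(msg, "pixel_scale must be positive")
  if (object@trap_diameter_um / object@pixel_scale < 20)
    msg <- c(msg, "trap diameter must span at least 20 px to be resolvable")
  lv <- c(object@background_level, object@foreground_level, object@rim_level,
          object@trap_line_level, object@droplet_level, object@cell_level)
  if (any(lv < 0 | lv > 1)) msg <- c(msg, "gray levels must lie in [0,1]")
  if (object@noise_sigma < 0) msg <- c(msg, "noise_sigma must be >= 0")
  if (object@noise_sigma >= abs(object@foreground_level - object@background_level) / 2)
    msg <- c(msg, "noise_sigma must stay below half the foreground/background contrast")
  if (object@pitch_factor <= 1) msg <- c(msg, "pitch_factor must exceed 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic trap-array scene with full ground truth
#'
#' A rendered-on-demand synthetic dataset: the generating [SceneSpec], the
#' per-trap ground truth (lattice position, pixel center, encapsulated cell
#' count, day-0 droplet diameter), the per-(trap, day) true spheroid
#' diameters, and the per-condition true fluorescence levels. Images are
#' produced deterministically from the stored seed by [renderScene()] and
#' [renderFluorescence()].
#'
#' @slot spec the generating [SceneSpec].
#' @slot traps one row per trap: `trap_id`, `grid_row`, `grid_col`,
#'   `center_row`, `center_col` (px), `cell_count`, `droplet_diameter_um`.
#' @slot diameters long table `trap_id`, `day`, `diameter_um` of true
#'   spheroid diameters (`NA` for empty traps).
#' @slot days imaging days.
#' @slot conditions named list of per-condition truth; each entry has
#'   `ki67` (true proliferating fraction in `[0,1]`) and `dead_fraction`.
#' @slot seed scene seed (also stamped into every per-day render).
#' @name SyntheticScene-class
#' @aliases SyntheticScene
#' @exportClass SyntheticScene
setClass("SyntheticScene", representation(
  spec = "SceneSpec",
  traps = "data.frame",
  diameters = "data.frame",
  days = "numeric",
  conditions = "list",
  seed = "integer"
))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  need <- c("trap_id", "center_row", "center_col", "cell_count")
  if (!all(need %in% names(object@traps)))
    msg <- c(msg, paste("traps table must contain:", paste(need, collapse = ", ")))
  else if (anyDuplicated(object@traps$trap_id))
    msg <- c(msg, "trap_ids must be unique")
  if (nrow(object@diameters) &&
      !all(c("trap_id", "day", "diameter_um") %in% names(object@diameters)))
    msg <- c(msg, "diameters table needs trap_id, day, diameter_um")
  if (length(msg)) msg else TRUE
})

#' Detected trap grid of one device image
#'
#' Trap centers and radii found by [detectTraps()], regularized to a fitted
#' lattice. Sites the detector interpolated (rather than detected) are
#' marked `provisional` and should be excluded from morphometric statistics
#' unless a spheroid is actually segmented inside them.
#'
#' @slot traps one row per trap: `trap_id`, `center_row`, `center_col`,
#'   `radius_px`, `provisional`.
#' @slot lattice fitted lattice: `pitch_row_px`, `pitch_col_px`,
#'   `rotation_deg`, `origin` (row, col of site (1,1)), `residual_px`.
#' @slot nominal_diameter_um nominal trap diameter.
#' @slot pixel_scale um per pixel.
#' @slot image_dim source image dimensions (rows, cols).
#' @slot metadata list; carries `warnings` such as a degraded lattice fit.
#' @name TrapGrid-class
#' @aliases TrapGrid
#' @exportClass TrapGrid
setClass("TrapGrid", representation(
  traps = "data.frame",
  lattice = "list",
  nominal_diameter_um = "numeric",
  pixel_scale = "numeric",
  image_dim = "integer",
  metadata = "list"
))

setValidity("TrapGrid", function(object) {
  tr <- object@traps
  msg <- character()
  need <- c("trap_id", "center_row", "center_col", "radius_px", "provisional")
  if (!all(need %in% names(tr)))
    return(paste("traps table must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(tr$trap_id)) msg <- c(msg, "trap_ids must be unique")
  if (nrow(tr)) {
    if (any(tr$center_row < 1 | tr$center_row > object@image_dim[1] |
            tr$center_col < 1 | tr$center_col > object@image_dim[2]))
      msg <- c(msg, "trap centers must lie inside the image")
    rel <- abs(2 * tr$radius_px * object@pixel_scale - object@nominal_diameter_um) /
      object@nominal_diameter_um
    if (any(rel > 0.15))
      msg <- c(msg, "trap radii must be within 15% of the nominal diameter")
  }
  if (length(msg)) msg else TRUE
})

#' Segmented spheroid mask for one trap on one day
#'
#' @slot trap_id integer trap identifier.
#' @slot day imaging day.
#' @slot mask logical matrix over the trap ROI (`TRUE` = spheroid).
#' @slot offset (row, col) of the ROI's top-left pixel in the full image.
#' @slot found `FALSE` when no object survived segmentation.
#' @name SpheroidMask-class
#' @aliases SpheroidMask
#' @exportClass SpheroidMask
setClass("SpheroidMask", representation(
  trap_id = "integer",
  day = "numeric",
  mask = "matrix",
  offset = "integer",
  found = "logical"
))

#' One-way ANOVA result with Fisher LSD pairwise comparisons
#'
#' @slot group_labels group names in input order.
#' @slot n,means,sds per-group sample size, mean and SD.
#' @slot F_statistic,df_between,df_within,p_value the omnibus test.
#' @slot ms_within pooled within-group mean square (the LSD variance).
#' @slot pairwise data.frame `group_i`, `group_j`, `mean_diff`, `t`,
#'   `LSD_p`, `label` filled by [fisherLSD()].
#' @slot flags character vector of degeneracy flags.
#' @name AnovaResult-class
#' @aliases AnovaResult
#' @exportClass AnovaResult
setClass("AnovaResult", representation(
  group_labels = "character",
  n = "integer",
  means = "numeric",
  sds = "numeric",
  F_statistic = "numeric",
  df_between = "integer",
  df_within = "integer",
  p_value = "numeric",
  ms_within = "numeric",
  pairwise = "data.frame",
  flags = "character"
))
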