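#' Construct a scene specification
#'
#' Builds the [SceneSpec] describing one synthetic device image. The two
#' layouts reproduce the physical devices: `"array150"` has 990 traps of
#' 150 um (33 x 30) and `"array300"` 450 traps of 300 um (30 x 15).
#' `rows`/`cols` may be overridden to generate smaller scenes of either
#' trap size.
#'
#' Defaults: 1 um/px so pixel and micrometer coordinates coincide; trap
#' pitch 1.3 x trap diameter; additive Gaussian noise sigma 0.05 and a 10%
#' linear illumination gradient across the width, which together define the
#' package's default degradation level. Set `noise_sigma = 0` and
#' `illumination_gradient = 0` for noise-free renders.
#'
#' @param layout_id `"array150"` or `"array300"`.
#' @param rows,cols lattice tiling; defaults to the layout's full device.
#' @param pixel_scale um per pixel.
#' @param pitch_factor trap center spacing / trap diameter.
#' @param background_level,foreground_level,rim_level,trap_line_level,droplet_level,cell_level
#'   brightfield gray levels in `[0,1]`.
#' @param texture_sigma SD of the granular spheroid-interior texture.
#' @param noise_sigma SD of additive Gaussian noise.
#' @param salt_pepper_frac fraction of impulse-noise pixels.
#' @param illumination_gradient fractional intensity slope across the width.
#' @param cell_radius_um radius of one rendered cell.
#' @param seed base seed for all rendering randomness.
#' @return a validated [SceneSpec].
#' @examples
#' sceneSpec("array300", rows = 5, cols = 5, noise_sigma = 0,
#'           illumination_gradient = 0)
#' @export
sceneSpec <- function(layout_id = c("array150", "array300"),
                      rows = NULL, cols = NULL,
                      pixel_scale = 1.0, pitch_factor = 1.3,
                      background_level = 0.85, foreground_level = 0.5,
                      rim_level = 0.25, trap_line_level = 0.55,
                      droplet_level = 0.60, cell_level = 0.30,
                      texture_sigma = 0.05, noise_sigma = 0.05,
                      salt_pepper_frac = 0, illumination_gradient = 0.1,
                      cell_radius_um = 8, seed = 1L) {
  layout_id <- match.arg(layout_id)
  lay <- .LAYOUTS[[layout_id]]
  new("SceneSpec",
      layout_id = layout_id,
      rows = as.integer(if (is.null(rows)) lay$rows else rows),
      cols = as.integer(if (is.null(cols)) lay$cols else cols),
      trap_diameter_um = lay$trap_diameter_um,
      pixel_scale = pixel_scale, pitch_factor = pitch_factor,
      background_level = background_level, foreground_level = foreground_level,
      rim_level = rim_level, trap_line_level = trap_line_level,
      droplet_level = droplet_level, cell_level = cell_level,
      texture_sigma = texture_sigma, noise_sigma = noise_sigma,
      salt_pepper_frac = salt_pepper_frac,
      illumination_gradient = illumination_gradient,
      cell_radius_um = cell_radius_um, seed = as.integer(seed))
}

# Derived geometry ----------------------------------------------------------

.trapRadiusPx <- function(spec) spec@trap_diameter_um / spec@pixel_scale / 2

.pitchPx <- function(spec)
  round(spec@pitch_factor * spec@trap_diameter_um / spec@pixel_scale)

.marginPx <- function(spec) ceiling(0.25 * .pitchPx(spec))

.imageDim <- function(spec) {
  p <- .pitchPx(spec); m <- .marginPx(spec)
  as.integer(c(spec@rows * p + 2 * m, spec@cols * p + 2 * m))
}

# One row per lattice site with its pixel center.
.trapCenterTable <- function(spec) {
  p <- .pitchPx(spec); m <- .marginPx(spec)
  g <- expand.grid(grid_col = seq_len(spec@cols), grid_row = seq_len(spec@rows))
  data.frame(
    trap_id = seq_len(nrow(g)),
    grid_row = g$grid_row, grid_col = g$grid_col,
    center_row = m + (g$grid_row - 0.5) * p,
    center_col = m + (g$grid_col - 0.5) * p
  )
}

#' Poisson cell-loading model for droplet encapsulation
#'
#' Cells per droplet are modeled as i.i.d. Poisson(`lambda`), the standard
#' model for passive droplet encapsulation; the occupancy (fraction of
#' droplets holding at least one cell) is then `1 - exp(-lambda)`. The
#' physical study this emulates reports measured occupancies, not a loading
#' law; Poisson loading is this generator's modeling choice.
#'
#' @param lambda_mean_cells_per_droplet Poisson mean (cells per droplet).
#' @param cell_radius_um radius used when rendering individual cells.
#' @return an object of class `LoadingModel`.
#' @examples
#' loadingModel(2.3026)   # occupancy 1 - exp(-2.3026) = 90%
#' @export
loadingModel <- function(lambda_mean_cells_per_droplet, cell_radius_um = 8) {
  .assertPositiveScalar(lambda_mean_cells_per_droplet, "lambda_mean_cells_per_droplet")
  .assertPositiveScalar(cell_radius_um, "cell_radius_um")
  structure(list(lambda = lambda_mean_cells_per_droplet,
                 cell_radius_um = cell_radius_um),
            class = "LoadingModel")
}

#' Gated spheroid growth model
#'
#' Growth of a track is gated on its initial encapsulated cell count:
#' tracks starting with at least `min_growth_count` cells grow linearly at
#' `daily_rate_um_per_day`; occupied tracks below the gate stay at their
#' initial diameter (stagnant). Day-to-day measurement jitter is i.i.d.
#' Gaussian. The initial diameter follows a cube-root cell-packing rule,
#' `d0 = initial_diameter_coef_um * count^(1/3)`.
#'
#' @param min_growth_count minimum initial cell count for growth (the gate).
#' @param daily_rate_um_per_day diameter increment per day for growing tracks.
#' @param jitter_sigma_um SD of per-day measurement jitter (um).
#' @param days ordered imaging days.
#' @param initial_diameter_coef_um scale of the cube-root initial-size rule.
#' @return an object of class `GrowthModel`.
#' @examples
#' growthModel()  # gate at 10 cells, 6 um/day, days 1/3/5/7
#' @export
growthModel <- function(min_growth_count = 10L, daily_rate_um_per_day = 6,
                        jitter_sigma_um = 1, days = c(1, 3, 5, 7),
                        initial_diameter_coef_um = 16) {
  if (!length(days)) stop("'days' must be a non-empty ordered vector", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE))
    stop("'days' must be strictly increasing", call. = FALSE)
  .assertPositiveScalar(min_growth_count, "min_growth_count")
  if (daily_rate_um_per_day < 0 || jitter_sigma_um < 0)
    stop("rate and jitter must be non-negative", call. = FALSE)
  structure(list(min_growth_count = as.integer(min_growth_count),
                 daily_rate_um_per_day = daily_rate_um_per_day,
                 jitter_sigma_um = jitter_sigma_um,
                 days = as.numeric(days),
                 initial_diameter_coef_um = initial_diameter_coef_um),
            class = "GrowthModel")
}

# True per-condition fluorescence levels for the drug/viability scenes.
# ki67 is the condition's true proliferating fraction; dead_fraction the
# fraction of cells rendered as dead; live_dead switches the FITC channel
# from a Ki-67 stain to a per-cell live (calcein) stain.
.defaultConditions <- function() {
  list(
    "E2 only"         = list(ki67 = 0.90, dead_fraction = 0, live_dead = FALSE),
    "vehicle"         = list(ki67 = 0.88, dead_fraction = 0, live_dead = FALSE),
    "50 nM ICI + E2"  = list(ki67 = 0.50, dead_fraction = 0, live_dead = FALSE),
    "100 nM ICI + E2" = list(ki67 = 0.08, dead_fraction = 0, live_dead = FALSE),
    "no E2 control"   = list(ki67 = 0.06, dead_fraction = 0, live_dead = FALSE),
    "live/dead"       = list(ki67 = NA_real_, dead_fraction = 0.10, live_dead = TRUE)
  )
}
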