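#' Accessors for package classes
#'
#' `traps()` returns the per-trap table of a [TrapGrid] or
#' [SyntheticScene]; `nTraps()` its row count; `trapLattice()` the fitted
#' lattice parameters of a [TrapGrid]; `groundTruth()` the long
#' per-(trap, day) true-diameter table of a [SyntheticScene];
#' `sceneSpecOf()` the generating [SceneSpec].
#'
#' @param x a [TrapGrid] or [SyntheticScene].
#' @return `traps()`: a data.frame; `nTraps()`: an integer;
#'   `trapLattice()`: a list; `groundTruth()`: a data.frame;
#'   `sceneSpecOf()`: a [SceneSpec].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traps", function(x) standardGeneric("traps"))

#' @rdname accessors
#' @export
setGeneric("nTraps", function(x) standardGeneric("nTraps"))

#' @rdname accessors
#' @export
setGeneric("trapLattice", function(x) standardGeneric("trapLattice"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("sceneSpecOf", function(x) standardGeneric("sceneSpecOf"))

#' @rdname accessors
setMethod("traps", "TrapGrid", function(x) x@traps)

#' @rdname accessors
setMethod("traps", "SyntheticScene", function(x) x@traps)

#' @rdname accessors
setMethod("nTraps", "TrapGrid", function(x) nrow(x@traps))

#' @rdname accessors
setMethod("nTraps", "SyntheticScene", function(x) nrow(x@traps))

#' @rdname accessors
setMethod("trapLattice", "TrapGrid", function(x) x@lattice)

#' @rdname accessors
setMethod("groundTruth", "SyntheticScene", function(x) x@diameters)

#' @rdname accessors
setMethod("sceneSpecOf", "SyntheticScene", function(x) x@spec)

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec '%s': %d x %d traps of %g um (%g um/px)\n",
              object@layout_id, object@rows, object@cols,
              object@trap_diameter_um, object@pixel_scale))
  cat(sprintf("  pitch %g x diameter; noise sigma %g, gradient %g, seed %d\n",
              object@pitch_factor, object@noise_sigma,
              object@illumination_gradient, object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d traps (%s), days %s, seed %d\n",
              nrow(object@traps), object@spec@layout_id,
              paste(object@days, collapse = "/"), object@seed))
  occ <- mean(object@traps$cell_count > 0)
  cat(sprintf("  occupancy %.1f%%; cells/droplet median %g\n",
              100 * occ, median(object@traps$cell_count[object@traps$cell_count > 0])))
})

setMethod("show", "TrapGrid", function(object) {
  cat(sprintf("TrapGrid: %d traps (%d provisional), nominal %g um\n",
              nrow(object@traps), sum(object@traps$provisional),
              object@nominal_diameter_um))
  lat <- object@lattice
  if (length(lat))
    cat(sprintf("  lattice pitch (%.2f, %.2f) px, rotation %.2f deg, residual %.2f px\n",
                lat$pitch_row_px, lat$pitch_col_px, lat$rotation_deg, lat$residual_px))
  if (length(object@metadata$warnings))
    cat("  warnings:", paste(object@metadata$warnings, collapse = "; "), "\n")
})

setMethod("show", "SpheroidMask", function(object) {
  cat(sprintf("SpheroidMask trap %d day %g: %s (area %d px)\n",
              object@trap_id, object@day,
              if (object@found) "found" else "not found", sum(object@mask)))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              object@df_between, object@df_within,
              object@F_statistic, object@p_value))
  df <- data.frame(group = object@group_labels, n = object@n,
                   mean = object@means, sd = object@sds)
  print(df, row.names = FALSE)
  if (nrow(object@pairwise)) {
    cat("Fisher LSD pairwise comparisons:\n")
    print(object@pairwise, row.names = FALSE)
  }
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})
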