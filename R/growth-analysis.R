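# Longitudinal growth analysis: linking per-day measurements into tracks,
# slope-based growth classification, minimum-cell threshold estimation,
# and size-distribution summaries.

#' Link per-day measurements into growth tracks
#'
#' Joins the tidy measurement table across days into one track per
#' reference trap. With a `correspondence` table (from [registerDays()]),
#' per-day trap ids are first remapped onto the reference grid. Days on
#' which a trap's spheroid was not found are recorded as missing
#' diameters, and every (trap, day) cell of the complete grid is present
#' in the output.
#'
#' @param measurements data.frame with at least `trap_id`, `day`, `found`,
#'   `equivalent_diameter_um` (a `cell_count` column, if present, is
#'   carried through as the track's initial count).
#' @param correspondence optional data.frame `day`, `trap_id`,
#'   `ref_trap_id` remapping each day's ids onto the reference grid.
#' @return long data.frame `trap_id`, `day`, `diameter_um`, plus
#'   `initial_cell_count` when available; sorted by (trap_id, day).
#' @export
linkTracks <- function(measurements, correspondence = NULL) {
  m <- as.data.frame(measurements)
  need <- c("trap_id", "day", "found", "equivalent_diameter_um")
  if (!all(need %in% names(m)))
    stop(paste("measurements must contain:", paste(need, collapse = ", ")),
         call. = FALSE)
  if (!is.null(correspondence)) {
    key <- paste(m$day, m$trap_id)
    ck <- paste(correspondence$day, correspondence$trap_id)
    hit <- match(key, ck)
    m$trap_id <- ifelse(is.na(hit), m$trap_id, correspondence$ref_trap_id[hit])
    m <- m[!is.na(m$trap_id), , drop = FALSE]
  }
  if (anyDuplicated(m[, c("trap_id", "day")]))
    stop("duplicate (trap_id, day) measurement rows", call. = FALSE)
  grid <- expand.grid(day = sort(unique(m$day)),
                      trap_id = sort(unique(m$trap_id)))
  hit <- match(paste(grid$trap_id, grid$day), paste(m$trap_id, m$day))
  out <- data.frame(trap_id = grid$trap_id, day = grid$day,
                    diameter_um = ifelse(!is.na(hit) & m$found[hit],
                                         m$equivalent_diameter_um[hit], NA_real_))
  if ("cell_count" %in% names(m)) {
    first <- m[order(m$day), ]
    first <- first[!duplicated(first$trap_id), ]
    out$initial_cell_count <- first$cell_count[match(out$trap_id, first$trap_id)]
  }
  out[order(out$trap_id, out$day), , drop = FALSE]
}

#' Classify growth tracks by their diameter-vs-day slope
#'
#' Fits an ordinary least-squares line of diameter against day for each
#' track and tests the slope one-sided against zero. A track is `growing`
#' when its slope is positive with p below `alpha`, `stagnant` otherwise,
#' and `unclassified` with fewer than two non-missing days. Tracks with
#' exactly two points have no residual degrees of freedom; their p-value
#' is `NA` and they are labeled stagnant (the test cannot reject).
#'
#' @param tracks long data.frame from [linkTracks()] (columns `trap_id`,
#'   `day`, `diameter_um`, optionally `initial_cell_count`).
#' @param alpha one-sided significance level for the slope test.
#' @return one row per track: `trap_id`, `n_days`, `slope_um_per_day`,
#'   `slope_p_value`, `label`, and `initial_cell_count` when available.
#' @export
classifyGrowth <- function(tracks, alpha = 0.05) {
  stopifnot(all(c("trap_id", "day", "diameter_um") %in% names(tracks)))
  ids <- unique(tracks$trap_id)
  res <- lapply(ids, function(id) {
    tr <- tracks[tracks$trap_id == id & !is.na(tracks$diameter_um), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2)
      return(data.frame(trap_id = id, n_days = n,
                        slope_um_per_day = NA_real_, slope_p_value = NA_real_,
                        label = "unclassified"))
    # OLS slope and its one-sided test, computed directly (vcov() via
    # summary.lm warns on the zero-residual fits jitter-free tracks give)
    sxx <- sum((tr$day - mean(tr$day))^2)
    slope <- sum((tr$day - mean(tr$day)) * (tr$diameter_um - mean(tr$diameter_um))) / sxx
    rss <- sum((tr$diameter_um - mean(tr$diameter_um) -
                  slope * (tr$day - mean(tr$day)))^2)
    p <- if (n > 2) {
      se <- sqrt(rss / (n - 2) / sxx)
      if (se == 0) { if (slope > 0) 0 else 1 }
      else pt(slope / se, df = n - 2, lower.tail = FALSE)
    } else NA_real_
    label <- if (!is.na(p) && slope > 0 && p < alpha) "growing" else "stagnant"
    data.frame(trap_id = id, n_days = n, slope_um_per_day = slope,
               slope_p_value = p, label = label)
  })
  out <- do.call(rbind, res)
  if ("initial_cell_count" %in% names(tracks)) {
    first <- tracks[!duplicated(tracks$trap_id), ]
    out$initial_cell_count <-
      first$initial_cell_count[match(out$trap_id, first$trap_id)]
  }
  out
}

#' Estimate the minimum cell count required for growth
#'
#' Finds the smallest integer threshold `c` that best separates growing
#' from stagnant tracks by their initial encapsulated cell count: the
#' maximum-accuracy split where tracks with `count >= c` are called
#' growing and tracks below are called stagnant (ties broken toward the
#' smallest `c`). If all classified tracks share one label the result is
#' flagged as a boundary estimate.
#'
#' @param track_summary data.frame from [classifyGrowth()] with
#'   `initial_cell_count` and `label` columns.
#' @return list: `threshold` (integer), `boundary` (logical flag),
#'   `accuracy` (fraction of tracks the split explains), and
#'   `diagnostics` (per-count data.frame `cell_count`, `n`,
#'   `growing_fraction`).
#' @export
estimateGrowthThreshold <- function(track_summary) {
  s <- track_summary
  s <- s[!is.na(s$initial_cell_count) & s$label %in% c("growing", "stagnant"), ,
         drop = FALSE]
  if (nrow(s) < 2) stop("need at least 2 classified tracks with known counts",
                        call. = FALSE)
  counts <- s$initial_cell_count
  growing <- s$label == "growing"
  diag_df <- aggregate(growing, by = list(cell_count = counts),
                       FUN = function(g) c(n = length(g), frac = mean(g)))
  diag_df <- data.frame(cell_count = diag_df$cell_count,
                        n = diag_df$x[, "n"],
                        growing_fraction = diag_df$x[, "frac"])
  if (all(growing))
    return(list(threshold = min(counts), boundary = TRUE, accuracy = 1,
                diagnostics = diag_df))
  if (!any(growing))
    return(list(threshold = max(counts), boundary = TRUE, accuracy = 1,
                diagnostics = diag_df))
  cand <- sort(unique(counts))
  acc <- vapply(cand, function(cc)
    (sum(growing & counts >= cc) + sum(!growing & counts < cc)) / length(counts),
    numeric(1))
  best <- cand[which.max(acc)]   # which.max returns the first (smallest) tie
  list(threshold = as.integer(best), boundary = FALSE,
       accuracy = max(acc), diagnostics = diag_df)
}

#' Summarize the spheroid size distribution on one day
#'
#' @param tracks long data.frame (`trap_id`, `day`, `diameter_um`) or any
#'   measurement table with those columns.
#' @param day which day to summarize.
#' @param bin_width histogram bin width in um.
#' @return list: `day`, `mean`, `sd`, `n`, `breaks`, `counts`, and `text`
#'   formatted as `"mean +/- SD (n)"`.
#' @export
summarizeDistribution <- function(tracks, day, bin_width = 10) {
  v <- tracks$diameter_um[tracks$day == day]
  v <- v[!is.na(v)]
  if (!length(v)) stop(sprintf("no measurements on day %g", day), call. = FALSE)
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  h <- graphics::hist(v, breaks = seq(lo, hi, by = bin_width), plot = FALSE)
  list(day = day, mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n = length(v), breaks = h$breaks, counts = h$counts,
       text = sprintf("%.1f ± %.1f µm (n = %d)", mean(v),
                      if (length(v) > 1) sd(v) else 0, length(v)))
}

#' Plot growth tracks and size histograms
#'
#' Base-graphics QC plots: `plotGrowthTracks()` draws every track's
#' diameter day-series (growing tracks in green, stagnant in gray);
#' `plotSizeHistogram()` draws the day's size distribution.
#'
#' @param tracks long track table from [linkTracks()].
#' @param summary classification table from [classifyGrowth()] (optional
#'   coloring).
#' @return invisibly, `NULL`; called for the plot side effect.
#' @export
plotGrowthTracks <- function(tracks, summary = NULL) {
  ok <- !is.na(tracks$diameter_um)
  plot(NA, xlim = range(tracks$day), ylim = range(tracks$diameter_um[ok]),
       xlab = "day", ylab = "equivalent diameter (µm)",
       main = "spheroid growth tracks")
  for (id in unique(tracks$trap_id)) {
    tr <- tracks[tracks$trap_id == id & ok, ]
    if (nrow(tr) < 2) next
    col <- "gray60"
    if (!is.null(summary)) {
      lab <- summary$label[summary$trap_id == id]
      if (length(lab) && lab == "growing") col <- "forestgreen"
    }
    graphics::lines(tr$day, tr$diameter_um, col = col)
  }
  invisible(NULL)
}

#' @rdname plotGrowthTracks
#' @param distribution result of [summarizeDistribution()].
#' @export
plotSizeHistogram <- function(distribution) {
  graphics::barplot(distribution$counts,
                    names.arg = head(distribution$breaks, -1),
                    xlab = "equivalent diameter (µm)", ylab = "traps",
                    main = sprintf("day %g: %s", distribution$day,
                                   distribution$text))
  invisible(NULL)
}
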