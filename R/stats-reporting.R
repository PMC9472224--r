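# Significance workflow: one-way ANOVA, Fisher LSD pairwise comparisons,
# and the ***(p < 0.001) / ns (p > 0.05) labeling convention.

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition `F = MS_between / MS_within` with `k - 1` and
#' `N - k` degrees of freedom, computed through `stats::lm`/`anova`.
#' Degenerate inputs are flagged rather than erroring: zero within-group
#' variance with unequal means gives an infinite F (p = 0, flag
#' `"infinite-F"`); fully identical data give F = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group (names optional).
#' @return an [AnovaResult] (pairwise table empty until [fisherLSD()]).
#' @examples
#' res <- oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' res@F_statistic
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(lengths(groups) < 1))
    stop("every group needs at least one observation", call. = FALSE)
  labs <- names(groups)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, function(g) if (length(g) > 1) sd(g) else NA_real_,
                numeric(1))
  k <- length(groups); N <- sum(n)
  dfb <- k - 1L; dfw <- N - k
  if (dfw < 1) stop("no within-group degrees of freedom", call. = FALSE)
  value <- unlist(groups, use.names = FALSE)
  label <- factor(rep(labs, n), levels = labs)
  ssw <- sum((value - means[as.integer(label)])^2)
  ssb <- sum(n * (means - mean(value))^2)
  flags <- character()
  if (ssw <= .Machine$double.eps * sum(value^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(value^2))) {
      Fv <- 0; p <- 1; msw <- 0
      flags <- "degenerate: all observations identical"
    } else {
      Fv <- Inf; p <- 0; msw <- 0
      flags <- "infinite-F: zero within-group variance with unequal means"
    }
  } else {
    at <- anova(lm(value ~ label))
    Fv <- at[["F value"]][1]
    p <- at[["Pr(>F)"]][1]
    msw <- at[["Mean Sq"]][2]
  }
  new("AnovaResult", group_labels = labs, n = unname(n),
      means = unname(means), sds = unname(sds),
      F_statistic = Fv, df_between = as.integer(dfb),
      df_within = as.integer(dfw), p_value = p, ms_within = msw,
      pairwise = data.frame(), flags = flags)
}

#' Fisher LSD pairwise comparisons
#'
#' Fills the pairwise table of an [AnovaResult] with least-significant-
#' difference tests: for each pair of groups,
#' `t = (mean_i - mean_j) / sqrt(MS_within * (1/n_i + 1/n_j))`, two-sided
#' p on the ANOVA's within-group degrees of freedom, unadjusted for
#' multiplicity (the LSD definition). By default LSD is applied without a
#' protected-F gate; with `protected = TRUE` all pairs are reported `"ns"`
#' unless the omnibus ANOVA has p < 0.05. Pairs involving a group with
#' fewer than 2 observations are flagged (`NA` p).
#'
#' @param result an [AnovaResult] from [oneWayAnova()].
#' @param protected require omnibus p < 0.05 before declaring pairwise
#'   significance.
#' @return the [AnovaResult] with its `pairwise` slot filled.
#' @export
fisherLSD <- function(result, protected = FALSE) {
  stopifnot(is(result, "AnovaResult"))
  k <- length(result@group_labels)
  pairs <- combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    diff <- result@means[i] - result@means[j]
    if (result@n[i] < 2 || result@n[j] < 2)
      return(data.frame(group_i = result@group_labels[i],
                        group_j = result@group_labels[j],
                        mean_diff = diff, t = NA_real_, LSD_p = NA_real_,
                        label = "flagged: n < 2"))
    if (result@ms_within == 0) {
      p <- if (abs(diff) > 0) 0 else 1
      tval <- if (abs(diff) > 0) Inf * sign(diff) else 0
    } else {
      se <- sqrt(result@ms_within * (1 / result@n[i] + 1 / result@n[j]))
      tval <- diff / se
      p <- 2 * pt(-abs(tval), df = result@df_within)
    }
    if (protected && result@p_value >= 0.05) {
      lab <- "ns"
    } else lab <- labelSignificance(p)
    data.frame(group_i = result@group_labels[i],
               group_j = result@group_labels[j],
               mean_diff = diff, t = tval, LSD_p = p, label = lab)
  })
  result@pairwise <- do.call(rbind, rows)
  if (protected) result@flags <- c(result@flags, "protected LSD (omnibus gate)")
  validObject(result)
  result
}

#' Significance label convention
#'
#' `"***"` for p < 0.001, `"ns"` for p > 0.05, and the numeric p rendered
#' to 3 significant digits (`"p=0.0100"`) in between — the convention
#' defines only the two extremes, so intermediate values are reported
#' numerically rather than inventing star tiers.
#'
#' @param p a probability in `[0, 1]`.
#' @return a label string.
#' @examples
#' labelSignificance(0.0005)  # "***"
#' labelSignificance(0.2)     # "ns"
#' labelSignificance(0.01)    # "p=0.0100"
#' @export
labelSignificance <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  if (p < 0.001) return("***")
  if (p > 0.05) return("ns")
  sprintf("p=%#.3g", p)
}
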