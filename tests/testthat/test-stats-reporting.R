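test_that("the three-group worked example matches the sums-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- oneWayAnova(g)
  # hand computation: SSb = 6, SSw = 6, dfb = 2, dfw = 6 -> F = 3
  expect_equal(res@F_statistic, 3, tolerance = 1e-12)
  expect_equal(res@df_between, 2L)
  expect_equal(res@df_within, 6L)
  expect_equal(res@p_value, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # independent oracle: base aov and unadjusted pooled-SD pairwise t tests
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  at <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(res@F_statistic, at[["F value"]][1], tolerance = 1e-12)
  expect_equal(res@p_value, at[["Pr(>F)"]][1], tolerance = 1e-12)

  lsd <- fisherLSD(res)@pairwise
  oracle <- stats::pairwise.t.test(df$y, df$grp, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  expect_equal(lsd$LSD_p[lsd$group_i == "a" & lsd$group_j == "b"],
               oracle["b", "a"], tolerance = 1e-12)
  expect_equal(lsd$LSD_p[lsd$group_i == "a" & lsd$group_j == "c"],
               oracle["c", "a"], tolerance = 1e-12)
  expect_equal(lsd$LSD_p[lsd$group_i == "b" & lsd$group_j == "c"],
               oracle["c", "b"], tolerance = 1e-12)
})

test_that("degenerate group structures are flagged, not fatal", {
  # identical groups: no between-group variance at all
  res0 <- oneWayAnova(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(res0@F_statistic, 0)
  expect_equal(res0@p_value, 1)

  # zero within-group variance with unequal means: infinite F
  res_inf <- oneWayAnova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(is.infinite(res_inf@F_statistic))
  expect_equal(res_inf@p_value, 0)
  expect_match(res_inf@flags, "infinite-F")

  expect_error(oneWayAnova(list(a = 1:3)), "2 groups")
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(2)
  x <- rnorm(12, 10, 2); y <- rnorm(15, 11, 2)
  res <- oneWayAnova(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res@F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res@p_value, tt$p.value, tolerance = 1e-10)
})

test_that("group order does not change the ANOVA or the pairwise set", {
  set.seed(3)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  r1 <- fisherLSD(oneWayAnova(g))
  r2 <- fisherLSD(oneWayAnova(g[c(3, 1, 2)]))
  expect_equal(r1@F_statistic, r2@F_statistic, tolerance = 1e-12)
  expect_equal(r1@p_value, r2@p_value, tolerance = 1e-12)
  key <- function(pw) {
    k <- apply(pw[, c("group_i", "group_j")], 1, function(z)
      paste(sort(z), collapse = "|"))
    pw$LSD_p[order(k)]
  }
  expect_equal(key(r1@pairwise), key(r2@pairwise), tolerance = 1e-12)
})

test_that("well-separated groups are called highly significant", {
  set.seed(4)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 10, 1)  # ~10 pooled SDs apart
  pw <- fisherLSD(oneWayAnova(list(a = a, b = b)))@pairwise
  expect_lt(pw$LSD_p, 1e-3)
  expect_equal(pw$label, "***")
  # identical groups: pairwise p ~ 1
  pw0 <- fisherLSD(oneWayAnova(list(a = a, b = a)))@pairwise
  expect_gt(pw0$LSD_p, 0.99)
})

test_that("type-I error is controlled at the nominal 5%", {
  # 3 equal-mean groups, n = 20, 10,000 replicates, vectorized
  set.seed(77)
  k <- 3; n <- 20; reps <- 10000
  x <- matrix(rnorm(k * n * reps), nrow = k * n)
  grp <- rep(seq_len(k), each = n)
  gm <- rowsum(x, grp) / n                      # k x reps group means
  tot <- colMeans(x)
  ssb <- n * rowSums((t(gm) - tot)^2)
  ssw <- colSums((x - gm[grp, ])^2)
  Fv <- (ssb / (k - 1)) / (ssw / (k * n - k))
  rej <- mean(Fv > qf(0.95, k - 1, k * n - k))
  expect_lt(abs(rej - 0.05), 0.007)
})

test_that("significance labels follow the ***/ns convention", {
  expect_equal(labelSignificance(0.0005), "***")
  expect_equal(labelSignificance(0.2), "ns")
  expect_equal(labelSignificance(0.01), "p=0.0100")
  expect_error(labelSignificance(1.2), "probability")
  expect_error(labelSignificance(-0.1), "probability")
})

test_that("protected LSD gates pairwise calls on the omnibus test", {
  set.seed(6)
  g <- list(a = rnorm(5), b = rnorm(5, 0.1), c = rnorm(5, 0.2))
  res <- oneWayAnova(g)
  if (res@p_value >= 0.05) {
    pw <- fisherLSD(res, protected = TRUE)@pairwise
    expect_true(all(pw$label == "ns"))
  }
  # groups with n < 2 are flagged, the others still computed
  resf <- fisherLSD(oneWayAnova(list(a = 1:5, b = 2, c = 2:6)))
  pwf <- resf@pairwise
  expect_true(any(grepl("flagged", pwf$label)))
  expect_true(any(is.finite(pwf$LSD_p)))
})
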