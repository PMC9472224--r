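# Trap detection: circular-Hough-style annulus matched filtering at the
# nominal radius band, followed by lattice regularization.

# Zero-mean, unit-norm ring template (dark-ring detector when correlated
# with the negated image).
.ringTemplate <- function(radius, thickness = 2) {
  size <- 2L * as.integer(ceiling(radius + thickness)) + 1L
  t <- .ringTile(radius, thickness, size) * 1
  t <- t - mean(t)
  t / sqrt(sum(t^2))
}

# Matched-filter responses of dark rings, one image per scanned radius.
.ringResponse <- function(img, radii, thickness) {
  neg <- -img
  responses <- lapply(radii, function(r)
    EBImage::imageData(EBImage::filter2(EBImage::Image(neg),
                                        .ringTemplate(r, thickness),
                                        boundary = "replicate")))
  list(responses = responses, radii = radii,
       response = Reduce(pmax, responses))
}

# Fit a (possibly slightly rotated) regular lattice to detected centers.
# Pitch and rotation are bootstrapped from the strongest detections
# (weakest candidates often include clutter: spheroid rims, noise); all
# candidates are then tested against the fitted lattice and kept only if
# they land on a site. Returns per-site fitted centers over the full
# bounding index grid, with undetected sites flagged provisional.
.fitLattice <- function(centers, weights = rep(1, nrow(centers)),
                        min_pitch = 0) {
  stopifnot(nrow(centers) >= 4)
  n <- nrow(centers)
  sub <- if (n >= 12) {
    order(weights, decreasing = TRUE)[seq_len(ceiling(0.6 * n))]
  } else seq_len(n)
  cs <- centers[sub, , drop = FALSE]
  # pitch and rotation from nearest-neighbour displacements of the subset;
  # traps are disjoint disks, so neighbour distances below min_pitch
  # (~one trap diameter) come from clutter and are ignored
  d <- as.matrix(stats::dist(cs))
  diag(d) <- Inf
  d[d < min_pitch] <- Inf
  nn <- apply(d, 1, which.min)
  nnd <- d[cbind(seq_len(nrow(d)), nn)]
  pitch0 <- median(nnd[is.finite(nnd)])
  ang <- c()
  for (i in seq_len(nrow(cs))) {
    close <- which(d[i, ] < 1.3 * pitch0)
    if (!length(close)) next
    a <- atan2(cs[close, 1] - cs[i, 1], cs[close, 2] - cs[i, 2]) * 180 / pi
    ang <- c(ang, ((a + 45) %% 90) - 45)
  }
  theta <- if (length(ang)) median(ang) else 0
  ct <- cos(theta * pi / 180); st <- sin(theta * pi / 180)
  mid <- colMeans(cs)
  toLat <- function(xy) cbind(ct * (xy[, 1] - mid[1]) - st * (xy[, 2] - mid[2]),
                              st * (xy[, 1] - mid[1]) + ct * (xy[, 2] - mid[2]))
  ls <- toLat(cs)
  rr <- ls[, 1]; cc <- ls[, 2]
  r0 <- min(rr); c0 <- min(cc)
  for (pass in 1:2) {
    i <- round((rr - r0) / pitch0)
    j <- round((cc - c0) / pitch0)
    fr <- lm(rr ~ i); fc <- lm(cc ~ j)
    pitch0 <- mean(c(coef(fr)[2], coef(fc)[2]))
  }
  # test every candidate against the fitted lattice
  la <- toLat(centers)
  ia <- round((la[, 1] - coef(fr)[1]) / coef(fr)[2])
  ja <- round((la[, 2] - coef(fc)[1]) / coef(fc)[2])
  resid_a <- sqrt((la[, 1] - coef(fr)[1] - coef(fr)[2] * ia)^2 +
                  (la[, 2] - coef(fc)[1] - coef(fc)[2] * ja)^2)
  ok <- resid_a <= 0.3 * pitch0
  # one detection per site: keep the strongest
  key <- paste(ia, ja)
  keep <- rep(FALSE, n)
  for (k in order(weights, decreasing = TRUE))
    if (ok[k] && !any(keep & key == key[k])) keep[k] <- TRUE
  if (sum(keep) >= 4) {
    rr <- la[keep, 1]; cc <- la[keep, 2]
    i <- ia[keep]; j <- ja[keep]
    fr <- lm(rr ~ i); fc <- lm(cc ~ j)
  }
  res <- sqrt(mean(c(stats::resid(fr), stats::resid(fc))^2))
  # trim border lattice rows/cols that almost no detection supports:
  # isolated clutter must not inflate the array's bounding box
  irange <- min(i):max(i); jrange <- min(j):max(j)
  repeat {
    occ_i <- vapply(irange, function(q) sum(i == q), numeric(1)) / length(jrange)
    occ_j <- vapply(jrange, function(q) sum(j == q), numeric(1)) / length(irange)
    drop_i <- length(irange) > 1 & (occ_i < 0.3 &
      seq_along(irange) %in% c(1L, length(irange)))
    drop_j <- length(jrange) > 1 & (occ_j < 0.3 &
      seq_along(jrange) %in% c(1L, length(jrange)))
    if (!any(drop_i) && !any(drop_j)) break
    irange <- irange[!drop_i]; jrange <- jrange[!drop_j]
    keep2 <- i %in% irange & j %in% jrange
    i <- i[keep2]; j <- j[keep2]; rr <- rr[keep2]; cc <- cc[keep2]
  }
  fr <- lm(rr ~ i); fc <- lm(cc ~ j)
  res <- sqrt(mean(c(stats::resid(fr), stats::resid(fc))^2))
  grid <- expand.grid(j = jrange, i = irange)
  fit_r <- coef(fr)[1] + coef(fr)[2] * grid$i
  fit_c <- coef(fc)[1] + coef(fc)[2] * grid$j
  # back to image frame
  out_r <- mid[1] + ct * fit_r + st * fit_c
  out_c <- mid[2] - st * fit_r + ct * fit_c
  provisional <- !(paste(grid$i, grid$j) %in% paste(i, j))
  list(centers = cbind(row = out_r, col = out_c),
       grid = grid, provisional = provisional,
       pitch_row_px = unname(coef(fr)[2]), pitch_col_px = unname(coef(fc)[2]),
       rotation_deg = theta,
       origin = c(row = out_r[1], col = out_c[1]),
       residual_px = res,
       index = cbind(i = i, j = j))
}

#' Detect the circular traps of a device image
#'
#' Locates traps by annulus matched filtering (circular Hough voting
#' restricted to radii within +/-15% of the nominal trap radius) on a
#' downsampled copy of the image, then regularizes the detections to a
#' fitted rectangular lattice. Lattice sites without a raw detection are
#' filled by interpolation and flagged `provisional`; final trap centers
#' are the fitted lattice positions.
#'
#' @param image numeric matrix (single-channel intensity, rows x cols).
#' @param nominal_diameter_um nominal trap diameter.
#' @param pixel_scale um per pixel.
#' @param radius_tolerance half-width of the scanned radius band (fraction
#'   of nominal).
#' @param min_response minimum ring contrast (intensity units) a
#'   detection must show; the absolute response floor is
#'   `min_response * sqrt(ring pixel count)`.
#' @return a [TrapGrid]. A degraded lattice fit (residual above a quarter
#'   pitch) is recorded in `metadata$warnings`.
#' @examples
#' sp <- sceneSpec("array300", rows = 3, cols = 3, noise_sigma = 0,
#'                 illumination_gradient = 0)
#' sc <- sceneFromDiameters(sp, rep(NA, 9), day = 1)
#' g <- detectTraps(renderScene(sc, 1)$image, 300, 1)
#' nTraps(g)
#' @export
detectTraps <- function(image, nominal_diameter_um, pixel_scale,
                        radius_tolerance = 0.15, min_response = 0.04) {
  if (length(dim(image)) != 2L)
    stop("'image' must be a single-channel 2-D intensity matrix", call. = FALSE)
  r_nom <- nominal_diameter_um / pixel_scale / 2
  if (2 * r_nom < 20)
    stop("nominal trap diameter must span at least 20 px", call. = FALSE)
  ds <- max(1L, as.integer(floor(r_nom / 12)))
  img_ds <- if (ds > 1L)
    EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                       w = floor(nrow(image) / ds),
                                       h = floor(ncol(image) / ds)))
  else image
  r_ds <- r_nom / ds
  radii <- r_ds * c(1 - radius_tolerance, 1, 1 + radius_tolerance)
  # template thickness tracks the rendered-wall scale (~4% of diameter)
  thick <- max(2, round(0.04 * 2 * r_nom / ds) + 1)
  rr <- .ringResponse(img_ds, radii, thick)
  ring_px <- 2 * pi * r_ds * thick
  # absolute floor rejects structureless images; the adaptive term then
  # separates true ring peaks from weaker clutter (spheroid rims, noise)
  floor0 <- min_response * sqrt(ring_px)
  # a ring center closer than its radius to the border cannot be a trap,
  # and replicate-padding makes the response unreliable there
  resp <- rr$response
  b <- ceiling(r_ds * (1 - radius_tolerance))
  resp[c(seq_len(b), nrow(resp) - seq_len(b) + 1L), ] <- -Inf
  resp[, c(seq_len(b), ncol(resp) - seq_len(b) + 1L)] <- -Inf
  # suppression radius just under one trap diameter: two true traps can
  # never be that close, while inter-trap clutter (e.g. the ring-like
  # response midway between four droplet rims) always is
  cand <- .localMaxima(resp, min_dist = 1.9 * r_ds, threshold = floor0)
  if (nrow(cand) < 4)
    stop("no array found: fewer than 4 trap detections", call. = FALSE)
  # separate true ring peaks from weaker clutter (spheroid rims, noise) at
  # the largest multiplicative gap in the sorted peak values; a homogeneous
  # population (no gap above 20%) is kept whole
  v <- sort(cand[, "value"], decreasing = TRUE)
  peaks <- cand
  if (length(v) > 4) {
    ks <- 4:(length(v) - 1)
    ratio <- v[ks] / v[ks + 1]
    if (max(ratio) >= 1.2) {
      cut <- v[ks[which.max(ratio)] + 1]
      peaks <- cand[cand[, "value"] > cut, , drop = FALSE]
    }
  }
  if (nrow(peaks) < 4)
    stop("no array found: fewer than 4 trap detections", call. = FALSE)

  # trap radius: the scanned radius responding best at the detected peaks
  pk_idx <- cbind(peaks[, "row"], peaks[, "col"])
  radius_scores <- vapply(rr$responses, function(m) mean(m[pk_idx]), numeric(1))
  best_radius <- rr$radii[which.max(radius_scores)]

  # sub-pixel refinement by 3x3 response centroid, then map to full res
  ref <- t(apply(peaks, 1, function(p) {
    r0 <- max(2, min(nrow(rr$response) - 1, p[1]))
    c0 <- max(2, min(ncol(rr$response) - 1, p[2]))
    w <- rr$response[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)]
    w <- w - min(w)
    if (sum(w) == 0) return(c(r0, c0))
    c(r0 + sum((-1:1) * rowSums(w)) / sum(w),
      c0 + sum((-1:1) * colSums(w)) / sum(w))
  }))
  # per-axis scale (floor() above makes it differ slightly from ds)
  sr <- nrow(image) / nrow(img_ds); sc_ <- ncol(image) / ncol(img_ds)
  centers <- cbind((ref[, 1] - 0.5) * sr + 0.5, (ref[, 2] - 0.5) * sc_ + 0.5)

  # centers already in full-res coordinates
  lat <- .fitLattice(centers, weights = peaks[, "value"],
                     min_pitch = 1.9 * r_nom)
  warnings <- character()
  if (lat$residual_px > 0.25 * lat$pitch_row_px)
    warnings <- c(warnings, "degraded lattice fit: residual exceeds a quarter pitch")

  # drop interpolated sites that fall outside the image
  keep <- lat$centers[, 1] >= 1 & lat$centers[, 1] <= nrow(image) &
          lat$centers[, 2] >= 1 & lat$centers[, 2] <= ncol(image)
  tr <- data.frame(
    trap_id = seq_len(sum(keep)),
    center_row = lat$centers[keep, 1],
    center_col = lat$centers[keep, 2],
    radius_px = best_radius * ds,
    provisional = lat$provisional[keep]
  )
  new("TrapGrid",
      traps = tr,
      lattice = list(pitch_row_px = lat$pitch_row_px,
                     pitch_col_px = lat$pitch_col_px,
                     rotation_deg = lat$rotation_deg,
                     origin = lat$origin,
                     residual_px = lat$residual_px),
      nominal_diameter_um = nominal_diameter_um,
      pixel_scale = pixel_scale,
      image_dim = dim(image),
      metadata = list(warnings = warnings, n_raw_detections = nrow(peaks),
                      downsample = ds))
}

#' Build a label map of trap disks
#'
#' Rasterizes every trap of a [TrapGrid] as a filled disk labeled by its
#' trap_id (0 = background). Disks must be pairwise disjoint.
#'
#' @param grid a [TrapGrid].
#' @param image_dim (rows, cols) of the output map; defaults to the grid's
#'   source image dimensions.
#' @return integer matrix label map.
#' @export
buildTrapMasks <- function(grid, image_dim = grid@image_dim) {
  tr <- traps(grid)
  if (!nrow(tr)) stop("empty trap grid", call. = FALSE)
  d <- as.matrix(stats::dist(tr[, c("center_row", "center_col")]))
  diag(d) <- Inf
  rsum <- outer(tr$radius_px, tr$radius_px, "+")
  bad <- which(d < rsum, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("overlapping trap disks: trap_ids %s",
                 paste(unique(apply(bad, 1, function(k)
                   paste(sort(tr$trap_id[k]), collapse = "/"))), collapse = ", ")),
         call. = FALSE)
  lab <- matrix(0L, image_dim[1], image_dim[2])
  for (i in seq_len(nrow(tr))) {
    roi <- .roiAround(tr$center_row[i], tr$center_col[i], tr$radius_px[i] + 1,
                      image_dim)
    d2 <- outer((seq_along(roi$rows) - roi$center[1])^2,
                (seq_along(roi$cols) - roi$center[2])^2, "+")
    tile <- lab[roi$rows, roi$cols]
    tile[d2 <= tr$radius_px[i]^2] <- tr$trap_id[i]
    lab[roi$rows, roi$cols] <- tile
  }
  lab
}

#' Serialize a trap grid to CSV + YAML
#'
#' Writes the per-trap table (trap_id, center, radius, provisional flag)
#' as CSV and the fitted lattice metadata (pitch, rotation, origin,
#' residual, nominal diameter, pixel scale) as YAML alongside it.
#'
#' @param grid a [TrapGrid].
#' @param csv_path output CSV path; the YAML is written next to it as
#'   `<stem>_lattice.yaml`.
#' @return invisibly, the CSV path.
#' @export
writeTrapGrid <- function(grid, csv_path) {
  write.csv(traps(grid), csv_path, row.names = FALSE)
  meta <- c(grid@lattice,
            list(nominal_diameter_um = grid@nominal_diameter_um,
                 pixel_scale = grid@pixel_scale,
                 image_dim = as.list(grid@image_dim),
                 warnings = grid@metadata$warnings))
  meta$origin <- as.list(meta$origin)
  yaml::write_yaml(meta, sub("\\.csv$", "_lattice.yaml", csv_path))
  invisible(csv_path)
}

#' Register two trap grids across imaging days
#'
#' Estimates the rigid transform (rotation + translation) carrying grid
#' `a`'s trap centers onto grid `b`'s by iterative closest point with a
#' Kabsch update, and returns the trap correspondence. Traps whose nearest
#' transformed counterpart is farther than half a pitch are flagged
#' unmatched.
#'
#' @param grid_a,grid_b [TrapGrid]s of the same device layout.
#' @param max_iter ICP iterations.
#' @return list with `rotation_deg`, `translation` (row, col),
#'   `correspondence` (data.frame `trap_id_a`, `trap_id_b`, `dist_px`;
#'   `trap_id_b` is `NA` for unmatched traps) and `rmsd_px`.
#' @export
registerDays <- function(grid_a, grid_b, max_iter = 20L) {
  if (abs(grid_a@nominal_diameter_um - grid_b@nominal_diameter_um) > 1e-8)
    stop("grids come from different layouts (nominal trap diameters differ)",
         call. = FALSE)
  A <- as.matrix(traps(grid_a)[, c("center_row", "center_col")])
  B <- as.matrix(traps(grid_b)[, c("center_row", "center_col")])
  pitch <- mean(c(grid_a@lattice$pitch_row_px, grid_a@lattice$pitch_col_px))
  R <- diag(2)
  tvec <- colMeans(B) - colMeans(A)
  match_b <- rep(NA_integer_, nrow(A))
  for (it in seq_len(max_iter)) {
    Ap <- A %*% t(R) + matrix(tvec, nrow(A), 2, byrow = TRUE)
    d2 <- outer(rowSums(Ap^2), rowSums(B^2), "+") - 2 * Ap %*% t(B)
    nn <- max.col(-d2)
    dist <- sqrt(pmax(d2[cbind(seq_len(nrow(A)), nn)], 0))
    ok <- dist < 0.5 * pitch
    if (sum(ok) < 3) break
    match_b <- ifelse(ok, nn, NA_integer_)
    Am <- A[ok, , drop = FALSE]; Bm <- B[nn[ok], , drop = FALSE]
    ca <- colMeans(Am); cb <- colMeans(Bm)
    H <- t(sweep(Am, 2, ca)) %*% sweep(Bm, 2, cb)
    sv <- svd(H)
    Rn <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
    tn <- cb - as.vector(Rn %*% ca)
    if (max(abs(Rn - R)) < 1e-12 && max(abs(tn - tvec)) < 1e-9) { R <- Rn; tvec <- tn; break }
    R <- Rn; tvec <- tn
  }
  Ap <- A %*% t(R) + matrix(tvec, nrow(A), 2, byrow = TRUE)
  dist <- rep(NA_real_, nrow(A))
  ok <- !is.na(match_b)
  dist[ok] <- sqrt(rowSums((Ap[ok, , drop = FALSE] -
                            B[match_b[ok], , drop = FALSE])^2))
  corr <- data.frame(trap_id_a = traps(grid_a)$trap_id,
                     trap_id_b = traps(grid_b)$trap_id[match_b],
                     dist_px = dist)
  list(rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       translation = c(row = unname(tvec[1]), col = unname(tvec[2])),
       correspondence = corr,
       rmsd_px = sqrt(mean(dist^2, na.rm = TRUE)))
}
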