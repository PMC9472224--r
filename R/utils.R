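# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derived sub-seed, kept inside 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Logical disk mask of a given radius inside a local square tile.
# Pixel (i, j) belongs to the disk iff its center lies within `radius`
# of (center_row, center_col); this rasterization rule is shared by the
# renderer and the ground-truth masks so both agree pixel-exactly.
.diskTile <- function(radius, size, center = (size + 1) / 2) {
  d2 <- outer((seq_len(size) - center[1])^2,
              (seq_len(size) - center[length(center)])^2, "+")
  d2 <= radius^2
}

# Ring (annulus) mask: radius +/- half thickness.
.ringTile <- function(radius, thickness, size, center = (size + 1) / 2) {
  d2 <- outer((seq_len(size) - center[1])^2,
              (seq_len(size) - center[length(center)])^2, "+")
  d2 <= (radius + thickness / 2)^2 & d2 >= (radius - thickness / 2)^2
}

# Clamp a square ROI of half-width h around (r, c) to the image; returns
# inclusive row/col ranges plus the center's position inside the ROI.
.roiAround <- function(r, c, h, dim) {
  r0 <- max(1L, as.integer(round(r - h))); r1 <- min(dim[1], as.integer(round(r + h)))
  c0 <- max(1L, as.integer(round(c - h))); c1 <- min(dim[2], as.integer(round(c + h)))
  list(rows = r0:r1, cols = c0:c1, center = c(r - r0 + 1, c - c0 + 1))
}

# TRUE where a pixel is >= its 8 neighbours (plateau pixels all kept;
# the greedy min-distance pass dedupes them).
.is3x3Max <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- x
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (x >= p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  ok
}

# Greedy local-maximum picking: 3x3-maximal candidates above `threshold`,
# visited in decreasing value order, accepted if no already-accepted peak
# lies within `min_dist`. Returns a matrix of (row, col, value).
.localMaxima <- function(x, min_dist, threshold) {
  idx <- which(x > threshold & .is3x3Max(x))
  if (!length(idx)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("row", "col", "value"))))
  v <- x[idx]
  ord <- order(v, decreasing = TRUE)
  idx <- idx[ord]; v <- v[ord]
  nr <- nrow(x)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  md2 <- min_dist^2
  for (k in seq_along(idx)) {
    if (length(keep_r)) {
      if (any((keep_r - rr[k])^2 + (keep_c - cc[k])^2 < md2)) next
    }
    keep_r <- c(keep_r, rr[k]); keep_c <- c(keep_c, cc[k]); keep_v <- c(keep_v, v[k])
  }
  cbind(row = keep_r, col = keep_c, value = keep_v)
}

# Rejection-sample `n` points inside a disk of radius R with pairwise
# separation >= min_sep. Gives up gracefully (returns what it placed) if the
# packing is too tight after max_tries attempts.
.packPoints <- function(n, R, min_sep, max_tries = 20000L) {
  pr <- numeric(0); pc <- numeric(0)
  tries <- 0L
  while (length(pr) < n && tries < max_tries) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi); r <- R * sqrt(runif(1))
    y <- r * sin(a); x <- r * cos(a)
    if (!length(pr) || all((pr - y)^2 + (pc - x)^2 >= min_sep^2)) {
      pr <- c(pr, y); pc <- c(pc, x)
    }
  }
  cbind(row = pr, col = pc)
}

# Rendered trap wall thickness (~4% of trap diameter, min 3 px) and the
# largest disk radius that stays clear of the wall.
.trapWall <- function(radius_px) max(3, round(0.08 * radius_px))

.trapInteriorRadius <- function(radius_px)
  radius_px - .trapWall(radius_px) / 2 - 2

.assertPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

# Stable short hash of an R object (provenance stamping).
.paramHash <- function(x) substr(rlang::hash(x), 1, 12)
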