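# Low-level raster operations shared by segmentation and spot detection.
# All kernels are parameterized in um and converted to voxels at the call
# site; arrays are plain numeric arrays (2D matrices or 3D).

gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigmaVox))
  k <- dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

# shift an array along one axis by `off` voxels, padding with `fill`
# (or replicating the edge when fill is NA)
shiftArray <- function(a, axis, off, fill = NA) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  n <- d[axis]
  idx <- seq_len(n) + off
  if (is.na(fill)) {
    idx <- pmin(pmax(idx, 1L), n)
    sel <- idx
  } else {
    sel <- ifelse(idx >= 1L & idx <= n, idx, NA_integer_)
  }
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- sel
  out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  if (!is.na(fill)) out[is.na(out)] <- fill
  dim(out) <- d
  out
}

convolveAxis <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_along(k))
    out <- out + k[j] * shiftArray(a, axis, j - 1L - r, fill = NA)
  out
}

# separable Gaussian blur; sigmaVox has one sigma per array dimension
gaussianSmooth <- function(a, sigmaVox) {
  for (ax in seq_along(sigmaVox))
    if (sigmaVox[ax] > 0) a <- convolveAxis(a, gaussKernel1d(sigmaVox[ax]), ax)
  a
}

# negative discrete Laplacian of a Gaussian-smoothed image: bright compact
# features give positive response
logFilter2d <- function(m, sigmaVox) {
  s <- gaussianSmooth(m, sigmaVox)
  lap <- shiftArray(s, 1L, -1L) + shiftArray(s, 1L, 1L) +
    shiftArray(s, 2L, -1L) + shiftArray(s, 2L, 1L) - 4 * s
  -lap
}

maxIntensityProject <- function(vol) apply(vol, c(1L, 2L), max)

#' Triangle-method histogram threshold
#'
#' Zack's geometric construction: the threshold is the histogram bin with
#' the largest perpendicular distance to the line joining the histogram
#' peak and the far empty tail.
#'
#' @param x numeric values.
#' @param nBins number of histogram bins.
#' @return threshold on the scale of \code{x}.
#' @export
triangleThreshold <- function(x, nBins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  h <- tabulate(pmin(nBins, 1L + floor((x - rng[1L]) / diff(rng) * nBins)),
                nbins = nBins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1L]; hi <- nz[length(nz)]
  # work on the longer tail; mirror so the tail is to the right of the peak
  flip <- (peak - lo) > (hi - peak)
  if (flip) {
    h <- rev(h)
    peak <- nBins - peak + 1L
    hi <- nBins - lo + 1L
  }
  if (hi <= peak) return(rng[1L] + (peak - 0.5) / nBins * diff(rng))
  bx <- seq.int(peak, hi)
  # line from (peak, h[peak]) to (hi, 0)
  vx <- hi - peak; vy <- -as.numeric(h[peak])
  dist <- abs((bx - peak) * vy - (h[bx] - h[peak]) * vx)
  tbin <- bx[which.max(dist)]
  if (flip) tbin <- nBins - tbin + 1L
  rng[1L] + (tbin - 0.5) / nBins * diff(rng)
}

# 3D local maxima within an anisotropic ellipsoidal neighborhood given in um.
# Plateau ties keep the lexicographically smallest coordinate.  Two stages:
# a cheap face-neighbour prefilter on the full array, then the exact
# ellipsoid comparison at the surviving candidates only.
localMaxima3d <- function(vol, radiusUm, voxelSize) {
  rv <- radiusUm / voxelSize
  if (all(floor(rv) < 1))
    stop("calibration too coarse: search neighborhood smaller than one voxel")
  ro <- floor(rv)
  offs <- expand.grid(dx = -ro[1L]:ro[1L], dy = -ro[2L]:ro[2L],
                      dz = -ro[3L]:ro[3L])
  keep <- with(offs, (dx / rv[1L])^2 + (dy / rv[2L])^2 + (dz / rv[3L])^2 <= 1 &
                 !(dx == 0 & dy == 0 & dz == 0))
  offs <- as.matrix(offs[keep, , drop = FALSE])
  lexPositive <- offs[, 1L] > 0 | (offs[, 1L] == 0 & offs[, 2L] > 0) |
    (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0)

  # stage 1: face neighbours only (a subset of the ellipsoid, so no true
  # maximum can be lost)
  d <- dim(vol)
  isCand <- array(TRUE, d)
  face <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (i in seq_len(nrow(face))) {
    o <- face[i, ]
    ax <- which(o != 0L)
    sh <- shiftArray(vol, ax, o[ax], fill = -Inf)
    lp <- o[1L] > 0 || (o[1L] == 0 && o[2L] > 0) ||
      (o[1L] == 0 && o[2L] == 0 && o[3L] > 0)
    isCand <- isCand & if (lp) vol >= sh else vol > sh
  }
  cand <- which(isCand, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)

  # stage 2: exact ellipsoid comparison at candidates
  vc <- vol[cand]
  ok <- rep(TRUE, nrow(cand))
  nxy <- d[1L] * d[2L]
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- cand[, 1L] + o[1L]
    nbY <- cand[, 2L] + o[2L]
    nbZ <- cand[, 3L] + o[3L]
    inb <- nb >= 1L & nb <= d[1L] & nbY >= 1L & nbY <= d[2L] &
      nbZ >= 1L & nbZ <= d[3L]
    lin <- nb[inb] + (nbY[inb] - 1L) * d[1L] + (nbZ[inb] - 1L) * nxy
    vn <- vol[lin]
    cmp <- if (lexPositive[i]) vc[inb] >= vn else vc[inb] > vn
    okSub <- ok[inb]
    okSub[!cmp] <- FALSE
    ok[inb] <- okSub
  }
  cand[ok, , drop = FALSE]
}

# trilinear interpolation of vol at um coordinates (m x 3); voxel centers at
# (index - 1) * voxelSize; outside samples return `outside`
trilinear <- function(vol, posUm, voxelSize, outside = NA_real_) {
  d <- dim(vol)
  g <- sweep(matrix(posUm, ncol = 3L), 2L, voxelSize, "/") + 1
  i0 <- floor(g)
  # samples exactly on the upper grid face belong to the last cell
  for (ax in 1:3) {
    hit <- i0[, ax] == d[ax] & g[, ax] <= d[ax] + 1e-9
    i0[hit, ax] <- d[ax] - 1L
  }
  f <- g - i0
  val <- rep(0, nrow(g))
  ok <- rep(TRUE, nrow(g))
  for (ax in 1:3) ok <- ok & i0[, ax] >= 1 & i0[, ax] + 1 <= d[ax]
  idx <- function(di) {
    ii <- i0[ok, , drop = FALSE] +
      matrix(di, sum(ok), 3L, byrow = TRUE)
    vol[cbind(ii[, 1L], ii[, 2L], ii[, 3L])]
  }
  if (any(ok)) {
    fx <- f[ok, 1L]; fy <- f[ok, 2L]; fz <- f[ok, 3L]
    acc <- rep(0, sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      acc <- acc + w * idx(c(dx, dy, dz))
    }
    val[ok] <- acc
  }
  val[!ok] <- outside
  val
}

umToVoxel <- function(posUm, voxelSize)
  sweep(matrix(posUm, ncol = 3L), 2L, voxelSize, "/") + 1

voxelToUm <- function(idx, voxelSize)
  sweep(matrix(idx, ncol = 3L) - 1, 2L, voxelSize, "*")
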