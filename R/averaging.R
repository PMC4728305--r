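# Polarity-aligned 3D averaging of BB subvolumes, Gaussian linescan fits
# and fiducial-based channel registration.

#' Polarity-aligned average volume
#'
#' @slot grid 3D numeric array of mean intensities; odd dimensions so a
#'   centre voxel exists; axis 1 is the anteroposterior (x) axis of the
#'   canonical cell frame.
#' @slot n number of contributing subvolumes.
#' @slot stepUm isotropic sampling step (um).
#' @slot channel channel name.
#' @export
setClass("AverageVolume",
  representation(grid = "array", n = "integer", stepUm = "numeric",
                 channel = "character"),
  validity = function(object) {
    if (any(dim(object@grid) %% 2L == 0L))
      return("grid dimensions must be odd")
    if (object@n < 1L) return("n must be >= 1")
    TRUE
  })

# orthonormal frame at BB p: x along the cell axis, z along the outward
# surface normal (radial direction), y completing the right-handed triad
bbFrame <- function(p, axis, mid) {
  rad <- p - mid
  rad <- rad - sum(rad * axis) * axis
  ln <- sqrt(sum(rad^2))
  if (ln < 1e-9) return(NULL)
  ez <- rad / ln
  ey <- cross3(ez, axis)
  list(ex = axis, ey = ey, ez = ez)
}

#' Extract oriented cubic subvolumes around selected BBs
#'
#' Resamples a cube about each selected BB with the cube's x axis along
#' the cell's anteroposterior axis and its azimuthal orientation fixed by
#' the local outward surface normal, using trilinear interpolation.
#' Subvolumes clipped by the stack border are dropped and counted.
#'
#' @param stack the cropped \linkS4class{ImageStack} (stack frame).
#' @param cellModel the (unrotated) \linkS4class{CellModel} for that stack.
#' @param selection BB indices to extract; default all BBs in the medial
#'   longitudinal quadrants (II and III).
#' @param sizeUm cube edge length (um); >= 3 um keeps neighbour peaks in
#'   view.
#' @param stepUm isotropic sampling step (um).
#' @param channel channel index or name.
#' @return list: \code{subvolumes} (list of 3D arrays), \code{nDropped},
#'   \code{stepUm}, \code{channel}.
#' @export
extractSubvolumes <- function(stack, cellModel, selection = NULL,
                              sizeUm = 4, stepUm = 0.2, channel = 1L) {
  vol <- voxelData(stack, channel)
  vs <- voxelSize(stack)
  if (is.null(selection)) {
    canon <- rotateToAxis(cellModel)
    dom <- assignDomains(canon)
    selection <- which(dom$quadrant %in% c("II", "III"))
  }
  if (!length(selection)) stop("no BBs selected")
  pos <- bbPositions(cellModel)
  mid <- (cellModel@poleAnterior + cellModel@polePosterior) / 2
  h <- floor(sizeUm / 2 / stepUm)
  s <- seq(-h, h) * stepUm
  grid <- as.matrix(expand.grid(sx = s, sy = s, sz = s))
  subs <- list()
  dropped <- 0L
  for (i in selection) {
    fr <- bbFrame(pos[i, ], cellModel@axis, mid)
    if (is.null(fr)) { dropped <- dropped + 1L; next }
    world <- sweep(grid[, 1L, drop = FALSE] %*% rbind(fr$ex) +
                     grid[, 2L, drop = FALSE] %*% rbind(fr$ey) +
                     grid[, 3L, drop = FALSE] %*% rbind(fr$ez),
                   2L, pos[i, ], "+")
    v <- trilinear(vol, world, vs, outside = NA_real_)
    if (anyNA(v)) { dropped <- dropped + 1L; next }
    subs[[length(subs) + 1L]] <- array(v, rep(2L * h + 1L, 3L))
  }
  if (!length(subs)) stop("no usable subvolume: all clipped or degenerate")
  list(subvolumes = subs, nDropped = dropped, stepUm = stepUm,
       channel = as.character(channel))
}

#' Voxelwise mean of subvolumes
#'
#' @param subvolumes result of \code{\link{extractSubvolumes}} or a list of
#'   identically shaped 3D arrays.
#' @param stepUm,channel sampling metadata when a bare list is given.
#' @return an \linkS4class{AverageVolume}.
#' @export
averageVolumes <- function(subvolumes, stepUm = NULL, channel = "ch") {
  if (is.list(subvolumes) && !is.null(subvolumes$subvolumes)) {
    stepUm <- subvolumes$stepUm
    channel <- subvolumes$channel
    subvolumes <- subvolumes$subvolumes
  }
  stopifnot(length(subvolumes) >= 1L)
  d <- dim(subvolumes[[1L]])
  for (s in subvolumes)
    if (!identical(dim(s), d)) stop("subvolume shape mismatch")
  acc <- Reduce(`+`, subvolumes) / length(subvolumes)
  new("AverageVolume", grid = acc, n = length(subvolumes),
      stepUm = as.numeric(stepUm), channel = as.character(channel))
}

refinePeak <- function(y, i) {
  # 3-point parabola around index i; returns fractional index
  if (i <= 1L || i >= length(y)) return(i)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(i)
  i + 0.5 * (y[i - 1L] - y[i + 1L]) / denom
}

#' Gaussian fit of the central linescan of an average volume
#'
#' The linescan is the central x row of the maximum z projection of the
#' average cube.  The nine central points are fit to a Gaussian with
#' offset; flanking (neighbour) peaks are detected on the full profile and
#' their centre-to-centre distances to the central peak reported.
#'
#' @param avg an \linkS4class{AverageVolume}.
#' @param nFit number of central points entering the fit (9, the
#'   reporting convention).
#' @return list: \code{converged}, \code{amplitude}, \code{centerUm},
#'   \code{sigmaUm}, \code{offset}, \code{r2}, \code{peakSpacingsUm},
#'   \code{profile}, \code{xUm}.
#' @export
linescanFit <- function(avg, nFit = 9L) {
  g <- avg@grid
  d <- dim(g)
  proj <- apply(g, c(1L, 2L), max)          # max projection along z
  prof <- proj[, (d[2L] + 1L) %/% 2L]       # central x row
  ctr <- (d[1L] + 1L) %/% 2L
  xUm <- (seq_len(d[1L]) - ctr) * avg@stepUm
  half <- (nFit - 1L) %/% 2L
  sel <- (ctr - half):(ctr + half)
  df <- data.frame(x = xUm[sel], y = prof[sel])
  model <- function(p, x) p[1L] * exp(-(x - p[2L])^2 / (2 * p[3L]^2)) + p[4L]
  start <- c(max(df$y) - min(df$y), 0,
             max(avg@stepUm, diff(range(df$x)) / 6), min(df$y))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) df$y - model(p, df$x),
                       control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(e) NULL)
  out <- list(converged = FALSE, amplitude = NA_real_, centerUm = NA_real_,
              sigmaUm = NA_real_, offset = NA_real_, r2 = NA_real_,
              peakSpacingsUm = numeric(0), profile = prof, xUm = xUm)
  if (!is.null(fit) && fit$info %in% 1:4) {
    cf <- fit$par
    ssres <- sum(fit$fvec^2)
    sstot <- sum((df$y - mean(df$y))^2)
    if (cf[1L] > 0 && sstot > 0) {
      out$converged <- TRUE
      out$amplitude <- cf[1L]; out$centerUm <- cf[2L]
      out$sigmaUm <- abs(cf[3L]); out$offset <- cf[4L]
      out$r2 <- 1 - ssres / sstot
    }
  }
  # flanking peaks: local maxima of the full profile outside the fit core,
  # with a prominence floor so sampling ripples are not called peaks
  isPk <- which(diff(sign(diff(prof))) == -2) + 1L
  isPk <- isPk[abs(xUm[isPk]) > max(abs(df$x))]
  floorVal <- min(prof) + 0.2 * (prof[ctr] - min(prof))
  isPk <- isPk[prof[isPk] >= floorVal]
  if (length(isPk)) {
    centre <- if (out$converged) out$centerUm else 0
    pk <- vapply(isPk, function(i)
      (refinePeak(prof, i) - ctr) * avg@stepUm, numeric(1))
    out$peakSpacingsUm <- abs(pk - centre)
  }
  out
}

fiducialCentroid <- function(g, stepUm) {
  # intensity-weighted centroid of the bright fiducial core (above half
  # maximum after offset subtraction); sub-step accurate for peaked marks
  g0 <- g - min(g)
  thr <- 0.5 * max(g0)
  w <- g0 * (g0 >= thr)
  if (sum(w) <= 0) stop("fiducial mark ambiguous: no signal above half maximum")
  d <- dim(g)
  ix <- slice.index(w, 1L); iy <- slice.index(w, 2L); iz <- slice.index(w, 3L)
  (c(sum(w * ix), sum(w * iy), sum(w * iz)) / sum(w) - 1) * stepUm
}

#' Register two datasets on a common fiducial channel
#'
#' Finds the rigid translation aligning dataset B's fiducial average to
#' dataset A's (intensity centroid of the fiducial core, sub-step
#' accurate) and applies the same translation to B's other channel,
#' producing one composite multi-channel average.  Both datasets are
#' already in the canonical cell frame, so rotation is not searched.
#'
#' @param avgAFiducial,avgAOther dataset A \linkS4class{AverageVolume}s.
#' @param avgBFiducial,avgBOther dataset B \linkS4class{AverageVolume}s on
#'   the same grid geometry.
#' @return list: \code{shiftUm} (numeric(3), displacement of B's fiducial
#'   relative to A's; B is translated by its negative), \code{composite}
#'   (named list of 3D arrays: fiducial, otherA, otherB).
#' @export
registerChannels <- function(avgAFiducial, avgAOther, avgBFiducial,
                             avgBOther) {
  A <- avgAFiducial@grid; B <- avgBFiducial@grid
  if (!identical(dim(A), dim(B))) stop("fiducial grids differ in shape")
  step <- avgAFiducial@stepUm
  shiftUm <- fiducialCentroid(B, step) - fiducialCentroid(A, step)
  shiftGrid <- function(g) {
    n <- dim(g)
    coords <- as.matrix(expand.grid(x = seq_len(n[1L]), y = seq_len(n[2L]),
                                    z = seq_len(n[3L])))
    src <- sweep((coords - 1) * step, 2L, shiftUm, "+")
    array(trilinear(g, src, rep(step, 3L), outside = 0), n)
  }
  list(shiftUm = shiftUm,
       composite = list(fiducial = A, otherA = avgAOther@grid,
                        otherB = shiftGrid(avgBOther@grid)))
}
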