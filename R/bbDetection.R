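# Identify individual BBs in 3D despite depth-dependent attenuation.
# Fixed stage order: local maxima -> depth-adaptive intensity threshold ->
# convex-hull interior filter -> skew/kurtosis oral-apparatus filter.
# Each stage only removes points.

#' Find 3D local intensity maxima
#'
#' The stack's marker channel is smoothed with a small Gaussian
#' (\code{detect_sigma_um}) and a voxel is a maximum iff its smoothed
#' intensity is >= every voxel within the anisotropic ellipsoidal search
#' neighbourhood (\code{maxima_xy_um} laterally, \code{maxima_z_um}
#' axially — the approximate dimensions of a single BB).  Plateau ties keep
#' the lexicographically smallest coordinate.  No intensity cut is applied
#' here: with no background subtraction the list deliberately oversamples
#' noise peaks, which the adaptive threshold removes next.
#'
#' @param stack cropped single-cell \linkS4class{ImageStack}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param channel marker channel.
#' @return data.frame: voxel indices \code{ix, iy, iz}, positions
#'   \code{x, y, z} (um, stack frame), smoothed \code{peak} intensity,
#'   \code{accepted}, \code{reason}.
#' @export
findMaxima <- function(stack, cfg = pipelineConfig(), channel = 1L) {
  vs <- voxelSize(stack)
  vol <- voxelData(stack, channel)
  sm <- gaussianSmooth(vol, cfg$detect_sigma_um / vs)
  idx <- localMaxima3d(sm, c(cfg$maxima_xy_um, cfg$maxima_xy_um,
                             cfg$maxima_z_um), vs)
  um <- voxelToUm(idx, vs)
  data.frame(ix = idx[, 1L], iy = idx[, 2L], iz = idx[, 3L],
             x = um[, 1L], y = um[, 2L], z = um[, 3L],
             peak = sm[idx], accepted = NA, reason = "none",
             stringsAsFactors = FALSE)
}

#' Depth-adaptive intensity threshold
#'
#' For each z plane the intensities of all maxima within a rolling window
#' of total depth \code{rolling_z_um} (symmetric about the plane) give
#' I_avg, I_sd and I_cv = I_sd / I_avg; a maximum is accepted iff its peak
#' exceeds \code{((S - I_cv * S) * I_sd) + I_avg} with sensitivity S
#' (default 6).  The multiplier is clamped at zero when I_cv > 1 so the
#' threshold never drops below the window mean.  The threshold adapts in z,
#' which keeps dim far-surface BBs above threshold despite attenuation.
#'
#' @param maxima data.frame from \code{\link{findMaxima}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return the data.frame with \code{accepted}, \code{threshold} filled;
#'   rejected rows get reason "noise".
#' @export
adaptiveThreshold <- function(maxima, cfg = pipelineConfig()) {
  if (nrow(maxima) < 2L) stop("need at least 2 maxima")
  half <- cfg$rolling_z_um / 2
  zs <- sort(unique(maxima$z))
  thr <- numeric(nrow(maxima))
  for (z in zs) {
    win <- abs(maxima$z - z) <= half
    ints <- maxima$peak[win]
    if (length(ints) < 2L) {
      warning("adaptive threshold window with < 2 maxima at z = ", z,
              "; falling back to whole-stack statistics")
      ints <- maxima$peak
    }
    avg <- mean(ints); s <- sd(ints); cv <- if (avg > 0) s / avg else 0
    mult <- max(0, cfg$sensitivity - cv * cfg$sensitivity)
    thr[maxima$z == z] <- mult * s + avg
  }
  maxima$threshold <- thr
  maxima$accepted <- maxima$peak > thr
  maxima$reason[!maxima$accepted] <- "noise"
  maxima
}

#' Remove interior maxima with a convex-hull depth cut
#'
#' Builds the 3D convex hull of the accepted maxima and deletes every
#' maximum farther than \code{interior_depth_um} from the hull surface
#' (exact point-to-facet distances).  Cortical BBs sit on the hull;
#' internalized BBs fall deep inside it.
#'
#' @param maxima data.frame with accepted flags filled.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return the data.frame; interior rows flagged with reason "interior".
#' @export
removeInterior <- function(maxima, cfg = pipelineConfig()) {
  acc <- which(maxima$accepted)
  if (length(acc) < 4L) return(maxima)
  pts <- as.matrix(maxima[acc, c("x", "y", "z")])
  hull <- tryCatch(convexHull3d(pts), error = function(e) {
    warning("degenerate point set, interior filter skipped: ",
            conditionMessage(e))
    NULL
  })
  if (is.null(hull)) return(maxima)
  d <- pointsHullDistance(pts, pts, hull)
  interior <- d > cfg$interior_depth_um
  maxima$accepted[acc[interior]] <- FALSE
  maxima$reason[acc[interior]] <- "interior"
  maxima$hullDistUm <- NA_real_
  maxima$hullDistUm[acc] <- d
  maxima
}

sampleMoments <- function(x) {
  # bias-uncorrected moment skewness and excess kurtosis (histogram-style)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(skew = NaN, kurt = NaN))
  c(skew = mean((x - m)^3) / m2^1.5, kurt = mean((x - m)^4) / m2^2 - 3)
}

#' Separate cortical from oral-apparatus maxima by box statistics
#'
#' A box of area \code{shape_box_um2} is centred over each accepted maximum
#' on its z plane; sample skewness and excess kurtosis of the pixel
#' histogram are computed on the mean-subtracted plane.  Cortical BBs are
#' isolated Gaussian peaks on dark background (both statistics positive);
#' OA maxima sit on a homogeneous bright plateau (negative).  A maximum is
#' moved to the OA set iff skew + kurtosis < \code{skewkurt_cutoff};
#' degenerate uniform boxes are treated as OA and flagged.
#'
#' @param maxima data.frame with accepted flags filled.
#' @param stack the cropped \linkS4class{ImageStack} (raw intensities).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param channel marker channel.
#' @return the data.frame with \code{skew}, \code{kurt}, \code{boxClipped};
#'   OA rows keep accepted = FALSE with reason "oral_apparatus".
#' @export
classifyOralApparatus <- function(maxima, stack, cfg = pipelineConfig(),
                                  channel = 1L) {
  vs <- voxelSize(stack)
  vol <- voxelData(stack, channel)
  d <- dim(vol)
  halfPx <- pmax(1L, round(sqrt(cfg$shape_box_um2) / 2 / vs[1:2]))
  maxima$skew <- NA_real_; maxima$kurt <- NA_real_
  maxima$boxClipped <- FALSE
  planeMeans <- vapply(seq_len(d[3L]), function(z) mean(vol[, , z]),
                       numeric(1))
  for (i in which(maxima$accepted)) {
    x0 <- maxima$ix[i] - halfPx[1L]; x1 <- maxima$ix[i] + halfPx[1L]
    y0 <- maxima$iy[i] - halfPx[2L]; y1 <- maxima$iy[i] + halfPx[2L]
    clipped <- x0 < 1L || y0 < 1L || x1 > d[1L] || y1 > d[2L]
    box <- vol[max(1L, x0):min(d[1L], x1), max(1L, y0):min(d[2L], y1),
               maxima$iz[i]] - planeMeans[maxima$iz[i]]
    mom <- sampleMoments(as.numeric(box))
    maxima$skew[i] <- mom[1L]; maxima$kurt[i] <- mom[2L]
    maxima$boxClipped[i] <- clipped
    sk <- mom[1L] + mom[2L]
    if (is.nan(sk) || sk < cfg$skewkurt_cutoff) {
      maxima$accepted[i] <- FALSE
      maxima$reason[i] <- "oral_apparatus"
    }
  }
  maxima
}

#' Measure per-channel BB intensities
#'
#' Zero-mean Gaussian-weighted (matched-filter) contrast in a sphere of
#' radius \code{intensity_radius_um} at each position.  The anisotropic
#' weights (\code{intensity_sigma_xy_um}, \code{intensity_sigma_z_um})
#' match a diffraction-limited spot; the filter is orthogonalized against
#' constant and linear terms over the aperture, so any additive local
#' background and any background ramp (camera offset, diffuse cytoplasmic
#' stain falling off at the cell edge, depth attenuation) cancel to first
#' order, which keeps intensity ratios between neighbouring BBs usable at
#' realistic photon counts.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param positions n x 3 matrix (um, stack frame).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return n x nchannel matrix with channel names.
#' @export
measureBBIntensities <- function(stack, positions, cfg = pipelineConfig()) {
  vs <- voxelSize(stack)
  r <- cfg$intensity_radius_um
  ro <- floor(r / vs)
  offs <- as.matrix(expand.grid(dx = -ro[1L]:ro[1L], dy = -ro[2L]:ro[2L],
                                dz = -ro[3L]:ro[3L]))
  offsUm <- sweep(offs, 2L, vs, "*")
  keep <- rowSums(offsUm^2) <= r^2
  sig <- c(cfg$intensity_sigma_xy_um, cfg$intensity_sigma_xy_um,
           cfg$intensity_sigma_z_um)
  w <- exp(-rowSums(sweep(offsUm^2, 2L, 2 * sig^2, "/")))[keep]
  offs <- offs[keep, , drop = FALSE]
  d <- dim(stack@voxels)
  nch <- d[4L]
  positions <- matrix(positions, ncol = 3L)
  ctrIdx <- round(sweep(positions, 2L, vs, "/")) + 1L
  out <- matrix(NA_real_, nrow(positions), nch,
                dimnames = list(NULL, paste0("intensity_",
                                             stack@channelNames)))
  offsUmK <- offsUm[keep, , drop = FALSE]
  orthogonalize <- function(sel) {
    B <- cbind(1, offsUmK[sel, , drop = FALSE])
    ws <- w[sel]
    wperp <- ws - B %*% qr.solve(crossprod(B), crossprod(B, ws))
    drop(wperp)
  }
  wperpFull <- orthogonalize(rep(TRUE, nrow(offs)))
  for (ch in seq_len(nch)) {
    vol <- stack@voxels[, , , ch, drop = TRUE]
    for (i in seq_len(nrow(positions))) {
      ii <- sweep(offs, 2L, ctrIdx[i, ], "+")
      ok <- ii[, 1L] >= 1 & ii[, 1L] <= d[1L] & ii[, 2L] >= 1 &
        ii[, 2L] <= d[2L] & ii[, 3L] >= 1 & ii[, 3L] <= d[3L]
      v <- vol[ii[ok, , drop = FALSE]]
      wperp <- if (all(ok)) wperpFull else orthogonalize(ok)
      out[i, ch] <- sum(wperp * v) / sum(wperp * w[ok])
    }
  }
  out
}

#' Full detection stage on a cropped stack
#'
#' Runs maxima search, adaptive threshold, interior filter and OA filter in
#' their fixed order and reports stage-by-stage counts.
#'
#' @param stack cropped single-cell \linkS4class{ImageStack}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param verbose log per-stage input/output counts.
#' @return list: \code{bbs} (data.frame of cortical BBs with per-channel
#'   intensities), \code{oa} (data.frame of OA-classified maxima),
#'   \code{audit} (every maximum with flags and thresholds).
#' @export
detectBBs <- function(stack, cfg = pipelineConfig(), verbose = FALSE) {
  mx <- findMaxima(stack, cfg)
  n0 <- nrow(mx)
  mx <- adaptiveThreshold(mx, cfg)
  n1 <- sum(mx$accepted)
  mx <- removeInterior(mx, cfg)
  n2 <- sum(mx$accepted)
  mx <- classifyOralApparatus(mx, stack, cfg)
  n3 <- sum(mx$accepted)
  if (verbose)
    message(sprintf(
      "maxima %d -> threshold %d -> interior %d -> cortical %d (OA %d)",
      n0, n1, n2, n3, sum(mx$reason == "oral_apparatus")))
  bbs <- mx[mx$accepted, c("x", "y", "z", "peak", "skew", "kurt")]
  rownames(bbs) <- NULL
  ints <- measureBBIntensities(stack, as.matrix(bbs[, c("x", "y", "z")]), cfg)
  bbs <- cbind(bbs, as.data.frame(ints))
  oa <- mx[mx$reason == "oral_apparatus", c("x", "y", "z", "peak")]
  rownames(oa) <- NULL
  list(bbs = bbs, oa = oa, audit = mx)
}
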