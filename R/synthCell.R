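# Ground-truthed synthetic Tetrahymena-like cells.  The cell is a prolate
# ellipsoid; ciliary rows are meridians at equal azimuthal offsets so
# within-row arc-length integration stays closed-form-checkable, and every
# anterior partner lies exactly in the plane through the BB and the two
# poles (the analytic zero-deviation limit).

#' Synthetic cell specification
#'
#' Builds a \linkS4class{CellSpec}.  Defaults describe a mid-cycle
#' \emph{Tetrahymena}: a 40 x 22 um prolate cell bearing 20 longitudinal
#' rows whose spacing tightens toward the anterior (1.0 um) and relaxes
#' toward the posterior (1.8 um), a dense anterior-ventral oral apparatus
#' of 150 BBs near the diffraction limit on a bright homogeneous plateau,
#' exponential depth attenuation that leaves the far surface at ~35% of the
#' near surface, and mixed Poisson/Gaussian camera noise.
#'
#' @param semiAxes ellipsoid semi-axes (um); x is the anteroposterior axis.
#' @param nRows number of ciliary rows.
#' @param spacingProfile function of normalized axial position (0 anterior,
#'   1 posterior) returning within-row spacing in um.
#' @param capAngleDeg polar angle left bare at each apex (rows converge and
#'   stop short of the tips).
#' @param oaCenter c(azimuth deg, normalized axial position) of the OA.
#' @param oaBBCount,oaSpacing oral-apparatus spot count and lateral spacing.
#' @param noiseModel c(Gaussian read-noise sd, Poisson photon scale).
#' @param attenuationCoeff fractional intensity loss per um of depth.
#' @param psfSigma Gaussian PSF sigma per axis (um).
#' @param voxelSize voxel size per axis (um).
#' @param amplitude mean spot amplitude per channel (centrin, poc1).
#' @param amplitudeCv fractional sd of per-BB amplitude variation.
#' @param background camera offset.
#' @param oaPlateau amplitude of the homogeneous OA plateau.
#' @param cytoplasm amplitude of the diffuse cytoplasmic stain filling the
#'   cell body.
#' @param seed integer seed for all generator randomness.
#' @return a \linkS4class{CellSpec}.
#' @examples
#' spec <- cellSpec(seed = 7)
#' gt <- placeBasalBodies(spec)
#' nrow(bbPositions(gt))
#' @export
cellSpec <- function(semiAxes = c(20, 11, 11),
                     nRows = 20L,
                     spacingProfile = function(u) 1.1 + 0.7 * u,
                     capAngleDeg = 13,
                     oaCenter = c(0, 0.15),
                     oaBBCount = 150L,
                     oaSpacing = 0.30,
                     noiseModel = c(6, 1),
                     attenuationCoeff = 0.051,
                     psfSigma = c(0.12, 0.12, 0.25),
                     voxelSize = c(0.125, 0.125, 0.30),
                     amplitude = c(1100, 1000),
                     amplitudeCv = 0.12,
                     background = 100,
                     oaPlateau = 500,
                     cytoplasm = 80,
                     seed = 1L) {
  new("CellSpec", semiAxes = as.numeric(semiAxes), nRows = as.integer(nRows),
      spacingProfile = spacingProfile, capAngleDeg = as.numeric(capAngleDeg),
      oaCenter = as.numeric(oaCenter), oaBBCount = as.integer(oaBBCount),
      oaSpacing = as.numeric(oaSpacing), noiseModel = as.numeric(noiseModel),
      attenuationCoeff = as.numeric(attenuationCoeff),
      psfSigma = as.numeric(psfSigma), voxelSize = as.numeric(voxelSize),
      amplitude = as.numeric(amplitude), amplitudeCv = as.numeric(amplitudeCv),
      background = as.numeric(background), oaPlateau = as.numeric(oaPlateau),
      cytoplasm = as.numeric(cytoplasm), seed = as.integer(seed))
}

stackMarginUm <- 2.5

cellCenterUm <- function(spec) spec@semiAxes + stackMarginUm

# ellipsoid surface point at polar angle theta (from the anterior apex,
# which sits at +x) and azimuth phi
ellipsoidPoint <- function(spec, theta, phi) {
  ctr <- cellCenterUm(spec)
  cbind(ctr[1L] + spec@semiAxes[1L] * cos(theta),
        ctr[2L] + spec@semiAxes[2L] * sin(theta) * cos(phi),
        ctr[3L] + spec@semiAxes[3L] * sin(theta) * sin(phi))
}

# meridian arc-length stations obeying the spacing profile; shared by all
# rows so rings are axially aligned
rowStations <- function(spec) {
  th0 <- spec@capAngleDeg * pi / 180
  thGrid <- seq(th0, pi - th0, length.out = 4096L)
  a <- spec@semiAxes[1L]; b <- spec@semiAxes[2L]
  dsdth <- sqrt(a^2 * sin(thGrid)^2 + b^2 * cos(thGrid)^2)
  arc <- c(0, cumsum((dsdth[-1L] + dsdth[-length(dsdth)]) / 2 * diff(thGrid)))
  total <- arc[length(arc)]
  stations <- numeric(0)
  s <- 0
  repeat {
    th <- stats::approx(arc, thGrid, xout = s, rule = 2L)$y
    stations <- c(stations, th)
    u <- (1 - cos(th)) / 2
    s <- s + spec@spacingProfile(u)
    if (s > total) break
  }
  if (length(stations) < 3L)
    stop("spacing profile too large: a row would hold fewer than 3 BBs")
  stations
}

#' Place basal bodies on a synthetic cell surface
#'
#' Rows are meridians of the ellipsoid at equal azimuthal offsets; within
#' each row, spacing follows the spec's profile integrated along the
#' meridian arc.  The oral apparatus is a sunflower-packed surface patch at
#' the spec's OA centre with inter-spot spacing near the diffraction limit.
#' Deterministic given the spec's seed.
#'
#' @param spec a \linkS4class{CellSpec}.
#' @return a \linkS4class{GroundTruth}.
#' @export
placeBasalBodies <- function(spec) {
  validObject(spec)
  withr::with_seed(spec@seed, {
    stations <- rowStations(spec)
    k <- length(stations)
    phis <- 2 * pi * (seq_len(spec@nRows) - 1L) / spec@nRows
    pos <- do.call(rbind, lapply(phis, function(phi)
      ellipsoidPoint(spec, stations, phi)))
    rowId <- rep(seq_len(spec@nRows), each = k)
    orderInRow <- rep(seq_len(k), times = spec@nRows)
    n <- nrow(pos)

    ctr <- cellCenterUm(spec)
    poleA <- ctr + c(spec@semiAxes[1L], 0, 0)
    poleP <- ctr - c(spec@semiAxes[1L], 0, 0)

    # oral apparatus: sunflower spiral in the tangent plane, projected back
    # onto the ellipsoid surface
    thOA <- acos(1 - 2 * spec@oaCenter[2L])
    phiOA <- spec@oaCenter[1L] * pi / 180
    oaC <- drop(ellipsoidPoint(spec, thOA, phiOA))
    nrm <- (oaC - ctr) / spec@semiAxes^2
    nrm <- nrm / sqrt(sum(nrm^2))
    t1 <- cross3(nrm, c(1, 0, 0)); t1 <- t1 / sqrt(sum(t1^2))
    t2 <- cross3(nrm, t1)
    m <- spec@oaBBCount
    if (m > 0L) {
      Rpatch <- spec@oaSpacing * sqrt(m / pi)
      kk <- seq_len(m)
      rr <- Rpatch * sqrt((kk - 0.5) / m)
      aa <- kk * pi * (3 - sqrt(5))
      oaPts <- t(vapply(seq_len(m), function(i) {
        p <- oaC + rr[i] * cos(aa[i]) * t1 + rr[i] * sin(aa[i]) * t2
        rel <- (p - ctr) / spec@semiAxes
        drop(ctr + (p - ctr) / sqrt(sum(rel^2)))
      }, numeric(3L)))
    } else oaPts <- matrix(numeric(0), 0L, 3L)

    amp <- function(nn) vapply(spec@amplitude, function(a)
      pmax(0.3 * a, a * (1 + spec@amplitudeCv * rnorm(nn))), numeric(nn))
    ints <- amp(n)
    oaInts <- amp(m)

    new("GroundTruth", positions = pos, rowId = as.integer(rowId),
        orderInRow = as.integer(orderInRow), poleAnterior = poleA,
        polePosterior = poleP, oaPositions = oaPts, oaCentroid = oaC,
        intensities = ints, oaIntensities = oaInts,
        channelNames = c("centrin", "poc1"),
        daughterFlags = rep(FALSE, n),
        gapFlanks = matrix(integer(0), 0L, 2L), spec = spec)
  })
}

# recompute daughter flags from the half-intensity rule against the
# posterior row neighbour (channel 2)
daughterRule <- function(gt) {
  n <- nrow(gt@positions)
  flags <- rep(FALSE, n)
  for (r in unique(gt@rowId)) {
    idx <- which(gt@rowId == r)
    idx <- idx[order(gt@orderInRow[idx])]
    if (length(idx) < 2L) next
    a <- idx[-length(idx)]          # anterior member of each pair
    p <- idx[-1L]                   # its posterior neighbour
    flags[a] <- gt@intensities[a, 2L] < 0.5 * gt@intensities[p, 2L]
  }
  flags
}

#' Inject structured perturbations into a ground truth
#'
#' Models the mutant phenotypes the pipeline must detect: spacing gaps
#' larger than 3 um (runs of BBs deleted until the surviving flanking pair
#' exceeds the threshold), row disorientation (lateral jitter of stated
#' angular sd about the meridian plane), and daughter BBs (channel-2
#' intensity dimmed below half of the posterior neighbour's).
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param gapRate per-site probability of opening a spacing gap.
#' @param disorientSd angular jitter sd in degrees.
#' @param daughterRate fraction of eligible BBs dimmed into daughters.
#' @param seed integer seed.
#' @param gapUm minimum flanking distance of an injected gap (um).
#' @return a perturbed \linkS4class{GroundTruth}; \code{gapFlanks} holds
#'   the indices (into the returned positions) flanking each gap.
#' @export
injectPerturbations <- function(gt, gapRate = 0, disorientSd = 0,
                                daughterRate = 0, seed = gt@spec@seed + 1L,
                                gapUm = 3) {
  stopifnot(gapRate >= 0, gapRate <= 1, daughterRate >= 0, daughterRate <= 1,
            disorientSd >= 0)
  if (gapRate == 0 && disorientSd == 0 && daughterRate == 0) return(gt)
  withr::with_seed(as.integer(seed), {
    pos <- gt@positions
    rowId <- gt@rowId
    ord <- gt@orderInRow
    ints <- gt@intensities
    n <- nrow(pos)
    keep <- rep(TRUE, n)
    flankPairs <- list()

    if (gapRate > 0) {
      for (r in unique(rowId)) {
        idx <- which(rowId == r)
        idx <- idx[order(ord[idx])]
        k <- length(idx)
        if (k < 5L) next
        sites <- which(runif(k) < gapRate)
        sites <- sites[sites >= 2L & sites <= k - 2L]
        blocked <- rep(FALSE, k)
        for (s in sites) {
          if (blocked[s]) next
          e <- s
          while (e <= k - 1L &&
                 sqrt(sum((pos[idx[s - 1L], ] - pos[idx[e + 1L], ])^2)) <= gapUm)
            e <- e + 1L
          if (e > k - 1L || any(blocked[s:e]) || !keep[idx[s - 1L]]) next
          keep[idx[s:e]] <- FALSE
          blocked[max(1L, s - 1L):min(k, e + 1L)] <- TRUE
          flankPairs[[length(flankPairs) + 1L]] <- c(idx[s - 1L], idx[e + 1L])
        }
      }
    }

    if (disorientSd > 0) {
      ctr <- cellCenterUm(gt@spec)
      rel <- sweep(pos, 2L, ctr)
      # azimuthal unit vector: normal to the meridian plane through the axis
      lat <- cbind(0, -rel[, 3L], rel[, 2L])
      lnorm <- sqrt(rowSums(lat^2))
      ok <- lnorm > 1e-9
      lat[ok, ] <- lat[ok, ] / lnorm[ok]
      u <- (gt@poleAnterior[1L] - pos[, 1L]) /
        (gt@poleAnterior[1L] - gt@polePosterior[1L])
      s <- gt@spec@spacingProfile(pmin(pmax(u, 0), 1))
      disp <- s * tan(rnorm(n, 0, disorientSd * pi / 180))
      pos <- pos + lat * disp
    }

    if (daughterRate > 0) {
      for (r in unique(rowId)) {
        idx <- which(rowId == r & keep)
        idx <- idx[order(ord[idx])]
        k <- length(idx)
        if (k < 2L) next
        # walk posterior -> anterior so references are final intensities
        for (i in seq.int(k - 1L, 1L)) {
          if (runif(1) < daughterRate) {
            ratio <- runif(1, 2.3, 4.0)
            ints[idx[i], 2L] <- ints[idx[i + 1L], 2L] / ratio
          }
        }
      }
    }

    newIdx <- cumsum(keep)
    flanks <- if (length(flankPairs))
      matrix(newIdx[do.call(rbind, flankPairs)], ncol = 2L)
    else matrix(integer(0), 0L, 2L)
    out <- gt
    out@positions <- pos[keep, , drop = FALSE]
    out@rowId <- rowId[keep]
    out@intensities <- ints[keep, , drop = FALSE]
    out@gapFlanks <- flanks
    # re-rank within rows after deletions
    ordNew <- integer(sum(keep))
    for (r in unique(out@rowId)) {
      ii <- which(out@rowId == r)
      ordNew[ii] <- rank(ord[keep][ii])
    }
    out@orderInRow <- as.integer(ordNew)
    out@daughterFlags <- daughterRule(out)
    validObject(out)
    out
  })
}

# local Gaussian patch for one spot; the caller adds it in its own frame
# so the full volume is never copied per spot
gaussianPatch <- function(d, voxelSize, posUm, ampl, sigmaUm) {
  g <- posUm / voxelSize + 1
  rad <- ceiling(4 * sigmaUm / voxelSize)
  lo <- pmax(1L, floor(g - rad)); hi <- pmin(d, ceiling(g + rad))
  if (any(lo > hi)) return(NULL)
  gx <- exp(-((seq.int(lo[1L], hi[1L]) - g[1L]) * voxelSize[1L])^2 /
              (2 * sigmaUm[1L]^2))
  gy <- exp(-((seq.int(lo[2L], hi[2L]) - g[2L]) * voxelSize[2L])^2 /
              (2 * sigmaUm[2L]^2))
  gz <- exp(-((seq.int(lo[3L], hi[3L]) - g[3L]) * voxelSize[3L])^2 /
              (2 * sigmaUm[3L]^2))
  list(lo = lo, hi = hi, patch = ampl * outer(outer(gx, gy), gz))
}

#' Render a synthetic cell into a calibrated image stack
#'
#' Each BB becomes a 3D Gaussian of the spec's PSF sigma, multiplied by the
#' exponential depth attenuation \code{(1 - k)^z}; the oral apparatus is
#' rendered on top of a homogeneous super-Gaussian plateau; camera offset
#' plus Poisson/Gaussian noise is added last.  Both channels share one grid.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param spec the generating \linkS4class{CellSpec} (defaults to
#'   \code{gt@spec}).
#' @return an \linkS4class{ImageStack}.
#' @export
renderStack <- function(gt, spec = gt@spec) {
  extent <- 2 * spec@semiAxes + 2 * stackMarginUm
  d <- as.integer(ceiling(extent / spec@voxelSize)) + 1L
  atten <- function(zUm) (1 - spec@attenuationCoeff)^zUm
  nch <- length(spec@amplitude)
  vox <- array(0, c(d, nch))
  allPos <- rbind(gt@positions, gt@oaPositions)
  allInt <- rbind(gt@intensities, gt@oaIntensities)
  # diffuse cytoplasmic stain: soft-edged ellipsoid fill, depth-attenuated
  cyto <- NULL
  if (spec@cytoplasm > 0) {
    ctr <- cellCenterUm(spec)
    ex2 <- (((seq_len(d[1L]) - 1) * spec@voxelSize[1L] - ctr[1L]) /
              spec@semiAxes[1L])^2
    ey2 <- (((seq_len(d[2L]) - 1) * spec@voxelSize[2L] - ctr[2L]) /
              spec@semiAxes[2L])^2
    ez2 <- (((seq_len(d[3L]) - 1) * spec@voxelSize[3L] - ctr[3L]) /
              spec@semiAxes[3L])^2
    rho2 <- outer(outer(ex2, ey2, "+"), ez2, "+")
    zAtt <- atten((seq_len(d[3L]) - 1) * spec@voxelSize[3L])
    cyto <- spec@cytoplasm * exp(-rho2^8) *
      rep(zAtt, each = d[1L] * d[2L])
    dim(cyto) <- d
  }
  withr::with_seed(spec@seed + 7L, {
    for (ch in seq_len(nch)) {
      vol <- array(0, d)
      if (!is.null(cyto)) vol <- vol + cyto
      for (i in seq_len(nrow(allPos))) {
        p <- gaussianPatch(d, spec@voxelSize, allPos[i, ],
                           allInt[i, ch] * atten(allPos[i, 3L]),
                           spec@psfSigma)
        if (is.null(p)) next
        vol[p$lo[1L]:p$hi[1L], p$lo[2L]:p$hi[2L], p$lo[3L]:p$hi[3L]] <-
          vol[p$lo[1L]:p$hi[1L], p$lo[2L]:p$hi[2L], p$lo[3L]:p$hi[3L]] +
          p$patch
      }
      if (spec@oaPlateau > 0 && nrow(gt@oaPositions) > 0) {
        Rpatch <- spec@oaSpacing * sqrt(spec@oaBBCount / pi) + 0.5
        ctrOA <- gt@oaCentroid
        rad <- ceiling((Rpatch + 1) / spec@voxelSize)
        g <- ctrOA / spec@voxelSize + 1
        lo <- pmax(1L, floor(g - rad)); hi <- pmin(d, ceiling(g + rad))
        xs <- (seq.int(lo[1L], hi[1L]) - 1) * spec@voxelSize[1L] - ctrOA[1L]
        ys <- (seq.int(lo[2L], hi[2L]) - 1) * spec@voxelSize[2L] - ctrOA[2L]
        zs <- (seq.int(lo[3L], hi[3L]) - 1) * spec@voxelSize[3L] - ctrOA[3L]
        dd <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
        plateau <- spec@oaPlateau * exp(-(dd / Rpatch)^4) *
          atten(ctrOA[3L])
        vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <-
          vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] + plateau
      }
      vol <- vol + spec@background
      ps <- spec@noiseModel[2L]
      if (ps > 0) vol[] <- rpois(length(vol), pmax(vol, 0) * ps) / ps
      if (spec@noiseModel[1L] > 0)
        vol <- vol + rnorm(length(vol), 0, spec@noiseModel[1L])
      vox[, , , ch] <- pmax(vol, 0)
    }
  })
  new("ImageStack", voxels = vox, voxelSize = spec@voxelSize,
      channelNames = gt@channelNames)
}

#' Write a ground-truth table as CSV
#'
#' Columns: x_um, y_um, z_um, row_id, order_in_row, is_oa, is_daughter and
#' one intensity column per channel.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
  cortical <- data.frame(
    x_um = gt@positions[, 1L], y_um = gt@positions[, 2L],
    z_um = gt@positions[, 3L], row_id = gt@rowId,
    order_in_row = gt@orderInRow, is_oa = FALSE,
    is_daughter = gt@daughterFlags)
  oa <- data.frame(
    x_um = gt@oaPositions[, 1L], y_um = gt@oaPositions[, 2L],
    z_um = gt@oaPositions[, 3L], row_id = NA_integer_,
    order_in_row = NA_integer_, is_oa = TRUE, is_daughter = FALSE)
  ints <- rbind(gt@intensities, gt@oaIntensities)
  colnames(ints) <- paste0("intensity_", gt@channelNames)
  out <- cbind(rbind(cortical, oa), as.data.frame(ints))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
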