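# Locate one complete cell in a field and crop the stack to it.  The mask
# pipeline follows the published recipe: MIP -> subtract mean -> large
# Gaussian -> small LoG -> large Gaussian -> Triangle threshold -> shape
# filter -> keep the largest survivor.  "Radius" of the smoothing kernels
# is interpreted as the Gaussian sigma in um (recorded in the config so
# the mapping can be changed).

regionDescriptors <- function(pix, pixelSize) {
  # pix: k x 2 integer matrix of pixel coordinates (x, y)
  areaUm2 <- nrow(pix) * prod(pixelSize)
  ptsUm <- sweep(pix, 2L, pixelSize, "*")
  h <- grDevices::chull(ptsUm)
  hp <- ptsUm[h, , drop = FALSE]
  # perimeter of the convex polygonal contour; these cells are convex, and
  # the polygon avoids the pixel-staircase overestimate
  per <- sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1L), , drop = FALSE])^2)))
  feret <- if (nrow(hp) > 1) max(stats::dist(hp)) else 0
  circ <- if (per > 0) 4 * pi * areaUm2 / per^2 else 0
  list(areaUm2 = areaUm2, feretUm = feret, circularity = min(circ, 1),
       bbox = as.integer(c(range(pix[, 1L]), range(pix[, 2L]))))
}

#' Shape filter for segmented 2D objects
#'
#' Rejects objects larger than 2000 um^2 in area, with maximum Feret
#' diameter above 60 um, or with circularity (4 pi area / perimeter^2)
#' below 0.85; the reason names the first failing test.
#'
#' @param areaUm2,feretUm,circularity region descriptors.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with \code{keep} (logical) and \code{reason}
#'   ("area", "feret", "circularity" or "none").
#' @export
shapeFilter <- function(areaUm2, feretUm, circularity,
                        cfg = pipelineConfig()) {
  if (areaUm2 > cfg$area_max_um2) return(list(keep = FALSE, reason = "area"))
  if (feretUm > cfg$feret_max_um) return(list(keep = FALSE, reason = "feret"))
  if (circularity < cfg$circularity_min)
    return(list(keep = FALSE, reason = "circularity"))
  list(keep = TRUE, reason = "none")
}

#' Segment the cell of interest from a field
#'
#' Builds the binary cell mask from the BB-marker channel's maximum
#' intensity projection and returns the largest object surviving the shape
#' filter.
#'
#' @param stack an \linkS4class{ImageStack} (channel 1 is the BB marker).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param channel marker channel index.
#' @return a \linkS4class{CellMask}.
#' @export
makeCellMask <- function(stack, cfg = pipelineConfig(), channel = 1L) {
  px <- voxelSize(stack)[1:2]
  mip <- maxIntensityProject(voxelData(stack, channel))
  img <- mip - mean(mip)
  img <- gaussianSmooth(img, cfg$blur_large_um / px)
  # small-radius LoG applied as an edge-enhancing term: boundaries between
  # touching features are accentuated while the homogenized cell stays a
  # filled bright object for the histogram threshold
  img <- img + logFilter2d(img, cfg$log_radius_um / px)
  img <- gaussianSmooth(img, cfg$blur_large_um / px)
  thr <- triangleThreshold(img, nBins = cfg$triangle_bins)
  bin <- img > thr
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- EBImage::imageData(lab)
  nObj <- max(lab)
  if (nObj == 0L) stop("no cell found")
  survivors <- list()
  for (o in seq_len(nObj)) {
    pix <- which(lab == o, arr.ind = TRUE)
    desc <- regionDescriptors(pix, px)
    f <- shapeFilter(desc$areaUm2, desc$feretUm, desc$circularity, cfg)
    if (f$keep) survivors[[length(survivors) + 1L]] <- c(list(label = o), desc)
  }
  if (!length(survivors)) stop("no cell found")
  areas <- vapply(survivors, function(s) s$areaUm2, numeric(1))
  best <- survivors[[which.max(areas)]]
  new("CellMask", mask = lab == best$label, pixelSize = px,
      areaUm2 = best$areaUm2, feretUm = best$feretUm,
      circularity = best$circularity, bbox = best$bbox,
      nDiscarded = length(survivors) - 1L)
}

#' Crop a stack to a cell mask
#'
#' Dilates the mask by \code{mask_dilate_um} (disc structuring element) to
#' absorb mask irregularities, zeroes voxels outside it in every channel
#' and z plane, and crops to the dilated bounding box (clamped at image
#' bounds).  Calibration is preserved and the crop origin recorded.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param mask a \linkS4class{CellMask} from the same stack.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return the cropped \linkS4class{ImageStack}.
#' @export
cropToMask <- function(stack, mask, cfg = pipelineConfig()) {
  if (!any(mask@mask)) stop("empty mask")
  px <- mask@pixelSize
  radPx <- round(cfg$mask_dilate_um / px[1L])
  m <- mask@mask
  if (radPx > 0) {
    brush <- EBImage::makeBrush(2L * radPx + 1L, shape = "disc")
    m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), brush)) > 0
  }
  pix <- which(m, arr.ind = TRUE)
  x0 <- max(1L, min(pix[, 1L])); x1 <- min(nrow(m), max(pix[, 1L]))
  y0 <- max(1L, min(pix[, 2L])); y1 <- min(ncol(m), max(pix[, 2L]))
  v <- stack@voxels
  d <- dim(v)
  mArr <- array(rep(m, d[3L] * d[4L]), dim = d)
  v <- v * mArr
  v <- v[x0:x1, y0:y1, , , drop = FALSE]
  new("ImageStack", voxels = v, voxelSize = stack@voxelSize,
      channelNames = stack@channelNames,
      originUm = stack@originUm +
        c((x0 - 1L) * px[1L], (y0 - 1L) * px[2L], 0))
}
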