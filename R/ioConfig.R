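# Stack i/o, pipeline configuration and result tables.  The tiff package
# cannot carry arbitrary metadata tags, so calibration travels in a JSON
# sidecar (<stem>.json) written next to every stack; intensities are scaled
# to [0,1] float32 pages with the scale factor recorded in the sidecar.

#' Pipeline configuration
#'
#' Flat key-value list of every tunable, with defaults at the published
#' values.  All lengths are micrometres.
#'
#' @param path optional JSON file whose entries override the defaults.
#' @param ... further named overrides (applied after the file).
#' @return a named list of class \code{ciliarrayConfig}.
#' @details Defaults: \code{blur_large_um} 1.0 and \code{log_radius_um} 0.12
#'  (cell-mask smoothing and Laplacian-of-Gaussian scales),
#'  \code{detect_sigma_um} 0.12 (spot pre-smoothing),
#'  \code{maxima_xy_um} 0.25 / \code{maxima_z_um} 0.6 (local-maxima search
#'  radii), \code{rolling_z_um} 1.5 (adaptive-threshold window),
#'  \code{sensitivity} 6 (adaptive-threshold multiplier),
#'  \code{interior_depth_um} 2.25 (convex-hull interior cut),
#'  \code{shape_box_um2} 1.0 and \code{skewkurt_cutoff} 1.0 (oral-apparatus
#'  discrimination), \code{mask_dilate_um} 5.0 (mask enlargement),
#'  \code{area_max_um2} 2000, \code{feret_max_um} 60,
#'  \code{circularity_min} 0.85 (cell shape filter),
#'  \code{fallback_link_um} 5.0 (row-linking fallback cutoff),
#'  \code{gap_um} 3.0 (large-gap threshold), \code{close_um} 1.0
#'  (close-pair threshold), \code{daughter_ratio} 2.0 (mother/daughter
#'  intensity cutoff), \code{pole_sphere_um} 5.0 (polarity integration
#'  radius), \code{intensity_radius_um} 0.5 (per-BB intensity aperture),
#'  \code{plane_weight} 1.0 (row-metric plane term weight),
#'  \code{triangle_bins} 256 (threshold histogram bins).
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    blur_large_um = 1.0, log_radius_um = 0.12, detect_sigma_um = 0.12,
    maxima_xy_um = 0.25, maxima_z_um = 0.6, rolling_z_um = 1.5,
    sensitivity = 6, interior_depth_um = 2.25, shape_box_um2 = 1.0,
    skewkurt_cutoff = 1.0, mask_dilate_um = 5.0, area_max_um2 = 2000,
    feret_max_um = 60, circularity_min = 0.85, fallback_link_um = 5.0,
    gap_um = 3.0, close_um = 1.0, daughter_ratio = 2.0,
    pole_sphere_um = 5.0, intensity_radius_um = 0.5,
    intensity_sigma_xy_um = 0.15, intensity_sigma_z_um = 0.30,
    plane_weight = 1.0, triangle_bins = 256L)
  if (!is.null(path)) {
    over <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  lens <- grep("_um$|_um2$", names(cfg), value = TRUE)
  if (any(unlist(cfg[lens]) <= 0)) stop("all lengths must be positive")
  if (cfg$daughter_ratio <= 1) stop("daughter_ratio must exceed 1")
  structure(cfg, class = c("ciliarrayConfig", "list"))
}

sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a calibrated stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are channel-z interleaved (z outer, channel inner); intensities are
#' stored as float32 in [0, 1] and the scale factor, voxel size and channel
#' names go to the sidecar.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path) {
  v <- stack@voxels
  d <- dim(v)
  scale <- max(v, 1e-12)
  pages <- vector("list", d[3L] * d[4L])
  i <- 0L
  for (z in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
    i <- i + 1L
    # tiff expects [row, col] = [y, x]
    pages[[i]] <- t(v[, , z, ch]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(voxel_size_um = stack@voxelSize, channel_names = stack@channelNames,
         n_z = d[3L], n_channels = d[4L], intensity_scale = scale),
    sidecarPath(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a calibrated z-stack
#'
#' Reads a multi-page TIFF written by \code{\link{writeStack}} (or any
#' channel-z interleaved float TIFF).  Calibration comes from the JSON
#' sidecar or, failing that, from \code{voxelSize}; a stack with no
#' calibration from either source is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param voxelSize optional numeric(3) calibration override (um).
#' @param nChannels optional channel count override (default from sidecar,
#'   else 1).
#' @param channelNames optional channel names.
#' @return an \linkS4class{ImageStack}.
#' @export
readStack <- function(path, voxelSize = NULL, nChannels = NULL,
                      channelNames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecarPath(path)))
    meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  if (is.null(voxelSize)) voxelSize <- meta$voxel_size_um
  if (is.null(voxelSize))
    stop("missing calibration: no sidecar metadata and no voxelSize override")
  if (is.null(nChannels)) nChannels <- if (!is.null(meta)) meta$n_channels else 1L
  scale <- if (!is.null(meta)) meta$intensity_scale else 1
  if (is.null(channelNames))
    channelNames <- if (!is.null(meta)) meta$channel_names
      else paste0("ch", seq_len(nChannels))
  nz <- length(pages) / nChannels
  if (nz != round(nz)) stop("page count not divisible by channel count")
  if (nz < 2L) stop("not a z-stack: fewer than 2 z planes")
  pg <- pages[[1L]]
  if (length(dim(pg)) > 2L) pg <- pg[, , 1L]  # tolerate RGB-coded pages
  d <- c(ncol(pg), nrow(pg), nz, nChannels)
  vox <- array(0, d)
  i <- 0L
  for (z in seq_len(nz)) for (ch in seq_len(nChannels)) {
    i <- i + 1L
    p <- pages[[i]]
    if (length(dim(p)) > 2L) p <- p[, , 1L]
    vox[, , z, ch] <- t(p) * scale
  }
  new("ImageStack", voxels = vox, voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames))
}

#' Write per-BB and per-cell result tables
#'
#' Emits a per-BB CSV (position, intensities, domain, anterior partner,
#' spacing, angular deviation, daughter flag) and a per-cell JSON summary
#' (counts, hull surface area and volume, poles, OA centroid) with a
#' deterministic column order.
#'
#' @param cellModel a \linkS4class{CellModel}.
#' @param rowGraph a \linkS4class{RowGraph} for the same cell.
#' @param domainTable data.frame from \code{\link{assignDomains}} (per-BB
#'   assignments) or NULL.
#' @param dir output directory (created if needed).
#' @param prefix file-name stem.
#' @return named list of the two file paths, invisibly.
#' @export
writeResults <- function(cellModel, rowGraph, domainTable = NULL, dir,
                         prefix = "cell") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bbs <- bbTable(cellModel)
  links <- rowLinks(rowGraph)
  n <- nrow(bbs)
  tab <- data.frame(
    bb_id = seq_len(n),
    x_um = if (n) bbs$x else numeric(0),
    y_um = if (n) bbs$y else numeric(0),
    z_um = if (n) bbs$z else numeric(0))
  for (cn in grep("^intensity_", names(bbs), value = TRUE)) tab[[cn]] <- bbs[[cn]]
  ord <- match(seq_len(n), links$bb)
  tab$anterior_id <- links$anterior[ord]
  tab$spacing_um <- links$lengthUm[ord]
  tab$ang_dev_deg <- links$angDevDeg[ord]
  tab$provenance <- links$provenance[ord]
  if (!is.null(domainTable) && n) {
    tab$quadrant <- domainTable$quadrant
    tab$rotational_bin <- domainTable$rotationalBin
  }
  if ("daughter" %in% names(bbs)) tab$daughter <- bbs$daughter
  csv <- file.path(dir, paste0(prefix, "_bbs.csv"))
  write.csv(tab, csv, row.names = FALSE)
  summ <- list(
    n_cortical_bbs = n,
    n_linked = sum(!is.na(links$anterior)),
    hull_area_um2 = cellModel@hullAreaUm2,
    hull_volume_um3 = cellModel@hullVolumeUm3,
    pole_anterior_um = cellModel@poleAnterior,
    pole_posterior_um = cellModel@polePosterior,
    oa_centroid_um = if (length(cellModel@oaCentroid)) cellModel@oaCentroid
      else NULL,
    polarity_note = cellModel@polarityNote)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(csv = csv, json = js))
}
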