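#' Calibrated multi-channel 3D image stack
#'
#' Container for a voxel grid with physical calibration.  Voxels are stored
#' as a 4D array indexed \code{[x, y, z, channel]}; the centre of voxel
#' \code{(1,1,1)} sits at the origin, so micrometre coordinates are
#' \code{(index - 1) * voxelSize}.  The z axis is the optical axis and
#' increases away from the coverslip.
#'
#' @slot voxels 4D numeric array \code{[x, y, z, channel]}, non-negative.
#' @slot voxelSize numeric(3), voxel edge lengths in micrometres (x, y, z).
#' @slot channelNames character vector, one name per channel.
#' @slot originUm numeric(3), physical position (um) of voxel (1,1,1) in the
#'   parent (pre-crop) frame; zero for freshly read or rendered stacks.
#' @export
setClass("ImageStack",
  representation(voxels = "array", voxelSize = "numeric",
                 channelNames = "character", originUm = "numeric"),
  prototype(originUm = c(0, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 4L)
      msg <- c(msg, "voxels must be a 4D array [x, y, z, channel]")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive lengths (um)")
    if (length(dim(object@voxels)) == 4L &&
        length(object@channelNames) != dim(object@voxels)[4L])
      msg <- c(msg, "one channel name per channel required")
    if (any(object@voxels < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cell specification
#'
#' Parameters of the synthetic \emph{Tetrahymena}-like cell generator.  The
#' cell is a prolate ellipsoid whose long (x) semi-axis is the
#' anteroposterior axis; basal bodies sit on \code{nRows} meridians at
#' arc-length spacings given by \code{spacingProfile}, a function of
#' normalized axial position (0 = anterior, 1 = posterior) returning
#' micrometres.  Rows stop \code{capAngleDeg} short of each apex, where
#' neighbouring meridians converge below BB spacing.
#'
#' @slot semiAxes numeric(3) ellipsoid semi-axes in um (x is anteroposterior).
#' @slot nRows integer number of ciliary rows (12--30).
#' @slot spacingProfile function(u in [0,1]) -> spacing um.
#' @slot capAngleDeg polar angle (deg) left bare at each apex.
#' @slot oaCenter numeric(2): azimuth (deg) and normalized axial position of
#'   the oral apparatus centre.
#' @slot oaBBCount integer number of oral-apparatus BBs.
#' @slot oaSpacing lateral spacing (um) of OA BBs, near the diffraction limit.
#' @slot noiseModel numeric(2): Gaussian read-noise sd and Poisson photon
#'   scale (photons per intensity unit; 0 disables shot noise).
#' @slot attenuationCoeff fractional intensity loss per um of depth.
#' @slot psfSigma numeric(3) Gaussian PSF sigma (um).
#' @slot voxelSize numeric(3) voxel size (um).
#' @slot amplitude numeric(2) mean spot amplitude per channel
#'   (channel 1 "centrin", channel 2 "poc1").
#' @slot amplitudeCv fractional sd of per-BB amplitude variation.
#' @slot background camera offset added to every voxel.
#' @slot oaPlateau amplitude of the homogeneous OA plateau.
#' @slot cytoplasm amplitude of the diffuse cytoplasmic fluorescence
#'   filling the cell body (immunofluorescence always carries some
#'   cytoplasmic stain; it also keeps the projected footprint contiguous).
#' @slot seed integer seed; all generator randomness derives from it.
#' @export
setClass("CellSpec",
  representation(semiAxes = "numeric", nRows = "integer",
                 spacingProfile = "function", capAngleDeg = "numeric",
                 oaCenter = "numeric", oaBBCount = "integer",
                 oaSpacing = "numeric", noiseModel = "numeric",
                 attenuationCoeff = "numeric", psfSigma = "numeric",
                 voxelSize = "numeric", amplitude = "numeric",
                 amplitudeCv = "numeric", background = "numeric",
                 oaPlateau = "numeric", cytoplasm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
      msg <- c(msg, "semiAxes must be 3 positive lengths")
    if (object@nRows < 12L || object@nRows > 30L)
      msg <- c(msg, "nRows must lie in [12, 30]")
    u <- seq(0, 1, length.out = 33L)
    if (any(!is.finite(object@spacingProfile(u))) ||
        any(object@spacingProfile(u) <= 0))
      msg <- c(msg, "spacing profile must be positive everywhere")
    if (any(object@voxelSize <= 0) || length(object@voxelSize) != 3L)
      msg <- c(msg, "voxelSize must be 3 positive lengths")
    if (object@attenuationCoeff < 0 || object@attenuationCoeff >= 1)
      msg <- c(msg, "attenuationCoeff must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic cell
#'
#' Positions are micrometres in the stack frame.  \code{daughterFlags} marks
#' BBs whose channel-2 (Poc1-like) intensity is less than half of their
#' posterior row neighbour's — the marker criterion for newly assembled
#' daughter BBs.
#'
#' @slot positions n x 3 matrix of cortical BB positions (um).
#' @slot rowId integer(n) row membership.
#' @slot orderInRow integer(n) anterior-to-posterior rank within the row.
#' @slot poleAnterior,polePosterior numeric(3) true apex positions (um).
#' @slot oaPositions m x 3 matrix of oral-apparatus BB positions.
#' @slot oaCentroid numeric(3) centre of the OA patch.
#' @slot intensities n x nchannel matrix of true per-BB spot amplitudes.
#' @slot oaIntensities m x nchannel matrix for OA BBs.
#' @slot channelNames character.
#' @slot daughterFlags logical(n).
#' @slot gapFlanks integer matrix (g x 2) of position row-indices flanking
#'   each injected spacing gap.
#' @slot spec the generating \linkS4class{CellSpec}.
#' @export
setClass("GroundTruth",
  representation(positions = "matrix", rowId = "integer",
                 orderInRow = "integer", poleAnterior = "numeric",
                 polePosterior = "numeric", oaPositions = "matrix",
                 oaCentroid = "numeric", intensities = "matrix",
                 oaIntensities = "matrix", channelNames = "character",
                 daughterFlags = "logical", gapFlanks = "matrix",
                 spec = "CellSpec"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@positions)
    if (ncol(object@positions) != 3L) msg <- c(msg, "positions must be n x 3")
    if (length(object@rowId) != n || length(object@orderInRow) != n ||
        length(object@daughterFlags) != n || nrow(object@intensities) != n)
      msg <- c(msg, "per-BB vectors must match nrow(positions)")
    for (r in unique(object@rowId)) {
      o <- object@orderInRow[object@rowId == r]
      if (any(sort(o) != seq_along(o)))
        msg <- c(msg, sprintf("row %d order not a permutation of 1..k", r))
    }
    if (length(msg)) msg else TRUE
  })

#' 2D cell mask with shape descriptors
#'
#' @slot mask logical matrix in maximum-intensity-projection space.
#' @slot pixelSize numeric(2) xy pixel size (um).
#' @slot areaUm2 region area (um^2).
#' @slot feretUm maximum Feret (caliper) diameter (um).
#' @slot circularity 4 pi area / perimeter^2.
#' @slot bbox integer(4) (x0, x1, y0, y1) bounding box in pixels.
#' @slot nDiscarded count of other objects that survived shape filtering
#'   but were smaller than the kept one.
#' @export
setClass("CellMask",
  representation(mask = "matrix", pixelSize = "numeric", areaUm2 = "numeric",
                 feretUm = "numeric", circularity = "numeric",
                 bbox = "integer", nDiscarded = "integer"))

#' Reconstructed cell model
#'
#' @slot bbs data.frame of cortical BBs: x, y, z (um), peak intensity,
#'   per-channel integrated intensities, box skew/kurtosis.
#' @slot poleAnterior,polePosterior numeric(3) pole positions (um).
#' @slot axis numeric(3) unit vector pointing posterior -> anterior.
#' @slot oaCentroid numeric(3) oral-apparatus centroid, or numeric(0) when
#'   no OA was classified.
#' @slot hullAreaUm2 convex-hull surface area of the BB cloud.
#' @slot hullVolumeUm3 convex-hull volume.
#' @slot polarityNote "intensity", "oa-override" or "ambiguous" — the cue
#'   that fixed anterior/posterior.
#' @export
setClass("CellModel",
  representation(bbs = "data.frame", poleAnterior = "numeric",
                 polePosterior = "numeric", axis = "numeric",
                 oaCentroid = "numeric", hullAreaUm2 = "numeric",
                 hullVolumeUm3 = "numeric", polarityNote = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@poleAnterior) == 3L && length(object@polePosterior) == 3L &&
        all(object@poleAnterior == object@polePosterior))
      msg <- c(msg, "poles must be distinct")
    if (length(object@axis) == 3L &&
        abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
      msg <- c(msg, "axis must have unit norm")
    if (length(msg)) msg else TRUE
  })

#' Directed anterior-partner row graph
#'
#' One row per cortical BB.  \code{anterior} is the index of the BB's
#' anterior partner within the same ciliary row (NA when unlinked);
#' in/out degree is at most one, so links form disjoint chains running
#' posterior to anterior.
#'
#' @slot links data.frame with columns \code{bb}, \code{anterior},
#'   \code{lengthUm}, \code{angDevDeg}, \code{provenance}
#'   ("reciprocal", "fallback" or "unlinked").
#' @export
setClass("RowGraph",
  representation(links = "data.frame"),
  validity = function(object) {
    l <- object@links
    need <- c("bb", "anterior", "lengthUm", "angDevDeg", "provenance")
    if (!all(need %in% names(l)))
      return(paste("links must have columns", paste(need, collapse = ", ")))
    ant <- l$anterior[!is.na(l$anterior)]
    if (anyDuplicated(ant))
      return("a BB may be the anterior partner of at most one BB")
    if (anyDuplicated(l$bb))
      return("one row per BB required")
    TRUE
  })
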