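#' Accessors for ciliarray classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "GroundTruth", function(x) x@channelNames)

#' @rdname accessors
#' @param channel channel index or name.
#' @export
setGeneric("voxelData", function(x, channel = 1L) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setMethod("voxelData", "ImageStack", function(x, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, x@channelNames)
  if (is.na(channel) || channel < 1L || channel > dim(x@voxels)[4L])
    stop("unknown channel")
  x@voxels[, , , channel, drop = TRUE]
})

#' @rdname accessors
#' @export
setGeneric("bbPositions", function(x) standardGeneric("bbPositions"))
#' @rdname accessors
#' @export
setMethod("bbPositions", "GroundTruth", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("bbPositions", "CellModel",
          function(x) as.matrix(x@bbs[, c("x", "y", "z")]))

#' @rdname accessors
#' @export
setGeneric("bbTable", function(x) standardGeneric("bbTable"))
#' @rdname accessors
#' @export
setMethod("bbTable", "CellModel", function(x) x@bbs)

#' @rdname accessors
#' @export
setGeneric("rowLinks", function(x) standardGeneric("rowLinks"))
#' @rdname accessors
#' @export
setMethod("rowLinks", "RowGraph", function(x) x@links)

#' @rdname accessors
#' @export
setGeneric("poles", function(x) standardGeneric("poles"))
#' @rdname accessors
#' @export
setMethod("poles", "CellModel",
          function(x) list(anterior = x@poleAnterior, posterior = x@polePosterior))
#' @rdname accessors
#' @export
setMethod("poles", "GroundTruth",
          function(x) list(anterior = x@poleAnterior, posterior = x@polePosterior))

#' @rdname accessors
#' @export
setGeneric("oaCentroid", function(x) standardGeneric("oaCentroid"))
#' @rdname accessors
#' @export
setMethod("oaCentroid", "CellModel", function(x) x@oaCentroid)
#' @rdname accessors
#' @export
setMethod("oaCentroid", "GroundTruth", function(x) x@oaCentroid)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d x %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4],
              paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  voxel size %.3f x %.3f x %.3f um; extent %.1f x %.1f x %.1f um\n",
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              d[1] * object@voxelSize[1], d[2] * object@voxelSize[2],
              d[3] * object@voxelSize[3]))
})

setMethod("show", "CellSpec", function(object) {
  cat(sprintf("CellSpec: prolate cell %.0f x %.0f x %.0f um, %d rows, seed %d\n",
              2 * object@semiAxes[1], 2 * object@semiAxes[2],
              2 * object@semiAxes[3], object@nRows, object@seed))
  cat(sprintf("  OA: %d BBs at azimuth %.0f deg, axial %.2f; attenuation %.3f/um\n",
              object@oaBBCount, object@oaCenter[1], object@oaCenter[2],
              object@attenuationCoeff))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cortical BBs in %d rows, %d OA BBs, %d daughter(s), %d gap(s)\n",
              nrow(object@positions), length(unique(object@rowId)),
              nrow(object@oaPositions), sum(object@daughterFlags),
              nrow(object@gapFlanks)))
})

setMethod("show", "CellModel", function(object) {
  cat(sprintf("CellModel: %d cortical BBs; hull %.0f um^2 / %.0f um^3; polarity via %s\n",
              nrow(object@bbs), object@hullAreaUm2, object@hullVolumeUm3,
              object@polarityNote))
  p <- object@poleAnterior; q <- object@polePosterior
  cat(sprintf("  anterior pole (%.1f, %.1f, %.1f), posterior pole (%.1f, %.1f, %.1f) um\n",
              p[1], p[2], p[3], q[1], q[2], q[3]))
})

setMethod("show", "RowGraph", function(object) {
  l <- object@links
  cat(sprintf("RowGraph: %d BBs, %d reciprocal / %d fallback links, %d unlinked\n",
              nrow(l), sum(l$provenance == "reciprocal"),
              sum(l$provenance == "fallback"), sum(l$provenance == "unlinked")))
})
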