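# Anteroposterior axis, polarity, oral apparatus location, and
# anterior-partner row connectivity.

#' Locate the two cell poles from the BB point cloud
#'
#' Each BB's maximum distance to any other BB is computed; the BBs carrying
#' the greatest such distances are the most anterior and most posterior
#' ones.  Walking down that ranking, each extreme BB is assigned to the
#' nearer end (sign of its projection on the provisional long axis, the
#' segment realizing the global maximum distance) until both clusters hold
#' \code{nExtreme} BBs; exact distance ties at the cutoff are included so
#' symmetric extreme rings contribute evenly.  The poles are the two
#' cluster centroids.
#'
#' @param positions n x 3 matrix (um), n >= 2 * nExtreme.
#' @param nExtreme BBs per pole cluster (10, following the published
#'   routine).
#' @return list: \code{poleA}, \code{poleB} (numeric(3)), \code{clusters}
#'   (index list).  Which pole is anterior is decided later by
#'   \code{\link{assignPolarity}}.
#' @export
findPoles <- function(positions, nExtreme = 10L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L * nExtreme)
    stop("need at least ", 2L * nExtreme, " BBs to locate poles")
  D <- as.matrix(stats::dist(positions))
  maxd <- apply(D, 1L, max)
  # elongation guard: a near-spherical cloud has no meaningful poles
  ev <- eigen(stats::cov(positions), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2L] > 0 && sqrt(ev[1L] / ev[2L]) < 1.25)
    stop("point cloud not elongated: poles ambiguous")
  far <- which(D == max(D), arr.ind = TRUE)[1L, ]
  axis0 <- positions[far[1L], ] - positions[far[2L], ]
  axis0 <- axis0 / sqrt(sum(axis0^2))
  proj <- drop(sweep(positions, 2L, colMeans(positions)) %*% axis0)
  ord <- order(maxd, decreasing = TRUE)
  cl1 <- integer(0); cl2 <- integer(0)
  for (i in ord) {
    if (proj[i] >= 0 && length(cl1) < nExtreme) cl1 <- c(cl1, i)
    else if (proj[i] < 0 && length(cl2) < nExtreme) cl2 <- c(cl2, i)
    if (length(cl1) == nExtreme && length(cl2) == nExtreme) break
  }
  if (length(cl1) < nExtreme || length(cl2) < nExtreme)
    stop("pole clusters not separable")
  # extend each cluster across exact distance ties at the cutoff, so that
  # perfectly symmetric rings do not leave a biased half-ring centroid
  eps <- 1e-9 * max(maxd)
  for (side in 1:2) {
    cl <- if (side == 1L) cl1 else cl2
    cut <- min(maxd[cl])
    extra <- setdiff(which(maxd >= cut - eps &
                             (if (side == 1L) proj >= 0 else proj < 0)), cl)
    if (side == 1L) cl1 <- c(cl1, extra) else cl2 <- c(cl2, extra)
  }
  list(poleA = colMeans(positions[cl1, , drop = FALSE]),
       poleB = colMeans(positions[cl2, , drop = FALSE]),
       clusters = list(cl1, cl2))
}

sphereIntensity <- function(stack, centerUm, radiusUm, channel = 1L) {
  vs <- voxelSize(stack)
  vol <- voxelData(stack, channel)
  d <- dim(vol)
  ro <- ceiling(radiusUm / vs)
  ctr <- round(centerUm / vs) + 1
  lo <- pmax(1, ctr - ro); hi <- pmin(d, ctr + ro)
  if (any(lo > hi)) return(0)
  xs <- ((lo[1L]:hi[1L]) - 1) * vs[1L] - centerUm[1L]
  ys <- ((lo[2L]:hi[2L]) - 1) * vs[2L] - centerUm[2L]
  zs <- ((lo[3L]:hi[3L]) - 1) * vs[3L] - centerUm[3L]
  dd <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  sub <- vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  sum(sub[dd <= radiusUm^2])
}

#' Decide which pole is anterior
#'
#' Integrates marker intensity in a sphere (radius \code{pole_sphere_um})
#' at each pole; the brighter pole is anterior (BB spacing tightens toward
#' the anterior, and the oral apparatus adds signal there).  When an OA
#' centroid is available it must fall in the anterior half; on disagreement
#' the OA cue wins and the call is flagged.
#'
#' @param stack cropped \linkS4class{ImageStack}.
#' @param poleA,poleB candidate poles from \code{\link{findPoles}}.
#' @param oaCentroid numeric(3) OA centroid or numeric(0).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list: \code{anterior}, \code{posterior}, \code{note}
#'   ("intensity", "oa-override" or "ambiguous").
#' @export
assignPolarity <- function(stack, poleA, poleB, oaCentroid = numeric(0),
                           cfg = pipelineConfig()) {
  ia <- sphereIntensity(stack, poleA, cfg$pole_sphere_um)
  ib <- sphereIntensity(stack, poleB, cfg$pole_sphere_um)
  hasOA <- length(oaCentroid) == 3L
  tie <- (max(ia, ib) == 0) || abs(ia - ib) / max(ia, ib) < 0.05
  if (tie && !hasOA) stop("polarity ambiguous")
  anterior <- if (ia >= ib) poleA else poleB
  posterior <- if (ia >= ib) poleB else poleA
  note <- if (tie) "oa-override" else "intensity"
  if (hasOA) {
    mid <- (poleA + poleB) / 2
    ax <- anterior - posterior
    if (sum((oaCentroid - mid) * ax) < 0) {
      tmp <- anterior; anterior <- posterior; posterior <- tmp
      note <- "oa-override"
    }
  }
  list(anterior = anterior, posterior = posterior, note = note)
}

#' Oral-apparatus centroid
#'
#' @param oaMaxima data.frame (or matrix) of OA-classified maxima with
#'   x, y, z columns.
#' @return numeric(3) centroid, or numeric(0) when no OA maxima exist.
#' @export
locateOralApparatus <- function(oaMaxima) {
  if (is.null(oaMaxima) || nrow(oaMaxima) == 0L) return(numeric(0))
  colMeans(as.matrix(oaMaxima[, c("x", "y", "z")]))
}

# per-BB unit normals of the plane through the BB and the two poles
polePlaneNormals <- function(positions, poleAnterior, polePosterior) {
  u <- sweep(-positions, 2L, poleAnterior, "+")    # poleA - b
  v <- sweep(-positions, 2L, polePosterior, "+")   # poleP - b
  nrm <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  len <- sqrt(rowSums(nrm^2))
  bad <- len < 1e-9          # BB collinear with the pole axis
  nrm[!bad, ] <- nrm[!bad, ] / len[!bad]
  nrm[bad, ] <- NA_real_
  nrm
}

#' Connect each BB to its anterior partner within a ciliary row
#'
#' A candidate partner of BB b must lie strictly anterior of b (greater
#' projection on the posterior-to-anterior axis).  The score of candidate
#' c is the Euclidean distance to b plus the distance of c from the plane
#' through b and the two poles — the row plane, so the metric prefers the
#' nearest BB that continues b's own meridian.  Forward and reverse
#' choices are computed for every unassigned BB and only reciprocal pairs
#' are accepted, all pairs of a round simultaneously; assigned BBs leave
#' the candidate pool and the rounds repeat until no new reciprocal pair
#' appears.  Remaining BBs fall back to the closest unassigned anterior
#' candidate if within \code{fallback_link_um}, else stay unlinked.
#'
#' @param positions n x 3 matrix of cortical BB positions (um).
#' @param poleAnterior,polePosterior pole positions (um).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{RowGraph}.
#' @export
connectRows <- function(positions, poleAnterior, polePosterior,
                        cfg = pipelineConfig()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  axis <- poleAnterior - polePosterior
  axis <- axis / sqrt(sum(axis^2))
  proj <- drop(positions %*% axis)
  D <- as.matrix(stats::dist(positions))
  N <- polePlaneNormals(positions, poleAnterior, polePosterior)
  # planeDist[b, c] = distance of c from b's pole plane; a BB on the pole
  # axis has no unique plane and its penalty vanishes (any candidate lies
  # in some plane through the axis and the BB)
  planeDist <- abs(N %*% t(positions) - rowSums(N * positions))
  planeDist[!is.finite(planeDist)] <- 0
  score <- D + cfg$plane_weight * planeDist
  anteriorOf <- outer(proj, proj, function(pb, pc) pc > pb)
  score[!anteriorOf] <- Inf
  diag(score) <- Inf

  partner <- rep(NA_integer_, n)     # anterior partner of each BB
  hasPosterior <- rep(FALSE, n)      # BB already receives a connection
  provenance <- rep("unlinked", n)
  sc <- score
  repeat {
    open <- which(is.na(partner))
    free <- which(!hasPosterior)
    if (!length(open) || !length(free)) break
    sub <- sc[open, free, drop = FALSE]
    fwd <- free[apply(sub, 1L, which.min)]
    fwd[!is.finite(apply(sub, 1L, min))] <- NA_integer_
    rev <- open[apply(sub, 2L, which.min)]
    rev[!is.finite(apply(sub, 2L, min))] <- NA_integer_
    newLink <- which(!is.na(fwd) & rev[match(fwd, free)] == open)
    if (!length(newLink)) break
    # simultaneous acceptance; a candidate can only be claimed by the BB it
    # reciprocates, so no conflicts arise within a round
    b <- open[newLink]; c_ <- fwd[newLink]
    partner[b] <- c_
    hasPosterior[c_] <- TRUE
    provenance[b] <- "reciprocal"
  }
  # fallback: closest unconnected anterior candidate within the cutoff,
  # processed by increasing distance
  open <- which(is.na(partner))
  if (length(open)) {
    cand <- which(!hasPosterior)
    if (length(cand)) {
      dsub <- D[open, cand, drop = FALSE]
      dsub[!anteriorOf[open, cand, drop = FALSE]] <- Inf
      ordIdx <- order(dsub)
      for (k in ordIdx) {
        if (!is.finite(dsub[k])) break
        bi <- open[(k - 1L) %% length(open) + 1L]
        ci <- cand[(k - 1L) %/% length(open) + 1L]
        if (!is.na(partner[bi]) || hasPosterior[ci]) next
        if (dsub[k] > cfg$fallback_link_um) break
        partner[bi] <- ci
        hasPosterior[ci] <- TRUE
        provenance[bi] <- "fallback"
      }
    }
  }

  len <- ifelse(is.na(partner), NA_real_, D[cbind(seq_len(n), partner)])
  ang <- rep(NA_real_, n)
  linked <- which(!is.na(partner))
  if (length(linked))
    ang[linked] <- angularDeviation(positions[linked, , drop = FALSE],
                                    positions[partner[linked], , drop = FALSE],
                                    poleAnterior, polePosterior)
  new("RowGraph", links = data.frame(
    bb = seq_len(n), anterior = partner, lengthUm = len, angDevDeg = ang,
    provenance = provenance, stringsAsFactors = FALSE))
}

#' Rotate a cell model into the canonical frame
#'
#' Rigid rotation (about the pole midpoint) taking the
#' posterior-to-anterior axis to +x; when an OA centroid exists its
#' azimuth about the axis becomes 0 degrees (the +y half-plane).  Pairwise
#' distances are preserved to machine precision.
#'
#' @param cellModel a \linkS4class{CellModel}.
#' @return the rotated \linkS4class{CellModel}.
#' @export
rotateToAxis <- function(cellModel) {
  mid <- (cellModel@poleAnterior + cellModel@polePosterior) / 2
  e1 <- cellModel@axis
  ref <- if (length(cellModel@oaCentroid) == 3L) cellModel@oaCentroid - mid
    else {
      w <- c(0, 1, 0)
      if (abs(sum(w * e1)) > 0.9) w <- c(0, 0, 1)
      w
    }
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(e1, e2)
  R <- rbind(e1, e2, e3)
  rot <- function(p) {
    if (length(p) == 0L) return(p)
    drop(R %*% (p - mid))
  }
  bbs <- cellModel@bbs
  xyz <- t(apply(as.matrix(bbs[, c("x", "y", "z")]), 1L,
                 function(p) rot(p)))
  bbs$x <- xyz[, 1L]; bbs$y <- xyz[, 2L]; bbs$z <- xyz[, 3L]
  new("CellModel", bbs = bbs, poleAnterior = rot(cellModel@poleAnterior),
      polePosterior = rot(cellModel@polePosterior), axis = c(1, 0, 0),
      oaCentroid = rot(cellModel@oaCentroid),
      hullAreaUm2 = cellModel@hullAreaUm2,
      hullVolumeUm3 = cellModel@hullVolumeUm3,
      polarityNote = cellModel@polarityNote)
}

#' Assemble a cell model from a detection result
#'
#' Finds poles, fixes polarity, locates the oral apparatus and computes
#' hull morphometrics.
#'
#' @param detection result of \code{\link{detectBBs}}.
#' @param stack the cropped \linkS4class{ImageStack}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{CellModel} (stack frame, not yet canonical).
#' @export
buildCellModel <- function(detection, stack, cfg = pipelineConfig()) {
  bbs <- detection$bbs
  pos <- as.matrix(bbs[, c("x", "y", "z")])
  pp <- findPoles(pos)
  oaC <- locateOralApparatus(detection$oa)
  pol <- assignPolarity(stack, pp$poleA, pp$poleB, oaC, cfg)
  axis <- pol$anterior - pol$posterior
  axis <- axis / sqrt(sum(axis^2))
  hm <- hullMetrics(pos)
  new("CellModel", bbs = bbs, poleAnterior = pol$anterior,
      polePosterior = pol$posterior, axis = axis, oaCentroid = oaC,
      hullAreaUm2 = hm$areaUm2, hullVolumeUm3 = hm$volumeUm3,
      polarityNote = pol$note)
}
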