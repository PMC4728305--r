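# Spacing, orientation, spatial domains, hull morphometrics, daughter-BB
# calls and intensity ratios on a reconstructed cell.

#' Angular deviation of anterior-partner links
#'
#' For each link the angle between the anterior partner and the plane
#' through the BB and the two cell poles: asin(out-of-plane distance /
#' link length), in degrees within [0, 90].  A perfect ciliary row keeps
#' every anterior partner in that plane, giving 0 degrees.
#'
#' @param bb m x 3 matrix of link base positions (um).
#' @param partner m x 3 matrix of anterior-partner positions.
#' @param poleAnterior,polePosterior pole positions (um).
#' @return numeric(m) degrees; NA (with a warning) where the BB is
#'   collinear with the pole axis and the plane is undefined.
#' @export
angularDeviation <- function(bb, partner, poleAnterior, polePosterior) {
  bb <- matrix(bb, ncol = 3L)
  partner <- matrix(partner, ncol = 3L)
  N <- polePlaneNormals(bb, poleAnterior, polePosterior)
  rel <- partner - bb
  len <- sqrt(rowSums(rel^2))
  out <- abs(rowSums(rel * N))
  bad <- !is.finite(out)
  if (any(bad))
    warning(sum(bad), " link(s) skipped: BB collinear with the pole axis")
  asin(pmin(1, out / len)) * 180 / pi
}

#' Spacing statistics of a row graph
#'
#' Link lengths are 3D Euclidean distances, so surface curvature between
#' partners is preserved.  Reports the per-link spacing vector, a 0.1 um
#' histogram, the large-gap frequency (links longer than \code{gap_um})
#' and the close-pair fraction (links shorter than \code{close_um}).
#'
#' @param rowGraph a \linkS4class{RowGraph}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param binUm histogram bin width.
#' @return list: \code{spacing}, \code{meanUm}, \code{sdUm}, \code{hist},
#'   \code{gapFrequency}, \code{closeFraction}, \code{nLinks},
#'   \code{flagged} (TRUE when the graph has no links).
#' @export
spacingStats <- function(rowGraph, cfg = pipelineConfig(), binUm = 0.1) {
  sp <- rowLinks(rowGraph)$lengthUm
  sp <- sp[!is.na(sp)]
  if (!length(sp))
    return(list(spacing = numeric(0), meanUm = NaN, sdUm = NaN, hist = NULL,
                gapFrequency = NaN, closeFraction = NaN, nLinks = 0L,
                flagged = TRUE))
  breaks <- seq(0, ceiling(max(sp) / binUm) * binUm + binUm, by = binUm)
  list(spacing = sp, meanUm = mean(sp), sdUm = sd(sp),
       hist = hist(sp, breaks = breaks, plot = FALSE),
       gapFrequency = mean(sp > cfg$gap_um),
       closeFraction = mean(sp < cfg$close_um),
       nLinks = length(sp), flagged = FALSE)
}

#' Assign BBs to longitudinal and rotational spatial domains
#'
#' Works in the canonical frame (\code{\link{rotateToAxis}}).  The
#' longitudinal coordinate is the Euclidean distance from the anterior
#' pole normalized by the pole-to-pole distance D: quadrant IV [0, 0.25)
#' (anterior), III [0.25, 0.5), II [0.5, 0.75), I [0.75, 1].  The
#' rotational coordinate is the azimuth about the axis relative to the
#' oral apparatus, folded to [0, 180] by the cell's mirror symmetry and
#' binned into 0, 45, 90, 135 degrees.
#'
#' @param cellModel a canonical-frame \linkS4class{CellModel}.
#' @return data.frame: \code{quadrant} (factor IV, III, II, I),
#'   \code{rotationalBin} (factor 0, 45, 90, 135; NA when the cell has no
#'   OA centroid).
#' @export
assignDomains <- function(cellModel) {
  pos <- bbPositions(cellModel)
  pa <- cellModel@poleAnterior
  D <- sqrt(sum((pa - cellModel@polePosterior)^2))
  dnorm_ <- sqrt(rowSums(sweep(pos, 2L, pa)^2)) / D
  dnorm_ <- pmin(dnorm_, 1)
  quad <- cut(dnorm_, breaks = c(0, 0.25, 0.5, 0.75, 1),
              labels = c("IV", "III", "II", "I"), include.lowest = TRUE,
              right = FALSE)
  quad[dnorm_ >= 0.75] <- "I"
  if (length(cellModel@oaCentroid) == 3L) {
    az <- abs(atan2(pos[, 3L], pos[, 2L]) * 180 / pi)  # folded to [0, 180]
    rot <- cut(az, breaks = c(0, 45, 90, 135, 180.000001),
               labels = c("0", "45", "90", "135"), include.lowest = TRUE,
               right = FALSE)
  } else {
    rot <- factor(rep(NA_character_, nrow(pos)),
                  levels = c("0", "45", "90", "135"))
  }
  data.frame(quadrant = quad, rotationalBin = rot)
}

#' Convex-hull morphometrics of the BB point cloud
#'
#' Surface area (facet-area sum), enclosed volume and BB densities.
#'
#' @param positions n x 3 matrix of cortical BB positions (um), n >= 4 and
#'   not coplanar.
#' @param rowGraph optional \linkS4class{RowGraph}; adds the mean linear
#'   density within rows (BBs per um of summed link length).
#' @return list: \code{areaUm2}, \code{volumeUm3}, \code{surfaceDensity}
#'   (BBs per um^2), \code{linearDensity} (or NA).
#' @export
hullMetrics <- function(positions, rowGraph = NULL) {
  positions <- as.matrix(positions)
  hull <- convexHull3d(positions)
  lin <- NA_real_
  if (!is.null(rowGraph)) {
    sp <- rowLinks(rowGraph)$lengthUm
    sp <- sp[!is.na(sp)]
    if (length(sp)) lin <- length(sp) / sum(sp)
  }
  list(areaUm2 = hull$areaUm2, volumeUm3 = hull$volumeUm3,
       surfaceDensity = nrow(positions) / hull$areaUm2,
       linearDensity = lin)
}

#' Call mother/daughter BB pairs from marker intensity ratios
#'
#' For each link (posterior p -> anterior a), if the posterior intensity
#' is at least \code{daughter_ratio}-fold (default 2) the anterior one,
#' the anterior BB is a newly assembled daughter and the posterior its
#' mother.  Zero anterior intensity gives an infinite ratio: the daughter
#' is called and the link flagged.
#'
#' @param rowGraph a \linkS4class{RowGraph}.
#' @param intensity numeric(n) per-BB marker intensity (Poc1-like channel),
#'   indexed like the graph's \code{bb} column.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list: \code{daughter}, \code{mother} logical(n); \code{ratio}
#'   numeric(n) posterior/anterior ratio stored at the anterior BB;
#'   \code{flagged} logical(n) infinite-ratio links.
#' @export
callDaughters <- function(rowGraph, intensity, cfg = pipelineConfig()) {
  l <- rowLinks(rowGraph)
  n <- nrow(l)
  daughter <- mother <- flagged <- rep(FALSE, n)
  ratio <- rep(NA_real_, n)
  linked <- which(!is.na(l$anterior))
  for (i in linked) {
    p <- l$bb[i]; a <- l$anterior[i]
    r <- if (intensity[a] <= 0) Inf else intensity[p] / intensity[a]
    ratio[a] <- r
    if (is.infinite(r)) flagged[a] <- TRUE
    if (r >= cfg$daughter_ratio) {
      daughter[a] <- TRUE
      mother[p] <- TRUE
    }
  }
  list(daughter = daughter, mother = mother, ratio = ratio, flagged = flagged)
}

#' Distribution of anterior/posterior intensity ratios across links
#'
#' @param rowGraph a \linkS4class{RowGraph}.
#' @param intensity numeric(n) per-BB marker intensity.
#' @param binWidth histogram bin width on the ratio scale.
#' @return list: \code{ratios} (anterior / posterior per link),
#'   \code{hist}.
#' @export
intensityRatioHistogram <- function(rowGraph, intensity, binWidth = 0.1) {
  l <- rowLinks(rowGraph)
  linked <- which(!is.na(l$anterior))
  ratios <- intensity[l$anterior[linked]] / intensity[l$bb[linked]]
  ratios <- ratios[is.finite(ratios)]
  h <- if (length(ratios))
    hist(ratios, breaks = seq(0, max(ratios) + binWidth, by = binWidth),
         plot = FALSE)
  else NULL
  list(ratios = ratios, hist = h)
}

#' Per-domain summary table
#'
#' Aggregates spacing, angular deviation and daughter fraction over the
#' 16 (longitudinal x rotational) spatial domains; BBs enter a domain's
#' statistics through their anterior link.
#'
#' @param rowGraph a \linkS4class{RowGraph}.
#' @param domains data.frame from \code{\link{assignDomains}}.
#' @param daughters optional result of \code{\link{callDaughters}}.
#' @return data.frame with one row per (quadrant, rotationalBin) cell.
#' @export
domainSummary <- function(rowGraph, domains, daughters = NULL) {
  l <- rowLinks(rowGraph)
  grid <- expand.grid(quadrant = levels(domains$quadrant),
                      rotationalBin = levels(domains$rotationalBin),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    inDom <- which(domains$quadrant == grid$quadrant[g] &
                     !is.na(domains$rotationalBin) &
                     domains$rotationalBin == grid$rotationalBin[g])
    li <- l[l$bb %in% inDom & !is.na(l$anterior), ]
    data.frame(
      quadrant = grid$quadrant[g], rotationalBin = grid$rotationalBin[g],
      n = nrow(li),
      meanSpacingUm = if (nrow(li)) mean(li$lengthUm) else NaN,
      sdSpacingUm = if (nrow(li) > 1) sd(li$lengthUm) else NA_real_,
      meanAngDevDeg = if (nrow(li)) mean(li$angDevDeg, na.rm = TRUE) else NaN,
      sdAngDevDeg = if (nrow(li) > 1) sd(li$angDevDeg, na.rm = TRUE)
        else NA_real_,
      daughterFraction = if (!is.null(daughters) && length(inDom))
        mean(daughters$daughter[inDom]) else NA_real_)
  })
  do.call(rbind, out)
}
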