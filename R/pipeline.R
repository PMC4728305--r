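# End-to-end single-cell pipeline: segment -> crop -> detect -> model ->
# link rows -> metrics.

#' Run the full analysis pipeline on one stack
#'
#' @param stack an \linkS4class{ImageStack} (channel 1 = BB marker,
#'   channel 2 = age-graded marker when present).
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param crop segment and crop the field first (disable for stacks that
#'   already contain exactly one cell reaching the border margins).
#' @param verbose log per-stage counts.
#' @return list: \code{stack} (cropped), \code{mask}, \code{detection},
#'   \code{cellModel} (stack frame), \code{canonical} (rotated frame),
#'   \code{rowGraph}, \code{domains}, \code{daughters}, \code{spacing},
#'   \code{domainSummary}.
#' @export
runPipeline <- function(stack, cfg = pipelineConfig(), crop = TRUE,
                        verbose = FALSE) {
  mask <- NULL
  if (crop) {
    mask <- makeCellMask(stack, cfg)
    stack <- cropToMask(stack, mask, cfg)
  }
  det <- detectBBs(stack, cfg, verbose = verbose)
  model <- buildCellModel(det, stack, cfg)
  rg <- connectRows(bbPositions(model), model@poleAnterior,
                    model@polePosterior, cfg)
  poc1Col <- grep("intensity_", names(det$bbs), value = TRUE)
  daughters <- NULL
  if (length(poc1Col) >= 2L) {
    daughters <- callDaughters(rg, det$bbs[[poc1Col[2L]]], cfg)
    model@bbs$daughter <- daughters$daughter
  }
  canon <- rotateToAxis(model)
  dom <- assignDomains(canon)
  sp <- spacingStats(rg, cfg)
  list(stack = stack, mask = mask, detection = det, cellModel = model,
       canonical = canon, rowGraph = rg, domains = dom,
       daughters = daughters, spacing = sp,
       domainSummary = domainSummary(rg, dom, daughters))
}

#' Match detected positions to ground truth
#'
#' Greedy nearest-neighbour one-to-one matching within a radius; the
#' standard recall/precision bookkeeping for detection benchmarks.
#'
#' @param detected m x 3 matrix (um).
#' @param truth n x 3 matrix (um).
#' @param radiusUm matching radius.
#' @return list: \code{recall}, \code{precision}, \code{matches}
#'   (2-column index matrix detected/truth), \code{localizationUm} (mean
#'   matched distance).
#' @export
matchToGroundTruth <- function(detected, truth, radiusUm = 0.5) {
  detected <- matrix(as.matrix(detected), ncol = 3L)
  truth <- matrix(as.matrix(truth), ncol = 3L)
  if (!nrow(detected) || !nrow(truth))
    return(list(recall = 0, precision = 0,
                matches = matrix(integer(0), 0L, 2L),
                localizationUm = NaN))
  dd <- outer(rowSums(detected^2), rowSums(truth^2), "+") -
    2 * detected %*% t(truth)
  dd[dd < 0] <- 0
  dd <- sqrt(dd)
  matches <- matrix(integer(0), 0L, 2L)
  dists <- numeric(0)
  repeat {
    k <- which.min(dd)
    if (!length(k) || !is.finite(dd[k]) || dd[k] > radiusUm) break
    i <- (k - 1L) %% nrow(dd) + 1L
    j <- (k - 1L) %/% nrow(dd) + 1L
    matches <- rbind(matches, c(i, j))
    dists <- c(dists, dd[k])
    dd[i, ] <- Inf
    dd[, j] <- Inf
  }
  list(recall = nrow(matches) / nrow(truth),
       precision = nrow(matches) / nrow(detected),
       matches = matches,
       localizationUm = if (length(dists)) mean(dists) else NaN)
}
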