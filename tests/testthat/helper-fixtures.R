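# Shared fixtures, built lazily and cached for the whole test run.  The
# rendered default cell is the expensive object most files need.

fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, build) {
  if (!exists(name, fixtureCache)) assign(name, build(), fixtureCache)
  get(name, fixtureCache)
}

# default preset cell: ground truth, rendered stack, full pipeline result
defaultCell <- function() cachedFixture("defaultCell", function() {
  spec <- cellSpec(seed = 101)
  gt <- placeBasalBodies(spec)
  stack <- renderStack(gt)
  res <- runPipeline(stack)
  list(spec = spec, gt = gt, stack = stack, res = res)
})

# constant 2 um spacing cell (no crop needed; used by averaging tests)
flatSpacingCell <- function() cachedFixture("flatSpacingCell", function() {
  spec <- cellSpec(seed = 102, spacingProfile = function(u) rep(2, length(u)))
  gt <- placeBasalBodies(spec)
  stack <- renderStack(gt)
  res <- runPipeline(stack, crop = FALSE)
  list(spec = spec, gt = gt, stack = stack, res = res)
})

# detected positions mapped back to the ground-truth (uncropped) frame
detectedInTruthFrame <- function(cell) {
  sweep(bbPositions(cell$res$cellModel), 2L, cell$res$stack@originUm, "+")
}

# ground-truth anterior successor (same row, next rank toward the anterior)
truthSuccessors <- function(gt) {
  succ <- rep(NA_integer_, nrow(gt@positions))
  for (i in seq_len(nrow(gt@positions))) {
    j <- which(gt@rowId == gt@rowId[i] &
                 gt@orderInRow == gt@orderInRow[i] - 1L)
    if (length(j)) succ[i] <- j
  }
  succ
}

# fraction of detected links that join truth row successors
linkAccuracy <- function(cell) {
  gt <- cell$gt
  det <- detectedInTruthFrame(cell)
  m <- matchToGroundTruth(det, gt@positions, 0.5)
  d2t <- rep(NA_integer_, nrow(det))
  d2t[m$matches[, 1L]] <- m$matches[, 2L]
  succ <- truthSuccessors(gt)
  l <- rowLinks(cell$res$rowGraph)
  ok <- which(!is.na(l$anterior) & !is.na(d2t[l$bb]) & !is.na(d2t[l$anterior]))
  mean(d2t[l$anterior[ok]] == succ[d2t[l$bb[ok]]], na.rm = TRUE)
}

# independent naive reimplementation of reciprocal row matching, used as
# the oracle for connectRows on small instances
bruteForceRows <- function(pos, poleA, poleP, fallbackUm = 5,
                           planeW = 1) {
  n <- nrow(pos)
  ax <- (poleA - poleP) / sqrt(sum((poleA - poleP)^2))
  proj <- drop(pos %*% ax)
  normals <- lapply(seq_len(n), function(b) {
    nn <- pracma::cross(poleA - pos[b, ], poleP - pos[b, ])
    ln <- sqrt(sum(nn^2))
    if (ln < 1e-9) NULL else nn / ln
  })
  planeDist <- function(b, c) {
    nn <- normals[[b]]
    # BB on the pole axis: every candidate lies in some plane through the
    # axis and b, so the penalty vanishes
    if (is.null(nn)) return(0)
    abs(sum((pos[c, ] - pos[b, ]) * nn))
  }
  sc <- function(b, c) sqrt(sum((pos[b, ] - pos[c, ])^2)) +
    planeW * planeDist(b, c)
  partner <- rep(NA_integer_, n)
  taken <- rep(FALSE, n)
  repeat {
    fwd <- rep(NA_integer_, n)
    for (b in which(is.na(partner))) {
      best <- Inf
      for (c in which(!taken)) {
        if (proj[c] <= proj[b]) next
        s <- sc(b, c)
        if (s < best) { best <- s; fwd[b] <- c }
      }
    }
    bwd <- rep(NA_integer_, n)
    for (c in which(!taken)) {
      best <- Inf
      for (b in which(is.na(partner))) {
        if (proj[c] <= proj[b]) next
        s <- sc(b, c)
        if (s < best) { best <- s; bwd[c] <- b }
      }
    }
    acc <- which(!is.na(fwd) & !is.na(bwd[fwd]) & bwd[fwd] == seq_len(n))
    if (!length(acc)) break
    for (b in acc) { partner[b] <- fwd[b]; taken[fwd[b]] <- TRUE }
  }
  # fallback pass, closest first
  repeat {
    best <- Inf; bb <- NA; cc <- NA
    for (b in which(is.na(partner))) for (c in which(!taken)) {
      if (proj[c] <= proj[b]) next
      dd <- sqrt(sum((pos[b, ] - pos[c, ])^2))
      if (dd < best) { best <- dd; bb <- b; cc <- c }
    }
    if (!is.finite(best) || best > fallbackUm) break
    partner[bb] <- cc; taken[cc] <- TRUE
  }
  partner
}
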