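# small synthetic stack helper: spots at given um positions on a quiet
# background, no noise unless asked
spotStack <- function(pos, amp = 1000, vs = c(0.125, 0.125, 0.3),
                      dimsUm = c(6, 6, 6), bg = 0, noiseSd = 0,
                      sigma = c(0.12, 0.12, 0.25)) {
  d <- as.integer(ceiling(dimsUm / vs)) + 1L
  vol <- array(bg, d)
  amp <- rep(amp, length.out = nrow(pos))
  for (i in seq_len(nrow(pos))) {
    p <- ciliarray:::gaussianPatch(d, vs, pos[i, ], amp[i], sigma)
    if (is.null(p)) next
    vol[p$lo[1L]:p$hi[1L], p$lo[2L]:p$hi[2L], p$lo[3L]:p$hi[3L]] <-
      vol[p$lo[1L]:p$hi[1L], p$lo[2L]:p$hi[2L], p$lo[3L]:p$hi[3L]] + p$patch
  }
  if (noiseSd > 0) vol <- vol + rnorm(length(vol), 0, noiseSd)
  vol[vol < 0] <- 0
  new("ImageStack", voxels = array(vol, c(d, 1L)), voxelSize = vs,
      channelNames = "centrin")
}

test_that("maxima search resolves spots by the anisotropic search radii", {
  # two spots 1.0 um apart in xy: both found
  st <- spotStack(rbind(c(2.5, 3, 3), c(3.5, 3, 3)))
  mx <- findMaxima(st)
  near <- mx[mx$peak > 100, ]
  expect_equal(nrow(near), 2L)
  # 0.2 um apart in xy (inside the 0.25 um search radius): merged to one
  st2 <- spotStack(rbind(c(2.9, 3, 3), c(3.1, 3, 3)))
  mx2 <- findMaxima(st2)
  expect_equal(sum(mx2$peak > 100), 1L)
  # coarse calibration errors
  stBad <- new("ImageStack",
               voxels = array(runif(8 * 8 * 4), c(8, 8, 4, 1)),
               voxelSize = c(1, 1, 1), channelNames = "ch")
  expect_error(findMaxima(stBad), "calibration too coarse")
})

test_that("maxima cover the ground truth of a noise-free cell", {
  spec <- cellSpec(semiAxes = c(6, 4, 4), nRows = 12L, oaBBCount = 0L,
                   noiseModel = c(0, 0), attenuationCoeff = 0,
                   background = 0, cytoplasm = 0, oaPlateau = 0, seed = 4,
                   spacingProfile = function(u) rep(1.5, length(u)),
                   capAngleDeg = 30)
  gt <- placeBasalBodies(spec)
  st <- renderStack(gt)
  mx <- findMaxima(st)
  vs <- voxelSize(st)
  found <- as.matrix(mx[, c("x", "y", "z")])
  for (i in seq_len(nrow(gt@positions))) {
    d <- sqrt(rowSums(sweep(found, 2L, gt@positions[i, ])^2))
    expect_lt(min(d), sqrt(sum(vs^2)))   # within one voxel diagonal
  }
})

test_that("the adaptive threshold evaluates the published formula", {
  # window built to have I_avg = 100, I_sd = 10 (population moments), so
  # threshold = ((6 - 0.1*6) * 10) + 100 = 154
  ints <- c(90, 110, 90, 110, 90, 110, 90, 110, 200)
  zs <- rep(1, length(ints))
  mx <- data.frame(ix = 1, iy = 1, iz = 1, x = 0, y = 0, z = zs,
                   peak = ints, accepted = NA, reason = "none")
  # population sd of the first 8 is 10; the 200 peak perturbs it, so use
  # a window of only the 8 calibration maxima plus the candidate placed in
  # a different z plane outside the rolling window
  mx$z[9] <- 10
  expect_warning(out <- adaptiveThreshold(mx, pipelineConfig()),
                 "falling back")
  win <- ints[1:8]
  avg <- mean(win); s <- sd(win); cv <- s / avg
  expect_equal(out$threshold[1L], (6 - cv * 6) * s + avg)
  # direct check of the printed arithmetic at avg 100, sd 10:
  expect_equal((6 - 0.1 * 6) * 10 + 100, 154)
})

test_that("equal-intensity windows degenerate to the mean threshold", {
  mx <- data.frame(ix = 1, iy = 1, iz = 1, x = 0, y = 0,
                   z = rep(1, 6), peak = rep(100, 6),
                   accepted = NA, reason = "none")
  out <- adaptiveThreshold(mx, pipelineConfig())
  expect_true(all(out$threshold == 100))
  # the formula degenerates to the window mean: only maxima strictly above
  # it could pass, and an all-equal window therefore keeps nothing
  expect_true(all(!out$accepted))
})

test_that("the threshold is invariant to global intensity scaling", {
  set.seed(6)
  mx <- data.frame(ix = 1, iy = 1, iz = 1, x = 0, y = 0,
                   z = rep(c(1, 1.2), 50),
                   peak = c(rexp(90, 1 / 50) + 100, runif(10, 400, 900)),
                   accepted = NA, reason = "none")
  out1 <- adaptiveThreshold(mx, pipelineConfig())
  mx2 <- mx; mx2$peak <- mx$peak * 7.3
  out2 <- adaptiveThreshold(mx2, pipelineConfig())
  expect_identical(out1$accepted, out2$accepted)
  expect_equal(out2$threshold, out1$threshold * 7.3)
})

test_that("interior maxima beyond 2.25 um from the hull are deleted", {
  set.seed(7)
  sph <- matrix(rnorm(900), ncol = 3L)
  sph <- sph / sqrt(rowSums(sph^2)) * 10 + 12
  depth3 <- sph[1:10, ] * NA
  dirs <- (sph[1:10, ] - 12) / 10
  depth3 <- 12 + dirs * 7            # 3 um under the surface
  onSurf <- sph[11:300, ]
  mx <- data.frame(x = c(onSurf[, 1L], depth3[, 1L]),
                   y = c(onSurf[, 2L], depth3[, 2L]),
                   z = c(onSurf[, 3L], depth3[, 3L]))
  mx$ix <- 1L; mx$iy <- 1L; mx$iz <- 1L
  mx$peak <- 1; mx$accepted <- TRUE; mx$reason <- "none"
  out <- removeInterior(mx, pipelineConfig())
  expect_true(all(out$accepted[1:290]))
  expect_true(all(!out$accepted[291:300]))
  expect_true(all(out$reason[291:300] == "interior"))
  # a coplanar set skips the filter with a warning
  flat <- mx[1:20, ]; flat$z <- 5
  expect_warning(out2 <- removeInterior(flat, pipelineConfig()),
                 "degenerate")
  expect_true(all(out2$accepted))
})

test_that("skew/kurtosis statistics separate spots from plateaus", {
  vs <- c(0.125, 0.125, 0.3)
  # isolated Gaussian spot on dark background
  st <- spotStack(matrix(c(3, 3, 3), 1L), bg = 10)
  mxRow <- data.frame(ix = round(3 / vs[1L]) + 1L, iy = round(3 / vs[2L]) + 1L,
                      iz = round(3 / vs[3L]) + 1L, x = 3, y = 3, z = 3,
                      peak = 1000, accepted = TRUE, reason = "none")
  out <- classifyOralApparatus(mxRow, st, pipelineConfig())
  expect_gt(out$skew[1L], 0)
  expect_gt(out$kurt[1L], 0)
  expect_true(out$accepted[1L])
  # dense near-diffraction-limit cluster on a bright plateau, the oral
  # apparatus condition: excluded
  grid <- as.matrix(expand.grid(x = seq(2, 4, by = 0.3),
                                y = seq(2, 4, by = 0.3)))
  cl <- cbind(grid, 3)
  stP <- spotStack(cl, amp = 600, bg = 10)
  v <- stP@voxels
  vs2 <- voxelSize(stP)
  xs <- (seq_len(dim(v)[1L]) - 1) * vs2[1L] - 3
  ys <- (seq_len(dim(v)[2L]) - 1) * vs2[2L] - 3
  plateau <- 500 * exp(-(sqrt(outer(xs^2, ys^2, "+")) / 1.3)^4)
  for (z in seq_len(dim(v)[3L])) v[, , z, 1L] <- v[, , z, 1L] + plateau
  stP@voxels <- v
  outP <- classifyOralApparatus(mxRow, stP, pipelineConfig())
  expect_lt(outP$skew[1L] + outP$kurt[1L], 1)
  expect_false(outP$accepted[1L])
  expect_equal(outP$reason[1L], "oral_apparatus")
  # perfectly uniform box: undefined moments, flagged and excluded
  stU <- st
  vU <- stU@voxels; vU[] <- 7; stU@voxels <- vU
  outU <- classifyOralApparatus(mxRow, stU, pipelineConfig())
  expect_false(outU$accepted[1L])
})

test_that("detection stages only ever remove candidates", {
  cell <- defaultCell()
  audit <- cell$res$detection$audit
  n0 <- nrow(audit)
  n1 <- sum(audit$reason != "noise")
  n2 <- sum(!audit$reason %in% c("noise", "interior"))
  n3 <- sum(audit$accepted)
  expect_true(n0 >= n1 && n1 >= n2 && n2 >= n3)
  expect_true(all(audit$reason[audit$accepted] == "none"))
})
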