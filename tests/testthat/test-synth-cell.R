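test_that("constant spacing profile yields constant within-row spacing", {
  spec <- cellSpec(semiAxes = c(10, 10, 10), nRows = 12L, capAngleDeg = 20,
                   spacingProfile = function(u) rep(2, length(u)),
                   oaBBCount = 0L, seed = 7)
  gt <- placeBasalBodies(spec)
  for (r in unique(gt@rowId)) {
    idx <- which(gt@rowId == r)
    idx <- idx[order(gt@orderInRow[idx])]
    d <- sqrt(rowSums(diff(gt@positions[idx, ])^2))
    # chord vs arc differ by curvature only; 1% at 2 um on a 10 um sphere
    expect_true(all(abs(d - 2) / 2 < 0.01))
  }
})

test_that("default preset produces a plausible cortical BB complement", {
  gt <- defaultCell()$gt
  n <- nrow(bbPositions(gt))
  expect_gte(n, 350)
  expect_lte(n, 650)
  expect_equal(length(unique(gt@rowId)), 20L)
  # all positions on the ellipsoid surface
  spec <- defaultCell()$spec
  ctr <- spec@semiAxes + 2.5
  rho <- rowSums(sweep(sweep(bbPositions(gt), 2L, ctr), 2L,
                       spec@semiAxes, "/")^2)
  expect_lt(max(abs(rho - 1)), 1e-9)
})

test_that("placement and rendering are deterministic given the seed", {
  spec <- cellSpec(seed = 55, oaBBCount = 30L)
  gt1 <- placeBasalBodies(spec)
  gt2 <- placeBasalBodies(spec)
  expect_identical(gt1@positions, gt2@positions)
  expect_identical(gt1@intensities, gt2@intensities)
  sm <- cellSpec(semiAxes = c(6, 4, 4), nRows = 12L, oaBBCount = 10L,
                 capAngleDeg = 25, seed = 55)
  st1 <- renderStack(placeBasalBodies(sm))
  st2 <- renderStack(placeBasalBodies(sm))
  expect_identical(st1@voxels, st2@voxels)
})

test_that("an oversized spacing profile is rejected", {
  spec <- cellSpec(spacingProfile = function(u) rep(40, length(u)))
  expect_error(placeBasalBodies(spec), "fewer than 3")
})

test_that("zero-rate perturbation is the identity", {
  gt <- defaultCell()$gt
  expect_identical(injectPerturbations(gt, 0, 0, 0), gt)
})

test_that("injected gaps leave flanking pairs farther apart than 3 um", {
  gt0 <- defaultCell()$gt
  gt <- injectPerturbations(gt0, gapRate = 0.03, disorientSd = 0,
                            daughterRate = 0, seed = 11)
  expect_gt(nrow(gt@gapFlanks), 0L)
  fd <- sqrt(rowSums((gt@positions[gt@gapFlanks[, 1L], , drop = FALSE] -
                        gt@positions[gt@gapFlanks[, 2L], , drop = FALSE])^2))
  expect_true(all(fd > 3))
  # flanks are row neighbours after deletion
  expect_true(all(gt@rowId[gt@gapFlanks[, 1L]] == gt@rowId[gt@gapFlanks[, 2L]]))
  expect_true(all(gt@orderInRow[gt@gapFlanks[, 2L]] -
                    gt@orderInRow[gt@gapFlanks[, 1L]] == 1L))
  # recompute pairwise distances of surviving points: only flank pairs (and
  # pre-existing > 3 um pairs, of which the default profile has none) gap
  spacings <- unlist(lapply(unique(gt@rowId), function(r) {
    idx <- which(gt@rowId == r)
    idx <- idx[order(gt@orderInRow[idx])]
    sqrt(rowSums(diff(gt@positions[idx, , drop = FALSE])^2))
  }))
  expect_equal(sum(spacings > 3), nrow(gt@gapFlanks))
})

test_that("daughter dimming follows the half-intensity rule and binomial count", {
  gt0 <- defaultCell()$gt
  gt <- injectPerturbations(gt0, 0, 0, daughterRate = 0.15, seed = 12)
  n <- nrow(gt@positions)
  # flags match an independent recomputation of the rule
  for (r in unique(gt@rowId)[1:5]) {
    idx <- which(gt@rowId == r)
    idx <- idx[order(gt@orderInRow[idx])]
    a <- idx[-length(idx)]; p <- idx[-1L]
    expect_identical(gt@daughterFlags[a],
                     unname(gt@intensities[a, 2L] < 0.5 * gt@intensities[p, 2L]))
    expect_false(gt@daughterFlags[idx[length(idx)]])
  }
  # count close to rate * eligible (binomial 3-sigma band)
  eligible <- n - length(unique(gt@rowId))
  expected <- 0.15 * eligible
  expect_lt(abs(sum(gt@daughterFlags) - expected),
            3 * sqrt(eligible * 0.15 * 0.85) + 3)
})

test_that("disorientation jitter moves BBs laterally with the stated sd", {
  gt0 <- defaultCell()$gt
  gt <- injectPerturbations(gt0, 0, disorientSd = 8, 0, seed = 13)
  disp <- gt@positions - gt0@positions
  # displacement is purely lateral (no x component: azimuthal direction)
  expect_lt(max(abs(disp[, 1L])), 1e-9)
  mag <- sqrt(rowSums(disp^2))
  expect_gt(sd(mag), 0)
})

test_that("rendered single spot peaks at the true position", {
  # geometry chosen so every spot is isolated (nearest neighbour ~2 um)
  spec <- cellSpec(semiAxes = c(8, 6, 6), nRows = 12L, oaBBCount = 0L,
                   noiseModel = c(0, 0), attenuationCoeff = 0,
                   background = 0, cytoplasm = 0, oaPlateau = 0, seed = 1,
                   spacingProfile = function(u) rep(3, length(u)),
                   capAngleDeg = 40)
  gt <- placeBasalBodies(spec)
  st <- renderStack(gt)
  vol <- voxelData(st, 1L)
  vs <- voxelSize(st)
  # every spot's voxel argmax within half a voxel of the truth
  for (i in seq_len(min(10L, nrow(gt@positions)))) {
    p <- gt@positions[i, ]
    lo <- pmax(1L, round(p / vs) - 2L); hi <- pmin(dim(vol), round(p / vs) + 4L)
    sub <- vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    am <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    peakUm <- (lo - 1L + am - 1L) * vs
    expect_true(all(abs(peakUm - p) <= vs / 2 + 1e-9))
  }
})

test_that("depth attenuation follows the exponential law", {
  # coefficient such that the far surface renders at 40% of the near one:
  # peak ratio front/back evaluates to 1 / 0.4 = 2.5
  depthSpan <- 6
  k <- 1 - 0.4^(1 / depthSpan)
  spec <- cellSpec(semiAxes = c(5, 3, 3), nRows = 12L, oaBBCount = 0L,
                   noiseModel = c(0, 0), attenuationCoeff = k,
                   background = 0, cytoplasm = 0, oaPlateau = 0,
                   amplitudeCv = 0, seed = 2,
                   spacingProfile = function(u) rep(2.5, length(u)),
                   capAngleDeg = 30)
  gt <- placeBasalBodies(spec)
  st <- renderStack(gt)
  vol <- voxelData(st, 1L)
  vs <- voxelSize(st)
  zs <- gt@positions[, 3L]
  front <- which.min(zs); back <- which(abs(zs - (min(zs) + depthSpan)) < 0.2)[1L]
  peakAt <- function(i) {
    p <- round(gt@positions[i, ] / vs) + 1L
    max(vol[(p[1L] - 1L):(p[1L] + 1L), (p[2L] - 1L):(p[2L] + 1L),
            (p[3L] - 1L):(p[3L] + 1L)])
  }
  ratio <- peakAt(front) / peakAt(back)
  expected <- (1 - k)^(zs[front] - zs[back])
  expect_lt(abs(ratio - expected) / expected, 0.1)
  expect_lt(abs(expected - 2.5) / 2.5, 0.1)
})

test_that("noise-free integrated signal matches the analytic Gaussian volume", {
  spec <- cellSpec(semiAxes = c(4, 3, 3), nRows = 12L, oaBBCount = 0L,
                   noiseModel = c(0, 0), attenuationCoeff = 0,
                   background = 0, cytoplasm = 0, oaPlateau = 0,
                   amplitudeCv = 0, seed = 3,
                   spacingProfile = function(u) rep(2.5, length(u)),
                   capAngleDeg = 35)
  gt <- placeBasalBodies(spec)
  st <- renderStack(gt)
  vol <- voxelData(st, 1L)
  vs <- voxelSize(st)
  gaussVol <- (2 * pi)^1.5 * prod(spec@psfSigma)
  expected <- sum(gt@intensities[, 1L]) * gaussVol / prod(vs)
  expect_lt(abs(sum(vol) - expected) / expected, 0.01)
})

test_that("rendered spot count is conserved (truth table round trip)", {
  gt <- defaultCell()$gt
  f <- file.path(tempdir(), "gt.csv")
  writeGroundTruth(gt, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), nrow(gt@positions) + nrow(gt@oaPositions))
  expect_equal(sum(tab$is_oa), nrow(gt@oaPositions))
  expect_equal(sum(tab$is_daughter), sum(gt@daughterFlags))
  unlink(f)
})
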