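test_that("background COV: zero for constant images, hand value, scale invariant", {
  rois <- roiSet(bgCenters = matrix(0, 1, 3), bgRadius = 50)
  const <- new("ActivityImage", data = array(7, c(4, 4, 1)), voxelSize = c(2, 2, 2))
  expect_equal(backgroundCOV(const, rois), 0)

  # voxels {1, 1, 3, 3}: mean 2, population SD 1 -> COV 0.5
  img <- new("ActivityImage", data = array(c(1, 1, 3, 3), c(2, 2, 1)),
             voxelSize = c(2, 2, 2))
  expect_equal(backgroundCOV(img, rois), 0.5)
  scaled <- img; scaled@data <- img@data * 17
  expect_equal(backgroundCOV(scaled, rois), 0.5)

  outside <- roiSet(bgCenters = matrix(c(500, 0, 0), 1, 3), bgRadius = 5)
  expect_error(backgroundCOV(img, outside), "no voxels")
})

test_that("recovery coefficients: exact on the ground truth, monotone after blur", {
  dro <- smallIQ()
  rois <- iqROISet(dro)
  rc <- recoveryCoefficients(dro@activity, rois, 21)
  expect_equal(rc$rcMean, rep(1, 6))
  expect_true(all(rc$rcMax >= rc$rcMean))

  blurred <- smoothSystemPSF(dro@activity, 7)
  rcB <- recoveryCoefficients(blurred, rois, 21)
  ord <- order(rois@sphereDiameters)
  expect_true(all(diff(rcB$rcMean[ord]) > 0))
  expect_true(all(rcB$rcMax >= rcB$rcMean))

  # intensity-scale invariance when the expected activity scales along
  scaled <- blurred; scaled@data <- blurred@data * 3
  rcS <- recoveryCoefficients(scaled, rois, 63)
  expect_equal(rcS$rcMean, rcB$rcMean, tolerance = 1e-12)

  expect_error(recoveryCoefficients(dro@activity, rois, 0), "expected > 0")
})

test_that("replicate statistics: SD identities and Poisson variance structure", {
  img <- array(runif(4 * 4 * 2), c(4, 4, 2))
  same <- new("ReplicateStack", images = array(rep(img, 3), c(4, 4, 2, 3)),
              voxelSize = c(3, 3, 3), seeds = 1:3,
              simParams = simulationParams(), reconParams = reconParams())
  st <- replicateStatistics(same)
  expect_true(all(st$sdImage@data == 0))
  expect_equal(st$meanImage@data, img)

  a <- array(runif(8), c(2, 2, 2)); b <- array(runif(8), c(2, 2, 2))
  two <- new("ReplicateStack", images = array(c(a, b), c(2, 2, 2, 2)),
             voxelSize = c(3, 3, 3), seeds = 1:2,
             simParams = simulationParams(), reconParams = reconParams())
  st2 <- replicateStatistics(two)
  expect_equal(st2$sdImage@data, abs(a - b) / sqrt(2), tolerance = 1e-12)

  one <- new("ReplicateStack", images = array(a, c(2, 2, 2, 1)),
             voxelSize = c(3, 3, 3), seeds = 1L,
             simParams = simulationParams(), reconParams = reconParams())
  expect_error(replicateStatistics(one), "2 replicates")
})

test_that("SD image is higher in hot spheres than in the cold background", {
  dro <- smallIQ(matrix = c(96, 96, 8))
  sp <- simulationParams(sensitivityFactor = 0.005, nReplicates = 4L, seed = 9L)
  st <- simulateReplicates(dro, sp, reconParams(iterations = 2L))
  sd <- replicateStatistics(st)$sdImage@data
  hot <- dro@activity@data == 21
  bg <- dro@activity@data == 2.1
  expect_gt(mean(sd[hot]), mean(sd[bg]))
})

test_that("COV scaling with duration follows the square-root law", {
  expect_equal(expectedCOVScaling(0.71, 30, 30), 0.71)
  expect_lt(abs(expectedCOVScaling(0.71, 30, 60) - 0.50), 0.005)
  expect_lt(abs(expectedCOVScaling(0.71, 30, 300) - 0.22), 0.005)
  expect_error(expectedCOVScaling(0.5, 0, 60), "positive")
  expect_error(expectedCOVScaling(-0.1, 30, 60), ">= 0")
})

test_that("expected TOF gain: closed form and break-even point", {
  expect_lt(abs(expectedTOFGain(450, 0.27) - 2.0), 0.05)
  expect_lt(abs(expectedTOFGain(350, 0.27) - 2.27), 0.005)
  breakEven <- 2 * 0.27 / 2.998e8 * 1e12  # c * dt = 2 D
  expect_equal(expectedTOFGain(breakEven, 0.27), 1)
  expect_error(expectedTOFGain(0, 0.27), "positive")
  expect_error(expectedTOFGain(450, -1), "positive")
})

test_that("background ROI placement is reproducible, inside the torso, away from spheres", {
  for (mat in list(c(96, 96, 16), c(170, 170, 15))) {
    vox <- if (mat[1] == 170) c(3, 3, 2) else c(3, 3, 3)
    dro <- generateIQPhantom(phantomSpec(voxelSize = vox, matrixSize = mat))
    r1 <- iqROISet(dro)
    r2 <- iqROISet(dro)
    expect_identical(r1@bgCenters, r2@bgCenters)
    expect_equal(nrow(r1@bgCenters), 6L)
    # fully inside the torso in-plane (erosion by the ROI radius)
    expect_true(all(PETsim:::inTorso2D(r1@bgCenters[, 1], r1@bgCenters[, 2],
                                       erodeBy = r1@bgRadius)))
    # >= 10 mm margin to every hot sphere surface in 3D
    for (i in seq_len(6)) {
      d <- sqrt(colSums((t(r1@bgCenters) - r1@sphereCenters[i, ])^2))
      expect_true(all(d >= r1@sphereDiameters[i] / 2 + r1@bgRadius + 10 - 1e-9))
    }
  }
})

test_that("sensitivity calibration recovers a known factor and rejects bad targets", {
  dro <- smallIQ(matrix = c(96, 96, 10))
  rois <- iqROISet(dro)
  spBase <- simulationParams(sensitivityFactor = 0.005, seed = 21L, nReplicates = 2L)
  rp <- reconParams(iterations = 2L)
  # measured COV at the known factor
  st <- simulateReplicates(dro, spBase, rp)
  target <- mean(vapply(1:2, function(i)
    backgroundCOV(getReplicate(st, i), rois), numeric(1)))
  # calibrate starting from a factor 4x off
  spStart <- simulationParams(sensitivityFactor = 0.02, seed = 21L)
  cal <- calibrateSensitivity(dro, target, spStart, rp, rois = rois,
                              nCalibrationReplicates = 2L, tol = 0.05)
  expect_lt(abs(cal$achievedCOV - target) / target, 0.05)
  # monotone: the higher of two factors in the history has the lower COV
  h <- cal$history[order(cal$history$factor), ]
  if (nrow(h) > 1) expect_true(all(diff(h$cov) < 0))

  expect_error(calibrateSensitivity(dro, -0.1, spStart, rp, rois = rois),
               "positive")
})

test_that("analyzeReplicates assembles COV, RC and SD images coherently", {
  dro <- smallIQ(matrix = c(96, 96, 10))
  sp <- simulationParams(sensitivityFactor = 0.01, nReplicates = 3L, seed = 2L)
  st <- simulateReplicates(dro, sp, reconParams(iterations = 2L))
  res <- analyzeReplicates(st, iqROISet(dro), expected = 21)
  expect_length(res@covPerReplicate, 3L)
  expect_equal(res@covMean, mean(res@covPerReplicate))
  expect_length(res@rcMean, 6L)
  expect_true(all(res@rcMax >= res@rcMean))
  expect_equal(dim(res@sdImage@data), dim(dro@activity@data))
})
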