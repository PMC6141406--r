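test_that("zero activity yields an all-zero projection set", {
  dro <- generateIQPhantom(phantomSpec(backgroundActivity = 0, sphereActivity = 0,
                                       voxelSize = 3, matrixSize = c(96, 96, 6)))
  ps <- simulateNoiseFree(dro, simulationParams())
  expect_true(all(ps@trues@data == 0))
  expect_true(all(ps@scatter@data == 0))
  expect_true(all(ps@randoms@data == 0))
})

test_that("expected counts are linear in the scan duration", {
  dro <- smallIQ(matrix = c(96, 96, 6))
  p1 <- simulateNoiseFree(dro, simulationParams(scanDuration = 60))
  p2 <- simulateNoiseFree(dro, simulationParams(scanDuration = 120))
  expect_equal(p2@trues@data, 2 * p1@trues@data, tolerance = 1e-12)
  expect_equal(p2@scatter@data, 2 * p1@scatter@data, tolerance = 1e-12)
  expect_equal(p2@randoms@data, 2 * p1@randoms@data, tolerance = 1e-12)
})

test_that("without attenuation the trues total equals sensitivity x duration x projected mass", {
  dro <- smallIQ(matrix = c(96, 96, 6))
  att0 <- new("AttenuationMap", data = array(0, dim(dro@activity@data)),
              voxelSize = dro@activity@voxelSize)
  params <- simulationParams(sensitivityFactor = 0.01, scanDuration = 80,
                             systemFWHM = 5)
  ps <- simulateNoiseFree(dro, params, attnOverride = att0)
  sm <- smoothSystemPSF(dro@activity, params@systemFWHM)
  expect_rel_equal(sum(ps@trues@data),
                   0.01 * 80 * sum(forwardProject(sm)@data), 1e-6)
})

test_that("scatter component: exact fraction, zero case, smoother than trues", {
  dro <- smallIQ(matrix = c(96, 96, 6))
  ps <- simulateNoiseFree(dro, simulationParams(scatterFraction = 0.3))
  expect_rel_equal(sum(ps@scatter@data), 0.3 * sum(ps@trues@data), 1e-6)
  ps0 <- simulateNoiseFree(dro, simulationParams(scatterFraction = 0))
  expect_true(all(ps0@scatter@data == 0))

  # normalised high-frequency energy along the radial axis is lower for scatter
  hf <- function(x) {
    d <- apply(x, c(1, 2), function(row) sum(diff(row)^2))
    sum(d) / sum(x^2)
  }
  expect_lt(hf(ps@scatter@data), hf(ps@trues@data))
})

test_that("randoms are uniform with the exact requested total", {
  dro <- smallIQ(matrix = c(96, 96, 6))
  ps <- simulateNoiseFree(dro, simulationParams(randomsFraction = 0.2))
  expect_equal(length(unique(as.vector(ps@randoms@data))), 1L)
  expect_rel_equal(sum(ps@randoms@data), 0.2 * sum(ps@trues@data), 1e-9)
  shape <- dim(ps@randoms@data)
  expect_equal(ps@randoms@data[1, 1, 1],
               0.2 * sum(ps@trues@data) / prod(shape))
  ps0 <- simulateNoiseFree(dro, simulationParams(randomsFraction = 0))
  expect_true(all(ps0@randoms@data == 0))
})

test_that("Poisson engine: zero means, determinism, first two moments", {
  base <- discImage(16, 4, 20, 0)  # zero image
  p <- forwardProject(base)
  psZero <- new("ProjectionSet", trues = p, scatter = zeroSino(p),
                randoms = zeroSino(p), attenuation = unitAttn(p),
                params = simulationParams())
  expect_true(all(addPoissonNoise(psZero, seed = 1)@data == 0))

  # constant mean-100 sinogram with >= 1e4 bins
  n <- 16
  const <- new("Sinogram", data = array(100, c(8, 128, n)), binSize = 4,
               sliceThickness = 4, angles = PETsim:::projectionAngles())
  psC <- new("ProjectionSet", trues = const, scatter = zeroSino(const),
             randoms = zeroSino(const), attenuation = unitAttn(const),
             params = simulationParams())
  d1 <- addPoissonNoise(psC, seed = 99)@data
  d2 <- addPoissonNoise(psC, seed = 99)@data
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1) / 100 - 1), 0.01)
  expect_lt(abs(var(as.vector(d1)) / mean(d1) - 1), 0.05)
})

test_that("expected prompts equal trues + scatter + randoms (count bookkeeping)", {
  dro <- smallIQ(matrix = c(72, 72, 2), voxel = c(4, 4, 4))
  ps <- simulateNoiseFree(dro, simulationParams(sensitivityFactor = 0.001))
  expected <- sum(ps@trues@data) + sum(ps@scatter@data) + sum(ps@randoms@data)
  totals <- vapply(seq_len(200), function(i)
    sum(addPoissonNoise(ps, seed = 1000 + i)@data), numeric(1))
  # mean of totals within 4 standard errors of the expectation
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(totals) - expected), 4 * se)
})

test_that("repositioning: identity, misalignment displacement, determinism", {
  iq <- smallIQ(matrix = c(96, 96, 8))
  none <- applyRepositioning(iq)
  expect_equal(none$dro@activity@data, iq@activity@data)
  expect_equal(none$correctionMu@data, PETsim:::droMu(iq)@data)

  # a compact object (margins on every axis) so no mass leaves the FOV
  dro <- generateCylinderPhantom(diameter = 160, voxelSize = 6,
                                 matrixSize = c(48, 48, 16), length = 48)
  mis <- applyRepositioning(dro, ctMisalignment = c(10, 0, 0))
  com <- function(a, voxel) {
    co <- (seq_len(dim(a)[1]) - 1 - (dim(a)[1] - 1) / 2) * voxel
    sum(apply(a, 1, sum) * co) / sum(a)
  }
  shiftX <- com(mis$correctionMu@data, 6) - com(PETsim:::droMu(dro)@data, 6)
  expect_lt(abs(shiftX - 10), 0.5)
  # truth pair untouched by pure misalignment
  expect_equal(mis$dro@activity@data, dro@activity@data)

  s1 <- applyRepositioning(dro, maxShift = c(5, 5, 2), seed = 7)
  s2 <- applyRepositioning(dro, maxShift = c(5, 5, 2), seed = 7)
  expect_identical(s1$shift, s2$shift)
  expect_equal(s1$dro@activity@data, s2$dro@activity@data)

  expect_error(applyRepositioning(dro, maxShift = c(500, 0, 0)), "half the field")
})

test_that("replicate stacks are reproducible and statistically distinct", {
  dro <- smallIQ(matrix = c(96, 96, 4))
  sp <- simulationParams(sensitivityFactor = 0.002, nReplicates = 3L, seed = 5L)
  rp <- reconParams(iterations = 2L)
  st1 <- simulateReplicates(dro, sp, rp)
  st2 <- simulateReplicates(dro, sp, rp)
  expect_identical(st1@images, st2@images)
  expect_identical(st1@seeds, st2@seeds)
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(max(abs(st1@images[, , , i] - st1@images[, , , j])), 0)
})

test_that("in the high-count limit a replicate approaches the noise-free reconstruction", {
  dro <- smallIQ(matrix = c(96, 96, 4))
  sp <- simulationParams(sensitivityFactor = 100, nReplicates = 1L, seed = 5L,
                         randomsFraction = 0, scatterFraction = 0)
  rp <- reconParams(iterations = 2L)
  st <- simulateReplicates(dro, sp, rp)
  ps <- simulateNoiseFree(dro, sp)
  recNF <- osemReconstruct(ps@trues, ps@attenuation, ps@scatter, ps@randoms, rp)
  recNF@data <- recNF@data / (100 * sp@scanDuration)
  m <- dro@activity@data > 0
  relDiff <- mean(abs(st@images[, , , 1][m] - recNF@data[m])) / mean(recNF@data[m])
  expect_lt(relDiff, 0.02)
})
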