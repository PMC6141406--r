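test_that("forward and back projection are exact adjoints", {
  set.seed(11)
  n <- 48
  img <- new("ActivityImage", data = array(abs(rnorm(n * n * 2)), c(n, n, 2)),
             voxelSize = c(2, 2, 2))
  y <- forwardProject(img)
  yr <- y
  yr@data <- array(rnorm(length(y@data)), dim(y@data))
  bp <- backProject(yr)
  lhs <- sum(y@data * yr@data)
  rhs <- sum(img@data * bp@data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("a centred point source projects to the central bin at every angle", {
  n <- 49
  a <- array(0, c(n, n, 1))
  a[(n + 1) / 2, (n + 1) / 2, 1] <- 1
  p <- forwardProject(new("ActivityImage", data = a, voxelSize = c(2, 2, 2)))
  peaks <- apply(p@data[1, , ], 1, which.max)
  expect_true(all(peaks == (n + 1) / 2))
})

test_that("projection of a uniform disc matches the closed-form Radon transform", {
  n <- 96; v <- 2; R <- 40; val <- 1
  di <- discImage(n, v, R, val)
  p <- forwardProject(di)
  co <- (seq_len(n) - 1 - (n - 1) / 2) * v
  expected <- 2 * val * sqrt(pmax(R^2 - co^2, 0))
  for (a in c(1, 33, 64, 100)) {
    err <- max(abs(p@data[1, a, ] - expected))
    expect_lt(err / max(expected), 0.05)
  }
  # mass conservation: bin sum x bin size = image sum x voxel area
  for (a in c(1, 50, 128))
    expect_rel_equal(sum(p@data[1, a, ]) * v, sum(di@data) * v * v, 0.01)
})

test_that("projecting a 90-degree-rotated image permutes the angles", {
  set.seed(4)
  n <- 48; v <- 2
  img <- array(0, c(n, n, 1))
  img[, , 1] <- matrix(abs(rnorm(n * n)), n)
  img <- PETsim:::gaussianBlur3D(img, c(6, 6, 0), c(v, v, v))
  co <- (seq_len(n) - 1 - (n - 1) / 2) * v
  img[, , 1][outer(co^2, co^2, `+`) > (n * v / 2 * 0.85)^2] <- 0
  p <- forwardProject(new("ActivityImage", data = img, voxelSize = c(v, v, v)))
  rot <- img
  rot[, , 1] <- t(img[, , 1])[, n:1]   # (x, y) -> (-y, x)
  pr <- forwardProject(new("ActivityImage", data = rot, voxelSize = c(v, v, v)))
  for (a in seq_len(128)) {
    b <- ((a - 1 - 64) %% 128) + 1
    ref <- if (a > 64) rev(p@data[1, b, ]) else p@data[1, b, ]
    expect_lt(max(abs(pr@data[1, a, ] - ref)), 1e-8 * max(p@data))
  }
})

test_that("back projection of a zero sinogram is zero and rejects bad shapes", {
  di <- discImage(32, 3, 30, 1)
  p <- forwardProject(di)
  z <- zeroSino(p)
  expect_true(all(backProject(z)@data == 0))
  bad <- di
  bad@data[1, 1, 1] <- NaN
  expect_error(forwardProject(bad), "non-finite")
  rect <- new("ActivityImage", data = array(0, c(16, 24, 1)), voxelSize = c(2, 2, 2))
  expect_error(forwardProject(rect), "square")
})

test_that("TOF sinogram marginalises exactly to the non-TOF projection", {
  di <- discImage(48, 4, 60, 2, nslice = 2)
  p <- forwardProject(di)
  pt <- forwardProjectTOF(di, 450)
  marg <- apply(pt@data, 1:3, sum)
  expect_lt(max(abs(marg - p@data)) / max(p@data), 1e-6)
})

test_that("TOF kernel width follows c*dt/2 and very wide kernels flatten the bins", {
  # 450 ps -> 67.5 mm spatial FWHM (c = 2.998e8 m/s)
  expect_equal(PETsim:::tofKernelFwhmMm(450), 2.998e8 * 450e-12 / 2 * 1000)
  expect_lt(abs(PETsim:::tofKernelFwhmMm(450) - 67.5), 0.1)

  # fitted FWHM of the TOF profile of a point source
  n <- 49; v <- 4
  a <- array(0, c(n, n, 1)); a[(n + 1) / 2, (n + 1) / 2, 1] <- 1
  pt <- forwardProjectTOF(new("ActivityImage", data = a, voxelSize = c(v, v, v)), 450)
  prof <- pt@data[1, 1, (n + 1) / 2, ]
  co <- (seq_len(n) - 1 - (n - 1) / 2) * v
  expect_lt(abs(PETsim:::profileFWHM(prof, co) - 67.455), 3)

  # flat-kernel limit: every TOF bin approaches (non-TOF)/(bin count)
  di <- discImage(32, 4, 40, 1)
  p <- forwardProject(di)
  ptBig <- forwardProjectTOF(di, 1e6)
  mid <- 10:22
  flat <- ptBig@data[1, 1, 16, mid]
  expect_lt(max(abs(flat - p@data[1, 1, 16] / 32)) / (p@data[1, 1, 16] / 32), 0.1)

  expect_error(forwardProjectTOF(di, 0), "positive")
  expect_error(forwardProjectTOF(di, -5), "positive")
})

test_that("collapseTOF returns the marginal sinogram", {
  di <- discImage(32, 4, 40, 1)
  pt <- forwardProjectTOF(di, 300)
  expect_equal(collapseTOF(pt)@data, apply(pt@data, 1:3, sum), tolerance = 1e-12)
})

test_that("CT to mu conversion is anchored, water-correct and monotone", {
  hu <- array(c(-1200, -1000, 0, 47, 500, 2000), c(6, 1, 1))
  ct <- new("CTImage", data = hu, voxelSize = c(1, 1, 1))
  mu <- ctToMu(ct)@data
  expect_equal(mu[2, 1, 1], 0)                 # air
  expect_lt(abs(mu[3, 1, 1] - 0.096), 0.002)   # water
  grid <- array(seq(-1000, 2000, by = 10), c(301, 1, 1))
  mug <- ctToMu(new("CTImage", data = grid, voxelSize = c(1, 1, 1)))@data
  expect_true(all(diff(as.vector(mug)) >= 0))
  expect_gte(min(mug), 0)
})

test_that("attenuation factors are exp(-mu line integral) with mm to cm conversion", {
  n <- 64; v <- 4
  zeroMu <- new("AttenuationMap", data = array(0, c(n, n, 1)), voxelSize = c(v, v, v))
  expect_true(all(attenuationFactors(zeroMu)@data == 1))

  centralFactor <- function(diam) {
    mu <- discImage(n, v, diam / 2, 0.096)
    af <- attenuationFactors(new("AttenuationMap", data = mu@data,
                                 voxelSize = mu@voxelSize))
    af@data[1, 1, n / 2]  # central LOR (bin nearest the axis)
  }
  a200 <- centralFactor(200)
  expect_rel_equal(a200, exp(-0.096 * 20), 0.05)
  a100 <- centralFactor(100); a300 <- centralFactor(250)
  expect_true(a100 > a200 && a200 > a300)

  neg <- new("AttenuationMap", data = array(-0.01, c(8, 8, 1)), voxelSize = c(4, 4, 4))
  expect_error(attenuationFactors(neg), ">= 0")
})

test_that("system PSF smoothing: identity at zero, correct FWHM, mass conserving", {
  di <- discImage(48, 2, 30, 3)
  expect_equal(smoothSystemPSF(di, 0)@data, di@data)

  n <- 65; v <- 1
  a <- array(0, c(n, n, 1)); a[33, 33, 1] <- 1
  delta <- new("ActivityImage", data = a, voxelSize = c(v, v, v))
  sm <- smoothSystemPSF(delta, c(7, 7, 0))
  co <- (seq_len(n) - 1 - (n - 1) / 2) * v
  expect_lt(abs(PETsim:::profileFWHM(sm@data[, 33, 1], co) - 7), 0.2)
  expect_rel_equal(sum(sm@data), sum(delta@data), 0.001)

  # a uniform image stays uniform in the interior
  u <- new("ActivityImage", data = array(4, c(32, 32, 8)), voxelSize = c(3, 3, 3))
  smu <- smoothSystemPSF(u, 5)
  expect_lt(max(abs(smu@data[10:22, 10:22, 4] - 4)), 1e-9)

  expect_error(smoothSystemPSF(di, c(-1, 0, 0)), ">= 0")
})
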