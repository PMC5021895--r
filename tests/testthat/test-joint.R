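# Joint model components: adaptive weight, sharpening offset, single-step
# updates against loop oracles, reductions, and model-level properties.

test_that("computeBeta follows the window range ratio with degenerate guards", {
  expect_equal(computeBeta(matrix(0.7, 6, 6), u = 2), matrix(0, 6, 6))
  expect_equal(computeBeta(matrix(0, 6, 6), u = 2), matrix(0, 6, 6))
  img <- matrix(0.2, 5, 5); img[3, 3] <- 0.8
  b <- computeBeta(img, u = 10)  # window covers the whole image everywhere
  expect_equal(b, matrix((0.8 - 0.2) / 0.8, 5, 5))
  set.seed(12)
  img <- matrix(runif(100), 10, 10)
  b <- computeBeta(img, u = 3)
  expect_true(all(b >= 0 & b <= 1))
})

test_that("computeAk is alpha times the squared distance to the nearest prototype", {
  img <- matrix(c(5, 3, 8, 6), 2, 2)
  a <- computeAk(img, prototypes = c(3, 8), alpha = 0.5)
  expect_equal(a[1, 1], 0.5 * min((5 - 3)^2, (5 - 8)^2))  # = 2
  expect_equal(a[2, 1], 0)   # exactly at a prototype
  expect_equal(a[1, 2], 0)
  set.seed(13)
  img <- matrix(runif(36), 6, 6)
  v <- c(0.2, 0.5, 0.9)
  a <- computeAk(img, v, alpha = 0.7)
  brute <- apply(sapply(v, function(vi) (as.vector(img) - vi)^2), 1, min)
  expect_equal(as.vector(a), 0.7 * brute, tolerance = 1e-14)
  expect_error(computeAk(img, v, alpha = 1.5), "alpha")
})

test_that("joint updates with beta=0, a=0, b=1 and delta kernel reduce to FCM", {
  set.seed(14)
  img <- matrix(runif(49), 7, 7)
  v <- c(0.3, 0.6)
  ones <- array(1, dim(img))
  u <- updateMembership(img, v, biasField = ones)
  D <- sapply(v, function(vi) (as.vector(img) - vi)^2)
  E <- D^(-1)
  expect_equal(matrix(u, ncol = 2), E / rowSums(E), tolerance = 1e-12)
  vNew <- updatePrototypes(img, u, biasField = ones)
  um <- matrix(u, ncol = 2)^2
  expect_equal(vNew, colSums(um * as.vector(img)) / colSums(um),
               tolerance = 1e-12)
})

test_that("bias update collapses to x/v for one crisp cluster with delta kernel", {
  set.seed(15)
  img <- matrix(runif(25) + 0.5, 5, 5)
  u1 <- array(1, dim = c(5, 5, 1))
  b <- updateBias(img, u1, prototypes = 1)
  expect_equal(b$bias, img, tolerance = 1e-12)
  b2 <- updateBias(img, u1, prototypes = 2)
  expect_equal(b2$bias, img / 2, tolerance = 1e-12)
})

test_that("single u/v/b updates match the loop transcription oracles", {
  ph <- makePhantom(shape = c(8, 8), classes = 3, geometry = "blobs",
                    biasModel = "linear-ramp", biasAmplitude = 0.2,
                    noisePercent = 10, seed = 16)
  img <- observedImage(ph)
  kern <- truncatedGaussianKernel(sigma = 1, rho = 2)
  v <- c(0.25, 0.5, 0.78)
  b <- smooth_test_bias(8, 8)
  xbar <- nonlocalMeanImage(img, s = 1, u = 2, h = 0.05)
  beta <- computeBeta(img, u = 2)
  ak <- computeAk(img, v, alpha = 0.9)

  u <- updateMembership(img, v, b, kern, m = 2, xbar = xbar, beta = beta,
                        ak = ak)
  expect_equal(u, oracle_update_u(img, v, b, kern@weights, 2, xbar, beta, ak),
               tolerance = 1e-12)
  vNew <- updatePrototypes(img, u, b, kern, m = 2, xbar = xbar, beta = beta)
  expect_equal(vNew, oracle_update_v(img, u, b, kern@weights, 2, xbar, beta),
               tolerance = 1e-12)
  bNew <- updateBias(img, u, vNew, kern, m = 2, xbar = xbar, beta = beta)
  expect_equal(bNew$bias,
               oracle_update_b(img, u, vNew, kern@weights, 2, xbar, beta),
               tolerance = 1e-12)
})

test_that("objective matches the CLIC criterion when beta = 0, a = 0", {
  set.seed(17)
  img <- matrix(runif(36), 6, 6)
  kern <- truncatedGaussianKernel(sigma = 1, rho = 1)
  v <- c(0.3, 0.8)
  b <- smooth_test_bias(6, 6)
  u <- updateMembership(img, v, b, kern)
  J <- jointObjective(img, u, v, b, kern)
  # direct CLIC criterion with explicit window loops
  Jdirect <- 0
  U <- u
  for (j in 1:6) for (i in 1:6) for (ci in 1:2) {
    for (dy in -1:1) for (dx in -1:1) {
      K <- kern@weights[dx + 2, dy + 2]
      br <- b[reflect1(i + dx, 6), reflect1(j + dy, 6)]
      Jdirect <- Jdirect + U[i, j, ci]^2 * K * (img[i, j] - br * v[ci])^2
    }
  }
  expect_equal(J, Jdirect, tolerance = 1e-10)
  # crisp exact labelling with b = 1, x at prototypes: J = 0
  imgc <- matrix(rep(c(0.3, 0.8), 18), 6, 6)
  uc <- updateMembership(imgc, v, array(1, c(6, 6)))
  expect_equal(jointObjective(imgc, uc, v, array(1, c(6, 6))), 0,
               tolerance = 1e-20)
})

test_that("correctImage inverts a multiplicative field exactly", {
  set.seed(18)
  x0 <- matrix(runif(64, 0.2, 1), 8, 8)
  b <- smooth_test_bias(8, 8)
  expect_equal(correctImage(x0, array(1, c(8, 8))), x0)
  expect_equal(correctImage(b, b), matrix(1, 8, 8), tolerance = 1e-14)
  expect_equal(correctImage(b * x0, b), x0, tolerance = 1e-13)
  expect_error(correctImage(x0, -b), "positive")
})

test_that("segmenting a doubled image yields the same partition with scaled outputs", {
  ph <- makePhantom(shape = c(32, 32), classes = 3, geometry = "blobs",
                    biasModel = "gaussian-bump", biasAmplitude = 0.2,
                    noisePercent = 5, seed = 19)
  x <- observedImage(ph)
  r1 <- suppressWarnings(segmentImage(x, method = "proposed", clusters = 3,
                                      seed = 19, epsilon = 1e-3))
  r2 <- suppressWarnings(segmentImage(2 * x, method = "proposed", clusters = 3,
                                      seed = 19, epsilon = 2e-3))
  expect_identical(labelMap(r1), labelMap(r2))
  expect_equal(prototypes(r2) / prototypes(r1), rep(2, 3), tolerance = 1e-8)
  expect_equal(biasField(r2), biasField(r1), tolerance = 1e-8)
})

test_that("a noise-free bias-free phantom is segmented perfectly", {
  ph <- makePhantom(shape = c(32, 32), classes = 3, seed = 20)
  res <- segmentImage(observedImage(ph), method = "proposed", clusters = 3,
                      seed = 20)
  expect_equal(jaccardValues(evaluate(res, ph)), rep(1, 3))
})

test_that("the bias field stays positive and smooth on phantom runs", {
  ph <- makePhantom(shape = c(32, 32), classes = 3, geometry = "blobs",
                    biasModel = "gaussian-bump", biasAmplitude = 0.3,
                    noisePercent = 5, seed = 21)
  res <- suppressWarnings(segmentImage(observedImage(ph), method = "proposed",
                                       clusters = 3, seed = 21))
  b <- biasField(res)
  expect_true(all(b > 0))
  expect_equal(mean(b), 1, tolerance = 1e-8)
  tv <- function(f) sum(abs(diff(f))) + sum(abs(t(diff(t(f)))))
  expect_lt(tv(b), tv(observedImage(ph)) / 2)
})

test_that("non-convergence returns the best state with a warning", {
  ph <- makePhantom(shape = c(16, 16), classes = 3, geometry = "blobs",
                    noisePercent = 10, seed = 22)
  expect_warning(
    res <- segmentImage(observedImage(ph), method = "fcm", clusters = 3,
                        seed = 22, maxIter = 2),
    "did not converge")
  expect_false(res@converged)
  expect_equal(res@iterations, 2L)
})

test_that("3D volumes run through the full joint pipeline", {
  set.seed(24)
  vol0 <- array(rep(c(0.2, 0.8), each = 500), dim = c(10, 10, 10))
  vol <- pmax(vol0 + rnorm(1000, sd = 0.05), 0)
  res <- suppressWarnings(segmentImage(vol, method = "proposed", clusters = 2,
                                       kernelRho = 2, patchRadius = 1,
                                       searchRadius = 2, seed = 24))
  expect_identical(dim(labelMap(res)), c(10L, 10L, 10L))
  expect_equal(prototypes(res), c(0.2, 0.8), tolerance = 0.05)
  expect_identical(labelMap(res) == 2L, vol0 == 0.8)
  expect_true(all(diff(objectiveTrace(res)) <= 1e-9))
})

test_that("masked pixels get label 0, unit bias, and are excluded from fitting", {
  ph <- makePhantom(shape = c(24, 24), classes = 3, geometry = "blobs",
                    noisePercent = 5, seed = 23)
  mask <- matrix(TRUE, 24, 24); mask[1:6, ] <- FALSE
  res <- suppressWarnings(segmentImage(observedImage(ph), method = "proposed",
                                       clusters = 3, seed = 23, mask = mask))
  expect_true(all(labelMap(res)[!mask] == 0L))
  expect_true(all(biasField(res)[!mask] == 1))
  expect_true(all(labelMap(res)[mask] > 0L))
})
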