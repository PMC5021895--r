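# Baseline models: FCM, BCFCM, GIFP_FCM, CLIC.

two_group_image <- function(seed = 1, n = 12, sd = 0.03) {
  set.seed(seed)
  g <- matrix(rep(c(0, 1), each = n * n / 2), n, n)
  pmax(g + rnorm(n * n, sd = sd), 0)
}

test_that("FCM recovers the means of two well-separated groups", {
  img <- two_group_image(seed = 2)
  res <- fcm(img, clusters = 2, seed = 2)
  v <- prototypes(res)
  lo <- mean(img[img < 0.5]); hi <- mean(img[img >= 0.5])
  expect_equal(v[1], lo, tolerance = 0.05)
  expect_equal(v[2], hi, tolerance = 0.05)
  expect_true(res@converged)
  expect_true(all(diff(objectiveTrace(res)) <= 1e-9))
})

test_that("FCM membership conventions: crisp at a prototype, 0.5 at the midpoint", {
  img <- matrix(c(0, 1, 0.5, 0.2, 0.9, 0.1), 2, 3)
  u <- updateMembership(img, prototypes = c(0, 1), biasField = array(1, dim(img)))
  expect_equal(u[1, 1, ], c(1, 0))   # exactly at prototype 1
  expect_equal(u[2, 1, ], c(0, 1))   # exactly at prototype 2
  expect_equal(u[1, 2, ], c(0.5, 0.5))  # equidistant
  expect_equal(rowSums(matrix(u, ncol = 2)), rep(1, 6), tolerance = 1e-12)
})

test_that("a constant image is rejected as degenerate", {
  expect_error(fcm(matrix(1, 8, 8), clusters = 2, seed = 1), "degenerate")
})

test_that("BCFCM with alpha = 0 is exactly FCM", {
  img <- two_group_image(seed = 3)
  rb <- bcfcm(img, clusters = 2, alphaBcfcm = 0, seed = 3)
  rf <- fcm(img, clusters = 2, seed = 3)
  expect_equal(prototypes(rb), prototypes(rf), tolerance = 1e-10)
  expect_equal(memberships(rb), memberships(rf), tolerance = 1e-10)
  expect_identical(labelMap(rb), labelMap(rf))
})

test_that("one BCFCM step matches the direct formula transcription", {
  set.seed(9)
  img <- matrix(runif(64), 8, 8)
  v0 <- c(0.25, 0.75)
  res <- suppressWarnings(
    bcfcm(img, clusters = 2, alphaBcfcm = 0.85, maxIter = 1, init = v0))
  orc <- oracle_bcfcm_step(img, v0, m = 2, alpha = 0.85)
  expect_equal(memberships(res), orc$u, tolerance = 1e-12)
  expect_equal(prototypes(res), orc$v, tolerance = 1e-12)
})

test_that("BCFCM assigns identical memberships across a constant region", {
  img <- matrix(0.9, 10, 10); img[, 1:3] <- 0.1
  res <- bcfcm(img, clusters = 2, seed = 4)
  u <- memberships(res)
  # deep-interior pixels of the bright region all see identical neighbourhoods
  expect_equal(u[5, 6, ], u[6, 8, ], tolerance = 1e-12)
})

test_that("one GIFP_FCM step matches the direct formula transcription", {
  set.seed(10)
  img <- matrix(runif(64), 8, 8)
  v0 <- c(0.3, 0.7)
  res <- suppressWarnings(
    gifpFcm(img, clusters = 2, alpha = 0.9, maxIter = 1, init = v0))
  orc <- oracle_gifp_step(img, v0, m = 2, alpha = 0.9)
  expect_equal(matrix(memberships(res), ncol = 2), orc$u, tolerance = 1e-12)
  expect_equal(prototypes(res), orc$v, tolerance = 1e-12)
})

test_that("GIFP_FCM memberships are crisper than FCM's", {
  img <- two_group_image(seed = 5, sd = 0.15)
  rg <- gifpFcm(img, clusters = 2, alpha = 0.9, seed = 5)
  rf <- fcm(img, clusters = 2, seed = 5)
  crisp <- function(r) mean(apply(matrix(memberships(r), ncol = 2), 1, max))
  expect_gt(crisp(rg), crisp(rf))
  expect_error(gifpFcm(img, clusters = 2, alpha = 1.2, seed = 5), "alpha")
})

test_that("all four models keep memberships normalized and objectives non-increasing", {
  ph <- makePhantom(shape = c(24, 24), classes = 3, geometry = "blobs",
                    biasModel = "linear-ramp", biasAmplitude = 0.2,
                    noisePercent = 8, seed = 6)
  x <- observedImage(ph)
  for (meth in c("fcm", "bcfcm", "gifp", "clic")) {
    res <- suppressWarnings(segmentImage(x, method = meth, clusters = 3,
                                         seed = 6))
    u <- matrix(memberships(res), ncol = 3)
    expect_equal(rowSums(u), rep(1, nrow(u)), tolerance = 1e-8)
    expect_true(all(u >= 0 & u <= 1))
    if (meth != "gifp")
      expect_true(all(diff(objectiveTrace(res)) <= 1e-9),
                  label = paste("descent for", meth))
  }
})

test_that("each GIFP sweep decreases its own fixed-offset Lagrangian", {
  # the sharpening offset a_k is a function of the prototypes, so the
  # recorded objective changes definition between sweeps; the guaranteed
  # property is coordinate descent of L(u, v; a_t) with a_t held fixed
  ph <- makePhantom(shape = c(24, 24), classes = 3, geometry = "blobs",
                    biasModel = "linear-ramp", biasAmplitude = 0.2,
                    noisePercent = 8, seed = 6)
  x <- as.vector(observedImage(ph))
  m <- 2; alpha <- 0.9
  L <- function(u, v, a) {
    D <- sapply(v, function(vi) (x - vi)^2)
    sum(u^m * D) + sum(a * rowSums(u * (1 - u^(m - 1))))
  }
  v <- c(0.25, 0.5, 0.8)
  for (sweep in 1:6) {
    D <- sapply(v, function(vi) (x - vi)^2)
    a <- alpha * apply(D, 1, min)
    before <- L(matrix(1 / 3, length(x), 3), v, a)
    st <- suppressWarnings(gifpFcm(array(x, c(24, 24)), clusters = 3,
                                   alpha = alpha, init = v, epsilon = 0,
                                   maxIter = 1))
    u <- matrix(memberships(st), ncol = 3)
    expect_lte(L(u, v, a), before + 1e-9)                 # u update
    expect_lte(L(u, prototypes(st), a), L(u, v, a) + 1e-9)  # v update
    v <- prototypes(st)
  }
})

test_that("relabelling clusters leaves the evaluated partition unchanged", {
  ph <- makePhantom(shape = c(24, 24), classes = 3, geometry = "blobs",
                    noisePercent = 5, seed = 7)
  res <- segmentImage(observedImage(ph), method = "fcm", clusters = 3, seed = 7)
  rep1 <- evaluate(res, ph)
  swapped <- labelMap(res)
  swapped[labelMap(res) == 1L] <- 2L
  swapped[labelMap(res) == 2L] <- 1L
  rep2 <- evaluate(swapped, labelMap(ph), classes = 3)
  expect_equal(sort(jaccardValues(rep1)), sort(jaccardValues(rep2)),
               tolerance = 1e-12)
})

test_that("CLIC recovers a known smooth bias on a clean phantom", {
  ph <- makePhantom(shape = c(48, 48), classes = 3, geometry = "blobs",
                    biasModel = "gaussian-bump", biasAmplitude = 0.2,
                    noisePercent = 0, seed = 8)
  res <- suppressWarnings(clic(observedImage(ph), clusters = 3, seed = 8))
  expect_gte(evaluate(res, ph)@biasCorrelation, 0.95)
})
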