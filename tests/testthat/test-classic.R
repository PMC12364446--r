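test_that("four-step phase retrieval inverts the cosine forward model", {
  # zero-phase case: (0.8, 0.5, 0.2, 0.5) -> 0
  wp <- wrappedPhase(matrix(0.8), matrix(0.5), matrix(0.2), matrix(0.5))
  expect_equal(wp$phase[1, 1], 0)

  # pi/3 with a = 0.5, b = 0.4
  im <- fourStepImages(matrix(pi / 3), a = 0.5, b = 0.4)
  expect_equal(im[[2]][1, 1], 0.15359, tolerance = 1e-4)
  wp <- wrappedPhase(im[[1]], im[[2]], im[[3]], im[[4]])
  expect_lt(abs(wp$phase[1, 1] - pi / 3), 1e-9)

  # dense sweep over phase, offset and modulation
  withr::with_seed(21, {
    phi <- matrix(seq(-pi + 1e-9, pi, length.out = 360), 18, 20)
    for (rep in 1:5) {
      a <- runif(1, 0.1, 0.9)
      b <- runif(1, 0.05, 0.5)
      im <- fourStepImages(phi, a, b)
      wp <- wrappedPhase(im[[1]], im[[2]], im[[3]], im[[4]])
      expect_lt(max(abs(wp$phase - phi)), 1e-9)
    }
  })

  # offset and positive-scaling invariance
  im <- fourStepImages(matrix(0.8), 0.5, 0.2)
  w1 <- wrappedPhase(im[[1]], im[[2]], im[[3]], im[[4]])$phase
  w2 <- wrappedPhase(3 * im[[1]] + 1, 3 * im[[2]] + 1, 3 * im[[3]] + 1,
                     3 * im[[4]] + 1)$phase
  expect_equal(w1, w2, tolerance = 1e-12)

  # unmodulated pixels are flagged invalid
  flat <- matrix(0.5)
  wp <- wrappedPhase(flat, flat, flat, flat)
  expect_false(wp$valid[1, 1])
  expect_error(wrappedPhase(flat, flat, flat, matrix(0.5, 2, 2)), "size")
})

test_that("temporal unwrapping resolves fringe orders exactly", {
  z <- matrix(0, 4, 4)
  expect_equal(unwrapTemporal(list(z, z), c(1, 4))$phase, z)

  # hand-computed single cascade step: truth 6.0 at f = 4, seed 1.5 at f = 1
  phi4 <- 6.0 - 2 * pi
  res <- unwrapTemporal(list(matrix(1.5), matrix(phi4)), c(1, 4))
  expect_equal(res$phase[1, 1], 6.0, tolerance = 1e-12)

  # construct-then-recover on smooth in-Nyquist fields over the full ladder
  withr::with_seed(31, {
    u <- matrix(0:31, 32, 32, byrow = TRUE) / 32
    v <- matrix(0:31, 32, 32) / 32
    for (rep in 1:5) {
      theta <- 2 * pi * (0.05 + 0.88 * u + 0.04 * sin(2 * pi * v) +
                           0.02 * runif(1))  # stays inside (0, 2*pi)
      wraps <- lapply(c(1, 4, 16, 64), function(f) {
        w <- (f * theta + pi) %% (2 * pi) - pi
        w[w <= -pi] <- pi
        w
      })
      res <- unwrapTemporal(wraps, c(1, 4, 16, 64))
      expect_lt(max(abs(res$phase - 64 * theta)), 1e-9)
      expect_true(all(res$reliable))
      # unwrap-wrap identity at the highest frequency
      rewrapped <- (res$phase + pi) %% (2 * pi) - pi
      rewrapped[rewrapped <= -pi] <- pi
      expect_lt(max(abs(rewrapped - wraps[[4]])), 1e-9)
    }
  })

  expect_error(unwrapTemporal(list(z, z), c(4, 1)), "increasing")
  expect_warning(unwrapTemporal(list(z, z), c(2, 5)), "non-integer")
})

test_that("calibration recovers known rational-model coefficients", {
  cc <- c(3000, 25, -1.5, 0.02, 0.8, -0.01)
  dd <- c(1, 0.01, 1e-4, 1e-6, -2e-4, 2e-6)
  truth <- calibrationCoefficients(cc, dd)
  withr::with_seed(41, {
    planes <- lapply(1:4, function(k) {
      phase <- matrix(runif(900, 0, 50), 30, 30)
      z <- depthMatrix(depthFromPhase(phase, truth))
      list(phase = phase, z = z)
    })
  })
  fit <- fitCalibration(planes)
  expect_lt(max(abs(fit@cc - cc) / pmax(abs(cc), 1)), 1e-6)
  expect_lt(max(abs(fit@dd - dd) / pmax(abs(dd), 1)), 1e-6)
  expect_lt(attr(fit, "residual"), 1e-6)

  expect_error(fitCalibration(planes[1:2]), "at least 3 planes")
})

test_that("geometric planes need more than two depths for calibration", {
  # phase affine in u per plane (as for real frontal planes): two planes
  # leave the 11-parameter design rank deficient
  u <- matrix(0:23, 24, 24, byrow = TRUE)
  mkplane <- function(z) list(phase = 0.3 + 0.05 * u + 500 / z, z = z)
  expect_error(fitCalibration(list(mkplane(80), mkplane(120))),
               "degeneracy")
})

test_that("noisy-phase calibration stays submillimetre at working range", {
  calib <- calibrateFromPlanes(imageSize = 64L)
  zs <- c(75, 95, 115, 135)
  freqs <- c(1, 4, 16, 64)
  errs <- withr::with_seed(51, vapply(zs, function(z) {
    sc <- defaultScene(imageSize = 64L, hasSample = FALSE,
                       backgroundDepth = z, backgroundAlbedo = 0.8)
    geom <- renderGeometry(sc)
    wraps <- lapply(freqs, function(f) {
      specs <- phaseShiftSequence(f)
      imgs <- lapply(specs, function(sp)
        shadeGeometry(sc, geom, renderPattern(sp)))
      ph <- wrappedPhase(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]])$phase
      w <- ph + matrix(rnorm(length(ph), sd = 0.01), nrow(ph))
      w
    })
    un <- unwrapTemporal(wraps, freqs)
    mean(abs(depthMatrix(depthFromPhase(un, calib)) - z))
  }, numeric(1)))
  expect_lt(max(errs), 0.5)
})

test_that("the rational depth model evaluates as printed", {
  # reduced form: z = 30 + phi at every pixel
  calib <- calibrationCoefficients(c(30, 1, 0, 0, 0, 0),
                                   c(1, 0, 0, 0, 0, 0))
  dm0 <- depthFromPhase(matrix(0, 3, 3), calib)
  expect_equal(depthMatrix(dm0), matrix(30, 3, 3))
  dm10 <- depthFromPhase(matrix(10, 3, 3), calib)
  expect_equal(depthMatrix(dm10), matrix(40, 3, 3))

  # random coefficients match an independent evaluation at one pixel
  withr::with_seed(61, {
    cc <- rnorm(6); dd <- c(1, rnorm(5) * 0.01)
  })
  calib2 <- calibrationCoefficients(cc, dd)
  u <- 3; v <- 7; phi <- 2.5
  phase <- matrix(0, 10, 10)
  phase[v + 1, u + 1] <- phi
  num <- cc[1] + cc[2] * phi + (cc[3] + cc[4] * phi) * u +
    (cc[5] + cc[6] * phi) * v
  den <- dd[1] + dd[2] * phi + (dd[3] + dd[4] * phi) * u +
    (dd[5] + dd[6] * phi) * v
  dm <- depthFromPhase(phase, calib2)
  expect_equal(depthMatrix(dm)[v + 1, u + 1], num / den, tolerance = 1e-12)

  # vanishing denominator flags the pixel instead of emitting infinities
  calib3 <- calibrationCoefficients(c(1, 0, 0, 0, 0, 0),
                                    c(1, -0.5, 0, 0, 0, 0))
  dm3 <- depthFromPhase(matrix(2, 2, 2), calib3)  # den = 1 - 0.5*2 = 0
  expect_true(all(!validMatrix(dm3)))
  expect_true(all(is.finite(depthMatrix(dm3))))

  expect_error(calibrationCoefficients(1:6, c(2, 0, 0, 0, 0, 0)), "gauge")
})

test_that("the variance mask thresholds fringe modulation", {
  flat <- replicate(16, matrix(0.5, 4, 4), simplify = FALSE)
  expect_equal(maskMatrix(varianceMask(flat)), matrix(0, 4, 4))

  # 8 values of 0 and 8 of 200 (8-bit scale): population variance 10000
  imgs <- c(replicate(8, matrix(0, 2, 2), simplify = FALSE),
            replicate(8, matrix(200 / 255, 2, 2), simplify = FALSE))
  expect_equal(maskMatrix(varianceMask(imgs)), matrix(1, 2, 2))

  # default threshold is 30 on the 8-bit scale, as configured
  expect_equal(formals(varianceMask)$gamma, 30)
  expect_equal(defaultConfig()$metrics$gamma, 30)
  expect_error(varianceMask(flat[1]), "at least 2")
})

test_that("morphological refinement removes speckles and fills holes", {
  m <- matrix(0, 32, 32)
  m[8:24, 8:24] <- 1
  expect_equal(maskMatrix(refineMask(m)), m)

  speck <- m; speck[2, 2] <- 1
  expect_equal(maskMatrix(refineMask(speck)), m)

  holed <- m; holed[16, 16] <- 0
  expect_equal(maskMatrix(refineMask(holed)), m)

  # idempotent with the same element
  r1 <- refineMask(speck)
  expect_equal(maskMatrix(refineMask(r1)), maskMatrix(r1))
})

test_that("the classical stack reconstructs simulated ground truth", {
  calib <- calibrateFromPlanes(imageSize = 128L)
  sc <- fixtureScene(128L)
  grp <- synthesizeGroup(sc, "classic_gt")
  gt <- groundTruthStack(grp, calib)
  sample <- grp@maskGT == 1
  err <- abs(depthMatrix(gt$depth) - grp@depthGT)
  expect_lt(mean(err[sample & validMatrix(gt$depth)]), 0.5)

  # background rejected by the variance mask
  bg <- grp@maskGT == 0
  expect_gte(mean(maskMatrix(gt$mask)[bg] == 0), 0.99)

  sweepGrp <- synthesizeGroup(sc, "sweep")
  expect_error(groundTruthStack(sweepGrp, calib), "classic_gt")
})

test_that("calibration coefficients round-trip as a text record", {
  calib <- calibrationCoefficients(c(3000, 25, -1.5, 0.02, 0.8, -0.01),
                                   c(1, 0.01, 1e-4, 1e-6, -2e-4, 2e-6))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCalibration(calib, f)
  back <- readCalibration(f)
  expect_equal(back@cc, calib@cc)
  expect_equal(back@dd, calib@dd)
})
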