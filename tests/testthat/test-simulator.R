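test_that("random poses are uniform within the configured ranges", {
  # degenerate ranges collapse to the identity pose
  degen <- list(translation = c(0, 0), rotation = c(0, 0), scale = c(1, 1))
  p <- sampleRandomPose(degen)
  expect_equal(p@translation, c(0, 0, 0))
  expect_equal(p@rotation, c(0, 0, 0))
  expect_equal(p@scale, c(1, 1, 1))

  # marginals stay within the stated bounds over many draws
  draws <- withr::with_seed(11, t(replicate(10000, {
    q <- sampleRandomPose()
    c(q@translation, q@rotation, q@scale)
  })))
  expect_true(all(draws[, 1:3] >= -10 & draws[, 1:3] <= 10))
  expect_true(all(draws[, 4:6] >= -15 & draws[, 4:6] <= 15))
  expect_true(all(draws[, 7:9] >= 0.85 & draws[, 7:9] <= 1.15))
  # and actually explore them
  expect_lt(min(draws[, 1]), -9)
  expect_gt(max(draws[, 1]), 9)

  # determinism contract
  expect_equal(sampleRandomPose(seed = 7), sampleRandomPose(seed = 7))
  expect_error(sampleRandomPose(list(translation = c(1, -1),
                                     rotation = c(0, 0),
                                     scale = c(1, 1))), "invalid config")
})

test_that("the renderer reproduces flat scenes exactly", {
  # frontal plane, constant unit pattern: depth = plane distance,
  # image = albedo
  sc <- defaultScene(imageSize = 32L, hasSample = FALSE,
                     backgroundDepth = 100, backgroundAlbedo = 0.8)
  fr <- renderFrame(sc, matrix(1, 720, 720))
  expect_equal(depthMatrix(fr$depth), matrix(100, 32, 32))
  expect_equal(fr$image, matrix(0.8, 32, 32), tolerance = 1e-12)

  # sample removed: every pixel carries the background depth
  sc2 <- defaultScene(imageSize = 16L, hasSample = FALSE)
  g <- renderGeometry(sc2)
  expect_true(all(g$depth == sc2@backgroundDepth))
  expect_true(all(g$hit == 0L))
})

test_that("rendered fringes match the analytic triangulation oracle", {
  z <- 110
  sc <- defaultScene(imageSize = 48L, hasSample = FALSE,
                     backgroundDepth = z, backgroundAlbedo = 0.8)
  spec <- patternSpec("sinusoidal", 1)
  fr <- renderFrame(sc, spec)
  cam <- sc@camera; proj <- sc@projector
  # per-pixel closed form, independent of the ray-marching renderer:
  # x = (u - u0) z / fc;  up = fp (x - bx) / z + u0p
  u <- matrix(0:47, 48, 48, byrow = TRUE)
  x <- (u - cam@principalPoint[1]) * z / cam@focalLength
  up <- proj@focalLength * (x - proj@translation[1]) / z +
    proj@principalPoint[1]
  oracle <- 0.8 * (1 + cos(2 * pi * spec@frequency * up / 720)) / 2
  expect_lt(max(abs(fr$image - oracle)), 1e-4)  # bilinear sampling bound
  # and bit-near once the oracle uses the same pattern-grid interpolation
  pat <- sinusoidalPattern(spec)
  lo <- floor(up); fu <- up - lo
  oracle2 <- 0.8 * ((1 - fu) * pat[1, lo + 1] + fu * pat[1, lo + 2])
  expect_lt(max(abs(fr$image - oracle2)), 1e-9)
})

test_that("posed sample depth maps stay between sample and background", {
  sc <- fixtureScene(64L)
  g <- renderGeometry(sc)
  expect_true(all(g$depth <= sc@backgroundDepth))
  expect_gt(min(g$depth), 70)
  expect_gt(mean(g$hit), 0.05)
  # rays miss everything only when the background is too small to cover
  scBad <- sc
  scBad@backgroundHalfwidth <- 1
  expect_error(renderGeometry(scBad), "misses both")
})

test_that("shot noise follows Poisson statistics", {
  z <- matrix(0, 10, 10)
  expect_equal(addShotNoise(z, 100), z)

  img <- matrix(0.5, 1000, 1000)
  noisy <- addShotNoise(img, 1e4, seed = 3)
  expect_lt(abs(mean(noisy) - 0.5), 1e-3)
  expect_lt(abs(stats::var(as.vector(noisy)) - 0.5 / 1e4),
            0.1 * 0.5 / 1e4)

  # high-photon limit reproduces the input
  img2 <- matrix(runif(256), 16, 16)
  expect_lt(max(abs(addShotNoise(img2, 1e9, seed = 4) - img2)), 1e-3)

  # mean preservation within 3 sigma on a constant patch
  img3 <- matrix(0.3, 64, 64)
  n3 <- addShotNoise(img3, 100, seed = 5)
  expect_lt(abs(mean(n3) - 0.3), 3 * sqrt(0.3 / 100 / length(img3)))

  expect_error(addShotNoise(img2, 0), "invalid config")
  expect_error(addShotNoise(img2 - 2, 10), "non-negative")
})

test_that("psnr follows its closed form and decreases with noise", {
  a <- matrix(0.5, 8, 8)
  expect_equal(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 0.1), 20)
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")

  sc <- fixtureScene(48L)
  img <- renderFrame(sc, patternSpec("binary", 20))$image
  vals <- vapply(c(1000, 100, 10), function(S)
    psnr(img, addShotNoise(img, S, seed = 8)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("frame groups hold the documented image counts", {
  sc <- fixtureScene(48L)
  sweep <- synthesizeGroup(sc, "sweep")
  expect_length(sweep@images, 22)
  expect_setequal(vapply(sweep@specs, function(s) s@frequency, numeric(1)),
                  seq(4, 24, by = 2))

  classic <- synthesizeGroup(sc, "classic_gt")
  expect_length(classic@images, 18)
  shifts <- vapply(classic@specs[1:16], function(s) s@phaseShift,
                   numeric(1))
  expect_equal(shifts, rep(c(0, pi / 2, pi, 3 * pi / 2), 4))
  kinds <- vapply(classic@specs[17:18], function(s) s@kind, character(1))
  expect_equal(kinds, c("sinusoidal", "binary"))

  # one pose, one shared ground truth per group
  expect_identical(dim(classic@depthGT), dim(classic@images[[1]]))
  expect_error(synthesizeGroup(sc, "wrong"), "unknown group mode")
})

test_that("datasets round-trip through disk deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- synthesizeDataset(4, c(2, 1, 1), d1, seed = 5, imageSize = 64L)
  m2 <- synthesizeDataset(4, c(2, 1, 1), d2, seed = 5, imageSize = 64L)
  expect_equal(nrow(m1), 8)  # two patterns per group
  perGroup <- m1$split[!duplicated(m1$group)]
  expect_equal(unname(table(perGroup)[c("train", "val", "test")]),
               c(2L, 1L, 1L), ignore_attr = TRUE)
  # same seed, same bytes
  m1$path <- NULL; m2$path <- NULL
  expect_equal(m1, m2)
  for (f in list.files(d1)) {
    expect_true(file.exists(file.path(d2, f)))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # images and rasters read back at their storage precision
  mf <- readManifest(d1)
  img <- readImageTIFF(file.path(d1, mf$path[1]))
  expect_equal(dim(img), c(64, 64))
  dep <- readDepthTIFF(file.path(d1, mf$depth_path[1]))
  expect_true(all(dep >= 70 & dep <= 140.0001))
  msk <- readMaskPNG(file.path(d1, mf$mask_path[1]))
  expect_true(all(msk %in% c(0, 1)))
  expect_error(synthesizeDataset(4, c(2, 1, 2), withr::local_tempdir()),
               "sum")
})
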