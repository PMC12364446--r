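test_that("network outputs respect their activation ranges", {
  # 2-channel softmax head on a 256x256 input sums to one per pixel
  cfgM <- unetConfig(baseWidth = 8L, headChannels = 2L,
                     inputSize = c(256L, 256L))
  netM <- buildNetwork(cfgM, seed = 2)
  x <- withr::with_seed(3, matrix(runif(256 * 256), 256, 256))
  fw <- forwardNetwork(netM, x)
  expect_equal(dim(fw$out), c(256, 256, 2, 1))
  expect_lt(max(abs(fw$out[, , 1, 1] + fw$out[, , 2, 1] - 1)), 1e-6)

  # sigmoid head stays strictly inside (0, 1)
  cfgD <- unetConfig(baseWidth = 8L, headChannels = 1L,
                     inputSize = c(64L, 64L))
  netD <- buildNetwork(cfgD, seed = 2)
  x64 <- withr::with_seed(4, matrix(runif(64 * 64), 64, 64))
  fwD <- forwardNetwork(netD, x64)
  expect_true(all(fwD$out > 0 & fwD$out < 1))

  expect_error(unetConfig(inputSize = c(100L, 100L)), "divisible")
  expect_error(forwardNetwork(netD, matrix(0, 32, 32)), "mismatch")
})

test_that("the tiny profile has the hand-counted parameter budget", {
  cfg <- unetConfig(baseWidth = 8L, headChannels = 1L,
                    inputSize = c(64L, 64L))
  tab <- architectureTable(cfg)
  # independent count from the table's channel bookkeeping
  byHand <- sum(ifelse(tab$kernel == "3x3",
                       9 * tab$in_channels * tab$out_channels,
                       tab$in_channels * tab$out_channels) +
                  tab$out_channels)
  expect_equal(parameterCount(cfg), byHand)
  expect_equal(byHand, 491108)
  # and the built network allocates exactly that many numbers
  net <- buildNetwork(cfg, seed = 1)
  allocated <- sum(vapply(net@params, function(p)
    length(p$w) + length(p$b), numeric(1)))
  expect_equal(allocated, 491108)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeArchitectureTable(cfg, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(sum(back$params), 491108)
})

test_that("depth rescale maps the unit interval onto 30-180 mm", {
  expect_equal(rescaleDepth(0), 30)
  expect_equal(rescaleDepth(1), 180)
  expect_equal(rescaleDepth(0.5), 105)
  expect_error(rescaleDepth(1.2), "contract violation")
  expect_error(rescaleDepth(-0.1), "contract violation")
})

test_that("mask binarisation is argmax with background ties", {
  mk <- function(p0, p1) array(c(p0, p1), c(1, 1, 2))
  expect_equal(maskMatrix(maskFromProbs(mk(0.9, 0.1))), matrix(0))
  expect_equal(maskMatrix(maskFromProbs(mk(0.1, 0.9))), matrix(1))
  expect_equal(maskMatrix(maskFromProbs(mk(0.5, 0.5))), matrix(0))
  allSample <- array(c(matrix(0, 4, 4), matrix(1, 4, 4)), c(4, 4, 2))
  expect_equal(maskMatrix(maskFromProbs(allSample)), matrix(1, 4, 4))
})

test_that("prediction fuses depth and mask by pixel-wise multiplication", {
  cfgD <- unetConfig(baseWidth = 2L, headChannels = 1L,
                     inputSize = c(32L, 32L))
  cfgM <- unetConfig(baseWidth = 2L, headChannels = 2L,
                     inputSize = c(32L, 32L))
  depthnet <- buildNetwork(cfgD, seed = 5)
  x <- withr::with_seed(6, matrix(runif(1024), 32, 32))

  # all-ones mask (DepthNet-only): final map equals the rescaled output
  pred <- predictDepth(x, NULL, depthnet)
  expect_equal(depthMatrix(pred$depth),
               rescaleDepth(pred$depthUnit), tolerance = 1e-12)
  expect_true(all(validMatrix(pred$depth)))

  # saturated MaskNet heads force an all-zero mask: all pixels invalid
  masknet <- buildNetwork(cfgM, seed = 5)
  for (l in 1:4) masknet@params[[sprintf("head%d", l)]]$b <- c(50, -50)
  pred0 <- predictDepth(x, masknet, depthnet)
  expect_true(all(maskMatrix(pred0$mask) == 0))
  expect_true(all(depthMatrix(pred0$depth) == 0))
  expect_true(all(!validMatrix(pred0$depth)))

  # the other saturation gives the all-ones case through the mask path
  for (l in 1:4) masknet@params[[sprintf("head%d", l)]]$b <- c(-50, 50)
  pred1 <- predictDepth(x, masknet, depthnet)
  expect_true(all(maskMatrix(pred1$mask) == 1))
  expect_equal(depthMatrix(pred1$depth), depthMatrix(pred$depth))
})

test_that("forward passes are deterministic and head-ablatable", {
  cfg <- unetConfig(baseWidth = 2L, headChannels = 1L,
                    inputSize = c(32L, 32L))
  net <- buildNetwork(cfg, seed = 7)
  x <- withr::with_seed(8, matrix(runif(1024), 32, 32))
  expect_identical(forwardNetwork(net, x)$out, forwardNetwork(net, x)$out)

  # same seed rebuilds identical weights
  expect_identical(buildNetwork(cfg, seed = 7)@params, net@params)

  # keeping only the full-resolution head still produces in-range output
  fw <- forwardNetwork(net, x, headMask = c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(fw$out > 0 & fw$out < 1))
  expect_false(isTRUE(all.equal(fw$out, forwardNetwork(net, x)$out)))
})

test_that("output ranges hold across random initialisations", {
  cfg2 <- unetConfig(baseWidth = 2L, headChannels = 2L,
                     inputSize = c(16L, 16L))
  cfg1 <- unetConfig(baseWidth = 2L, headChannels = 1L,
                     inputSize = c(16L, 16L))
  x <- withr::with_seed(9, matrix(runif(256), 16, 16))
  for (s in 1:100) {
    if (s %% 2 == 0) {
      fw <- forwardNetwork(buildNetwork(cfg2, seed = s), x)
      expect_lt(max(abs(fw$out[, , 1, 1] + fw$out[, , 2, 1] - 1)), 1e-6)
      expect_true(all(fw$out >= 0 & fw$out <= 1))
    } else {
      fw <- forwardNetwork(buildNetwork(cfg1, seed = s), x)
      expect_true(all(fw$out > 0 & fw$out < 1))
    }
  }
})

test_that("backpropagation matches finite differences at a smooth point", {
  cfg <- unetConfig(baseWidth = 2L, headChannels = 1L,
                    inputSize = c(16L, 16L))
  net <- buildNetwork(cfg, seed = 3)
  # positive biases keep every ReLU strictly active and pools untied, so
  # the loss is differentiable at the test point
  withr::with_seed(10, {
    for (nm in names(net@params))
      net@params[[nm]]$b <- abs(rnorm(length(net@params[[nm]]$b))) + 2
    x <- matrix(runif(256), 16, 16)
    r <- array(rnorm(256), c(16, 16, 1, 1))
  })
  lossOf <- function(n) sum(r * forwardNetwork(n, x)$logits)
  fw <- forwardNetwork(net, x, keepCache = TRUE)
  gr <- backwardNetwork(net, fw$cache, r)
  withr::with_seed(11, {
    np <- net; nn <- net; dirdot <- 0; h <- 1e-5
    for (nm in names(net@params)) for (part in c("w", "b")) {
      dv <- rnorm(length(net@params[[nm]][[part]]))
      np@params[[nm]][[part]] <- net@params[[nm]][[part]] + h * dv
      nn@params[[nm]][[part]] <- net@params[[nm]][[part]] - h * dv
      dirdot <- dirdot + sum(gr[[nm]][[part]] * dv)
    }
    fd <- (lossOf(np) - lossOf(nn)) / (2 * h)
  })
  expect_lt(abs(fd - dirdot) / abs(fd), 1e-3)
})

test_that("checkpoints round-trip through disk", {
  cfg <- unetConfig(baseWidth = 2L, headChannels = 1L,
                    inputSize = c(16L, 16L))
  net <- buildNetwork(cfg, seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  back <- loadCheckpoint(f)
  expect_identical(back@params, net@params)
})
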