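test_that("ssim matches its reference formulation", {
  a <- withr::with_seed(1, matrix(runif(400, 50, 150), 20, 20))
  expect_equal(ssim(a, a), 1.0)

  # constant 0 versus constant max-range: closed form C1 / (L^2 + C1)
  L <- 150
  z <- matrix(0, 16, 16); m <- matrix(L, 16, 16)
  C1 <- (0.01 * L)^2
  expect_equal(ssim(z, m, L = L), C1 / (L^2 + C1), tolerance = 1e-12)
  expect_lt(ssim(z, m, L = L), 1e-3)

  # symmetry on random pairs
  withr::with_seed(2, for (i in 1:5) {
    x <- matrix(runif(400, 0, 150), 20, 20)
    y <- matrix(runif(400, 0, 150), 20, 20)
    expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  })

  # windowed-loop reference implementation agrees
  withr::with_seed(3, {
    x <- matrix(runif(169, 40, 140), 13, 13)
    y <- x + matrix(rnorm(169, sd = 10), 13, 13)
  })
  expect_equal(ssim(x, y), bruteSSIM(x, y), tolerance = 1e-10)

  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), "window larger")
  expect_error(ssim(a, matrix(0, 3, 3)), "equal shapes")
})

test_that("the ssim gradient matches finite differences", {
  withr::with_seed(4, {
    a <- matrix(runif(900, 50, 150), 30, 30)
    b <- matrix(runif(900, 50, 150), 30, 30)
    dv <- matrix(rnorm(900), 30, 30)
  })
  sg <- EndoFPP:::ssimGrad(a, b)
  h <- 1e-4
  fd <- (ssim(a + h * dv, b) - ssim(a - h * dv, b)) / (2 * h)
  expect_equal(sum(sg$grad * dv), fd, tolerance = 1e-6)
})

test_that("the depth loss is the documented L1/SSIM mixture", {
  withr::with_seed(5, {
    d <- matrix(runif(1024, 80, 120), 32, 32)
    m <- matrix(0, 32, 32); m[, 1:16] <- 1  # half-image mask
  })
  expect_equal(depthLoss(d, d, m), 0)

  # constant +10 mm offset inside the half mask: hand-evaluated two terms
  dhat <- d + 10
  X <- dhat * m; Yt <- d * m
  expected <- 0.85 * 5 + 0.15 * (1 - bruteSSIM(X, Yt)) / 2
  expect_equal(depthLoss(dhat, d, m), expected, tolerance = 1e-8)

  # non-increasing along the line from a perturbed map back to the truth
  withr::with_seed(6, pert <- matrix(rnorm(1024, sd = 5), 32, 32))
  losses <- vapply(seq(1, 0, by = -0.1), function(t)
    depthLoss(d + t * pert, d, m), numeric(1))
  expect_true(all(diff(losses) <= 1e-12))

  expect_warning(l0 <- depthLoss(d, d + 5, matrix(0, 32, 32)),
                 "degenerate mask")
  expect_equal(l0, 0)
  expect_error(depthLoss(d, d, matrix(1, 2, 2)), "equal shapes")
})

test_that("the dice loss reproduces hand-computed overlap cases", {
  # exact hard prediction: loss 0 (the stabiliser cancels)
  m <- matrix(0, 10, 10); m[3:7, 3:7] <- 1
  expect_lt(diceLoss(EndoFPP:::maskOneHot(m), m), 1e-6)

  # completely disjoint halves on 100 pixels: loss ~ 1
  left <- matrix(0, 10, 10); left[, 1:5] <- 1
  right <- 1 - left
  expect_equal(diceLoss(EndoFPP:::maskOneHot(right), left), 1,
               tolerance = 1e-4)

  # 50% overlap of equal-size bands: Dice 0.5 per class, loss 0.5
  m1 <- matrix(0, 8, 8); m1[, 1:4] <- 1
  m2 <- matrix(0, 8, 8); m2[, 3:6] <- 1
  expect_equal(diceLoss(EndoFPP:::maskOneHot(m2), m1), 0.5,
               tolerance = 1e-4)

  # bounded in [0, 1] and monotone over nested masks
  vals <- vapply(0:6, function(k) {
    mk <- matrix(0, 8, 8)
    if (k > 0) mk[, seq_len(k)] <- 1
    diceLoss(EndoFPP:::maskOneHot(mk), m1)
  }, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals[1:5]) <= 1e-9))  # growing overlap, shrinking loss

  expect_error(diceLoss(array(0, c(4, 4, 3)), m1), "class-count")
})

test_that("the dice gradient matches finite differences", {
  withr::with_seed(7, {
    m <- matrix(rbinom(64, 1, 0.4), 8, 8)
    logits <- array(rnorm(128), c(8, 8, 2))
  })
  probs <- exp(logits)
  probs <- probs / array(rep(probs[, , 1] + probs[, , 2], 2), dim(probs))
  dl <- diceLoss(probs, m, gradient = TRUE)
  dv <- withr::with_seed(8, array(rnorm(128), c(8, 8, 2)))
  h <- 1e-6
  fd <- (diceLoss(probs + h * dv, m) - diceLoss(probs - h * dv, m)) / (2 * h)
  expect_equal(sum(dl$grad * dv), fd, tolerance = 1e-6)
})

test_that("evaluation metrics reproduce hand computations", {
  # perfect prediction
  d <- matrix(100, 4, 4); m <- matrix(1, 4, 4)
  rep0 <- evalMetrics(d, m, d, m)
  expect_equal(rep0@mae, 0)
  expect_equal(rep0@absRel, 0)
  expect_equal(unname(rep0@accDelta), c(1, 1))
  expect_equal(rep0@dsc, 1)
  expect_equal(rep0@miou, 1)

  # two-pixel case: Y = (100, 100), Yhat = (105, 100)
  Y <- matrix(c(100, 100), 1, 2)
  Yhat <- matrix(c(105, 100), 1, 2)
  ones <- matrix(1, 1, 2)
  rep2 <- evalMetrics(Yhat, ones, Y, ones, deltas = 1.1)
  expect_equal(rep2@mae, 2.5)
  expect_equal(rep2@absRel, (5 / 105 + 0) / 2, tolerance = 1e-12)
  expect_equal(unname(rep2@accDelta), 1)

  # segmentation counting: truth everywhere, prediction on the left half
  m4 <- matrix(1, 4, 4)
  mhat <- matrix(0, 4, 4); mhat[, 1:2] <- 1
  d4 <- matrix(100, 4, 4)
  rep4 <- evalMetrics(d4, mhat, d4, m4)
  expect_equal(rep4@dsc, 2 * 8 / (16 + 8), tolerance = 1e-12)
  expect_equal(rep4@miou, (0.5 + 0) / 2)
  expect_equal(rep4@nExcluded, 8L)  # masked-away pixels leave the ratios

  expect_error(evalMetrics(d4, mhat, d4, matrix(0, 4, 4)), "undefined")
})

test_that("evaluation metrics agree with the brute-force pixel oracle", {
  for (s in 1:1000) {
    withr::with_seed(s, {
      d <- matrix(runif(64, 50, 150), 8, 8)
      dhat <- d + matrix(rnorm(64, sd = 10), 8, 8)
      m <- matrix(rbinom(64, 1, 0.6), 8, 8)
      mhat <- matrix(rbinom(64, 1, 0.6), 8, 8)
    })
    if (!any(m == 1) || !any(m == 1 & mhat == 1)) next
    ref <- bruteMetrics(dhat, mhat, d, m)
    rep <- evalMetrics(dhat, mhat, d, m)
    expect_equal(rep@mae, ref$mae, tolerance = 1e-12)
    expect_equal(rep@absRel, ref$absRel, tolerance = 1e-12)
    expect_equal(unname(rep@accDelta), ref$acc, tolerance = 1e-12)
    expect_equal(rep@dsc, ref$dsc, tolerance = 1e-12)
    expect_equal(rep@miou, ref$miou, tolerance = 1e-12)
  }
})

test_that("delta-accuracy is non-decreasing in delta", {
  withr::with_seed(9, {
    d <- matrix(runif(256, 70, 140), 16, 16)
    dhat <- d * matrix(exp(rnorm(256, sd = 0.08)), 16, 16)
    m <- matrix(1, 16, 16)
  })
  rep <- evalMetrics(dhat, m, d, m, deltas = c(1.02, 1.05, 1.1, 1.21, 1.5))
  expect_true(all(diff(rep@accDelta) >= 0))
})

test_that("the paired t-test matches the closed form", {
  res <- pairedTTest(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-res$t, df = 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)

  # antisymmetry
  swapped <- pairedTTest(c(0, 0, 0), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  # equal means with positive variance: p near 1
  res2 <- pairedTTest(c(1, 2), c(2, 1))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  expect_error(pairedTTest(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(pairedTTest(1:3, 1:2), "equal lengths")
})
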