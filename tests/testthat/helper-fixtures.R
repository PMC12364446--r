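# Shared fixtures: forward-model image sets, tiny scenes and a cached
# desk-scale training run reused by the acceptance and ablation tests.

# four-step forward model: I_k = a + b*cos(phi + theta_k)
fourStepImages <- function(phi, a = 0.5, b = 0.3) {
  lapply(c(0, pi / 2, pi, 3 * pi / 2), function(t) a + b * cos(phi + t))
}

# a small posed scene with a perturbed dome, deterministic
fixtureScene <- function(imageSize = 128L, seed = 4L) {
  withr::with_seed(seed, {
    pose <- sampleRandomPose()
    surf <- sampleSurface(perturbation = randomPerturbation())
    defaultScene(imageSize = imageSize, surface = surf, pose = pose)
  })
}

# naive reference SSIM: explicit windowed loops, independent of the
# package's filtering-based implementation
bruteSSIM <- function(a, b, L = 150, ksize = 11L, sigma = 1.5) {
  r <- ksize %/% 2
  k1 <- outer(-r:r, -r:r, function(i, j)
    exp(-(i^2 + j^2) / (2 * sigma^2)))
  k1 <- k1 / sum(k1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  H <- nrow(a); W <- ncol(a)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  svals <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    wa <- matrix(0, ksize, ksize); wb <- matrix(0, ksize, ksize)
    for (di in -r:r) for (dj in -r:r) {
      wa[di + r + 1, dj + r + 1] <- a[refl(i + di, H), refl(j + dj, W)]
      wb[di + r + 1, dj + r + 1] <- b[refl(i + di, H), refl(j + dj, W)]
    }
    mua <- sum(k1 * wa); mub <- sum(k1 * wb)
    saa <- sum(k1 * wa^2) - mua^2
    sbb <- sum(k1 * wb^2) - mub^2
    sab <- sum(k1 * wa * wb) - mua * mub
    svals[i, j] <- (2 * mua * mub + C1) * (2 * sab + C2) /
      ((mua^2 + mub^2 + C1) * (saa + sbb + C2))
  }
  mean(svals)
}

# brute-force reference for the evaluation metrics (pixel loops)
bruteMetrics <- function(dhat, mhat, d, m, deltas = c(1.1, 1.21)) {
  Y <- d * m; Yhat <- dhat * mhat
  mae <- 0; nV <- 0; absrel <- 0; nR <- 0
  accs <- numeric(length(deltas))
  for (i in seq_along(Y)) {
    if (m[i] == 1) {
      nV <- nV + 1
      mae <- mae + abs(Y[i] - Yhat[i])
      if (Yhat[i] != 0) {
        nR <- nR + 1
        absrel <- absrel + abs(Y[i] - Yhat[i]) / Yhat[i]
        rat <- max(Y[i] / Yhat[i], Yhat[i] / Y[i])
        for (k in seq_along(deltas)) if (rat < deltas[k])
          accs[k] <- accs[k] + 1
      }
    }
  }
  i1 <- sum(mhat == 1 & m == 1); u1 <- sum(mhat == 1 | m == 1)
  i0 <- sum(mhat == 0 & m == 0); u0 <- sum(mhat == 0 | m == 0)
  list(mae = mae / nV, absRel = absrel / nR, acc = accs / nR,
       dsc = 2 * i1 / (sum(mhat == 1) + sum(m == 1)),
       miou = (ifelse(u0 > 0, i0 / u0, 1) + ifelse(u1 > 0, i1 / u1, 1)) / 2)
}

# one desk-scale training run shared between the acceptance criteria
.tinyRunCache <- new.env(parent = emptyenv())
tinyRunCached <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (is.null(.tinyRunCache[[key]]))
    .tinyRunCache[[key]] <- runSingleShotExperiment(
      seed = seed, profile = trainingProfile("tiny"), frequency = 20,
      kind = "binary", useVal = FALSE)
  .tinyRunCache[[key]]
}

# a smaller profile for the ablation-direction comparison: both variants
# are trained identically on the same scenes
miniProfile <- function() {
  list(name = "mini", renderSize = 256L, imageSize = 64L,
       nTrain = 150L, nVal = 0L, nTest = 40L, baseWidth = 8L,
       depth = trainConfig(lr = 1e-3, milestones = c(20), epochs = 12,
                           profile = "tiny"),
       mask = trainConfig(lr = 1e-3, milestones = c(20), epochs = 8,
                          profile = "tiny"))
}
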