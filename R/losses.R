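# Training losses (masked L1 + SSIM for depth, Dice for segmentation) with
# analytic gradients, the depth/segmentation evaluation metrics, and the
# paired comparison test.

gaussFilt <- function(x, ksize, sigma) cpp_gauss_filter(x, sigma, ksize)

#' Structural similarity index (SSIM)
#'
#' The standard windowed formulation with a Gaussian weighting window
#' (11x11, sigma 1.5 by default) and stabilisation constants `C1 = (K1*L)^2`,
#' `C2 = (K2*L)^2` where `L` is the declared dynamic range (150 mm for depth
#' maps, the span of the depth rescale).
#'
#' @param a,b Equally sized matrices.
#' @param L Dynamic range of the data.
#' @param ksize Window size (odd).
#' @param sigma Window standard deviation.
#' @param K1,K2 Stabilisation factors.
#' @return Scalar mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, L = 150, ksize = 11L, sigma = 1.5, K1 = 0.01,
                 K2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("ssim requires equal shapes")
  mean(ssimMap(a, b, L, ksize, sigma, K1, K2)$S)
}

ssimMap <- function(a, b, L, ksize, sigma, K1, K2) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mua <- gaussFilt(a, ksize, sigma)
  mub <- gaussFilt(b, ksize, sigma)
  saa <- gaussFilt(a * a, ksize, sigma) - mua * mua
  sbb <- gaussFilt(b * b, ksize, sigma) - mub * mub
  sab <- gaussFilt(a * b, ksize, sigma) - mua * mub
  A1 <- 2 * mua * mub + C1
  A2 <- 2 * sab + C2
  B1 <- mua * mua + mub * mub + C1
  B2 <- saa + sbb + C2
  list(S = A1 * A2 / (B1 * B2), mua = mua, mub = mub, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2)
}

# gradient of mean(SSIM(a, b)) with respect to a
ssimGrad <- function(a, b, L = 150, ksize = 11L, sigma = 1.5, K1 = 0.01,
                     K2 = 0.03) {
  m <- ssimMap(a, b, L, ksize, sigma, K1, K2)
  BB <- m$B1 * m$B2
  dS_dmua <- 2 * m$mub * m$A2 / BB - 2 * m$mua * m$A1 * m$A2 / (m$B1 * BB)
  dS_dsaa <- -m$A1 * m$A2 / (BB * m$B2)
  dS_dsab <- 2 * m$A1 / BB
  g <- gaussFilt(dS_dmua, ksize, sigma) +
    2 * a * gaussFilt(dS_dsaa, ksize, sigma) -
    2 * gaussFilt(m$mua * dS_dsaa, ksize, sigma) +
    b * gaussFilt(dS_dsab, ksize, sigma) -
    gaussFilt(m$mub * dS_dsab, ksize, sigma)
  list(value = mean(m$S), grad = g / length(a))
}

#' Depth reconstruction loss (masked L1 + SSIM)
#'
#' `Ld = alpha * mean|Dhat*M - D*M| + (1 - alpha) * (1 - SSIM(Dhat*M,
#' D*M)) / 2` with `alpha = 0.85`; the L1 mean runs over all pixels of the
#' masked (zero-filled) maps and the SSIM dynamic range is the 150 mm depth
#' span. Zero exactly when the masked maps agree.
#'
#' @param dhat Predicted depth (mm matrix).
#' @param d Ground-truth depth (mm matrix).
#' @param m Binary mask matrix (or [BinaryMask-class]).
#' @param alpha L1/SSIM weight.
#' @param gradient Also return the gradient with respect to `dhat`.
#' @param L SSIM dynamic range (mm).
#' @param l1Scope `"all"` (default) averages the L1 term over every pixel
#'   of the masked, zero-filled maps, matching the printed norm of masked
#'   images; `"valid"` averages over the masked pixels only.
#' @return Scalar loss, or `list(value, grad)` when `gradient = TRUE`.
#' @export
depthLoss <- function(dhat, d, m, alpha = 0.85, gradient = FALSE, L = 150,
                      l1Scope = c("all", "valid")) {
  l1Scope <- match.arg(l1Scope)
  if (is(m, "BinaryMask")) m <- m@mask
  if (!identical(dim(dhat), dim(d)) || !identical(dim(dhat), dim(m)))
    stop("depth loss requires equal shapes")
  if (all(m == 0)) {
    warning("degenerate mask: no sample pixels; depth loss is 0")
    if (gradient)
      return(list(value = 0, grad = matrix(0, nrow(dhat), ncol(dhat))))
    return(0)
  }
  X <- dhat * m
  Yt <- d * m
  nL1 <- if (l1Scope == "all") length(X) else sum(m)
  l1 <- sum(abs(X - Yt)) / nL1
  if (!gradient) {
    sv <- ssim(X, Yt, L = L)
    return(alpha * l1 + (1 - alpha) * (1 - sv) / 2)
  }
  sg <- ssimGrad(X, Yt, L = L)
  value <- alpha * l1 + (1 - alpha) * (1 - sg$value) / 2
  grad <- (alpha * sign(X - Yt) / nL1 -
             (1 - alpha) / 2 * sg$grad) * m
  list(value = value, grad = grad)
}

maskOneHot <- function(m) {
  if (is(m, "BinaryMask")) m <- m@mask
  array(c(1 - m, m), c(dim(m), 2))
}

#' Dice segmentation loss
#'
#' `Lm = 1 - (1/C) * sum_j (2 * sum_i M_ij Mhat_ij + beta) / (sum_i M_ij +
#' sum_i Mhat_ij + beta)` over the `C = 2` classes with the stabiliser
#' `beta = 0.001`.
#'
#' @param probs Predicted per-pixel class probabilities, `H x W x 2` (or
#'   with a trailing batch dim of 1).
#' @param m Ground-truth mask ([BinaryMask-class], 0/1 matrix, or an
#'   `H x W x 2` one-hot array).
#' @param beta Stabiliser.
#' @param gradient Also return the gradient with respect to `probs`.
#' @return Scalar loss in `[0, 1]`, or `list(value, grad)`.
#' @export
diceLoss <- function(probs, m, beta = 0.001, gradient = FALSE) {
  if (length(dim(probs)) == 4) probs <- probs[, , , 1]
  onehot <- if (length(dim(m)) == 3) m else maskOneHot(m)
  if (dim(probs)[3] != 2 || dim(onehot)[3] != 2)
    stop("class-count mismatch: two classes expected")
  dscs <- numeric(2)
  grad <- if (gradient) array(0, dim(probs)) else NULL
  for (j in 1:2) {
    pj <- probs[, , j]
    mj <- onehot[, , j]
    num <- 2 * sum(pj * mj) + beta
    den <- sum(mj) + sum(pj) + beta
    dscs[j] <- num / den
    if (gradient) grad[, , j] <- -(1 / 2) * (2 * mj * den - num) / den^2
  }
  value <- 1 - mean(dscs)
  if (gradient) list(value = value, grad = grad) else value
}

#' Depth and segmentation evaluation metrics
#'
#' Forms `Y = D * M` and `Yhat = Dhat * Mhat` and evaluates, over the valid
#' set `V = {M = 1}`: mean absolute error, mean absolute relative error
#' (denominator the prediction `Yhat`), delta-accuracies (fraction of `V`
#' with `max(Y/Yhat, Yhat/Y) < delta`), the sample-class Dice score and the
#' mean IoU over both classes. Valid pixels where the prediction is zero are
#' excluded from the ratio metrics and counted in `nExcluded`.
#'
#' @param dhat Predicted depth (mm matrix or [DepthMap-class]).
#' @param mhat Predicted mask ([BinaryMask-class] or 0/1 matrix).
#' @param d Ground-truth depth.
#' @param m Ground-truth mask.
#' @param deltas Accuracy thresholds; 1.1 and 1.1^2 = 1.21 by default.
#' @param absRelDenominator `"prediction"` (default) divides the relative
#'   error by the predicted depth; `"truth"` gives the conventional
#'   divide-by-ground-truth form.
#' @return A [MetricsReport-class].
#' @export
evalMetrics <- function(dhat, mhat, d, m, deltas = c(1.1, 1.21),
                        absRelDenominator = c("prediction", "truth")) {
  absRelDenominator <- match.arg(absRelDenominator)
  if (is(dhat, "DepthMap")) dhat <- dhat@depth
  if (is(d, "DepthMap")) d <- d@depth
  if (is(mhat, "BinaryMask")) mhat <- mhat@mask
  if (is(m, "BinaryMask")) m <- m@mask
  Y <- d * m
  Yhat <- dhat * mhat
  V <- m == 1
  if (!any(V)) stop("metrics undefined: the valid set V is empty")
  err <- abs(Y - Yhat)
  mae <- mean(err[V])
  ok <- V & Yhat != 0
  nExcluded <- sum(V) - sum(ok)
  absRel <- if (absRelDenominator == "prediction")
    mean(err[ok] / Yhat[ok]) else mean(err[ok] / Y[ok])
  ratio <- pmax(Y[ok] / Yhat[ok], Yhat[ok] / Y[ok])
  accDelta <- vapply(deltas, function(dl) mean(ratio < dl), numeric(1))
  names(accDelta) <- format(deltas)
  inter1 <- sum(mhat == 1 & m == 1)
  union1 <- sum(mhat == 1 | m == 1)
  inter0 <- sum(mhat == 0 & m == 0)
  union0 <- sum(mhat == 0 | m == 0)
  iou1 <- if (union1 > 0) inter1 / union1 else 1
  iou0 <- if (union0 > 0) inter0 / union0 else 1
  dsc <- 2 * inter1 / (sum(mhat == 1) + sum(m == 1))
  new("MetricsReport", mae = mae, absRel = absRel, accDelta = accDelta,
      dsc = dsc, miou = (iou0 + iou1) / 2, nValid = as.integer(sum(V)),
      nExcluded = as.integer(nExcluded))
}

#' Two-tailed paired t-test on per-case metrics
#'
#' Thin wrapper around the standard paired t-test, with an explicit error
#' when the differences are constant (degenerate test).
#'
#' @param metricA,metricB Equal-length per-case metric vectors.
#' @return List with `t`, `p`, `df` and `meanDiff`.
#' @export
pairedTTest <- function(metricA, metricB) {
  if (length(metricA) != length(metricB))
    stop("paired test requires equal lengths")
  if (length(metricA) < 2) stop("paired test requires at least 2 pairs")
  if (stats::var(metricA - metricB) == 0)
    stop("degenerate test: the paired differences have zero variance")
  tt <- stats::t.test(metricA, metricB, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), meanDiff = unname(tt$estimate))
}

#' Write a metrics table as delimited text
#' @param table `data.frame` of per-case or per-cell metrics.
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
writeMetricsTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
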