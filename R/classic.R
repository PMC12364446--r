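# Conventional multi-frequency phase-shifting FPP: four-step wrapped-phase
# retrieval, temporal unwrapping across a frequency ladder, rational
# phase-to-depth calibration, and the variance-based segmentation mask.

#' Four-step wrapped phase retrieval
#'
#' For images `I_k = a + b * cos(phi + theta_k)` at shifts `theta = (0, pi/2,
#' pi, 3*pi/2)`, the per-pixel wrapped phase is `atan2(I4 - I2, I1 - I3)`,
#' invariant to the offset `a` and to positive scaling of `b`. Pixels with no
#' modulation (all differences zero) are flagged invalid.
#'
#' @param i0,i90,i180,i270 Equally sized intensity matrices at the four phase
#'   shifts.
#' @return List with `phase` (radians in `(-pi, pi]`) and logical `valid`.
#' @export
wrappedPhase <- function(i0, i90, i180, i270) {
  dims <- list(dim(i0), dim(i90), dim(i180), dim(i270))
  if (length(unique(dims)) != 1)
    stop("the four phase-shifted images must share one size")
  num <- i270 - i90
  den <- i0 - i180
  valid <- !(num == 0 & den == 0)
  phase <- atan2(num, den)
  phase[phase <= -pi] <- pi
  list(phase = phase, valid = valid)
}

wrapToPi <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Temporal phase unwrapping over an ascending frequency ladder
#'
#' Seeds at the lowest frequency, whose phase is shifted into `[0, 2*pi)` (a
#' one-cycle field is then unambiguous), and cascades upward: `Phi_{k+1} =
#' phi_{k+1} + 2*pi * round((r_k * Phi_k - phi_{k+1}) / (2*pi))` with `r_k =
#' f_{k+1} / f_k`. Pixels whose cascade residual exceeds `pi` at any step are
#' flagged as unreliable.
#'
#' @param wrapped List of wrapped phase matrices (radians), lowest frequency
#'   first.
#' @param frequencies Strictly increasing frequencies matching `wrapped`.
#' @return List with `phase` (absolute phase at the highest frequency),
#'   `frequency`, and logical `reliable`.
#' @export
unwrapTemporal <- function(wrapped, frequencies) {
  if (length(wrapped) != length(frequencies) || length(wrapped) < 1)
    stop("one wrapped map per frequency required")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  ratios <- frequencies[-1] / frequencies[-length(frequencies)]
  if (any(abs(ratios - round(ratios)) > 1e-9))
    warning("non-integer frequency ratio in the unwrapping cascade")
  phi <- wrapped[[1]]
  phi <- phi + 2 * pi * (phi < 0)  # lowest frequency into [0, 2*pi)
  reliable <- matrix(TRUE, nrow(phi), ncol(phi))
  for (k in seq_along(ratios)) {
    target <- ratios[k] * phi
    nxt <- wrapped[[k + 1]]
    resid <- target - nxt
    phi <- nxt + 2 * pi * round(resid / (2 * pi))
    reliable <- reliable & (abs(phi - target) <= pi)
  }
  list(phase = phi, frequency = frequencies[length(frequencies)],
       reliable = reliable)
}

calibDesignRow <- function(u, v, phi, z) {
  cbind(1, phi, u, phi * u, v, phi * v,
        -z * phi, -z * u, -z * phi * u, -z * v, -z * phi * v)
}

#' Fit the rational phase-to-depth calibration
#'
#' Rearranges `z * (d0 + d1*phi + (d2 + d3*phi)*u + (d4 + d5*phi)*v) = c0 +
#' c1*phi + (c2 + c3*phi)*u + (c4 + c5*phi)*v` with the gauge `d0 = 1` into a
#' linear least-squares problem for the 11 free coefficients.
#'
#' @param planes List of calibration views; each element is a list with
#'   `phase` (unwrapped phase matrix), `z` (known depth: scalar or matrix)
#'   and optionally `valid` (logical matrix).
#' @param maxPixels Per-plane pixel subsample cap (deterministic strided
#'   subsample) to bound the solve.
#' @return A [CalibrationCoefficients-class]; the RMS residual of the fit is
#'   attached as attribute `"residual"` (mm).
#' @export
fitCalibration <- function(planes, maxPixels = 20000L) {
  if (length(planes) < 3)
    stop("calibration degeneracy: at least 3 planes spanning distinct ",
         "depths are required")
  rows <- lapply(planes, function(p) {
    ph <- p$phase
    H <- nrow(ph); W <- ncol(ph)
    z <- if (length(p$z) == 1) matrix(p$z, H, W) else p$z
    valid <- if (is.null(p$valid)) matrix(TRUE, H, W) else p$valid
    idx <- which(valid)
    if (length(idx) > maxPixels)
      idx <- idx[seq(1, length(idx), length.out = maxPixels)]
    uu <- (col(ph) - 1)[idx]
    vv <- (row(ph) - 1)[idx]
    list(A = calibDesignRow(uu, vv, ph[idx], z[idx]), z = z[idx])
  })
  A <- do.call(rbind, lapply(rows, `[[`, "A"))
  zvec <- unlist(lapply(rows, `[[`, "z"))
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    deficient <- colnames(A, do.NULL = FALSE)[qrA$pivot[-seq_len(qrA$rank)]]
    stop("calibration degeneracy: design matrix rank ", qrA$rank, " < 11; ",
         "deficient directions at pivot columns ",
         paste(qrA$pivot[-seq_len(qrA$rank)], collapse = ", "),
         " - add planes spanning more depths")
  }
  coef <- qr.coef(qrA, zvec)
  resid <- sqrt(mean((A %*% coef - zvec)^2))
  out <- calibrationCoefficients(cc = coef[1:6],
                                 dd = c(1, coef[7:11]))
  attr(out, "residual") <- resid
  out
}

#' Depth from unwrapped phase via the rational calibration model
#'
#' `z = (c0 + c1*phi + (c2 + c3*phi)*u + (c4 + c5*phi)*v) / (d0 + d1*phi +
#' (d2 + d3*phi)*u + (d4 + d5*phi)*v)` with `(u, v)` the 0-based column/row
#' pixel indices. Pixels whose denominator magnitude falls below `tol` are
#' marked invalid rather than propagating infinities.
#'
#' @param phase Unwrapped phase matrix (radians) or the list returned by
#'   [unwrapTemporal()].
#' @param calib A [CalibrationCoefficients-class].
#' @param tol Denominator tolerance.
#' @return A [DepthMap-class] (mm).
#' @export
depthFromPhase <- function(phase, calib, tol = 1e-9) {
  if (is.list(phase)) phase <- phase$phase
  validObject(calib)
  u <- col(phase) - 1
  v <- row(phase) - 1
  cc <- calib@cc; dd <- calib@dd
  num <- cc[1] + cc[2] * phase + (cc[3] + cc[4] * phase) * u +
    (cc[5] + cc[6] * phase) * v
  den <- dd[1] + dd[2] * phase + (dd[3] + dd[4] * phase) * u +
    (dd[5] + dd[6] * phase) * v
  valid <- abs(den) >= tol
  z <- matrix(0, nrow(phase), ncol(phase))
  z[valid] <- num[valid] / den[valid]
  depthMap(z, valid)
}

#' Variance-based segmentation mask
#'
#' A pixel is sample (1) when the population variance of its intensities
#' across the 16 phase-shifted images, taken on the 8-bit acquisition scale,
#' reaches the threshold `gamma`; background reflects so little of the
#' pattern that its modulation variance stays below threshold.
#'
#' @param images List of at least 2 equally sized intensity matrices in
#'   `[0, 1]` (16 in the standard protocol).
#' @param gamma Variance threshold on the 8-bit intensity scale; 30 by
#'   default.
#' @param scale Intensity scale applied before the variance (255 maps unit
#'   range onto 8-bit).
#' @return A [BinaryMask-class].
#' @export
varianceMask <- function(images, gamma = 30, scale = 255) {
  if (length(images) < 2)
    stop("variance mask requires at least 2 images")
  n <- length(images)
  mu <- Reduce(`+`, images) / n
  musq <- Reduce(`+`, lapply(images, function(x) x * x)) / n
  v <- pmax(musq - mu * mu, 0) * scale^2  # population variance, 8-bit scale
  binaryMask((v >= gamma) * 1)
}

#' Morphological cleanup of a binary mask
#'
#' Opening (erosion then dilation) followed by closing (dilation then
#' erosion) with a square structuring element: removes speckles smaller than
#' the element and fills comparable holes. Idempotent when re-applied with
#' the same element.
#'
#' @param mask A [BinaryMask-class] or 0/1 matrix.
#' @param size Structuring element side (odd; 5 by default).
#' @return A [BinaryMask-class].
#' @export
refineMask <- function(mask, size = 5L) {
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  kern <- EBImage::makeBrush(as.integer(size), shape = "box")
  m <- EBImage::opening(m, kern)
  m <- EBImage::closing(m, kern)
  binaryMask((m > 0.5) * 1)
}

#' Classical ground-truth depth and mask for a frame group
#'
#' Runs the conventional pipeline on a `classic_gt` group: four-step wrapped
#' phase at each ladder frequency, temporal unwrapping, rational
#' phase-to-depth evaluation for the depth map; variance mask plus
#' morphological cleanup for the segmentation.
#'
#' @param group A [FrameGroup-class] in `classic_gt` mode.
#' @param calib A [CalibrationCoefficients-class].
#' @param gamma Variance threshold (8-bit scale).
#' @return List with `depth` (a [DepthMap-class]) and `mask`
#'   (a [BinaryMask-class]).
#' @export
groundTruthStack <- function(group, calib, gamma = 30) {
  if (group@mode != "classic_gt")
    stop("ground-truth stack requires a classic_gt group, got '",
         group@mode, "'")
  freqs <- c(1, 4, 16, 64)
  wrappedMaps <- lapply(seq_along(freqs), function(k) {
    i <- (k - 1) * 4
    wp <- tryCatch(
      wrappedPhase(group@images[[i + 1]], group@images[[i + 2]],
                   group@images[[i + 3]], group@images[[i + 4]]),
      error = function(e)
        stop("wrapped-phase stage failed at frequency ", freqs[k], ": ",
             conditionMessage(e)))
    wp$phase
  })
  unwrapped <- tryCatch(unwrapTemporal(wrappedMaps, freqs),
    error = function(e) stop("unwrapping stage failed: ",
                             conditionMessage(e)))
  depth <- tryCatch(depthFromPhase(unwrapped, calib),
    error = function(e) stop("depth stage failed: ", conditionMessage(e)))
  mask <- tryCatch(refineMask(varianceMask(group@images[1:16], gamma)),
    error = function(e) stop("mask stage failed: ", conditionMessage(e)))
  list(depth = depth, mask = mask)
}

#' Render calibration planes and fit the depth model
#'
#' Renders background-only (plane) scenes at the given depths through the
#' full classical pipeline (phase-shift sequences at the ladder frequencies,
#' wrapped-phase retrieval, temporal unwrapping) and fits the rational
#' calibration from them.
#'
#' @param depths Plane depths in mm (at least 3, spanning the working
#'   range).
#' @param imageSize Render resolution.
#' @param scene Optional template scene; its background depth and albedo are
#'   overridden per plane.
#' @return A [CalibrationCoefficients-class] (see [fitCalibration()]).
#' @export
calibrateFromPlanes <- function(depths = seq(70, 140, by = 17.5),
                                imageSize = 256L, scene = NULL) {
  freqs <- c(1, 4, 16, 64)
  planes <- lapply(depths, function(z) {
    sc <- defaultScene(imageSize = imageSize, hasSample = FALSE,
                       backgroundDepth = z, backgroundAlbedo = 0.8)
    geom <- renderGeometry(sc)
    wrappedMaps <- lapply(freqs, function(f) {
      specs <- phaseShiftSequence(f)
      imgs <- lapply(specs, function(sp) shadeGeometry(sc, geom,
                                                       renderPattern(sp)))
      wrappedPhase(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]])$phase
    })
    un <- unwrapTemporal(wrappedMaps, freqs)
    list(phase = un$phase, z = z, valid = un$reliable)
  })
  fitCalibration(planes)
}

#' Write and read calibration coefficients as a 12-number text record
#' @param calib A [CalibrationCoefficients-class].
#' @param path File path.
#' @return `writeCalibration` returns `path` invisibly; `readCalibration`
#'   the coefficients object.
#' @export
writeCalibration <- function(calib, path) {
  writeLines(format(c(calib@cc, calib@dd), digits = 17), path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- as.numeric(readLines(path))
  if (length(x) != 12) stop("calibration record must hold 12 numbers")
  calibrationCoefficients(cc = x[1:6], dd = x[7:12])
}
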