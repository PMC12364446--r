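#' @useDynLib EndoFPP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---------------------------------------------------------------------------
# Pattern domain
# ---------------------------------------------------------------------------

#' Projector fringe pattern specification
#'
#' Describes one projector pattern: sinusoidal or binary fringes at a given
#' spatial frequency (cycles across the full pattern width), a phase shift in
#' radians, pixel dimensions, fringe orientation and an intensity range.
#'
#' @slot kind `"sinusoidal"` or `"binary"`.
#' @slot frequency Cycles across the pattern width (the spatial frequency
#'   customarily quoted in Hz for structured-light projectors).
#' @slot phaseShift Phase offset in radians.
#' @slot width,height Pattern size in pixels.
#' @slot orientation `"vertical"` (phase varies along columns, u) or
#'   `"horizontal"`.
#' @slot intensityRange Numeric length-2 `(lo, hi)` within `[0, 1]`.
#' @exportClass PatternSpec
setClass("PatternSpec",
  representation(kind = "character", frequency = "numeric",
                 phaseShift = "numeric", width = "integer",
                 height = "integer", orientation = "character",
                 intensityRange = "numeric"),
  prototype(kind = "sinusoidal", frequency = 1, phaseShift = 0,
            width = 720L, height = 720L, orientation = "vertical",
            intensityRange = c(0, 1)))

setValidity("PatternSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("sinusoidal", "binary"))
    msg <- c(msg, "kind must be 'sinusoidal' or 'binary'")
  if (!is.finite(object@frequency) || object@frequency < 0)
    msg <- c(msg, "frequency must be finite and >= 0")
  if (!is.finite(object@phaseShift))
    msg <- c(msg, "phase shift must be finite")
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "pattern size must be at least 1x1")
  if (length(object@intensityRange) != 2 ||
      !all(is.finite(object@intensityRange)) ||
      object@intensityRange[1] >= object@intensityRange[2] ||
      object@intensityRange[1] < 0 || object@intensityRange[2] > 1)
    msg <- c(msg, "intensityRange must be (lo, hi) with 0 <= lo < hi <= 1")
  if (!object@orientation %in% c("vertical", "horizontal"))
    msg <- c(msg, "orientation must be 'vertical' or 'horizontal'")
  if (length(msg)) msg else TRUE
})

#' Construct a PatternSpec
#'
#' @param kind Pattern waveform, `"sinusoidal"` or `"binary"`.
#' @param frequency Cycles across the pattern width.
#' @param phaseShift Phase offset in radians.
#' @param width,height Pattern size in pixels.
#' @param orientation `"vertical"` or `"horizontal"` fringes.
#' @param intensityRange Numeric `(lo, hi)` in `[0, 1]`.
#' @return A [PatternSpec-class] object.
#' @examples
#' patternSpec("binary", frequency = 20)
#' @export
patternSpec <- function(kind = c("sinusoidal", "binary"), frequency = 1,
                        phaseShift = 0, width = 720L, height = 720L,
                        orientation = c("vertical", "horizontal"),
                        intensityRange = c(0, 1)) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  new("PatternSpec", kind = kind, frequency = as.numeric(frequency),
      phaseShift = as.numeric(phaseShift), width = as.integer(width),
      height = as.integer(height), orientation = orientation,
      intensityRange = as.numeric(intensityRange))
}

setMethod("show", "PatternSpec", function(object) {
  cat(sprintf("PatternSpec: %s, %g cycles, shift %.4g rad, %dx%d (%s)\n",
              object@kind, object@frequency, object@phaseShift,
              object@width, object@height, object@orientation))
})

# ---------------------------------------------------------------------------
# Simulator domain
# ---------------------------------------------------------------------------

#' Pinhole camera/projector model
#'
#' @slot focalLength Focal length in pixels.
#' @slot principalPoint `(u0, v0)` in pixels, 0-based.
#' @slot rotation 3x3 rotation (world to device), orthonormal.
#' @slot translation Device origin in world coordinates, mm.
#' @slot imageSize `(W, H)` in pixels.
#' @exportClass PinholeModel
setClass("PinholeModel",
  representation(focalLength = "numeric", principalPoint = "numeric",
                 rotation = "matrix", translation = "numeric",
                 imageSize = "integer"))

setValidity("PinholeModel", function(object) {
  msg <- character()
  if (object@focalLength <= 0) msg <- c(msg, "focal length must be > 0")
  if (length(object@principalPoint) != 2)
    msg <- c(msg, "principal point must have two components")
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(R %*% t(R) - diag(3))) > 1e-9)
    msg <- c(msg, "rotation must be orthonormal (R R^T = I within 1e-9)")
  if (length(object@translation) != 3)
    msg <- c(msg, "translation must have three components")
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    msg <- c(msg, "image size must be (W, H) with positive entries")
  if (length(msg)) msg else TRUE
})

#' Construct a pinhole model
#'
#' @param focalLength Focal length in pixels.
#' @param principalPoint `(u0, v0)` pixels (0-based).
#' @param rotation 3x3 orthonormal rotation matrix.
#' @param translation Position in world coordinates (mm).
#' @param imageSize `(W, H)` pixels.
#' @return A [PinholeModel-class].
#' @export
pinholeModel <- function(focalLength, principalPoint, rotation = diag(3),
                         translation = c(0, 0, 0), imageSize) {
  new("PinholeModel", focalLength = as.numeric(focalLength),
      principalPoint = as.numeric(principalPoint), rotation = rotation,
      translation = as.numeric(translation),
      imageSize = as.integer(imageSize))
}

#' Diamond tissue-phantom surface
#'
#' A diamond (45-degree square) support of the given side length carrying a
#' smooth raised-cosine dome plus an optional band-limited perturbation; the
#' perturbation rows are `(amplitude mm, fx, fy, phase)` with spatial
#' frequencies in cycles per half-diagonal.
#'
#' @slot sideLength Diamond edge length in mm.
#' @slot domeAmplitude Dome height in mm.
#' @slot perturbation k x 4 matrix of low-order smooth modes.
#' @slot albedo Diffuse reflectance in `[0, 1]`.
#' @exportClass SampleSurface
setClass("SampleSurface",
  representation(sideLength = "numeric", domeAmplitude = "numeric",
                 perturbation = "matrix", albedo = "numeric"),
  prototype(sideLength = 40, domeAmplitude = 10,
            perturbation = matrix(numeric(0), 0, 4), albedo = 0.8))

setValidity("SampleSurface", function(object) {
  msg <- character()
  if (object@sideLength <= 0) msg <- c(msg, "side length must be > 0")
  if (!is.finite(object@domeAmplitude))
    msg <- c(msg, "dome amplitude must be finite")
  if (ncol(object@perturbation) != 4)
    msg <- c(msg, "perturbation must have 4 columns (amp, fx, fy, phase)")
  if (object@albedo < 0 || object@albedo > 1)
    msg <- c(msg, "albedo must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a sample surface
#' @param sideLength Diamond edge length (mm).
#' @param domeAmplitude Dome height (mm).
#' @param perturbation k x 4 matrix `(amp, fx, fy, phase)` of smooth modes.
#' @param albedo Diffuse reflectance.
#' @return A [SampleSurface-class].
#' @export
sampleSurface <- function(sideLength = 40, domeAmplitude = 10,
                          perturbation = matrix(numeric(0), 0, 4),
                          albedo = 0.8) {
  new("SampleSurface", sideLength = as.numeric(sideLength),
      domeAmplitude = as.numeric(domeAmplitude),
      perturbation = perturbation, albedo = as.numeric(albedo))
}

#' Rigid pose of the phantom
#'
#' @slot translation `(tx, ty, tz)` mm, relative to the nominal position.
#' @slot rotation `(rx, ry, rz)` degrees.
#' @slot scale `(sx, sy, sz)` unitless.
#' @exportClass SamplePose
setClass("SamplePose",
  representation(translation = "numeric", rotation = "numeric",
                 scale = "numeric"),
  prototype(translation = c(0, 0, 0), rotation = c(0, 0, 0),
            scale = c(1, 1, 1)))

setValidity("SamplePose", function(object) {
  if (length(object@translation) != 3 || length(object@rotation) != 3 ||
      length(object@scale) != 3)
    return("translation, rotation and scale must each have 3 components")
  if (any(object@scale <= 0)) return("scale factors must be positive")
  TRUE
})

#' Construct a sample pose
#' @param translation `(tx, ty, tz)` mm.
#' @param rotation `(rx, ry, rz)` degrees.
#' @param scale `(sx, sy, sz)`.
#' @return A [SamplePose-class].
#' @export
samplePose <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                       scale = c(1, 1, 1)) {
  new("SamplePose", translation = as.numeric(translation),
      rotation = as.numeric(rotation), scale = as.numeric(scale))
}

setMethod("show", "SamplePose", function(object) {
  cat(sprintf("SamplePose: t=(%.2f, %.2f, %.2f) mm, r=(%.2f, %.2f, %.2f) deg, s=(%.3f, %.3f, %.3f)\n",
              object@translation[1], object@translation[2],
              object@translation[3], object@rotation[1], object@rotation[2],
              object@rotation[3], object@scale[1], object@scale[2],
              object@scale[3]))
})

#' Structured-light scene description
#'
#' World frame = camera frame: the camera sits at the origin looking along +z.
#' The projector is a second pinhole device, offset by a small baseline (an
#' approximately coaxial arrangement). The phantom sits near `nominalDistance`
#' along the optical axis, perturbed by `pose`; a large background cuboid face
#' sits at `backgroundDepth`.
#'
#' @slot camera,projector [PinholeModel-class] devices.
#' @slot surface [SampleSurface-class].
#' @slot pose [SamplePose-class].
#' @slot nominalDistance Nominal phantom distance (mm).
#' @slot backgroundDepth Background face distance (mm).
#' @slot backgroundHalfwidth Lateral half-extent of the background (mm).
#' @slot backgroundAlbedo Background reflectance.
#' @slot workingRange Working distance range (mm).
#' @slot hasSample Whether the phantom is present (calibration planes drop it).
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(camera = "PinholeModel", projector = "PinholeModel",
                 surface = "SampleSurface", pose = "SamplePose",
                 nominalDistance = "numeric", backgroundDepth = "numeric",
                 backgroundHalfwidth = "numeric",
                 backgroundAlbedo = "numeric", workingRange = "numeric",
                 hasSample = "logical"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  maxSampleDepth <- object@nominalDistance + object@pose@translation[3]
  if (object@hasSample && object@backgroundDepth <= maxSampleDepth)
    msg <- c(msg, "background must lie behind the sample")
  if (length(object@workingRange) != 2 ||
      object@workingRange[1] >= object@workingRange[2])
    msg <- c(msg, "working range must be an increasing pair")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %dx%d camera (f=%.1f px), projector f=%.1f px, baseline %.1f mm\n",
    object@camera@imageSize[1], object@camera@imageSize[2],
    object@camera@focalLength, object@projector@focalLength,
    sqrt(sum(object@projector@translation^2))))
  cat(sprintf("  sample at %.1f mm (%s), background at %.1f mm\n",
              object@nominalDistance + object@pose@translation[3],
              if (object@hasSample) "present" else "absent",
              object@backgroundDepth))
})

#' A co-registered group of fringe images of one scene pose
#'
#' @slot images List of camera intensity matrices in `[0, 1]`.
#' @slot specs List of the [PatternSpec-class] each image was shaded with.
#' @slot depthGT Ground-truth depth matrix (mm).
#' @slot maskGT Ground-truth sample mask matrix (0/1) or NULL.
#' @slot pose The [SamplePose-class] shared by all images.
#' @slot mode `"sweep"` (22 static fringe images, 4-24 cycles x two kinds) or
#'   `"classic_gt"` (16 phase-shifted images I1..I16 plus IS and IB).
#' @exportClass FrameGroup
setClass("FrameGroup",
  representation(images = "list", specs = "list", depthGT = "matrix",
                 maskGT = "ANY", pose = "SamplePose", mode = "character"))

setValidity("FrameGroup", function(object) {
  msg <- character()
  if (!object@mode %in% c("sweep", "classic_gt"))
    msg <- c(msg, "mode must be 'sweep' or 'classic_gt'")
  n <- length(object@images)
  if (object@mode == "sweep" && n != 22L)
    msg <- c(msg, "sweep groups must contain 22 images")
  if (object@mode == "classic_gt" && n != 18L)
    msg <- c(msg, "classic_gt groups must contain 18 images")
  if (length(object@specs) != n)
    msg <- c(msg, "one PatternSpec per image required")
  dims <- unique(lapply(object@images, dim))
  if (length(dims) > 1) msg <- c(msg, "all images must share one size")
  if (n > 0 && !identical(dim(object@images[[1]]), dim(object@depthGT)))
    msg <- c(msg, "depthGT must match the image size")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrameGroup", function(object) {
  d <- dim(object@depthGT)
  cat(sprintf("FrameGroup (%s): %d images of %dx%d, depth range %.1f-%.1f mm\n",
              object@mode, length(object@images), d[2], d[1],
              min(object@depthGT), max(object@depthGT)))
})

# ---------------------------------------------------------------------------
# Classical pipeline domain
# ---------------------------------------------------------------------------

#' Rational phase-to-depth calibration coefficients
#'
#' The twelve parameters `c0..c5`, `d0..d5` of the rational mapping
#' `z = (c0 + c1*phi + (c2 + c3*phi)*u + (c4 + c5*phi)*v) /
#'      (d0 + d1*phi + (d2 + d3*phi)*u + (d4 + d5*phi)*v)`
#' with the gauge `d0 = 1`.
#'
#' @slot cc Numeric length 6, `c0..c5`.
#' @slot dd Numeric length 6, `d0..d5` with `d0 = 1`.
#' @exportClass CalibrationCoefficients
setClass("CalibrationCoefficients",
  representation(cc = "numeric", dd = "numeric"))

setValidity("CalibrationCoefficients", function(object) {
  msg <- character()
  if (length(object@cc) != 6 || length(object@dd) != 6)
    msg <- c(msg, "cc and dd must each have 6 entries")
  if (abs(object@dd[1] - 1) > 1e-12)
    msg <- c(msg, "gauge requires d0 = 1")
  if (length(msg)) msg else TRUE
})

#' Construct calibration coefficients
#' @param cc Numeric `c0..c5`.
#' @param dd Numeric `d0..d5` (`d0` must equal 1).
#' @return A [CalibrationCoefficients-class].
#' @export
calibrationCoefficients <- function(cc, dd) {
  new("CalibrationCoefficients", cc = as.numeric(cc), dd = as.numeric(dd))
}

setMethod("show", "CalibrationCoefficients", function(object) {
  cat("CalibrationCoefficients (z = rational(u, v, phi), d0 = 1 gauge)\n")
  cat("  c:", format(object@cc, digits = 6), "\n")
  cat("  d:", format(object@dd, digits = 6), "\n")
})

#' Depth map with validity channel
#'
#' @slot depth Matrix of per-pixel depth (mm).
#' @slot valid Logical matrix flagging pixels with a defined depth.
#' @exportClass DepthMap
setClass("DepthMap", representation(depth = "matrix", valid = "matrix"))

setValidity("DepthMap", function(object) {
  if (!identical(dim(object@depth), dim(object@valid)))
    return("depth and valid must share dimensions")
  if (!is.logical(object@valid)) return("valid must be logical")
  if (any(!is.finite(object@depth[object@valid])))
    return("depth must be finite on valid pixels")
  TRUE
})

#' Construct a DepthMap
#' @param depth Depth matrix (mm).
#' @param valid Logical validity matrix (default: all finite pixels).
#' @return A [DepthMap-class].
#' @export
depthMap <- function(depth, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(depth)
  depth[!valid] <- 0
  new("DepthMap", depth = depth, valid = valid)
}

#' @describeIn depthMap Extract the depth matrix (mm).
#' @param x A `DepthMap`.
#' @export
depthMatrix <- function(x) x@depth

#' @describeIn depthMap Extract the logical validity matrix.
#' @export
validMatrix <- function(x) x@valid

setMethod("show", "DepthMap", function(object) {
  d <- dim(object@depth)
  v <- object@depth[object@valid]
  cat(sprintf("DepthMap %dx%d: %d/%d valid, range %.2f-%.2f mm\n",
              d[2], d[1], sum(object@valid), length(object@valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' Binary segmentation mask
#'
#' @slot mask Matrix with entries in `{0, 1}`; 1 marks the sample.
#' @exportClass BinaryMask
setClass("BinaryMask", representation(mask = "matrix"))

setValidity("BinaryMask", function(object) {
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary (0/1)")
  TRUE
})

#' Construct a BinaryMask
#' @param mask 0/1 matrix (1 = sample).
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(mask) {
  storage.mode(mask) <- "double"
  new("BinaryMask", mask = mask)
}

#' @describeIn binaryMask Extract the 0/1 matrix.
#' @param x A `BinaryMask`.
#' @export
maskMatrix <- function(x) x@mask

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask %dx%d: %.1f%% sample\n", d[2], d[1],
              100 * mean(object@mask)))
})

# ---------------------------------------------------------------------------
# Metrics domain
# ---------------------------------------------------------------------------

#' Depth and segmentation evaluation report
#'
#' @slot mae Mean absolute depth error over valid pixels (mm).
#' @slot absRel Mean absolute relative error over valid pixels (unitless).
#' @slot accDelta Named vector of delta-accuracies (fractions).
#' @slot dsc Dice score of the sample class.
#' @slot miou Mean intersection-over-union across the two classes.
#' @slot nValid Number of valid pixels.
#' @slot nExcluded Valid pixels excluded from ratio metrics because the
#'   prediction is zero there.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(mae = "numeric", absRel = "numeric", accDelta = "numeric",
                 dsc = "numeric", miou = "numeric", nValid = "integer",
                 nExcluded = "integer"))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (object@mae < 0) msg <- c(msg, "MAE must be non-negative")
  # ratio metrics may be NaN when every valid pixel was excluded
  fr <- c(object@accDelta, object@dsc, object@miou)
  if (any(fr < -1e-12 | fr > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d valid pixels (%d excluded from ratios)\n",
              object@nValid, object@nExcluded))
  cat(sprintf("  MAE %.3f mm | Abs Rel %.4f | %s\n", object@mae,
              object@absRel,
              paste(sprintf("acc(%s)=%.4f", names(object@accDelta),
                            object@accDelta), collapse = " | ")))
  cat(sprintf("  DSC %.4f | mIoU %.4f\n", object@dsc, object@miou))
})

#' Coerce a MetricsReport to a one-row data.frame
#' @param report A [MetricsReport-class].
#' @return A one-row `data.frame` with one column per metric.
#' @export
metricsAsRow <- function(report) {
  row <- data.frame(mae = report@mae, abs_rel = report@absRel,
                    dsc = report@dsc, miou = report@miou,
                    n_valid = report@nValid, n_excluded = report@nExcluded)
  for (nm in names(report@accDelta))
    row[[paste0("acc_", nm)]] <- report@accDelta[[nm]]
  row
}
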