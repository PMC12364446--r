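# Analytic structured-light scene simulator: renders fringe-illuminated
# images of a posed diamond phantom with exact ground-truth depth, models
# Poisson shot noise, and assembles frame groups and datasets.

withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations applied in x, then y, then z order (`R = Rz Ry Rx`),
#' angles in degrees.
#'
#' @param rx,ry,rz Rotation angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotationMatrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Default endoscopic structured-light scene
#'
#' Camera at the origin looking along +z with focal length `1.1 * imageSize`
#' pixels (the 4 cm phantom fits the field of view over the whole working
#' range); projector with a 720-pixel-wide pattern, focal length 600 px and a
#' 25 mm lateral baseline -- an approximately coaxial geometry. The projector
#' principal point is chosen so its pattern is centred on the camera axis at
#' the nominal 105 mm distance. Background face at 140 mm.
#'
#' @param imageSize Camera image size in pixels (square).
#' @param patternSize Projector pattern size in pixels (square).
#' @param baseline Projector lateral offset (mm).
#' @param nominalDistance Nominal phantom distance (mm).
#' @param backgroundDepth Background face distance (mm).
#' @param backgroundAlbedo Background reflectance (dim, so its fringe
#'   modulation stays below the variance-mask threshold).
#' @param surface A [SampleSurface-class].
#' @param pose A [SamplePose-class].
#' @param hasSample Set `FALSE` for background-only (calibration plane)
#'   scenes.
#' @return A [SceneSpec-class].
#' @export
defaultScene <- function(imageSize = 256L, patternSize = 720L,
                         baseline = 25, nominalDistance = 105,
                         backgroundDepth = 140, backgroundAlbedo = 0.025,
                         surface = sampleSurface(), pose = samplePose(),
                         hasSample = TRUE) {
  W <- as.integer(imageSize)
  fc <- 1.1 * W
  cam <- pinholeModel(fc, c((W - 1) / 2, (W - 1) / 2), imageSize = c(W, W))
  Wp <- as.integer(patternSize)
  fp <- 600 * Wp / 720
  u0p <- (Wp - 1) / 2 + fp * baseline / nominalDistance
  proj <- pinholeModel(fp, c(u0p, (Wp - 1) / 2),
                       translation = c(baseline, 0, 0),
                       imageSize = c(Wp, Wp))
  new("SceneSpec", camera = cam, projector = proj, surface = surface,
      pose = pose, nominalDistance = nominalDistance,
      backgroundDepth = backgroundDepth, backgroundHalfwidth = 400,
      backgroundAlbedo = backgroundAlbedo, workingRange = c(70, 140),
      hasSample = hasSample)
}

#' Default pose randomisation ranges
#'
#' Translations of -1 to 1 cm, rotations of -15 to +15 degrees and scale
#' factors of 0.85 to 1.15 along all three axes.
#'
#' @return List with elements `translation` (mm), `rotation` (degrees) and
#'   `scale`, each a length-2 range.
#' @export
defaultPoseRanges <- function() {
  list(translation = c(-10, 10), rotation = c(-15, 15), scale = c(0.85, 1.15))
}

#' Draw a random phantom pose
#'
#' Each pose component is drawn uniformly and independently within its range.
#'
#' @param ranges List with `translation`, `rotation`, `scale` ranges (see
#'   [defaultPoseRanges()]).
#' @param seed Optional integer seed (the global RNG state is restored).
#' @return A [SamplePose-class].
#' @export
sampleRandomPose <- function(ranges = defaultPoseRanges(), seed = NULL) {
  for (nm in c("translation", "rotation", "scale")) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("invalid config: pose range '", nm, "' must be an ordered pair")
  }
  withSeed(seed, {
    samplePose(
      translation = stats::runif(3, ranges$translation[1],
                                 ranges$translation[2]),
      rotation = stats::runif(3, ranges$rotation[1], ranges$rotation[2]),
      scale = stats::runif(3, ranges$scale[1], ranges$scale[2]))
  })
}

#' Draw a random band-limited surface perturbation
#'
#' Low-order smooth modes that diversify the phantom's dome shape; amplitudes
#' up to `maxAmp` mm, spatial frequencies up to 1.5 cycles per half-diagonal.
#'
#' @param nModes Number of modes.
#' @param maxAmp Maximum mode amplitude (mm).
#' @return k x 4 matrix `(amp, fx, fy, phase)` suitable for
#'   [sampleSurface()].
#' @export
randomPerturbation <- function(nModes = 3L, maxAmp = 2) {
  cbind(stats::runif(nModes, 0, maxAmp),
        stats::runif(nModes, 0.3, 1.5),
        stats::runif(nModes, 0.3, 1.5),
        stats::runif(nModes, 0, 2 * pi))
}

#' Ray-cast the scene geometry
#'
#' Computes, for every camera pixel, the first intersection of its viewing
#' ray with the posed phantom heightfield (falling back to the background
#' face), giving the depth map (z-distance in mm), world coordinates of the
#' hit point and the sample/background flag.
#'
#' @param scene A [SceneSpec-class].
#' @param zStep Coarse marching step (mm) before bisection refinement; the
#'   surface function is monotone along viewing rays except at grazing
#'   silhouette pixels, so a 2 mm step loses at most subpixel silhouette
#'   detail.
#' @param zTol Bisection tolerance (mm).
#' @return List with matrices `depth`, `x`, `y` and integer matrix `hit`.
#' @export
renderGeometry <- function(scene, zStep = 2, zTol = 1e-4) {
  validObject(scene)
  cam <- scene@camera
  surf <- scene@surface
  pose <- scene@pose
  Rm <- rotationMatrix(pose@rotation[1], pose@rotation[2], pose@rotation[3])
  ctr <- c(pose@translation[1], pose@translation[2],
           scene@nominalDistance + pose@translation[3])
  a <- surf@sideLength / sqrt(2)  # half-diagonal of the diamond
  cpp_render_geometry(cam@imageSize[1], cam@imageSize[2], cam@focalLength,
                      cam@principalPoint[1], cam@principalPoint[2],
                      Rm, pose@scale, ctr, scene@hasSample, a,
                      surf@domeAmplitude, surf@perturbation,
                      scene@backgroundDepth, scene@backgroundHalfwidth,
                      zStep, zTol)
}

projectToProjector <- function(scene, geom) {
  proj <- scene@projector
  t <- proj@translation
  xp <- geom$x - t[1]
  yp <- geom$y - t[2]
  zp <- geom$depth - t[3]
  list(u = proj@focalLength * xp / zp + proj@principalPoint[1],
       v = proj@focalLength * yp / zp + proj@principalPoint[2])
}

shadeGeometry <- function(scene, geom, pattern) {
  pp <- projectToProjector(scene, geom)
  sampled <- cpp_bilinear_sample(pattern, pp$u, pp$v)
  albedo <- ifelse(geom$hit == 1L, scene@surface@albedo,
                   scene@backgroundAlbedo)
  albedo * sampled
}

#' Render one fringe-illuminated frame
#'
#' Shades each camera pixel with `albedo * pattern`, the pattern sampled
#' bilinearly at the projector-plane projection of the pixel's surface hit
#' point; pixels projecting outside the pattern receive ambient 0.
#'
#' @param scene A [SceneSpec-class].
#' @param pattern Pattern intensity matrix (e.g. from [renderPattern()]), or
#'   a [PatternSpec-class] which is rendered first.
#' @param geom Optional precomputed [renderGeometry()] result (the geometry
#'   is shared between all patterns of one pose).
#' @return List with `image` (intensity matrix in `[0, 1]`) and `depth`
#'   (a [DepthMap-class], all pixels valid).
#' @export
renderFrame <- function(scene, pattern, geom = NULL) {
  if (is(pattern, "PatternSpec")) pattern <- renderPattern(pattern)
  if (is.null(geom)) geom <- renderGeometry(scene)
  list(image = shadeGeometry(scene, geom, pattern),
       depth = depthMap(geom$depth))
}

#' Add Poisson shot noise
#'
#' Each pixel is replaced by `Poisson(I * S) / S` (clipped to `[0, 1]`), so
#' darker pixels carry proportionally more noise, as for physical photon
#' arrival.
#'
#' @param image Intensity matrix with non-negative entries.
#' @param photonScale Photons per unit intensity `S > 0`.
#' @param seed Optional seed (global RNG state restored).
#' @return Noisy intensity matrix, same shape.
#' @export
addShotNoise <- function(image, photonScale, seed = NULL) {
  if (!is.finite(photonScale) || photonScale <= 0)
    stop("invalid config: photonScale must be positive")
  if (any(image < 0)) stop("intensities must be non-negative")
  withSeed(seed, {
    noisy <- stats::rpois(length(image), image * photonScale) / photonScale
    matrix(pmin(pmax(noisy, 0), 1), nrow(image), ncol(image))
  })
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(peak^2 / MSE)`; identical images yield `Inf`.
#'
#' @param clean,noisy Images of identical shape.
#' @param peak Peak value of the image range (1 for unit-range images).
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(clean, noisy, peak = 1) {
  if (!identical(dim(clean), dim(noisy)))
    stop("psnr requires images of identical shape")
  mse <- mean((clean - noisy)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Calibrate the photon budget against a target mean PSNR
#'
#' Renders a reference batch of randomly posed binary-fringe scenes and
#' root-finds the photon scale `S` whose simulated per-image PSNR (averaged
#' in dB over the batch, including the `[0, 1]` clipping of the noisy
#' images) matches `targetPSNR`.
#'
#' @param targetPSNR Target mean PSNR in dB.
#' @param nScenes Reference batch size.
#' @param imageSize Render resolution.
#' @param frequency,kind Single-shot pattern used for the reference batch.
#' @param seed RNG seed for the reference poses and noise draws.
#' @return The calibrated photon scale (photons per unit intensity).
#' @export
calibratePhotonScale <- function(targetPSNR = 27.56, nScenes = 10L,
                                 imageSize = 256L, frequency = 20,
                                 kind = "binary", seed = 1L) {
  spec <- patternSpec(kind, frequency = frequency)
  pattern <- renderPattern(spec)
  clean <- withSeed(seed, lapply(seq_len(nScenes), function(i) {
    pose <- sampleRandomPose()
    surf <- sampleSurface(perturbation = randomPerturbation())
    scene <- defaultScene(imageSize = imageSize, surface = surf,
                          pose = pose)
    renderFrame(scene, pattern)$image
  }))
  meanPSNR <- function(logS) {
    S <- 10^logS
    mean(vapply(seq_along(clean), function(i)
      psnr(clean[[i]], addShotNoise(clean[[i]], S, seed = seed + i)),
      numeric(1)))
  }
  10^stats::uniroot(function(l) meanPSNR(l) - targetPSNR,
                    c(0, 4), tol = 1e-4)$root
}

#' The package's calibrated default photon scale
#'
#' Photon budget calibrated once (see [calibratePhotonScale()]) so the mean
#' PSNR of noisy versus clean rendered images over a reference batch matches
#' 27.56 dB.
#'
#' @return Photon scale (photons per unit intensity).
#' @export
defaultPhotonScale <- function() 39.7

maskFromDepth <- function(depth, backgroundDepth, margin = 5) {
  (depth < backgroundDepth - margin) * 1
}

#' Downsample a binary mask by majority vote
#'
#' Block-majority downsampling for integer reduction factors (a target
#' pixel is sample when at least half of its source block is); keeps mask
#' boundaries aligned with the image content, unlike interpolating the
#' thresholded depth.
#'
#' @param mask 0/1 matrix.
#' @param targetSize Output side length (must divide the input evenly).
#' @return 0/1 matrix of size `targetSize`.
#' @export
downsampleMask <- function(mask, targetSize) {
  H <- nrow(mask)
  f <- H / targetSize
  if (f != round(f))
    stop("mask downsampling requires an integer reduction factor")
  if (f == 1) return(mask)
  block <- matrix(colMeans(matrix(mask, nrow = f)), nrow = targetSize)
  # block is (targetSize x (W)) after row pooling; pool columns likewise
  block <- t(matrix(colMeans(matrix(t(block), nrow = f)),
                    nrow = ncol(mask) / f))
  (block >= 0.5) * 1
}

#' Synthesize a co-registered frame group for one pose
#'
#' In `"sweep"` mode the group holds 22 static fringe images: frequencies 4
#' to 24 in steps of 2, for both binary and sinusoidal patterns. In
#' `"classic_gt"` mode it holds the 18 images of the classical ground-truth
#' protocol: 16 phase-shifted sinusoidal images I1..I16 (frequencies 1, 4,
#' 16, 64 crossed with shifts 0, pi/2, pi, 3*pi/2) plus the two single-shot
#' images IS (sinusoidal) and IB (binary) at `singleShotFrequency`.
#'
#' @param scene A [SceneSpec-class].
#' @param mode `"sweep"` or `"classic_gt"`.
#' @param photonScale Poisson photon budget, or `NULL` for noiseless images.
#' @param singleShotFrequency Frequency of IS and IB in classic mode.
#' @param maskMargin Ground-truth mask margin (mm): a pixel is sample iff its
#'   depth is at least this much in front of the background.
#' @param seed Optional RNG seed for the shot noise.
#' @return A [FrameGroup-class] with shared `depthGT` and `maskGT`.
#' @export
synthesizeGroup <- function(scene, mode = c("sweep", "classic_gt"),
                            photonScale = NULL, singleShotFrequency = 20,
                            maskMargin = 5, seed = NULL) {
  if (!is.character(mode) || !(mode[1] %in% c("sweep", "classic_gt")))
    stop("unknown group mode: ", mode[1])
  mode <- match.arg(mode)
  specs <- if (mode == "sweep") {
    unlist(lapply(c("binary", "sinusoidal"), function(k)
      lapply(seq(4, 24, by = 2), function(f)
        patternSpec(k, frequency = f))), recursive = FALSE)
  } else {
    c(unlist(lapply(c(1, 4, 16, 64), function(f)
        phaseShiftSequence(f, "sinusoidal")), recursive = FALSE),
      list(patternSpec("sinusoidal", frequency = singleShotFrequency),
           patternSpec("binary", frequency = singleShotFrequency)))
  }
  geom <- renderGeometry(scene)
  images <- withSeed(seed, lapply(specs, function(sp) {
    img <- shadeGeometry(scene, geom, renderPattern(sp))
    if (!is.null(photonScale)) img <- addShotNoise(img, photonScale)
    img
  }))
  mask <- maskFromDepth(geom$depth, scene@backgroundDepth, maskMargin)
  new("FrameGroup", images = images, specs = specs, depthGT = geom$depth,
      maskGT = mask, pose = scene@pose, mode = mode)
}

# --- image/depth/mask file I/O -------------------------------------------

#' Read and write simulator rasters
#'
#' Fringe images are stored as 16-bit grayscale TIFF; depth maps as 32-bit
#' float TIFF holding metres (mm / 1000, so values stay in the unit range the
#' TIFF readers preserve); masks as 8-bit PNG with sample pixels at 255.
#'
#' @param image Intensity matrix in `[0, 1]`.
#' @param depth Depth matrix in mm.
#' @param mask 0/1 matrix.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the matrix (depth
#'   in mm).
#' @name rasterIO
NULL

#' @rdname rasterIO
#' @export
writeImageTIFF <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname rasterIO
#' @export
readImageTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname rasterIO
#' @export
writeDepthTIFF <- function(depth, path) {
  tiff::writeTIFF(depth / 1000, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname rasterIO
#' @export
readDepthTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * 1000
}

#' @rdname rasterIO
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask, path)
  invisible(path)
}

#' @rdname rasterIO
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}

#' Synthesize a dataset on disk
#'
#' Draws `nGroups` random scenes (pose and surface perturbation), renders the
#' requested images for each, adds shot noise, and writes images, depth maps,
#' masks and a tab-separated manifest under `outDir`. The split assigns the
#' first `split[1]` groups to train, the next `split[2]` to validation and
#' the rest to test.
#'
#' @param nGroups Number of scene poses.
#' @param split Integer triple `(train, validation, test)`; must sum to
#'   `nGroups`.
#' @param outDir Output directory (created if needed).
#' @param seed Master RNG seed; the whole dataset is a deterministic
#'   function of it.
#' @param imageSize Render resolution.
#' @param mode `"single"` writes one image per pattern in `patterns`;
#'   `"classic_gt"` and `"sweep"` write full [synthesizeGroup()] groups.
#' @param patterns For `"single"` mode: list of [PatternSpec-class] rendered
#'   per group (default: the binary and sinusoidal single-shot patterns at
#'   20 cycles).
#' @param photonScale Photon budget (`NULL` for noiseless).
#' @param maskMargin Ground-truth mask margin (mm).
#' @param verbose Log file writes.
#' @return The manifest `data.frame`, invisibly.
#' @export
synthesizeDataset <- function(nGroups, split, outDir, seed = 1L,
                              imageSize = 256L,
                              mode = c("single", "classic_gt", "sweep"),
                              patterns = list(
                                patternSpec("binary", frequency = 20),
                                patternSpec("sinusoidal", frequency = 20)),
                              photonScale = defaultPhotonScale(),
                              maskMargin = 5, verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(split) != 3 || sum(split) != nGroups)
    stop("split fractions must sum to the number of groups")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  splitNames <- rep(c("train", "val", "test"), times = split)
  rendered <- if (mode == "single") lapply(patterns, renderPattern)
  rows <- list()
  withSeed(seed, {
    for (g in seq_len(nGroups)) {
      pose <- sampleRandomPose()
      surf <- sampleSurface(perturbation = randomPerturbation())
      scene <- defaultScene(imageSize = imageSize, surface = surf,
                            pose = pose)
      if (mode == "single") {
        geom <- renderGeometry(scene)
        depth <- geom$depth
        mask <- maskFromDepth(depth, scene@backgroundDepth, maskMargin)
        images <- lapply(rendered, function(p) {
          img <- shadeGeometry(scene, geom, p)
          if (!is.null(photonScale)) img <- addShotNoise(img, photonScale)
          img
        })
        specs <- patterns
      } else {
        grp <- synthesizeGroup(scene, mode, photonScale = photonScale,
                               maskMargin = maskMargin)
        depth <- grp@depthGT
        mask <- grp@maskGT
        images <- grp@images
        specs <- grp@specs
      }
      depthPath <- file.path(outDir, sprintf("group%04d_depth.tif", g))
      maskPath <- file.path(outDir, sprintf("group%04d_mask.png", g))
      writeDepthTIFF(depth, depthPath)
      writeMaskPNG(mask, maskPath)
      for (k in seq_along(images)) {
        sp <- specs[[k]]
        imgPath <- file.path(outDir,
          sprintf("group%04d_img%02d_%s_f%02d.tif", g, k, sp@kind,
                  round(sp@frequency)))
        writeImageTIFF(images[[k]], imgPath)
        if (verbose)
          message(sprintf("[synthesizeDataset] wrote %s", imgPath))
        rows[[length(rows) + 1]] <- data.frame(
          path = basename(imgPath), group = g, index = k, kind = sp@kind,
          frequency = sp@frequency, phase_shift = sp@phaseShift,
          mode = mode, split = splitNames[g],
          depth_path = basename(depthPath),
          mask_path = basename(maskPath))
      }
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read one frame group back from a dataset directory
#'
#' @param outDir Dataset directory.
#' @param groupId Group number.
#' @param manifest Optional preloaded manifest.
#' @return A [FrameGroup-class] (for classic/sweep datasets) or a list of
#'   images, depth and mask (for single-shot datasets).
#' @export
readFrameGroup <- function(outDir, groupId, manifest = NULL) {
  if (is.null(manifest)) manifest <- readManifest(outDir)
  rows <- manifest[manifest$group == groupId, ]
  if (nrow(rows) == 0) stop("no such group in manifest: ", groupId)
  rows <- rows[order(rows$index), ]
  images <- lapply(file.path(outDir, rows$path), readImageTIFF)
  specs <- lapply(seq_len(nrow(rows)), function(i)
    patternSpec(rows$kind[i], frequency = rows$frequency[i],
                phaseShift = rows$phase_shift[i]))
  depth <- readDepthTIFF(file.path(outDir, rows$depth_path[1]))
  mask <- readMaskPNG(file.path(outDir, rows$mask_path[1]))
  mode <- rows$mode[1]
  if (mode %in% c("classic_gt", "sweep"))
    new("FrameGroup", images = images, specs = specs, depthGT = depth,
        maskGT = mask, pose = samplePose(), mode = mode)
  else
    list(images = images, specs = specs, depth = depth, mask = mask)
}

#' Read a dataset manifest
#' @param outDir Dataset directory holding `manifest.tsv`.
#' @return The manifest `data.frame`.
#' @export
readManifest <- function(outDir) {
  utils::read.table(file.path(outDir, "manifest.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
}
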