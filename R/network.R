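# The two-path single-shot predictor: a modified five-level U-Net with
# multi-level decoder heads, implemented on the package's own conv/pool/
# upsample kernels (forward and reverse-mode passes).

#' U-Net configuration
#'
#' The modified five-level U-Net: per level two 3x3 zero-padded convolutions
#' with ReLU, 2x2 max pooling between encoder levels, 2x2 bicubic upsampling
#' with encoder-decoder skip concatenation on the way up, and a 1x1
#' convolution head at every decoder level whose logits are bicubically
#' upsampled to full resolution and summed before the final activation
#' (softmax for 2 output channels, sigmoid for 1).
#'
#' @param baseWidth Channels at the first level; levels use
#'   `baseWidth * 2^(level-1)`. The default 32 is the paper-scale profile;
#'   8 gives the tiny desk-scale profile.
#' @param inChannels Input channels (1 for grayscale fringe images).
#' @param headChannels Output channels: 2 (softmax, MaskNet) or 1 (sigmoid,
#'   DepthNet).
#' @param inputSize `(H, W)`; must be divisible by 16 (four poolings).
#' @param levels Number of levels (fixed at 5).
#' @return A config list.
#' @export
unetConfig <- function(baseWidth = 32L, inChannels = 1L, headChannels = 1L,
                       inputSize = c(256L, 256L), levels = 5L) {
  if (levels != 5L) stop("the architecture is a five-level U-Net")
  if (any(inputSize %% 2^(levels - 1) != 0))
    stop("config error: input size must be divisible by ",
         2^(levels - 1))
  if (!headChannels %in% c(1L, 2L))
    stop("headChannels must be 1 (sigmoid) or 2 (softmax)")
  list(levels = as.integer(levels), baseWidth = as.integer(baseWidth),
       inChannels = as.integer(inChannels),
       headChannels = as.integer(headChannels),
       inputSize = as.integer(inputSize),
       widths = as.integer(baseWidth * 2^(0:(levels - 1))))
}

#' Layer-by-layer architecture summary
#'
#' @param config A [unetConfig()] list.
#' @return `data.frame` with one row per parameterised layer (name, kernel,
#'   input/output channels, parameter count).
#' @export
architectureTable <- function(config) {
  w <- config$widths
  rows <- list()
  addRow <- function(name, kernel, ci, co)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = name, kernel = kernel, in_channels = ci, out_channels = co,
      params = ifelse(kernel == "3x3", 9L * ci * co + co, ci * co + co))
  prev <- config$inChannels
  for (l in 1:5) {
    addRow(sprintf("enc%d_conv1", l), "3x3", prev, w[l])
    addRow(sprintf("enc%d_conv2", l), "3x3", w[l], w[l])
    prev <- w[l]
  }
  for (l in 4:1) {
    addRow(sprintf("dec%d_conv1", l), "3x3", w[l + 1] + w[l], w[l])
    addRow(sprintf("dec%d_conv2", l), "3x3", w[l], w[l])
    addRow(sprintf("head%d", l), "1x1", w[l], config$headChannels)
  }
  do.call(rbind, rows)
}

#' Total trainable parameter count
#' @param config A [unetConfig()] list.
#' @return Integer parameter count.
#' @export
parameterCount <- function(config) sum(architectureTable(config)$params)

#' Write the architecture summary as delimited text
#' @param config A [unetConfig()] list.
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
writeArchitectureTable <- function(config, path) {
  utils::write.table(architectureTable(config), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-path network container
#'
#' Holds the configuration and the parameter tensors of one U-Net path
#' (MaskNet or DepthNet).
#'
#' @slot config A [unetConfig()] list.
#' @slot params Named list of `(w, b)` parameter pairs.
#' @exportClass FringeNet
setClass("FringeNet", representation(config = "list", params = "list"))

setMethod("show", "FringeNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "FringeNet: five-level U-Net, base width %d, %d -> %d channels, %dx%d, %d parameters\n",
    cfg$baseWidth, cfg$inChannels, cfg$headChannels, cfg$inputSize[1],
    cfg$inputSize[2], parameterCount(cfg)))
})

#' Build (initialise) a network
#'
#' He-normal initialisation for the ReLU convolutions (sd `sqrt(2 /
#' fan_in)`), Xavier for the linear 1x1 heads, zero biases; fully
#' reproducible given `seed`.
#'
#' @param config A [unetConfig()] list.
#' @param seed Integer seed for the weight draw.
#' @return A [FringeNet-class].
#' @export
buildNetwork <- function(config, seed = 1L) {
  tab <- architectureTable(config)
  params <- withSeed(seed, {
    p <- list()
    for (i in seq_len(nrow(tab))) {
      ci <- tab$in_channels[i]; co <- tab$out_channels[i]
      if (tab$kernel[i] == "3x3") {
        sd <- sqrt(2 / (9 * ci))
        p[[tab$layer[i]]] <- list(
          w = array(stats::rnorm(9 * ci * co, sd = sd), c(3, 3, ci, co)),
          b = numeric(co))
      } else {
        sd <- sqrt(1 / ci)
        p[[tab$layer[i]]] <- list(
          w = matrix(stats::rnorm(ci * co, sd = sd), ci, co),
          b = numeric(co))
      }
    }
    p
  })
  new("FringeNet", config = config, params = params)
}

as4d <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x
}

upsampleTimes <- function(x, times) {
  for (i in seq_len(times)) x <- cpp_upsample2_fwd(x)
  x
}

downGradTimes <- function(g, times) {
  for (i in seq_len(times)) g <- cpp_upsample2_bwd(g)
  g
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

softmaxChannels <- function(y) {
  # 2-channel softmax along dim 3
  m <- pmax(y[, , 1, , drop = FALSE], y[, , 2, , drop = FALSE])
  e1 <- exp(y[, , 1, , drop = FALSE] - m)
  e2 <- exp(y[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  out <- y
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

#' Network forward pass
#'
#' @param net A [FringeNet-class].
#' @param x Input: `H x W` matrix, `H x W x C` or `H x W x C x B` array.
#' @param headMask Logical length 4 enabling the decoder-level heads
#'   (levels 4..1 order is irrelevant; index `l` switches head `l`). The
#'   default enables all four; the ablation hook disables all but head 1.
#' @param keepCache Keep intermediate activations for [backwardNetwork()].
#' @return List with `out` (activated output, `H x W x n x B`), `logits`
#'   (pre-activation head sum), and `cache` when requested.
#' @export
forwardNetwork <- function(net, x, headMask = rep(TRUE, 4),
                           keepCache = FALSE) {
  cfg <- net@config
  p <- net@params
  x <- as4d(x)
  d <- dim(x)
  if (d[1] != cfg$inputSize[1] || d[2] != cfg$inputSize[2] ||
      d[3] != cfg$inChannels)
    stop("input size mismatch versus the network configuration")
  cache <- list(x = x, headMask = headMask)
  conv <- function(xin, name) {
    if (!keepCache)
      return(pmax(cpp_conv3x3_fwd(xin, p[[name]]$w, p[[name]]$b), 0))
    # keep the im2col workspace so the reverse pass need not rebuild it
    fw <- cpp_conv3x3_fwd_ws(xin, p[[name]]$w, p[[name]]$b)
    cache[[paste0("ws_", name)]] <<- fw$ws
    pmax(fw$y, 0)
  }
  enc <- vector("list", 5)
  inp <- x
  for (l in 1:5) {
    a1 <- conv(inp, sprintf("enc%d_conv1", l))
    a2 <- conv(a1, sprintf("enc%d_conv2", l))
    enc[[l]] <- a2
    if (keepCache) cache[[paste0("enc", l)]] <- list(a1 = a1, a2 = a2)
    if (l < 5) {
      pooled <- cpp_maxpool2_fwd(a2)
      if (keepCache) cache[[paste0("pool", l)]] <- pooled$idx
      inp <- pooled$y
    }
  }
  dec <- enc[[5]]
  logits <- NULL
  for (l in 4:1) {
    up <- cpp_upsample2_fwd(dec)
    catx <- catChannels(up, enc[[l]])
    a1 <- conv(catx, sprintf("dec%d_conv1", l))
    a2 <- conv(a1, sprintf("dec%d_conv2", l))
    if (keepCache) cache[[paste0("dec", l)]] <- list(a1 = a1, a2 = a2)
    dec <- a2
    if (headMask[l]) {
      hn <- sprintf("head%d", l)
      hl <- cpp_conv1x1_fwd(dec, p[[hn]]$w, p[[hn]]$b)
      full <- upsampleTimes(hl, l - 1)
      logits <- if (is.null(logits)) full else logits + full
    }
  }
  out <- if (cfg$headChannels == 2L) softmaxChannels(logits) else
    1 / (1 + exp(-logits))
  list(out = out, logits = logits, cache = if (keepCache) cache else NULL)
}

#' Network backward pass
#'
#' Reverse-mode differentiation through the whole U-Net given the gradient
#' of the loss with respect to the summed head logits.
#'
#' @param net A [FringeNet-class].
#' @param cache Cache from [forwardNetwork()] with `keepCache = TRUE`.
#' @param gLogits Gradient array matching the logits (`H x W x n x B`).
#' @return Named list of parameter gradients (same shapes as the
#'   parameters).
#' @export
backwardNetwork <- function(net, cache, gLogits) {
  p <- net@params
  headMask <- cache$headMask
  grads <- list()
  convBwd <- function(name, g, wantGx = TRUE)
    cpp_conv3x3_bwd_ws(cache[[paste0("ws_", name)]], p[[name]]$w, g,
                       wantGx)
  gdec <- vector("list", 4)  # pending gradient w.r.t. dec_l output
  for (l in 1:4) {
    if (!headMask[l]) next
    gh <- downGradTimes(gLogits, l - 1)
    hn <- sprintf("head%d", l)
    hb <- cpp_conv1x1_bwd(cache[[paste0("dec", l)]]$a2, p[[hn]]$w, gh)
    grads[[hn]] <- list(w = hb$gw, b = hb$gb)
    gdec[[l]] <- hb$gx
  }
  gencSkip <- vector("list", 5)  # gradient into enc_l via skip connection
  gUpChain <- NULL               # gradient into upsample2(dec_{l+1})
  for (l in 1:4) {
    cc <- cache[[paste0("dec", l)]]
    g <- gdec[[l]]
    if (!is.null(gUpChain)) g <- if (is.null(g)) gUpChain else g + gUpChain
    if (is.null(g)) g <- array(0, dim(cc$a2))
    n1 <- sprintf("dec%d_conv1", l); n2 <- sprintf("dec%d_conv2", l)
    g <- g * (cc$a2 > 0)
    b2 <- convBwd(n2, g)
    grads[[n2]] <- list(w = b2$gw, b = b2$gb)
    g <- b2$gx * (cc$a1 > 0)
    b1 <- convBwd(n1, g)
    grads[[n1]] <- list(w = b1$gw, b = b1$gb)
    nup <- net@config$widths[l + 1]
    gUp <- b1$gx[, , seq_len(nup), , drop = FALSE]
    gencSkip[[l]] <- b1$gx[, , nup + seq_len(dim(b1$gx)[3] - nup), ,
                           drop = FALSE]
    gUpChain <- cpp_upsample2_bwd(gUp)
  }
  gPooled <- NULL  # gradient flowing into enc_l's pooled output
  for (l in 5:1) {
    cc <- cache[[paste0("enc", l)]]
    g <- if (l == 5) gUpChain else gencSkip[[l]]
    if (!is.null(gPooled)) {
      dpool <- cpp_maxpool2_bwd(cache[[paste0("pool", l)]], gPooled,
                                dim(cc$a2)[1], dim(cc$a2)[2])
      g <- g + dpool
    }
    n1 <- sprintf("enc%d_conv1", l); n2 <- sprintf("enc%d_conv2", l)
    g <- g * (cc$a2 > 0)
    b2 <- convBwd(n2, g)
    grads[[n2]] <- list(w = b2$gw, b = b2$gb)
    g <- b2$gx * (cc$a1 > 0)
    b1 <- convBwd(n1, g, wantGx = l > 1)  # no input gradient at the stem
    grads[[n1]] <- list(w = b1$gw, b = b1$gb)
    gPooled <- if (l > 1) b1$gx else NULL
  }
  grads
}

#' Map unit-interval depth output to millimetres
#'
#' `D = slope * d + intercept`; the defaults (150, 30) place the sigmoid's
#' `(0, 1)` range onto 30-180 mm, covering the 70-140 mm working distances
#' with margin.
#'
#' @param d Unit-interval depth values (matrix/array).
#' @param slope,intercept Rescale constants (mm).
#' @return Depth in mm, same shape.
#' @export
rescaleDepth <- function(d, slope = 150, intercept = 30) {
  if (any(d < 0 | d > 1))
    stop("contract violation: unit-depth values must lie in [0, 1]")
  slope * d + intercept
}

#' Binarise MaskNet probabilities
#'
#' Per-pixel argmax over the 2-channel simplex; exact ties go to background.
#'
#' @param probs `H x W x 2` (or `H x W x 2 x 1`) array; channel 1 is
#'   background, channel 2 sample.
#' @return A [BinaryMask-class].
#' @export
maskFromProbs <- function(probs) {
  probs <- as4d(probs)
  m <- (probs[, , 2, 1, drop = FALSE] > probs[, , 1, 1, drop = FALSE]) * 1
  binaryMask(matrix(m, dim(probs)[1], dim(probs)[2]))
}

#' Single-shot depth prediction
#'
#' Runs a preprocessed fringe image through MaskNet and DepthNet and fuses
#' the outputs by pixel-wise multiplication: background pixels get depth 0
#' and are flagged invalid.
#'
#' @param image Preprocessed single-shot image (matrix in `[0, 1]`).
#' @param masknet,depthnet [FringeNet-class] paths (masknet may be `NULL`
#'   for the DepthNet-only ablation, which uses an all-ones mask).
#' @param slope,intercept Depth rescale constants (mm).
#' @return List with `maskProbs`, `depthUnit`, `mask` (a
#'   [BinaryMask-class]) and `depth` (a [DepthMap-class]; the final masked
#'   map).
#' @export
predictDepth <- function(image, masknet, depthnet, slope = 150,
                         intercept = 30) {
  fd <- forwardNetwork(depthnet, image)
  dUnit <- fd$out[, , 1, 1]
  if (!is.null(masknet)) {
    fm <- forwardNetwork(masknet, image)
    maskProbs <- fm$out[, , , 1]
    mask <- maskFromProbs(fm$out)
  } else {
    maskProbs <- NULL
    mask <- binaryMask(matrix(1, nrow(dUnit), ncol(dUnit)))
  }
  dmm <- rescaleDepth(dUnit, slope, intercept) * mask@mask
  list(maskProbs = maskProbs, depthUnit = dUnit, mask = mask,
       depth = depthMap(dmm, mask@mask == 1))
}

#' Save / load network checkpoints
#'
#' Checkpoints are RDS files holding the configuration and parameters.
#'
#' @param net A [FringeNet-class] (or a list of them).
#' @param path File path.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint` the
#'   restored object.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)
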