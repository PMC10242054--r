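## Surrogate-gradient training: the two backpropagation regimes.
##
## ITBP (independent-temporal): the clean label is bit-plane encoded and the
## loss is the 2^s-weighted per-plane squared error between label planes and
## output planes; gradients flow through the spatial path of each time step
## only -- the membrane state carried between steps is treated as a constant.
##
## STBP (spatio-temporal): the output stack is decoded to a real-valued image
## by the differentiable weighted sum, the loss is the plain MSE against the
## clean image, and gradients flow through both space and time (through the
## carried membrane potentials, including the soft-reset path).

#' Weighted bit-plane loss (independent-temporal training)
#'
#' \code{L = (1/N) * sum_s 2^s * || o_s - ohat_s ||_F^2} where \code{s} is the
#' significance exponent of a plane (most significant plane first in storage,
#' so stored plane \code{t} has \code{s = T - t}). A single flipped bit on the
#' plane of significance \code{s} costs exactly \code{2^s / N}.
#'
#' @param targetPlanes bit-plane \code{SpikePlaneStack} of the encoded label.
#' @param outputPlanes \code{SpikePlaneStack} produced by the network.
#' @param n number of training examples the batch represents.
#' @return a \code{LossReport}; \code{perPlane} holds the unnormalised
#'   contribution of each stored plane and sums to \code{total * n}.
#' @export
itbpLoss <- function(targetPlanes, outputPlanes, n = 1L) {
  stopifnot(is(targetPlanes, "SpikePlaneStack"), is(outputPlanes, "SpikePlaneStack"))
  a <- planes(targetPlanes); b <- planes(outputPlanes)
  if (!identical(dim(a), dim(b))) stop("plane stacks have mismatched shapes")
  T <- dim(a)[1L]
  w <- 2^((T - 1):0)
  perPlane <- vapply(seq_len(T), function(t) w[t] * sum((a[t, , ] - b[t, , ])^2),
                     numeric(1))
  new("LossReport", total = sum(perPlane) / n, perPlane = perPlane,
      n = as.integer(n))
}

#' Decoded-image MSE loss (spatio-temporal training)
#'
#' \code{L = (1/N) * || y - yhat ||_F^2} between the clean label and the
#' (real-valued) decoded network output.
#'
#' @param label a \code{GrayImage} (the clean target).
#' @param decoded numeric matrix of the decoded output, same shape.
#' @param n number of training examples the batch represents.
#' @return a \code{LossReport} with an empty per-plane breakdown.
#' @export
stbpLoss <- function(label, decoded, n = 1L) {
  stopifnot(is(label, "GrayImage"))
  y <- pixels(label)
  decoded <- as.matrix(decoded)
  if (!identical(dim(y), dim(decoded))) stop("label/decoded shape mismatch")
  new("LossReport", total = sum((y - decoded)^2) / n, perPlane = numeric(0),
      n = as.integer(n))
}

## Reverse-tape backpropagation. caches come from .forwardBatch(keepCache=TRUE),
## dOut is a list (length T) of gradients w.r.t. the output spikes of each
## step. detachTime = TRUE implements the independent-temporal regime: the
## carried membrane state contributes no gradient path between steps.
.backwardBatch <- function(model, caches, dOut, nimg, detachTime) {
  spec <- model@spec
  W8 <- model@env$weights
  grads <- lapply(W8, function(w) array(0, dim = dim(w)))
  carry <- list()  # per neuron layer: dL/d(post-reset potential) from step t+1
  T <- length(caches)
  revTape <- rev(model@tape)
  for (t in rev(seq_len(T))) {
    vals <- caches[[t]]$vals
    ucs <- caches[[t]]$ucs
    deltas <- list(out = dOut[[t]])
    addDelta <- function(node, d) {
      cur <- deltas[[node]]
      deltas[[node]] <<- if (is.null(cur)) d else cur + d
    }
    for (op in revTape) {
      if (op$op == "conv") {
        d <- deltas[[op$to]]
        if (is.null(d)) next
        bw <- .conv_bw(vals[[op$from]], W8[[op$w]], d, op$cin, nimg, op$k,
                       op$stride)
        grads[[op$w]] <- grads[[op$w]] + bw$dW
        addDelta(op$from, bw$dX)
      } else if (op$op == "sn") {
        key <- as.character(op$id)
        d <- deltas[[op$to]]
        cfg <- .neuronCfg(spec, op$cfg)
        uc <- ucs[[key]]
        sg <- surrogateGrad(uc - cfg@vThreshold, cfg@surrogateScale)
        duc <- if (is.null(d)) array(0, dim = dim(uc)) else d * sg
        if (!detachTime && !is.null(carry[[key]]))
          duc <- duc + carry[[key]] * (1 - cfg@vThreshold * sg)
        if (!detachTime)
          carry[[key]] <- if (cfg@kind == "IF") duc else duc * (1 - 1 / cfg@tau)
        dx <- if (cfg@kind == "IF") duc else duc / cfg@tau
        addDelta(op$from, dx)
      } else if (op$op == "up") {
        d <- deltas[[op$to]]
        if (is.null(d)) next
        addDelta(op$from, .upPool(d))
      } else if (op$op == "concat") {
        d <- deltas[[op$to]]
        if (is.null(d)) next
        ps <- .catSlices(op$c1, op$c2, nimg)
        addDelta(op$from1, d[, , ps$p1, drop = FALSE])
        addDelta(op$from2, d[, , ps$p2, drop = FALSE])
      }
    }
  }
  grads
}

## Stack a list of GrayImages into the batched (T, H, W, N) binary input.
.encodeBatch <- function(images, codec, how = "uwe") {
  stks <- if (how == "uwe") lapply(images, uweEncode, config = codec)
          else lapply(images, function(im)
            suppressWarnings(ttfsEncode(im, T = codec@T, config = codec)))
  d <- dim(planes(stks[[1]]))
  arr <- array(0, dim = c(d, length(stks)))
  for (i in seq_along(stks)) arr[, , , i] <- planes(stks[[i]])
  arr
}

.adamInit <- function(weights) {
  list(step = 0L,
       m = lapply(weights, function(w) array(0, dim = dim(w))),
       v = lapply(weights, function(w) array(0, dim = dim(w))))
}

.adamUpdate <- function(model, grads, config) {
  env <- model@env
  if (is.null(env$adam)) env$adam <- .adamInit(env$weights)
  st <- env$adam
  st$step <- st$step + 1L
  b1 <- config@beta1; b2 <- config@beta2; eps <- config@epsilon
  lr <- config@learningRate
  for (nm in names(env$weights)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^st$step)
    vhat <- st$v[[nm]] / (1 - b2^st$step)
    env$weights[[nm]] <- env$weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  env$adam <- st
  invisible(model)
}

## Forward + loss + gradient for one batch; shared by trainStep and the
## gradient tests. Returns the loss report, gradients, and the raw outputs.
.batchGradients <- function(model, noisy, clean, config, codec) {
  nimg <- length(noisy)
  T <- model@spec@T
  input <- .encodeBatch(noisy, codec, config@inputCodec)
  fw <- .forwardBatch(model, input, nimg = nimg, keepCache = TRUE)
  out <- fw$out  # (T, H, W, N), binary
  w <- 2^((T - 1):0)
  d <- dim(out)
  if (config@mode == "ITBP") {
    target <- .encodeBatch(clean, codec)
    diffs <- out - target
    perPlane <- vapply(seq_len(T), function(t) w[t] * sum(diffs[t, , , ]^2),
                       numeric(1))
    total <- sum(perPlane) / nimg
    dOut <- lapply(seq_len(T), function(t) {
      array(2 * w[t] / nimg * diffs[t, , , ], dim = c(d[2], d[3], d[4]))
    })
    loss <- new("LossReport", total = total, perPlane = perPlane,
                n = as.integer(nimg))
    detach <- TRUE
  } else if (config@stbpDecoder == "uwd") {
    decoded <- array(0, dim = d[2:4])
    for (t in seq_len(T)) decoded <- decoded + w[t] * array(out[t, , , ], dim = d[2:4])
    y <- array(0, dim = d[2:4])
    for (i in seq_len(nimg)) y[, , i] <- pixels(clean[[i]])
    resid <- decoded - y
    total <- sum(resid^2) / nimg
    dOut <- lapply(seq_len(T), function(t) {
      array(2 * w[t] / nimg * resid, dim = c(d[2], d[3], d[4]))
    })
    loss <- new("LossReport", total = total, perPlane = numeric(0),
                n = as.integer(nimg))
    detach <- FALSE
  } else {
    # MPD in the loss path: tanh of the theta-weighted spike sum, compared
    # with the clean image on the unit scale; gradients flow through the
    # tanh and the geometric weights
    th <- codec@mpdTheta^(0:(T - 1))
    acc <- array(0, dim = d[2:4])
    for (t in seq_len(T)) acc <- acc + th[t] * array(out[t, , , ], dim = d[2:4])
    mdec <- tanh(acc)
    peak <- 2^codec@nBits - 1
    y <- array(0, dim = d[2:4])
    for (i in seq_len(nimg)) y[, , i] <- pixels(clean[[i]]) / peak
    resid <- mdec - y
    total <- sum(resid^2) / nimg
    dAcc <- 2 / nimg * resid * (1 - mdec^2)
    dOut <- lapply(seq_len(T), function(t) {
      array(th[t] * dAcc, dim = c(d[2], d[3], d[4]))
    })
    loss <- new("LossReport", total = total, perPlane = numeric(0),
                n = as.integer(nimg))
    detach <- FALSE
  }
  grads <- .backwardBatch(model, fw$caches, dOut, nimg, detachTime = detach)
  list(loss = loss, grads = grads, out = out)
}

#' One optimisation step
#'
#' Runs a minibatch through the network and updates the weights in place with
#' one Adam step. In \code{ITBP} mode both the noisy input and the clean
#' label are bit-plane encoded, the forward pass detaches the carried
#' membrane state between time steps, and the weighted per-plane loss
#' (\code{\link{itbpLoss}}) drives the surrogate gradients through the
#' spatial path only. In \code{STBP} mode gradients also flow through time
#' and the loss is the MSE between the clean image and the weighted-sum
#' decoded output (\code{\link{stbpLoss}}), with gradients carried through
#' the decoding weights.
#'
#' @param model a \code{SpikingModel} (modified in place).
#' @param noisyImage,cleanImage a \code{GrayImage} or list of them (a batch).
#' @param config a \code{TrainConfig}.
#' @param codec the \code{CodecConfig} used for encoding (default 8-bit).
#' @return a \code{LossReport} for the batch.
#' @export
trainStep <- function(model, noisyImage, cleanImage, config = trainConfig(),
                      codec = codecConfig()) {
  stopifnot(is(model, "SpikingModel"), is(config, "TrainConfig"))
  if (is(noisyImage, "GrayImage")) noisyImage <- list(noisyImage)
  if (is(cleanImage, "GrayImage")) cleanImage <- list(cleanImage)
  if (length(noisyImage) != length(cleanImage))
    stop("noisy and clean batches must have equal length")
  if (.usesLiteralGate(model))
    stop("training does not support literalGate neuron dynamics")
  r <- .batchGradients(model, noisyImage, cleanImage, config, codec)
  .adamUpdate(model, r$grads, config)
  r$loss
}

.usesLiteralGate <- function(model) {
  model@spec@bodyNeuron@literalGate || model@spec@headNeuron@literalGate
}

#' Train a model on a paired dataset
#'
#' Standard epoch loop: seeded shuffling, minibatches of
#' \code{config@batchSize}, one Adam step per batch. No learning-rate
#' schedule is applied.
#'
#' @param model a \code{SpikingModel} (modified in place).
#' @param bundle a \code{DatasetBundle} of clean/noisy pairs.
#' @param config a \code{TrainConfig}.
#' @param codec a \code{CodecConfig}.
#' @param verbose print a line per epoch.
#' @return data.frame with one row per epoch: \code{epoch}, \code{meanLoss}.
#' @export
trainModel <- function(model, bundle, config = trainConfig(),
                       codec = codecConfig(), verbose = FALSE) {
  stopifnot(is(bundle, "DatasetBundle"))
  n <- length(bundle)
  if (n == 0L) stop("empty dataset")
  set.seed(config@seed)
  log <- data.frame(epoch = integer(0), meanLoss = numeric(0))
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(n)
    losses <- c()
    starts <- seq(1, n, by = config@batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + config@batchSize - 1L, n)]
      report <- trainStep(model, bundle@noisy[idx], bundle@clean[idx], config,
                          codec)
      losses <- c(losses, report@total)
    }
    log <- rbind(log, data.frame(epoch = ep, meanLoss = mean(losses)))
    if (verbose)
      message(sprintf("epoch %d: mean batch loss %.4f", ep, mean(losses)))
  }
  log
}

#' Denoise a single image
#'
#' The full inference pipeline: bit-plane encode, spiking forward pass,
#' weighted-sum decode.
#'
#' @param model a trained \code{SpikingModel}.
#' @param image a noisy \code{GrayImage}.
#' @param codec a \code{CodecConfig}.
#' @return the reconstructed \code{GrayImage}.
#' @export
denoiseImage <- function(model, image, codec = codecConfig()) {
  uwdDecode(modelForward(model, uweEncode(image, codec)), codec)
}

#' Evaluate a model on a paired dataset
#'
#' For every pair, encodes the noisy image, runs the network, decodes, and
#' reports MSE/PSNR of both the noisy input and the reconstruction against
#' the clean image. Evaluation never mutates the weights.
#'
#' @param model a \code{SpikingModel}.
#' @param bundle a \code{DatasetBundle}.
#' @param codec a \code{CodecConfig}.
#' @return data.frame with one row per image: \code{mseNoisy},
#'   \code{psnrNoisy}, \code{mseDenoised}, \code{psnrDenoised}.
#' @export
evaluateModel <- function(model, bundle, codec = codecConfig()) {
  stopifnot(is(bundle, "DatasetBundle"))
  n <- length(bundle)
  if (n == 0L) stop("empty dataset")
  rows <- lapply(seq_len(n), function(i) {
    clean <- bundle@clean[[i]]; noisy <- bundle@noisy[[i]]
    rec <- denoiseImage(model, noisy, codec)
    mN <- psnr(noisy, clean); mD <- psnr(rec, clean)
    data.frame(mseNoisy = mN@mse, psnrNoisy = mN@psnr,
               mseDenoised = mD@mse, psnrDenoised = mD@psnr)
  })
  do.call(rbind, rows)
}
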