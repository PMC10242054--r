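#' Pixel matrix of a GrayImage
#' @param object a \code{GrayImage}.
#' @return numeric matrix of integer-valued intensities.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(object) object@pixels)

#' Bit depth of a GrayImage
#' @param object a \code{GrayImage}.
#' @export
setGeneric("nBits", function(object) standardGeneric("nBits"))

#' @rdname nBits
#' @export
setMethod("nBits", "GrayImage", function(object) object@nBits)

#' Spike planes of a SpikePlaneStack
#' @param object a \code{SpikePlaneStack}.
#' @return 3-D binary array (T x H x W).
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))

#' @rdname planes
#' @export
setMethod("planes", "SpikePlaneStack", function(object) object@planes)

#' Number of time steps / planes
#' @param object a \code{SpikePlaneStack}.
#' @export
setGeneric("nTimeSteps", function(object) standardGeneric("nTimeSteps"))

#' @rdname nTimeSteps
#' @export
setMethod("nTimeSteps", "SpikePlaneStack", function(object) dim(object@planes)[1L])

#' Plane coding convention
#' @param object a \code{SpikePlaneStack}.
#' @return \code{"bitplane"} or \code{"latency"}.
#' @export
setGeneric("codingType", function(object) standardGeneric("codingType"))

#' @rdname codingType
#' @export
setMethod("codingType", "SpikePlaneStack", function(object) object@coding)

#' Plane weights of a bit-plane stack
#'
#' Returns the strictly decreasing powers of two \code{2^(T-1), ..., 2^0}
#' attached to the planes of a bit-plane coded stack (most significant plane
#' first). Latency-coded stacks have no weights and raise an error.
#'
#' @param object a \code{SpikePlaneStack}.
#' @export
setGeneric("planeWeights", function(object) standardGeneric("planeWeights"))

#' @rdname planeWeights
#' @export
setMethod("planeWeights", "SpikePlaneStack", function(object) {
  if (object@coding != "bitplane")
    stop("plane weights are defined for bit-plane coded stacks only")
  T <- dim(object@planes)[1L]
  2^((T - 1):0)
})

#' Number of trainable parameters of a model
#' @param object a \code{SpikingModel}.
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d, %d-bit, range [%g, %g]\n",
              d[1], d[2], object@nBits, min(object@pixels), max(object@pixels)))
})

setMethod("show", "SpikePlaneStack", function(object) {
  d <- dim(object@planes)
  cat(sprintf("SpikePlaneStack: %d planes of %d x %d, coding = %s, density = %.3f\n",
              d[1], d[2], d[3], object@coding, mean(object@planes)))
})

setMethod("show", "SpikingModel", function(object) {
  s <- object@spec
  cat(sprintf(paste0("SpikingModel (fully spiking U-net): depth %d, base %d",
                     " channels, T = %d\n  %d convolution layers, %s",
                     " parameters, 0 biases\n"),
              s@depth, s@baseChannels, s@T, length(object@weights),
              format(parameterCount(object), big.mark = ",")))
})

setMethod("show", "EnergyReport", function(object) {
  cat("Event-driven energy comparison (units of 1e-7 J):\n")
  cat(sprintf("  spike rate          %10.4f\n", object@spikeRate))
  cat(sprintf("  #OP (conventional)  %10.4g\n", object@opAnn))
  cat(sprintf("  #OP (spiking slots) %10.4g\n", object@opSnn))
  cat(sprintf("  energy conventional %10.2f\n", object@energyAnn))
  cat(sprintf("  energy spiking      %10.2f\n", object@energySnn))
  cat(sprintf("  ratio               %10.2f\n", object@ratio))
})

setMethod("show", "LossReport", function(object) {
  cat(sprintf("LossReport: total = %g over %d example(s)\n",
              object@total, object@n))
  if (length(object@perPlane))
    cat("  per-plane:", paste(signif(object@perPlane, 6), collapse = " "), "\n")
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: mse = %g, psnr = %s dB\n", object@mse,
              if (is.finite(object@psnr)) sprintf("%.4f", object@psnr) else "Inf"))
})

setMethod("show", "DatasetBundle", function(object) {
  d <- if (length(object@clean)) dim(pixels(object@clean[[1]])) else c(0, 0)
  cat(sprintf("DatasetBundle: %d clean/noisy pairs of %d x %d, eta = %g\n",
              length(object@clean), d[1], d[2], object@eta))
})

#' Number of images in a DatasetBundle
#' @param x a \code{DatasetBundle}.
#' @export
setMethod("length", "DatasetBundle", function(x) length(x@clean))

#' Clean images of a bundle
#' @param object a \code{DatasetBundle}.
#' @export
setGeneric("cleanImages", function(object) standardGeneric("cleanImages"))

#' @rdname cleanImages
#' @export
setMethod("cleanImages", "DatasetBundle", function(object) object@clean)

#' Noisy images of a bundle
#' @param object a \code{DatasetBundle}.
#' @export
setGeneric("noisyImages", function(object) standardGeneric("noisyImages"))

#' @rdname noisyImages
#' @export
setMethod("noisyImages", "DatasetBundle", function(object) object@noisy)
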