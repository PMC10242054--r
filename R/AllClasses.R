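#' @import methods
NULL

#' GrayImage: an n-bit grayscale image
#'
#' A thin S4 container for a single-channel image stored as an integer-valued
#' matrix on \code{[0, 2^nBits - 1]}. All codec, noise and metric functions in
#' the package consume and produce \code{GrayImage} objects, which guarantees
#' that pixel values stay integral and in range (the bit-plane codec is only
#' lossless under that contract).
#'
#' @slot pixels numeric matrix (H x W) of integer-valued intensities.
#' @slot nBits single integer bit depth; 8 for ordinary grayscale images.
#'
#' @examples
#' img <- GrayImage(matrix(0:15, 4, 4), nBits = 8L)
#' pixels(img)[1, 1]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", nBits = "integer"),
  validity = function(object) {
    msg <- character()
    p <- object@pixels
    if (length(object@nBits) != 1L || is.na(object@nBits) || object@nBits < 1L)
      msg <- c(msg, "nBits must be a single positive integer")
    if (nrow(p) < 1L || ncol(p) < 1L)
      msg <- c(msg, "image must have at least one row and one column")
    if (anyNA(p)) msg <- c(msg, "pixels contain NA")
    else {
      if (any(p != round(p)))
        msg <- c(msg, "pixels must be integer-valued")
      if (length(object@nBits) == 1L && !is.na(object@nBits)) {
        hi <- 2^object@nBits - 1
        if (any(p < 0) || any(p > hi))
          msg <- c(msg, sprintf("pixels must lie in [0, %d]", hi))
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' @param pixels numeric matrix of integer-valued intensities.
#' @param nBits integer bit depth (default 8).
#' @rdname GrayImage-class
#' @export
GrayImage <- function(pixels, nBits = 8L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, nBits = as.integer(nBits))
}

#' SpikePlaneStack: a stack of binary spike planes
#'
#' Holds a T x H x W binary array of spike planes. Two codings exist:
#' \describe{
#'   \item{bitplane}{planes are the binary expansion of an image, stored
#'     most-significant-plane first, so plane \code{t} carries the weight
#'     \code{2^(T - t)} (significance exponent \code{T - t}); produced by
#'     \code{\link{uweEncode}} and consumed by \code{\link{uwdDecode}}.}
#'   \item{latency}{planes index time of first spike (time-to-first-spike
#'     coding, \code{\link{ttfsEncode}}); plane weights are not defined.}
#' }
#'
#' @slot planes 3-D binary array, time/significance first.
#' @slot coding either \code{"bitplane"} or \code{"latency"}.
#' @export
setClass("SpikePlaneStack",
  representation(planes = "array", coding = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@planes)
    if (length(d) != 3L) msg <- c(msg, "planes must be a 3-D array (T x H x W)")
    if (!all(object@planes %in% c(0, 1)))
      msg <- c(msg, "planes must be strictly binary (0/1)")
    if (!object@coding %in% c("bitplane", "latency"))
      msg <- c(msg, "coding must be 'bitplane' or 'latency'")
    if (length(msg)) msg else TRUE
  }
)

#' @param planes 3-D binary array (T x H x W).
#' @param coding plane semantics, \code{"bitplane"} (default) or
#'   \code{"latency"}.
#' @rdname SpikePlaneStack-class
#' @export
SpikePlaneStack <- function(planes, coding = "bitplane") {
  storage.mode(planes) <- "double"
  new("SpikePlaneStack", planes = planes, coding = coding)
}

#' Codec configuration
#'
#' Bundles the parameters shared by the spike codecs: the bit depth
#' \code{nBits}, the number of time steps \code{T} (equal to \code{nBits} for
#' the lossless bit-plane codec), the geometric decay \code{mpdTheta} of the
#' membrane-potential decoder, and the rounding rule used by the
#' time-to-first-spike encoder.
#'
#' @slot nBits integer bit depth.
#' @slot T integer number of time steps.
#' @slot mpdTheta geometric weight base of the membrane-potential decoder,
#'   strictly inside (0, 1); default 0.8.
#' @slot ttfsRounding \code{"floor"} (default) or \code{"nearest"}.
#' @export
setClass("CodecConfig",
  representation(nBits = "integer", T = "integer", mpdTheta = "numeric",
                 ttfsRounding = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nBits < 1L) msg <- c(msg, "nBits must be >= 1")
    if (object@T < 1L) msg <- c(msg, "T must be >= 1")
    if (object@mpdTheta <= 0 || object@mpdTheta >= 1)
      msg <- c(msg, "mpdTheta must be in (0, 1)")
    if (!object@ttfsRounding %in% c("floor", "nearest"))
      msg <- c(msg, "ttfsRounding must be 'floor' or 'nearest'")
    if (length(msg)) msg else TRUE
  }
)

#' @param nBits integer bit depth (default 8).
#' @param T number of time steps; defaults to \code{nBits}.
#' @param mpdTheta geometric base of the MPD weights (default 0.8).
#' @param ttfsRounding rounding of the TTFS spike latency.
#' @rdname CodecConfig-class
#' @export
codecConfig <- function(nBits = 8L, T = nBits, mpdTheta = 0.8,
                        ttfsRounding = c("floor", "nearest")) {
  new("CodecConfig", nBits = as.integer(nBits), T = as.integer(T),
      mpdTheta = mpdTheta, ttfsRounding = match.arg(ttfsRounding))
}

#' Spiking neuron configuration
#'
#' Parameters of a discrete-time integrate-and-fire neuron layer. The update
#' per step is: charge (IF: \code{u <- u + x}; LIF: \code{u <- u + (x - u)/tau}),
#' fire where \code{u >= vThreshold} (Heaviside with \code{h(0) = 1}), then
#' soft-reset \code{u <- u - vThreshold * o}. The surrogate derivative used in
#' training is \code{1 / (1 + (surrogateScale * (u - vThreshold))^2)}.
#'
#' \code{literalGate = TRUE} switches the charge step to the multiplicative
#' gate \code{u <- u * g(o_prev) + x} with \code{g = tau} (IF) or
#' \code{g = tau * exp(-o/tau)} (LIF). With \code{tau} slightly above 1 this
#' gate amplifies the carried potential; it is provided for study of that
#' regime only and is rejected by the training routines.
#'
#' @slot kind \code{"IF"} or \code{"LIF"}.
#' @slot vThreshold firing threshold, membrane-potential units.
#' @slot tau leak time constant (> 1), used by LIF only.
#' @slot surrogateScale scale of the surrogate derivative (default \code{pi}).
#' @slot literalGate logical; use the multiplicative gate form (see above).
#' @export
setClass("NeuronConfig",
  representation(kind = "character", vThreshold = "numeric", tau = "numeric",
                 surrogateScale = "numeric", literalGate = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("IF", "LIF")) msg <- c(msg, "kind must be IF or LIF")
    if (object@vThreshold <= 0) msg <- c(msg, "vThreshold must be > 0")
    if (object@kind == "LIF" && object@tau <= 1)
      msg <- c(msg, "tau must be > 1 for LIF neurons")
    if (object@surrogateScale <= 0) msg <- c(msg, "surrogateScale must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' @param kind \code{"IF"} (default) or \code{"LIF"}.
#' @param vThreshold firing threshold (default 1).
#' @param tau LIF time constant (default 1.1).
#' @param surrogateScale surrogate sharpness (default \code{pi}).
#' @param literalGate logical, default \code{FALSE}.
#' @rdname NeuronConfig-class
#' @export
neuronConfig <- function(kind = c("IF", "LIF"), vThreshold = 1.0, tau = 1.1,
                         surrogateScale = pi, literalGate = FALSE) {
  new("NeuronConfig", kind = match.arg(kind), vThreshold = vThreshold,
      tau = tau, surrogateScale = surrogateScale, literalGate = literalGate)
}

#' Spiking neuron state
#'
#' Membrane potentials of one neuron layer, carried across time steps.
#'
#' @slot u numeric array of membrane potentials (any shape).
#' @slot t integer index of the last completed time step.
#' @export
setClass("NeuronState", representation(u = "array", t = "integer"),
  validity = function(object) {
    if (anyNA(object@u) || any(!is.finite(object@u)))
      "membrane potentials must be finite" else TRUE
  })

#' @param u initial membrane potentials (array or vector; vectors are kept as
#'   1-D arrays).
#' @rdname NeuronState-class
#' @export
neuronState <- function(u) {
  if (is.null(dim(u))) u <- array(u, dim = length(u))
  new("NeuronState", u = u, t = 0L)
}

#' Architecture of the fully spiking U-net denoiser
#'
#' Describes a shallow U-net in which every nonlinearity is a spiking neuron
#' and every convolution is bias-free. Channel widths double at each encoder
#' level: the stem maps the per-step input channels to \code{baseChannels},
#' level \code{l} works at \code{baseChannels * 2^l} channels. Downsampling is
#' a stride-2 convolution + neuron; upsampling is nearest-neighbour (which
#' preserves binarity) followed by convolution + neuron; skip connections
#' concatenate spike planes. The 1x1 head carries its own neuron with a low
#' threshold so that output spikes form readily.
#'
#' @slot inChannels channels fed per time step (1 for grayscale).
#' @slot depth number of encoder levels (>= 1).
#' @slot baseChannels width of the first level.
#' @slot T number of time steps the network is run for.
#' @slot bodyNeuron \code{NeuronConfig} for every layer except the head.
#' @slot headNeuron \code{NeuronConfig} of the final 1x1 convolution.
#' @slot inputSkip logical; concatenate the raw input plane onto the last
#'   decoder features so the 1x1 head sees it directly. With the head's skip
#'   columns initialised to the identity and its feature columns to zero,
#'   training starts from the identity reconstruction and learns corrections
#'   — the standard shortcut design for reconstruction networks.
#' @export
setClass("NetworkSpec",
  representation(inChannels = "integer", depth = "integer",
                 baseChannels = "integer", T = "integer",
                 bodyNeuron = "NeuronConfig", headNeuron = "NeuronConfig",
                 inputSkip = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    if (object@inChannels < 1L) msg <- c(msg, "inChannels must be >= 1")
    if (object@T < 1L) msg <- c(msg, "T must be >= 1")
    if (length(msg)) msg else TRUE
  }
)

#' @param inChannels per-step input channels (default 1).
#' @param depth encoder levels (default 2).
#' @param baseChannels first-level width (default 16).
#' @param T time steps (default 8).
#' @param bodyNeuron neuron configuration of the body (default IF,
#'   threshold 1.0).
#' @param headNeuron neuron configuration of the 1x1 head (default IF,
#'   threshold 0.077).
#' @param inputSkip logical; default \code{TRUE} (see slot description).
#' @rdname NetworkSpec-class
#' @export
networkSpec <- function(inChannels = 1L, depth = 2L, baseChannels = 16L,
                        T = 8L,
                        bodyNeuron = neuronConfig("IF", vThreshold = 1.0),
                        headNeuron = neuronConfig("IF", vThreshold = 0.077),
                        inputSkip = TRUE) {
  new("NetworkSpec", inChannels = as.integer(inChannels),
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      T = as.integer(T), bodyNeuron = bodyNeuron, headNeuron = headNeuron,
      inputSkip = inputSkip)
}

#' A built spiking U-net model
#'
#' Produced by \code{\link{buildUVTSNN}}. Holds the architecture spec, the
#' per-layer weight matrices (bias-free by construction), a static tape of
#' operations used by the forward and backward passes, and a private
#' environment carrying mutable run state (membrane potentials, spike traces,
#' optimizer moments).
#'
#' @slot spec the \code{NetworkSpec}.
#' @slot weights named list of weight matrices, one per convolution, each of
#'   shape \code{outChannels x (inChannels * k * k)}.
#' @slot layers list of layer descriptors (internal).
#' @slot tape list of tape operations (internal).
#' @slot env environment with mutable state.
#' @export
setClass("SpikingModel",
  representation(spec = "NetworkSpec", weights = "list", layers = "list",
                 tape = "list", env = "environment"))

#' Training configuration
#'
#' @slot mode \code{"ITBP"} (weighted bit-plane loss on encoded labels,
#'   gradients spatial-only) or \code{"STBP"} (decoded-image MSE, gradients
#'   through space and time).
#' @slot learningRate Adam learning rate (default 0.001).
#' @slot batchSize minibatch size (default 50).
#' @slot epochs number of passes over the data.
#' @slot seed integer seed governing shuffling and initialisation.
#' @slot beta1,beta2,epsilon Adam moment decays and stabiliser (standard
#'   published defaults).
#' @slot inputCodec \code{"uwe"} (default) or \code{"ttfs"}: how the noisy
#'   input is spike-coded before the forward pass, so codec and
#'   backpropagation regime can be varied independently.
#' @slot stbpDecoder \code{"uwd"} (default) or \code{"mpd"}: the decoder in
#'   the STBP loss path. MPD compares its tanh-squashed readout against the
#'   clean image on the unit scale.
#' @export
setClass("TrainConfig",
  representation(mode = "character", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer",
                 beta1 = "numeric", beta2 = "numeric", epsilon = "numeric",
                 inputCodec = "character", stbpDecoder = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("ITBP", "STBP"))
      msg <- c(msg, "mode must be ITBP or STBP")
    if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
    if (!object@inputCodec %in% c("uwe", "ttfs"))
      msg <- c(msg, "inputCodec must be 'uwe' or 'ttfs'")
    if (!object@stbpDecoder %in% c("uwd", "mpd"))
      msg <- c(msg, "stbpDecoder must be 'uwd' or 'mpd'")
    if (length(msg)) msg else TRUE
  }
)

#' @param mode \code{"ITBP"} (default) or \code{"STBP"}.
#' @param learningRate Adam step size (default 0.001).
#' @param batchSize minibatch size (default 50).
#' @param epochs training epochs (default 5).
#' @param seed RNG seed (default 1).
#' @param beta1,beta2,epsilon Adam hyper-parameters.
#' @param inputCodec input spike coding, \code{"uwe"} (default, lossless) or
#'   \code{"ttfs"}.
#' @param stbpDecoder decoder in the STBP loss path, \code{"uwd"} (default)
#'   or \code{"mpd"}.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(mode = c("ITBP", "STBP"), learningRate = 0.001,
                        batchSize = 50L, epochs = 5L, seed = 1L,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        inputCodec = c("uwe", "ttfs"),
                        stbpDecoder = c("uwd", "mpd")) {
  new("TrainConfig", mode = match.arg(mode), learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), beta1 = beta1, beta2 = beta2, epsilon = epsilon,
      inputCodec = match.arg(inputCodec), stbpDecoder = match.arg(stbpDecoder))
}

#' Gaussian noise configuration
#'
#' \code{eta} is the standard deviation of zero-mean additive Gaussian noise
#' on the unit image scale; noisy values are clipped to [0, 1] and
#' re-quantized to the image's bit depth.
#'
#' @slot eta noise level in [0, 1].
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseConfig", representation(eta = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@eta < 0 || object@eta > 1) "eta must be in [0, 1]" else TRUE
  })

#' @param eta noise standard deviation on the [0,1] scale.
#' @param seed RNG seed (default 1).
#' @rdname NoiseConfig-class
#' @export
noiseConfig <- function(eta, seed = 1L) {
  new("NoiseConfig", eta = eta, seed = as.integer(seed))
}

#' Loss report
#'
#' @slot total scalar loss, already divided by the number of examples.
#' @slot perPlane per-significance-plane contributions (ITBP only; sums to
#'   \code{total * n}).
#' @slot n number of training examples the loss was averaged over.
#' @export
setClass("LossReport",
  representation(total = "numeric", perPlane = "numeric", n = "integer"))

#' Reconstruction metric report
#'
#' @slot mse mean squared error on the integer pixel scale.
#' @slot psnr peak signal-to-noise ratio in dB (peak \code{2^n - 1});
#'   \code{Inf} when the images are identical.
#' @export
setClass("MetricReport", representation(mse = "numeric", psnr = "numeric"))

#' Energy report
#'
#' Event-driven energy accounting for a spiking network against a conventional
#' network of the same architecture: the conventional network pays
#' \code{ePerOp} per activation operation, the spiking network pays
#' \code{ePerSpike} only for slots that actually carry a spike. Energies are
#' reported in units of 1e-7 J.
#'
#' @slot opAnn activation-operation count of the conventional network.
#' @slot opSnn neuron-time-slot count of the spiking network.
#' @slot spikeRate fraction of slots carrying a spike, in [0, 1].
#' @slot ePerOp energy per operation, pJ (default 4.6).
#' @slot ePerSpike energy per spike, pJ (default 0.9).
#' @slot energyAnn,energySnn energies in 1e-7 J.
#' @slot ratio energyAnn / energySnn computed from the two-decimal rounded
#'   energies; \code{NA} when the spiking energy is zero.
#' @export
setClass("EnergyReport",
  representation(opAnn = "numeric", opSnn = "numeric", spikeRate = "numeric",
                 ePerOp = "numeric", ePerSpike = "numeric",
                 energyAnn = "numeric", energySnn = "numeric",
                 ratio = "numeric"))

#' A paired clean/noisy image dataset
#'
#' @slot clean,noisy index-aligned lists of \code{GrayImage}s of equal length
#'   and shape.
#' @slot eta the noise level the noisy half was generated with.
#' @export
setClass("DatasetBundle",
  representation(clean = "list", noisy = "list", eta = "numeric"),
  validity = function(object) {
    if (length(object@clean) != length(object@noisy))
      return("clean and noisy lists must have equal length")
    ok <- vapply(seq_along(object@clean), function(i) {
      identical(dim(pixels(object@clean[[i]])), dim(pixels(object@noisy[[i]])))
    }, logical(1))
    if (!all(ok)) "clean/noisy image shapes must align" else TRUE
  })
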