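## Fully spiking U-net: builder, forward pass, checkpointing.
##
## The model is represented as a static "tape" of operations (conv / neuron /
## upsample / concat) derived once from the NetworkSpec. The forward pass
## interprets the tape per time step, carrying per-layer membrane potentials;
## the backward pass (training.R) replays it in reverse. Batched activations
## are 3-D arrays of dim (H, W, C*N), slice = channel-within-image fastest.

.convLayer <- function(name, cin, cout, k, stride, from, to) {
  list(op = "conv", w = name, cin = cin, cout = cout, k = k,
       stride = stride, from = from, to = to)
}

.snLayer <- function(id, cfg, from, to) {
  list(op = "sn", id = id, cfg = cfg, from = from, to = to)
}

#' Build a fully spiking U-net denoiser
#'
#' Constructs the model described by a \code{\link{networkSpec}}: a stem
#' convolution, \code{depth} encoder levels (stride-2 convolution + a refining
#' convolution, widths doubling per level), a mirrored decoder
#' (nearest-neighbour upsampling + convolution, concatenative skip, fusing
#' convolution) and a 1x1 spiking head. Every convolution is 3x3 (head: 1x1)
#' and bias-free, and every nonlinearity is a spiking neuron, so all
#' inter-layer traffic is binary. Weights use Kaiming-uniform initialisation
#' (\code{U(-sqrt(6/fanIn), sqrt(6/fanIn))}) from the current RNG stream.
#'
#' The default spec (depth 2, 16 base channels) has 115,360 parameters.
#'
#' @param spec a \code{NetworkSpec}.
#' @return a \code{SpikingModel}.
#' @examples
#' m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 4L))
#' parameterCount(m)
#' @export
buildUVTSNN <- function(spec = networkSpec()) {
  stopifnot(is(spec, "NetworkSpec"))
  ch <- spec@baseChannels * 2^(0:spec@depth)  # width per level
  layers <- list()
  tape <- list()
  snId <- 0L
  addConv <- function(name, cin, cout, k, stride, from, to) {
    l <- .convLayer(name, cin, cout, k, stride, from, to)
    layers[[name]] <<- l
    tape[[length(tape) + 1L]] <<- l
  }
  addSn <- function(cfg, from, to) {
    snId <<- snId + 1L
    tape[[length(tape) + 1L]] <<- .snLayer(snId, cfg, from, to)
  }
  addConv("stem", spec@inChannels, ch[1], 3L, 1L, "x", "stem.pre")
  addSn("body", "stem.pre", "enc0")
  cur <- "enc0"
  for (l in seq_len(spec@depth)) {
    dn <- sprintf("down%d", l); rf <- sprintf("refine%d", l)
    addConv(dn, ch[l], ch[l + 1], 3L, 2L, cur, paste0(dn, ".pre"))
    addSn("body", paste0(dn, ".pre"), paste0("dn", l))
    addConv(rf, ch[l + 1], ch[l + 1], 3L, 1L, paste0("dn", l), paste0(rf, ".pre"))
    addSn("body", paste0(rf, ".pre"), paste0("enc", l))
    cur <- paste0("enc", l)
  }
  for (l in rev(seq_len(spec@depth))) {
    upn <- sprintf("up%d", l); dc <- sprintf("dec%d", l)
    tape[[length(tape) + 1L]] <- list(op = "up", from = cur,
                                      to = paste0(upn, ".nn"))
    addConv(upn, ch[l + 1], ch[l], 3L, 1L, paste0(upn, ".nn"),
            paste0(upn, ".pre"))
    addSn("body", paste0(upn, ".pre"), paste0("up", l))
    skip <- paste0("enc", l - 1)
    tape[[length(tape) + 1L]] <- list(op = "concat", from1 = skip,
                                      from2 = paste0("up", l),
                                      c1 = ch[l], c2 = ch[l],
                                      to = paste0(dc, ".cat"))
    addConv(dc, 2L * ch[l], ch[l], 3L, 1L, paste0(dc, ".cat"),
            paste0(dc, ".pre"))
    addSn("body", paste0(dc, ".pre"), paste0("dec", l))
    cur <- paste0("dec", l)
  }
  if (spec@inputSkip) {
    tape[[length(tape) + 1L]] <- list(op = "concat", from1 = "x", from2 = cur,
                                      c1 = spec@inChannels, c2 = ch[1],
                                      to = "head.cat")
    addConv("head", spec@inChannels + ch[1], spec@inChannels, 1L, 1L,
            "head.cat", "head.pre")
  } else {
    addConv("head", ch[1], spec@inChannels, 1L, 1L, cur, "head.pre")
  }
  addSn("head", "head.pre", "out")

  weights <- lapply(layers, function(l) {
    fanIn <- l$cin * l$k^2
    lim <- sqrt(6 / fanIn)
    matrix(stats::runif(l$cout * l$cin * l$k^2, -lim, lim),
           nrow = l$cout, ncol = l$cin * l$k^2)
  })
  if (spec@inputSkip) {
    # identity-initialised head: the skip weight equals the head threshold,
    # so an input spike charges the head to exactly V_th, fires (h(0) = 1)
    # and the soft reset clears the full charge -- the pass-through is exact
    # at every step. Feature columns start at zero, so training begins from
    # the identity reconstruction and learns corrections.
    hw <- matrix(0, spec@inChannels, spec@inChannels + ch[1])
    hw[, seq_len(spec@inChannels)] <- diag(spec@inChannels) *
      spec@headNeuron@vThreshold
    weights[["head"]] <- hw
  }
  env <- new.env(parent = emptyenv())
  env$weights <- weights
  env$states <- list()
  env$adam <- NULL
  env$trace <- NULL
  new("SpikingModel", spec = spec, weights = weights, layers = layers,
      tape = tape, env = env)
}

#' Current weights of a model
#'
#' Training updates the model in place (the weights live in the model's state
#' environment); this accessor returns the current values.
#'
#' @param model a \code{SpikingModel}.
#' @return named list of weight matrices.
#' @export
modelWeights <- function(model) model@env$weights

#' @rdname parameterCount
#' @export
setMethod("parameterCount", "SpikingModel",
          function(object) sum(vapply(object@env$weights, length, numeric(1))))

#' Reset all membrane potentials
#'
#' Clears the per-layer neuron states so the next forward pass starts from
#' zero potentials. \code{\link{modelForward}} does this automatically before
#' each sample/batch, keeping results independent of earlier inputs.
#'
#' @param model a \code{SpikingModel}.
#' @return the model, invisibly.
#' @export
resetState <- function(model) {
  model@env$states <- list()
  invisible(model)
}

.upNearest <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.upPool <- function(d) {
  # backward of nearest x2 upsampling: sum each 2x2 block
  dd <- dim(d)
  ro <- seq(1, dd[1], 2); re <- seq(2, dd[1], 2)
  co <- seq(1, dd[2], 2); ce <- seq(2, dd[2], 2)
  d[ro, co, , drop = FALSE] + d[re, co, , drop = FALSE] +
    d[ro, ce, , drop = FALSE] + d[re, ce, , drop = FALSE]
}

.catSlices <- function(c1, c2, n) {
  # output slice positions of each input when concatenating channels
  newC <- c1 + c2
  list(p1 = as.vector(outer(seq_len(c1), (seq_len(n) - 1) * newC, "+")),
       p2 = as.vector(outer(c1 + seq_len(c2), (seq_len(n) - 1) * newC, "+")))
}

.neuronCfg <- function(spec, which) {
  if (which == "head") spec@headNeuron else spec@bodyNeuron
}

## Batched forward over T time steps.
## input: array (T, H, W, C*N). Returns output (T, H, W, C*N), optional
## per-step caches for backprop, and spike traces per neuron layer.
.forwardBatch <- function(model, input, nimg, keepCache = FALSE,
                          trace = FALSE) {
  spec <- model@spec
  d <- dim(input)
  T <- d[1]; H <- d[2]; W <- d[3]
  if (H %% 2^spec@depth != 0 || W %% 2^spec@depth != 0)
    stop(sprintf("spatial size %dx%d is not divisible by 2^depth = %d; pad the image first",
                 H, W, 2^spec@depth))
  if (!all(input %in% c(0, 1)))
    stop("the network is fully spiking: inputs must be binary spike planes")
  resetState(model)
  W8 <- model@env$weights
  snCount <- sum(vapply(model@tape, function(o) o$op == "sn", logical(1)))
  traceSpikes <- if (trace) numeric(snCount) else NULL
  traceSlots <- if (trace) numeric(snCount) else NULL
  states <- list()
  out <- array(0, dim = d)
  caches <- if (keepCache) vector("list", T) else NULL
  for (t in seq_len(T)) {
    vals <- list(x = array(input[t, , , ], dim = c(H, W, d[4])))
    ucs <- list()
    for (op in model@tape) {
      if (op$op == "conv") {
        vals[[op$to]] <- .conv_fw(vals[[op$from]], W8[[op$w]], op$cin, nimg,
                                  op$k, op$stride)
      } else if (op$op == "sn") {
        cfg <- .neuronCfg(spec, op$cfg)
        xin <- vals[[op$from]]
        key <- as.character(op$id)
        u <- states[[key]]
        if (is.null(u)) u <- array(0, dim = dim(xin))
        r <- .chargeFire(u, xin, cfg)
        states[[key]] <- r$u
        vals[[op$to]] <- r$spikes
        ucs[[key]] <- r$uc
        if (trace) {
          traceSpikes[op$id] <- traceSpikes[op$id] + sum(r$spikes)
          traceSlots[op$id] <- traceSlots[op$id] + length(r$spikes)
        }
      } else if (op$op == "up") {
        vals[[op$to]] <- .upNearest(vals[[op$from]])
      } else if (op$op == "concat") {
        a <- vals[[op$from1]]; b <- vals[[op$from2]]
        da <- dim(a)
        res <- array(0, dim = c(da[1], da[2], (op$c1 + op$c2) * nimg))
        ps <- .catSlices(op$c1, op$c2, nimg)
        res[, , ps$p1] <- a
        res[, , ps$p2] <- b
        vals[[op$to]] <- res
      }
    }
    out[t, , , ] <- vals[["out"]]
    if (keepCache) caches[[t]] <- list(vals = vals, ucs = ucs)
  }
  model@env$states <- states
  if (trace) model@env$trace <- list(spikes = traceSpikes, slots = traceSlots)
  list(out = out, caches = caches,
       trace = if (trace) model@env$trace else NULL)
}

#' Forward pass of the spiking U-net
#'
#' Runs a binary spike-plane stack through the network, one plane per time
#' step, carrying membrane potentials across steps. Neuron states are reset
#' to zero before the pass, so results do not depend on previous inputs.
#' The output is again a binary stack of the same shape.
#'
#' @param model a \code{SpikingModel}.
#' @param input a \code{SpikePlaneStack} with \code{T} planes matching the
#'   model spec.
#' @param detachTime logical; severs the carried membrane state from the
#'   gradient graph between steps (independent-temporal training). Forward
#'   values are identical either way; the flag matters only to
#'   \code{\link{trainStep}}.
#' @param trace logical; record per-layer spike counts for the energy model
#'   (retrievable with \code{\link{spikeTraces}}).
#' @return a \code{SpikePlaneStack} of output spikes.
#' @export
modelForward <- function(model, input, detachTime = FALSE, trace = FALSE) {
  stopifnot(is(model, "SpikingModel"), is(input, "SpikePlaneStack"))
  pl <- planes(input)
  d <- dim(pl)
  if (d[1] != model@spec@T)
    stop("input stack depth does not match the model's T")
  arr <- array(pl, dim = c(d, 1L))
  r <- .forwardBatch(model, arr, nimg = 1L, keepCache = FALSE, trace = trace)
  SpikePlaneStack(array(r$out, dim = d), coding = codingType(input))
}

#' Spike traces of the last instrumented forward pass
#'
#' @param model a \code{SpikingModel} that has been run with
#'   \code{trace = TRUE}.
#' @return list with per-neuron-layer \code{spikes} and \code{slots} counts.
#' @export
spikeTraces <- function(model) {
  if (is.null(model@env$trace))
    stop("no traces recorded: run modelForward(..., trace = TRUE) first")
  model@env$trace
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the architecture spec and the current weights in a
#' single RDS container so a saved model can be rebuilt exactly.
#'
#' @param model a \code{SpikingModel}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the rebuilt \code{SpikingModel}.
#' @export
saveCheckpoint <- function(model, path) {
  spec <- model@spec
  obj <- list(format = "vtsnn-checkpoint-1",
              spec = list(inChannels = spec@inChannels, depth = spec@depth,
                          baseChannels = spec@baseChannels, T = spec@T,
                          bodyNeuron = .cfgToList(spec@bodyNeuron),
                          headNeuron = .cfgToList(spec@headNeuron)),
              weights = model@env$weights)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "vtsnn-checkpoint-1"))
    stop("not a recognised checkpoint file")
  s <- obj$spec
  spec <- networkSpec(inChannels = s$inChannels, depth = s$depth,
                      baseChannels = s$baseChannels, T = s$T,
                      bodyNeuron = .cfgFromList(s$bodyNeuron),
                      headNeuron = .cfgFromList(s$headNeuron))
  model <- buildUVTSNN(spec)
  stopifnot(identical(names(model@env$weights), names(obj$weights)))
  model@env$weights <- obj$weights
  model
}

.cfgToList <- function(cfg) {
  list(kind = cfg@kind, vThreshold = cfg@vThreshold, tau = cfg@tau,
       surrogateScale = cfg@surrogateScale, literalGate = cfg@literalGate)
}

.cfgFromList <- function(l) {
  neuronConfig(kind = l$kind, vThreshold = l$vThreshold, tau = l$tau,
               surrogateScale = l$surrogateScale, literalGate = l$literalGate)
}
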