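#' Surrogate derivative of the firing nonlinearity
#'
#' The Heaviside firing rule has zero derivative almost everywhere, so
#' gradient training replaces it with the smooth surrogate
#' \code{1 / (1 + (scale * v)^2)} evaluated at \code{v = u - vThreshold}
#' (the distance of the membrane potential from the firing boundary). The
#' surrogate is even, takes its maximum 1 at the boundary and decays
#' quadratically away from it.
#'
#' @param v membrane potential minus threshold (any numeric array).
#' @param scale sharpness; default \code{pi}.
#' @return values in (0, 1], same shape as \code{v}.
#' @examples
#' surrogateGrad(0)      # 1
#' surrogateGrad(1 / pi) # 0.5
#' @export
surrogateGrad <- function(v, scale = pi) {
  if (any(!is.finite(v))) stop("v must be finite")
  1 / (1 + (scale * v)^2)
}

## Core charge/fire/reset update shared by neuronStep and the network forward.
## Returns the spikes, the post-reset potential and the pre-reset ("charged")
## potential needed by the surrogate during backpropagation.
.chargeFire <- function(u, x, config) {
  uc <- if (config@literalGate) {
    g <- if (config@kind == "IF") config@tau else config@tau * exp(-.lastSpike(u) / config@tau)
    u * g + x
  } else if (config@kind == "IF") {
    u + x
  } else {
    u + (x - u) / config@tau
  }
  o <- (uc >= config@vThreshold) * 1  # Heaviside with h(0) = 1
  list(spikes = o, u = uc - config@vThreshold * o, uc = uc)
}

## literalGate needs the previous spike map; it is stored alongside u as an
## attribute so the public NeuronState keeps a single array slot.
.lastSpike <- function(u) {
  s <- attr(u, "lastSpike")
  if (is.null(s)) 0 else s
}

#' One discrete time step of a spiking neuron layer
#'
#' Charges the membrane by the input current (IF: \code{u <- u + x}; LIF:
#' \code{u <- u + (x - u)/tau}), emits a spike wherever the charged potential
#' reaches the threshold (\code{h(0) = 1}: a potential exactly at threshold
#' fires), then soft-resets by subtracting the threshold from firing units so
#' residual charge above threshold is preserved.
#'
#' @param state a \code{NeuronState} with potentials shaped like the input.
#' @param input numeric array of input currents, same shape as \code{state@u}.
#' @param config a \code{NeuronConfig}.
#' @return list with elements \code{spikes} (binary array) and \code{state}
#'   (updated \code{NeuronState}).
#' @examples
#' st <- neuronState(0)
#' neuronStep(st, 1.0, neuronConfig("IF"))$spikes  # fires at threshold
#' @export
neuronStep <- function(state, input, config) {
  stopifnot(is(state, "NeuronState"), is(config, "NeuronConfig"))
  if (is.null(dim(input))) input <- array(input, dim = length(input))
  if (!identical(dim(input), dim(state@u)))
    stop("input shape does not match neuron state shape")
  if (anyNA(input) || any(!is.finite(input))) stop("input current must be finite")
  r <- .chargeFire(state@u, input, config)
  u <- r$u
  if (config@literalGate) attr(u, "lastSpike") <- r$spikes
  newState <- new("NeuronState", u = u, t = state@t + 1L)
  list(spikes = r$spikes, state = newState)
}

#' Run a neuron layer over a sequence of inputs
#'
#' Applies \code{\link{neuronStep}} once per time step, carrying the membrane
#' potential forward. \code{detachTime} marks the carried state as severed
#' from the gradient graph between steps — the regime used by
#' independent-temporal training. Detachment changes gradients only: the
#' forward spike outputs are identical with the flag on or off.
#'
#' @param inputs numeric array whose first dimension is time (T x ...).
#' @param config a \code{NeuronConfig}.
#' @param detachTime logical; forward values are unaffected.
#' @param state optional initial \code{NeuronState}; zeros by default.
#' @return list with \code{spikes} (binary array, same shape as
#'   \code{inputs}), \code{potentials} (pre-reset potentials per step, used by
#'   the surrogate) and \code{state} (final \code{NeuronState}).
#' @export
runSequence <- function(inputs, config, detachTime = FALSE, state = NULL) {
  d <- dim(inputs)
  if (is.null(d)) d <- c(length(inputs), 1L)
  T <- d[1L]
  if (T < 1L || length(inputs) == 0L) stop("empty input sequence")
  stepDim <- if (length(d) > 1L) d[-1L] else 1L
  if (is.null(state)) state <- neuronState(array(0, dim = stepDim))
  spikes <- array(0, dim = d)
  pots <- array(0, dim = d)
  idx <- slice.index(array(0, dim = d), 1L)
  for (t in seq_len(T)) {
    xt <- array(inputs[idx == t], dim = stepDim)
    r <- .chargeFire(state@u, xt, config)
    u <- r$u
    if (config@literalGate) attr(u, "lastSpike") <- r$spikes
    state <- new("NeuronState", u = u, t = state@t + 1L)
    spikes[idx == t] <- r$spikes
    pots[idx == t] <- r$uc
  }
  list(spikes = spikes, potentials = pots, state = state,
       detachTime = detachTime)
}
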