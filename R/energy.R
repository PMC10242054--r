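#' Peak signal-to-noise ratio between two images
#'
#' Standard PSNR with peak \code{2^n - 1} (255 for 8-bit images):
#' \code{psnr = 10 * log10(peak^2 / mse)}. Identical images have zero MSE and
#' are reported with \code{psnr = Inf}.
#'
#' @param a,b \code{GrayImage}s of the same shape and bit depth.
#' @return a \code{MetricReport} with slots \code{mse} and \code{psnr}.
#' @examples
#' x <- GrayImage(matrix(0, 2, 2)); y <- GrayImage(matrix(c(255, 0, 0, 0), 2, 2))
#' psnr(x, y)  # mse = 255^2/4, psnr ~ 6.02 dB
#' @export
psnr <- function(a, b) {
  stopifnot(is(a, "GrayImage"), is(b, "GrayImage"))
  pa <- pixels(a); pb <- pixels(b)
  if (!identical(dim(pa), dim(pb))) stop("images have different shapes")
  peak <- 2^max(nBits(a), nBits(b)) - 1
  mse <- mean((pa - pb)^2)
  p <- if (mse > 0) 10 * log10(peak^2 / mse) else Inf
  new("MetricReport", mse = mse, psnr = p)
}

#' Count spikes from recorded forward traces
#'
#' Sums the spike counts recorded by an instrumented forward pass
#' (\code{modelForward(..., trace = TRUE)}) over all neuron layers and time
#' steps, and divides by the total number of neuron-time slots to obtain the
#' spike rate that drives the event-driven energy estimate.
#'
#' @param model a \code{SpikingModel} with recorded traces, or a trace list
#'   as returned by \code{\link{spikeTraces}}.
#' @return list with \code{totalSpikes}, \code{totalSlots} and
#'   \code{spikeRate}.
#' @export
countSpikes <- function(model) {
  tr <- if (is(model, "SpikingModel")) spikeTraces(model) else model
  if (is.null(tr$spikes) || !length(tr$spikes)) stop("no traces recorded")
  total <- sum(tr$spikes)
  slots <- sum(tr$slots)
  list(totalSpikes = total, totalSlots = slots, spikeRate = total / slots)
}

#' Event-driven energy comparison
#'
#' Compares the energy of a conventional network against a spiking network of
#' the same architecture under the standard 45 nm CMOS accounting: every
#' activation operation of the conventional network costs \code{ePerOp}
#' (4.6 pJ), while the spiking network pays \code{ePerSpike} (0.9 pJ) only
#' for the neuron-time slots that actually carry a spike, so
#' \code{energySnn = opSnn * spikeRate * ePerSpike}. Convolution
#' multiply-accumulates are excluded on both sides. Energies are reported in
#' units of 1e-7 J, and the headline ratio is taken between the two-decimal
#' rounded energies (the printable quantities).
#'
#' @param opAnn activation-operation count of the conventional network.
#' @param opSnn neuron-time-slot count of the spiking network.
#' @param spikeRate fraction of slots carrying a spike, in [0, 1].
#' @param ePerOp pJ per conventional operation (default 4.6).
#' @param ePerSpike pJ per spike (default 0.9).
#' @return an \code{EnergyReport}; \code{ratio} is \code{NA} when the spiking
#'   energy rounds to zero.
#' @examples
#' energyReport(18.39e6, 2.51e6, 0.1366)  # 845.94 vs 3.09, ratio 273.77
#' @export
energyReport <- function(opAnn, opSnn, spikeRate, ePerOp = 4.6,
                         ePerSpike = 0.9) {
  if (opAnn < 0 || opSnn < 0) stop("operation counts must be nonnegative")
  if (spikeRate < 0 || spikeRate > 1) stop("spikeRate must be in [0, 1]")
  toUnits <- 1e-12 / 1e-7  # pJ -> 1e-7 J
  eAnn <- round(opAnn * ePerOp * toUnits, 2)
  eSnn <- round(opSnn * spikeRate * ePerSpike * toUnits, 2)
  ratio <- if (eSnn > 0) round(eAnn / eSnn, 2) else NA_real_
  new("EnergyReport", opAnn = opAnn, opSnn = opSnn, spikeRate = spikeRate,
      ePerOp = ePerOp, ePerSpike = ePerSpike, energyAnn = eAnn,
      energySnn = eSnn, ratio = ratio)
}

#' Energy report from a model run
#'
#' Convenience wrapper: counts spikes and slots from a model's recorded
#' traces and builds the \code{\link{energyReport}}, taking the
#' conventional-network operation count to equal the spiking network's
#' neuron-slot count (same architecture, one activation per slot).
#'
#' @param model a \code{SpikingModel} run with \code{trace = TRUE}.
#' @param ePerOp,ePerSpike energy constants in pJ.
#' @return an \code{EnergyReport}.
#' @export
modelEnergy <- function(model, ePerOp = 4.6, ePerSpike = 0.9) {
  cs <- countSpikes(model)
  energyReport(cs$totalSlots, cs$totalSlots, cs$spikeRate, ePerOp, ePerSpike)
}
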