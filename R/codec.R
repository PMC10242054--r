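#' Tensor n-mode product
#'
#' Multiplies the mode-\code{mode} unfolding of an N-way array by a matrix and
#' refolds the result: if \code{Q = nModeProduct(P, B, n)} then
#' \code{unfold(Q, n) = B \%*\% unfold(P, n)}. The dimension of the result
#' along \code{mode} is \code{nrow(matrix)}. This is the algebra behind the
#' weighted spike-plane decoder, where a 1 x T weight matrix collapses the
#' plane dimension of a T x H x W stack.
#'
#' @param tensor an N-way numeric array.
#' @param matrix a J x I numeric matrix with \code{I = dim(tensor)[mode]}.
#' @param mode the mode (dimension index) to contract over.
#' @return an N-way array with \code{dim(result)[mode] == nrow(matrix)}.
#' @examples
#' p <- array(1, c(2, 2, 2))
#' nModeProduct(p, matrix(1, 1, 2), 1)  # 1 x 2 x 2 array of twos
#' @export
nModeProduct <- function(tensor, matrix, mode) {
  d <- dim(tensor)
  if (is.null(d)) stop("tensor must be an array with a dim attribute")
  N <- length(d)
  if (mode < 1L || mode > N) stop("mode must be in 1..", N)
  if (!is.matrix(matrix)) matrix <- base::matrix(matrix, nrow = 1L)
  if (ncol(matrix) != d[mode])
    stop(sprintf("shape mismatch: matrix has %d columns but tensor mode %d has extent %d",
                 ncol(matrix), mode, d[mode]))
  perm <- c(mode, seq_len(N)[-mode])
  unfolded <- base::matrix(aperm(tensor, perm), nrow = d[mode])
  res <- matrix %*% unfolded
  newd <- d[perm]
  newd[1L] <- nrow(matrix)
  aperm(array(res, dim = newd), order(perm))
}

#' Undistorted weighted encoding (UWE)
#'
#' Losslessly converts an n-bit image into n binary spike planes by successive
#' subtraction of powers of two, most significant bit first: plane \code{t}
#' of the result holds bit \code{T - t} of every pixel, so the weighted sum
#' \code{sum_t 2^(T-t) * plane_t} reproduces the image exactly. This is the
#' exact digital behavioural model of a successive-approximation ADC.
#'
#' @param image a \code{GrayImage} whose bit depth equals \code{config@nBits}.
#' @param config a \code{CodecConfig}; \code{T} must equal \code{nBits}.
#' @return a bit-plane coded \code{SpikePlaneStack} with \code{T} planes.
#' @seealso \code{\link{uwdDecode}} for the exact inverse.
#' @examples
#' img <- GrayImage(matrix(146, 1, 1))
#' planes(uweEncode(img))[, 1, 1]  # 1 0 0 1 0 0 1 0
#' @export
uweEncode <- function(image, config = codecConfig()) {
  stopifnot(is(image, "GrayImage"), is(config, "CodecConfig"))
  if (nBits(image) != config@nBits)
    stop("image bit depth does not match config@nBits")
  if (config@T != config@nBits)
    stop("UWE requires T == nBits")
  validObject(image)  # rejects out-of-range pixels rather than clipping
  p <- pixels(image)
  T <- config@T
  out <- array(0, dim = c(T, nrow(p), ncol(p)))
  resid <- p
  for (t in seq_len(T)) {
    w <- 2^(T - t)
    bit <- (resid >= w) * 1
    resid <- resid - w * bit
    out[t, , ] <- bit
  }
  SpikePlaneStack(out, coding = "bitplane")
}

#' Undistorted weighted decoding (UWD)
#'
#' Exact inverse of \code{\link{uweEncode}}: contracts the plane dimension of
#' a binary stack with the decoding matrix \code{A = (2^(T-1), ..., 2^0)} via
#' the tensor n-mode product, recovering the integer image.
#'
#' @param spikes a bit-plane coded \code{SpikePlaneStack}.
#' @param config a \code{CodecConfig} with \code{T} equal to the stack depth.
#' @return a \code{GrayImage} with values in \code{[0, 2^T - 1]}.
#' @export
uwdDecode <- function(spikes, config = codecConfig()) {
  stopifnot(is(spikes, "SpikePlaneStack"), is(config, "CodecConfig"))
  pl <- planes(spikes)
  if (!all(pl %in% c(0, 1))) stop("spike planes must be strictly binary")
  T <- dim(pl)[1L]
  if (T != config@T) stop("stack depth does not match config@T")
  A <- matrix(2^((T - 1):0), nrow = 1L)
  dec <- nModeProduct(pl, A, 1L)
  GrayImage(dec[1, , , drop = TRUE], nBits = config@T)
}

#' Time-to-first-spike encoding (TTFS)
#'
#' Latency coding: each pixel emits at most one spike, at time step
#' \code{t = (max(x) - x) / max(x) * T} (0-based), rounded according to
#' \code{config@ttfsRounding}; the brightest pixels spike at step 0 and a
#' rounded latency \code{>= T} falls outside the coding window and emits no
#' spike. After rounding the code is lossy for \code{T < 2^n}: distinct
#' intensities can share a latency.
#'
#' @param image a \code{GrayImage}.
#' @param T number of time steps (default from \code{config}).
#' @param config a \code{CodecConfig} providing the rounding rule.
#' @return a latency-coded \code{SpikePlaneStack} with \code{T} planes.
#' @export
ttfsEncode <- function(image, T = config@T, config = codecConfig()) {
  stopifnot(is(image, "GrayImage"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  p <- pixels(image)
  out <- array(0, dim = c(T, nrow(p), ncol(p)))
  mx <- max(p)
  if (mx == 0) {
    warning("all-zero image: TTFS emits no spikes")
    return(SpikePlaneStack(out, coding = "latency"))
  }
  tReal <- (mx - p) / mx * T
  tIdx <- switch(config@ttfsRounding, floor = floor(tReal), nearest = round(tReal))
  inWin <- which(tIdx < T)
  hw <- arrayInd(inWin, dim(p))
  out[cbind(tIdx[inWin] + 1L, hw)] <- 1
  SpikePlaneStack(out, coding = "latency")
}

#' Membrane-potential decoding (MPD)
#'
#' Real-valued readout of a spike stack: each plane is weighted geometrically
#' with base \code{theta} (most significant plane gets \code{theta^0 = 1},
#' the last plane \code{theta^(T-1)}), the weighted spikes are summed per
#' pixel, and the sum is squashed through \code{tanh}. Unlike the weighted
#' bit-plane decoder this readout is floating-point and bounded strictly
#' inside (-1, 1), so it cannot be lossless.
#'
#' @param spikes a \code{SpikePlaneStack}.
#' @param config a \code{CodecConfig} providing \code{mpdTheta} (default 0.8).
#' @return a numeric matrix in (-1, 1) (0 where no spikes occurred).
#' @export
mpdDecode <- function(spikes, config = codecConfig()) {
  stopifnot(is(spikes, "SpikePlaneStack"), is(config, "CodecConfig"))
  pl <- planes(spikes)
  if (!all(pl %in% c(0, 1))) stop("spike planes must be strictly binary")
  T <- dim(pl)[1L]
  w <- config@mpdTheta^(0:(T - 1))
  acc <- nModeProduct(pl, matrix(w, nrow = 1L), 1L)
  tanh(acc[1, , , drop = TRUE])
}
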