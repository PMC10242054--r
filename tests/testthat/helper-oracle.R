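# Independent oracles used by the gradient and codec tests.
#
# The naive convolution is a direct quadruple loop (no im2col, no GEMM) and
# the oracle gradient routine recomputes each time step's backward pass
# separately from stored states, summing per-step weight gradients. Both are
# deliberately written against the mathematical definitions rather than the
# package's internals, so agreement is a genuine cross-check.

naiveConvFw <- function(x, w, cin, k, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]
  pad <- (k - 1) %/% 2
  H2 <- (H + 2 * pad - k) %/% stride + 1
  W2 <- (W + 2 * pad - k) %/% stride + 1
  cout <- nrow(w)
  y <- array(0, c(H2, W2, cout))
  for (co in seq_len(cout)) for (ci in seq_len(cin))
    for (ky in 0:(k - 1)) for (kx in 0:(k - 1)) {
      wv <- w[co, (ci - 1) * k * k + ky * k + kx + 1]
      if (wv == 0) next
      for (oy in seq_len(H2)) for (ox in seq_len(W2)) {
        iy <- (oy - 1) * stride - pad + ky + 1
        ix <- (ox - 1) * stride - pad + kx + 1
        if (iy >= 1 && iy <= H && ix >= 1 && ix <= W)
          y[oy, ox, co] <- y[oy, ox, co] + wv * x[iy, ix, ci]
      }
    }
  y
}

naiveConvBw <- function(x, w, dy, cin, k, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]
  pad <- (k - 1) %/% 2
  H2 <- dim(dy)[1]; W2 <- dim(dy)[2]
  cout <- nrow(w)
  dW <- array(0, dim(w))
  dX <- array(0, dim(x))
  for (co in seq_len(cout)) for (ci in seq_len(cin))
    for (ky in 0:(k - 1)) for (kx in 0:(k - 1)) {
      col <- (ci - 1) * k * k + ky * k + kx + 1
      for (oy in seq_len(H2)) for (ox in seq_len(W2)) {
        iy <- (oy - 1) * stride - pad + ky + 1
        ix <- (ox - 1) * stride - pad + kx + 1
        if (iy >= 1 && iy <= H && ix >= 1 && ix <= W) {
          dW[co, col] <- dW[co, col] + dy[oy, ox, co] * x[iy, ix, ci]
          dX[iy, ix, ci] <- dX[iy, ix, ci] + dy[oy, ox, co] * w[co, col]
        }
      }
    }
  list(dW = dW, dX = dX)
}

oracleUp <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

oraclePool <- function(d) {
  dd <- dim(d)
  ro <- seq(1, dd[1], 2); re <- seq(2, dd[1], 2)
  co <- seq(1, dd[2], 2); ce <- seq(2, dd[2], 2)
  d[ro, co, , drop = FALSE] + d[re, co, , drop = FALSE] +
    d[ro, ce, , drop = FALSE] + d[re, ce, , drop = FALSE]
}

oracleNeuronCfg <- function(model, which) {
  if (which == "head") model@spec@headNeuron else model@spec@bodyNeuron
}

# Forward replay of a model's tape on a single image (T, H, W) input, naive
# convolutions, recording per step: all node values, charged potentials, and
# the membrane state at the START of each step (needed to recompute a step in
# isolation).
oracleForward <- function(model, input) {
  T <- dim(input)[1]
  W8 <- modelWeights(model)
  states <- list()
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    vals <- list(x = array(input[t, , ], c(dim(input)[2], dim(input)[3], 1)))
    ucs <- list(); uBefore <- list()
    for (op in model@tape) {
      if (op$op == "conv") {
        vals[[op$to]] <- naiveConvFw(vals[[op$from]], W8[[op$w]], op$cin,
                                     op$k, op$stride)
      } else if (op$op == "sn") {
        cfg <- oracleNeuronCfg(model, op$cfg)
        xin <- vals[[op$from]]
        key <- as.character(op$id)
        u <- states[[key]]
        if (is.null(u)) u <- array(0, dim(xin))
        uBefore[[key]] <- u
        uc <- if (cfg@kind == "IF") u + xin else u + (xin - u) / cfg@tau
        o <- (uc >= cfg@vThreshold) * 1
        states[[key]] <- uc - cfg@vThreshold * o
        vals[[op$to]] <- o
        ucs[[key]] <- uc
      } else if (op$op == "up") {
        vals[[op$to]] <- oracleUp(vals[[op$from]])
      } else if (op$op == "concat") {
        a <- vals[[op$from1]]; b <- vals[[op$from2]]
        da <- dim(a)
        res <- array(0, c(da[1], da[2], op$c1 + op$c2))
        res[, , seq_len(op$c1)] <- a
        res[, , op$c1 + seq_len(op$c2)] <- b
        vals[[op$to]] <- res
      }
    }
    steps[[t]] <- list(vals = vals, ucs = ucs, uBefore = uBefore)
  }
  steps
}

# Per-step recomputed gradients: every time step is treated as an isolated
# one-step network whose initial membrane potentials are the stored values;
# gradients are accumulated over steps. This is the defining computation of
# temporally independent backpropagation.
oracleGradientsPerStep <- function(model, input, dOut) {
  steps <- oracleForward(model, input)
  W8 <- modelWeights(model)
  grads <- lapply(W8, function(w) array(0, dim(w)))
  for (t in seq_along(steps)) {
    st <- steps[[t]]
    deltas <- list(out = dOut[[t]])
    add <- function(node, d) {
      deltas[[node]] <<- if (is.null(deltas[[node]])) d else deltas[[node]] + d
    }
    for (op in rev(model@tape)) {
      if (op$op == "conv") {
        d <- deltas[[op$to]]; if (is.null(d)) next
        bw <- naiveConvBw(st$vals[[op$from]], W8[[op$w]], d, op$cin, op$k,
                          op$stride)
        grads[[op$w]] <- grads[[op$w]] + bw$dW
        add(op$from, bw$dX)
      } else if (op$op == "sn") {
        d <- deltas[[op$to]]; if (is.null(d)) next
        cfg <- oracleNeuronCfg(model, op$cfg)
        uc <- st$ucs[[as.character(op$id)]]
        sg <- 1 / (1 + (cfg@surrogateScale * (uc - cfg@vThreshold))^2)
        duc <- d * sg
        add(op$from, if (cfg@kind == "IF") duc else duc / cfg@tau)
      } else if (op$op == "up") {
        d <- deltas[[op$to]]; if (is.null(d)) next
        add(op$from, oraclePool(d))
      } else if (op$op == "concat") {
        d <- deltas[[op$to]]; if (is.null(d)) next
        add(op$from1, d[, , seq_len(op$c1), drop = FALSE])
        add(op$from2, d[, , op$c1 + seq_len(op$c2), drop = FALSE])
      }
    }
  }
  grads
}

relErr <- function(a, b) {
  num <- max(abs(a - b))
  den <- max(abs(a), abs(b), 1e-12)
  num / den
}

randomGray <- function(H = 8, W = 8, nBits = 8L) {
  GrayImage(matrix(sample(0:(2^nBits - 1), H * W, replace = TRUE), H, W),
            nBits = nBits)
}
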