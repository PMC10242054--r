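test_that("default architecture lands near 0.12 M parameters, all bias-free", {
  set.seed(1)
  m <- buildUVTSNN(networkSpec())
  n <- parameterCount(m)
  expect_gte(n, 0.12e6 * 0.8)
  expect_lte(n, 0.12e6 * 1.2)
  # weights are plain conv matrices; no bias vectors exist anywhere
  expect_true(all(vapply(modelWeights(m), is.matrix, logical(1))))
  expect_equal(n, sum(vapply(m@layers, function(l) l$cout * l$cin * l$k^2,
                             numeric(1))))
})

test_that("a minimal model builds and runs on an 8x8 input", {
  set.seed(2)
  m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 1L))
  st <- uweEncode(randomGray(8, 8))
  out <- modelForward(m, st)
  expect_s4_class(out, "SpikePlaneStack")
  expect_equal(dim(planes(out)), c(8L, 8L, 8L))
})

test_that("zero input leaves a zero-bias network quiescent", {
  set.seed(3)
  m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 4L))
  z <- SpikePlaneStack(array(0, c(8, 8, 8)))
  out <- modelForward(m, z, trace = TRUE)
  expect_true(all(planes(out) == 0))
  cs <- countSpikes(m)
  expect_equal(cs$totalSpikes, 0)
  expect_equal(cs$spikeRate, 0)
})

test_that("outputs are binary and every inter-layer activation is a spike", {
  set.seed(4)
  m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 4L))
  st <- uweEncode(randomGray(8, 8))
  out <- modelForward(m, st)
  expect_true(all(planes(out) %in% c(0, 1)))
  # instrument the internal pass: all neuron outputs and all conv inputs
  # (the only inter-layer traffic) must be binary
  arr <- array(planes(st), dim = c(dim(planes(st)), 1L))
  r <- vtsnn:::.forwardBatch(m, arr, nimg = 1L, keepCache = TRUE)
  for (cache in r$caches) {
    for (op in m@tape) {
      if (op$op == "conv")
        expect_true(all(cache$vals[[op$from]] %in% c(0, 1)))
      if (op$op == "sn")
        expect_true(all(cache$vals[[op$to]] %in% c(0, 1)))
    }
  }
})

test_that("forward is deterministic and independent of previous samples", {
  set.seed(5)
  m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 4L))
  a <- uweEncode(randomGray(8, 8))
  b <- uweEncode(randomGray(8, 8))
  outA1 <- modelForward(m, a)
  modelForward(m, b)  # pollute internal state with a different sample
  outA2 <- modelForward(m, a)
  expect_identical(planes(outA1), planes(outA2))
})

test_that("the network rejects non-binary input and bad sizes", {
  set.seed(6)
  m <- buildUVTSNN(networkSpec(depth = 2L, baseChannels = 2L))
  arr <- array(0, c(8, 8, 8, 1)); arr[1, 1, 1, 1] <- 0.5
  expect_error(vtsnn:::.forwardBatch(m, arr, 1L), "binary")
  odd <- array(0, c(8, 6, 6, 1))
  expect_error(vtsnn:::.forwardBatch(m, odd, 1L), "pad")
  st4 <- SpikePlaneStack(array(0, c(4, 8, 8)))
  expect_error(modelForward(m, st4), "depth|T")
})

test_that("checkpoints round-trip spec and weights exactly", {
  set.seed(7)
  m <- buildUVTSNN(networkSpec(depth = 1L, baseChannels = 3L,
                               bodyNeuron = neuronConfig("LIF", vThreshold = 0.9,
                                                         tau = 1.2)))
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(modelWeights(m), modelWeights(m2))
  expect_equal(m2@spec@bodyNeuron@tau, 1.2)
  st <- uweEncode(randomGray(8, 8))
  expect_identical(planes(modelForward(m, st)), planes(modelForward(m2, st)))
  expect_error(loadCheckpoint(file.path(tempdir(), "nope.rds")), "not found")
})
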