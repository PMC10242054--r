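test_that("n-mode product matches identity, summation and brute-force cases", {
  set.seed(1)
  p <- array(rnorm(24), c(2, 3, 4))
  for (m in 1:3)
    expect_equal(nModeProduct(p, diag(dim(p)[m]), m), p)

  ones <- array(1, c(2, 2, 2))
  q <- nModeProduct(ones, matrix(1, 1, 2), 1)
  expect_equal(dim(q), c(1L, 2L, 2L))
  expect_true(all(q == 2))

  p <- array(sample(-5:5, 60, replace = TRUE), c(3, 4, 5))
  b <- matrix(sample(-3:3, 8, replace = TRUE), 2, 4)
  q <- nModeProduct(p, b, 2)
  # triple-loop oracle
  expect_equal(dim(q), c(3L, 2L, 5L))
  for (i in 1:3) for (j in 1:2) for (l in 1:5)
    expect_equal(q[i, j, l], sum(b[j, ] * p[i, , l]))

  expect_error(nModeProduct(p, matrix(1, 2, 3), 2), "mismatch")
})

test_that("bit-plane encoding produces the binary expansion, MSB first", {
  expect_equal(planes(uweEncode(GrayImage(matrix(0, 1, 1))))[, 1, 1], rep(0, 8))
  expect_equal(planes(uweEncode(GrayImage(matrix(255, 1, 1))))[, 1, 1], rep(1, 8))
  # 146 = 128 + 16 + 2
  expect_equal(planes(uweEncode(GrayImage(matrix(146, 1, 1))))[, 1, 1],
               c(1, 0, 0, 1, 0, 0, 1, 0))
  expect_error(GrayImage(matrix(256, 1, 1)), "pixels")
  expect_error(GrayImage(matrix(3.5, 2, 2)), "integer")
})

test_that("weighted-sum identity: planes weighted by 2^s reproduce the image", {
  set.seed(7)
  img <- randomGray(9, 13)
  st <- uweEncode(img)
  w <- planeWeights(st)
  expect_equal(w, 2^(7:0))
  recon <- apply(sweep(planes(st), 1, w, "*"), c(2, 3), sum)
  expect_equal(recon, pixels(img))
})

test_that("round trip decode(encode(x)) is the identity, exhaustively", {
  vals <- GrayImage(matrix(0:255, 16, 16))
  expect_identical(pixels(uwdDecode(uweEncode(vals))), pixels(vals))
  set.seed(3)
  for (i in 1:20) {
    img <- randomGray(28, 28)
    expect_identical(pixels(uwdDecode(uweEncode(img))), pixels(img))
  }
  # all-ones stack decodes to 255 everywhere
  st <- SpikePlaneStack(array(1, c(8, 2, 2)))
  expect_true(all(pixels(uwdDecode(st)) == 255))
})

test_that("decoder validates binarity and depth", {
  bad <- array(0, c(8, 2, 2)); bad[1, 1, 1] <- 0.5
  expect_error(SpikePlaneStack(bad), "binary")
  st <- uweEncode(randomGray(4, 4))
  expect_error(uwdDecode(st, codecConfig(nBits = 4L)), "depth")
})

test_that("TTFS latency coding follows the stated timing rules", {
  cfg <- codecConfig()
  img <- GrayImage(matrix(c(200, 0, 100, 200), 2, 2))
  st <- ttfsEncode(img, T = 8, config = cfg)
  expect_s4_class(st, "SpikePlaneStack")
  expect_equal(codingType(st), "latency")
  pl <- planes(st)
  # maximal pixel spikes at time 0 (plane 1)
  expect_equal(pl[1, 1, 1], 1)
  expect_equal(pl[1, 2, 2], 1)
  # zero pixel: t = T, outside the window, no spike at all
  expect_equal(sum(pl[, 2, 1]), 0)
  # half of max with floor rounding: single spike at step 4 (plane 5)
  expect_equal(which(pl[, 1, 2] == 1), 5L)
  expect_equal(sum(pl[, 1, 2]), 1)
  # each pixel emits at most one spike
  expect_true(all(apply(pl, c(2, 3), sum) <= 1))
})

test_that("TTFS warns and stays silent on an all-zero image", {
  expect_warning(st <- ttfsEncode(GrayImage(matrix(0, 3, 3)), T = 8), "no spikes")
  expect_equal(sum(planes(st)), 0)
})

test_that("TTFS at T = 8 collides distinct 8-bit values; bit-plane coding never does", {
  img <- GrayImage(matrix(0:255, 1, 256))
  codes <- planes(ttfsEncode(img, T = 8))
  key <- apply(codes, 3, paste, collapse = "")
  expect_lt(length(unique(key)), 256)      # lossy after time quantisation
  # exhibit one concrete collision of two distinct values
  dup <- which(duplicated(key))[1]
  twin <- which(key == key[dup])[1]
  expect_false(dup == twin)
  expect_identical(codes[, 1, dup], codes[, 1, twin])
  # the bit-plane code separates all 256 values
  ucodes <- planes(uweEncode(img))
  expect_equal(length(unique(apply(ucodes, 3, paste, collapse = ""))), 256L)
})

test_that("membrane-potential decoding is tanh of the geometric spike sum", {
  z <- SpikePlaneStack(array(0, c(8, 2, 2)))
  expect_true(all(mpdDecode(z) == 0))
  one <- array(0, c(8, 1, 1)); one[1, 1, 1] <- 1  # most significant plane
  expect_equal(as.numeric(mpdDecode(SpikePlaneStack(one))), tanh(1),
               tolerance = 1e-12)
  # bounded in (-1, 1) and monotone: adding a spike never decreases output
  set.seed(5)
  pl <- array(rbinom(8 * 4 * 4, 1, 0.4), c(8, 4, 4))
  v0 <- mpdDecode(SpikePlaneStack(pl))
  expect_true(all(v0 > -1 & v0 < 1))
  zeros <- which(pl == 0)
  for (i in sample(zeros, 5)) {
    pl2 <- pl; pl2[i] <- 1
    expect_true(all(mpdDecode(SpikePlaneStack(pl2)) >= v0))
  }
})
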