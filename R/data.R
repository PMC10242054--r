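#' Corrupt an image with Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation \code{eta}
#' on the unit image scale: \code{pixel/(2^n - 1) + N(0, eta^2)}, clipped to
#' [0, 1] and re-quantized to the image's bit depth (the bit-plane encoder
#' requires integer pixels). Fully reproducible given the seed.
#'
#' @param image a \code{GrayImage}.
#' @param config a \code{NoiseConfig} (noise level \code{eta} and seed).
#' @return a noisy \code{GrayImage} of the same shape and bit depth.
#' @export
addGaussianNoise <- function(image, config) {
  stopifnot(is(image, "GrayImage"), is(config, "NoiseConfig"))
  peak <- 2^nBits(image) - 1
  p <- pixels(image) / peak
  set.seed(config@seed)
  noisy <- p + stats::rnorm(length(p), mean = 0, sd = config@eta)
  noisy <- pmin(pmax(noisy, 0), 1)
  GrayImage(matrix(round(noisy * peak), nrow(p), ncol(p)), nBits = nBits(image))
}

## One synthetic glyph: bright strokes (random line segments and arcs) on a
## dark background, lightly smoothed, in the spirit of handwritten-digit data.
.synthImage <- function(H, W) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  img <- matrix(0, H, W)
  nStrokes <- sample(2:4, 1)
  for (s in seq_len(nStrokes)) {
    kind <- sample(c("segment", "arc"), 1)
    width <- stats::runif(1, 0.8, 1.6)
    amp <- stats::runif(1, 180, 255)
    if (kind == "segment") {
      a <- c(stats::runif(1, 0.15, 0.85) * H, stats::runif(1, 0.15, 0.85) * W)
      b <- c(stats::runif(1, 0.15, 0.85) * H, stats::runif(1, 0.15, 0.85) * W)
      ab <- b - a
      len2 <- sum(ab^2)
      tpar <- ((yy - a[1]) * ab[1] + (xx - a[2]) * ab[2]) / max(len2, 1e-9)
      tpar <- pmin(pmax(tpar, 0), 1)
      dist2 <- (yy - (a[1] + tpar * ab[1]))^2 + (xx - (a[2] + tpar * ab[2]))^2
    } else {
      ctr <- c(stats::runif(1, 0.25, 0.75) * H, stats::runif(1, 0.25, 0.75) * W)
      rad <- stats::runif(1, 0.15, 0.35) * min(H, W)
      th0 <- stats::runif(1, 0, 2 * pi)
      th1 <- th0 + stats::runif(1, pi / 2, 2 * pi)
      ang <- atan2(yy - ctr[1], xx - ctr[2])
      rr <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
      dAng <- (ang - th0) %% (2 * pi)
      onArc <- dAng <= (th1 - th0)
      dist2 <- (rr - rad)^2
      dist2[!onArc] <- Inf
    }
    img <- pmax(img, amp * exp(-dist2 / (2 * width^2)))
  }
  # light binomial smoothing, then re-quantize
  sm <- img
  sm[2:(H - 1), ] <- (img[1:(H - 2), ] + 2 * img[2:(H - 1), ] + img[3:H, ]) / 4
  img2 <- sm
  img2[, 2:(W - 1)] <- (sm[, 1:(W - 2)] + 2 * sm[, 2:(W - 1)] + sm[, 3:W]) / 4
  pmin(pmax(round(img2), 0), 255)
}

#' Generate a synthetic clean/noisy image dataset
#'
#' Draws seeded 8-bit images with the gross statistics of handwritten-glyph
#' data -- a dark background crossed by a few bright, slightly smoothed
#' strokes and arcs -- and pairs each with a Gaussian-corrupted copy at noise
#' level \code{eta}. The generator exists so that every pipeline stage is
#' testable without downloading external datasets.
#'
#' @param nImages number of images (>= 1).
#' @param H,W image size in pixels (default 28 x 28).
#' @param eta Gaussian noise level on the unit scale (default 0.2).
#' @param seed RNG seed; the whole bundle is a pure function of it.
#' @return a \code{DatasetBundle}.
#' @examples
#' b <- generateSynthetic(3, seed = 7)
#' length(b)
#' @export
generateSynthetic <- function(nImages, H = 28L, W = 28L, eta = 0.2,
                              seed = 1L) {
  if (nImages < 1L) stop("nImages must be >= 1")
  if (H < 4L || W < 4L) stop("image dimensions must be at least 4 x 4")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  set.seed(seed)
  clean <- vector("list", nImages)
  noisy <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    img <- GrayImage(.synthImage(H, W))
    clean[[i]] <- img
    p <- pixels(img) / 255
    ns <- pmin(pmax(p + stats::rnorm(length(p), 0, eta), 0), 1)
    noisy[[i]] <- GrayImage(matrix(round(ns * 255), H, W))
  }
  new("DatasetBundle", clean = clean, noisy = noisy, eta = eta)
}

#' Read images from an IDX container file
#'
#' Parses the big-endian IDX format used to distribute handwritten-digit
#' datasets: magic bytes \code{00 00 <type> <ndims>}, big-endian uint32
#' dimensions, then raw data. Supports unsigned-byte (type 0x08) files of 2
#' or 3 dimensions (a single image or a stack of images).
#'
#' @param path file path.
#' @return list of 8-bit \code{GrayImage}s.
#' @export
readIDX <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || magic[1] != as.raw(0) || magic[2] != as.raw(0))
    stop("bad IDX magic number in ", path)
  if (magic[3] != as.raw(0x08))
    stop("unsupported IDX data type 0x", as.character(magic[3]),
         " (only unsigned byte 0x08 is supported)")
  ndim <- as.integer(magic[4])
  if (!ndim %in% c(2L, 3L)) stop("unsupported IDX dimensionality: ", ndim)
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims <= 0)) stop("truncated IDX header in ", path)
  total <- prod(dims)
  data <- readBin(con, "integer", n = total, size = 1L, signed = FALSE)
  if (length(data) < total) stop("truncated IDX data in ", path)
  if (ndim == 2L) {
    m <- matrix(data, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    return(list(GrayImage(m)))
  }
  nimg <- dims[1]; H <- dims[2]; W <- dims[3]
  lapply(seq_len(nimg), function(i) {
    off <- (i - 1) * H * W
    GrayImage(matrix(data[off + seq_len(H * W)], nrow = H, ncol = W,
                     byrow = TRUE))
  })
}

#' Write images to an IDX container file
#'
#' Inverse of \code{\link{readIDX}}: writes a 3-D unsigned-byte IDX file
#' (images x rows x cols, big-endian header, row-major pixel order).
#'
#' @param images list of 8-bit \code{GrayImage}s of identical shape.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeIDX <- function(images, path) {
  if (is(images, "GrayImage")) images <- list(images)
  stopifnot(length(images) >= 1L)
  d <- dim(pixels(images[[1]]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0, 0, 0x08, 3)), con)
  writeBin(as.integer(c(length(images), d[1], d[2])), con, size = 4L,
           endian = "big")
  for (img in images) {
    p <- pixels(img)
    if (!identical(dim(p), d)) stop("all images must share one shape")
    writeBin(as.integer(t(p)), con, size = 1L)
  }
  invisible(path)
}

#' Read an 8-bit grayscale image file (PNG or PGM)
#'
#' PNGs are read through the \pkg{png} package (color images are converted to
#' grayscale by channel averaging); PGM supports both the plain-text (P2) and
#' binary (P5) variants.
#'
#' @param path file path ending in \code{.png} or \code{.pgm}.
#' @return a \code{GrayImage}.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                         c(1, 2), mean)
    return(GrayImage(round(a * 255)))
  }
  if (ext == "pgm") return(.readPGM(path))
  stop("unsupported image format: .", ext)
}

#' Write an 8-bit grayscale image file (PNG or PGM)
#'
#' @param image a \code{GrayImage} (bit depths above 8 are rejected).
#' @param path output path ending in \code{.png} or \code{.pgm} (plain-text
#'   P2 PGM is written).
#' @return \code{path}, invisibly.
#' @export
saveImageFile <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  if (nBits(image) > 8L) stop("only 8-bit images can be written")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pixels(image) / 255, path)
  } else if (ext == "pgm") {
    p <- pixels(image)
    lines <- c("P2", sprintf("%d %d", ncol(p), nrow(p)), "255",
               apply(p, 1, paste, collapse = " "))
    writeLines(lines, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

.readPGM <- function(path) {
  head2 <- readBin(path, "raw", n = 2L)
  magic <- rawToChar(head2)
  if (magic == "P2") {
    toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    vals <- as.numeric(toks[-1])
    W <- vals[1]; H <- vals[2]; maxv <- vals[3]
    px <- vals[-(1:3)]
    if (length(px) != H * W) stop("truncated PGM file")
    return(GrayImage(matrix(round(px / maxv * 255), H, W, byrow = TRUE)))
  }
  if (magic == "P5") {
    con <- file(path, "rb")
    on.exit(close(con))
    readToken <- function() {
      tok <- ""
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L) stop("truncated PGM header")
        if (grepl("[ \t\r\n]", ch)) { if (nzchar(tok)) return(tok) }
        else if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                       if (!length(c2) || c2 == "\n") break } }
        else tok <- paste0(tok, ch)
      }
    }
    stopifnot(readToken() == "P5")
    W <- as.integer(readToken()); H <- as.integer(readToken())
    maxv <- as.integer(readToken())
    px <- readBin(con, "integer", n = H * W, size = 1L, signed = FALSE)
    if (length(px) != H * W) stop("truncated PGM file")
    return(GrayImage(matrix(round(px / maxv * 255), H, W, byrow = TRUE)))
  }
  stop("not a PGM file: ", path)
}
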