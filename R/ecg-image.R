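#' Default render configuration for paper-format ECG images
#'
#' @param mmPerS paper speed (mm/s), default 25.
#' @param mmPerMv amplitude scale (mm/mV), default 10.
#' @param pxPerMm raster resolution (pixels/mm), default 2.
#' @param seconds seconds of signal rendered per lead strip, default 10.
#' @param mvRange vertical amplitude range per strip (mV).
#' @return List of render parameters.
#' @export
ecgImageConfig <- function(mmPerS = 25, mmPerMv = 10, pxPerMm = 2,
                           seconds = 10, mvRange = c(-1.5, 1.5)) {
  list(mmPerS = mmPerS, mmPerMv = mmPerMv, pxPerMm = pxPerMm,
       seconds = seconds, mvRange = mvRange)
}

#' Render a multi-lead ECG segment as a paper-format image
#'
#' Deterministically rasterizes each lead as a horizontal strip at the
#' configured paper speed and gain, draws the standard 5 mm grid (pixel value
#' 0.5) and overlays the trace (value 1) on the background (value 0). Identical
#' input and configuration always produce a bit-identical image.
#'
#' @param leads numeric matrix (samples x leads) or vector; amplitudes in mV.
#' @param fs sampling rate in Hz.
#' @param config render parameters from [ecgImageConfig()].
#' @return An [EcgImage-class].
#' @export
renderEcgImage <- function(leads, fs, config = ecgImageConfig()) {
  leads <- as.matrix(leads)
  if (!nrow(leads) || !ncol(leads))
    stopWith("autonomiq_input_error", "empty segment")
  nS <- min(nrow(leads), round(config$seconds * fs))
  width <- round(config$seconds * config$mmPerS * config$pxPerMm)
  height <- round(diff(config$mvRange) * config$mmPerMv * config$pxPerMm)
  gridStep <- round(5 * config$pxPerMm)
  M <- ncol(leads)
  pix <- matrix(0, nrow = height * M, ncol = width)
  leadRows <- vector("list", M)
  for (m in seq_len(M)) {
    rows <- (m - 1) * height + seq_len(height)
    leadRows[[m]] <- rows
    strip <- matrix(0, height, width)
    strip[seq(1, height, by = gridStep), ] <- 0.5
    strip[, seq(1, width, by = gridStep)] <- 0.5
    # trace: one sample per pixel column, vertically connected
    colIdx <- pmin(nS, pmax(1L, round(seq(1, nS, length.out = width))))
    v <- leads[colIdx, m]
    y <- round((config$mvRange[2] - v) * config$mmPerMv * config$pxPerMm) + 1L
    y <- pmin(height, pmax(1L, y))
    prev <- y[1]
    for (cc in seq_len(width)) {
      strip[min(prev, y[cc]):max(prev, y[cc]), cc] <- 1
      prev <- y[cc]
    }
    pix[rows, ] <- strip
  }
  methods::new("EcgImage", pixels = pix, leadRows = leadRows,
               config = config)
}

setMethod("show", "EcgImage", function(object) {
  cat(sprintf("EcgImage: %d lead strip(s), %d x %d px\n",
              length(object@leadRows), nrow(object@pixels),
              ncol(object@pixels)))
})

#' Structural similarity between two images
#'
#' Global SSIM from means, standard deviations and cross-covariance:
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'   {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, where `L` is the dynamic
#' range. Defaults follow the standard convention `K1 = 0.01`, `K2 = 0.03`;
#' both are configurable. The result lies in \[-1, 1\], is symmetric, and
#' equals 1 for identical inputs.
#'
#' @param x,y numeric matrices or vectors of identical dimension.
#' @param L dynamic range of the pixel values (default 1).
#' @param K1,K2 stabilization constants.
#' @return SSIM value in \[-1, 1\].
#' @examples
#' ssimIndex(matrix(2, 4, 4), matrix(4, 4, 4))  # (16 + C1) / (20 + C1)
#' @export
ssimIndex <- function(x, y, L = 1, K1 = 0.01, K2 = 0.03) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stopWith("autonomiq_input_error", "image dimensions differ")
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

#' Similarity between two multi-lead ECG images
#'
#' Computes the per-strip SSIM for every pair of lead strips (M x M pairs for
#' M leads) and returns the mean as the final similarity.
#'
#' @param x,y [EcgImage-class] objects with identical strip geometry.
#' @param ... passed to [ssimIndex()].
#' @return Mean SSIM over all lead-strip pairs.
#' @export
ecgImageSimilarity <- function(x, y, ...) {
  sx <- lapply(x@leadRows, function(r) x@pixels[r, , drop = FALSE])
  sy <- lapply(y@leadRows, function(r) y@pixels[r, , drop = FALSE])
  vals <- outer(seq_along(sx), seq_along(sy),
                Vectorize(function(i, j) ssimIndex(sx[[i]], sy[[j]], ...)))
  mean(vals)
}

#' Write an ECG image as PNG (debug output)
#'
#' @param image an [EcgImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly. Requires the `png` package.
#' @export
writeEcgImagePng <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopWith("autonomiq_io_error", "the 'png' package is required for PNG output")
  png::writePNG(1 - image@pixels, path)
  invisible(path)
}
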