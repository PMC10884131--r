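# Small numerical helpers shared across modules.

#' Bilinear lookup of image values at fractional pixel coordinates
#'
#' Coordinates are 1-based pixel centers; points are clamped to the image
#' border before interpolation.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of equal length.
#' @return interpolated values.
#' @export
bilinear_lookup <- function(img, row, col) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(row, 1), H)
  c_ <- pmin(pmax(col, 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c_), W - 1L)
  fr <- r - r0; fc <- c_ - c0
  i00 <- (c0 - 1) * H + r0
  v00 <- img[i00];       v10 <- img[i00 + 1]
  v01 <- img[i00 + H];   v11 <- img[i00 + H + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Bilinear resize of a matrix to a new shape
#'
#' Pixel-center alignment: destination pixel j samples source coordinate
#' `(j - 0.5) * src/dst + 0.5`, so constant images are preserved exactly and
#' the physical field of view is unchanged.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output shape.
#' @return `out_h x out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  rows <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  cols <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  grid_r <- rep(rows, times = out_w)
  grid_c <- rep(cols, each = out_h)
  matrix(bilinear_lookup(img, grid_r, grid_c), out_h, out_w)
}

gauss_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian smoothing with edge renormalization (kernel mass
# falling outside the image is redistributed, so constants are preserved).
gauss_smooth2d <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- gauss_kernel_1d(sigma_px)
  sm <- conv1_renorm(mat, k)
  t(conv1_renorm(t(sm), k))
}

# Convolve each column with kernel k, renormalizing at the edges.
conv1_renorm <- function(mat, k) {
  H <- nrow(mat); r <- (length(k) - 1L) / 2L
  out <- matrix(0, H, ncol(mat))
  wsum <- numeric(H)
  for (i in seq_along(k)) {
    off <- i - r - 1L
    src <- seq_len(H) + off
    ok <- src >= 1L & src <= H
    out[ok, ] <- out[ok, ] + k[i] * mat[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + k[i]
  }
  out / wsum
}

# Unit-marginal-variance smoothed white noise field (one slice).
smooth_noise_slice <- function(H, W, sigma_px) {
  z <- matrix(stats::rnorm(H * W), H, W)
  if (sigma_px <= 0) return(z)
  k <- gauss_kernel_1d(sigma_px)
  zs <- conv1_renorm(z, k)
  zs <- t(conv1_renorm(t(zs), k))
  # separable filtering of white noise: interior variance = (sum k_i^2)^2
  zs / sum(k^2)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
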