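voxels_of <- function(x) if (inherits(x, "image_stack")) x$voxels else x

check_same_shape <- function(ref, test) {
  a <- voxels_of(ref); b <- voxels_of(test)
  if (!identical(dim(a), dim(b))) stop("stacks have different shapes")
  list(ref = a, test = b)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the dynamic range (max - min) of the reference stack.
#' Zero for identical stacks; an error for a flat (zero-range) reference.
#'
#' @param ref,test [image_stack()]s or arrays of identical shape.
#' @return nonnegative scalar.
#' @export
nrmse <- function(ref, test) {
  v <- check_same_shape(ref, test)
  rng <- diff(range(v$ref))
  if (rng == 0) stop("reference has zero dynamic range")
  sqrt(mean((v$test - v$ref)^2)) / rng
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 * log10(peak^2 / MSE)`. The peak defaults to 100, the top of the
#' uptake scale; use 255 for raw 8-bit comparisons. Identical stacks give
#' `Inf` (the MSE = 0 sentinel).
#'
#' @param ref,test stacks or arrays of identical shape.
#' @param peak signal peak (default 100).
#' @return scalar in dB, `Inf` when MSE is 0.
#' @export
psnr <- function(ref, test, peak = 100) {
  v <- check_same_shape(ref, test)
  mse <- mean((v$test - v$ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Standard SSIM with an 11 x 11 Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, and dynamic range `L = 100` (the uptake
#' scale), computed per slice over the valid (fully windowed) region and
#' averaged over slices. For images smaller than the window, a single
#' uniform window covering the whole image is used.
#'
#' @param ref,test stacks or arrays of identical shape.
#' @param win window side (odd, default 11).
#' @param sigma Gaussian window sigma in pixels.
#' @param K1,K2 stability constants.
#' @param L dynamic range of the data.
#' @return scalar in `[-1, 1]`; 1 for identical inputs.
#' @export
ssim <- function(ref, test, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 100) {
  v <- check_same_shape(ref, test)
  d <- dim(v$ref)
  if (length(d) == 2L) { dim(v$ref) <- c(d, 1L); dim(v$test) <- c(d, 1L); d <- dim(v$ref) }
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mean(vapply(seq_len(d[3]), function(k)
    ssim_slice(v$ref[, , k], v$test[, , k], win, sigma, C1, C2), 0))
}

ssim_slice <- function(x, y, win, sigma, C1, C2) {
  if (min(dim(x)) < win) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  r <- (win - 1L) / 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  f <- function(m) conv2_valid_sep(m, k)
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2; vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

# 'valid' separable 2-D convolution with a symmetric 1-D kernel k
conv2_valid_sep <- function(m, k) {
  n <- length(k); H <- nrow(m); W <- ncol(m)
  a <- matrix(0, H - n + 1L, W)
  for (i in seq_len(n)) a <- a + k[i] * m[i:(H - n + i), , drop = FALSE]
  b <- matrix(0, H - n + 1L, W - n + 1L)
  for (i in seq_len(n)) b <- b + k[i] * a[, i:(W - n + i), drop = FALSE]
  b
}

#' Joint histogram of two co-registered stacks
#'
#' Counts voxel pairs over an `n_bins x n_bins` grid spanning `[0,100]^2`
#' (reference on rows, test on columns). Raw counts are returned; the
#' `log10(count + 1)` display transform is left to the plotting helper.
#'
#' @param ref,test uptake-scale stacks or arrays of identical shape.
#' @param n_bins number of bins per axis (default 100).
#' @param limits value range covered (default `c(0, 100)`).
#' @return list with `counts` (matrix), `edges` (bin edges).
#' @export
joint_histogram <- function(ref, test, n_bins = 100L, limits = c(0, 100)) {
  v <- check_same_shape(ref, test)
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1L)
  bin <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                               1L), n_bins)
  counts <- unclass(table(factor(bin(v$ref), levels = seq_len(n_bins)),
                          factor(bin(v$test), levels = seq_len(n_bins))))
  dimnames(counts) <- NULL
  list(counts = counts, edges = edges)
}

#' Per-segment paired comparison of two error sets
#'
#' Mirrors the segment-wise statistical design: for each of the 17
#' segments, the paired differences (or, if `errors_b` is omitted, the
#' errors themselves against zero) are tested with a paired t-test when a
#' Shapiro-Wilk screen does not reject normality at alpha = 0.05, and a
#' Wilcoxon signed-rank test otherwise; two-sided p-values at alpha = 0.05.
#'
#' @param errors_a 17 x n matrix of per-segment errors (one column per case).
#' @param errors_b optional matching matrix; when given, `a - b` is tested.
#' @param alpha significance level (default 0.05).
#' @return data frame: `segment`, `mean_diff`, `test`, `p`, `significant`.
#' @export
paired_segment_comparison <- function(errors_a, errors_b = NULL, alpha = 0.05) {
  errors_a <- as.matrix(errors_a)
  stopifnot(nrow(errors_a) == 17L)
  n <- ncol(errors_a)
  if (n < 5L) stop("need at least 5 cases for the segment-wise comparison")
  if (!is.null(errors_b)) {
    errors_b <- as.matrix(errors_b)
    stopifnot(identical(dim(errors_a), dim(errors_b)))
    d <- errors_a - errors_b
  } else d <- errors_a
  res <- lapply(1:17, function(s) {
    ds <- d[s, ]
    if (stats::sd(ds) == 0) {
      p <- if (all(ds == 0)) 1 else 0   # constant differences: degenerate
      return(data.frame(segment = s, mean_diff = mean(ds),
                        test = "degenerate", p = p, significant = p < alpha))
    }
    normal <- stats::shapiro.test(ds)$p.value >= 0.05
    if (normal) {
      ht <- stats::t.test(ds)
      test <- "t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(ds, exact = FALSE))
      test <- "wilcoxon"
    }
    data.frame(segment = s, mean_diff = mean(ds), test = test,
               p = ht$p.value, significant = ht$p.value < alpha)
  })
  do.call(rbind, res)
}

#' Voxel-wise similarity report for one case
#'
#' @param pet reference stack; `spect`, `spect_spt` test stacks (the
#'   latter optional).
#' @param n_bins joint-histogram bins.
#' @return data frame with one row per method: `method`, `nrmse`,
#'   `psnr_db`, `ssim`; joint histograms attached as attribute
#'   `"joint_hist"` (named list).
#' @export
similarity_report <- function(pet, spect, spect_spt = NULL, n_bins = 100L) {
  methods <- list(spect = spect)
  if (!is.null(spect_spt)) methods$spect_spt <- spect_spt
  rows <- lapply(names(methods), function(m)
    data.frame(method = m, nrmse = nrmse(pet, methods[[m]]),
               psnr_db = psnr(pet, methods[[m]]),
               ssim = ssim(pet, methods[[m]])))
  out <- do.call(rbind, rows)
  attr(out, "joint_hist") <- lapply(methods, function(s)
    joint_histogram(pet, s, n_bins))
  out
}
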