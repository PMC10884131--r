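ref_stack <- function(seed = 1, d = c(16, 16, 2)) {
  set.seed(seed)
  array(stats::runif(prod(d)) * 100, d)
}

test_that("nrmse: identity, closed form, and permutation symmetry", {
  x <- ref_stack()
  expect_equal(nrmse(x, x), 0)
  ref <- array(rep(c(0, 100), each = 8), c(4, 4, 1))
  expect_equal(nrmse(ref, ref + 10), 0.1)
  set.seed(2); perm <- sample(length(x))
  y <- x + stats::rnorm(length(x))
  xp <- array(x[perm], dim(x)); yp <- array(y[perm], dim(x))
  expect_equal(nrmse(x, y), nrmse(xp, yp))
  expect_error(nrmse(array(5, c(2, 2, 1)), array(5, c(2, 2, 1))), "dynamic range")
  expect_error(nrmse(x, x[, , 1, drop = FALSE]), "shapes")
})

test_that("psnr: closed forms and sentinel", {
  x <- ref_stack()
  expect_equal(psnr(x, x + 10), 20)            # 10 log10(100^2 / 100)
  expect_equal(psnr(x, x + 100, peak = 100), 0) # MSE = peak^2
  expect_identical(psnr(x, x), Inf)
})

test_that("ssim: identity, anticorrelation, and the uniform-window oracle", {
  pair <- quiet_pair(noise_scale = 0.5, seed = 4)
  v <- pair$spect$voxels
  expect_equal(ssim(v, v), 1)
  expect_lt(ssim(v, 100 - v), 0)
  # 8x8 pair: single uniform window, checked against the direct formula
  set.seed(5)
  a <- matrix(stats::runif(64) * 100, 8, 8)
  b <- a * 0.7 + 10 + matrix(stats::rnorm(64, sd = 5), 8, 8)
  C1 <- (0.01 * 100)^2; C2 <- (0.03 * 100)^2
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  direct <- ((2 * ma * mb + C1) * (2 * cab + C2)) /
    ((ma^2 + mb^2 + C1) * (va + vb + C2))
  expect_equal(ssim(a, b), direct)
})

test_that("similarity metrics are invariant to common quarter-turn rotations", {
  x <- ref_stack(seed = 6, d = c(12, 12, 1))
  y <- x + array(stats::rnorm(144, sd = 4), dim(x))
  y <- pmin(pmax(y, 0), 100)
  rot90 <- function(a) array(t(apply(a[, , 1], 2, rev)), dim(a))
  expect_equal(nrmse(x, y), nrmse(rot90(x), rot90(y)))
  expect_equal(psnr(x, y), psnr(rot90(x), rot90(y)))
  expect_equal(ssim(x, y), ssim(rot90(x), rot90(y)))
})

test_that("psnr strictly decreases along a noise ladder", {
  x <- ref_stack(seed = 7)
  set.seed(8)
  eps <- array(stats::rnorm(length(x)), dim(x))
  vals <- vapply(c(1, 2, 5, 10, 20), function(s) psnr(x, x + s * eps), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("joint histograms count exactly and conserve marginals", {
  x <- ref_stack(seed = 9)
  jh <- joint_histogram(x, x, n_bins = 20)
  expect_equal(sum(jh$counts), length(x))
  expect_equal(sum(diag(jh$counts)), length(x))   # identical stacks: diagonal
  # 4-voxel toy pair against a hand count
  ref <- array(c(5, 15, 15, 95), c(2, 2, 1))
  test <- array(c(5, 15, 25, 5), c(2, 2, 1))
  jh2 <- joint_histogram(ref, test, n_bins = 10)
  expect_equal(jh2$counts[1, 1], 1)   # (5, 5)
  expect_equal(jh2$counts[2, 2], 1)   # (15, 15)
  expect_equal(jh2$counts[2, 3], 1)   # (15, 25)
  expect_equal(jh2$counts[10, 1], 1)  # (95, 5)
  expect_equal(sum(jh2$counts), 4)
  # marginal over the test axis equals the reference 1-D histogram
  y <- ref_stack(seed = 10)
  jh3 <- joint_histogram(x, y, n_bins = 25)
  edges <- jh3$edges
  ref_hist <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                                 1), 25), 25)
  expect_equal(unname(rowSums(jh3$counts)), ref_hist)
})

test_that("paired segment comparison flags planted shifts and not nulls", {
  set.seed(11)
  n <- 20
  a <- matrix(stats::rnorm(17 * n, sd = 1), 17, n)
  expect_true(all(!paired_segment_comparison(a, a)$significant))
  b <- a; b[4, ] <- b[4, ] + 10
  res <- paired_segment_comparison(b, a)
  expect_equal(nrow(res), 17)
  expect_true(res$significant[4])
  expect_lt(sum(res$significant[-4]), 3)
  expect_error(paired_segment_comparison(a[, 1:3], a[, 1:3]), "at least 5")
  # one-sample mode against zero
  res0 <- paired_segment_comparison(b - a)
  expect_true(res0$significant[4])
})

test_that("similarity_report assembles per-method rows with histograms", {
  pair <- quiet_pair(noise_scale = 0.5, seed = 12)
  pp <- preprocess_pair(pair$spect, pair$pet)
  rep_ <- similarity_report(pp$pet, pp$spect)
  expect_equal(rep_$method, "spect")
  expect_true(rep_$nrmse > 0 && rep_$ssim < 1)
  expect_named(attr(rep_, "joint_hist"), "spect")
})
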