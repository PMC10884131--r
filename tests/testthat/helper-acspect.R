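# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops, separate from the package's vectorized implementations.

quiet_pair <- function(matrix_size = 48, noise_scale = 0, seed = 1,
                       defects = list(), attenuation = NULL, ...) {
  cfg <- phantom_config(matrix_size = matrix_size, noise_scale = noise_scale,
                        seed = seed, ...)
  generate_patient_pair(cfg, defects = defects, attenuation = attenuation,
                        seed = seed)
}

# randomized case used by the recovery / null-control cohorts
random_case <- function(i, seed0, matrix_size = 64, attenuation = NULL,
                        noise_scale = 0.5) {
  set.seed(seed0 + i)
  ctr <- (matrix_size + 1) / 2 + stats::runif(2, -2, 2)
  cfg <- phantom_config(matrix_size = matrix_size,
                        ring_center = ctr,
                        endo_radius_mm = 17 * stats::runif(1, 0.92, 1.08),
                        epi_radius_mm = 24 * stats::runif(1, 0.92, 1.08),
                        baseline_uptake = stats::runif(1, 76, 84),
                        noise_scale = noise_scale,
                        seed = seed0 + i)
  generate_patient_pair(cfg, attenuation = attenuation, seed = seed0 + i)
}

# --- brute-force AHA segment quantifier (explicit loops) --------------------

oracle_bilinear <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- min(max(r, 1), H); c <- min(max(c, 1), W)
  r0 <- min(floor(r), H - 1); c0 <- min(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * img[r0, c0] + fr * (1 - fc) * img[r0 + 1, c0] +
    (1 - fr) * fc * img[r0, c0 + 1] + fr * fc * img[r0 + 1, c0 + 1]
}

oracle_ray_max <- function(img, center, theta_deg, step = 0.5,
                           oversample = 1) {
  H <- nrow(img); W <- ncol(img)
  rmax <- min(center[1] - 1, H - center[1], center[2] - 1, W - center[2])
  radii <- seq(0, rmax, by = step / oversample)
  best <- -Inf
  for (r in radii) {
    rr <- center[1] - sin(theta_deg * pi / 180) * r
    cc <- center[2] + cos(theta_deg * pi / 180) * r
    v <- oracle_bilinear(img, rr, cc)
    if (v > best) best <- v
  }
  best
}

oracle_slab_of_slice <- function(n) {
  base <- n %/% 7; rem <- n %% 7
  sizes <- rep(base, 7)
  if (rem > 0) for (j in 1:rem) sizes[j] <- sizes[j] + 1
  rings <- c(sum(sizes[1:2]), sum(sizes[3:4]), sum(sizes[5:6]), sizes[7])
  rep(c("basal", "mid", "apical", "apex"), times = rings)
}

oracle_segment_of <- function(theta, ring) {
  theta <- theta %% 360
  if (ring == "apex") return(17L)
  if (ring == "apical") {
    if (theta >= 45 && theta < 135) return(13L)
    if (theta >= 135 && theta < 225) return(14L)
    if (theta >= 225 && theta < 315) return(15L)
    return(16L)
  }
  base <- if (theta >= 60 && theta < 120) 1L else
    if (theta >= 120 && theta < 180) 2L else
      if (theta >= 180 && theta < 240) 3L else
        if (theta >= 240 && theta < 300) 4L else
          if (theta >= 300) 5L else 6L
  if (ring == "mid") base + 6L else base
}

oracle_segment_table <- function(stack, center) {
  slabs <- oracle_slab_of_slice(dim(stack$voxels)[3])
  sums <- numeric(17); counts <- numeric(17)
  for (k in seq_along(slabs)) {
    img <- stack$voxels[, , k]
    for (a in 0:359) {
      seg <- oracle_segment_of(a, slabs[k])
      v <- oracle_ray_max(img, center, a)
      sums[seg] <- sums[seg] + v
      counts[seg] <- counts[seg] + 1
    }
  }
  sums / counts
}

# --- brute-force AUC by pair counting ---------------------------------------

oracle_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# mean absolute error of selected segments between two uptake stacks
segment_mae <- function(stack_a, stack_ref, segs, center) {
  a <- segment_table(stack_a, center)$value
  b <- segment_table(stack_ref, center)$value
  mean(abs(a[segs] - b[segs]))
}
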