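#' Longitudinal slab partition of a short-axis stack
#'
#' The stack is divided base-to-apex into seven near-equal longitudinal
#' divisions (size difference at most one, larger divisions toward the base);
#' divisions 1-2 form the basal ring, 3-4 the mid ring, 5-6 the apical ring
#' and division 7 the apex. Stacks with fewer than seven slices (but at
#' least four) are accepted with a warning: each ring then receives at least
#' one slice, extras going to the basal then mid ring.
#'
#' @param n_slices number of slices, base to apex.
#' @return a list with `slab_of_slice` (character vector, one of
#'   `basal/mid/apical/apex` per slice), `division_sizes` (7 integers) and
#'   `ring_slices` (named list of slice indices per ring).
#' @export
partition_slabs <- function(n_slices) {
  stopifnot(length(n_slices) == 1L, n_slices == round(n_slices))
  if (n_slices < 4L)
    stop("need at least 4 slices to populate basal/mid/apical/apex rings")
  if (n_slices < 7L) {
    warning("fewer than 7 slices; ring sizes degenerate")
    ring_sizes <- c(basal = 1L, mid = 1L, apical = 1L, apex = 1L)
    extras <- n_slices - 4L
    add <- c(min(extras, 1L), if (extras > 1L) 1L else 0L)
    ring_sizes["basal"] <- ring_sizes["basal"] + add[1]
    ring_sizes["mid"] <- ring_sizes["mid"] + (if (length(add) > 1) add[2] else 0L)
    division_sizes <- c(ring_sizes["basal"], 0L, ring_sizes["mid"], 0L,
                        ring_sizes["apical"], 0L, ring_sizes["apex"])
  } else {
    base <- n_slices %/% 7L
    r <- n_slices %% 7L
    division_sizes <- rep(base, 7L)
    if (r > 0) division_sizes[seq_len(r)] <- division_sizes[seq_len(r)] + 1L
    ring_sizes <- c(basal = sum(division_sizes[1:2]),
                    mid = sum(division_sizes[3:4]),
                    apical = sum(division_sizes[5:6]),
                    apex = division_sizes[7])
  }
  slab <- rep(c("basal", "mid", "apical", "apex"), times = ring_sizes)
  idx <- split(seq_len(n_slices), factor(slab, levels = c("basal", "mid", "apical", "apex")))
  list(slab_of_slice = slab,
       division_sizes = as.integer(division_sizes),
       ring_slices = idx)
}

#' Per-angle radial maximum profiles of one short-axis slice
#'
#' For each integer degree (360 profiles per slice) the maximum intensity is
#' taken along the radial ray from the LV center to the image-inscribed
#' radius, sampled every half pixel with bilinear interpolation.
#'
#' @param slice_img numeric matrix.
#' @param center `c(row, col)`; must lie inside the image.
#' @param n_angles number of equally spaced rays (default 360).
#' @param step radial sampling step in pixels (default 0.5).
#' @return numeric vector of length `n_angles`; element `i` is the maximum
#'   along anatomical angle `i - 1` degrees (see [aha_segment_of()]).
#' @export
radial_max_profiles <- function(slice_img, center, n_angles = 360L, step = 0.5) {
  H <- nrow(slice_img); W <- ncol(slice_img)
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W)
    stop("center must lie inside the image")
  rmax <- min(center[1] - 1, H - center[1], center[2] - 1, W - center[2])
  radii <- seq(0, rmax, by = step)
  th <- (seq_len(n_angles) - 1L) * 360 / n_angles
  stp <- angle_step(th)
  rows <- center[1] + outer(radii, stp$row)   # n_r x n_angles
  cols <- center[2] + outer(radii, stp$col)
  vals <- matrix(bilinear_lookup(slice_img, as.vector(rows), as.vector(cols)),
                 nrow = length(radii))
  apply(vals, 2L, max)
}

#' LV center as the intensity centroid of the middle slice
#' @param stack an [image_stack()] (uptake scale).
#' @return `c(row, col)`.
#' @export
lv_center <- function(stack) {
  mid <- stack$voxels[, , ceiling(n_slices(stack) / 2)]
  s <- sum(mid)
  if (s <= 0) return((dim(mid) + 1) / 2)
  rows <- rowSums(mid); cols <- colSums(mid)
  c(sum(seq_along(rows) * rows) / s, sum(seq_along(cols) * cols) / s)
}

#' Representative AHA 17-segment values of a stack
#'
#' Implements the polar-profile quantifier: the stack is partitioned into
#' seven longitudinal divisions grouped into basal/mid/apical/apex rings;
#' on every slice 360 per-degree radial maximum profiles are taken around
#' the LV center; basal and mid rings are split into six 60-degree sectors
#' (60 profiles per slice per segment), the apical ring into four 90-degree
#' sectors (90 profiles per slice per segment), and the apex slab
#' contributes all 360 profiles of each of its slices to segment #17. Each
#' segment's representative value is the mean of all its per-angle maxima
#' across slices; `n_profiles` records the profile count.
#'
#' @param stack an [image_stack()] on the uptake scale.
#' @param center optional `c(row, col)` LV center; defaults to [lv_center()].
#' @param n_angles angular sampling (default 360, i.e. 1-degree steps).
#' @param step radial sampling step in pixels.
#' @return a `data.frame` with columns `segment`, `value`, `n_profiles`.
#' @export
segment_table <- function(stack, center = NULL, n_angles = 360L, step = 0.5) {
  if (stack$scale != "uptake") stop("segment_table expects an uptake-scale stack")
  if (is.null(center)) center <- lv_center(stack)
  part <- partition_slabs(n_slices(stack))
  th <- (seq_len(n_angles) - 1L) * 360 / n_angles
  sums <- numeric(17L); counts <- integer(17L)
  for (k in seq_len(n_slices(stack))) {
    ring <- part$slab_of_slice[k]
    prof <- radial_max_profiles(stack$voxels[, , k], center, n_angles, step)
    seg <- aha_segment_of(th, ring)
    agg <- rowsum(prof, seg)
    sums[as.integer(rownames(agg))] <- sums[as.integer(rownames(agg))] + agg
    counts <- counts + tabulate(seg, nbins = 17L)
  }
  data.frame(segment = 1:17, value = sums / counts, n_profiles = counts)
}
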