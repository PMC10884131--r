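#' Phantom configuration
#'
#' Describes the simulated left ventricle and the two acquisition
#' geometries. Defaults follow the study conventions: both modalities
#' reconstruct 128 x 128 short-axis slices, SPECT at 2.4 mm pixels and
#' 2.4 mm slices, PET at 1.6 mm pixels and 1.6 mm slices. The LV is an
#' annular myocardium whose endo/epicardial radii taper toward the apex;
#' the apex slab is a filled disc.
#'
#' @param matrix_size pixels per side (even; default 128).
#' @param pet_pixel_mm,pet_slice_mm PET geometry (1.6 mm).
#' @param spect_pixel_mm,spect_slice_mm SPECT geometry (2.4 mm).
#' @param lv_length_mm base-to-apex extent (default 38.4 mm = 16 SPECT
#'   slices = 24 PET slices).
#' @param ring_center `c(row, col)` in pixels, or `NULL` for image center.
#' @param endo_radius_mm,epi_radius_mm radii at the base; both taper
#'   linearly toward the apex (see Details).
#' @param baseline_uptake myocardial uptake in (0, 100].
#' @param noise_scale scale of the Poisson-like perturbation: the voxel
#'   noise standard deviation is `noise_scale * sqrt(intensity)`.
#' @param noise_corr_mm correlation length (Gaussian sigma, mm) of the
#'   noise field; reconstruction-filtered emission images have spatially
#'   smooth noise, not voxel-white noise.
#' @param seed integer seed used by [generate_patient_pair()].
#'
#' @details Radial taper: at normalized long-axis position `t` (0 at base,
#' 1 at apex) the epicardial radius is `epi * (1 - 0.40 t)` and the
#' endocardial radius `endo * (1 - 0.75 t)`; on apex-slab slices the cavity
#' is closed (endo = 0), giving a filled disc.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(matrix_size = 128L,
                           pet_pixel_mm = 1.6, pet_slice_mm = 1.6,
                           spect_pixel_mm = 2.4, spect_slice_mm = 2.4,
                           lv_length_mm = 38.4,
                           ring_center = NULL,
                           endo_radius_mm = 17, epi_radius_mm = 24,
                           baseline_uptake = 80,
                           noise_scale = 0.5, noise_corr_mm = 4,
                           seed = 1L) {
  stopifnot(matrix_size %% 2 == 0, matrix_size >= 16,
            baseline_uptake > 0, baseline_uptake <= 100,
            endo_radius_mm < epi_radius_mm, noise_scale >= 0)
  if (is.null(ring_center)) ring_center <- rep((matrix_size + 1) / 2, 2)
  structure(list(matrix_size = as.integer(matrix_size),
                 pet_pixel_mm = pet_pixel_mm, pet_slice_mm = pet_slice_mm,
                 spect_pixel_mm = spect_pixel_mm, spect_slice_mm = spect_slice_mm,
                 lv_length_mm = lv_length_mm, ring_center = ring_center,
                 endo_radius_mm = endo_radius_mm, epi_radius_mm = epi_radius_mm,
                 baseline_uptake = baseline_uptake, noise_scale = noise_scale,
                 noise_corr_mm = noise_corr_mm, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Perfusion defect specification
#'
#' @param segments AHA segment numbers (subset of 1..17), nonempty.
#' @param severity fractional uptake reduction in `[0, 1]`.
#' @param state `"stress"`, `"rest"` or `"both"`.
#' @return a `defect_spec` list.
#' @export
defect_spec <- function(segments, severity, state = c("both", "stress", "rest")) {
  state <- match.arg(state)
  segments <- as.integer(segments)
  stopifnot(length(segments) >= 1, all(segments %in% 1:17),
            severity >= 0, severity <= 1)
  structure(list(segments = segments, severity = severity, state = state),
            class = "defect_spec")
}

#' Attenuation-field specification
#'
#' A separable smooth field: an angular raised-cosine bump (deepest at
#' `peak_direction_deg`, zero outside `angular_width_deg`) times a per-slab
#' longitudinal multiplier. The default points at the inferior wall
#' (270 degrees in the package convention), emulating the classic inferior-
#' wall photon-attenuation artifact of non-corrected SPECT.
#'
#' @param min_factor strongest attenuation, in (0, 1]. The per-voxel factor
#'   ranges in `[min_factor, 1]`.
#' @param peak_direction_deg angle of maximal attenuation (default 270 =
#'   inferior wall).
#' @param angular_width_deg full angular width of the bump (default 120).
#' @param longitudinal_profile multipliers in `[0, 1]` for the
#'   basal/mid/apical/apex slabs (default all 1).
#' @return an `attenuation_spec` list.
#' @export
attenuation_spec <- function(min_factor = 0.8, peak_direction_deg = 270,
                             angular_width_deg = 120,
                             longitudinal_profile = c(basal = 1, mid = 1,
                                                      apical = 1, apex = 1)) {
  stopifnot(min_factor > 0, min_factor <= 1, angular_width_deg > 0,
            length(longitudinal_profile) == 4,
            all(longitudinal_profile >= 0 & longitudinal_profile <= 1))
  names(longitudinal_profile) <- c("basal", "mid", "apical", "apex")
  structure(list(min_factor = min_factor,
                 peak_direction_deg = peak_direction_deg,
                 angular_width_deg = angular_width_deg,
                 longitudinal_profile = longitudinal_profile),
            class = "attenuation_spec")
}

phantom_radii <- function(config, t) {
  list(endo = config$endo_radius_mm * (1 - 0.75 * t),
       epi  = config$epi_radius_mm * (1 - 0.40 * t))
}

#' Rasterize one annular myocardium slice
#'
#' @param config a [phantom_config()].
#' @param slice_index slice number (1 = base).
#' @param pixel_mm,n_slices geometry of the stack being built (default the
#'   SPECT geometry of `config`).
#' @return numeric matrix with in-ring pixels at `baseline_uptake`,
#'   background 0. Slices in the apex slab are filled discs.
#' @export
make_ring_slice <- function(config, slice_index,
                            pixel_mm = config$spect_pixel_mm,
                            n_slices = round(config$lv_length_mm / config$spect_slice_mm)) {
  stopifnot(slice_index >= 1, slice_index <= n_slices)
  t <- (slice_index - 0.5) / n_slices
  rad <- phantom_radii(config, t)
  part <- suppressWarnings(partition_slabs(n_slices))
  if (part$slab_of_slice[slice_index] == "apex") rad$endo <- 0
  if (rad$endo >= rad$epi) stop("degenerate radii: endo >= epi")
  n <- config$matrix_size
  ctr <- config$ring_center
  d_mm <- sqrt(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+")) * pixel_mm
  img <- matrix(0, n, n)
  img[d_mm >= rad$endo & d_mm <= rad$epi] <- config$baseline_uptake
  img
}

phantom_stack <- function(config, modality = c("spect", "pet"),
                          state = "stress") {
  modality <- match.arg(modality)
  px <- if (modality == "spect") config$spect_pixel_mm else config$pet_pixel_mm
  sl <- if (modality == "spect") config$spect_slice_mm else config$pet_slice_mm
  ns <- round(config$lv_length_mm / sl)
  vox <- array(0, c(config$matrix_size, config$matrix_size, ns))
  for (k in seq_len(ns))
    vox[, , k] <- make_ring_slice(config, k, pixel_mm = px, n_slices = ns)
  image_stack(vox, px, sl, state = state, modality = modality)
}

#' Segment identity of every voxel of a stack
#' @noRd
segment_field <- function(stack, center) {
  d <- dim(stack$voxels)
  part <- suppressWarnings(partition_slabs(d[3]))
  ang <- pixel_angle(rep(seq_len(d[1]), times = d[2]),
                     rep(seq_len(d[2]), each = d[1]), center)
  seg <- array(0L, d)
  for (k in seq_len(d[3]))
    seg[, , k] <- aha_segment_of(ang, part$slab_of_slice[k])
  seg
}

#' Apply a perfusion defect to a stack
#'
#' Voxels whose (slab, angle) location maps to one of the listed AHA
#' segments are multiplied by `1 - severity`; all other voxels are
#' unchanged. The rasterized wedge is dilated by each pixel's angular
#' footprint (`atan(2 / radius)`), so that every bilinearly interpolated
#' sample strictly inside the sector mixes only defected pixels: without
#' the dilation, the radial-maximum quantifier latches onto bright
#' neighboring-sector pixels at the boundary and the defected segment's
#' representative value is biased above `baseline * (1 - severity)`.
#' Neighboring segments are essentially unaffected because their ray
#' maxima are taken at radii with clean samples.
#'
#' @param stack an [image_stack()] (uptake scale).
#' @param defect a [defect_spec()].
#' @param center LV center `c(row, col)`; default image center.
#' @return the modified stack.
#' @export
apply_defect <- function(stack, defect, center = NULL) {
  stopifnot(inherits(defect, "defect_spec"))
  d <- dim(stack$voxels)
  if (is.null(center)) center <- (d[1:2] + 1) / 2
  part <- suppressWarnings(partition_slabs(d[3]))
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  ang <- pixel_angle(rows, cols, center)
  rad <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  # a bilinear sample mixes pixels within ~sqrt(2) px; atan(1.45/r) bounds
  # their angular offset at pixel radius r
  margin <- atan2(1.45, rad) * 180 / pi
  ring_of_slab <- c(basal = "basal", mid = "mid", apical = "apical", apex = "apex")
  vox <- stack$voxels
  for (k in seq_len(d[3])) {
    ring <- ring_of_slab[[part$slab_of_slice[k]]]
    ring_segs <- switch(ring, basal = 1:6, mid = 7:12, apical = 13:16, apex = 17L)
    segs <- intersect(defect$segments, ring_segs)
    if (!length(segs)) next
    hit <- rep(FALSE, d[1] * d[2])
    for (s in segs) {
      iv <- aha_sector_interval(s)
      hit <- hit | (ang_dist_interval(ang, iv[1], iv[2]) <= margin)
    }
    sl <- vox[, , k]
    sl[hit] <- sl[hit] * (1 - defect$severity)
    vox[, , k] <- sl
  }
  stack_with(stack, vox)
}

#' Apply a smooth attenuation field to a stack
#'
#' The per-voxel factor is
#' `1 - (1 - min_factor) * bump(angle) * longitudinal_profile[slab]`, where
#' `bump` is a raised cosine centered on `peak_direction_deg` with full
#' width `angular_width_deg`. The factor therefore lies in
#' `[min_factor, 1]`, reaches its minimum at the peak direction, and equals
#' 1 wherever attenuation is disabled.
#'
#' @param stack an [image_stack()] (uptake scale).
#' @param spec an [attenuation_spec()], or `NULL` for identity.
#' @param center LV center; default image center.
#' @return list with elements `stack` (attenuated) and `field` (the factor
#'   array, same dimensions as the stack).
#' @export
apply_attenuation <- function(stack, spec, center = NULL) {
  d <- dim(stack$voxels)
  if (is.null(spec)) return(list(stack = stack, field = array(1, d)))
  stopifnot(inherits(spec, "attenuation_spec"))
  if (is.null(center)) center <- (d[1:2] + 1) / 2
  part <- suppressWarnings(partition_slabs(d[3]))
  ang <- pixel_angle(rep(seq_len(d[1]), times = d[2]),
                     rep(seq_len(d[2]), each = d[1]), center)
  dth <- abs((ang - spec$peak_direction_deg + 180) %% 360 - 180)
  bump <- ifelse(dth <= spec$angular_width_deg / 2,
                 0.5 * (1 + cos(2 * pi * dth / spec$angular_width_deg)), 0)
  field <- array(1, d)
  for (k in seq_len(d[3])) {
    lp <- spec$longitudinal_profile[[part$slab_of_slice[k]]]
    field[, , k] <- 1 - (1 - spec$min_factor) * bump * lp
  }
  list(stack = stack_with(stack, stack$voxels * field), field = field)
}

add_emission_noise <- function(stack, noise_scale, noise_corr_mm) {
  if (noise_scale <= 0) return(stack)
  d <- dim(stack$voxels)
  sigma_px <- noise_corr_mm / stack$pixel_mm
  vox <- stack$voxels
  for (k in seq_len(d[3])) {
    z <- smooth_noise_slice(d[1], d[2], sigma_px)
    vox[, , k] <- clip01(vox[, , k] + noise_scale * sqrt(vox[, , k]) * z,
                         0, 100)
  }
  stack_with(stack, vox)
}

#' Generate one synthetic patient: paired SPECT and PET stacks plus truth
#'
#' Both stacks share the same underlying anatomy and defects; the SPECT
#' stack is additionally multiplied by the attenuation field. The PET
#' stack is rasterized at PET geometry (1.6 mm), the SPECT stack at SPECT
#' geometry (2.4 mm). Poisson-like spatially correlated noise is added to
#' each modality independently. Deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @param defects list of [defect_spec()] objects (possibly empty).
#' @param attenuation an [attenuation_spec()] or `NULL`.
#' @param seed integer; overrides `config$seed` when given.
#' @param state `"stress"` or `"rest"`; defects are filtered by their
#'   `state` field (`"both"` always applies).
#' @return list with `spect`, `pet` ([image_stack()]s, uptake scale) and
#'   `truth` (list: `true_segment_values` [17], `defect_map` [logical,
#'   SPECT geometry], `attenuation_field` [SPECT geometry]).
#' @export
generate_patient_pair <- function(config, defects = list(), attenuation = NULL,
                                  seed = config$seed, state = "stress") {
  stopifnot(inherits(config, "phantom_config"))
  if (inherits(defects, "defect_spec")) defects <- list(defects)
  set.seed(as.integer(seed))
  active <- Filter(function(d) d$state %in% c("both", state), defects)

  build <- function(modality) {
    st <- phantom_stack(config, modality, state)
    for (d in active) st <- apply_defect(st, d, center = config$ring_center)
    st
  }
  pet <- build("pet")
  spect <- build("spect")
  att <- apply_attenuation(spect, attenuation, center = config$ring_center)
  spect <- att$stack

  pet <- add_emission_noise(pet, config$noise_scale, config$noise_corr_mm)
  spect <- add_emission_noise(spect, config$noise_scale, config$noise_corr_mm)

  truth_vals <- rep(config$baseline_uptake, 17L)
  for (d in active)
    truth_vals[d$segments] <- truth_vals[d$segments] * (1 - d$severity)
  clean_spect <- build("spect")
  base_spect <- phantom_stack(config, "spect", state)
  dmap <- (clean_spect$voxels != base_spect$voxels) & (base_spect$voxels > 0)
  list(spect = spect, pet = pet,
       truth = list(true_segment_values = truth_vals,
                    defect_map = dmap,
                    attenuation_field = att$field))
}

#' Write a phantom truth table as CSV (segment, true_value)
#' @param truth the `truth` element of [generate_patient_pair()].
#' @param path output CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(data.frame(segment = 1:17,
                              true_value = truth$true_segment_values),
                   path, row.names = FALSE)
  invisible(path)
}
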