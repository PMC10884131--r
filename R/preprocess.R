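#' Align the slice count of a stack by nearest-neighbor selection
#'
#' Matches the dataset-pairing convention: the finer-sliced stack (PET) is
#' aligned to the slice count of the coarser one by nearest-neighbor
#' interpolation along the long axis -- each output slice is the input
#' slice whose physical position is nearest to the target position, with
#' no interpolation of intensities. Slice positions are slab centers
#' measured from the basal-most slice; the physical extent
#' `n_in * slice_mm` is preserved, so the output slice thickness is
#' `extent / n_target`.
#'
#' @param stack an [image_stack()].
#' @param n_target desired number of slices (>= 1).
#' @return an [image_stack()] with exactly `n_target` slices.
#' @export
align_slice_counts <- function(stack, n_target) {
  stopifnot(n_target >= 1)
  n_in <- n_slices(stack)
  if (n_in < 1L) stop("empty stack")
  L <- n_in * stack$slice_mm
  pos_in <- (seq_len(n_in) - 0.5) * stack$slice_mm
  pos_out <- (seq_len(n_target) - 0.5) * L / n_target
  idx <- vapply(pos_out, function(p) which.min(abs(pos_in - p)), 1L)
  stack_with(stack, stack$voxels[, , idx, drop = FALSE],
             slice_mm = L / n_target)
}

#' In-plane magnification and center crop
#'
#' Magnifies each slice by `pixel_mm / target_pixel_mm` (bilinear) and
#' center-crops to `out_size x out_size`, reproducing the 2.4/1.6 SPECT
#' enlargement convention (128 -> 192, cropped back to 128). The retained
#' window covers a physical extent of `out_size * target_pixel_mm`.
#'
#' @param stack an [image_stack()].
#' @param target_pixel_mm desired pixel size (<= `stack$pixel_mm`).
#' @param out_size output matrix size.
#' @return an [image_stack()] at `target_pixel_mm`, with an attribute
#'   `"resample_record"` (scale factor, magnified size, interpolation).
#' @export
resample_and_crop <- function(stack, target_pixel_mm, out_size = dim(stack$voxels)[1]) {
  if (stack$pixel_mm < target_pixel_mm)
    stop("target pixel size must be finer than or equal to the input's")
  d <- dim(stack$voxels)
  factor <- stack$pixel_mm / target_pixel_mm
  new_size <- round(d[1] * factor)
  if (new_size < out_size)
    stop("magnified image (", new_size, ") smaller than requested crop (", out_size, ")")
  start <- floor((new_size - out_size) / 2) + 1L
  sel <- start:(start + out_size - 1L)
  vox <- array(0, c(out_size, out_size, d[3]))
  for (k in seq_len(d[3])) {
    mag <- if (new_size == d[1]) stack$voxels[, , k] else
      bilinear_resize(stack$voxels[, , k], new_size, new_size)
    vox[, , k] <- mag[sel, sel]
  }
  out <- stack_with(stack, vox, pixel_mm = target_pixel_mm)
  attr(out, "resample_record") <- list(scale_factor = factor,
                                       magnified_size = new_size,
                                       interpolation = "bilinear")
  out
}

#' Quantize a stack to 8 bits (per-stack normalization)
#'
#' The per-stack maximum maps linearly to 255 (per-stack, not per-slice,
#' so relative uptake across slices is preserved). The maximum is kept in
#' the scale record so the inverse map is exact on the 256 levels. An
#' all-zero stack maps to all-zero with unit scale.
#'
#' @param stack an [image_stack()] with nonnegative intensities.
#' @return an [image_stack()] on the `uint8` scale with
#'   `scale_record = list(max = <stack maximum>)`.
#' @export
to_uint8 <- function(stack) {
  if (stack$scale == "uint8") return(stack)
  if (any(stack$voxels < 0)) stop("negative intensities")
  m <- max(stack$voxels)
  if (m == 0)
    return(stack_with(stack, stack$voxels, scale = "uint8",
                      scale_record = list(max = 1)))
  q <- round(stack$voxels / m * 255)
  stack_with(stack, q, scale = "uint8", scale_record = list(max = m))
}

#' Invert the 8-bit quantization using the stack's scale record
#' @param stack a `uint8` stack produced by [to_uint8()].
#' @return the stack on its original intensity scale (uptake).
#' @export
from_uint8 <- function(stack) {
  stopifnot(stack$scale == "uint8")
  m <- stack$scale_record$max %||% 1
  stack_with(stack, stack$voxels / 255 * m, scale = "uptake",
             scale_record = NULL)
}

#' Convert an 8-bit stack to the 0-100 uptake scale
#'
#' The study convention: signal value `v` of the 8-bit image (max = 255)
#' becomes `100 * v / 255`, so 255 maps to an uptake of 100.
#'
#' @param stack a `uint8` [image_stack()].
#' @return an uptake-scale [image_stack()].
#' @export
to_uptake <- function(stack) {
  stopifnot(stack$scale == "uint8")
  stack_with(stack, 100 * stack$voxels / 255, scale = "uptake",
             scale_record = NULL)
}

#' Bilinear resize to the network matrix size (and back)
#'
#' The translation network operates at a fixed square size (256 in the
#' full-scale profile); inputs are bilinearly upsized before translation
#' and outputs downsized back to the original matrix. A constant image
#' survives the round trip exactly.
#'
#' @param img square numeric matrix or [image_stack()].
#' @param size target side length.
#' @return same type as `img`, resized.
#' @export
resize_for_network <- function(img, size) {
  if (inherits(img, "image_stack")) {
    d <- dim(img$voxels)
    vox <- array(0, c(size, size, d[3]))
    for (k in seq_len(d[3]))
      vox[, , k] <- resize_for_network(img$voxels[, , k], size)
    return(stack_with(img, vox, pixel_mm = img$pixel_mm * d[1] / size))
  }
  if (nrow(img) != ncol(img)) stop("non-square image")
  if (nrow(img) == size) return(img)
  bilinear_resize(img, size, size)
}

#' @rdname resize_for_network
#' @export
downsize_after_network <- function(img, size) resize_for_network(img, size)

#' Standard preprocessing of one SPECT/PET pair
#'
#' Chains the pairing steps: PET slice count aligned to SPECT; SPECT
#' magnified to the PET pixel size and center-cropped to the PET matrix;
#' both converted to 8 bits and then to the 0-100 uptake scale.
#'
#' @param spect,pet [image_stack()]s on the uptake scale.
#' @return list of uptake-scale stacks `spect`, `pet` on a common geometry.
#' @export
preprocess_pair <- function(spect, pet) {
  pet_al <- align_slice_counts(pet, n_slices(spect))
  sp_rs <- resample_and_crop(spect, pet$pixel_mm, dim(pet$voxels)[1])
  list(spect = to_uptake(to_uint8(sp_rs)),
       pet = to_uptake(to_uint8(pet_al)))
}
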