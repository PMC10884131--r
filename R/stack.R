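#' Short-axis image stack
#'
#' The common currency of the pipeline: an ordered base-to-apex stack of
#' square short-axis slices together with its physical geometry and
#' acquisition metadata. Voxels are stored as a `rows x cols x slices` array.
#' Two intensity scales are supported: `"uptake"` (continuous, 0-100, the
#' relative-uptake convention used for all quantification) and `"uint8"`
#' (integer 0-255, the on-disk representation).
#'
#' @param voxels numeric array `rows x cols x slices` (a matrix is treated as
#'   a single slice); rows must equal cols.
#' @param pixel_mm in-plane pixel size in mm.
#' @param slice_mm slice thickness in mm.
#' @param state acquisition state, `"stress"` or `"rest"`.
#' @param modality `"spect"`, `"pet"`, or `"spect_spt"` (the translated,
#'   attenuation-corrected SPECT).
#' @param scale `"uptake"` or `"uint8"`.
#' @param scale_record optional list recording the 8-bit quantization (see
#'   [to_uint8()]).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_mm, slice_mm,
                        state = c("stress", "rest"),
                        modality = c("spect", "pet", "spect_spt"),
                        scale = c("uptake", "uint8"),
                        scale_record = NULL) {
  state <- match.arg(state)
  modality <- match.arg(modality)
  scale <- match.arg(scale)
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  d <- dim(voxels)
  if (d[1] != d[2]) stop("slices must be square (rows == cols)")
  if (d[3] < 1L) stop("stack needs at least one slice")
  stopifnot(is.numeric(pixel_mm), pixel_mm > 0, is.numeric(slice_mm), slice_mm > 0)
  if (scale == "uptake") {
    rng <- range(voxels)
    if (rng[1] < -1e-9 || rng[2] > 100 + 1e-9)
      stop("uptake-scale voxels must lie in [0, 100]")
  } else {
    if (any(voxels < 0 | voxels > 255) || any(voxels != round(voxels)))
      stop("uint8-scale voxels must be integers in [0, 255]")
  }
  structure(list(voxels = voxels, pixel_mm = pixel_mm, slice_mm = slice_mm,
                 state = state, modality = modality, scale = scale,
                 scale_record = scale_record),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s/%s  %dx%d x %d slices  %.2f mm px, %.2f mm slice  [%s]\n",
              x$modality, x$state, d[1], d[2], d[3], x$pixel_mm, x$slice_mm, x$scale))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

#' Replace the voxel array of a stack, keeping (or overriding) metadata
#' @noRd
stack_with <- function(stack, voxels, ...) {
  dots <- list(...)
  args <- list(voxels = voxels, pixel_mm = stack$pixel_mm,
               slice_mm = stack$slice_mm, state = stack$state,
               modality = stack$modality, scale = stack$scale,
               scale_record = stack$scale_record)
  args[names(dots)] <- dots
  do.call(image_stack, args)
}

# ---- plain-text PGM (P2) slice files + metadata sidecar -------------------

stack_basename <- function(case_id, state, modality)
  sprintf("%s_%s_%s", case_id, state, modality)

write_pgm <- function(mat, path) {
  stopifnot(all(mat >= 0 & mat <= 255), all(mat == round(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(mat), nrow(mat)), "255"), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(mat, 1L, paste, collapse = " "), con)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), what = integer(),
              quiet = TRUE)
  if (txt[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- tok[1]; h <- tok[2]; maxv <- tok[3]
  if (maxv != 255) stop("expected 8-bit PGM (maxval 255)")
  vals <- tok[-(1:3)]
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a stack as per-slice 8-bit PGM files plus a metadata sidecar
#'
#' Files are named `<case>_<state>_<modality>_<slice:03d>.pgm`, slices ordered
#' base to apex. Uptake-scale stacks are quantized with [to_uint8()] first and
#' the quantization maximum is recorded in the sidecar so the inverse map is
#' exact on the 256 levels.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param case_id case identifier used in file names.
#' @return invisibly, the vector of files written.
#' @export
write_stack_pgm <- function(stack, dir, case_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (stack$scale == "uptake") stack <- to_uint8(stack)
  base <- stack_basename(case_id, stack$state, stack$modality)
  files <- character(0)
  for (k in seq_len(n_slices(stack))) {
    f <- file.path(dir, sprintf("%s_%03d.pgm", base, k))
    write_pgm(stack$voxels[, , k], f)
    files <- c(files, f)
  }
  meta <- file.path(dir, sprintf("%s_meta.txt", base))
  writeLines(c(sprintf("pixel_mm: %.6g", stack$pixel_mm),
               sprintf("slice_mm: %.6g", stack$slice_mm),
               sprintf("state: %s", stack$state),
               sprintf("modality: %s", stack$modality),
               sprintf("n_slices: %d", n_slices(stack)),
               sprintf("u8_max: %.10g", stack$scale_record$max %||% 1)),
             meta)
  invisible(c(files, meta))
}

#' Read a stack written by [write_stack_pgm()]
#'
#' @param dir directory holding the slice files.
#' @param case_id,state,modality identify the stack.
#' @return an [image_stack()] on the `uint8` scale with its scale record.
#' @export
read_stack_pgm <- function(dir, case_id, state, modality) {
  base <- stack_basename(case_id, state, modality)
  meta <- read_sidecar(file.path(dir, sprintf("%s_meta.txt", base)))
  n <- as.integer(meta$n_slices)
  slices <- lapply(seq_len(n), function(k)
    read_pgm(file.path(dir, sprintf("%s_%03d.pgm", base, k))))
  vox <- array(unlist(slices), c(dim(slices[[1]]), n))
  image_stack(vox, as.numeric(meta$pixel_mm), as.numeric(meta$slice_mm),
              state = meta$state, modality = meta$modality, scale = "uint8",
              scale_record = list(max = as.numeric(meta$u8_max)))
}

read_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
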