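#' Image stack with physical pixel spacing
#'
#' The basic carrier for ultramicroscopy slices, MR volumes and synthetic
#' phantoms: a 2D or 3D numeric grid together with the physical size of a
#' voxel along each axis, in micrometres. For 3D data the array axes are
#' (row, column, plane), i.e. plane index last, matching how multi-page TIFF
#' stacks are read page by page.
#'
#' @param values numeric matrix (2D) or 3D array; all values must be finite.
#' @param spacing numeric vector of voxel sizes in µm, one per array axis
#'   (a scalar is recycled). Must be strictly positive.
#' @return An object of class `image_stack`: a list with elements `values`
#'   and `spacing`.
#' @examples
#' img <- image_stack(matrix(0, 32, 32), spacing = 5.16)
#' dim(img$values)
#' @export
image_stack <- function(values, spacing) {
  if (!is.numeric(values) && !is.logical(values)) {
    stop("`values` must be a numeric array")
  }
  values <- if (is.matrix(values) || length(dim(values)) >= 2) values else
    stop("`values` must be a matrix or array with >= 2 dimensions")
  nd <- length(dim(values))
  if (nd < 2 || nd > 3) stop("`values` must be 2D or 3D")
  if (!all(is.finite(values))) stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, nd)
  if (length(spacing) != nd) stop("`spacing` must have one entry per axis")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  structure(list(values = values + 0, spacing = spacing),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_stack> %s voxels, spacing %s um, range [%.4g, %.4g]\n",
              paste(d, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

is_image_stack <- function(x) inherits(x, "image_stack")

stopifnot_stack <- function(img) {
  if (!is_image_stack(img)) stop("expected an `image_stack`")
  invisible(img)
}

# linear (or nearest) interpolation weight matrix mapping an axis of length n
# at spacing `s` onto n_new samples at spacing `t`; voxel-center convention.
interp_matrix <- function(n, s, t, order) {
  n_new <- max(1L, as.integer(round(n * s / t)))
  u <- ((seq_len(n_new) - 0.5) * t) / s + 0.5   # continuous old index
  u <- pmin(pmax(u, 1), n)
  W <- matrix(0, n_new, n)
  if (order == "nearest") {
    idx <- pmin(pmax(round(u), 1), n)
    W[cbind(seq_len(n_new), idx)] <- 1
  } else {
    lo <- pmin(floor(u), n - 1L)
    lo <- pmax(lo, 1L)
    w <- u - lo
    W[cbind(seq_len(n_new), lo)] <- W[cbind(seq_len(n_new), lo)] + (1 - w)
    W[cbind(seq_len(n_new), lo + 1L)] <- W[cbind(seq_len(n_new), lo + 1L)] + w
  }
  W
}

apply_along_axis <- function(arr, W, axis) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  out <- W %*% m
  dnew <- d[perm]
  dnew[1] <- nrow(W)
  out <- array(out, dnew)
  aperm(out, order(perm))
}

#' Rescale a stack to a target physical resolution
#'
#' Resamples an image so that each voxel measures `target_spacing` µm along
#' every axis (or per-axis values), preserving the physical extent of the
#' grid to within one voxel. This mirrors the standard preprocessing step of
#' rescaling light-sheet slices to a common fine resolution (e.g. 0.5 µm)
#' before vessel segmentation.
#'
#' @param img an [image_stack()].
#' @param target_spacing target voxel size in µm (scalar or per-axis vector).
#' @param order interpolation order, `"linear"` (default) or `"nearest"`.
#' @return A new `image_stack` at the requested spacing.
#' @export
rescale_to_resolution <- function(img, target_spacing,
                                  order = c("linear", "nearest")) {
  stopifnot_stack(img)
  order <- match.arg(order)
  d <- dim(img$values)
  nd <- length(d)
  target <- as.numeric(target_spacing)
  if (length(target) == 1) target <- rep(target, nd)
  if (length(target) != nd || any(target <= 0)) {
    stop("`target_spacing` must be positive, scalar or one per axis")
  }
  if (all(abs(target - img$spacing) < 1e-12)) return(img)
  factor <- img$spacing / target
  if (any(factor > 64)) {
    stop("refusing upscale factor > 64 (target spacing too fine)")
  }
  vals <- img$values
  for (ax in seq_len(nd)) {
    W <- interp_matrix(d[ax], img$spacing[ax], target[ax], order)
    vals <- apply_along_axis(vals, W, ax)
  }
  image_stack(vals, target)
}

#' Write / read a stack as multi-page TIFF
#'
#' Intensities are min-max scaled to \[0, 1\] for 32-bit float TIFF storage;
#' the original range and the voxel spacing are kept in a JSON sidecar
#' (`<path>.json`) so that [read_stack_tiff()] restores the stack exactly.
#'
#' @param img an [image_stack()].
#' @param path output TIFF file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(img, path) {
  stopifnot_stack(img)
  v <- img$values
  rng <- range(v)
  scl <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  pages <- if (length(dim(scl)) == 2) list(scl) else
    lapply(seq_len(dim(scl)[3]), function(k) scl[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(spacing_um = img$spacing, range = rng),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- if (length(pages) == 1) pages[[1]] else
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    rng <- meta$range
    if (diff(rng) > 0) arr <- arr * diff(rng) + rng[1]
    image_stack(arr, meta$spacing_um)
  } else {
    image_stack(arr, rep(1, length(dim(arr))))
  }
}

#' Write / read a stack as NIfTI
#'
#' Voxel spacing is stored in the NIfTI pixdim field. Spacing is carried in
#' µm throughout this package (also for MR volumes), so round trips through
#' these two functions are unit-consistent.
#'
#' @param img an [image_stack()] (2D or 3D).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(img, path) {
  stopifnot_stack(img)
  nim <- RNifti::asNifti(img$values)
  RNifti::pixdim(nim) <- img$spacing
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  image_stack(arr, RNifti::pixdim(nim)[seq_len(length(dim(arr)))])
}
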