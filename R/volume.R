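#' 3D image volume
#'
#' Lightweight container for a 3D scalar grid with anisotropic voxel spacing,
#' the carrier for T2-weighted and ADC intensities, masks, grade maps and
#' per-class probability maps. Arrays are indexed `[x, y, z]` (1-based, R
#' convention); `spacing` is `c(px, py, dz)` in millimetres, where `px`/`py`
#' are the in-plane pixel sizes and `dz` the distance between consecutive
#' slices.
#'
#' @param data numeric or logical 3D array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, voxel spacing in mm (`px`, `py`, `dz`);
#'   all strictly positive.
#' @param origin numeric length-3, position of voxel (1,1,1) in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Coerce image_volume or plain array to a 3D array.
as_vol_array <- function(x) {
  if (inherits(x, "image_volume")) x$data else {
    if (length(dim(x)) != 3L) stop("expected a 3D array or image_volume")
    x
  }
}

vol_spacing <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "image_volume")) x$spacing else default
}

#' Volume of one voxel in cubic millimetres
#' @param spacing numeric length-3 spacing in mm, or an `image_volume`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(spacing) {
  if (inherits(spacing, "image_volume")) spacing <- spacing$spacing
  prod(spacing)
}

#' Read / write volumes as NIfTI
#'
#' Masks and grade maps are stored with integer codes (0 outside the prostate,
#' 1 prostate/normal tissue; grade maps add 2 indolent and 3 aggressive).
#'
#' @param vol an `image_volume`.
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `image_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  attributes(arr) <- list(dim = dim(arr))    # drop NIfTI header attributes
  image_volume(arr, spacing = RNifti::pixdim(img)[1:3])
}

# -- small numeric kernels shared by morphology, smoothing ------------------

# Same-size 3D convolution with zero padding outside the grid, via FFT.
# `kern` must have odd dimensions; for the symmetric kernels used here
# convolution and correlation coincide.
conv3d_same <- function(x, kern) {
  dx <- dim(x); dk <- dim(kern)
  if (any(dk %% 2L == 0L)) stop("kernel dimensions must be odd")
  dp <- dx + dk - 1L
  xp <- array(0, dp)
  xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, dp)
  kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  r <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / prod(dp)
  c0 <- (dk + 1L) / 2L
  r[c0[1]:(c0[1] + dx[1] - 1L),
    c0[2]:(c0[2] + dx[2] - 1L),
    c0[3]:(c0[3] + dx[3] - 1L), drop = FALSE]
}

# Separable Gaussian smoothing; sigma_px per axis in voxels (0 = no smoothing
# along that axis).
gauss_smooth <- function(arr, sigma_px = c(1, 1, 0)) {
  kern1 <- function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1(sigma_px[1]); ky <- kern1(sigma_px[2]); kz <- kern1(sigma_px[3])
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- c(length(kx), length(ky), length(kz))
  conv3d_same(arr, kern)
}
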