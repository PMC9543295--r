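#' Crop and resample a volume to the analysis grid
#'
#' Brings a volume to the common in-plane grid used by the models: a
#' `target_xy` x `target_xy` plane at `target_pixel_mm` pixel size, centred
#' on the in-plane centroid of the prostate mask. Slices are untouched.
#' Intensities are interpolated bilinearly, categorical volumes (masks,
#' grade maps) by nearest neighbour so no new codes appear. If the prostate
#' extent exceeds the target field of view the function errors rather than
#' silently truncating the gland.
#'
#' @param volume an `image_volume`.
#' @param prostate_mask logical array (or `image_volume`) on the source grid,
#'   used for centring and the field-of-view check.
#' @param target_pixel_mm target in-plane pixel size (default 0.29).
#' @param target_xy target in-plane dimension (default 224).
#' @param method `"linear"` for intensities, `"nearest"` for categorical
#'   volumes.
#' @return An `image_volume` on the target grid.
#' @export
crop_resample <- function(volume, prostate_mask, target_pixel_mm = 0.29,
                          target_xy = 224L, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "image_volume"))
  pm <- as_vol_array(prostate_mask) > 0.5
  if (!any(pm)) stop("prostate mask is empty")
  arr <- volume$data
  d <- dim(arr)
  if (!all(dim(pm) == d)) stop("mask and volume grids differ")
  sp <- volume$spacing
  idx <- which(pm, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  # prostate extent in mm must fit the target field of view
  ext_x <- (diff(range(idx[, 1])) + 1) * sp[1]
  ext_y <- (diff(range(idx[, 2])) + 1) * sp[2]
  fov <- target_xy * target_pixel_mm
  if (ext_x > fov || ext_y > fov)
    stop(sprintf("prostate extent (%.1f x %.1f mm) exceeds target field of view (%.1f mm)",
                 ext_x, ext_y, fov))
  # target voxel centres in source index coordinates
  tx <- cx + ((seq_len(target_xy) - (target_xy + 1) / 2) * target_pixel_mm) / sp[1]
  ty <- cy + ((seq_len(target_xy) - (target_xy + 1) / 2) * target_pixel_mm) / sp[2]
  out <- array(0, c(target_xy, target_xy, d[3]))
  if (method == "nearest") {
    ix <- round(tx); iy <- round(ty)
    okx <- ix >= 1 & ix <= d[1]; oky <- iy >= 1 & iy <= d[2]
    out[okx, oky, ] <- arr[ix[okx], iy[oky], , drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(tx), 1L), d[1] - 1L); fx <- pmin(pmax(tx - x0, 0), 1)
    y0 <- pmin(pmax(floor(ty), 1L), d[2] - 1L); fy <- pmin(pmax(ty - y0, 0), 1)
    inx <- tx >= 1 & tx <= d[1]; iny <- ty >= 1 & ty <= d[2]
    wx0 <- 1 - fx
    wy0 <- 1 - fy
    for (z in seq_len(d[3])) {
      sl <- arr[, , z]
      a00 <- sl[x0, y0, drop = FALSE]; a10 <- sl[x0 + 1L, y0, drop = FALSE]
      a01 <- sl[x0, y0 + 1L, drop = FALSE]; a11 <- sl[x0 + 1L, y0 + 1L, drop = FALSE]
      plane <- a00 * outer(wx0, wy0) + a10 * outer(fx, wy0) +
               a01 * outer(wx0, fy) + a11 * outer(fx, fy)
      plane[!inx, ] <- 0; plane[, !iny] <- 0
      out[, , z] <- plane
    }
  }
  image_volume(out, c(target_pixel_mm, target_pixel_mm, sp[3]))
}

#' Normalize MRI intensities within the prostate
#'
#' `"zscore"` standardizes to zero mean and unit variance within the mask
#' (applied to the whole volume); it is invariant to affine intensity
#' transforms of the input and idempotent. `"histogram"` first applies
#' piecewise-linear landmark standardization — deciles within the mask are
#' mapped onto a template landmark set — and then z-scores; this reduces
#' inter-scanner decile spread before the final scaling. Both are declared
#' approximations to scanner-specific standardization recipes.
#'
#' @param volume an `image_volume`.
#' @param prostate_mask logical array; must be nonempty.
#' @param method `"zscore"` (default) or `"histogram"`.
#' @param template landmark template for `"histogram"`: 11 increasing values
#'   the mask deciles map onto (default `seq(0, 1, 0.1)`).
#' @return An `image_volume` of normalized intensities.
#' @export
normalize_intensity <- function(volume, prostate_mask,
                                method = c("zscore", "histogram"),
                                template = seq(0, 1, 0.1)) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "image_volume"))
  pm <- as_vol_array(prostate_mask) > 0.5
  if (!any(pm)) stop("prostate mask is empty")
  arr <- volume$data
  if (method == "histogram") {
    lm <- stats::quantile(arr[pm], probs = seq(0, 1, 0.1), names = FALSE)
    if (any(diff(lm) <= 0)) {
      # collapse duplicate landmarks (flat histogram regions)
      keep <- c(TRUE, diff(lm) > 0)
      lm <- lm[keep]; tmpl <- template[keep]
    } else tmpl <- template
    if (length(lm) < 2L) stop("constant-intensity volume: cannot normalize")
    arr <- array(stats::approx(lm, tmpl, xout = arr, rule = 2)$y, dim(arr))
  }
  mu <- mean(arr[pm]); s <- stats::sd(arr[pm])
  if (!is.finite(s) || s == 0) stop("constant-intensity volume: zero variance in mask")
  image_volume((arr - mu) / s, volume$spacing)
}

#' Stack adjacent slices as channels (2.5D input)
#'
#' For each slice i the channels are slices i-(k-1)/2 .. i+(k-1)/2, with edge
#' slices replicated at the volume boundary. `k = 3` is the standard 2.5D
#' input (three consecutive slices); `k = 1` is plain per-slice 2D
#' extraction.
#'
#' @param volume an `image_volume` or 3D array.
#' @param k odd number of slices to stack; must not exceed the slice count.
#' @return 4D array `[x, y, k, n_slices]`: per-slice multi-channel planes.
#' @export
stack_adjacent_slices <- function(volume, k = 3L) {
  arr <- as_vol_array(volume)
  d <- dim(arr)
  if (k %% 2L != 1L) stop("k must be odd")
  if (k > d[3]) stop("k exceeds the number of slices")
  h <- (k - 1L) %/% 2L
  out <- array(0, c(d[1], d[2], k, d[3]))
  for (i in seq_len(d[3]))
    for (j in seq_len(k)) {
      src <- min(max(i + j - 1L - h, 1L), d[3])
      out[, , j, i] <- arr[, , src]
    }
  out
}

#' Read a phantom spec from a YAML config file
#'
#' Every [phantom_spec()] field can be given in the YAML file; omitted
#' fields take their defaults.
#'
#' @param path YAML file path.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(phantom_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown phantom spec fields: ", paste(unknown, collapse = ", "))
  do.call(phantom_spec, cfg)
}
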