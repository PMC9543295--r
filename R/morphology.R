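#' Structuring element for lesion formation
#'
#' Builds the 3D structuring element used to form lesions from pixel-level
#' annotations: three stacked in-plane disks of radii 0.5, 1.5 and 0.5 mm
#' (one disk per slice, the largest in the middle). Radii are converted to
#' pixels by round-half-up with a minimum of 1 pixel, so the kernel adapts to
#' the in-plane resolution; along Z the element always spans `slice_count`
#' adjacent slices regardless of the physical slice spacing, because it is
#' defined slice-wise.
#'
#' @param pixel_size_mm in-plane pixel size in mm (assumed isotropic in-plane).
#' @param disk_radii_mm in-plane disk radii in mm, one per slice of the
#'   element; default `c(0.5, 1.5, 0.5)`.
#' @return Logical 3D array, odd-sized, point-symmetric.
#' @examples
#' dim(make_structuring_element(0.29))  # 11 x 11 x 3 (disk radii 2, 5, 2 px)
#' @export
make_structuring_element <- function(pixel_size_mm, disk_radii_mm = c(0.5, 1.5, 0.5)) {
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be positive")
  r_px <- pmax(1L, as.integer(floor(disk_radii_mm / pixel_size_mm + 0.5)))
  rmax <- max(r_px)
  side <- 2L * rmax + 1L
  off <- seq(-rmax, rmax)
  d2 <- outer(off^2, off^2, `+`)
  kern <- array(FALSE, c(side, side, length(r_px)))
  for (i in seq_along(r_px))
    kern[, , i] <- d2 <= r_px[i]^2
  kern
}

# Pad a logical/0-1 array by `p` (per-axis) zeros on each side.
pad_array <- function(x, p) {
  d <- dim(x)
  out <- array(FALSE, d + 2L * p)
  out[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3])] <- x
  out
}

crop_array <- function(x, p, d) {
  x[p[1] + seq_len(d[1]), p[2] + seq_len(d[2]), p[3] + seq_len(d[3]), drop = FALSE]
}

#' Binary morphology with an arbitrary 3D structuring element
#'
#' Dilation, erosion and closing on logical volumes, computed by FFT
#' convolution with zero (background) padding. `binary_close` performs the
#' closing on an enlarged canvas so that it equals the mathematical closing of
#' the voxel set in an unbounded grid — in particular it is extensive
#' (`output >= input` voxelwise) everywhere, including at the image border.
#'
#' @param mask logical 3D array (or `image_volume` of 0/1).
#' @param kern logical 3D structuring element with odd dimensions, e.g. from
#'   [make_structuring_element()].
#' @return Logical 3D array of the same dimensions as `mask`.
#' @export
binary_dilate <- function(mask, kern) {
  m <- as_vol_array(mask)
  conv3d_same(m * 1, kern * 1) > 0.5
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, kern) {
  m <- as_vol_array(mask)
  conv3d_same(m * 1, kern * 1) > sum(kern) - 0.5
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, kern) {
  m <- as_vol_array(mask)
  d <- dim(m)
  p <- (dim(kern) - 1L) %/% 2L
  mp <- pad_array(m, p)
  crop_array(binary_erode(binary_dilate(mp, kern), kern), p, d)
}

# Half neighbourhood offsets (each unordered pair once) for 6- and
# 26-connectivity in 3D.
half_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else if (connectivity == 26L) {
    offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
    offs <- offs[!(offs$ox == 0 & offs$oy == 0 & offs$oz == 0), ]
    # keep lexicographically positive half
    keep <- offs$oz > 0 | (offs$oz == 0 & offs$oy > 0) |
      (offs$oz == 0 & offs$oy == 0 & offs$ox > 0)
    lapply(which(keep), function(i) as.integer(offs[i, ]))
  } else stop("connectivity must be 6 or 26")
}

#' Label 3D connected components
#'
#' Connected-component labeling of a binary volume under 6- or
#' 26-connectivity, built on a voxel-adjacency graph (igraph). Components are
#' numbered 1..n in order of their first voxel in array (column-major) order.
#'
#' @param mask logical 3D array or `image_volume`.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners); default 26.
#' @return Integer array of the same dimensions: 0 background, 1..n component
#'   labels.
#' @export
label_components <- function(mask, connectivity = 26L) {
  m <- as_vol_array(mask)
  d <- dim(m)
  fg <- which(m)
  n <- length(fg)
  out <- array(0L, d)
  if (n == 0L) return(out)
  idvol <- array(0L, d)
  idvol[fg] <- seq_len(n)
  idp <- array(0L, d + 2L)
  idp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- idvol
  edges <- vector("list", 0L)
  core <- idvol
  for (off in half_offsets(as.integer(connectivity))) {
    sh <- idp[(2L + off[1]):(d[1] + 1L + off[1]),
              (2L + off[2]):(d[2] + 1L + off[2]),
              (2L + off[3]):(d[3] + 1L + off[3]), drop = FALSE]
    hit <- core > 0L & sh > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- rbind(core[hit], sh[hit])
  }
  if (length(edges)) {
    ev <- as.vector(do.call(cbind, edges))
    g <- igraph::make_graph(ev, n = n, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
  }
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in array order
  u <- unique(memb)
  relab <- integer(max(memb))
  relab[u] <- seq_along(u)
  out[fg] <- relab[memb]
  out
}
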