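# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Queue-based flood fill connected-component labeling.
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  offs <- offs[!(offs$ox == 0 & offs$oy == 0 & offs$oz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$ox) + abs(offs$oy) + abs(offs$oz) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        ni <- vi + as.integer(offs[k, ])
        if (any(ni < 1L) || any(ni > d)) next
        nl <- (ni[3] - 1L) * d[1] * d[2] + (ni[2] - 1L) * d[1] + ni[1]
        if (mask[nl] && lab[nl] == 0L) {
          lab[nl] <- nxt
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

# Pair-counting ROC-AUC (ties count 1/2).
auc_bruteforce <- function(pos, neg) {
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

dice_bruteforce <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i]) sa <- sa + 1
    if (b[i]) sb <- sb + 1
  }
  if (sa + sb == 0) return(NA_real_)
  2 * inter / (sa + sb)
}

# Independent re-evaluation of the two-branch 1% rule.
classify_bruteforce <- function(na, ni, NL, thr = 0.01) {
  fa <- na / NL
  fi <- ni / NL
  if (fa >= thr) return("aggressive")
  if (fi >= thr) return("indolent")
  "benign"
}

# Random blobby 3D mask spanning at least `min_slices` slices.
random_prostate_mask <- function(d = c(24, 24, 8), min_slices = 4) {
  repeat {
    ctr <- d / 2 + stats::runif(3, -2, 2)
    ax <- c(stats::runif(1, d[1] / 4, d[1] / 2.2),
            stats::runif(1, d[2] / 4, d[2] / 2.2),
            stats::runif(1, d[3] / 3, d[3] / 2))
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    q <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
         ((g$z - ctr[3]) / ax[3])^2
    m <- array(q <= 1, d)
    if (sum(apply(m, 3, any)) >= min_slices && any(m)) return(m)
  }
}

# Small phantom spec used across tests: 64 mm field of view at 1 mm pixels,
# 12 slices at 3 mm, lesions 4-6 mm radius.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_x = 64L, grid_y = 64L, n_slices = 12L,
                   pixel_size_mm = 1.0, slice_spacing_mm = 3.0,
                   n_lesions = 2L, lesion_radius_range_mm = c(4, 6))
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Hand-built grade map fixture: prostate block with one or two rectangular
# "lesions" whose sizes are chosen in voxels (1 x 1 x 3 mm voxels).
grade_fixture <- function(d = c(32L, 32L, 6L)) {
  pm <- array(FALSE, d)
  pm[3:30, 3:30, 1:6] <- TRUE
  gm <- array(0L, d)
  gm[pm] <- 1L
  list(pm = pm, gm = gm, spacing = c(1, 1, 3))
}
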