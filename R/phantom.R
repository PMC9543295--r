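#' Specification of a synthetic prostate phantom
#'
#' Parameters of the seeded phantom generator. The defaults emulate the
#' geometry of clinical co-registered prostate MRI: 224 x 224 in-plane grids
#' at 0.29 x 0.29 mm pixels, 3 mm slice spacing (valid range 3-4.2 mm), and
#' imperfect human annotations — radiologists miss ~20% of lesions
#' (MRI-invisible or hardly visible tumors), annotate only a subset of
#' slices, and underestimate lesion extent so that outline volumes average
#' about 68% of the full pathology extent; pathologists outline the full
#' extent on the slices they annotate but skip some slices.
#'
#' @param grid_x,grid_y in-plane voxel counts (default 224 x 224).
#' @param n_slices number of axial slices (8-16 is typical).
#' @param pixel_size_mm in-plane pixel size in mm (default 0.29).
#' @param slice_spacing_mm distance between slices in mm; must lie in
#'   `[3, 4.2]` (default 3).
#' @param n_lesions lesions planted per case.
#' @param lesion_radius_range_mm `(min, max)` ellipsoid semi-axis range in mm.
#' @param aggressive_fraction_range `(min, max)` fraction of a lesion's
#'   cancer voxels that are Gleason-pattern-4+ when the lesion is not drawn
#'   pure indolent.
#' @param indolent_lesion_prob probability a lesion is pure Gleason-pattern-3
#'   (aggressive fraction 0).
#' @param lesion_contrast relative signal drop of lesions on T2w/ADC
#'   (0 = MRI-invisible lesion).
#' @param noise_sigma additive Gaussian noise scale.
#' @param smooth_sigma_mm in-plane Gaussian smoothing of the intensity
#'   images, in mm.
#' @param rad_miss_prob probability a lesion gets no radiologist outline
#'   (default 0.2).
#' @param rad_shrink_factor in-plane linear scale of radiologist outlines
#'   about the per-slice centroid; with the default slice-skip probability
#'   the default 0.87 gives outline volumes ~= 0.68 x the true lesion volume
#'   on average.
#' @param rad_slice_skip_prob,path_slice_skip_prob per-lesion-slice
#'   probability that the radiologist / pathologist skips that slice.
#' @param min_separation_mm minimum gap between lesion surfaces, kept larger
#'   than the reach of the lesion-formation structuring element so planted
#'   lesions stay distinct after morphological closing.
#' @param seed master seed; identical spec + seed reproduce a byte-identical
#'   cohort.
#' @return Object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(grid_x = 224L, grid_y = 224L, n_slices = 12L,
                         pixel_size_mm = 0.29, slice_spacing_mm = 3.0,
                         n_lesions = 2L,
                         lesion_radius_range_mm = c(4.5, 7),
                         aggressive_fraction_range = c(0.2, 0.8),
                         indolent_lesion_prob = 0.3,
                         lesion_contrast = 0.4, noise_sigma = 0.05,
                         smooth_sigma_mm = 0.6,
                         rad_miss_prob = 0.2, rad_shrink_factor = 0.87,
                         rad_slice_skip_prob = 0.1,
                         path_slice_skip_prob = 0.1,
                         min_separation_mm = 5, seed = 1L) {
  spec <- list(grid_x = as.integer(grid_x), grid_y = as.integer(grid_y),
               n_slices = as.integer(n_slices),
               pixel_size_mm = pixel_size_mm,
               slice_spacing_mm = slice_spacing_mm,
               n_lesions = as.integer(n_lesions),
               lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
               aggressive_fraction_range = as.numeric(aggressive_fraction_range),
               indolent_lesion_prob = indolent_lesion_prob,
               lesion_contrast = lesion_contrast, noise_sigma = noise_sigma,
               smooth_sigma_mm = smooth_sigma_mm,
               rad_miss_prob = rad_miss_prob,
               rad_shrink_factor = rad_shrink_factor,
               rad_slice_skip_prob = rad_slice_skip_prob,
               path_slice_skip_prob = path_slice_skip_prob,
               min_separation_mm = min_separation_mm,
               seed = as.integer(seed))
  probs <- c(spec$rad_miss_prob, spec$rad_slice_skip_prob,
             spec$path_slice_skip_prob, spec$indolent_lesion_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (spec$pixel_size_mm <= 0 || spec$smooth_sigma_mm < 0)
    stop("lengths must be positive")
  if (spec$slice_spacing_mm < 3 || spec$slice_spacing_mm > 4.2)
    stop("slice_spacing_mm must be in [3, 4.2] mm")
  rr <- spec$lesion_radius_range_mm
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
    stop("lesion_radius_range_mm must be positive with min <= max")
  af <- spec$aggressive_fraction_range
  if (length(af) != 2L || any(af < 0 | af > 1) || af[1] > af[2])
    stop("aggressive_fraction_range must be fractions with min <= max")
  if (spec$rad_shrink_factor <= 0 || spec$rad_shrink_factor > 1)
    stop("rad_shrink_factor must be in (0, 1]")
  if (spec$grid_x < 8L || spec$grid_y < 8L || spec$n_slices < 3L)
    stop("grid too small")
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d @ %.3g x %.3g x %.3g mm, %d lesion(s)/case, seed %d\n",
              x$grid_x, x$grid_y, x$n_slices, x$pixel_size_mm, x$pixel_size_mm,
              x$slice_spacing_mm, x$n_lesions, x$seed))
  invisible(x)
}

# mm coordinates of voxel centres along each axis, centred on the grid.
grid_coords_mm <- function(spec) {
  list(x = (seq_len(spec$grid_x) - (spec$grid_x + 1) / 2) * spec$pixel_size_mm,
       y = (seq_len(spec$grid_y) - (spec$grid_y + 1) / 2) * spec$pixel_size_mm,
       z = (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) * spec$slice_spacing_mm)
}

# Filled ellipsoidal gland spanning most slices; semi-axes scale with the
# field of view so phantoms remain anatomically proportioned at any grid.
gland_mask <- function(spec) {
  co <- grid_coords_mm(spec)
  ax <- 0.33 * spec$grid_x * spec$pixel_size_mm
  ay <- 0.28 * spec$grid_y * spec$pixel_size_mm
  az <- (spec$n_slices - 2) / 2 * spec$slice_spacing_mm
  q <- outer(outer((co$x / ax)^2, (co$y / ay)^2, `+`), (co$z / az)^2, `+`)
  q <= 1
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate one synthetic phantom case
#'
#' Builds a co-registered case: an ellipsoidal prostate mask, randomly
#' oriented ellipsoidal lesions with per-voxel Gleason-pattern assignment
#' (a contiguous aggressive component occupying the drawn aggressive
#' fraction), T2w and ADC intensity volumes (tissue level minus
#' `lesion_contrast` inside lesions, smoothed, plus seeded noise), the truth
#' grade map and lesion set, and simulated radiologist and pathologist
#' outline volumes.
#'
#' @param spec a [phantom_spec()].
#' @param case_seed integer seed for this case; the same spec and case_seed
#'   reproduce identical voxel arrays.
#' @param case_id identifier recorded on the case.
#' @return Object of class `phantom_case`: list with `case_id`, `t2w`, `adc`
#'   (`image_volume`s), `prostate_mask`, `truth_grade_map`, `truth_lesions`
#'   (a `lesion_set`), `rad_outline`, `path_outline`, `spacing`, `case_seed`.
#' @export
generate_phantom <- function(spec, case_seed = spec$seed,
                             case_id = sprintf("case_%d", case_seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(case_seed, {
    d <- c(spec$grid_x, spec$grid_y, spec$n_slices)
    spacing <- c(spec$pixel_size_mm, spec$pixel_size_mm, spec$slice_spacing_mm)
    mask <- gland_mask(spec)
    co <- grid_coords_mm(spec)
    interior <- which(mask)
    grade <- array(0L, d)
    grade[mask] <- 1L

    lesion_vox <- list()
    lesion_info <- list()
    rr <- spec$lesion_radius_range_mm
    ax <- 0.33 * spec$grid_x * spec$pixel_size_mm
    ay <- 0.28 * spec$grid_y * spec$pixel_size_mm
    az <- (spec$n_slices - 2) / 2 * spec$slice_spacing_mm
    int_ind <- arrayInd(interior, d)
    int_mm <- cbind(co$x[int_ind[, 1]], co$y[int_ind[, 2]], co$z[int_ind[, 3]])
    lesion_codes <- list()
    # whole-case placement attempts: if one lesion cannot be placed, restart
    # the case layout (earlier lesions may simply be in the way)
    for (attempt in seq_len(25L)) {
      lesion_vox <- list(); lesion_info <- list(); lesion_codes <- list()
      failed <- FALSE
      for (li in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in seq_len(40L)) {
        r <- stats::runif(3, rr[1], rr[2])
        rot <- random_rotation()
        # centres for which a ball of radius max(r) provably fits in the
        # gland ellipsoid: sum_i ((|c_i| + r) / axis_i)^2 <= 1
        fit <- ((abs(int_mm[, 1]) + max(r)) / ax)^2 +
               ((abs(int_mm[, 2]) + max(r)) / ay)^2 +
               ((abs(int_mm[, 3]) + max(r)) / az)^2 <= 1
        if (!any(fit)) next
        # keep centres whose surface gap to already-placed lesions is at
        # least min_separation_mm (conservative: centre distance minus both
        # maximal radii), so lesions stay distinct after morphological
        # closing
        if (length(lesion_vox)) {
          cand <- int_mm[fit, , drop = FALSE]
          ok <- rep(TRUE, nrow(cand))
          for (pl in lesion_info) {
            dc <- sqrt((cand[, 1] - pl$center[1])^2 +
                       (cand[, 2] - pl$center[2])^2 +
                       (cand[, 3] - pl$center[3])^2)
            ok <- ok & (dc - pl$rmax - max(r) >= spec$min_separation_mm)
          }
          if (!any(ok)) next
          okw <- which(ok)
          cmm <- cand[okw[sample.int(length(okw), 1L)], ]
        } else {
          fitw <- which(fit)
          cmm <- int_mm[fitw[sample.int(length(fitw), 1L)], ]
        }
        # voxelize within the bounding box
        rmax <- max(r)
        bx <- which(abs(co$x - cmm[1]) <= rmax + spec$pixel_size_mm)
        by <- which(abs(co$y - cmm[2]) <= rmax + spec$pixel_size_mm)
        bz <- which(abs(co$z - cmm[3]) <= rmax + spec$slice_spacing_mm)
        if (!length(bx) || !length(by) || !length(bz)) next
        gridb <- expand.grid(x = bx, y = by, z = bz)
        D <- rbind(co$x[gridb$x] - cmm[1], co$y[gridb$y] - cmm[2],
                   co$z[gridb$z] - cmm[3])
        U <- crossprod(rot, D)
        inside <- colSums((U / r)^2) <= 1
        if (!any(inside)) next
        lin <- (gridb$z[inside] - 1L) * d[1] * d[2] +
               (gridb$y[inside] - 1L) * d[1] + gridb$x[inside]
        if (!all(mask[lin])) next               # must fit inside the gland
        # aggressive component: contiguous half-space split at the drawn
        # fraction along a random direction through the lesion
        f <- if (stats::runif(1) < spec$indolent_lesion_prob) 0 else
          stats::runif(1, spec$aggressive_fraction_range[1],
                       spec$aggressive_fraction_range[2])
        n <- length(lin)
        n_agg <- round(f * n)
        codes <- rep(2L, n)
        if (n_agg > 0) {
          w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
          proj <- colSums(w * D[, inside, drop = FALSE])
          codes[order(proj, decreasing = TRUE)[seq_len(n_agg)]] <- 3L
        }
        lesion_vox[[li]] <- lin
        lesion_codes[[li]] <- codes
        lesion_info[[li]] <- list(n_agg = sum(codes == 3L),
                                  n_ind = sum(codes == 2L),
                                  center = cmm, rmax = max(r))
        placed <- TRUE
        break
      }
      if (!placed) { failed <- TRUE; break }
      }
      if (!failed) break
      if (attempt == 25L)
        stop(sprintf("lesion placement failed for %s: prostate mask too small for requested radii",
                     case_id))
    }
    for (li in seq_along(lesion_vox))
      grade[lesion_vox[[li]]] <- lesion_codes[[li]]

    truth <- new_lesion_set(lesion_vox, d, spacing, provenance = "truth")
    for (i in seq_along(lesion_vox)) {
      truth$table$n_aggressive[i] <- lesion_info[[i]]$n_agg
      truth$table$n_indolent[i] <- lesion_info[[i]]$n_ind
      truth$table$class[i] <- classify_lesion(lesion_info[[i]]$n_agg,
                                              lesion_info[[i]]$n_ind,
                                              truth$table$NL[i])
    }
    truth$table$kept <- truth$table$volume_mm3 >= 250

    lesion_any <- array(FALSE, d)
    for (v in lesion_vox) lesion_any[v] <- TRUE
    sig <- spec$smooth_sigma_mm / spec$pixel_size_mm
    make_modality <- function(outside_level) {
      img <- array(outside_level, d)
      img[mask] <- 1
      img[lesion_any] <- 1 - spec$lesion_contrast
      img <- gauss_smooth(img, c(sig, sig, 0))
      img + stats::rnorm(length(img)) * spec$noise_sigma
    }
    t2w <- make_modality(0.45)
    adc <- make_modality(0.60)

    case <- structure(list(case_id = case_id,
                           t2w = image_volume(t2w, spacing),
                           adc = image_volume(adc, spacing),
                           prostate_mask = mask,
                           truth_grade_map = grade,
                           truth_lesions = truth,
                           rad_outline = NULL, path_outline = NULL,
                           spacing = spacing, case_seed = as.integer(case_seed),
                           spec = spec),
                      class = "phantom_case")
    case$rad_outline <- simulate_radiologist_outline(case, spec,
                                                     derive_seed(case_seed, 104729L))
    case$path_outline <- simulate_pathologist_outline(case, spec,
                                                      derive_seed(case_seed, 224737L))
    case
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %d x %d x %d, %d lesion(s), %d rad-outlined\n",
              x$case_id, dim(x$prostate_mask)[1], dim(x$prostate_mask)[2],
              dim(x$prostate_mask)[3], length(x$truth_lesions),
              {
                ov <- x$rad_outline
                if (is.null(ov)) 0L else
                  sum(vapply(x$truth_lesions$voxels,
                             function(v) any(ov[v]), logical(1)))
              }))
  invisible(x)
}

#' Simulate an imperfect radiologist outline volume
#'
#' For each true lesion, with probability `1 - rad_miss_prob` the radiologist
#' outlines it: the lesion mask is shrunk in-plane by `rad_shrink_factor`
#' about each slice's centroid (a voxel is kept iff its pre-image under the
#' scaling lies inside the lesion slice), then individual slices are dropped
#' with `rad_slice_skip_prob`. With miss probability 1 the outline volume is
#' all zero (a fully missed case); with shrink 1 and no skipping the outline
#' equals the lesion mask. Outlines never extend outside the prostate.
#'
#' @param case a `phantom_case`.
#' @param spec the [phantom_spec()] (annotator parameters).
#' @param seed RNG seed for the annotator's choices.
#' @return Logical 3D outline volume.
#' @export
simulate_radiologist_outline <- function(case, spec, seed) {
  with_seed(seed, {
    d <- dim(case$prostate_mask)
    out <- array(FALSE, d)
    s <- spec$rad_shrink_factor
    for (vox in case$truth_lesions$voxels) {
      if (stats::runif(1) < spec$rad_miss_prob) next
      ind <- arrayInd(vox, d)
      for (z in sort(unique(ind[, 3]))) {
        sl <- ind[ind[, 3] == z, , drop = FALSE]
        if (stats::runif(1) < spec$rad_slice_skip_prob) next
        cx <- mean(sl[, 1]); cy <- mean(sl[, 2])
        inslice <- matrix(FALSE, d[1], d[2])
        inslice[sl[, 1:2, drop = FALSE]] <- TRUE
        px <- pmin(pmax(round(cx + (sl[, 1] - cx) / s), 1L), d[1])
        py <- pmin(pmax(round(cy + (sl[, 2] - cy) / s), 1L), d[2])
        keep <- inslice[cbind(px, py)]
        if (any(keep))
          out[cbind(sl[keep, 1:2, drop = FALSE], z)] <- TRUE
      }
    }
    out
  })
}

#' Simulate a pathologist cancer-outline volume
#'
#' The pathologist outlines the full lesion extent on each annotated slice
#' but skips individual lesion slices with probability
#' `path_slice_skip_prob`; the outline carries no grade information (binary).
#'
#' @inheritParams simulate_radiologist_outline
#' @return Logical 3D outline volume.
#' @export
simulate_pathologist_outline <- function(case, spec, seed) {
  with_seed(seed, {
    d <- dim(case$prostate_mask)
    out <- array(FALSE, d)
    for (vox in case$truth_lesions$voxels) {
      ind <- arrayInd(vox, d)
      for (z in sort(unique(ind[, 3]))) {
        if (stats::runif(1) < spec$path_slice_skip_prob) next
        sl <- ind[ind[, 3] == z, , drop = FALSE]
        out[cbind(sl[, 1:2, drop = FALSE], z)] <- TRUE
      }
    }
    out
  })
}

#' Generate a seeded phantom cohort
#'
#' Per-case seeds are derived deterministically from the master seed with a
#' splittable scheme, so cohorts are reproducible and extensible (adding
#' cases does not reshuffle earlier ones).
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of cases (>= 1).
#' @param seed master seed; defaults to `spec$seed`.
#' @return Object of class `phantom_cohort`: named list of `phantom_case`s
#'   (names are case ids) with attributes `spec` and `seed`.
#' @export
generate_cohort <- function(spec, n_cases, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), n_cases >= 1)
  cases <- vector("list", n_cases)
  ids <- sprintf("case_%03d", seq_len(n_cases))
  for (i in seq_len(n_cases)) {
    cases[[i]] <- tryCatch(
      generate_phantom(spec, derive_seed(seed, i), case_id = ids[i]),
      error = function(e) stop(sprintf("case %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  }
  names(cases) <- ids
  structure(cases, spec = spec, seed = as.integer(seed),
            class = c("phantom_cohort", "list"))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, master seed %d\n",
              length(x), attr(x, "seed")))
  invisible(x)
}

#' Per-lesion radiologist outline volume ratio
#'
#' Ratio of radiologist-outlined voxels to true lesion voxels for each
#' outlined lesion of a case (missed lesions, ratio 0, are excluded): the
#' quantity whose cohort mean the annotator model calibrates to ~0.68.
#'
#' @param case a `phantom_case`.
#' @return Numeric vector, one ratio per outlined lesion (possibly empty).
#' @export
outline_volume_ratio <- function(case) {
  r <- vapply(case$truth_lesions$voxels,
              function(v) sum(case$rad_outline[v]) / length(v), numeric(1))
  r[r > 0]
}

#' Write / read a phantom cohort as NIfTI plus a JSON manifest
#'
#' Each case is written as one NIfTI file per channel (t2w, adc, prostate
#' mask, grade map, radiologist and pathologist outlines; masks use integer
#' codes, grade maps 0 outside / 1 normal / 2 indolent / 3 aggressive),
#' with a cohort manifest (`manifest.json`) mapping case ids to file paths
#' and recording the spec, its MD5 hash, and the master seed.
#' `read_cohort` reconstructs each case; truth lesion sets are rebuilt as the
#' connected components of the grade map's cancer voxels (planted lesions
#' are generated well-separated, so this recovers them exactly).
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @param connectivity connectivity used to rebuild lesion sets on read.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `phantom_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- attr(cohort, "spec")
  spec_json <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json"); writeLines(spec_json, tf)
  manifest <- list(seed = attr(cohort, "seed"), spec = unclass(spec),
                   spec_md5 = unname(tools::md5sum(tf)), cases = list())
  unlink(tf)
  channels <- c("t2w", "adc", "prostate", "grade", "rad", "path")
  for (cid in names(cohort)) {
    case <- cohort[[cid]]
    sp <- case$spacing
    vols <- list(t2w = case$t2w,
                 adc = case$adc,
                 prostate = image_volume(case$prostate_mask * 1L, sp),
                 grade = image_volume(case$truth_grade_map, sp),
                 rad = image_volume(case$rad_outline * 1L, sp),
                 path = image_volume(case$path_outline * 1L, sp))
    files <- stats::setNames(file.path(dir, sprintf("%s_%s.nii.gz", cid, channels)),
                             channels)
    for (ch in channels) write_volume(vols[[ch]], files[[ch]])
    manifest$cases[[cid]] <- as.list(stats::setNames(basename(files), channels))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, connectivity = 26L) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  spec <- do.call(phantom_spec, manifest$spec[setdiff(names(manifest$spec), character(0))])
  cases <- list()
  for (cid in names(manifest$cases)) {
    f <- manifest$cases[[cid]]
    rd <- function(ch) read_volume(file.path(dir, f[[ch]]))
    t2w <- rd("t2w"); adc <- rd("adc")
    pm <- as_vol_array(rd("prostate")) > 0.5
    grade <- array(as.integer(round(as_vol_array(rd("grade")))), dim(pm))
    sp <- t2w$spacing
    lab <- label_components(grade >= 2L, connectivity)
    vox <- if (max(lab) > 0) {
      w <- which(lab > 0); v <- split(w, lab[w]); names(v) <- NULL; v
    } else list()
    truth <- new_lesion_set(vox, dim(pm), sp, provenance = "truth")
    truth <- classify_lesions(truth, grade)
    truth$table$kept <- truth$table$volume_mm3 >= 250
    cases[[cid]] <- structure(
      list(case_id = cid, t2w = t2w, adc = adc, prostate_mask = pm,
           truth_grade_map = grade, truth_lesions = truth,
           rad_outline = as_vol_array(rd("rad")) > 0.5,
           path_outline = as_vol_array(rd("path")) > 0.5,
           spacing = sp, case_seed = NA_integer_, spec = spec),
      class = "phantom_case")
  }
  structure(cases, spec = spec, seed = manifest$seed,
            class = c("phantom_cohort", "list"))
}
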