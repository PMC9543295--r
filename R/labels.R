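#' Lesion volume in cubic millimetres
#'
#' Volume of a 3D lesion, `LV = PSx * PSy * Dz * NL`, where `PSx`, `PSy` are
#' the in-plane pixel sizes, `Dz` the distance between consecutive slices and
#' `NL` the number of voxels in the lesion (counted on the closed lesion mask).
#'
#' @param NL voxel count (non-negative integer, vectorised).
#' @param PSx,PSy in-plane pixel sizes in mm.
#' @param Dz slice spacing in mm.
#' @return Lesion volume(s) in mm^3, the exact product.
#' @examples
#' lesion_volume(1000, 0.29, 0.29, 3.0)  # 252.3
#' @export
lesion_volume <- function(NL, PSx, PSy, Dz) {
  if (any(c(PSx, PSy, Dz) <= 0)) stop("pixel sizes and slice spacing must be positive")
  if (any(NL < 0)) stop("NL must be non-negative")
  PSx * PSy * Dz * NL
}

#' Classify a lesion from its grade-voxel composition (1% rule)
#'
#' A lesion containing at least 1% aggressive (Gleason pattern 4 and above)
#' voxels is aggressive; otherwise, if it contains at least 1% indolent
#' (Gleason pattern 3) voxels it is indolent; otherwise it is benign tissue.
#'
#' @param n_aggressive,n_indolent voxel counts of each grade inside the
#'   lesion (vectorised).
#' @param NL total lesion voxel count; must be positive.
#' @param threshold fraction threshold, default 0.01.
#' @return Character vector in `c("aggressive", "indolent", "benign")`.
#' @export
classify_lesion <- function(n_aggressive, n_indolent, NL, threshold = 0.01) {
  if (any(NL <= 0)) stop("NL must be positive")
  if (any(n_aggressive + n_indolent > NL)) stop("grade counts exceed lesion size")
  ifelse(n_aggressive / NL >= threshold, "aggressive",
         ifelse(n_indolent / NL >= threshold, "indolent", "benign"))
}

#' Classify a lesion from a targeted-biopsy Gleason grade group
#'
#' Mapping used when no per-voxel grade map exists and lesions are confirmed
#' by targeted biopsy: grade group >= 2 is aggressive, grade group 1 is
#' indolent, and a benign biopsy means normal tissue.
#'
#' @param grade_group integer 1..5, or the string `"benign"` (vectorised).
#' @return Character vector in `c("aggressive", "indolent", "normal")`.
#' @export
classify_from_grade_group <- function(grade_group) {
  vapply(as.list(grade_group), function(g) {
    if (identical(g, "benign")) return("normal")
    g <- suppressWarnings(as.numeric(g))
    if (is.na(g) || g != as.integer(g) || g < 1 || g > 5)
      stop("grade_group must be 1..5 or \"benign\"")
    if (g >= 2) "aggressive" else "indolent"
  }, character(1))
}

# Internal constructor for a lesion set.
new_lesion_set <- function(voxels, dim, spacing, provenance = NA_character_) {
  NL <- vapply(voxels, length, integer(1))
  n <- length(voxels)
  tab <- data.frame(
    lesion_id = seq_len(n),
    NL = NL,
    volume_mm3 = lesion_volume(NL, spacing[1], spacing[2], spacing[3]),
    n_aggressive = rep(NA_integer_, n),
    n_indolent = rep(NA_integer_, n),
    class = rep(NA_character_, n),
    kept = rep(NA, n),
    stringsAsFactors = FALSE
  )
  structure(list(voxels = voxels, table = tab, dim = dim, spacing = spacing,
                 provenance = provenance),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  nk <- sum(x$table$kept %in% TRUE)
  nd <- sum(x$table$kept %in% FALSE)
  cat(sprintf("<lesion_set> %d lesions (%d kept, %d discarded)%s\n",
              nrow(x$table), nk, nd,
              if (!is.na(x$provenance)) paste0(", provenance: ", x$provenance) else ""))
  if (nrow(x$table)) print(x$table, ...)
  invisible(x)
}

#' @export
length.lesion_set <- function(x) nrow(x$table)

#' Form 3D lesions from a binary annotation mask
#'
#' Converts pixel-level annotations into lesions continuous in the MRI
#' volume: morphological closing with the stacked-disk structuring element,
#' intersection with the prostate mask, then 3D connected-component
#' labeling. Voxel counts (`NL`) are taken on the closed mask. With
#' `per_component = TRUE` (used for human outlines) each connected component
#' of the raw mask is closed separately, so closing never merges outlines of
#' distinct annotated lesions.
#'
#' @param mask logical 3D array or `image_volume`: the pixel-level annotation.
#' @param spacing voxel spacing `c(px, py, dz)` in mm (taken from `mask` if it
#'   is an `image_volume`).
#' @param prostate_mask optional logical array; closed lesions are clipped to
#'   it.
#' @param connectivity 6 or 26 (default 26).
#' @param selem structuring element; default [make_structuring_element()] at
#'   the in-plane pixel size.
#' @param per_component close each raw connected component separately.
#' @param provenance optional string recorded on the result.
#' @return A `lesion_set` (pre-filter: `kept` is `NA` until
#'   [filter_lesions()]).
#' @export
form_lesions <- function(mask, spacing = NULL, prostate_mask = NULL,
                         connectivity = 26L, selem = NULL,
                         per_component = FALSE, provenance = NA_character_) {
  if (is.null(spacing)) spacing <- vol_spacing(mask)
  m <- as_vol_array(mask)
  if (!is.logical(m)) m <- m > 0.5
  d <- dim(m)
  pm <- if (is.null(prostate_mask)) NULL else as_vol_array(prostate_mask) > 0.5
  if (!is.null(pm) && any(m & !pm))
    stop("annotation mask extends outside the prostate mask")
  if (is.null(selem)) selem <- make_structuring_element(spacing[1])
  clip <- function(x) if (is.null(pm)) x else x & pm
  voxels <- list()
  if (!any(m)) return(new_lesion_set(voxels, d, spacing, provenance))
  if (per_component) {
    raw <- label_components(m, connectivity)
    for (i in seq_len(max(raw))) {
      comp <- raw == i
      closed <- clip(binary_close(comp, selem))
      voxels[[length(voxels) + 1L]] <- which(closed)
    }
  } else {
    closed <- clip(binary_close(m, selem))
    lab <- label_components(closed, connectivity)
    nlab <- max(lab)
    if (nlab > 0) {
      w <- which(lab > 0)
      voxels <- split(w, lab[w])
      names(voxels) <- NULL
    }
  }
  new_lesion_set(voxels, d, spacing, provenance)
}

#' Discard lesions below the clinical volume threshold
#'
#' Lesions with volume less than `min_volume` mm^3 (default 250, half the
#' 500 mm^3 clinical-significance threshold of PI-RADS v2) are discarded;
#' a lesion of exactly `min_volume` is kept. Both kept and discarded lesions
#' are retained in the table for descriptive statistics.
#'
#' @param lesion_set a `lesion_set`.
#' @param min_volume threshold in mm^3; strict `<` discards.
#' @return The `lesion_set` with its `kept` column filled in.
#' @export
filter_lesions <- function(lesion_set, min_volume = 250) {
  stopifnot(inherits(lesion_set, "lesion_set"))
  lesion_set$table$kept <- lesion_set$table$volume_mm3 >= min_volume
  lesion_set
}

#' Fill grade composition and class of each lesion from a grade map
#'
#' Counts aggressive (code 3) and indolent (code 2) voxels of the grade map
#' inside every lesion and applies the 1% rule via [classify_lesion()].
#'
#' @param lesion_set a `lesion_set`.
#' @param grade_map integer 3D array or `image_volume` with codes 0 outside,
#'   1 normal, 2 indolent, 3 aggressive.
#' @inheritParams classify_lesion
#' @return The `lesion_set` with `n_aggressive`, `n_indolent`, `class` filled.
#' @export
classify_lesions <- function(lesion_set, grade_map, threshold = 0.01) {
  stopifnot(inherits(lesion_set, "lesion_set"))
  g <- as_vol_array(grade_map)
  if (!all(dim(g) == lesion_set$dim)) stop("grade map grid mismatch")
  tab <- lesion_set$table
  for (i in seq_len(nrow(tab))) {
    gv <- g[lesion_set$voxels[[i]]]
    tab$n_aggressive[i] <- sum(gv == 3L)
    tab$n_indolent[i] <- sum(gv == 2L)
    tab$class[i] <- classify_lesion(tab$n_aggressive[i], tab$n_indolent[i],
                                    tab$NL[i], threshold)
  }
  lesion_set$table <- tab
  lesion_set
}

label_class_code <- c(benign = 1L, normal = 1L, indolent = 2L, aggressive = 3L)

#' Derive a label volume under one of the four labeling strategies
#'
#' Produces an integer-coded label volume (0 outside prostate, 1 normal,
#' 2 indolent cancer, 3 aggressive cancer) plus the lesion set behind it:
#'
#' * `LRad` — pathology-confirmed radiologist outlines: each annotated 3D
#'   component is closed separately, volume-filtered, and classified by the
#'   grade-map voxels inside it (1% rule); benign-classed outlines are left
#'   as normal tissue.
#' * `LPath` — pathologist cancer outlines, processed identically.
#' * `LLesionDPath` — lesion-level labels from the grade map itself: lesions
#'   formed on the cancer voxels (codes 2/3), filtered, classified, and each
#'   kept lesion painted uniformly with its class.
#' * `LPixelDPath` — same lesion footprints, but within each kept lesion the
#'   per-voxel grade codes are copied, so mixed lesions retain both indolent
#'   and aggressive components. Voxels added by closing (no grade code) take
#'   the majority cancer code within the structuring-element neighbourhood,
#'   ties resolved aggressive.
#'
#' @param grade_map integer array or `image_volume`, codes 0/1/2/3.
#' @param label_type one of `"LRad"`, `"LPath"`, `"LLesionDPath"`,
#'   `"LPixelDPath"`.
#' @param outline logical array or `image_volume`: the human outline volume
#'   (required for `LRad`/`LPath`, ignored otherwise).
#' @param prostate_mask logical array or `image_volume`.
#' @param spacing voxel spacing in mm; taken from `grade_map` if an
#'   `image_volume`.
#' @param connectivity 6 or 26.
#' @param min_volume lesion volume threshold in mm^3.
#' @param threshold 1% rule threshold.
#' @return An object of class `label_volume`: list with `codes` (integer
#'   array), `label_type`, `lesion_set`, `spacing`.
#' @export
derive_label <- function(grade_map, label_type, outline = NULL,
                         prostate_mask = NULL, spacing = NULL,
                         connectivity = 26L, min_volume = 250,
                         threshold = 0.01) {
  label_type <- match.arg(label_type, c("LRad", "LPath", "LLesionDPath", "LPixelDPath"))
  if (is.null(spacing)) spacing <- vol_spacing(grade_map)
  g <- as_vol_array(grade_map)
  pm <- if (is.null(prostate_mask)) g > 0L else as_vol_array(prostate_mask) > 0.5
  if (!all(dim(pm) == dim(g))) stop("prostate mask grid mismatch")
  selem <- make_structuring_element(spacing[1])

  human <- label_type %in% c("LRad", "LPath")
  if (human) {
    if (is.null(outline)) stop(label_type, " requires an outline volume")
    ov <- as_vol_array(outline) > 0.5
    if (!all(dim(ov) == dim(g))) stop("outline and grade map grids differ")
    ls <- form_lesions(ov, spacing, pm, connectivity, selem,
                       per_component = TRUE, provenance = label_type)
  } else {
    cancer <- g >= 2L
    ls <- form_lesions(cancer, spacing, pm, connectivity, selem,
                       per_component = FALSE, provenance = label_type)
  }
  ls <- filter_lesions(ls, min_volume)
  ls <- classify_lesions(ls, g, threshold)

  codes <- array(0L, dim(g))
  codes[pm] <- 1L
  tab <- ls$table
  if (label_type == "LPixelDPath") {
    # majority cancer code in the structuring-element neighbourhood, for
    # voxels the closing added (they carry no grade code)
    c2 <- conv3d_same((g == 2L) * 1, selem * 1)
    c3 <- conv3d_same((g == 3L) * 1, selem * 1)
    fill <- ifelse(c3 >= c2 - 1e-9, 3L, 2L)
  }
  for (i in seq_len(nrow(tab))) {
    if (!isTRUE(tab$kept[i])) next
    vox <- ls$voxels[[i]]
    if (label_type == "LPixelDPath") {
      gv <- g[vox]
      inside <- gv >= 2L
      codes[vox[inside]] <- gv[inside]
      codes[vox[!inside]] <- fill[vox[!inside]]
    } else {
      cl <- label_class_code[[tab$class[i]]]
      if (cl >= 2L) codes[vox] <- cl
    }
  }
  structure(list(codes = codes, label_type = label_type, lesion_set = ls,
                 spacing = spacing),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tb <- x$lesion_set$table
  cat(sprintf("<label_volume> %s: %d lesions kept (%d aggressive, %d indolent), %d discarded\n",
              x$label_type, sum(tb$kept %in% TRUE),
              sum(tb$kept %in% TRUE & tb$class == "aggressive"),
              sum(tb$kept %in% TRUE & tb$class == "indolent"),
              sum(tb$kept %in% FALSE)))
  invisible(x)
}

#' Lesion table across a list of label volumes
#'
#' Binds the per-lesion tables of derived labels into one data frame with
#' `case_id` and `label_type` columns, the analogue of a descriptive
#' annotation-statistics table (kept and discarded lesions both included).
#'
#' @param labels_by_case named list: case_id -> `label_volume`.
#' @return data.frame with columns case_id, label_type, lesion_id, NL,
#'   volume_mm3, n_aggressive, n_indolent, class, kept.
#' @export
lesion_table <- function(labels_by_case) {
  rows <- lapply(names(labels_by_case), function(cid) {
    lv <- labels_by_case[[cid]]
    tb <- lv$lesion_set$table
    if (!nrow(tb)) return(NULL)
    cbind(case_id = cid, label_type = lv$label_type, tb)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(case_id = character(), label_type = character(),
                      lesion_id = integer(), NL = integer(),
                      volume_mm3 = numeric(), n_aggressive = integer(),
                      n_indolent = integer(), class = character(),
                      kept = logical())
  rownames(out) <- NULL
  out
}
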