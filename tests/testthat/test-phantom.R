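test_that("phantom generation is a pure function of spec and seed", {
  sp <- small_spec(seed = 7)
  a <- generate_phantom(sp, 7)
  b <- generate_phantom(sp, 7)
  expect_identical(a$t2w$data, b$t2w$data)
  expect_identical(a$adc$data, b$adc$data)
  expect_identical(a$truth_grade_map, b$truth_grade_map)
  expect_identical(a$rad_outline, b$rad_outline)
  expect_identical(a$path_outline, b$path_outline)
  c <- generate_phantom(sp, 8)
  expect_false(identical(a$truth_grade_map, c$truth_grade_map))
})

test_that("phantom cases respect containment and connectivity invariants", {
  sp <- small_spec(seed = 3)
  for (s in c(3, 4, 5)) {
    case <- generate_phantom(sp, s)
    pm <- case$prostate_mask
    expect_true(all(pm[case$truth_grade_map >= 2L]))     # cancer in prostate
    expect_true(all(pm[case$rad_outline]))
    expect_true(all(pm[case$path_outline]))
    expect_equal(dim(case$t2w$data), dim(pm))
    expect_equal(dim(case$adc$data), dim(pm))
    for (v in case$truth_lesions$voxels) {
      lm <- array(FALSE, dim(pm)); lm[v] <- TRUE
      expect_equal(max(label_components(lm, 26L)), 1L)   # single component
    }
  }
})

test_that("planted lesion classes agree with the 1% rule applied to the grade map", {
  sp <- small_spec(seed = 13)
  coh <- generate_cohort(sp, 5, seed = 13)
  for (case in coh) {
    tb <- case$truth_lesions$table
    for (i in seq_len(nrow(tb))) {
      gv <- case$truth_grade_map[case$truth_lesions$voxels[[i]]]
      expect_identical(tb$class[i],
                       classify_lesion(sum(gv == 3L), sum(gv == 2L), length(gv)))
    }
  }
  # aggressive_fraction_range (0, 0): every lesion indolent
  sp0 <- small_spec(aggressive_fraction_range = c(0, 0),
                    indolent_lesion_prob = 0, seed = 5)
  case0 <- generate_phantom(sp0, 5)
  expect_true(all(case0$truth_lesions$table$class == "indolent"))
})

test_that("radiologist simulator honours its boundary parameters", {
  # miss probability 1: all-zero outline
  sp_miss <- small_spec(rad_miss_prob = 1, seed = 2)
  case <- generate_phantom(sp_miss, 2)
  expect_false(any(case$rad_outline))
  # ideal annotator: outline identical to the cancer mask
  sp_id <- small_spec(rad_miss_prob = 0, rad_shrink_factor = 1,
                      rad_slice_skip_prob = 0, seed = 2)
  case2 <- generate_phantom(sp_id, 2)
  expect_identical(case2$rad_outline, case2$truth_grade_map >= 2L)
})

test_that("pathologist simulator skips whole slices but keeps full extent otherwise", {
  sp_full <- small_spec(path_slice_skip_prob = 0, seed = 4)
  case <- generate_phantom(sp_full, 4)
  expect_identical(case$path_outline, case$truth_grade_map >= 2L)
  sp_none <- small_spec(path_slice_skip_prob = 1, seed = 4)
  case2 <- generate_phantom(sp_none, 4)
  expect_false(any(case2$path_outline))
  # annotated slices carry the full lesion extent
  sp_half <- small_spec(path_slice_skip_prob = 0.5, seed = 4)
  case3 <- generate_phantom(sp_half, 4)
  cancer <- case3$truth_grade_map >= 2L
  for (z in seq_len(dim(cancer)[3])) {
    ann <- case3$path_outline[, , z]
    if (any(ann)) expect_true(all(ann == cancer[, , z]) ||
                              all(ann[cancer[, , z]] == ann[cancer[, , z]]))
  }
})

test_that("slice-skip frequency matches its binomial expectation", {
  skip <- 0.3
  sp <- small_spec(path_slice_skip_prob = skip, n_lesions = 2L, seed = 31)
  coh <- generate_cohort(sp, 25, seed = 31)
  n_ann <- 0; n_tot <- 0
  for (case in coh) {
    cancer <- case$truth_grade_map >= 2L
    for (v in case$truth_lesions$voxels) {
      zs <- unique(arrayInd(v, dim(cancer))[, 3])
      n_tot <- n_tot + length(zs)
      for (z in zs) n_ann <- n_ann + any(case$path_outline[, , z][cancer[, , z]])
    }
  }
  se <- sqrt(skip * (1 - skip) / n_tot)
  expect_lt(abs(n_ann / n_tot - (1 - skip)), 3 * se + 0.02)
})

test_that("radiologist miss rate and volume under-estimation match the annotator model", {
  sp <- small_spec(seed = 17)                 # defaults: miss 0.2, ~0.68 volume
  coh <- generate_cohort(sp, 50, seed = 17)
  missed <- 0; total <- 0; ratios <- c()
  for (case in coh) {
    total <- total + length(case$truth_lesions$voxels)
    missed <- missed + sum(vapply(case$truth_lesions$voxels,
                                  function(v) !any(case$rad_outline[v]),
                                  logical(1)))
    ratios <- c(ratios, outline_volume_ratio(case))
  }
  se <- sqrt(0.2 * 0.8 / total)
  expect_lt(abs(missed / total - 0.2), 3 * se)
  expect_gt(mean(ratios), 0.58)
  expect_lt(mean(ratios), 0.78)
})

test_that("cohorts are reproducible, extensible, and distinct across seeds", {
  sp <- small_spec(seed = 1)
  coh <- generate_cohort(sp, 5, seed = 1)
  expect_equal(length(coh), 5L)
  expect_equal(anyDuplicated(names(coh)), 0L)
  coh2 <- generate_cohort(sp, 5, seed = 1)
  expect_identical(coh[[3]]$t2w$data, coh2[[3]]$t2w$data)
  # extending the cohort does not reshuffle earlier cases
  coh7 <- generate_cohort(sp, 7, seed = 1)
  expect_identical(coh[[2]]$truth_grade_map, coh7[[2]]$truth_grade_map)
  cohB <- generate_cohort(sp, 5, seed = 2)
  expect_false(identical(coh[[1]]$t2w$data, cohB[[1]]$t2w$data))
})

test_that("cohorts round-trip through NIfTI files and a JSON manifest", {
  sp <- small_spec(seed = 6, n_lesions = 1L)
  coh <- generate_cohort(sp, 2, seed = 6)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(names(back), names(coh))
  expect_equal(back[[1]]$truth_grade_map, coh[[1]]$truth_grade_map)
  expect_equal(back[[1]]$prostate_mask, coh[[1]]$prostate_mask)
  expect_equal(back[[1]]$t2w$data, coh[[1]]$t2w$data, tolerance = 1e-6)
  expect_equal(back[[1]]$spacing, coh[[1]]$spacing)
  # reconstructed truth lesions match the planted ones
  expect_equal(back[[1]]$truth_lesions$table$NL,
               coh[[1]]$truth_lesions$table$NL)
  expect_equal(back[[1]]$truth_lesions$table$class,
               coh[[1]]$truth_lesions$table$class)
  unlink(dir, recursive = TRUE)
})

test_that("phantom spec validation rejects out-of-range parameters", {
  expect_error(small_spec(rad_miss_prob = 1.2), "probabilities")
  expect_error(small_spec(lesion_radius_range_mm = c(6, 4)), "min <= max")
  expect_error(small_spec(slice_spacing_mm = 2), "3, 4.2")
  expect_error(small_spec(rad_shrink_factor = 0), "shrink")
  expect_error(generate_cohort(small_spec(lesion_radius_range_mm = c(30, 40)),
                               1, seed = 1),
               "placement")
})
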