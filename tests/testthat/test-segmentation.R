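test_that("water thresholding covers parenchyma and excludes background", {
  ph <- default_phantom()
  cand <- threshold_kidney_candidates(ph$dixon)
  par <- truth_mask(ph, c("parenchyma_L", "parenchyma_R"))
  bg <- array(ph$truth$labels == 0L, dim(cand))
  expect_identical(sum(par & !cand), 0L)   # superset of parenchyma
  expect_identical(sum(cand & bg), 0L)     # no background voxels
  # under noise the candidates still cover essentially all parenchyma
  phn <- generate_phantom(phantom_config(noise_sd = 0.05, seed = 3L))
  candn <- threshold_kidney_candidates(phn$dixon)
  parn <- truth_mask(phn, c("parenchyma_L", "parenchyma_R"))
  expect_gte(sum(candn & parn) / sum(parn), 0.99)
})

test_that("degenerate images are rejected by the threshold step", {
  flat <- structure(list(water = array(0, c(20, 20, 8)),
                         fat = array(0, c(20, 20, 8)),
                         in_phase = array(0, c(20, 20, 8)),
                         opposed = array(0, c(20, 20, 8)),
                         voxel_spacing_mm = c(1, 1, 1)),
                    class = "dixon_volume")
  expect_error(threshold_kidney_candidates(flat), "empty input")
  const <- flat
  const$water <- array(5, c(20, 20, 8))
  const$in_phase <- array(5, c(20, 20, 8))
  expect_error(threshold_kidney_candidates(const))
})

test_that("prior-box selection splits clean candidates by side", {
  ph <- default_phantom()
  kid_l <- truth_mask(ph, kidney_classes("L"))
  kid_r <- truth_mask(ph, kidney_classes("R"))
  masks <- select_kidney_components(kid_l | kid_r)
  expect_identical(masks$whole_left, kid_l)
  expect_identical(masks$whole_right, kid_r)
})

test_that("undersized or missing components are reported per side", {
  ph <- default_phantom()
  cand <- threshold_kidney_candidates(ph$dixon)
  big <- segmentation_config(min_component_voxels = 10^6)
  expect_error(select_kidney_components(cand, big, require_both = TRUE),
               "kidney not found on side 'left'")
  w <- capture_warnings(m <- select_kidney_components(cand, big))
  expect_length(w, 2L)
  expect_match(w, "kidney not found", all = TRUE)
  expect_false(any(m$whole_left) || any(m$whole_right))
  # a half-volume with only the left kidney warns about the right side
  half <- cand
  half[(dim(cand)[1] %/% 2):dim(cand)[1], , ] <- FALSE
  expect_warning(m2 <- select_kidney_components(half),
                 "no kidney candidate found on side 'right'")
  expect_true(any(m2$whole_left))
  expect_false(any(m2$whole_right))
})

test_that("contour refinement is a no-op at zero iterations and stationary on a sharp kidney", {
  ph <- default_phantom()
  kid_r <- truth_mask(ph, kidney_classes("R"))
  cfg0 <- segmentation_config(contour_iterations = 0L)
  expect_identical(refine_boundary(kid_r, ph$dixon, cfg0), kid_r)
  refined <- refine_boundary(kid_r, ph$dixon)
  expect_gte(dice(refined, kid_r), 0.99)
  # single connected component
  expect_identical(refined, renocomp:::largest_component(refined))
})

test_that("refinement sheds an abutting liver from a merged seed", {
  ph <- default_phantom()
  kid_r <- truth_mask(ph, kidney_classes("R"))
  liver <- truth_mask(ph, "liver")
  gs <- dim(kid_r)
  box <- default_prior_boxes()$right
  inbox <- array(FALSE, gs)
  lo <- pmax(1L, ceiling(box[1, ] * gs)); hi <- pmin(gs, floor(box[2, ] * gs))
  inbox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  seed <- kid_r | (liver & inbox)
  expect_gt(sum(seed & liver), 0)      # the seed really is contaminated
  refined <- refine_boundary(seed, ph$dixon)
  expect_gte(dice(refined, kid_r), 0.90)
  expect_identical(sum(refined & liver), 0L)
})

test_that("compartment classes partition the whole-kidney masks exactly", {
  ph <- default_phantom()
  seg <- default_segmentation()
  codes <- label_codes()
  lab <- seg$labels$labels
  whole <- seg$masks$whole_left | seg$masks$whole_right
  kidney_lab <- array(lab %in% codes[c(kidney_classes("L"), kidney_classes("R"))],
                      dim(lab))
  expect_identical(kidney_lab, whole)
  # classes are pairwise disjoint by construction of a single label array;
  # assert each voxel in the mask carries exactly one kidney class
  expect_identical(sum(lab[whole] == 0L), 0L)
})

test_that("pure-fat sinus yields an empty pelvis class and accurate fat overlap", {
  cfg <- phantom_config(sinus_fat_fraction = 1, pelvis_fraction = 0)
  ph <- generate_phantom(cfg)
  seg <- suppressWarnings(segment_kidneys(ph$dixon))
  codes <- label_codes()
  expect_identical(sum(seg$labels$labels %in% codes[c("pelvis_L", "pelvis_R")]), 0L)
  fat_t <- truth_mask(ph, c("sinus_fat_L", "sinus_fat_R"))
  fat_s <- seg_mask(seg, c("sinus_fat_L", "sinus_fat_R"))
  expect_gte(dice(fat_s, fat_t), 0.85)
})

test_that("sinus-free kidneys are labelled entirely as parenchyma", {
  ph0 <- generate_phantom(small_phantom_config(sinus_fraction = 0))
  seg0 <- suppressWarnings(segment_kidneys(ph0$dixon))
  codes <- label_codes()
  sinus_codes <- codes[c("sinus_fat_L", "sinus_fat_R", "pelvis_L", "pelvis_R",
                         "sinus_fluid_L", "sinus_fluid_R")]
  expect_identical(sum(seg0$labels$labels %in% sinus_codes), 0L)
})

test_that("sinus candidate count is monotone in the intensity factor", {
  ph <- default_phantom()
  seg <- default_segmentation()
  codes <- label_codes()
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(f) {
    cfg <- segmentation_config(sinus_intensity_factor = f)
    lv <- suppressWarnings(separate_compartments(ph$dixon, seg$masks, cfg))
    sum(lv$labels %in% codes[c("sinus_fat_L", "sinus_fat_R", "pelvis_L",
                               "pelvis_R")])
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("measured sinus fat grows with the configured fat fraction", {
  v <- vapply(c(0.3, 0.6), function(f) {
    ph <- generate_phantom(small_phantom_config(sinus_fat_fraction = f))
    seg <- suppressWarnings(segment_kidneys(ph$dixon))
    compute_volumes(seg$labels)$sinus_fat_ml
  }, numeric(1))
  expect_lt(v[1], v[2])
})

test_that("volumes recovered from the default noiseless phantom match truth", {
  ph <- default_phantom()
  gt <- ground_truth_volumes(ph$truth)
  sv <- compute_volumes(default_segmentation()$labels)
  expect_lte(abs(sv$renal_volume_ml - gt$renal_volume_ml) / gt$renal_volume_ml,
             0.05)
  expect_lte(abs(sv$sinus_fat_ml - gt$sinus_fat_ml) / gt$sinus_fat_ml, 0.15)
})

test_that("full segmentation is reproducible on identical input", {
  ph <- generate_phantom(small_phantom_config(noise_sd = 0.03, seed = 5L))
  a <- suppressWarnings(segment_kidneys(ph$dixon))
  b <- suppressWarnings(segment_kidneys(ph$dixon))
  expect_identical(a$labels$labels, b$labels$labels)
})

test_that("reader edits are applied in order with exact bookkeeping", {
  ph <- generate_phantom(small_phantom_config())
  seg <- suppressWarnings(segment_kidneys(ph$dixon))
  lv <- seg$labels
  codes <- label_codes()
  # empty script is the identity
  same <- apply_edits(lv, edit_script())
  expect_identical(same$labels, lv$labels)
  # erasing 10 parenchyma voxels reduces the count by exactly 10
  par_idx <- which(lv$labels == codes[["parenchyma_L"]])[1:10]
  erased <- apply_edits(lv, edit_script(edit_erase(par_idx)))
  expect_identical(sum(erased$labels == codes[["parenchyma_L"]]),
                   sum(lv$labels == codes[["parenchyma_L"]]) - 10L)
  # erase then re-assign restores the labels; audit shows both actions
  restored <- apply_edits(lv, edit_script(edit_erase(par_idx),
                                          edit_assign(par_idx, "parenchyma_L")))
  expect_identical(restored$labels, lv$labels)
  expect_identical(nrow(attr(restored, "audit")), 2L)
  expect_error(apply_edits(lv, edit_script(edit_erase(length(lv$labels) + 5L))),
               "out of bounds")
  expect_error(apply_edits(lv, edit_script(edit_assign(1L, "no_such_class"))),
               "unknown label")
})

test_that("dice coefficient follows its definition", {
  m <- function() array(FALSE, dim = c(5, 5, 8))
  a <- m(); a[1:100] <- TRUE
  b <- m(); b[51:150] <- TRUE   # |a|=|b|=100, overlap 50
  d <- m(); d[101:150] <- TRUE  # disjoint from a
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, d), 0.0)
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(m(), m()), 1.0)  # both empty, by convention
  expect_error(dice(a, array(TRUE, c(5, 8, 5))), "shape")
})
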