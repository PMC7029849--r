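# Stepwise semi-automated kidney segmentation on Dixon volumes:
# water-image thresholding -> prior-box component selection -> contour
# refinement against abutting organs -> compartment separation inside the
# whole-kidney mask -> optional reader edits.

#' Segmentation configuration
#'
#' @param body_threshold_method `"otsu"` (automatic bimodal threshold) or
#'   `"fixed"` (fraction of the water-channel maximum, see
#'   `fixed_threshold_frac`).
#' @param fixed_threshold_frac Fraction of the maximum water intensity used
#'   when `body_threshold_method = "fixed"`.
#' @param kidney_prior_boxes List of two numeric matrices (`left`, `right`),
#'   each 2 x 3 (rows: lower/upper corner) in normalized [0,1] coordinates.
#'   Boxes must not overlap. Encodes prior knowledge of kidney location in a
#'   coronal abdominal acquisition.
#' @param min_component_voxels Smallest admissible kidney candidate
#'   component.
#' @param fill_ratio_band Admissible bounding-box fill ratio for a kidney
#'   candidate (a solid ellipsoid is about 0.52); components outside the
#'   band fail the shape check.
#' @param contour_iterations Boundary-refinement iterations (0 = no-op).
#' @param contour_smoothing Majority-smoothing passes applied per iteration.
#' @param sinus_intensity_factor Sinus candidates have water intensity below
#'   this factor times the parenchyma reference intensity; in (0, 1).
#' @param fat_fraction_threshold Sinus voxels with fat fraction
#'   F/(W+F) above this are sinus fat; in (0, 1].
#' @param pelvis_fat_fraction_max Sinus voxels with fat fraction below this
#'   are pelvis/fluid.
#' @param interior_erosion_radius Erosion radius (voxels) restricting sinus
#'   candidates to the kidney interior (parenchyma surrounds the sinus).
#' @param slice_wise Logical: apply the candidate threshold per coronal
#'   slice instead of per volume.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(body_threshold_method = c("otsu", "fixed"),
                                fixed_threshold_frac = 0.5,
                                kidney_prior_boxes = default_prior_boxes(),
                                min_component_voxels = 500L,
                                fill_ratio_band = c(0.2, 0.9),
                                contour_iterations = 35L,
                                contour_smoothing = 1L,
                                sinus_intensity_factor = 0.6,
                                fat_fraction_threshold = 0.5,
                                pelvis_fat_fraction_max = 0.2,
                                interior_erosion_radius = 1L,
                                slice_wise = FALSE) {
  body_threshold_method <- match.arg(body_threshold_method)
  bx <- kidney_prior_boxes
  if (!is.list(bx) || !all(c("left", "right") %in% names(bx)))
    stop("kidney_prior_boxes must be a list with elements 'left' and 'right'",
         call. = FALSE)
  for (b in bx) {
    if (!is.matrix(b) || any(dim(b) != c(2L, 3L)) || any(b < 0) || any(b > 1) ||
        any(b[1, ] >= b[2, ]))
      stop("each prior box must be a 2x3 matrix of corners within [0,1]^3",
           call. = FALSE)
  }
  overlap <- all(bx$left[1, ] < bx$right[2, ] & bx$right[1, ] < bx$left[2, ])
  if (overlap) stop("prior boxes must not overlap", call. = FALSE)
  if (sinus_intensity_factor <= 0 || sinus_intensity_factor >= 1)
    stop("sinus_intensity_factor must be in (0, 1)", call. = FALSE)
  if (fat_fraction_threshold <= 0 || fat_fraction_threshold > 1)
    stop("fat_fraction_threshold must be in (0, 1]", call. = FALSE)
  structure(list(body_threshold_method = body_threshold_method,
                 fixed_threshold_frac = fixed_threshold_frac,
                 kidney_prior_boxes = bx,
                 min_component_voxels = as.integer(min_component_voxels),
                 fill_ratio_band = fill_ratio_band,
                 contour_iterations = as.integer(contour_iterations),
                 contour_smoothing = as.integer(contour_smoothing),
                 sinus_intensity_factor = sinus_intensity_factor,
                 fat_fraction_threshold = fat_fraction_threshold,
                 pelvis_fat_fraction_max = pelvis_fat_fraction_max,
                 interior_erosion_radius = as.integer(interior_erosion_radius),
                 slice_wise = isTRUE(slice_wise)),
            class = "segmentation_config")
}

#' Default kidney prior boxes
#'
#' Left and right flank boxes in normalized coordinates for a coronal
#' abdominal volume; the y range excludes the upper abdomen so liver and
#' spleen centroids fall outside.
#' @return List of two 2 x 3 corner matrices.
#' @export
default_prior_boxes <- function() {
  list(left  = rbind(c(0.02, 0.30, 0.02), c(0.48, 0.80, 0.98)),
       right = rbind(c(0.52, 0.30, 0.02), c(0.98, 0.80, 0.98)))
}

box_mask <- function(grid_shape, box) {
  lo <- pmax(1L, ceiling(box[1, ] * grid_shape))
  hi <- pmin(grid_shape, floor(box[2, ] * grid_shape))
  m <- array(FALSE, dim = grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Threshold kidney candidate voxels on the water image
#'
#' Restricts to the body region (largest bright connected component of the
#' in-phase channel), then keeps voxels whose water intensity exceeds an
#' automatically chosen threshold (Otsu by default, or a fixed fraction of
#' the water maximum). Bright water-image tissue — renal parenchyma plus
#' liver/spleen — survives; fat and fluid do not.
#'
#' @param vol A `dixon_volume`.
#' @param cfg A [segmentation_config()].
#' @return Logical candidate mask.
#' @export
threshold_kidney_candidates <- function(vol, cfg = segmentation_config()) {
  stopifnot(inherits(vol, "dixon_volume"))
  W <- vol$water
  if (!all(is.finite(W))) stop("water channel must be finite", call. = FALSE)
  if (all(W == 0)) stop("empty input: water channel is all zero", call. = FALSE)
  ip <- vol$in_phase
  body_thr <- tryCatch(otsu_threshold(as.vector(ip)),
                       error = function(e) stop("empty input: ", conditionMessage(e),
                                                call. = FALSE))
  body <- largest_component(ip > body_thr)
  thr_of <- function(x) {
    if (cfg$body_threshold_method == "fixed") cfg$fixed_threshold_frac * max(x)
    else otsu_threshold(x)
  }
  out <- array(FALSE, dim = dim(W))
  if (cfg$slice_wise) {
    for (k in seq_len(dim(W)[3])) {
      wk <- W[, , k]; bk <- body[, , k]
      if (!any(bk)) next
      vals <- wk[bk]
      if (length(unique(vals)) < 2L) next
      out[, , k] <- bk & wk > thr_of(vals)
    }
  } else {
    thr <- thr_of(W[body])
    out <- body & W > thr
  }
  out
}

#' Select kidney components within anatomical prior boxes
#'
#' Within each prior box, keeps the largest connected candidate component
#' exceeding `min_component_voxels` and checks its bounding-box fill ratio
#' against the configured band (an ellipsoid-likeness screen). Sides with no
#' admissible component yield an empty mask with a warning unless
#' `require_both` is set.
#'
#' @param candidates Logical candidate mask from
#'   [threshold_kidney_candidates()].
#' @param cfg A [segmentation_config()].
#' @param require_both Error (instead of warn) when a side has no admissible
#'   component.
#' @return Object of class `kidney_masks`: logical masks `whole_left`,
#'   `whole_right` and a `provenance` character vector.
#' @export
select_kidney_components <- function(candidates, cfg = segmentation_config(),
                                     require_both = FALSE) {
  if (!any(candidates)) stop("candidate mask is empty", call. = FALSE)
  gs <- dim(candidates)
  pick <- function(side) {
    box <- cfg$kidney_prior_boxes[[side]]
    inbox <- candidates & box_mask(gs, box)
    empty <- array(FALSE, dim = gs)
    if (!any(inbox)) {
      msg <- paste0("no kidney candidate found on side '", side, "'")
      if (require_both) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      return(empty)
    }
    cc <- label_components(inbox)
    comp <- cc$labels == 1L
    if (cc$sizes[1] < cfg$min_component_voxels) {
      msg <- paste0("kidney not found on side '", side,
                    "': largest component has ", cc$sizes[1],
                    " voxels (< ", cfg$min_component_voxels, ")")
      if (require_both) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      return(empty)
    }
    fr <- extent_fill_ratio(comp)
    if (fr < cfg$fill_ratio_band[1] || fr > cfg$fill_ratio_band[2]) {
      msg <- paste0("kidney not found on side '", side,
                    "': component fill ratio ", signif(fr, 3),
                    " outside admissible band")
      if (require_both) stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      return(empty)
    }
    comp
  }
  left <- pick("left")
  right <- pick("right")
  structure(list(whole_left = left, whole_right = right,
                 provenance = c("threshold", "component-selection")),
            class = "kidney_masks")
}

#' Refine a kidney mask by region-competition contour evolution
#'
#' Iterative energy-minimizing boundary evolution on the water channel with
#' morphological regularization. Each iteration re-estimates a robust
#' parenchyma intensity (median and MAD over the mask) and an exterior
#' intensity from a narrow band outside the mask; boundary voxels move in or
#' out of the mask according to which region model explains them better,
#' with a homogeneity band that sheds abutting organs of different water
#' intensity (e.g. liver at 0.7 of the parenchyma signal). After evolution
#' the mask is closed, interior cavities (the hypointense sinus) are filled,
#' and the largest connected component is kept. The cumulative volume change
#' of the evolution phase is capped at 20% of the seed volume as a guard
#' against collapse.
#'
#' @param mask Logical seed mask (nonempty).
#' @param vol A `dixon_volume`.
#' @param cfg A [segmentation_config()]; `contour_iterations = 0` returns
#'   the input unchanged.
#' @return Refined logical mask (single connected component).
#' @export
refine_boundary <- function(mask, vol, cfg = segmentation_config()) {
  stopifnot(inherits(vol, "dixon_volume"))
  if (!any(mask)) stop("seed mask is empty", call. = FALSE)
  if (cfg$contour_iterations == 0L) return(mask)
  W <- vol$water
  vol0 <- sum(mask)
  cur <- mask
  for (it in seq_len(cfg$contour_iterations)) {
    c_in <- stats::median(W[cur])
    sigma <- max(stats::mad(W[cur]), 0.08 * abs(c_in), 1e-6)
    band <- 2.5 * sigma
    ring_out <- dilate_n(cur, 2L) & !cur
    c_out <- if (any(ring_out)) stats::median(W[ring_out]) else 0
    shell_in <- cur & !erode6(cur)
    shell_out <- dilate6(cur) & !cur
    add <- shell_out & abs(W - c_in) <= band & abs(W - c_in) < abs(W - c_out)
    drop <- shell_in & abs(W - c_in) > band
    nxt <- (cur & !drop) | add
    for (sm in seq_len(cfg$contour_smoothing)) nxt <- majority_smooth(nxt)
    if (!any(nxt)) stop("refinement collapse: mask vanished during evolution",
                        call. = FALSE)
    if (abs(sum(nxt) - vol0) / vol0 > 0.20) break
    cur <- nxt
  }
  out <- fill_holes(close_n(cur, 2L))
  out <- largest_component(out)
  if (!any(out)) stop("refinement collapse: mask vanished during evolution",
                      call. = FALSE)
  out
}

#' Separate a whole-kidney mask into parenchyma, sinus fat and pelvis/fluid
#'
#' Implements the compartment rules inside each whole-kidney mask:
#' the parenchyma reference intensity is the median water intensity over the
#' mask's outer shell; sinus candidates are interior voxels (mask eroded by
#' `interior_erosion_radius`, encoding that parenchyma surrounds the sinus)
#' whose water intensity falls below `sinus_intensity_factor` times the
#' reference; among them, voxels with fat fraction F/(W+F) above
#' `fat_fraction_threshold` are sinus fat and voxels below
#' `pelvis_fat_fraction_max` are pelvis/fluid; everything else in the mask
#' is parenchyma. The output classes partition the input masks exactly.
#'
#' @param vol A `dixon_volume`.
#' @param masks A `kidney_masks` object.
#' @param cfg A [segmentation_config()].
#' @return A `label_volume` using [label_codes()]; segmented fluid is coded
#'   as the pelvis class (the intensity model cannot distinguish pelvis from
#'   other sinus fluid).
#' @export
separate_compartments <- function(vol, masks, cfg = segmentation_config()) {
  stopifnot(inherits(vol, "dixon_volume"), inherits(masks, "kidney_masks"))
  if (!any(masks$whole_left) && !any(masks$whole_right))
    stop("both kidney masks are empty", call. = FALSE)
  codes <- label_codes()
  W <- vol$water; F_ <- vol$fat
  ff <- F_ / pmax(W + F_, .Machine$double.eps)
  labels <- array(0L, dim = dim(W))
  for (side in c("L", "R")) {
    mask <- if (side == "L") masks$whole_left else masks$whole_right
    if (!any(mask)) next
    interior <- erode_n(mask, cfg$interior_erosion_radius)
    shell <- mask & !interior
    ref <- stats::median(W[if (any(shell)) shell else mask])
    sinus <- interior & W < cfg$sinus_intensity_factor * ref
    if (!any(sinus))
      warning("no sinus candidates on side '", side,
              "'; sinus volume is zero", call. = FALSE)
    fat <- sinus & ff > cfg$fat_fraction_threshold
    pel <- sinus & !fat & ff < cfg$pelvis_fat_fraction_max
    labels[mask] <- codes[[paste0("parenchyma_", side)]]
    labels[fat] <- codes[[paste0("sinus_fat_", side)]]
    labels[pel] <- codes[[paste0("pelvis_", side)]]
  }
  structure(list(labels = labels, code_map = codes,
                 voxel_spacing_mm = vol$voxel_spacing_mm),
            class = "label_volume")
}

#' Reader edit script
#'
#' An ordered list of manual corrections: each step erases a voxel set
#' (to background) or assigns it a label, mirroring the manual cleanup of
#' voxels mistakenly labelled as renal tissue.
#'
#' @param ... Steps created with `edit_erase(voxels)` or
#'   `edit_assign(voxels, label)`, where `voxels` are linear voxel indices.
#' @return Object of class `edit_script`.
#' @export
edit_script <- function(...) {
  steps <- list(...)
  for (s in steps)
    if (!is.list(s) || is.null(s$action)) stop("invalid edit step", call. = FALSE)
  structure(steps, class = "edit_script")
}

#' @rdname edit_script
#' @param voxels Integer linear voxel indices.
#' @export
edit_erase <- function(voxels) list(action = "erase", voxels = as.integer(voxels))

#' @rdname edit_script
#' @param label Label name (see [label_codes()]) or integer code.
#' @export
edit_assign <- function(voxels, label) {
  list(action = "assign", voxels = as.integer(voxels), label = label)
}

#' Apply reader edits to a label volume
#'
#' Applies the steps of an [edit_script()] in order and records an audit log
#' of voxels changed per action.
#'
#' @param labels A `label_volume`.
#' @param edits An `edit_script`.
#' @return The edited `label_volume` with an `audit` attribute (data frame:
#'   action, label, n_voxels, n_changed).
#' @export
apply_edits <- function(labels, edits) {
  stopifnot(inherits(labels, "label_volume"), inherits(edits, "edit_script"))
  n <- length(labels$labels)
  audit <- data.frame(action = character(0), label = character(0),
                      n_voxels = integer(0), n_changed = integer(0),
                      stringsAsFactors = FALSE)
  arr <- labels$labels
  for (s in edits) {
    if (length(s$voxels) && (min(s$voxels) < 1L || max(s$voxels) > n))
      stop("edit voxel index out of bounds: ",
           s$voxels[which(s$voxels < 1L | s$voxels > n)[1]], call. = FALSE)
    if (s$action == "erase") {
      code <- labels$code_map[["background"]]
      lab_name <- "background"
    } else {
      code <- if (is.character(s$label)) {
        if (!s$label %in% names(labels$code_map))
          stop("unknown label: ", s$label, call. = FALSE)
        labels$code_map[[s$label]]
      } else as.integer(s$label)
      if (!code %in% labels$code_map)
        stop("unknown label code: ", code, call. = FALSE)
      lab_name <- names(labels$code_map)[match(code, labels$code_map)]
    }
    changed <- sum(arr[s$voxels] != code)
    arr[s$voxels] <- code
    audit <- rbind(audit, data.frame(action = s$action, label = lab_name,
                                     n_voxels = length(s$voxels),
                                     n_changed = changed,
                                     stringsAsFactors = FALSE))
  }
  out <- labels
  out$labels <- arr
  attr(out, "audit") <- audit
  out
}

#' Dice overlap coefficient
#'
#' `2|A . B| / (|A| + |B|)` between two binary masks of equal shape;
#' defined as 1 when both are empty.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Numeric in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Run the full kidney segmentation pipeline
#'
#' Convenience wrapper: thresholding, prior-box component selection,
#' boundary refinement per side, compartment separation and optional reader
#' edits.
#'
#' @param vol A `dixon_volume`.
#' @param cfg A [segmentation_config()].
#' @param edits Optional [edit_script()].
#' @return List with `labels` (a `label_volume`), `masks` (refined
#'   `kidney_masks`) and `provenance`.
#' @export
segment_kidneys <- function(vol, cfg = segmentation_config(), edits = NULL) {
  cand <- threshold_kidney_candidates(vol, cfg)
  masks <- select_kidney_components(cand, cfg)
  prov <- masks$provenance
  for (side in c("whole_left", "whole_right")) {
    if (any(masks[[side]]))
      masks[[side]] <- refine_boundary(masks[[side]], vol, cfg)
  }
  prov <- c(prov, "contour-refinement")
  labels <- separate_compartments(vol, masks, cfg)
  if (!is.null(edits)) {
    labels <- apply_edits(labels, edits)
    prov <- c(prov, "manual-edits")
  }
  masks$provenance <- prov
  list(labels = labels, masks = masks, provenance = prov)
}
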