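# Voxel-summation volumetry: label volumes -> per-subject compartment
# volumes in ml, with exact integer voxel accounting retained for testing.

#' Compartment volumes by voxel summation
#'
#' Converts a label volume (ground truth or segmentation output) into
#' compartment volumes: per-class voxel count times the voxel volume (mm^3),
#' divided by 1000 to give ml. The whole-kidney (renal) volume per side is
#' parenchyma + sinus fat + sinus fluid + pelvis; the sinus volume is
#' sinus fat + sinus fluid + pelvis. Totals sum both sides.
#'
#' @param labels A `label_volume` (integer labels, `code_map`,
#'   `voxel_spacing_mm`).
#' @param subject_id Optional subject identifier carried into the result.
#' @return An object of class `compartment_volumes`: a list with
#'   `renal_volume_ml`, `sinus_volume_ml`, `sinus_fat_ml`, a `per_side`
#'   data frame, `n_voxels` per class, `voxel_volume_mm3` and
#'   `voxel_spacing_mm`.
#' @export
compute_volumes <- function(labels, subject_id = NA_character_) {
  stopifnot(inherits(labels, "label_volume"))
  cm <- labels$code_map
  needed <- c("background", "parenchyma_L", "parenchyma_R", "sinus_fat_L",
              "sinus_fat_R", "pelvis_L", "pelvis_R", "sinus_fluid_L",
              "sinus_fluid_R")
  if (!all(needed %in% names(cm)))
    stop("code_map is missing entries: ",
         paste(setdiff(needed, names(cm)), collapse = ", "), call. = FALSE)
  present <- sort(unique(as.vector(labels$labels)))
  if (!all(present %in% cm))
    stop("label volume contains codes not in code_map: ",
         paste(setdiff(present, cm), collapse = ", "), call. = FALSE)

  vox_mm3 <- prod(labels$voxel_spacing_mm)
  counts <- vapply(cm, function(code) sum(labels$labels == code), integer(1))
  ml <- counts * vox_mm3 / 1000

  side_ml <- function(side) {
    cls <- paste0(c("parenchyma_", "sinus_fat_", "sinus_fluid_", "pelvis_"), side)
    sinus_cls <- paste0(c("sinus_fat_", "sinus_fluid_", "pelvis_"), side)
    c(renal = sum(ml[cls]),
      sinus = sum(ml[sinus_cls]),
      sinus_fat = unname(ml[paste0("sinus_fat_", side)]),
      parenchyma = unname(ml[paste0("parenchyma_", side)]))
  }
  per_side <- rbind(L = side_ml("L"), R = side_ml("R"))
  structure(list(subject_id = subject_id,
                 renal_volume_ml = sum(per_side[, "renal"]),
                 sinus_volume_ml = sum(per_side[, "sinus"]),
                 sinus_fat_ml = sum(per_side[, "sinus_fat"]),
                 per_side = as.data.frame(per_side),
                 n_voxels = counts,
                 voxel_volume_mm3 = vox_mm3,
                 voxel_spacing_mm = labels$voxel_spacing_mm),
            class = "compartment_volumes")
}

#' @export
print.compartment_volumes <- function(x, ...) {
  cat("Compartment volumes",
      if (!is.na(x$subject_id)) paste0("(subject ", x$subject_id, ")"), "\n")
  cat(sprintf("  Renal volume: %.1f ml\n  Sinus volume: %.1f ml\n  Sinus fat:    %.1f ml\n",
              x$renal_volume_ml, x$sinus_volume_ml, x$sinus_fat_ml))
  invisible(x)
}

#' @export
as.data.frame.compartment_volumes <- function(x, ...) {
  data.frame(subject_id = x$subject_id,
             renal_volume_ml = round(x$renal_volume_ml, 1),
             sinus_volume_ml = round(x$sinus_volume_ml, 1),
             sinus_fat_ml = round(x$sinus_fat_ml, 1),
             renal_left_ml = round(x$per_side["L", "renal"], 1),
             renal_right_ml = round(x$per_side["R", "renal"], 1),
             sinus_fat_left_ml = round(x$per_side["L", "sinus_fat"], 1),
             sinus_fat_right_ml = round(x$per_side["R", "sinus_fat"], 1),
             stringsAsFactors = FALSE)
}

#' Cohort volume table
#'
#' Binds a list of `compartment_volumes` into one data frame (one row per
#' subject, volumes rounded to 0.1 ml as reported) and optionally writes it
#' as CSV.
#'
#' @param volumes List of `compartment_volumes`.
#' @param file Optional path; when given the table is written as CSV.
#' @return The combined data frame, invisibly when `file` is given.
#' @export
volumes_table <- function(volumes, file = NULL) {
  stopifnot(length(volumes) > 0)
  tab <- do.call(rbind, lapply(volumes, as.data.frame))
  rownames(tab) <- NULL
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
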