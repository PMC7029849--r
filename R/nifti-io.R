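# NIfTI-1 input/output for Dixon channels and label volumes, one file per
# channel plus a JSON sidecar for the label code map.

channel_suffixes <- c(water = "_W", fat = "_F", in_phase = "_IP",
                      opposed = "_OP")

nifti_with_spacing <- function(arr, spacing) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  img
}

#' Write a Dixon volume as NIfTI files
#'
#' Writes one `.nii.gz` file per channel with suffixes `_W`, `_F`, `_IP`,
#' `_OP`, RAS-oriented with the voxel spacing in the header.
#'
#' @param vol A `dixon_volume`.
#' @param prefix Path prefix (directory + basename) for the channel files.
#' @return Invisibly, the vector of written paths.
#' @export
write_dixon_nifti <- function(vol, prefix) {
  stopifnot(inherits(vol, "dixon_volume"))
  paths <- character(0)
  for (ch in names(channel_suffixes)) {
    p <- paste0(prefix, channel_suffixes[[ch]], ".nii.gz")
    RNifti::writeNifti(nifti_with_spacing(vol[[ch]], vol$voxel_spacing_mm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a Dixon volume from NIfTI channel files
#'
#' @param prefix Path prefix used by [write_dixon_nifti()].
#' @return A `dixon_volume`.
#' @export
read_dixon_nifti <- function(prefix) {
  chans <- lapply(channel_suffixes, function(sfx) {
    p <- paste0(prefix, sfx, ".nii.gz")
    if (!file.exists(p)) stop("missing channel file: ", p, call. = FALSE)
    img <- RNifti::readNifti(p)
    list(arr = array(as.numeric(img), dim = dim(img)),
         spacing = RNifti::pixdim(img))
  })
  sp <- chans[[1]]$spacing
  structure(list(water = chans$water$arr, fat = chans$fat$arr,
                 in_phase = chans$in_phase$arr, opposed = chans$opposed$arr,
                 voxel_spacing_mm = as.numeric(sp)),
            class = "dixon_volume")
}

#' Write a label volume as NIfTI plus JSON code map
#'
#' @param labels A `label_volume`.
#' @param prefix Path prefix; writes `<prefix>_labels.nii.gz` and
#'   `<prefix>_labels.json`.
#' @return Invisibly, the written paths.
#' @export
write_label_nifti <- function(labels, prefix) {
  stopifnot(inherits(labels, "label_volume"))
  p_img <- paste0(prefix, "_labels.nii.gz")
  p_json <- paste0(prefix, "_labels.json")
  RNifti::writeNifti(nifti_with_spacing(labels$labels, labels$voxel_spacing_mm),
                     p_img, datatype = "int16")
  jsonlite::write_json(as.list(labels$code_map), p_json, auto_unbox = TRUE)
  invisible(c(p_img, p_json))
}

#' Read a label volume written by [write_label_nifti()]
#'
#' @param prefix Path prefix.
#' @return A `label_volume`.
#' @export
read_label_nifti <- function(prefix) {
  p_img <- paste0(prefix, "_labels.nii.gz")
  p_json <- paste0(prefix, "_labels.json")
  img <- RNifti::readNifti(p_img)
  cm <- unlist(jsonlite::read_json(p_json))
  structure(list(labels = array(as.integer(img), dim = dim(img)),
                 code_map = stats::setNames(as.integer(cm), names(cm)),
                 voxel_spacing_mm = as.numeric(RNifti::pixdim(img))),
            class = "label_volume")
}
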