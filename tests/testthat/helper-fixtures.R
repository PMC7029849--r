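# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

# default-geometry noiseless phantom (the study conditions)
default_phantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- generate_phantom(phantom_config())
  .fixtures$ph
}

default_segmentation <- function() {
  if (is.null(.fixtures$seg))
    .fixtures$seg <- suppressWarnings(segment_kidneys(default_phantom()$dixon))
  .fixtures$seg
}

# compact phantom for cheap structural checks
small_phantom_config <- function(...) {
  args <- list(grid_shape = c(48, 64, 24), kidney_axes_mm = c(16, 30, 14))
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_config, args)
}

# binary mask of truth classes by name
truth_mask <- function(ph, classes) {
  codes <- label_codes()
  array(ph$truth$labels %in% codes[classes], dim(ph$truth$labels))
}

kidney_classes <- function(side) {
  paste0(c("parenchyma_", "sinus_fat_", "sinus_fluid_", "pelvis_"), side)
}

seg_mask <- function(seg, classes) {
  codes <- label_codes()
  array(seg$labels$labels %in% codes[classes], dim(seg$labels$labels))
}
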