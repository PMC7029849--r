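#' Compartment label codes
#'
#' Integer codes used by both the phantom ground truth and the segmentation
#' output. Background is 0; each renal compartment is coded per side (L/R);
#' liver and spleen are confounder organs that the kidney pipeline must
#' exclude.
#'
#' @return Named integer vector mapping class names to label codes.
#' @export
label_codes <- function() {
  c(background   = 0L,
    parenchyma_L = 1L, parenchyma_R = 2L,
    sinus_fat_L  = 3L, sinus_fat_R  = 4L,
    pelvis_L     = 5L, pelvis_R     = 6L,
    sinus_fluid_L = 7L, sinus_fluid_R = 8L,
    liver = 9L, spleen = 10L)
}

# Noiseless (water, fat) signal fractions per tissue class. The scanner
# sequence does not fix these; they are a modelling choice: parenchyma is
# bright on the water image, sinus fat is bright on the fat image, and sinus
# fluid / pelvis is hypointense on T1w water (long-T1 urine), which is the
# contrast the compartment separation exploits.
tissue_signals <- function(liver_steatosis = 0) {
  rbind(
    background  = c(0.00, 0.00),
    body        = c(0.30, 0.25),
    parenchyma  = c(0.90, 0.05),
    sinus_fat   = c(0.08, 0.90),
    pelvis      = c(0.35, 0.00),
    sinus_fluid = c(0.35, 0.00),
    liver       = c(0.70, 0.20 + liver_steatosis),
    spleen      = c(0.80, 0.05))
}

#' Configuration for the synthetic Dixon phantom
#'
#' Defines the geometry and signal model of a coronal abdominal phantom:
#' two ellipsoidal kidneys with an interior renal sinus that opens toward
#' the midline (hilum), the sinus split into fat, fluid and a central
#' fluid-filled pelvis, and optional liver/spleen blobs abutting the
#' kidneys. Default voxel spacing follows a 256 x 256 matrix over a
#' 488 x 716 mm field of view with 1.7 mm partitions.
#'
#' @param grid_shape Integer vector of 3: voxels per axis (x = left-right,
#'   y = superior-inferior, z = anterior-posterior). All >= 16.
#' @param voxel_spacing_mm Numeric vector of 3, mm per voxel, all > 0.
#' @param kidney_axes_mm Ellipsoid semi-axes (mm) used for both kidneys.
#' @param sinus_fraction Fraction of kidney volume occupied by the sinus,
#'   in [0, 1).
#' @param sinus_fat_fraction Fraction of the sinus that is fat, in [0, 1].
#' @param pelvis_fraction Fraction of the sinus that is fluid-filled pelvis,
#'   in [0, 1]; `sinus_fat_fraction + pelvis_fraction <= 1`, the remainder is
#'   non-pelvic sinus fluid.
#' @param confounders Logical: add liver and spleen blobs (the liver touches
#'   the right kidney's upper pole).
#' @param liver_steatosis Extra fat signal fraction added to the liver.
#' @param noise_sd Gaussian noise SD per channel, relative to unit tissue
#'   signal.
#' @param bias_field_amp Amplitude of a low-order polynomial multiplicative
#'   bias field (0 = off).
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(80L, 96L, 40L),
                           voxel_spacing_mm = c(1.9, 2.8, 1.7),
                           kidney_axes_mm = c(26, 50, 22),
                           sinus_fraction = 0.15,
                           sinus_fat_fraction = 0.65,
                           pelvis_fraction = 0.20,
                           confounders = TRUE,
                           liver_steatosis = 0,
                           noise_sd = 0,
                           bias_field_amp = 0,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be 3 integers, all >= 16", call. = FALSE)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("voxel_spacing_mm must be 3 positive values", call. = FALSE)
  if (length(kidney_axes_mm) != 3L || any(kidney_axes_mm <= 0))
    stop("kidney_axes_mm must be 3 positive values", call. = FALSE)
  if (sinus_fraction < 0 || sinus_fraction >= 1)
    stop("sinus_fraction must be in [0, 1)", call. = FALSE)
  if (sinus_fat_fraction < 0 || sinus_fat_fraction > 1 ||
      pelvis_fraction < 0 || pelvis_fraction > 1 ||
      sinus_fat_fraction + pelvis_fraction > 1 + 1e-12)
    stop("sinus_fat_fraction and pelvis_fraction must lie in [0, 1] and sum to <= 1",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 kidney_axes_mm = as.numeric(kidney_axes_mm),
                 sinus_fraction = sinus_fraction,
                 sinus_fat_fraction = sinus_fat_fraction,
                 pelvis_fraction = pelvis_fraction,
                 confounders = isTRUE(confounders),
                 liver_steatosis = liver_steatosis,
                 noise_sd = noise_sd,
                 bias_field_amp = bias_field_amp,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Two-point Dixon signal model
#'
#' Maps water and fat signal fractions of a voxel to the four reconstructed
#' channel intensities: water, fat, in-phase (W + F) and opposed-phase
#' (|W - F|), with optional additive Gaussian noise per channel. Vectorized
#' over voxels; noise uses the current R random number generator state.
#'
#' @param water_fraction,fat_fraction Signal fractions in [0, 1] with
#'   `water_fraction + fat_fraction <= 1` (the remainder is signal-free).
#' @param noise_sd Gaussian noise SD, >= 0.
#' @return A list with numeric components `water`, `fat`, `in_phase`,
#'   `opposed`, each the length of the inputs.
#' @examples
#' dixon_signal(0.2, 0.8)          # in-phase 1.0, opposed 0.6
#' dixon_signal(0.5, 0.5)$opposed  # symmetric voxel cancels: 0
#' @export
dixon_signal <- function(water_fraction, fat_fraction, noise_sd = 0) {
  if (any(water_fraction < 0) || any(fat_fraction < 0))
    stop("signal fractions must be non-negative", call. = FALSE)
  if (any(water_fraction > 1) || any(fat_fraction > 1) ||
      any(water_fraction + fat_fraction > 1 + 1e-12))
    stop("water_fraction + fat_fraction must be <= 1", call. = FALSE)
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single value >= 0", call. = FALSE)
  n <- max(length(water_fraction), length(fat_fraction))
  W <- rep_len(water_fraction, n)
  F_ <- rep_len(fat_fraction, n)
  out <- list(water = W, fat = F_, in_phase = W + F_, opposed = abs(W - F_))
  if (noise_sd > 0)
    out <- lapply(out, function(ch) ch + stats::rnorm(n, 0, noise_sd))
  out
}

# Squared normalized ellipsoidal radius of the voxel-center grid relative to
# a center and semi-axes (mm). coords is a list of three arrays.
ellipsoid_rho2 <- function(coords, center, axes) {
  ((coords$x - center[1]) / axes[1])^2 +
  ((coords$y - center[2]) / axes[2])^2 +
  ((coords$z - center[3]) / axes[3])^2
}

voxel_center_coords <- function(grid_shape, spacing) {
  ax <- function(i) (seq_len(grid_shape[i]) - 0.5) * spacing[i]
  list(x = array(rep(ax(1), times = prod(grid_shape[2:3])), dim = grid_shape),
       y = array(rep(rep(ax(2), each = grid_shape[1]), times = grid_shape[3]),
                 dim = grid_shape),
       z = array(rep(ax(3), each = prod(grid_shape[1:2])), dim = grid_shape))
}

#' Generate a synthetic Dixon phantom with ground-truth labels
#'
#' Builds a coronal abdominal volume containing two ellipsoidal kidneys with
#' an interior renal sinus (fat / fluid / central pelvis) that opens toward
#' the midline, plus optional liver and spleen confounder blobs, and renders
#' the four Dixon channels from the tissue signal model. The sinus is an
#' interior ellipsoid scaled so its volume fraction of the kidney equals
#' `sinus_fraction` exactly (before voxelization), shifted medially until
#' tangent to the kidney surface so it models the hilar opening.
#'
#' @param config A [phantom_config()].
#' @return A list with components `dixon` (class `dixon_volume`: arrays
#'   `water`, `fat`, `in_phase`, `opposed` plus `voxel_spacing_mm`) and
#'   `truth` (class `label_volume`: integer `labels`, `code_map`,
#'   `voxel_spacing_mm`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape; sp <- config$voxel_spacing_mm
  extent <- gs * sp
  axes <- config$kidney_axes_mm
  centers <- list(L = c(0.25 * extent[1], 0.5 * extent[2], 0.5 * extent[3]),
                  R = c(0.75 * extent[1], 0.5 * extent[2], 0.5 * extent[3]))
  for (side in names(centers)) {
    c0 <- centers[[side]]
    if (any(c0 - axes < 0) || any(c0 + axes > extent))
      stop("kidney ellipsoid exceeds grid extent on side ", side, call. = FALSE)
  }
  coords <- voxel_center_coords(gs, sp)
  labels <- array(0L, dim = gs)
  codes <- label_codes()

  s <- config$sinus_fraction
  t_sin <- s^(1 / 3)                       # sinus/kidney linear scale
  f_fat <- config$sinus_fat_fraction
  f_pel <- config$pelvis_fraction
  rho_pel <- f_pel^(1 / 3)                 # pelvis: innermost sinus core
  rho_fat <- (1 - f_fat)^(1 / 3)           # fat: outermost sinus shell

  for (side in c("L", "R")) {
    c0 <- centers[[side]]
    kid <- ellipsoid_rho2(coords, c0, axes) <= 1
    labels[kid] <- codes[[paste0("parenchyma_", side)]]
    if (s > 0) {
      # medial shift toward internal tangency so the sinus opens toward the
      # midline; a 3 mm parenchyma bridge is kept at the hilum so the sinus
      # stays enclosed (the cortex surrounds the medulla/sinus)
      medial <- if (side == "L") +1 else -1
      shift <- max((1 - t_sin) * axes[1] - 3, 0)
      c_sin <- c0 + c(medial * shift, 0, 0)
      rho2 <- ellipsoid_rho2(coords, c_sin, t_sin * axes)
      sinus <- kid & rho2 <= 1
      rho <- sqrt(pmax(rho2, 0))
      fat <- sinus & rho > rho_fat
      pel <- sinus & rho <= rho_pel
      fluid <- sinus & !fat & !pel
      labels[fat] <- codes[[paste0("sinus_fat_", side)]]
      labels[pel] <- codes[[paste0("pelvis_", side)]]
      labels[fluid] <- codes[[paste0("sinus_fluid_", side)]]
    }
  }

  if (config$confounders) {
    # liver overlaps the right kidney's upper pole (kidney label wins),
    # spleen abuts the left kidney; centroids sit outside the kidney prior
    # boxes so component selection can reject them
    liv_c <- c(0.75 * extent[1] + 4, 0.5 * extent[2] - axes[2] - 30, 0.5 * extent[3])
    liv_ax <- c(28, 42, 20)
    liv <- ellipsoid_rho2(coords, liv_c, liv_ax) <= 1 & labels == 0L
    labels[liv] <- codes[["liver"]]
    spl_c <- c(0.25 * extent[1] - 6, 0.5 * extent[2] - axes[2] - 36, 0.5 * extent[3])
    spl_ax <- c(20, 30, 18)
    spl <- ellipsoid_rho2(coords, spl_c, spl_ax) <= 1 & labels == 0L
    labels[spl] <- codes[["spleen"]]
  }

  # render channels from the tissue table; a soft-tissue torso surrounds
  # the organs (labelled background: it is not a renal compartment)
  sig <- tissue_signals(config$liver_steatosis)
  code_to_tissue <- c("background",
                      "parenchyma", "parenchyma",
                      "sinus_fat", "sinus_fat",
                      "pelvis", "pelvis",
                      "sinus_fluid", "sinus_fluid",
                      "liver", "spleen")
  tis <- code_to_tissue[labels + 1L]
  torso <- ellipsoid_rho2(coords, extent / 2,
                          c(0.47, 0.46, 0.46) * extent) <= 1
  tis[labels == 0L & torso] <- "body"
  Wm <- array(sig[tis, 1L], dim = gs)
  Fm <- array(sig[tis, 2L], dim = gs)

  if (config$bias_field_amp != 0) {
    u <- 2 * coords$x / extent[1] - 1
    v <- 2 * coords$y / extent[2] - 1
    w <- 2 * coords$z / extent[3] - 1
    field <- 1 + config$bias_field_amp * (0.4 * u + 0.3 * v - 0.3 * w + 0.3 * u * v)
    Wm <- Wm * field
    Fm <- Fm * field
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  ch <- dixon_signal(as.vector(Wm), as.vector(Fm), config$noise_sd)
  # noiseless channel algebra is applied before noise, so in_phase = W + F
  # and opposed = |W - F| hold exactly at noise_sd = 0
  dix <- structure(list(water = array(ch$water, gs),
                        fat = array(ch$fat, gs),
                        in_phase = array(ch$in_phase, gs),
                        opposed = array(ch$opposed, gs),
                        voxel_spacing_mm = sp),
                   class = "dixon_volume")
  truth <- structure(list(labels = labels, code_map = codes,
                          voxel_spacing_mm = sp),
                     class = "label_volume")
  list(dixon = dix, truth = truth)
}

#' @export
print.dixon_volume <- function(x, ...) {
  cat("Dixon volume:", paste(dim(x$water), collapse = " x "),
      "voxels, spacing", paste(signif(x$voxel_spacing_mm, 3), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("Label volume:", paste(dim(x$labels), collapse = " x "), "voxels\n")
  cnt <- table(factor(x$labels, levels = x$code_map,
                      labels = names(x$code_map)))
  print(cnt[cnt > 0])
  invisible(x)
}

#' Ground-truth compartment volumes from a label volume
#'
#' Voxel-summation volumetry of the phantom's ground-truth labels: each
#' class volume is its voxel count times the voxel volume, reported in ml.
#' The whole-kidney volume includes the sinus content (fat, fluid, pelvis),
#' matching a whole-kidney-mask-then-subdivide workflow.
#'
#' @param truth A `label_volume`.
#' @return A `compartment_volumes` object (see [compute_volumes()]).
#' @export
ground_truth_volumes <- function(truth) {
  compute_volumes(truth)
}
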