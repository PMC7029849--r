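# Internal 3-D binary image primitives.
#
# All masks are logical 3-D arrays. Connectivity is 6-neighbour (faces only)
# throughout; that is the conservative choice for separating organs that
# touch diagonally.

# Shift an array by one voxel along an axis, padding with `fill`.
shift_array <- function(a, axis, by, fill = FALSE) {
  stopifnot(axis %in% 1:3, by %in% c(-1L, 1L))
  d <- dim(a)
  out <- array(fill, dim = d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by == 1L) {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- 1:(d[axis] - 1L)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1L)
    idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (by in c(-1L, 1L))
    out <- out | shift_array(mask, ax, by, FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (by in c(-1L, 1L))
    out <- out & shift_array(mask, ax, by, FALSE)
  out
}

dilate_n <- function(mask, n) { for (i in seq_len(n)) mask <- dilate6(mask); mask }
erode_n  <- function(mask, n) { for (i in seq_len(n)) mask <- erode6(mask); mask }

# Morphological closing: dilate then erode, radius n.
close_n <- function(mask, n) erode_n(dilate_n(mask, n), n)

# Count of 6-neighbours that are TRUE, per voxel.
neighbor_count <- function(mask) {
  cnt <- array(0L, dim = dim(mask))
  for (ax in 1:3) for (by in c(-1L, 1L))
    cnt <- cnt + shift_array(mask, ax, by, FALSE)
  cnt
}

# Majority smoothing: a voxel is foreground iff voxel + neighbours vote >= 4
# of 7. Preserves flat surfaces, shaves one-voxel spikes and fills pits.
majority_smooth <- function(mask) {
  (neighbor_count(mask) + mask) >= 4L
}

# Label 6-connected components. Returns an integer array (0 = background)
# and component sizes, largest first in the relabelled output.
label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  lab <- 0L
  remaining <- mask
  while (any(remaining)) {
    lab <- lab + 1L
    seed <- which(remaining)[1L]
    comp <- array(FALSE, dim = d)
    comp[seed] <- TRUE
    frontier <- comp
    repeat {
      grown <- dilate6(frontier) & remaining & !comp
      if (!any(grown)) break
      comp <- comp | grown
      frontier <- grown
    }
    labels[comp] <- lab
    remaining <- remaining & !comp
  }
  sizes <- tabulate(labels[labels > 0L], nbins = lab)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(lab)
  relabel[ord] <- seq_len(lab)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  list(labels = labels, sizes = sizes[ord])
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  cc <- label_components(mask)
  cc$labels == 1L
}

# Fill interior cavities: background components that do not touch the array
# border become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, dim = d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  # flood the outside from the border
  outside <- bg & border
  repeat {
    grown <- dilate6(outside) & bg & !outside
    if (!any(grown)) break
    outside <- outside | grown
  }
  mask | (bg & !outside)
}

# Otsu's threshold on a numeric vector: maximizes between-class variance on a
# 256-bin histogram. Returns the threshold value on the data scale.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite values", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("otsu_threshold: constant input", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nbins)
  w <- cumsum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  m <- cumsum(h * mids)
  n <- w[nbins]; mtot <- m[nbins]
  w1 <- w[-nbins]; m1 <- m[-nbins]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mtot * w1[valid] / n - m1[valid])^2 /
    (w1[valid] / n * w2[valid] / n) / n^2
  br[which.max(between) + 1L]
}

# Bounding-box fill ratio of a mask: volume / axis-aligned bounding box
# volume. A solid ellipsoid is ~pi/6 ~ 0.52.
extent_fill_ratio <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  box <- prod(apply(idx, 2L, function(v) diff(range(v)) + 1L))
  nrow(idx) / box
}
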