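#' 3D median filter
#'
#' Replaces every voxel by the median of its `(2r+1)` box neighbourhood,
#' with mirror reflection at the stack edges. Suppresses shot-noise impulses
#' before thresholding without shifting edges.
#'
#' @param stack A [voxel_grid()].
#' @param radius Non-negative integer radius in voxels, length 1 (isotropic)
#'   or 3 `(z, y, x)`.
#' @return A filtered `voxel_grid` of identical shape and geometry.
#' @export
median_filter_3d <- function(stack, radius = 1L) {
  stopifnot(inherits(stack, "voxel_grid"))
  r <- as.integer(rep_len(radius, 3L))
  if (any(r < 0)) abort("`radius` must be non-negative.")
  if (all(r == 0L)) return(stack)
  out <- stack
  out$data <- median3d_cpp(stack$data, r[1], r[2], r[3])
  out
}

# Ellipsoid structuring element offsets for a physical radius (um), corrected
# for voxel anisotropy. Returns an m x 3 integer matrix of (dz, dy, dx).
ellipsoid_se <- function(radius_um, dz, dy, dx) {
  r <- c(radius_um / dz, radius_um / dy, radius_um / dx)
  rr <- pmax(1L, floor(r))
  g <- expand.grid(dz = -rr[1]:rr[1], dy = -rr[2]:rr[2], dx = -rr[3]:rr[3])
  keep <- (g$dz / r[1])^2 + (g$dy / r[2])^2 + (g$dx / r[3])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' 3D white top-hat filter
#'
#' Input minus its grayscale morphological opening with a flat ellipsoidal
#' structuring element of the given physical radius (converted per axis to
#' voxels, so anisotropic stacks get an anisotropic element). Structures
#' broader than the element — diffuse dye background in particular — are
#' removed; tubules thinner than it pass through unchanged. Output is
#' non-negative by construction.
#'
#' @param stack A [voxel_grid()].
#' @param radius_um Physical radius of the structuring element in
#'   micrometres (default 1).
#' @return A background-subtracted `voxel_grid`.
#' @export
tophat_filter_3d <- function(stack, radius_um = 1.0) {
  stopifnot(inherits(stack, "voxel_grid"))
  se <- ellipsoid_se(radius_um, stack$dz, stack$dy, stack$dx)
  d <- dim(stack$data)
  if (any(2L * apply(abs(se), 2, max) + 1L > d)) {
    abort("Structuring element larger than the stack.")
  }
  eroded <- morph3d_cpp(stack$data, se, 0L)
  opened <- morph3d_cpp(eroded, se, 1L)
  out <- stack
  out$data <- pmax(stack$data - opened, 0)
  dim(out$data) <- d
  out
}

#' Threshold at a constant intensity
#'
#' Masks are made by thresholding at a constant value; the boundary is
#' inclusive (voxels exactly at the threshold are foreground), so a zero
#' threshold gives an all-true mask.
#'
#' @param stack A [voxel_grid()].
#' @param value Non-negative constant threshold.
#' @return A `binary_mask`: logical 3D array plus the source geometry.
#' @export
threshold_constant <- function(stack, value) {
  stopifnot(inherits(stack, "voxel_grid"))
  if (!is.numeric(value) || length(value) != 1L || value < 0) {
    abort("`value` must be a non-negative scalar.")
  }
  binary_mask(stack$data >= value, stack)
}

binary_mask <- function(data, grid) {
  storage.mode(data) <- "logical"
  structure(list(data = data, dz = grid$dz, dy = grid$dy, dx = grid$dx),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Suggest a constant threshold from a background region
#'
#' The pipeline always applies a user-chosen constant threshold; this helper
#' proposes one as `mean + k * sd` of a designated background region.
#'
#' @param stack A [voxel_grid()].
#' @param background Logical array (same shape) marking background voxels, or
#'   `NULL` to use the first z-slice's outer border.
#' @param k Multiplier on the background standard deviation (default 3).
#' @return A single suggested threshold value.
#' @export
suggest_threshold <- function(stack, background = NULL, k = 3) {
  stopifnot(inherits(stack, "voxel_grid"))
  if (is.null(background)) {
    d <- dim(stack$data)
    background <- array(FALSE, d)
    background[1, c(1, d[2]), ] <- TRUE
    background[1, , c(1, d[3])] <- TRUE
  }
  check_same_shape(stack$data, background, "stack and background region")
  v <- stack$data[background]
  mean(v) + k * sd(v)
}

#' Label connected mitochondrial objects
#'
#' 3D connected-component labelling of a binary mask under 6-, 18- or
#' 26-connectivity. Labels are consecutive from 1 in first-encounter order of
#' a `(z, y, x)` lexicographic scan, so repeated runs are byte-identical.
#'
#' @param mask A `binary_mask` from [threshold_constant()].
#' @param connectivity 6, 18 or 26 (default 26: tubules cross voxel corners).
#' @return A `label_map`: integer 3D array (0 = background), `n_labels`, and
#'   the mask geometry.
#' @export
label_objects <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  lab <- label3d_cpp(mask$data, as.integer(connectivity))
  structure(list(data = lab, n_labels = max(lab),
                 dz = mask$dz, dy = mask$dy, dx = mask$dx),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_map> %d x %d x %d, %d objects\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

#' Classify a mitochondrial object by volume
#'
#' Three morphology classes: `small` (< low bound) for tiny fragmented
#' mitochondria, `medium` (closed interval between the bounds), and `network`
#' (> high bound) for fused networks. Defaults are 2 and 10 cubic
#' micrometres; both boundaries belong to the middle class.
#'
#' @param volume_um3 Object volume(s) in cubic micrometres.
#' @param bounds Two increasing volumes `(low, high)`.
#' @return Character vector in `{"small", "medium", "network"}`.
#' @examples
#' classify_size(c(1.9, 2, 10, 10.5))
#' @export
classify_size <- function(volume_um3, bounds = c(2, 10)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  if (any(volume_um3 < 0)) abort("Volumes must be non-negative.")
  dplyr::case_when(
    volume_um3 < bounds[1] ~ "small",
    volume_um3 > bounds[2] ~ "network",
    .default = "medium"
  )
}

#' Measure labelled objects
#'
#' Per-object voxel count, physical volume, mean/total intensity and size
#' class. Intensities are read from the supplied stack — conventionally the
#' unfiltered input, so the membrane-potential readout is not distorted by
#' the morphology filters used to build the mask.
#'
#' @param labels A `label_map`.
#' @param intensity A [voxel_grid()] of identical shape to read intensities
#'   from.
#' @param bounds Size-class bounds passed to [classify_size()].
#' @return A tibble with one row per object: `object_id, voxel_count,
#'   volume_um3, mean_intensity, total_intensity, size_class`.
#' @export
measure_objects <- function(labels, intensity, bounds = c(2, 10)) {
  stopifnot(inherits(labels, "label_map"), inherits(intensity, "voxel_grid"))
  check_same_shape(labels$data, intensity$data, "label map and intensity stack")
  vv <- labels$dz * labels$dy * labels$dx
  if (labels$n_labels == 0L) {
    return(tibble::tibble(
      object_id = integer(), voxel_count = integer(), volume_um3 = double(),
      mean_intensity = double(), total_intensity = double(),
      size_class = character()
    ))
  }
  idx <- labels$data > 0L
  lab <- labels$data[idx]
  val <- intensity$data[idx]
  counts <- tabulate(lab, nbins = labels$n_labels)
  totals <- as.numeric(rowsum(val, lab, reorder = TRUE))
  tibble::tibble(
    object_id = seq_len(labels$n_labels),
    voxel_count = counts,
    volume_um3 = counts * vv,
    mean_intensity = totals / counts,
    total_intensity = totals,
    size_class = classify_size(counts * vv, bounds)
  )
}

#' Segment mitochondria in one stack
#'
#' The full segmentation chain: 3D median filter, white top-hat, constant
#' threshold, connected-component labelling, object measurement. The mask is
#' built from the filtered data but intensities are measured on the input
#' stack. Accepts raw or externally deconvolved stacks through the same code
#' path.
#'
#' @param stack Mitochondrial-channel [voxel_grid()].
#' @param config An [analysis_config()]; `threshold_mito` must be set.
#' @return A list with `labels` (a `label_map`) and `objects` (the
#'   [measure_objects()] tibble).
#' @export
segment_mito <- function(stack, config = analysis_config(threshold_mito = 0)) {
  stopifnot(inherits(stack, "voxel_grid"), inherits(config, "analysis_config"))
  if (is.null(config$threshold_mito)) {
    abort("`config$threshold_mito` is required (see suggest_threshold()).")
  }
  filtered <- median_filter_3d(stack, config$median_radius)
  filtered <- tophat_filter_3d(filtered, config$tophat_radius_um)
  mask <- threshold_constant(filtered, config$threshold_mito)
  labels <- label_objects(mask, config$connectivity)
  objects <- measure_objects(labels, stack, config$size_class_bounds)
  list(labels = labels, objects = objects)
}

#' Write a label map as a 16-bit multi-page TIFF
#'
#' @param labels A `label_map` (at most 65535 objects).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (labels$n_labels > 65535L) abort("Too many labels for 16-bit output.")
  g <- voxel_grid(labels$data + 0, labels$dz, labels$dy, labels$dx,
                  channel = "mito", bit_depth = 16L)
  write_stack(g, path)
}
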