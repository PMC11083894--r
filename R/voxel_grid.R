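#' Create a voxel grid
#'
#' A `voxel_grid` holds one channel's 3D intensity stack together with its
#' physical voxel dimensions. The array is indexed `(z, y, x)` (slice, row,
#' column), 0 is the darkest intensity, and all physical quantities are in
#' micrometres. Geometry always comes from the caller (acquisition metadata
#' or a config file), never from pixel data.
#'
#' @param data 3D numeric array of non-negative intensities, dim `(z, y, x)`.
#'   A matrix is promoted to a single-slice stack.
#' @param dz,dy,dx Voxel edge lengths in micrometres (> 0). Typical confocal
#'   values: 0.103 x 0.103 um laterally with a 0.15 um z-step at 63x, or
#'   0.325 x 0.325 x 0.35 um at 20x.
#' @param channel Which stain the channel carries: `"mito"` (membrane
#'   potential dye), `"nucleus"` (Hoechst) or `"cell"` (Calcein-AM).
#' @param bit_depth Integer bit depth of the source acquisition (default 16).
#' @return A `voxel_grid` object.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), dz = 0.35, dy = 0.325, dx = 0.325)
#' dim(g$data)
#' voxel_volume(g)
#' @export
voxel_grid <- function(data, dz, dy, dx, channel = c("mito", "nucleus", "cell"),
                       bit_depth = 16L) {
  channel <- match.arg(channel)
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array indexed (z, y, x).")
  }
  if (anyNA(data) || any(data < 0)) {
    abort("Intensities must be non-negative and non-missing.")
  }
  for (d in c(dz = dz, dy = dy, dx = dx)) {
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
      abort("Voxel dimensions dz, dy, dx must be positive finite scalars.")
    }
  }
  structure(
    list(data = data, dz = dz, dy = dy, dx = dx,
         channel = channel, bit_depth = as.integer(bit_depth)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid [%s]> %d x %d x %d voxels (z,y,x), %.3f x %.3f x %.3f um, %d-bit\n",
    x$channel, d[1], d[2], d[3], x$dz, x$dy, x$dx, x$bit_depth))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param grid A [voxel_grid()].
#' @return Voxel volume in cubic micrometres (`dz * dy * dx`).
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$dz * grid$dy * grid$dx
}

#' Bundle the acquisition channels of one cell
#'
#' Groups the mitochondrial channel with the optional nucleus (Hoechst) and
#' whole-cell (Calcein-AM) channels of a three-colour acquisition. All present
#' channels must share array shape and voxel geometry.
#'
#' @param mito `voxel_grid` of the membrane-potential dye channel (required).
#' @param nucleus,cell Optional `voxel_grid`s for the nuclear and whole-cell
#'   stains.
#' @return A `channel_set` object.
#' @export
channel_set <- function(mito, nucleus = NULL, cell = NULL) {
  stopifnot(inherits(mito, "voxel_grid"))
  ref <- c(dim(mito$data), mito$dz, mito$dy, mito$dx)
  for (ch in list(nucleus = nucleus, cell = cell)) {
    if (is.null(ch)) next
    stopifnot(inherits(ch, "voxel_grid"))
    if (!isTRUE(all.equal(c(dim(ch$data), ch$dz, ch$dy, ch$dx), ref))) {
      abort("All channels must share array shape and voxel dimensions.")
    }
  }
  structure(list(mito = mito, nucleus = nucleus, cell = cell),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  present <- names(x)[!vapply(x, is.null, logical(1))]
  cat("<channel_set> channels:", paste(present, collapse = ", "), "\n")
  invisible(x)
}

#' Rectangular regions of interest
#'
#' Builds the ROI table used by the photostability analysis: one row per
#' rectangle, 0-based top-left corner, extents in pixels. ROIs used for
#' photostability measurements conventionally cover 100-150 square
#' micrometres; [build_series()] warns (but does not fail) outside that range.
#'
#' @param roi_id Identifier, any atomic vector.
#' @param y0,x0 0-based top-left pixel of each rectangle.
#' @param height,width Rectangle extents in pixels (>= 1).
#' @return A tibble with class `roi_table`.
#' @examples
#' roi_table(c("a", "b"), y0 = c(0, 40), x0 = c(0, 40), height = 30, width = 35)
#' @export
roi_table <- function(roi_id, y0, x0, height, width) {
  out <- tibble::tibble(
    roi_id = roi_id,
    y0 = as.integer(y0), x0 = as.integer(x0),
    height = as.integer(height), width = as.integer(width)
  )
  if (any(out$y0 < 0 | out$x0 < 0) || any(out$height < 1 | out$width < 1)) {
    abort("ROIs need non-negative corners and positive extents.")
  }
  if (anyDuplicated(out$roi_id)) abort("`roi_id` values must be unique.")
  class(out) <- c("roi_table", class(out))
  out
}

#' Analysis configuration
#'
#' Collects the tunable parameters of the segmentation and morphometry
#' pipeline. Filter radii are in voxels per axis `(z, y, x)` for the median
#' filter and in physical micrometres for the top-hat structuring element
#' (converted to an anisotropy-corrected ellipsoid of voxels at run time).
#' Thresholds are constant intensity values, one per channel, honouring
#' mask creation by thresholding at a constant value; [suggest_threshold()]
#' helps pick one from a background region.
#'
#' @param threshold_mito Constant threshold for the mitochondrial channel
#'   (required for segmentation; no data-driven default).
#' @param threshold_nucleus,threshold_cell Constant thresholds for the
#'   nuclear and whole-cell channels.
#' @param median_radius Median filter radius in voxels, length 1 or 3 (z,y,x).
#' @param tophat_radius_um Physical radius of the top-hat structuring element
#'   in micrometres.
#' @param connectivity Voxel connectivity for object labelling: 6, 18 or 26.
#'   26 is the default: mitochondrial tubules routinely traverse voxels
#'   diagonally and 6-connectivity fragments them.
#' @param size_class_bounds Two increasing volumes (um^3) separating small /
#'   medium / network objects; defaults to `c(2, 10)`.
#' @param fill_holes_cell,fill_holes_nucleus Whether to fill internal cavities
#'   (e.g. vacuoles) in the respective channel mask. Default fills the cell
#'   channel only.
#' @param seed Integer seed recorded with the run for provenance.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(threshold_mito = NULL,
                            threshold_nucleus = NULL,
                            threshold_cell = NULL,
                            median_radius = 1L,
                            tophat_radius_um = 1.0,
                            connectivity = 26L,
                            size_class_bounds = c(2, 10),
                            fill_holes_cell = TRUE,
                            fill_holes_nucleus = FALSE,
                            seed = 1L) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18 or 26.")
  }
  if (length(size_class_bounds) != 2L ||
      !(size_class_bounds[1] < size_class_bounds[2])) {
    abort("`size_class_bounds` must be two strictly increasing volumes.")
  }
  for (th in list(threshold_mito, threshold_nucleus, threshold_cell)) {
    if (!is.null(th) && (!is.numeric(th) || th < 0)) {
      abort("Thresholds must be non-negative.")
    }
  }
  if (any(median_radius < 0)) abort("`median_radius` must be >= 0.")
  structure(
    list(threshold_mito = threshold_mito,
         threshold_nucleus = threshold_nucleus,
         threshold_cell = threshold_cell,
         median_radius = as.integer(rep_len(median_radius, 3L)),
         tophat_radius_um = tophat_radius_um,
         connectivity = as.integer(connectivity),
         size_class_bounds = as.numeric(size_class_bounds),
         fill_holes_cell = isTRUE(fill_holes_cell),
         fill_holes_nucleus = isTRUE(fill_holes_nucleus),
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

# shared validation helper
check_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b))) {
    abort(paste0("Shape mismatch between ", what, "."))
  }
  invisible(TRUE)
}
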