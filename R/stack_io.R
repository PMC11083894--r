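#' Read a multi-page TIFF z-stack
#'
#' Pages become z-slices in acquisition order; intensities are returned
#' unmodified on the integer scale implied by `bit_depth` (the `tiff` package
#' reads samples as [0, 1] fractions, which are rescaled back). Voxel
#' geometry is supplied by the caller, never inferred from file metadata;
#' if the file disagrees with the supplied geometry the supplied values win.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param dz,dy,dx Voxel edge lengths in micrometres.
#' @inheritParams voxel_grid
#' @return A [voxel_grid()] with dim `(n_pages, height, width)`.
#' @export
read_stack <- function(path, dz, dy, dx, channel = "mito", bit_depth = 16L) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (length(shp) != 2L) abort("Expected single-sample (grayscale) pages.")
  for (p in pages) {
    if (!identical(dim(p), shp)) abort("TIFF pages have inconsistent shapes.")
  }
  scale <- 2^bit_depth - 1
  data <- array(0, c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) data[i, , ] <- round(pages[[i]] * scale)
  voxel_grid(data, dz = dz, dy = dy, dx = dx, channel = channel,
             bit_depth = bit_depth)
}

#' Write a voxel grid as a multi-page TIFF
#'
#' Inverse of [read_stack()]: integer intensities in `[0, 2^bit_depth - 1]`
#' round-trip losslessly.
#'
#' @param grid A [voxel_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  scale <- 2^grid$bit_depth - 1
  if (max(grid$data) > scale) {
    abort("Intensities exceed the range of the declared bit depth.")
  }
  nz <- dim(grid$data)[1]
  pages <- lapply(seq_len(nz), function(z) grid$data[z, , ] / scale)
  bps <- if (grid$bit_depth <= 8) 8L else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bps)
  invisible(path)
}

#' Write the per-object measurement table
#'
#' One row per labelled mitochondrial object, full precision, CSV. The
#' columns are `cell_id, object_id, voxel_count, volume_um3, mean_intensity,
#' total_intensity, size_class`; a round-trip through
#' [read_objects_table()] reproduces the values exactly.
#'
#' @param records Tibble of object records as returned by [measure_objects()]
#'   (a `cell_id` column is added if absent).
#' @param path Output CSV path.
#' @param cell_id Cell identifier used when `records` has no `cell_id`.
#' @return `path`, invisibly.
#' @export
write_objects_table <- function(records, path, cell_id = "cell1") {
  cols <- c("cell_id", "object_id", "voxel_count", "volume_um3",
            "mean_intensity", "total_intensity", "size_class")
  if (!"cell_id" %in% names(records)) {
    records <- dplyr::mutate(records, cell_id = cell_id, .before = 1L)
  }
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    abort(paste0("Records lack columns: ", paste(missing, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(records, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_objects_table
#' @export
read_objects_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(),
    object_id = readr::col_integer(),
    voxel_count = readr::col_integer(),
    volume_um3 = readr::col_double(),
    mean_intensity = readr::col_double(),
    total_intensity = readr::col_double(),
    size_class = readr::col_character()
  ))
}

#' Read an ROI definition CSV
#'
#' Expects columns `roi_id, y0, x0, height, width` (0-based corners, pixel
#' extents), the on-disk form of [roi_table()].
#'
#' @param path CSV path.
#' @return An `roi_table` tibble.
#' @export
read_roi_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    roi_id = readr::col_character(), y0 = readr::col_integer(),
    x0 = readr::col_integer(), height = readr::col_integer(),
    width = readr::col_integer()
  ))
  roi_table(df$roi_id, df$y0, df$x0, df$height, df$width)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognised keys are the arguments of [analysis_config()] plus the voxel
#' dimensions `dz, dy, dx`; `median_radius` and `size_class_bounds` may be
#' comma-separated. Returns the config together with any geometry found.
#'
#' @param path Path to the config file.
#' @return A list with elements `config` ([analysis_config()]) and `geometry`
#'   (named list with any of dz, dy, dx, possibly empty).
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  sep <- regexpr("[=:]", lines)
  if (any(sep < 0)) abort("Config lines must look like `key = value`.")
  keys <- trimws(substr(lines, 1L, sep - 1L))
  vals <- trimws(substring(lines, sep + 1L))
  parsed <- setNames(as.list(vals), keys)
  num <- function(key) {
    if (is.null(parsed[[key]])) return(NULL)
    as.numeric(strsplit(parsed[[key]], ",")[[1]])
  }
  lgl <- function(key, default) {
    if (is.null(parsed[[key]])) return(default)
    tolower(parsed[[key]]) %in% c("true", "1", "yes")
  }
  cfg <- analysis_config(
    threshold_mito = num("threshold_mito"),
    threshold_nucleus = num("threshold_nucleus"),
    threshold_cell = num("threshold_cell"),
    median_radius = if (is.null(num("median_radius"))) 1L else num("median_radius"),
    tophat_radius_um = if (is.null(num("tophat_radius_um"))) 1.0 else num("tophat_radius_um"),
    connectivity = if (is.null(num("connectivity"))) 26L else num("connectivity"),
    size_class_bounds = if (is.null(num("size_class_bounds"))) c(2, 10) else num("size_class_bounds"),
    fill_holes_cell = lgl("fill_holes_cell", TRUE),
    fill_holes_nucleus = lgl("fill_holes_nucleus", FALSE),
    seed = if (is.null(num("seed"))) 1L else as.integer(num("seed"))
  )
  geom <- Filter(Negate(is.null),
                 list(dz = num("dz"), dy = num("dy"), dx = num("dx")))
  list(config = cfg, geometry = geom)
}
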