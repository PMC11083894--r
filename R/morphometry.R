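#' Fill internal cavities in a 3D mask
#'
#' Background components not 6-connected to the array border become
#' foreground — e.g. vacuoles inside a Calcein-stained cell, which would
#' otherwise be subtracted from the cell volume. Foreground is never removed,
#' and the operation is idempotent.
#'
#' @param mask A `binary_mask`.
#' @return A `binary_mask` with cavities filled.
#' @export
fill_holes_3d <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  out <- mask
  out$data <- fillholes3d_cpp(mask$data)
  out
}

#' Physical volume of a mask
#'
#' @param mask A `binary_mask`.
#' @return True-voxel count times voxel volume, in cubic micrometres.
#' @export
channel_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * mask$dz * mask$dy * mask$dx
}

#' Size-class composition of an object table
#'
#' Percentage of objects, by count, in each of the small / medium / network
#' volume classes.
#'
#' @param records Object tibble from [measure_objects()].
#' @return A tibble with columns `size_class` and `pct`, always three rows in
#'   class order; all-`NA` percentages if `records` is empty.
#' @export
size_class_percentages <- function(records) {
  lv <- c("small", "medium", "network")
  if (nrow(records) == 0L) {
    return(tibble::tibble(size_class = lv, pct = NA_real_))
  }
  counts <- table(factor(records$size_class, levels = lv))
  tibble::tibble(size_class = lv, pct = 100 * as.numeric(counts) / nrow(records))
}

#' Quantify one cell
#'
#' Runs [segment_mito()] on the mitochondrial channel, thresholds the
#' whole-cell channel (with hole filling) and the nuclear channel, and
#' assembles the per-cell summary: object count, total mitochondrial volume
#' and intensity, nucleus / cell / cytoplasm volumes, percentage of
#' mitochondrial volume per cytoplasm volume, and size-class percentages.
#'
#' The nuclear mask is intersected with the cell mask before measuring, so
#' cytoplasm volume (cell minus nucleus) can never go negative even with
#' noisy masks; in multi-nucleated cells all nuclear voxels are pooled. When
#' cytoplasm volume is zero the percentage field is `NA`.
#'
#' @param channels A [channel_set()]; nucleus and cell channels are optional,
#'   in which case the dependent fields are `NA`.
#' @param config An [analysis_config()] with the relevant thresholds set.
#' @param cell_id Identifier recorded in the output row.
#' @return A list with `quant` (one-row tibble), `objects` (per-object
#'   tibble) and `labels` (the mitochondrial `label_map`).
#' @export
quantify_cell <- function(channels, config, cell_id = "cell1") {
  stopifnot(inherits(channels, "channel_set"),
            inherits(config, "analysis_config"))
  seg <- segment_mito(channels$mito, config)
  objects <- dplyr::mutate(seg$objects, cell_id = cell_id, .before = 1L)

  cell_vol <- NA_real_
  nuc_vol <- NA_real_
  cell_mask <- NULL
  if (!is.null(channels$cell)) {
    if (is.null(config$threshold_cell)) {
      abort("`config$threshold_cell` is required when a cell channel is given.")
    }
    cell_mask <- threshold_constant(channels$cell, config$threshold_cell)
    if (config$fill_holes_cell) cell_mask <- fill_holes_3d(cell_mask)
    cell_vol <- channel_volume(cell_mask)
  }
  if (!is.null(channels$nucleus)) {
    if (is.null(config$threshold_nucleus)) {
      abort("`config$threshold_nucleus` is required when a nucleus channel is given.")
    }
    nuc_mask <- threshold_constant(channels$nucleus, config$threshold_nucleus)
    if (config$fill_holes_nucleus) nuc_mask <- fill_holes_3d(nuc_mask)
    if (!is.null(cell_mask)) nuc_mask$data <- nuc_mask$data & cell_mask$data
    nuc_vol <- channel_volume(nuc_mask)
  }
  cyt_vol <- cell_vol - nuc_vol
  total_mt_vol <- sum(objects$volume_um3)
  pct <- pct_mt_per_cytoplasm(total_mt_vol, cyt_vol)
  if (!is.na(cyt_vol) && cyt_vol == 0) {
    warn(paste0("Cell ", cell_id,
                ": cytoplasm volume is zero; % mt per cytoplasm undefined."))
  }
  scp <- size_class_percentages(objects)
  quant <- tibble::tibble(
    cell_id = cell_id,
    n_objects = nrow(objects),
    total_mt_volume_um3 = total_mt_vol,
    nucleus_volume_um3 = nuc_vol,
    cell_volume_um3 = cell_vol,
    cytoplasm_volume_um3 = cyt_vol,
    pct_mt_per_cytoplasm = pct,
    total_mt_intensity = sum(objects$total_intensity),
    pct_small = scp$pct[1], pct_medium = scp$pct[2], pct_network = scp$pct[3]
  )
  list(quant = quant, objects = objects, labels = seg$labels)
}

#' Percentage of mitochondrial volume per cytoplasm volume
#'
#' `100 * total mitochondrial volume / cytoplasm volume`; `NA` when the
#' cytoplasm volume is zero or missing.
#'
#' @param total_mt_volume_um3,cytoplasm_volume_um3 Volumes in cubic
#'   micrometres (vectorised).
#' @return Percentage(s).
#' @examples
#' pct_mt_per_cytoplasm(714, 4043)
#' @export
pct_mt_per_cytoplasm <- function(total_mt_volume_um3, cytoplasm_volume_um3) {
  dplyr::if_else(
    is.na(cytoplasm_volume_um3) | cytoplasm_volume_um3 <= 0,
    NA_real_,
    100 * total_mt_volume_um3 / cytoplasm_volume_um3
  )
}

#' Group summary: mean and standard deviation per field
#'
#' Summarises a table of per-cell quantifications as sample mean and sample
#' standard deviation (n - 1 denominator) for every numeric column, the form
#' in which per-group morphometrics are conventionally reported. With a
#' single cell the SD is reported as 0 and flagged.
#'
#' @param quants Tibble of per-cell rows (e.g. stacked `quant` rows from
#'   [quantify_cell()]).
#' @param label Optional group label recorded in the output.
#' @return A tibble with columns `group, field, n, mean, sd, sd_defined`.
#' @export
summarize_group <- function(quants, label = "group") {
  if (nrow(quants) < 1L) abort("Need at least one cell.")
  num <- dplyr::select(quants, dplyr::where(is.numeric))
  out <- tidyr::pivot_longer(num, dplyr::everything(),
                             names_to = "field", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$field),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (sum(!is.na(.data$value)) > 1L) sd(.data$value, na.rm = TRUE) else 0,
    sd_defined = sum(!is.na(.data$value)) > 1L,
    .groups = "drop"
  )
  out <- dplyr::mutate(out, group = label, .before = 1L)
  out[match(names(num), out$field), , drop = FALSE]
}
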