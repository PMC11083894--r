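#' Quantify many cells
#'
#' Runs [quantify_cell()] over a list of [channel_set()]s and stacks the
#' per-cell rows.
#'
#' @param channel_sets Named list of `channel_set`s (names become cell ids).
#' @param config An [analysis_config()].
#' @return A list with `quants` (tibble, one row per cell) and `objects`
#'   (tibble, one row per object across all cells).
#' @export
quantify_cells <- function(channel_sets, config) {
  ids <- names(channel_sets)
  if (is.null(ids)) ids <- paste0("cell", seq_along(channel_sets))
  res <- purrr::map2(channel_sets, ids,
                     function(ch, id) quantify_cell(ch, config, cell_id = id))
  list(
    quants = purrr::map_dfr(res, "quant"),
    objects = purrr::map_dfr(res, "objects")
  )
}

#' Group report: summary table and size-class composition
#'
#' Produces the per-group report: mean and SD of the five standard per-cell
#' columns (object count, total mitochondrial volume, cytoplasm volume, %
#' mitochondrial volume per cytoplasm, total mitochondrial intensity) plus
#' the mean size-class percentages. Intensity fields are flagged as not
#' comparable across staining sessions: absolute dye intensity is only
#' meaningful within one staining and imaging session.
#'
#' @param quants Per-cell tibble from [quantify_cells()] (or stacked
#'   [quantify_cell()] rows).
#' @param label Group label.
#' @return A list with `summary` (field, n, mean, sd, cross_session_comparable)
#'   and `size_classes` (size_class, mean pct).
#' @export
report_group <- function(quants, label = "group") {
  fields <- c("n_objects", "total_mt_volume_um3", "cytoplasm_volume_um3",
              "pct_mt_per_cytoplasm", "total_mt_intensity")
  summ <- summarize_group(dplyr::select(quants, dplyr::any_of(fields)), label)
  summ <- dplyr::mutate(
    summ,
    cross_session_comparable = !grepl("intensity", .data$field)
  )
  cls <- tibble::tibble(
    group = label,
    size_class = c("small", "medium", "network"),
    pct = c(mean(quants$pct_small, na.rm = TRUE),
            mean(quants$pct_medium, na.rm = TRUE),
            mean(quants$pct_network, na.rm = TRUE))
  )
  list(summary = summ, size_classes = cls)
}

#' Run the full pipeline over a manifest of cells
#'
#' For every row of the manifest: read the channel TIFFs, segment and
#' quantify, and write the per-cell object table. Then write the per-cell
#' quantification table, the group report, and a run manifest recording the
#' configuration snapshot, input hashes, seed and package version, so a
#' rerun with the same inputs is byte-identical.
#'
#' @param manifest Tibble/data frame with columns `cell_id, mito` and
#'   optionally `nucleus, cell` (TIFF paths), or a path to such a CSV.
#' @param config An [analysis_config()].
#' @param geometry Named list/vector with voxel dimensions `dz, dy, dx` (um).
#' @param out_dir Output directory (created if needed).
#' @param group Group label for the report.
#' @return Invisibly, a list with `quants`, `objects`, `report` and
#'   `manifest_path`.
#' @export
run_pipeline <- function(manifest, config, geometry, out_dir,
                         group = "group") {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, col_types = readr::cols())
  }
  if (!all(c("cell_id", "mito") %in% names(manifest))) {
    abort("Manifest needs at least `cell_id` and `mito` columns.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- as.list(geometry)

  paths <- unlist(manifest[intersect(names(manifest),
                                     c("mito", "nucleus", "cell"))])
  paths <- paths[!is.na(paths) & nzchar(paths)]
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    bad <- manifest$cell_id[apply(manifest, 1, function(r) any(r %in% missing))]
    abort(paste0("Missing input file(s) for cell(s): ",
                 paste(unique(bad), collapse = ", ")))
  }

  read_ch <- function(path, channel) {
    if (is.null(path) || is.na(path) || !nzchar(path)) return(NULL)
    read_stack(path, dz = geometry$dz, dy = geometry$dy, dx = geometry$dx,
               channel = channel)
  }
  channel_sets <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    channel_set(
      mito = read_ch(row$mito, "mito"),
      nucleus = if ("nucleus" %in% names(row)) read_ch(row$nucleus, "nucleus"),
      cell = if ("cell" %in% names(row)) read_ch(row$cell, "cell")
    )
  })
  names(channel_sets) <- manifest$cell_id

  res <- quantify_cells(channel_sets, config)
  readr::write_csv(res$quants, file.path(out_dir, "cell_quantifications.csv"))
  write_objects_table(res$objects, file.path(out_dir, "objects.csv"))
  rep <- report_group(res$quants, label = group)
  readr::write_csv(rep$summary, file.path(out_dir, "group_summary.csv"))
  readr::write_csv(rep$size_classes, file.path(out_dir, "size_classes.csv"))

  mp <- write_run_manifest(
    out_dir,
    command = "run_pipeline",
    config = config,
    inputs = paths,
    seed = config$seed
  )
  invisible(list(quants = res$quants, objects = res$objects, report = rep,
                 manifest_path = mp))
}

#' Write a run manifest
#'
#' Records command, configuration snapshot, input-file MD5 hashes, seed,
#' package version and timestamp as `run_manifest.json` in the output
#' directory — one manifest per output directory.
#'
#' @param out_dir Output directory.
#' @param command Command or function name being recorded.
#' @param config An [analysis_config()] (stored as a flat snapshot).
#' @param inputs Character vector of input file paths to hash.
#' @param seed Integer seed used for the run.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(out_dir, command, config, inputs = character(),
                               seed = config$seed) {
  manifest <- list(
    command = command,
    config = unclass(config),
    input_hashes = as.list(tools::md5sum(inputs)),
    seed = seed,
    tool_version = as.character(utils::packageVersion("mitonet3d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
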