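## Plain-text I/O: coordinate-table CSVs, scene serialization (one
## whitespace-delimited integer matrix per channel + JSON channel map; the
## offline R stack has no TIFF codec), and the run manifest.

.SIGNAL_COLS <- c("nucleus_id", "case", "fraction", "chromosome",
                  "x_um", "y_um", "basal_x_um", "basal_y_um",
                  "apex_x_um", "apex_y_um", "L_um", "l_um")

#' Write / read a coordinate-table CSV
#'
#' The interchange schema: one row per FISH signal with its nucleus geometry.
#'
#' @param signals data.frame containing at least the schema columns.
#' @param path CSV file path.
#' @return `read_signals_csv` returns the data.frame (chromosome as
#'   character).
#' @export
write_signals_csv <- function(signals, path) {
  miss <- setdiff(.SIGNAL_COLS, names(signals))
  if (length(miss))
    stp_data_error("coordinate table lacks columns: %s", paste(miss, collapse = ", "))
  utils::write.csv(signals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  if (!file.exists(path)) stp_data_error("coordinate table not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(chromosome = "character"))
  miss <- setdiff(.SIGNAL_COLS, names(d))
  if (length(miss))
    stp_data_error("coordinate table lacks columns: %s", paste(miss, collapse = ", "))
  d
}

#' Serialize / load a rendered scene as plain text
#'
#' Each channel becomes `<name>_<channel>.txt` (whitespace-delimited integer
#' matrix); the channel map goes to `<name>_channelmap.json` and the ground
#' truth sidecars to `<name>_cells.csv` / `<name>_signals.csv`.
#'
#' @param scene a scene from [render_images()].
#' @param dir output directory.
#' @param name file-name stem.
#' @return `read_scene` returns the scene list.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(scene$channels)) {
    utils::write.table(scene$channels[[ch]],
                       file.path(dir, sprintf("%s_%s.txt", name, ch)),
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(scene$channel_map,
                       file.path(dir, sprintf("%s_channelmap.json", name)),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(scene$truth_cells,
                   file.path(dir, sprintf("%s_cells.csv", name)), row.names = FALSE)
  utils::write.csv(scene$truth_signals,
                   file.path(dir, sprintf("%s_signals.csv", name)), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir, name = "scene") {
  cm_path <- file.path(dir, sprintf("%s_channelmap.json", name))
  if (!file.exists(cm_path))
    stp_config_error("missing channel-map sidecar: %s", cm_path)
  channel_map <- jsonlite::read_json(cm_path, simplifyVector = TRUE)
  channel_map$roles <- as.list(channel_map$roles)
  channels <- lapply(names(channel_map$roles), function(ch) {
    as.matrix(utils::read.table(file.path(dir, sprintf("%s_%s.txt", name, ch))))
  })
  names(channels) <- names(channel_map$roles)
  channels <- lapply(channels, function(m) { dimnames(m) <- NULL; m })
  tc_path <- file.path(dir, sprintf("%s_cells.csv", name))
  ts_path <- file.path(dir, sprintf("%s_signals.csv", name))
  list(channels = channels, channel_map = channel_map,
       truth_cells = if (file.exists(tc_path))
         utils::read.csv(tc_path, stringsAsFactors = FALSE) else NULL,
       truth_signals = if (file.exists(ts_path))
         utils::read.csv(ts_path, stringsAsFactors = FALSE,
                         colClasses = c(chromosome = "character")) else NULL)
}
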