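## Orchestration: simulate -> (render/measure | take coordinates) ->
## classify -> aggregate -> stats, with a JSON manifest and a JSON-lines log.
## Cells are keyed by nucleus_id throughout so topology and epimark results
## join on the same cell, mirroring sequential staining of fixed positions.

.log_line <- function(log_path, event, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), event = event),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Generates (or loads) a population, measures it in coordinate or image
#' mode, classifies epimarks, aggregates topology tables, repositioning
#' calls, distances and chromocenter clusters, and writes all outputs plus a
#' manifest under `out_dir`.
#'
#' @param config an `stp_config` (see [preset_from_tables()], [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param mode `"coords"` (analyze the generator's coordinate tables) or
#'   `"image"` (render scenes, re-measure them, analyze the measurements).
#' @param seed overrides `config$seed`.
#' @param signals_csv,cells_csv optional paths to pre-existing input tables;
#'   when given, simulation is skipped (coordinate mode only).
#' @param max_cells image mode: render only this many cells (all by default).
#' @return invisibly, a list with every intermediate and final table and the
#'   manifest.
#' @export
run_all <- function(config = preset_from_tables(), out_dir, mode = c("coords", "image"),
                    seed = NULL, signals_csv = NULL, cells_csv = NULL,
                    max_cells = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  .log_line(log_path, "start", mode = mode, seed = seed)

  ## ------- acquire signals + cells -------------------------------------
  if (!is.null(signals_csv)) {
    signals <- read_signals_csv(signals_csv)
    cells <- if (!is.null(cells_csv))
      utils::read.csv(cells_csv, stringsAsFactors = FALSE) else NULL
    pop <- NULL
  } else {
    pop <- generate_population(config, seed)
    config <- pop$config   # carries the realized epimark thresholds
    if (mode == "coords") {
      signals <- pop$signals
      cells <- pop$cells
    } else {
      scenes <- render_images(pop, max_cells = max_cells, seed = seed + 1L)
      measured <- lapply(scenes, measure_scene)
      signals <- do.call(rbind, lapply(measured, `[[`, "signals"))
      cells <- do.call(rbind, lapply(measured, `[[`, "cells"))
      meta <- pop$cells[, c("nucleus_id", "case", "fraction", "bearing")]
      m <- match(signals$nucleus_id, meta$nucleus_id)
      signals <- cbind(signals, meta[m, c("case", "fraction", "bearing")])
      mc <- match(cells$nucleus_id, meta$nucleus_id)
      cells <- cbind(cells, meta[mc, c("case", "fraction", "bearing")])
      .log_line(log_path, "image_measured",
                n_scenes = length(scenes), n_cells = nrow(cells),
                n_spots = nrow(signals))
    }
  }
  .log_line(log_path, "input", n_signals = nrow(signals),
            n_cells = if (is.null(cells)) 0L else nrow(cells))

  ## ------- geometry ----------------------------------------------------
  ann <- annotate_signals(signals, d_mode = config$d_mode)
  .log_line(log_path, "geometry_filter",
            kept = sum(ann$keep), dropped = sum(!ann$keep),
            total = nrow(ann))

  ## ------- epimarks ----------------------------------------------------
  if (!is.null(cells) && all(c("i_5mC", "i_5hmC") %in% names(cells))) {
    thr <- config$epimark$thresholds
    if (!is.null(thr)) {
      parts <- lapply(split(cells, cells$fraction), function(cc) {
        tr <- thr[thr$fraction == cc$fraction[1], ]
        classify_epimarks(cc, "fixed_k_sd",
                          list(thr_5mC = tr$thr_5mC, thr_5hmC = tr$thr_5hmC))
      })
      cells <- do.call(rbind, parts)
    } else {
      cells <- classify_epimarks(cells, "otsu")
    }
    rownames(cells) <- NULL
    m <- match(ann$nucleus_id, cells$nucleus_id)
    ann$stratum <- cells$stratum[m]
    excluded <- sum(is.na(ann$stratum))
    ann$stratum[is.na(ann$stratum)] <- "mixed"
    .log_line(log_path, "epimarks", n_hyper = sum(cells$stratum == "hyper"),
              n_hypo = sum(cells$stratum == "hypo"),
              n_mixed = sum(cells$stratum == "mixed"),
              signals_without_cell = excluded)
  } else ann$stratum <- "mixed"

  ## ------- aggregation -------------------------------------------------
  topo <- summarize_topology(ann)
  utils::write.csv(topo, file.path(out_dir, "topology_summary.csv"),
                   row.names = FALSE)
  zones <- topo[, c("chromosome", "fraction", "epistate", "n_signals",
                    "a_pct", "a_sd", "m_pct", "m_sd", "b_pct", "b_sd")]
  utils::write.csv(zones, file.path(out_dir, "zone_frequencies.csv"),
                   row.names = FALSE)
  radial <- topo[, c("chromosome", "fraction", "epistate", "n_signals",
                     "mean_d", "se_d", "mean_h", "se_h")]
  utils::write.csv(radial, file.path(out_dir, "radial_positions.csv"),
                   row.names = FALSE)

  dists <- pair_signals(ann[ann$keep, ])
  dist_sum <- if (!is.null(dists)) distance_summary(dists, min_n = 1L) else NULL
  if (!is.null(dist_sum))
    utils::write.csv(dist_sum, file.path(out_dir, "distances.csv"),
                     row.names = FALSE)

  ## ------- repositioning calls -----------------------------------------
  fr <- config$fractions
  calls <- list()
  kept <- ann[ann$keep, ]
  for (ch in unique(kept$chromosome)) {
    groups <- lapply(fr, function(f)
      kept[kept$chromosome == ch & kept$fraction == f,
           c("d_over_l", "h_over_l")])
    names(groups) <- fr
    groups <- groups[vapply(groups, nrow, 1L) >= 2L]
    if (length(groups) < 2L) next
    prs <- utils::combn(names(groups), 2)
    for (j in seq_len(ncol(prs))) {
      cl <- call_repositioning(groups, pair = prs[, j])
      calls[[length(calls) + 1L]] <- data.frame(
        chromosome = ch, from = prs[1, j], to = prs[2, j],
        direction = cl$direction, p_d = cl$p_d, p_h = cl$p_h,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else NULL
  if (!is.null(calls))
    utils::write.csv(calls, file.path(out_dir, "repositioning_calls.csv"),
                     row.names = FALSE)

  ## ------- chromocenters ------------------------------------------------
  chromo <- list()
  for (f in fr) {
    mm <- topo[topo$fraction == f & topo$epistate == "all" &
                 !topo$chromosome %in% c("18-X", "18-Y"), ]
    if (nrow(mm) < 3L) next
    k <- config$cluster_k[[f]] %||% 3L
    cl <- chromocenter_cluster(mm, k = k, method = config$cluster_method)
    writeLines(cl$newick, file.path(out_dir, sprintf("chromocenters_%s.nwk", f)))
    chromo[[f]] <- list(partition = cl$partition,
                        hull_area = chromocenter_hull_area(mm),
                        hull_area_mirrored = chromocenter_hull_area(mm, TRUE))
  }

  manifest <- list(
    seed = seed, mode = mode, d_mode = config$d_mode,
    package_version = as.character(utils::packageVersion("spermtopo")),
    outputs = list.files(out_dir),
    n_signals_in = nrow(signals), n_signals_kept = sum(ann$keep),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(log_path, "done")
  invisible(list(population = pop, signals = ann, cells = cells, topology = topo,
                 distances = dist_sum, calls = calls, chromocenters = chromo,
                 manifest = manifest))
}
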