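## Preset tables. The package ships, as plain CSV, the printed summary values
## of the study it operationalizes: per-chromosome/fraction/epistate radial
## means (D/L, H/L) and linear-zone frequencies, per-fraction epimark-positive
## proportions and chromatin-class proportions, per-case semen parameters, and
## per-pair centromere distance means. These drive the synthetic generator and
## the worked-example arithmetic.

.stp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "spermtopo")
  if (path == "")
    stp_config_error("bundled preset '%s' not found; is the package installed?", file)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

## wide (raw_all ... DGC_hypo) -> long (fraction, epistate, value)
.preset_long <- function(wide, id_cols, value_name = "value") {
  combos <- expand.grid(epistate = c("all", "hyper", "hypo"),
                        fraction = c("raw", "SU", "DGC"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    col <- paste0(combos$fraction[i], "_", combos$epistate[i])
    d <- wide[, id_cols, drop = FALSE]
    d$fraction <- combos$fraction[i]
    d$epistate <- combos$epistate[i]
    d[[value_name]] <- wide[[col]]
    d
  }))
  rownames(out) <- NULL
  out
}

#' Radial positioning presets (printed means and SEs)
#'
#' @return long data.frame: chromosome (`4,7,8,9,18,18-X,18-Y,X,Y`), axis
#'   (`d`/`h`), fraction, epistate (`all`/`hyper`/`hypo`), `mean`, `se`.
#' @export
radial_presets <- function() {
  w <- .stp_extdata("radial_presets.csv")
  m <- .preset_long(w[w$stat == "mean", ], c("chromosome", "axis"), "mean")
  s <- .preset_long(w[w$stat == "se", ], c("chromosome", "axis"), "se")
  merge(m, s, by = c("chromosome", "axis", "fraction", "epistate"), sort = FALSE)
}

#' Linear zone frequency presets (printed means, %)
#'
#' @return long data.frame: chromosome, zone (`a`/`m`/`b`), fraction,
#'   epistate, `pct`.
#' @export
zone_presets <- function() {
  w <- .stp_extdata("zone_presets.csv")
  .preset_long(w, c("chromosome", "zone"), "pct")
}

#' Epimark positivity presets (printed %, per fraction)
#' @return data.frame: fraction, pos_5mC_pct, pos_5hmC_pct.
#' @export
epimark_presets <- function() .stp_extdata("epimark_presets.csv")

#' Chromatin-class presets (printed %, per fraction)
#' @return data.frame with aniline-blue class, AO and TUNEL proportions.
#' @export
chromatin_presets <- function() .stp_extdata("chromatin_presets.csv")

#' Per-case semen parameters
#' @return data.frame, one row per case K1-K5.
#' @export
semen_params <- function() .stp_extdata("semen_params.csv")

#' Inter-centromere distance presets (printed means and SEs, um)
#' @return data.frame: pair, fraction, mean_um, se_um.
#' @export
distance_presets <- function() .stp_extdata("distance_presets.csv")

#' Default generator configuration built from the bundled preset tables
#'
#' Returns the full synthetic-population configuration whose positional,
#' epimark and chromatin-class targets equal the bundled printed means.
#' Per-signal positional dispersions are not printed anywhere, so the defaults
#' `sd_axial = 0.12` and `sd_h = 0.05` are documented package choices (they
#' give SEs of the mean near the printed 0.006-0.008 at n = 1000).
#'
#' @param n_cases number of donors (default 5).
#' @param cells_per_case cells generated per case and fraction (default 200).
#' @param seed integer seed stored in the config; `generate_population()`
#'   uses it unless overridden.
#' @return a `stp_config` list; see the package vignette for field meanings.
#' @export
preset_from_tables <- function(n_cases = 5L, cells_per_case = 200L, seed = 1L) {
  epi <- epimark_presets()
  structure(list(
    seed = as.integer(seed),
    n_cases = as.integer(n_cases),
    cells_per_case = as.integer(cells_per_case),
    fractions = c("raw", "SU", "DGC"),
    chromosomes = c("4", "7", "8", "9", "18", "X", "Y"),
    position_mode = "radial",          # "radial" or "zone"
    radial = radial_presets(),
    zone = zone_presets(),
    sd_axial = 0.12,
    sd_h = 0.05,
    t_range = c(0.02, 0.98),
    h_margin = 0.95,
    nucleus = list(L_mean = 6.0, L_sd = 0.3, shape_ratio = 1.7),
    d_mode = "axial",                  # measurement mode matching the presets
    cluster_k = list(raw = 3L, SU = 4L, DGC = 2L),
    cluster_method = "ward.D2",
    epimark = list(
      pos = data.frame(fraction = epi$fraction,
                       p_5mC = epi$pos_5mC_pct / 100,
                       p_5hmC = epi$pos_5hmC_pct / 100),
      rho = 0.7, sigma_log = 0.5, amplitude = 500),
    chromatin = chromatin_presets(),
    render = list(pixel_size = 0.1,    # um / px
                  image_px = 420L,
                  cells_per_image = 9L,
                  spot_sigma_um = 0.15,
                  nuclear_amplitude = 3000,
                  spot_amplitude = 5000,
                  background = 200,
                  read_noise_sd = 20,
                  max_place_attempts = 200L)
  ), class = "stp_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys override the defaults of
#' [preset_from_tables()]. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return `stp_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stp_config_error("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- preset_from_tables()
  if (length(user)) {
    bad <- setdiff(names(user), c(names(cfg), "mode", "out"))
    if (length(bad))
      stp_config_error("unknown config field(s): %s", paste(bad, collapse = ", "))
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]))
        utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
    }
  }
  cfg
}
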