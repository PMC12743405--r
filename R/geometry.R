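## Nuclear coordinate model.
##
## A decondensed sperm head on a slide is treated as an ellipse with a
## longitudinal axis running from the basal tail-attachment point to the apex
## (length L, um) and a short axis at the widest part (length l, um). Each
## FISH signal is reduced to its centroid and expressed in two normalized
## systems: linear thirds along the axis (zones b/m/a) and radial (D/L, H/L)
## coordinates, where D is the distance to the basal point and H the unsigned
## perpendicular distance to the axis. Because a sperm lies flat in one of two
## mirror-image poses, H carries no usable sign and is always folded.

#' Construct nucleus geometry records
#'
#' Validates and bundles per-nucleus axis geometry. All coordinates in um.
#'
#' @param nucleus_id character vector of nucleus labels.
#' @param basal_x,basal_y coordinates of the basal (tail-attachment) end.
#' @param apex_x,apex_y coordinates of the apical end.
#' @param l short-axis length (um) at the widest part.
#' @param qc_band length-2 numeric, accepted L/l window (see [shape_qc()]).
#' @return data.frame with columns `nucleus_id`, `basal_x`, `basal_y`,
#'   `apex_x`, `apex_y`, `L`, `l`, `qc_pass`.
#' @export
nucleus_geometry <- function(nucleus_id, basal_x, basal_y, apex_x, apex_y, l,
                             qc_band = c(1.2, 2.2)) {
  L <- sqrt((apex_x - basal_x)^2 + (apex_y - basal_y)^2)
  if (any(!is.finite(L)) || any(L <= 0))
    stp_data_error("invalid geometry: degenerate longitudinal axis (L <= 0)")
  if (any(!is.finite(l)) || any(l <= 0))
    stp_data_error("invalid geometry: short axis l must be positive")
  if (any(L < l))
    stp_data_error("invalid geometry: L < l for nucleus %s",
                   paste(nucleus_id[L < l], collapse = ", "))
  data.frame(nucleus_id = as.character(nucleus_id),
             basal_x = basal_x, basal_y = basal_y,
             apex_x = apex_x, apex_y = apex_y,
             L = L, l = l,
             qc_pass = shape_qc(L, l, qc_band),
             stringsAsFactors = FALSE)
}

#' Axial fraction of a signal along the basal-apex axis
#'
#' Signed projection of (centroid - basal point) onto the unit basal-to-apex
#' vector, divided by the axis length L. 0 at the basal point, 1 at the apex.
#'
#' @param x,y signal centroid (um), vectorized.
#' @param basal_x,basal_y,apex_x,apex_y nucleus axis endpoints (um).
#' @return numeric vector of axial fractions (unclamped).
#' @export
axial_fraction <- function(x, y, basal_x, basal_y, apex_x, apex_y) {
  ux <- apex_x - basal_x
  uy <- apex_y - basal_y
  L2 <- ux^2 + uy^2
  if (any(!is.finite(L2)) || any(L2 <= 0))
    stp_data_error("invalid geometry: degenerate longitudinal axis (L = 0)")
  ((x - basal_x) * ux + (y - basal_y) * uy) / L2
}

#' Linear zone (b / m / a) from axial fraction
#'
#' The nucleus is divided into three equal territories along its longitudinal
#' axis: `b` near the basal (tail) region, `m` middle, `a` near the apex.
#' Boundaries are half-open thirds, apex-inclusive: t < 1/3 is `b`,
#' 1/3 <= t < 2/3 is `m`, t >= 2/3 is `a`. Axial fractions outside [0, 1] by
#' at most `eps` are clamped; beyond that the signal is an assignment error
#' and gets `NA`.
#'
#' @param t axial fractions (see [axial_fraction()]).
#' @param eps clamping tolerance outside the unit interval (default 0.02).
#' @return factor with levels `b`, `m`, `a`; `NA` for out-of-nucleus signals.
#' @export
linear_zone <- function(t, eps = 0.02) {
  bad <- !is.finite(t) | t < -eps | t > 1 + eps
  tc <- pmin(pmax(t, 0), 1)
  z <- ifelse(tc < 1 / 3, "b", ifelse(tc < 2 / 3, "m", "a"))
  z[bad] <- NA_character_
  factor(z, levels = c("b", "m", "a"))
}

#' Normalized radial position (D/L, H/L) of a signal
#'
#' H is the unsigned perpendicular distance from the centroid to the
#' basal-apex line (mirror-folded; sperm lie in one of two mirror poses).
#' D is either the Euclidean distance from the centroid to the basal point
#' (`d_mode = "euclidean"`, literal reading) or the axial projection
#' (`d_mode = "axial"`, which has maximum 1.0 inside the nucleus). Both are
#' normalized by L.
#'
#' @inheritParams axial_fraction
#' @param d_mode `"euclidean"` or `"axial"`.
#' @return data.frame with columns `d_over_l`, `h_over_l`, `axial_fraction`.
#' @export
radial_position <- function(x, y, basal_x, basal_y, apex_x, apex_y,
                            d_mode = c("euclidean", "axial")) {
  d_mode <- match.arg(d_mode)
  t <- axial_fraction(x, y, basal_x, basal_y, apex_x, apex_y)
  L <- sqrt((apex_x - basal_x)^2 + (apex_y - basal_y)^2)
  ## squared distance to basal minus squared axial component = H^2
  d2 <- (x - basal_x)^2 + (y - basal_y)^2
  h2 <- pmax(d2 - (t * L)^2, 0)
  h_over_l <- sqrt(h2) / L
  d_over_l <- if (d_mode == "euclidean") sqrt(d2) / L else t
  data.frame(d_over_l = d_over_l, h_over_l = h_over_l, axial_fraction = t)
}

#' Shape quality control on the L/l ratio
#'
#' Decondensed sperm heads keep a roughly constant elongation; nuclei whose
#' axis ratio L/l falls outside the accepted window are flagged as swollen,
#' collapsed or mis-segmented and excluded from topology measurement. The
#' default window \[1.2, 2.2\] is deliberately permissive.
#'
#' @param L,l axis lengths (um).
#' @param band length-2 numeric, inclusive accepted L/l interval.
#' @return logical vector, `TRUE` for nuclei passing QC.
#' @export
shape_qc <- function(L, l, band = c(1.2, 2.2)) {
  if (any(L <= 0) || any(l <= 0))
    stp_data_error("shape_qc: axis lengths must be positive")
  r <- L / l
  r >= band[1] & r <= band[2]
}

#' Distance between two centromere signals of the same nucleus
#'
#' @param x1,y1,x2,y2 centroids (um), vectorized.
#' @param nucleus_id1,nucleus_id2 optional nucleus labels; if supplied they
#'   must match pairwise.
#' @return numeric vector of Euclidean distances (um).
#' @export
intercentromere_distance <- function(x1, y1, x2, y2,
                                     nucleus_id1 = NULL, nucleus_id2 = NULL) {
  if (!is.null(nucleus_id1) && !is.null(nucleus_id2) &&
      any(as.character(nucleus_id1) != as.character(nucleus_id2)))
    stp_data_error("intercentromere_distance: signals from different nuclei")
  sqrt((x2 - x1)^2 + (y2 - y1)^2)
}

#' Annotate a signal table with zones and radial positions
#'
#' Takes a coordinate table in the package CSV schema (one row per FISH
#' signal, with its nucleus geometry) and appends `axial_fraction`, `zone`,
#' `d_over_l`, `h_over_l` and a `keep` flag. Signals whose axial fraction is
#' outside \[0, 1\] by more than `eps`, or whose nucleus fails shape QC, get
#' `keep = FALSE` with a `drop_reason`.
#'
#' @param signals data.frame with columns `x_um`, `y_um`, `basal_x_um`,
#'   `basal_y_um`, `apex_x_um`, `apex_y_um`, `L_um`, `l_um`.
#' @param d_mode see [radial_position()].
#' @param eps clamp tolerance for the axial fraction.
#' @param qc_band accepted L/l window.
#' @return the input with measurement columns appended.
#' @export
annotate_signals <- function(signals, d_mode = c("euclidean", "axial"),
                             eps = 0.02, qc_band = c(1.2, 2.2)) {
  d_mode <- match.arg(d_mode)
  need <- c("x_um", "y_um", "basal_x_um", "basal_y_um",
            "apex_x_um", "apex_y_um", "L_um", "l_um")
  miss <- setdiff(need, names(signals))
  if (length(miss))
    stp_data_error("signal table lacks columns: %s", paste(miss, collapse = ", "))
  rp <- radial_position(signals$x_um, signals$y_um,
                        signals$basal_x_um, signals$basal_y_um,
                        signals$apex_x_um, signals$apex_y_um, d_mode)
  t <- rp$axial_fraction
  out_of_nucleus <- t < -eps | t > 1 + eps
  qc <- shape_qc(signals$L_um, signals$l_um, qc_band)
  signals$axial_fraction <- pmin(pmax(t, 0), 1)
  signals$zone <- linear_zone(t, eps)
  signals$d_over_l <- rp$d_over_l
  signals$h_over_l <- rp$h_over_l
  signals$keep <- !out_of_nucleus & qc
  signals$drop_reason <- ifelse(out_of_nucleus, "spot_assignment",
                                ifelse(!qc, "shape_qc", NA_character_))
  signals
}
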