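## Image front-end. Stands in for manual microscope scoring: global Otsu
## threshold + connected components on the nuclear-stain channel, an
## intensity-moment ellipse fit per component (for a uniform ellipse the
## axis length is 4x the principal standard deviation), local-maxima FISH
## spot detection with sub-pixel centroids, and background-subtracted
## per-nucleus IF intensity.
##
## Images are numeric matrices (row = y, column = x); pixel centers sit at
## integer coordinates, 0-based in um terms: x_um = (col - 1) * pixel_size.
## There is no TIFF reader in this stack, so multi-channel scenes are plain
## lists of matrices with a channel-map sidecar (see read_scene/write_scene).

## 8-connected component labelling by BFS flood fill
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  queue <- integer(sum(mask))
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    qlen <- 1L
    while (qlen > 0L) {
      p <- queue[qlen]; qlen <- qlen - 1L
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- rr + (cc - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          qlen <- qlen + 1L
          queue[qlen] <- q
        }
      }
    }
  }
  lab
}

.nuclear_channel <- function(channels, channel_map) {
  role <- vapply(channel_map$roles, identity, "")
  hit <- names(role)[role == "nuclear"]
  if (length(hit) != 1L)
    stp_config_error("channel map must name exactly one 'nuclear' channel")
  channels[[hit]]
}

#' Segment elliptical nuclei from the nuclear-stain channel
#'
#' Otsu global threshold, 8-connected components, area-band and solidity
#' filters, border exclusion, and an intensity-moment ellipse fit giving the
#' center, orientation and axis lengths (`L`, `l`) of each nucleus.
#'
#' @param channels named list of image matrices.
#' @param channel_map list with `pixel_size` (um/px) and `roles` (named list
#'   channel -> role; one role must be `"nuclear"`).
#' @param params optional overrides: `area_band_um2` (default `c(15, 80)`),
#'   `min_solidity` (0.9), `exclude_border` (`TRUE`).
#' @return list with `nuclei` (data.frame: label, cx_um, cy_um, L_um, l_um,
#'   theta, area_um2, solidity, touches_border) and `labels` (the full label
#'   matrix, for spot assignment and IF measurement), plus filter counts in
#'   attribute `counts`.
#' @export
segment_nuclei <- function(channels, channel_map, params = list()) {
  img <- .nuclear_channel(channels, channel_map)
  ps <- channel_map$pixel_size
  area_band <- params$area_band_um2 %||% c(15, 80)
  min_solidity <- params$min_solidity %||% 0.9
  exclude_border <- params$exclude_border %||% TRUE
  if (diff(range(img)) == 0)
    return(list(nuclei = .empty_nuclei(), labels = matrix(0L, nrow(img), ncol(img))))
  thr <- otsu_threshold(as.numeric(img))
  mask <- img > thr
  if (!any(mask))
    return(list(nuclei = .empty_nuclei(), labels = matrix(0L, nrow(img), ncol(img))))
  lab <- .label_components(mask)
  bg_med <- stats::median(img[lab == 0L])
  nr <- nrow(img); nc <- ncol(img)
  rows <- list(); counts <- c(total = max(lab), border = 0L, filtered = 0L)
  for (id in seq_len(max(lab))) {
    px <- which(lab == id)
    r <- (px - 1L) %% nr + 1L
    cl <- (px - 1L) %/% nr + 1L
    area_um2 <- length(px) * ps^2
    touches <- any(r == 1L | r == nr | cl == 1L | cl == nc)
    hull <- grDevices::chull(cl, r)
    solidity <- if (length(hull) >= 3L)
      length(px) / max(.shoelace(cbind(cl, r)[hull, , drop = FALSE]), 1) else 0
    ok_shape <- area_um2 >= area_band[1] && area_um2 <= area_band[2] &&
      solidity >= min_solidity
    if (!ok_shape) { counts["filtered"] <- counts["filtered"] + 1L; lab[px] <- 0L; next }
    if (touches && exclude_border) {
      counts["border"] <- counts["border"] + 1L; lab[px] <- 0L; next
    }
    w <- pmax(img[px] - bg_med, 0)
    w <- w / sum(w)
    mx <- sum(w * cl); my <- sum(w * r)
    cxx <- sum(w * (cl - mx)^2); cyy <- sum(w * (r - my)^2)
    cxy <- sum(w * (cl - mx) * (r - my))
    e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
    Lf <- 4 * sqrt(e$values[1]) * ps
    lf <- 4 * sqrt(e$values[2]) * ps
    theta <- atan2(e$vectors[2, 1], e$vectors[1, 1])
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, cx_um = (mx - 1) * ps, cy_um = (my - 1) * ps,
      L_um = Lf, l_um = lf, theta = theta, area_um2 = area_um2,
      solidity = solidity, touches_border = touches)
  }
  nuclei <- if (length(rows)) do.call(rbind, rows) else .empty_nuclei()
  structure(list(nuclei = nuclei, labels = lab), counts = counts)
}

.empty_nuclei <- function() {
  data.frame(label = integer(), cx_um = numeric(), cy_um = numeric(),
             L_um = numeric(), l_um = numeric(), theta = numeric(),
             area_um2 = numeric(), solidity = numeric(),
             touches_border = logical())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve the basal end of a fitted nucleus
#'
#' The moment fit gives an axis with two indistinguishable ends; a basal-end
#' annotation (here: the simulator's ground-truth sidecar; on real data the
#' visible tail) selects the endpoint nearer the hint. Without a hint the
#' nucleus is flagged axis-ambiguous.
#'
#' @param nucleus one row of `segment_nuclei()$nuclei`.
#' @param hint length-2 numeric (x_um, y_um) of the annotated basal end, or
#'   `NULL`.
#' @return data.frame row: basal/apex coordinates, `L_um`, `l_um`,
#'   `axis_ambiguous`.
#' @export
assign_basal_end <- function(nucleus, hint = NULL) {
  ex <- nucleus$L_um / 2 * cos(nucleus$theta)
  ey <- nucleus$L_um / 2 * sin(nucleus$theta)
  p1 <- c(nucleus$cx_um - ex, nucleus$cy_um - ey)
  p2 <- c(nucleus$cx_um + ex, nucleus$cy_um + ey)
  if (is.null(hint)) {
    return(data.frame(basal_x_um = p1[1], basal_y_um = p1[2],
                      apex_x_um = p2[1], apex_y_um = p2[2],
                      L_um = nucleus$L_um, l_um = nucleus$l_um,
                      axis_ambiguous = TRUE))
  }
  d1 <- sum((hint - p1)^2); d2 <- sum((hint - p2)^2)
  if (isTRUE(all.equal(d1, d2)))
    stp_data_error("assign_basal_end: hint equidistant from both axis ends")
  basal <- if (d1 < d2) p1 else p2
  apex <- if (d1 < d2) p2 else p1
  data.frame(basal_x_um = basal[1], basal_y_um = basal[2],
             apex_x_um = apex[1], apex_y_um = apex[2],
             L_um = nucleus$L_um, l_um = nucleus$l_um,
             axis_ambiguous = FALSE)
}

#' Detect FISH spots in one channel
#'
#' Local maxima above `background median + k * MAD`, with minimum separation
#' (greedy suppression by intensity) and sub-pixel localization by
#' intensity-weighted centroid over a 5x5 window. Each spot is assigned to
#' the nucleus whose mask contains its centroid; spots outside all masks are
#' discarded.
#'
#' @param channel image matrix.
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param pixel_size um per pixel.
#' @param params overrides: `k_mad` (5), `min_sep_px` (3).
#' @return data.frame: x_um, y_um, peak, label (nucleus), one row per spot.
#' @export
detect_spots <- function(channel, labels, pixel_size, params = list()) {
  k <- params$k_mad %||% 5
  min_sep <- params$min_sep_px %||% 3
  bg <- channel[labels == 0L]
  thr <- stats::median(bg) + k * stats::mad(bg)
  nr <- nrow(channel); nc <- ncol(channel)
  ## strict local maxima over the 8-neighborhood, away from the 2px border
  core <- channel[3:(nr - 2), 3:(nc - 2)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core >= channel[3:(nr - 2) + dr, 3:(nc - 2) + dc]
  }
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(x_um = numeric(), y_um = numeric(),
                                      peak = numeric(), label = integer()))
  r <- (idx - 1L) %% nrow(core) + 3L
  cl <- (idx - 1L) %/% nrow(core) + 3L
  v <- core[idx]
  o <- order(-v)
  r <- r[o]; cl <- cl[o]; v <- v[o]
  keep <- rep(TRUE, length(r))
  for (i in seq_along(r)) {
    if (!keep[i]) next
    if (i < length(r)) {
      later <- (i + 1L):length(r)
      clash <- abs(r[later] - r[i]) < min_sep & abs(cl[later] - cl[i]) < min_sep
      keep[later[clash]] <- FALSE
    }
  }
  r <- r[keep]; cl <- cl[keep]; v <- v[keep]
  bg_med <- stats::median(bg)
  out <- lapply(seq_along(r), function(i) {
    rw <- (r[i] - 2L):(r[i] + 2L)
    cw <- (cl[i] - 2L):(cl[i] + 2L)
    wv <- pmax(channel[rw, cw] - bg_med, 0)
    if (sum(wv) == 0) return(NULL)
    rc <- sum(row(wv) * wv) / sum(wv) + r[i] - 3L
    cc <- sum(col(wv) * wv) / sum(wv) + cl[i] - 3L
    lb <- labels[round(rc), round(cc)]
    if (lb == 0L) return(NULL)
    data.frame(x_um = (cc - 1) * pixel_size, y_um = (rc - 1) * pixel_size,
               peak = v[i], label = lb)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(data.frame(x_um = numeric(), y_um = numeric(),
                                      peak = numeric(), label = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background-subtracted mean IF intensity of one nucleus
#'
#' Mean within-mask intensity minus the median of all out-of-mask pixels.
#'
#' @param channel image matrix.
#' @param labels nucleus label matrix.
#' @param label nucleus label id.
#' @return numeric scalar.
#' @export
measure_if_intensity <- function(channel, labels, label) {
  inside <- labels == label
  if (!any(inside)) stp_data_error("measure_if_intensity: empty mask")
  mean(channel[inside]) - stats::median(channel[labels == 0L])
}

#' Measure a rendered scene end to end
#'
#' Segments nuclei, resolves basal ends from the scene's annotation sidecar,
#' detects spots in every FISH channel, measures IF intensities, and returns
#' tables in the coordinate schema so downstream analysis is identical for
#' image mode and coordinate mode. Segmented nuclei are matched to the truth
#' sidecar by nearest center (within half a nucleus length).
#'
#' @param scene a scene from [render_images()].
#' @param params optional segmentation/detection overrides.
#' @return list with `signals` (coordinate-schema table), `cells` (per-cell
#'   measured IF intensities and geometry), `nuclei` (raw fit table).
#' @export
measure_scene <- function(scene, params = list()) {
  seg <- segment_nuclei(scene$channels, scene$channel_map, params)
  nuc <- seg$nuclei
  truth <- scene$truth_cells
  ps <- scene$channel_map$pixel_size
  if (nrow(nuc) == 0L)
    return(list(signals = NULL, cells = NULL, nuclei = nuc))
  ## match each fitted nucleus to a truth cell by center distance
  tcx <- (truth$basal_x_um + truth$apex_x_um) / 2
  tcy <- (truth$basal_y_um + truth$apex_y_um) / 2
  geo <- vector("list", nrow(nuc))
  match_id <- character(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    d2 <- (tcx - nuc$cx_um[i])^2 + (tcy - nuc$cy_um[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > nuc$L_um[i] / 2) { match_id[i] <- NA; next }
    match_id[i] <- truth$nucleus_id[j]
    geo[[i]] <- assign_basal_end(nuc[i, ],
                                 hint = c(truth$basal_x_um[j], truth$basal_y_um[j]))
  }
  ok <- !is.na(match_id)
  roles <- vapply(scene$channel_map$roles, identity, "")
  if_ch <- names(roles)[startsWith(roles, "if:")]
  cells <- do.call(rbind, lapply(which(ok), function(i) {
    g <- geo[[i]]
    ii <- vapply(if_ch, function(ch)
      measure_if_intensity(scene$channels[[ch]], seg$labels, nuc$label[i]), 0)
    data.frame(nucleus_id = match_id[i], label = nuc$label[i], g,
               i_5mC = unname(ii[match("if:5mC", roles[if_ch])]),
               i_5hmC = unname(ii[match("if:5hmC", roles[if_ch])]),
               stringsAsFactors = FALSE)
  }))
  fish_ch <- names(roles)[startsWith(roles, "fish:")]
  signals <- do.call(rbind, lapply(fish_ch, function(ch) {
    sp <- detect_spots(scene$channels[[ch]], seg$labels, ps, params)
    if (nrow(sp) == 0L) return(NULL)
    m <- match(sp$label, cells$label)
    sp <- sp[!is.na(m), ]; m <- m[!is.na(m)]
    if (!nrow(sp)) return(NULL)
    data.frame(nucleus_id = cells$nucleus_id[m],
               chromosome = sub("fish:", "", roles[[ch]]),
               x_um = sp$x_um, y_um = sp$y_um,
               basal_x_um = cells$basal_x_um[m], basal_y_um = cells$basal_y_um[m],
               apex_x_um = cells$apex_x_um[m], apex_y_um = cells$apex_y_um[m],
               L_um = cells$L_um[m], l_um = cells$l_um[m],
               stringsAsFactors = FALSE)
  }))
  list(signals = signals, cells = cells, nuclei = nuc)
}
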