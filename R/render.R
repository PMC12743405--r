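## Scene renderer: turns generated ground truth into multi-channel images.
## Channels: uniform ellipse fill for the nuclear stain, Gaussian FISH spots
## (sigma 0.15 um) at the true signal coordinates in one channel per
## chromosome, uniform per-cell IF fills at the cell's 5mC/5hmC intensity,
## then Poisson shot noise on signal + background plus Gaussian read noise,
## clamped to the 16-bit range.

.add_ellipse <- function(img, cx, cy, ux, uy, a, b, amplitude, ps) {
  nr <- nrow(img); nc <- ncol(img)
  rpx <- ceiling(a / ps) + 2L
  c0 <- round(cx / ps) + 1L; r0 <- round(cy / ps) + 1L
  cols <- max(1L, c0 - rpx):min(nc, c0 + rpx)
  rows <- max(1L, r0 - rpx):min(nr, r0 + rpx)
  xs <- (cols - 1) * ps - cx
  ys <- (rows - 1) * ps - cy
  X <- matrix(xs, length(rows), length(cols), byrow = TRUE)
  Y <- matrix(ys, length(rows), length(cols))
  e <- ((X * ux + Y * uy) / a)^2 + ((-X * uy + Y * ux) / b)^2
  img[rows, cols] <- img[rows, cols] + amplitude * (e <= 1)
  img
}

.add_spot <- function(img, x, y, sigma, amplitude, ps) {
  nr <- nrow(img); nc <- ncol(img)
  rpx <- ceiling(5 * sigma / ps)
  c0 <- round(x / ps) + 1L; r0 <- round(y / ps) + 1L
  cols <- max(1L, c0 - rpx):min(nc, c0 + rpx)
  rows <- max(1L, r0 - rpx):min(nr, r0 + rpx)
  dx <- (cols - 1) * ps - x
  dy <- (rows - 1) * ps - y
  g <- amplitude * outer(exp(-dy^2 / (2 * sigma^2)), exp(-dx^2 / (2 * sigma^2)))
  img[rows, cols] <- img[rows, cols] + g
  img
}

.apply_noise <- function(img, background, read_noise_sd) {
  lam <- img + background
  noisy <- stats::rpois(length(lam), lam) +
    stats::rnorm(length(lam), 0, read_noise_sd)
  matrix(pmin(pmax(round(noisy), 0), 65535), nrow(img), ncol(img))
}

#' Render a generated population into multi-channel scenes
#'
#' Cells are split into scenes of `config$render$cells_per_image`; nuclei are
#' placed by rejection sampling (uniform centers, pairwise separation of one
#' nucleus length plus margin, random orientation). Each scene carries its
#' ground-truth sidecars in the scene coordinate frame, including the
#' basal-end annotation required to orient fitted axes.
#'
#' @param population an `stp_population` from [generate_population()].
#' @param max_cells optionally render only the first `max_cells` cells.
#' @param seed RNG seed for placement and noise.
#' @param noise apply Poisson + Gaussian noise (default `TRUE`).
#' @return list of scenes; each has `channels`, `channel_map`, `truth_cells`,
#'   `truth_signals`.
#' @export
render_images <- function(population, max_cells = NULL, seed = 1L,
                          noise = TRUE) {
  set.seed(seed)
  cfg <- population$config
  rc <- cfg$render
  ps <- rc$pixel_size
  cells <- population$cells
  if (!is.null(max_cells)) cells <- cells[seq_len(min(max_cells, nrow(cells))), ]
  n_scene <- ceiling(nrow(cells) / rc$cells_per_image)
  fov_um <- (rc$image_px - 1) * ps
  scenes <- vector("list", n_scene)
  for (s in seq_len(n_scene)) {
    idx <- ((s - 1L) * rc$cells_per_image + 1L):min(s * rc$cells_per_image, nrow(cells))
    cc <- cells[idx, ]
    nsc <- nrow(cc)
    ## rejection-sample non-overlapping centers
    pad <- max(cc$L_um) / 2 + 1
    sep <- max(cc$L_um) + 1
    centers <- matrix(NA_real_, nsc, 2)
    for (i in seq_len(nsc)) {
      ok <- FALSE
      for (att in seq_len(rc$max_place_attempts)) {
        p <- stats::runif(2, pad, fov_um - pad)
        if (i == 1L || all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                         matrix(p, i - 1L, 2, byrow = TRUE))^2)) > sep)) {
          centers[i, ] <- p; ok <- TRUE; break
        }
      }
      if (!ok)
        stp_data_error("render_images: could not place %d nuclei in %d attempts; lower the density",
                       nsc, rc$max_place_attempts)
    }
    theta <- stats::runif(nsc, 0, 2 * pi)
    ux <- cos(theta); uy <- sin(theta)
    cc$basal_x_um <- centers[, 1] - cc$L_um / 2 * ux
    cc$basal_y_um <- centers[, 2] - cc$L_um / 2 * uy
    cc$apex_x_um <- centers[, 1] + cc$L_um / 2 * ux
    cc$apex_y_um <- centers[, 2] + cc$L_um / 2 * uy
    ## signal coordinates in the scene frame
    sg <- population$signals[population$signals$nucleus_id %in% cc$nucleus_id, ]
    m <- match(sg$nucleus_id, cc$nucleus_id)
    sg$x_um <- cc$basal_x_um[m] + sg$true_t * cc$L_um[m] * ux[m] +
      sg$true_h_signed * cc$L_um[m] * (-uy[m])
    sg$y_um <- cc$basal_y_um[m] + sg$true_t * cc$L_um[m] * uy[m] +
      sg$true_h_signed * cc$L_um[m] * (ux[m])
    sg$basal_x_um <- cc$basal_x_um[m]; sg$basal_y_um <- cc$basal_y_um[m]
    sg$apex_x_um <- cc$apex_x_um[m];   sg$apex_y_um <- cc$apex_y_um[m]

    blank <- function() matrix(0, rc$image_px, rc$image_px)
    chroms_here <- unique(sg$chromosome)
    channels <- c(list(ch1 = blank()),
                  stats::setNames(replicate(length(chroms_here), blank(),
                                            simplify = FALSE),
                                  paste0("fish_", chroms_here)),
                  list(if_5mC = blank(), if_5hmC = blank()))
    roles <- c(list(ch1 = "nuclear"),
               stats::setNames(as.list(paste0("fish:", chroms_here)),
                               paste0("fish_", chroms_here)),
               list(if_5mC = "if:5mC", if_5hmC = "if:5hmC"))
    for (i in seq_len(nsc)) {
      a <- cc$L_um[i] / 2; b <- cc$l_um[i] / 2
      channels$ch1 <- .add_ellipse(channels$ch1, centers[i, 1], centers[i, 2],
                                   ux[i], uy[i], a, b, rc$nuclear_amplitude, ps)
      channels$if_5mC <- .add_ellipse(channels$if_5mC, centers[i, 1], centers[i, 2],
                                      ux[i], uy[i], a, b, cc$i_5mC[i], ps)
      channels$if_5hmC <- .add_ellipse(channels$if_5hmC, centers[i, 1], centers[i, 2],
                                       ux[i], uy[i], a, b, cc$i_5hmC[i], ps)
    }
    for (j in seq_len(nrow(sg))) {
      ch <- paste0("fish_", sg$chromosome[j])
      channels[[ch]] <- .add_spot(channels[[ch]], sg$x_um[j], sg$y_um[j],
                                  rc$spot_sigma_um, rc$spot_amplitude, ps)
    }
    if (noise)
      channels <- lapply(channels, .apply_noise, background = rc$background,
                         read_noise_sd = rc$read_noise_sd)
    scenes[[s]] <- list(channels = channels,
                        channel_map = list(pixel_size = ps, roles = roles),
                        truth_cells = cc, truth_signals = sg)
  }
  scenes
}
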