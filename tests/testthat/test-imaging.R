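# Build a bare test image: ellipse indicator + optional Gaussian spots.
draw_ellipse_img <- function(nr, nc, cx, cy, a, b, theta = 0, amp = 1000) {
  img <- matrix(0, nr, nc)
  X <- matrix(rep(seq_len(nc) - 1, each = nr), nr) - cx
  Y <- matrix(rep(seq_len(nr) - 1, nc), nr) - cy
  u <- c(cos(theta), sin(theta))
  e <- ((X * u[1] + Y * u[2]) / a)^2 + ((-X * u[2] + Y * u[1]) / b)^2
  img + amp * (e <= 1)
}

cm1 <- list(pixel_size = 0.1, roles = list(ch1 = "nuclear"))

test_that("segment_nuclei on blank and rendered scenes", {
  blank <- matrix(5, 120, 120)
  expect_equal(nrow(segment_nuclei(list(ch1 = blank), cm1)$nuclei), 0L)
  # three disjoint ellipses with L = 6 um, l = 3.5 um at 0.1 um/px
  img <- draw_ellipse_img(300, 300, 60, 60, 30, 17.5, theta = 0.4) +
    draw_ellipse_img(300, 300, 200, 80, 30, 17.5, theta = 2.0) +
    draw_ellipse_img(300, 300, 120, 220, 30, 17.5, theta = 5.1)
  seg <- segment_nuclei(list(ch1 = img), cm1)
  expect_equal(nrow(seg$nuclei), 3L)
  expect_true(all(abs(seg$nuclei$L_um - 6.0) / 6.0 < 0.05))
  expect_true(all(abs(seg$nuclei$l_um - 3.5) / 3.5 < 0.05))
  expect_true(all(seg$nuclei$solidity >= 0.9))
})

test_that("nuclei clipped by the image border are excluded by default", {
  img <- draw_ellipse_img(200, 200, 25, 100, 30, 17.5)   # clipped at x = 0
  seg <- segment_nuclei(list(ch1 = img), cm1)
  expect_equal(nrow(seg$nuclei), 0L)
  keep <- segment_nuclei(list(ch1 = img), cm1, params = list(exclude_border = FALSE,
                                                             min_solidity = 0))
  expect_equal(nrow(keep$nuclei), 1L)
  expect_true(keep$nuclei$touches_border)
})

test_that("segment_nuclei requires exactly one nuclear channel", {
  img <- matrix(0, 50, 50)
  expect_error(segment_nuclei(list(a = img), list(pixel_size = 0.1,
                                                  roles = list(a = "fish:4"))),
               class = "stp_config_error")
})

test_that("assign_basal_end follows the annotation hint", {
  nuc <- data.frame(label = 1L, cx_um = 5, cy_um = 5, L_um = 6, l_um = 3.5,
                    theta = 0)
  g <- assign_basal_end(nuc, hint = c(2.1, 5))
  expect_equal(c(g$basal_x_um, g$basal_y_um), c(2, 5))
  expect_equal(c(g$apex_x_um, g$apex_y_um), c(8, 5))
  expect_false(g$axis_ambiguous)
  expect_true(assign_basal_end(nuc, hint = NULL)$axis_ambiguous)
  expect_error(assign_basal_end(nuc, hint = c(5, 5)), class = "stp_data_error")
})

test_that("detect_spots localizes Gaussian spots to sub-pixel accuracy", {
  set.seed(51)
  img <- draw_ellipse_img(200, 200, 100, 100, 40, 25, amp = 0)
  labels <- matrix(1L, 200, 200)
  labels[1:50, ] <- 0L   # background region for the MAD estimate
  noise <- matrix(rnorm(200 * 200, 100, 5), 200)
  expect_equal(nrow(detect_spots(noise, labels, 0.1)), 0L)
  # one spot, sigma 0.15 um = 1.5 px, truth at (101.3, 99.6) px 0-based
  xs <- matrix(rep(0:199, each = 200), 200)
  ys <- matrix(rep(0:199, 200), 200)
  spot <- 2000 * exp(-((xs - 101.3)^2 + (ys - 99.6)^2) / (2 * 1.5^2))
  sp <- detect_spots(noise + spot, labels, 0.1)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_um / 0.1 - 101.3), 0.5)
  expect_lt(abs(sp$y_um / 0.1 - 99.6), 0.5)
  # two spots >= 3 sigma apart resolve separately
  spot2 <- spot + 2000 * exp(-((xs - 110)^2 + (ys - 99.6)^2) / (2 * 1.5^2))
  expect_equal(nrow(detect_spots(noise + spot2, labels, 0.1)), 2L)
})

test_that("measure_if_intensity subtracts background and preserves ratios", {
  set.seed(52)
  base <- matrix(rnorm(300 * 300, 200, 10), 300)
  nucA <- draw_ellipse_img(300, 300, 70, 70, 30, 17.5, amp = 1000)
  nucB <- draw_ellipse_img(300, 300, 200, 200, 30, 17.5, amp = 2000)
  labels <- matrix(0L, 300, 300)
  labels[nucA > 0] <- 1L; labels[nucB > 0] <- 2L
  flat <- measure_if_intensity(base, labels, 1L)
  expect_lt(abs(flat), 5)                              # ~0 after subtraction
  a <- measure_if_intensity(base + nucA + nucB, labels, 1L)
  b <- measure_if_intensity(base + nucA + nucB, labels, 2L)
  expect_lt(abs(a - 1000) / 1000, 0.05)
  expect_lt(abs(b / a - 2), 0.1)
  expect_error(measure_if_intensity(base, labels, 9L), class = "stp_data_error")
})

test_that("rendered scenes round-trip the imaging pipeline", {
  scenes <- tiny_scene(cells_per_case = 6, seed = 53)
  ms <- measure_scene(scenes[[1]])
  truth <- scenes[[1]]$truth_cells
  expect_gte(nrow(ms$cells), 4L)     # border exclusions allowed
  m <- match(ms$cells$nucleus_id, truth$nucleus_id)
  expect_true(all(!is.na(m)))
  expect_true(all(abs(ms$cells$L_um - truth$L_um[m]) / truth$L_um[m] < 0.05))
  expect_true(all(abs(ms$cells$i_5mC - truth$i_5mC[m]) /
                    pmax(truth$i_5mC[m], 1) < 0.15))
  # every detected spot belongs to a matched nucleus
  expect_true(all(ms$signals$nucleus_id %in% ms$cells$nucleus_id))
})

test_that("scene serialization round-trips as plain text", {
  scenes <- tiny_scene(cells_per_case = 3, seed = 54)
  dir <- file.path(tempdir(), "scene_io")
  write_scene(scenes[[1]], dir, "s1")
  back <- read_scene(dir, "s1")
  expect_equal(back$channels, scenes[[1]]$channels)
  expect_equal(back$channel_map$roles, scenes[[1]]$channel_map$roles)
  expect_equal(back$truth_signals$x_um, scenes[[1]]$truth_signals$x_um)
  expect_error(read_scene(dir, "nope"), class = "stp_config_error")
})
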