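test_that("axial_fraction matches hand-computed projections", {
  expect_equal(axial_fraction(5, 1, 0, 0, 10, 0), 0.5)
  expect_equal(axial_fraction(0, 0, 0, 0, 10, 0), 0)
  # hand dot product: ((7.5-0)*10 + (-1.2-0)*0) / 10^2 = 0.75
  expect_equal(axial_fraction(7.5, -1.2, 0, 0, 10, 0), 0.75)
  # rotated axis, same relative position
  expect_equal(axial_fraction(1, 7.5, 1, 0, 1, 10), 0.75)
  expect_error(axial_fraction(1, 1, 0, 0, 0, 0), class = "stp_data_error")
})

test_that("linear_zone applies half-open thirds with clamping", {
  expect_equal(as.character(linear_zone(c(0.10, 0.50, 0.90))), c("b", "m", "a"))
  expect_equal(as.character(linear_zone(1 / 3)), "m")
  expect_equal(as.character(linear_zone(2 / 3)), "a")
  expect_equal(as.character(linear_zone(c(-0.01, 1.015))), c("b", "a")) # clamped
  expect_true(all(is.na(linear_zone(c(-0.05, 1.2)))))                   # flagged
})

test_that("radial_position matches hand computation in both D modes", {
  rp <- radial_position(0, 0, 0, 0, 10, 0)
  expect_equal(unlist(rp[c("d_over_l", "h_over_l")], use.names = FALSE), c(0, 0))
  rp <- radial_position(10, 0, 0, 0, 10, 0)
  expect_equal(unlist(rp[c("d_over_l", "h_over_l")], use.names = FALSE), c(1, 0))
  rp <- radial_position(6, 1.5, 0, 0, 10, 0, d_mode = "euclidean")
  expect_equal(rp$d_over_l, sqrt(36 + 2.25) / 10, tolerance = 1e-12)
  expect_equal(rp$h_over_l, 0.15)
  rp <- radial_position(6, 1.5, 0, 0, 10, 0, d_mode = "axial")
  expect_equal(rp$d_over_l, 0.6)
})

test_that("shape_qc gates on the L/l ratio band", {
  expect_true(shape_qc(6.0, 3.5, c(1.2, 2.2)))    # ratio 1.714
  expect_false(shape_qc(5, 5))                    # circle, ratio 1
  expect_false(shape_qc(10, 2))                   # ratio 5
  expect_error(shape_qc(-1, 2), class = "stp_data_error")
})

test_that("intercentromere_distance is Euclidean and guards nucleus identity", {
  expect_equal(intercentromere_distance(0, 0, 3, 4), 5)
  expect_equal(intercentromere_distance(1, 1, 1, 1), 0)
  expect_error(intercentromere_distance(0, 0, 1, 1, "n1", "n2"),
               class = "stp_data_error")
})

test_that("radial coordinates are invariant under rigid motion and mirror", {
  set.seed(11)
  for (rep in 1:25) {
    basal <- runif(2, -5, 5); apex <- basal + runif(2, 2, 8)
    sig <- basal + runif(2, -1, 6)
    ref <- radial_position(sig[1], sig[2], basal[1], basal[2], apex[1], apex[2])
    # rotation + translation
    th <- runif(1, 0, 2 * pi); shift <- runif(2, -10, 10)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tb <- rot %*% basal + shift; ta <- rot %*% apex + shift; ts <- rot %*% sig + shift
    got <- radial_position(ts[1], ts[2], tb[1], tb[2], ta[1], ta[2])
    expect_equal(got$d_over_l, ref$d_over_l, tolerance = 1e-9)
    expect_equal(got$h_over_l, ref$h_over_l, tolerance = 1e-9)
    # reflection across the longitudinal axis folds onto the same H
    u <- (apex - basal) / sqrt(sum((apex - basal)^2))
    d <- sig - basal
    mir <- basal + 2 * u * sum(d * u) - d   # reflect across the axis
    gm <- radial_position(mir[1], mir[2], basal[1], basal[2], apex[1], apex[2])
    expect_equal(gm$h_over_l, ref$h_over_l, tolerance = 1e-9)
    expect_equal(gm$d_over_l, ref$d_over_l, tolerance = 1e-9)
  }
})

test_that("euclidean D dominates axial D and equals it on the axis", {
  set.seed(12)
  t <- runif(50); h <- runif(50, 0, 0.3)
  eu <- radial_position(t * 10, h * 10, 0, 0, 10, 0, "euclidean")
  ax <- radial_position(t * 10, h * 10, 0, 0, 10, 0, "axial")
  expect_true(all(eu$d_over_l >= ax$d_over_l - 1e-12))
  on_axis <- radial_position(4, 0, 0, 0, 10, 0)
  expect_equal(on_axis$d_over_l, 0.4)
})

test_that("in-ellipse signals satisfy the H/L bound l/(2L)", {
  set.seed(13)
  L <- 6; l <- 3.5
  t <- runif(400); hmax <- (l / 2) * sqrt(1 - (2 * t - 1)^2)
  h <- runif(400, -1, 1) * hmax
  rp <- radial_position(t * L, h, 0, 0, L, 0)
  expect_true(all(rp$h_over_l <= l / (2 * L) + 1e-6))
  # with the default shape ratio the bound is ~0.294, consistent with the
  # conventional H/L maximum of about 0.3
  expect_lt(l / (2 * L), 0.3)
})

test_that("zone counts equal the brute-force histogram of axial fractions", {
  set.seed(14)
  t <- runif(1000, -0.01, 1.01)
  z <- table(linear_zone(t))
  o <- oracle_zone_freq(t) * length(t)
  expect_equal(as.numeric(z[c("b", "m", "a")]), as.numeric(o))
})

test_that("annotate_signals flags bad geometry and out-of-nucleus spots", {
  sig <- data.frame(nucleus_id = c("a", "a", "b"), case = "K1", fraction = "raw",
                    chromosome = "4",
                    x_um = c(3, 12, 3), y_um = c(0.5, 0, 0.2),
                    basal_x_um = 0, basal_y_um = 0,
                    apex_x_um = c(10, 10, 10), apex_y_um = 0,
                    L_um = 10, l_um = c(6, 6, 1))
  ann <- annotate_signals(sig)
  expect_equal(ann$keep, c(TRUE, FALSE, FALSE))
  expect_equal(ann$drop_reason, c(NA, "spot_assignment", "shape_qc"))
})
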