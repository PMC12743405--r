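test_that("preset_from_tables exposes the bundled printed targets", {
  cfg <- preset_from_tables()
  r <- cfg$radial
  expect_equal(r$mean[r$chromosome == "X" & r$fraction == "raw" &
                        r$epistate == "all" & r$axis == "d"], 0.598)
  expect_equal(cfg$epimark$pos$p_5mC[cfg$epimark$pos$fraction == "raw"], 0.5782)
  ch <- cfg$chromatin
  expect_equal(ch$ab_pink_pct[ch$fraction == "raw"] / 100, 0.7547)
  z <- cfg$zone
  expect_equal(z$pct[z$chromosome == "X" & z$fraction == "raw" &
                       z$epistate == "all" & z$zone == "a"], 27.10)
})

test_that("the seed fully determines generated output", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 30)
  a <- generate_population(cfg, seed = 61)
  b <- generate_population(cfg, seed = 61)
  expect_identical(a$cells, b$cells)
  expect_identical(a$signals, b$signals)
  c_ <- generate_population(cfg, seed = 62)
  expect_false(identical(a$signals$x_um, c_$signals$x_um))
})

test_that("no generated signal violates the mirror-fold h bound", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 400)
  pop <- generate_population(cfg, seed = 63)
  bound <- 1 / (2 * cfg$nucleus$shape_ratio)   # l/(2L), ~0.294
  expect_true(all(abs(pop$signals$true_h_signed) <= bound + 1e-9))
  expect_true(all(pop$signals$true_t >= cfg$t_range[1] &
                    pop$signals$true_t <= cfg$t_range[2]))
  # placement respects the ellipse: recomputed fold-back never exceeds the
  # local half-width
  w <- (pop$signals$l_um / 2) *
    sqrt(pmax(1 - (2 * pop$signals$true_t - 1)^2, 0))
  expect_true(all(abs(pop$signals$true_h_signed) * pop$signals$L_um <= w + 1e-9))
})

test_that("radial-mode groups recover their analytic expectations", {
  cfg <- preset_from_tables(n_cases = 2, cells_per_case = 500)
  cfg$fractions <- "raw"
  pop <- generate_population(cfg, seed = 64)
  ann <- annotate_signals(pop$signals, d_mode = "axial")
  ann$stratum <- ann$true_stratum
  topo <- suppressWarnings(summarize_topology(ann, min_n = 1))
  for (i in seq_len(nrow(topo))) {
    exp_dh <- expected_radial_mean(cfg, topo$chromosome[i], topo$fraction[i],
                                   topo$epistate[i])
    n <- topo$n_signals[i]
    expect_lt(abs(topo$mean_d[i] - exp_dh[["d"]]),
              3 * cfg$sd_axial / sqrt(n) + 1e-9)
    expect_lt(abs(topo$mean_h[i] - exp_dh[["h"]]), 3 * cfg$sd_h / sqrt(n) + 1e-9)
  }
})

test_that("zone-preset mode states zone frequencies directly", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 400)
  cfg$fractions <- "raw"
  cfg$position_mode <- "zone"
  cfg$zone$pct <- 100 / 3    # uniform thirds for every key
  pop <- generate_population(cfg, seed = 65)
  ann <- annotate_signals(pop$signals, d_mode = "axial")
  for (ch in c("4", "X")) {
    g <- ann[ann$chromosome == ch, ]
    fr <- table(g$zone) / nrow(g)
    tol <- 3 * sqrt((1 / 3) * (2 / 3) / nrow(g))
    expect_true(all(abs(fr - 1 / 3) < tol))
  }
  # implied_zone_probs reports the stated multinomial in zone mode
  expect_equal(unname(implied_zone_probs(cfg, "4", "raw", "all")),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("population pair distances match the Monte-Carlo oracle within 1%", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 8000)
  cfg$fractions <- "raw"
  pop <- generate_population(cfg, seed = 66)
  d <- pair_signals(pop$signals, pairs = list(c("4", "8")))
  oracle <- expected_pair_distance(cfg, c("4", "8"), "raw", n_mc = 50000L,
                                   seed = 67)
  expect_lt(abs(mean(d$distance_um) - oracle) / oracle, 0.01)
})

test_that("distance calibration hits a stated target mean", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 500)
  cfg$fractions <- "raw"
  cal <- calibrate_pair_distance(cfg, c("4", "8"), "raw", target_um = 1.888,
                                 n_mc = 20000L, seed = 68)
  pop <- generate_population(cal, seed = 69)
  d <- pair_signals(pop$signals, pairs = list(c("4", "8")))$distance_um
  expect_gte(length(d), 500L)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1.888), 3 * se)
})

test_that("infeasible presets are rejected", {
  cfg <- preset_from_tables(n_cases = 1, cells_per_case = 5)
  cfg$radial$mean[cfg$radial$axis == "d" & cfg$radial$chromosome == "4"] <- 1.2
  expect_error(generate_population(cfg, seed = 70), class = "stp_config_error")
})
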