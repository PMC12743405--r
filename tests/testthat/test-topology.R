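make_group <- function(d, h, case = "K1") {
  data.frame(case = case, fraction = "raw", chromosome = "4", bearing = "X",
             stratum = "mixed", zone = linear_zone(pmin(pmax(d, 0), 1)),
             d_over_l = d, h_over_l = h)
}

# groups built with stratum "mixed" leave hyper/hypo empty; those warnings are
# by design
sumtopo <- function(...) suppressWarnings(summarize_topology(...))

test_that("summarize_topology pools radial stats and per-case zone freqs", {
  g <- make_group(c(0.4, 0.6), c(0.1, 0.1))
  res <- sumtopo(g, min_n = 1)
  row <- res[res$epistate == "all", ]
  expect_equal(row$mean_d, 0.5)
  expect_equal(row$se_d, sd(c(0.4, 0.6)) / sqrt(2))   # = 0.1
  expect_equal(row$se_d, 0.1)
  expect_equal(row$se_h, 0)                            # identical H values
  # zone frequencies against the brute-force histogram oracle
  set.seed(41)
  t <- runif(500)
  g2 <- make_group(t, rep(0.1, 500))
  r2 <- sumtopo(g2, min_n = 1)
  r2 <- r2[r2$epistate == "all", ]
  o <- oracle_zone_freq(t) * 100
  expect_equal(c(r2$b_pct, r2$m_pct, r2$a_pct), unname(o[c("b", "m", "a")]))
  expect_warning(summarize_topology(make_group(0.5, 0.1)[0, ], min_n = 1))
})

test_that("summarize_topology splits chromosome 18 by bearing", {
  sig <- data.frame(case = "K1", fraction = "raw", chromosome = "18",
                    bearing = rep(c("X", "Y"), each = 10), stratum = "mixed",
                    zone = factor("m", levels = c("b", "m", "a")),
                    d_over_l = rep(c(0.4, 0.6), each = 10),
                    h_over_l = 0.1)
  res <- sumtopo(sig, min_n = 1)
  res <- res[res$epistate == "all", ]
  expect_setequal(res$chromosome, c("18", "18-X", "18-Y"))
  expect_equal(res$mean_d[res$chromosome == "18-X"], 0.4)
  expect_equal(res$mean_d[res$chromosome == "18-Y"], 0.6)
  expect_equal(res$mean_d[res$chromosome == "18"], 0.5)
})

test_that("call_repositioning detects constructed shifts with direction", {
  set.seed(42)
  a <- make_group(rnorm(200, 0.5, 0.1), abs(rnorm(200, 0.12, 0.04)))
  none <- call_repositioning(list(raw = a, SU = a))
  expect_equal(none$direction, "none")
  b <- a; b$d_over_l <- b$d_over_l + 0.2
  up <- call_repositioning(list(raw = a, SU = b))
  expect_equal(up$direction, "basal-apical")
  expect_lt(up$p_d, 0.05)
  c_ <- a; c_$h_over_l <- c_$h_over_l * 1.5
  out <- call_repositioning(list(raw = a, SU = c_))
  expect_equal(out$direction, "center-periphery")
  # reversed shift flips the direction label
  dn <- call_repositioning(list(raw = b, SU = a))
  expect_equal(dn$direction, "apical-basal")
})

test_that("call_repositioning uses Dunn-adjusted pairs with three fractions", {
  set.seed(43)
  a <- make_group(rnorm(150, 0.45, 0.1), abs(rnorm(150, 0.12, 0.04)))
  b <- make_group(rnorm(150, 0.45, 0.1), abs(rnorm(150, 0.12, 0.04)))
  c_ <- make_group(rnorm(150, 0.75, 0.1), abs(rnorm(150, 0.12, 0.04)))
  res <- call_repositioning(list(raw = a, SU = b, DGC = c_), pair = c("raw", "DGC"))
  expect_equal(res$direction, "basal-apical")
  null_pair <- call_repositioning(list(raw = a, SU = b, DGC = c_),
                                  pair = c("raw", "SU"))
  expect_equal(null_pair$direction, "none")
})

test_that("chromocenter_cluster matches the naive Ward oracle", {
  set.seed(44)
  for (rep in 1:8) {
    m <- cbind(runif(7, 0.4, 0.65), runif(7, 0.1, 0.2))
    rownames(m) <- c("4", "7", "8", "9", "18", "X", "Y")
    oracle <- oracle_ward_partitions(m)
    for (k in c(2, 3, 4)) {
      got <- chromocenter_cluster(m, k = k)
      expect_equal(canon_partition(got$partition), canon_partition(oracle[[k]]),
                   info = sprintf("rep %d k %d", rep, k))
    }
  }
})

test_that("chromocenter_cluster respects trivial cuts, heights and Newick", {
  m <- cbind(c(0.4, 0.5, 0.6, 0.45), c(0.1, 0.15, 0.12, 0.11))
  rownames(m) <- c("4", "7", "8", "9")
  all_one <- chromocenter_cluster(m, k = 1)
  expect_length(all_one$partition, 1L)
  singletons <- chromocenter_cluster(m, k = 4)
  expect_length(singletons$partition, 4L)
  expect_true(all(diff(all_one$heights) >= -1e-12))   # Ward reducibility
  expect_match(all_one$newick, "^\\(.*\\);$")
  expect_error(chromocenter_cluster(m, k = 5), class = "stp_data_error")
  # coincident points merge at height zero
  m2 <- rbind(a = c(0.5, 0.1), b = c(0.5, 0.1), c = c(0.9, 0.3))
  cc <- chromocenter_cluster(m2, k = 2)
  expect_equal(min(cc$heights), 0)
  expect_setequal(vapply(cc$partition, paste, "", collapse = ","), c("a,b", "c"))
})

test_that("hull areas match an independent shoelace oracle", {
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  expect_equal(chromocenter_hull_area(tri), 0.5)
  set.seed(45)
  for (rep in 1:10) {
    pts <- cbind(runif(7), runif(7))
    hull <- pts[grDevices::chull(pts), ]
    expect_equal(chromocenter_hull_area(pts), oracle_convex_area(hull),
                 tolerance = 1e-9)
    shift <- sweep(pts, 2, runif(2, -3, 3), "+")
    expect_equal(chromocenter_hull_area(shift), chromocenter_hull_area(pts),
                 tolerance = 1e-9)
  }
  expect_warning(a0 <- chromocenter_hull_area(cbind(1:3, 1:3)))
  expect_equal(a0, 0)
  # mirror union doubles a triangle sitting on the H = 0 axis
  tri2 <- cbind(c(0, 1, 0.5), c(0, 0, 0.4))
  expect_equal(chromocenter_hull_area(tri2, include_mirror = TRUE),
               2 * chromocenter_hull_area(tri2), tolerance = 1e-9)
})

test_that("pair_signals joins within nuclei and distance_summary folds", {
  sig <- data.frame(nucleus_id = rep(c("n1", "n2"), each = 2),
                    case = "K1", fraction = rep(c("raw", "SU"), each = 2),
                    chromosome = rep(c("4", "8"), 2),
                    x_um = c(0, 3, 0, 0), y_um = c(0, 4, 0, 1))
  d <- pair_signals(sig, pairs = list(c("4", "8")))
  expect_equal(nrow(d), 2L)
  expect_equal(sort(d$distance_um), c(1, 5))
  suppressWarnings(ds <- distance_summary(d, min_n = 1))
  expect_equal(ds$fold_vs_ref[ds$fraction == "raw"], 1.00)
  expect_equal(ds$fold_vs_ref[ds$fraction == "SU"],
               round_half_up(1 / 5, 2))
  expect_error(distance_summary(d[0, ]), class = "stp_data_error")
})
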