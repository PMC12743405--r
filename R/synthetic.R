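## Seeded synthetic sperm populations.
##
## The generator states a world matching the study design it emulates:
## n_cases donors x 3 fractions (raw, SU, DGC) x cells_per_case cells; each
## cell is a haploid nucleus carrying one centromere signal for chromosomes
## 4, 7, 8, 9, 18 and one sex chromosome (X or Y, equiprobable). Positions are
## drawn per (chromosome, fraction, epistate) preset either as truncated
## normals on the axial fraction ("radial" mode, preset = printed D/L means)
## or as multinomial zones with uniform placement within the zone ("zone"
## mode, preset = printed a/m/b frequencies). Perpendicular offsets |h|/L are
## truncated normals bounded by 0.95x the local ellipse half-width, with a
## random mirror sign. Truncation shifts a raw normal's mean, so locations
## are numerically corrected to realize the preset means in expectation.
## Epimark intensities follow a bivariate lognormal (log-scale correlation
## rho); positivity thresholds are the lognormal quantiles matching the
## printed positive proportions, so flags, strata and intensities cohere.

.t_lims <- function(config) config$t_range

## half-width of the ellipse at axial fraction t, as a fraction of L
.h_bound <- function(t, config) {
  hw <- config$h_margin / (2 * config$nucleus$shape_ratio)
  hw * sqrt(pmax(1 - (2 * t - 1)^2, 0))
}

## density grid of the axial fraction under a preset (for the h correction)
.t_grid <- function(params, config, n = 201L) {
  lim <- .t_lims(config)
  t <- seq(lim[1], lim[2], length.out = n)
  w <- if (params$mode == "radial") {
    stats::dnorm(t, params$mu_t, config$sd_axial)
  } else {
    thirds <- findInterval(t, c(1 / 3, 2 / 3)) + 1L   # 1=b 2=m 3=a
    c(params$p_b, params$p_m, params$p_a)[thirds]
  }
  list(t = t, w = w / sum(w))
}

## corrected |h| location so that the realized mean (averaged over the
## t-dependent ellipse bound) equals the preset mean
.solve_h_location <- function(target, params, config) {
  g <- .t_grid(params, config)
  b <- .h_bound(g$t, config)
  f <- function(mu) sum(g$w * .truncnorm_mean(mu, config$sd_h, 0, b)) - target
  if (f(1) < 0)
    stp_config_error("infeasible preset: |h| mean %.3f above the ellipse bound", target)
  stats::uniroot(f, lower = -1, upper = 1, tol = 1e-9)$root
}

## per-(position-chromosome, fraction, epistate) draw parameters, corrected
.generator_params <- function(config) {
  lim <- .t_lims(config)
  rad <- config$radial
  zon <- config$zone
  keys <- unique(rad[, c("chromosome", "fraction", "epistate")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- rad$chromosome == k$chromosome & rad$fraction == k$fraction &
      rad$epistate == k$epistate
    d_mean <- rad$mean[sel & rad$axis == "d"]
    h_mean <- rad$mean[sel & rad$axis == "h"]
    p <- list(chromosome = k$chromosome, fraction = k$fraction,
              epistate = k$epistate, mode = config$position_mode,
              target_t = d_mean, target_h = h_mean)
    if (config$position_mode == "radial") {
      p$mu_t <- .truncnorm_solve_location(d_mean, config$sd_axial, lim[1], lim[2])
    } else {
      zs <- zon$chromosome == k$chromosome & zon$fraction == k$fraction &
        zon$epistate == k$epistate
      pr <- c(b = zon$pct[zs & zon$zone == "b"],
              m = zon$pct[zs & zon$zone == "m"],
              a = zon$pct[zs & zon$zone == "a"])
      pr <- pr / sum(pr)
      p$p_b <- pr[["b"]]; p$p_m <- pr[["m"]]; p$p_a <- pr[["a"]]
    }
    p$mu_h <- .solve_h_location(h_mean, p, config)
    out[[i]] <- p
  }
  names(out) <- paste(keys$chromosome, keys$fraction, keys$epistate, sep = "|")
  out
}

## P(Z1 > q1, Z2 > q2) for standard bivariate normal with correlation rho
.bvn_upper_prob <- function(q1, q2, rho) {
  f <- function(z) stats::dnorm(z) *
    stats::pnorm((q2 - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
  stats::integrate(f, q1, Inf, rel.tol = 1e-10)$value
}

#' Epistate stratum probabilities implied by the epimark model
#'
#' @param config generator configuration.
#' @param fraction one of the configured fractions.
#' @return named numeric: P(hyper), P(hypo), P(mixed).
#' @export
stratum_probs <- function(config, fraction) {
  pos <- config$epimark$pos
  row <- pos[pos$fraction == fraction, ]
  if (nrow(row) != 1L) stp_config_error("unknown fraction '%s'", fraction)
  q1 <- stats::qnorm(1 - row$p_5mC)
  q2 <- stats::qnorm(1 - row$p_5hmC)
  rho <- config$epimark$rho
  hyper <- .bvn_upper_prob(q1, q2, rho)
  hypo <- .bvn_upper_prob(-q1, -q2, rho)   # both below by symmetry
  c(hyper = hyper, hypo = hypo, mixed = 1 - hyper - hypo)
}

#' Zone probabilities implied by a radial-mode positional preset
#'
#' Independent closed-form oracle for what zone frequencies the generator's
#' truncated-normal axial model induces (radial mode) or states (zone mode).
#'
#' @param config generator configuration.
#' @param chromosome position key (`4,...,18-X,18-Y,X,Y`).
#' @param fraction,epistate preset key.
#' @return named numeric: P(b), P(m), P(a).
#' @export
implied_zone_probs <- function(config, chromosome, fraction, epistate = "all") {
  p <- .generator_params(config)[[paste(chromosome, fraction, epistate, sep = "|")]]
  if (is.null(p)) stp_config_error("no preset for %s/%s/%s", chromosome, fraction, epistate)
  if (p$mode == "zone") return(c(b = p$p_b, m = p$p_m, a = p$p_a))
  lim <- .t_lims(config)
  cuts <- c(lim[1], 1 / 3, 2 / 3, lim[2])
  cdf <- stats::pnorm(cuts, p$mu_t, config$sd_axial)
  pr <- diff(cdf) / (cdf[4] - cdf[1])
  c(b = pr[1], m = pr[2], a = pr[3])
}

#' Generate a synthetic sperm population with ground truth
#'
#' Draws cells, nuclei, epimark intensities, chromatin classes and per-signal
#' coordinates under `config`; the seed fully determines the output.
#'
#' @param config an `stp_config`, e.g. from [preset_from_tables()].
#' @param seed overrides `config$seed` when given.
#' @return `stp_population` list with elements `cells` (one row per cell),
#'   `signals` (one row per FISH signal, coordinate-table schema plus ground
#'   truth columns) and `config` (echo, with realized epimark thresholds).
#' @export
generate_population <- function(config = preset_from_tables(), seed = NULL) {
  if (!inherits(config, "stp_config")) stp_config_error("config must be an stp_config")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(seed)
  gp <- .generator_params(config)
  nc <- config$n_cases * config$cells_per_case
  fr_all <- rep(config$fractions, each = nc)
  case_all <- rep(rep(sprintf("K%d", seq_len(config$n_cases)),
                      each = config$cells_per_case), times = length(config$fractions))
  n <- length(fr_all)
  id <- sprintf("%s_%s_c%03d", fr_all, case_all,
                rep(seq_len(config$cells_per_case), times = n / config$cells_per_case))

  L <- .rtruncnorm(n, config$nucleus$L_mean, config$nucleus$L_sd,
                   config$nucleus$L_mean - 3 * config$nucleus$L_sd,
                   config$nucleus$L_mean + 3 * config$nucleus$L_sd)
  l <- L / config$nucleus$shape_ratio
  bearing <- sample(c("X", "Y"), n, replace = TRUE)

  ## epimark latent bivariate normal -> lognormal intensities + flags
  rho <- config$epimark$rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  A <- config$epimark$amplitude
  sig <- config$epimark$sigma_log
  i_5mC <- A * exp(sig * z1)
  i_5hmC <- A * exp(sig * z2)
  pos <- config$epimark$pos
  pidx <- match(fr_all, pos$fraction)
  thr_5mC <- A * exp(sig * stats::qnorm(1 - pos$p_5mC))
  thr_5hmC <- A * exp(sig * stats::qnorm(1 - pos$p_5hmC))
  pos_5mC <- i_5mC > thr_5mC[pidx]
  pos_5hmC <- i_5hmC > thr_5hmC[pidx]
  stratum <- ifelse(pos_5mC & pos_5hmC, "hyper",
                    ifelse(!pos_5mC & !pos_5hmC, "hypo", "mixed"))

  ## chromatin classes (labels only; chemistry is out of scope)
  chem <- config$chromatin
  cidx <- match(fr_all, chem$fraction)
  ab <- character(n)
  for (f in unique(fr_all)) {
    s <- fr_all == f
    r <- chem[chem$fraction == f, ]
    pr <- c(r$ab_pink_pct, r$ab_purple_pct, r$ab_navy_pct)
    ab[s] <- sample(c("pink", "purple", "navy"), sum(s), TRUE, pr / sum(pr))
  }
  ao <- ifelse(stats::runif(n) < chem$ao_fragmented_pct[cidx] / 100,
               "red_yellow", "green")
  tunel <- ifelse(stats::runif(n) < chem$tunel_positive_pct[cidx] / 100,
                  "positive", "negative")

  ## pose: well-separated grid centers, random orientation
  theta <- stats::runif(n, 0, 2 * pi)
  gx <- ((seq_len(n) - 1L) %% 60L) * 20
  gy <- ((seq_len(n) - 1L) %/% 60L) * 20
  ux <- cos(theta); uy <- sin(theta)
  basal_x <- gx - L / 2 * ux; basal_y <- gy - L / 2 * uy
  apex_x <- gx + L / 2 * ux;  apex_y <- gy + L / 2 * uy

  cells <- data.frame(nucleus_id = id, case = case_all, fraction = fr_all,
                      bearing = bearing, L_um = L, l_um = l,
                      basal_x_um = basal_x, basal_y_um = basal_y,
                      apex_x_um = apex_x, apex_y_um = apex_y,
                      i_5mC = i_5mC, i_5hmC = i_5hmC,
                      true_pos_5mC = pos_5mC, true_pos_5hmC = pos_5hmC,
                      true_stratum = stratum,
                      ab_class = ab, ao_class = ao, tunel_class = tunel,
                      stringsAsFactors = FALSE)

  ## signals: chromosomes 4,7,8,9,18 in every cell; sex chromosome by bearing
  lim <- .t_lims(config)
  sig_list <- list()
  for (chrom in config$chromosomes) {
    keep <- if (chrom %in% c("X", "Y")) bearing == chrom else rep(TRUE, n)
    idx <- which(keep)
    pos_key <- if (chrom == "18") paste0("18-", bearing[idx]) else rep(chrom, length(idx))
    epi_key <- ifelse(stratum[idx] == "mixed", "all", stratum[idx])
    key <- paste(pos_key, fr_all[idx], epi_key, sep = "|")
    pars <- gp[key]
    if (config$position_mode == "radial") {
      mu_t <- vapply(pars, `[[`, 0, "mu_t")
      t <- .rtruncnorm(length(idx), mu_t, config$sd_axial, lim[1], lim[2])
    } else {
      pb <- vapply(pars, `[[`, 0, "p_b")
      pm <- vapply(pars, `[[`, 0, "p_m")
      u <- stats::runif(length(idx))
      zone_i <- 1L + (u >= pb) + (u >= pb + pm)  # 1=b 2=m 3=a
      zlo <- c(lim[1], 1 / 3, 2 / 3)[zone_i]
      zhi <- c(1 / 3, 2 / 3, lim[2])[zone_i]
      t <- stats::runif(length(idx), zlo, zhi)
    }
    mu_h <- vapply(pars, `[[`, 0, "mu_h")
    h <- .rtruncnorm(length(idx), mu_h, config$sd_h, 0, .h_bound(t, config))
    s <- sample(c(-1, 1), length(idx), replace = TRUE)
    nx <- -uy[idx]; ny <- ux[idx]   # unit normal to the axis
    x <- basal_x[idx] + t * L[idx] * ux[idx] + s * h * L[idx] * nx
    y <- basal_y[idx] + t * L[idx] * uy[idx] + s * h * L[idx] * ny
    sig_list[[chrom]] <- data.frame(
      nucleus_id = id[idx], case = case_all[idx], fraction = fr_all[idx],
      chromosome = chrom, bearing = bearing[idx],
      x_um = x, y_um = y,
      basal_x_um = basal_x[idx], basal_y_um = basal_y[idx],
      apex_x_um = apex_x[idx], apex_y_um = apex_y[idx],
      L_um = L[idx], l_um = l[idx],
      true_t = t, true_h_signed = s * h,
      true_stratum = stratum[idx],
      stringsAsFactors = FALSE)
  }
  signals <- do.call(rbind, sig_list)
  rownames(signals) <- NULL

  config$epimark$thresholds <- data.frame(fraction = pos$fraction,
                                          thr_5mC = thr_5mC, thr_5hmC = thr_5hmC)
  config$seed <- seed
  structure(list(cells = cells, signals = signals, config = config),
            class = "stp_population")
}

#' Monte-Carlo oracle for the expected inter-centromere distance of a pair
#'
#' Direct sampling from the positional presets (independent placement of the
#' two chromosomes in the same nucleus), bypassing the population machinery.
#'
#' @param config generator configuration.
#' @param pair e.g. `c("4", "8")`; sex-paired 18 uses keys `18-X`/`18-Y`.
#' @param fraction,epistate preset key.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the oracle draw.
#' @return expected distance (um).
#' @export
expected_pair_distance <- function(config, pair, fraction, epistate = "all",
                                   n_mc = 20000L, seed = 1L) {
  set.seed(seed)
  gp <- .generator_params(config)
  lim <- .t_lims(config)
  L <- .rtruncnorm(n_mc, config$nucleus$L_mean, config$nucleus$L_sd,
                   config$nucleus$L_mean - 3 * config$nucleus$L_sd,
                   config$nucleus$L_mean + 3 * config$nucleus$L_sd)
  pt <- matrix(0, n_mc, 4)
  for (j in 1:2) {
    p <- gp[[paste(pair[j], fraction, epistate, sep = "|")]]
    if (is.null(p)) stp_config_error("no preset for %s/%s/%s", pair[j], fraction, epistate)
    t <- if (p$mode == "radial") {
      .rtruncnorm(n_mc, p$mu_t, config$sd_axial, lim[1], lim[2])
    } else {
      u <- stats::runif(n_mc)
      zone_i <- 1L + (u >= p$p_b) + (u >= p$p_b + p$p_m)
      stats::runif(n_mc, c(lim[1], 1 / 3, 2 / 3)[zone_i],
                   c(1 / 3, 2 / 3, lim[2])[zone_i])
    }
    h <- .rtruncnorm(n_mc, p$mu_h, config$sd_h, 0, .h_bound(t, config)) *
      sample(c(-1, 1), n_mc, replace = TRUE)
    pt[, 2 * j - 1] <- t * L
    pt[, 2 * j] <- h * L
  }
  mean(sqrt((pt[, 1] - pt[, 3])^2 + (pt[, 2] - pt[, 4])^2))
}

#' Calibrate positional spread to hit a target mean pair distance
#'
#' Independent placement induces, rather than states, the mean distance of a
#' chromosome pair. This helper finds a common multiplier on `sd_axial` and
#' `sd_h` such that the Monte-Carlo expected distance matches `target_um`,
#' and returns the modified config.
#'
#' @inheritParams expected_pair_distance
#' @param target_um target mean distance (um).
#' @return config with scaled `sd_axial`, `sd_h`.
#' @export
calibrate_pair_distance <- function(config, pair, fraction, target_um,
                                    epistate = "all", n_mc = 20000L, seed = 1L) {
  base_a <- config$sd_axial; base_h <- config$sd_h
  f <- function(s) {
    cfg <- config
    cfg$sd_axial <- base_a * s
    cfg$sd_h <- base_h * s
    expected_pair_distance(cfg, pair, fraction, epistate, n_mc, seed) - target_um
  }
  s <- stats::uniroot(f, lower = 0.3, upper = 2.5, tol = 1e-4)$root
  config$sd_axial <- base_a * s
  config$sd_h <- base_h * s
  config
}

## preset lookup: target (d, h) means for one position key
.preset_dh <- function(config, pos_chrom, fraction, epistate) {
  r <- config$radial
  sel <- r$chromosome == pos_chrom & r$fraction == fraction & r$epistate == epistate
  c(d = r$mean[sel & r$axis == "d"], h = r$mean[sel & r$axis == "h"])
}

#' Expected group mean (D/L, H/L) under the generator
#'
#' Analytic oracle for what a measured group mean should recover. Stratified
#' groups (`hyper` / `hypo`) target their presets directly. The `all` group
#' is a mixture over strata (mixed cells draw from the `all` preset), with
#' weights from [stratum_probs()]. Chromosome `18` without bearing context is
#' an equal mixture of the `18-X` and `18-Y` presets.
#'
#' @param config generator configuration.
#' @param chromosome summary key (`4,...,18,18-X,18-Y,X,Y`).
#' @param fraction,epistate group key (`epistate` in all/hyper/hypo).
#' @return named numeric `c(d = , h = )`.
#' @export
expected_radial_mean <- function(config, chromosome, fraction, epistate = "all") {
  pos_keys <- if (chromosome == "18") c("18-X", "18-Y") else chromosome
  one_key <- function(pk) {
    if (epistate != "all") return(.preset_dh(config, pk, fraction, epistate))
    w <- stratum_probs(config, fraction)
    w[["hyper"]] * .preset_dh(config, pk, fraction, "hyper") +
      w[["hypo"]] * .preset_dh(config, pk, fraction, "hypo") +
      w[["mixed"]] * .preset_dh(config, pk, fraction, "all")
  }
  rowMeans(vapply(pos_keys, one_key, numeric(2)))
}

#' Expected zone frequencies under the generator
#'
#' Companion oracle to [expected_radial_mean()] for the b/m/a zone
#' probabilities (closed-form truncated-normal integrals in radial mode, the
#' stated multinomial in zone mode), mixed over strata and 18-bearing the
#' same way.
#'
#' @inheritParams expected_radial_mean
#' @return named numeric `c(b = , m = , a = )`, probabilities.
#' @export
expected_zone_freq <- function(config, chromosome, fraction, epistate = "all") {
  pos_keys <- if (chromosome == "18") c("18-X", "18-Y") else chromosome
  one_key <- function(pk) {
    if (epistate != "all")
      return(implied_zone_probs(config, pk, fraction, epistate))
    w <- stratum_probs(config, fraction)
    w[["hyper"]] * implied_zone_probs(config, pk, fraction, "hyper") +
      w[["hypo"]] * implied_zone_probs(config, pk, fraction, "hypo") +
      w[["mixed"]] * implied_zone_probs(config, pk, fraction, "all")
  }
  rowMeans(vapply(pos_keys, one_key, numeric(3)))
}
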