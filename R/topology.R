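## Aggregation of per-signal measurements into the standard topology outputs:
## zone-frequency tables, radial mean +/- SE tables, repositioning calls,
## inter-centromere distance summaries, Ward chromocenter clustering and
## chromocenter hull areas.

.EPISTATES <- c("all", "hyper", "hypo")

.one_group_summary <- function(g, min_n) {
  n <- nrow(g)
  zl <- split(g$zone, g$case)
  per_case <- t(vapply(zl, function(z) {
    tb <- table(factor(z, levels = c("a", "m", "b")))
    100 * as.numeric(tb) / length(z)
  }, numeric(3)))
  colnames(per_case) <- c("a", "m", "b")
  sdv <- if (nrow(per_case) > 1L) apply(per_case, 2, stats::sd) else rep(NA_real_, 3)
  data.frame(
    n_signals = n,
    mean_d = mean(g$d_over_l), se_d = stats::sd(g$d_over_l) / sqrt(n),
    mean_h = mean(g$h_over_l), se_h = stats::sd(g$h_over_l) / sqrt(n),
    a_pct = mean(per_case[, "a"]), a_sd = sdv[1],
    m_pct = mean(per_case[, "m"]), m_sd = sdv[2],
    b_pct = mean(per_case[, "b"]), b_sd = sdv[3],
    low_n = n < min_n)
}

#' Summarize topology per chromosome x fraction x epistate
#'
#' Zone frequencies are computed per case and averaged (mean +/- SD across
#' cases); radial coordinates are pooled over signals (mean +/- SE with
#' per-signal n). Chromosome 18 is additionally summarized within X- and
#' Y-bearing cells (rows `18-X`, `18-Y`); `epistate = "all"` includes every
#' cell, `hyper`/`hypo` the concordant-positive/-negative cells only.
#'
#' @param signals annotated signal table (see [annotate_signals()]) with
#'   columns `case`, `fraction`, `chromosome`, `bearing`, `stratum`, `zone`,
#'   `d_over_l`, `h_over_l` and optionally `keep` (only `TRUE` rows used).
#' @param min_n below this group size a `low_n` flag is set (default 100).
#' @return data.frame, one row per non-empty group.
#' @export
summarize_topology <- function(signals, min_n = 100L) {
  if (!is.null(signals$keep)) signals <- signals[signals$keep, ]
  if (nrow(signals) == 0L) {
    warning("summarize_topology: no signals after filtering")
    return(NULL)
  }
  if (!"stratum" %in% names(signals)) signals$stratum <- "mixed"
  chroms <- unique(signals$chromosome)
  keys <- c(chroms, if ("18" %in% chroms) c("18-X", "18-Y"))
  out <- list()
  for (ch in keys) {
    base <- if (ch %in% c("18-X", "18-Y")) {
      signals[signals$chromosome == "18" & signals$bearing == sub("18-", "", ch), ]
    } else signals[signals$chromosome == ch, ]
    for (fr in unique(signals$fraction)) {
      for (ep in .EPISTATES) {
        g <- base[base$fraction == fr, ]
        if (ep != "all") g <- g[g$stratum == ep, ]
        if (nrow(g) == 0L) {
          warning(sprintf("summarize_topology: empty group %s/%s/%s skipped",
                          ch, fr, ep))
          next
        }
        row <- .one_group_summary(g, min_n)
        out[[length(out) + 1L]] <-
          cbind(data.frame(chromosome = ch, fraction = fr, epistate = ep,
                           stringsAsFactors = FALSE), row)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call repositioning of a chromosome between two groups
#'
#' Per axis (D/L and H/L) the two groups are compared with a rank test: the
#' Mann-Whitney test when only two groups are supplied, or Kruskal-Wallis
#' followed by Dunn's test (Bonferroni-adjusted over fraction pairs) when all
#' fractions are supplied and a `pair` is named. Because one call combines
#' two axis-level tests, each axis is tested at `alpha / 2` (Bonferroni over
#' axes, configurable) so that the family-wise false-call rate is `alpha`.
#' Directions: higher mean D/L in the second group is "basal-apical" (toward
#' the apex), higher mean H/L is "center-periphery".
#'
#' @param groups named list of data.frames with `d_over_l`, `h_over_l`; two
#'   or more groups.
#' @param pair length-2 character naming the compared groups (defaults to the
#'   first two).
#' @param alpha family significance level.
#' @param axis_adjust apply the alpha/2 split across axes (default `TRUE`).
#' @return list with `direction`, `p_d`, `p_h`, `pair`, and the per-axis
#'   significance flags.
#' @export
call_repositioning <- function(groups, pair = NULL, alpha = 0.05,
                               axis_adjust = TRUE) {
  if (length(groups) < 2L) stp_data_error("call_repositioning: need >= 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(pair)) pair <- names(groups)[1:2]
  if (any(vapply(groups[pair], nrow, 1L) < 2L))
    stp_data_error("call_repositioning: both compared groups need >= 2 signals")
  a_axis <- if (axis_adjust) alpha / 2 else alpha
  axis_p <- function(col) {
    vals <- lapply(groups, `[[`, col)
    if (length(groups) == 2L) {
      two_group_test(vals[[pair[1]]], vals[[pair[2]]], force = "ranksum")$p
    } else {
      kd <- kw_dunn(vals, alpha = a_axis)
      pw <- kd$pairwise
      hit <- (pw$group1 == pair[1] & pw$group2 == pair[2]) |
             (pw$group1 == pair[2] & pw$group2 == pair[1])
      pw$p_adj[hit]
    }
  }
  p_d <- axis_p("d_over_l")
  p_h <- axis_p("h_over_l")
  dm <- mean(groups[[pair[2]]]$d_over_l) - mean(groups[[pair[1]]]$d_over_l)
  hm <- mean(groups[[pair[2]]]$h_over_l) - mean(groups[[pair[1]]]$h_over_l)
  sig_d <- is.finite(p_d) && p_d < a_axis
  sig_h <- is.finite(p_h) && p_h < a_axis
  direction <- if (sig_d && sig_h) "both"
  else if (sig_d) { if (dm > 0) "basal-apical" else "apical-basal" }
  else if (sig_h) { if (hm > 0) "center-periphery" else "periphery-center" }
  else "none"
  list(direction = direction, p_d = p_d, p_h = p_h, pair = pair,
       sig_d = sig_d, sig_h = sig_h, delta_d = dm, delta_h = hm)
}

#' Ward clustering of per-chromosome mean positions (chromocenters)
#'
#' Agglomerative Ward linkage on Euclidean distances between the 2D mean
#' (D/L, H/L) points, cut at `k` clusters. `"ward.D2"` (squared-update Ward
#' on raw Euclidean input) is the default; `"ward.D"` is also accepted.
#'
#' @param means data.frame with columns `chromosome`, `mean_d`, `mean_h`, or
#'   a 2-column matrix with chromosome rownames.
#' @param k number of clusters, 1 <= k <= number of chromosomes.
#' @param method hclust Ward variant.
#' @return list with `partition` (list of chromosome-name vectors, ordered by
#'   first member), `tree` (hclust), `heights`, `newick` (string).
#' @export
chromocenter_cluster <- function(means, k, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (is.data.frame(means)) {
    m <- as.matrix(means[, c("mean_d", "mean_h")])
    rownames(m) <- means$chromosome
  } else m <- means
  if (k > nrow(m) || k < 1L)
    stp_data_error("chromocenter_cluster: k = %d outside [1, %d]", k, nrow(m))
  tree <- stats::hclust(stats::dist(m), method = method)
  ct <- stats::cutree(tree, k = k)
  part <- unname(split(names(ct), ct))
  part <- part[order(vapply(part, `[`, "", 1L))]
  newick <- ape::write.tree(ape::as.phylo(tree))
  list(partition = part, tree = tree, heights = tree$height, newick = newick)
}

## shoelace polygon area on ordered vertices
.shoelace <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Convex-hull area of chromocenter mean positions
#'
#' Area of the convex hull of the per-chromosome mean (D/L, H/L) points, in
#' normalized units squared. With `include_mirror` the point set is unioned
#' with its reflection across H = 0 before hulling (mirror poses).
#'
#' @param means as in [chromocenter_cluster()].
#' @param include_mirror union with the H-mirrored points (default `FALSE`).
#' @return hull area (0 with a warning for collinear points).
#' @export
chromocenter_hull_area <- function(means, include_mirror = FALSE) {
  if (is.data.frame(means)) {
    m <- as.matrix(means[, c("mean_d", "mean_h")])
  } else m <- means
  if (nrow(m) < 3L) stp_data_error("chromocenter_hull_area: need >= 3 points")
  if (include_mirror) m <- rbind(m, cbind(m[, 1], -m[, 2]))
  idx <- grDevices::chull(m[, 1], m[, 2])
  if (length(idx) < 3L) {
    warning("chromocenter_hull_area: collinear points, area 0")
    return(0)
  }
  .shoelace(m[idx, , drop = FALSE])
}

#' Pair centromere signals within nuclei
#'
#' Joins the signals of two chromosomes cell by cell and computes their
#' Euclidean distance in um.
#'
#' @param signals signal table with `nucleus_id`, `chromosome`, `x_um`,
#'   `y_um`, `case`, `fraction`.
#' @param pairs list of length-2 character vectors (default the four studied
#'   pairs 4-8, 7-9, 18-X, 18-Y).
#' @return data.frame: pair, nucleus_id, case, fraction, distance_um.
#' @export
pair_signals <- function(signals,
                         pairs = list(c("4", "8"), c("7", "9"),
                                      c("18", "X"), c("18", "Y"))) {
  out <- lapply(pairs, function(pr) {
    a <- signals[signals$chromosome == pr[1],
                 c("nucleus_id", "case", "fraction", "x_um", "y_um")]
    b <- signals[signals$chromosome == pr[2], c("nucleus_id", "x_um", "y_um")]
    j <- merge(a, b, by = "nucleus_id", suffixes = c("_1", "_2"))
    if (nrow(j) == 0L) return(NULL)
    data.frame(pair = paste(pr, collapse = "-"),
               nucleus_id = j$nucleus_id, case = j$case, fraction = j$fraction,
               distance_um = intercentromere_distance(j$x_um_1, j$y_um_1,
                                                      j$x_um_2, j$y_um_2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distance summary per pair and fraction with fold changes
#'
#' Mean +/- SE of the per-cell distances for each pair x fraction, plus the
#' fold change of each fraction relative to `ref_fraction`, reported half-up
#' to `digits` decimals.
#'
#' @param distances output of [pair_signals()].
#' @param ref_fraction reference fraction for fold changes (default `"raw"`).
#' @param min_n warn threshold on group size (default 100).
#' @param digits fold-change reporting precision.
#' @return data.frame: pair, fraction, n, mean_um, se_um, fold_vs_ref.
#' @export
distance_summary <- function(distances, ref_fraction = "raw", min_n = 100L,
                             digits = 2) {
  if (is.null(distances) || nrow(distances) == 0L)
    stp_data_error("distance_summary: empty input")
  out <- list()
  for (pr in unique(distances$pair)) {
    sub <- distances[distances$pair == pr, ]
    fr_means <- sapply(unique(sub$fraction), function(fr)
      mean(sub$distance_um[sub$fraction == fr]))
    for (fr in unique(sub$fraction)) {
      d <- sub$distance_um[sub$fraction == fr]
      if (length(d) == 0L) next
      if (length(d) < min_n)
        warning(sprintf("distance_summary: %s/%s has n = %d < %d",
                        pr, fr, length(d), min_n))
      fold <- if (ref_fraction %in% names(fr_means))
        round_half_up(mean(d) / fr_means[[ref_fraction]], digits) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        pair = pr, fraction = fr, n = length(d), mean_um = mean(d),
        se_um = stats::sd(d) / sqrt(length(d)), fold_vs_ref = fold,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
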