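## Summary statistics and the hypothesis-testing policy: Shapiro-Wilk gated
## choice between Welch's t and the Mann-Whitney (Wilcoxon rank-sum) test for
## two groups, Kruskal-Wallis with Dunn's post hoc for three or more, at
## alpha = 0.05 throughout.

#' Mean, SD and SE of a sample
#'
#' @param values numeric vector, n >= 2.
#' @return list with `n`, `mean`, `sd` (sample, n-1 denominator), `se` =
#'   sd / sqrt(n).
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L)
    stp_data_error("summary_stats: need at least 2 values for SD/SE")
  s <- stats::sd(values)
  list(n = n, mean = mean(values), sd = s, se = s / sqrt(n))
}

#' Percent change between two values
#'
#' @param ref reference value (non-zero).
#' @param new new value.
#' @return `100 * (new - ref) / ref`.
#' @export
percent_change <- function(ref, new) {
  if (any(ref == 0)) stp_data_error("percent_change: reference is zero")
  100 * (new - ref) / ref
}

#' Fold change between two positive values
#'
#' `direction = "increase"` reports new/ref, `"decrease"` reports ref/new, so
#' the reported fold is always >= 1 when the change goes the named way.
#'
#' @param ref,new positive values.
#' @param direction `"increase"` or `"decrease"`.
#' @param digits reporting precision (half-up); `NULL` for unrounded.
#' @return fold change.
#' @export
fold_change <- function(ref, new, direction = c("increase", "decrease"),
                        digits = 2) {
  direction <- match.arg(direction)
  if (any(ref <= 0) || any(new <= 0))
    stp_data_error("fold_change: values must be positive")
  f <- if (direction == "increase") new / ref else ref / new
  if (is.null(digits)) f else round_half_up(f, digits)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with the policy's input checks.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stp_data_error("shapiro_wilk: n must be in [3, 5000], got %d", n)
  if (diff(range(values)) == 0)
    stp_data_error("shapiro_wilk: constant sample, W undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Two-group comparison under the normality-gated policy
#'
#' If `normality_gate` is on and both groups pass Shapiro-Wilk at `alpha`, an
#' unpaired Welch t-test is used; otherwise the Mann-Whitney rank-sum test
#' (normal approximation with continuity correction, robust to ties). All
#' p-values two-sided.
#'
#' @param x,y numeric vectors, each n >= 3.
#' @param alpha gate/report significance level.
#' @param normality_gate logical; `FALSE` forces the rank-sum test.
#' @param force `"auto"`, `"welch"` or `"ranksum"` explicit override.
#' @return list with `statistic`, `p`, `test` (label of the test used).
#' @export
two_group_test <- function(x, y, alpha = 0.05, normality_gate = TRUE,
                           force = c("auto", "welch", "ranksum")) {
  force <- match.arg(force)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stp_data_error("two_group_test: each group needs n >= 3")
  all_tied <- diff(range(c(x, y))) == 0
  if (all_tied) {
    warning("two_group_test: all values tied; p = 1")
    return(list(statistic = NA_real_, p = 1, test = "ranksum"))
  }
  use_welch <- switch(force,
    welch = TRUE,
    ranksum = FALSE,
    auto = normality_gate &&
      diff(range(x)) > 0 && diff(range(y)) > 0 &&
      shapiro_wilk(x)$p > alpha && shapiro_wilk(y)$p > alpha)
  if (use_welch) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "welch_t")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "ranksum")
  }
}

#' Kruskal-Wallis omnibus with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis across all groups; pairwise Dunn z-tests on
#' the joint mean ranks with Bonferroni adjustment (capped at 1) across all
#' pairs. With exactly two groups the comparison delegates to the rank-sum
#' branch of [two_group_test()].
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the `significant` flags.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return list with `omnibus_p`, `omnibus_statistic`, and `pairwise`
#'   (data.frame: group1, group2, z, p_raw, p_adj, significant).
#' @export
kw_dunn <- function(groups, alpha = 0.05, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) == 0L))
    stp_data_error("kw_dunn: empty group")
  k <- length(groups)
  if (k < 2L) stp_data_error("kw_dunn: need at least 2 groups")
  if (k == 2L) {
    tt <- two_group_test(groups[[1]], groups[[2]], alpha = alpha, force = "ranksum")
    pw <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                     z = NA_real_, p_raw = tt$p, p_adj = tt$p,
                     significant = tt$p < alpha, stringsAsFactors = FALSE)
    return(list(omnibus_p = tt$p, omnibus_statistic = tt$statistic, pairwise = pw))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (diff(range(values)) == 0) {
    warning("kw_dunn: all values tied; omnibus p = 1")
    pairs <- utils::combn(names(groups), 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = 0,
                     p_raw = 1, p_adj = 1, significant = FALSE,
                     stringsAsFactors = FALSE)
    return(list(omnibus_p = 1, omnibus_statistic = 0, pairwise = pw))
  }
  kw <- stats::kruskal.test(values, g)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- if (adjust == "bonferroni") pmin(p_raw * ncol(pairs), 1) else p_raw
  list(omnibus_p = kw$p.value,
       omnibus_statistic = unname(kw$statistic),
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p_raw = p_raw, p_adj = p_adj,
                             significant = p_adj < alpha,
                             stringsAsFactors = FALSE))
}
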