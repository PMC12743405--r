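## 5mC/5hmC stratification and chromatin-class tabulation.
##
## Each cell carries a background-subtracted IF intensity per mark. A mark is
## "positive" either against a fixed threshold background_mean + k * SD
## (k = 2 default; background statistics must be supplied, e.g. by the
## simulator) or against a per-mark Otsu threshold on the cell-intensity
## histogram. Cells positive for both marks are "hyper", negative for both
## "hypo", discordant "mixed"; mixed cells count toward positive frequencies
## but are excluded from hyper/hypo topology stratification.

#' Classify cells into 5mC/5hmC positivity and hyper/hypo strata
#'
#' @param profiles data.frame with numeric columns `i_5mC`, `i_5hmC`.
#' @param method `"fixed_k_sd"` or `"otsu"`.
#' @param params for `fixed_k_sd`: either `thr_5mC`/`thr_5hmC` (explicit
#'   thresholds) or `bg_mean_5mC`, `bg_sd_5mC`, `bg_mean_5hmC`, `bg_sd_5hmC`
#'   plus `k` (default 2).
#' @return input with `pos_5mC`, `pos_5hmC`, `stratum` appended.
#' @export
classify_epimarks <- function(profiles, method = c("fixed_k_sd", "otsu"),
                              params = list()) {
  method <- match.arg(method)
  if (!all(c("i_5mC", "i_5hmC") %in% names(profiles)))
    stp_data_error("profiles must have columns i_5mC, i_5hmC")
  thr <- if (method == "otsu") {
    if (nrow(profiles) < 2L)
      stp_data_error("otsu classification needs >= 2 cells")
    c(otsu_threshold(profiles$i_5mC), otsu_threshold(profiles$i_5hmC))
  } else {
    k <- if (is.null(params$k)) 2 else params$k
    t1 <- if (!is.null(params$thr_5mC)) params$thr_5mC
          else if (!is.null(params$bg_mean_5mC) && !is.null(params$bg_sd_5mC))
            params$bg_mean_5mC + k * params$bg_sd_5mC
    t2 <- if (!is.null(params$thr_5hmC)) params$thr_5hmC
          else if (!is.null(params$bg_mean_5hmC) && !is.null(params$bg_sd_5hmC))
            params$bg_mean_5hmC + k * params$bg_sd_5hmC
    if (is.null(t1) || is.null(t2))
      stp_config_error("fixed_k_sd needs thresholds or background stats per mark")
    c(t1, t2)
  }
  profiles$pos_5mC <- profiles$i_5mC > thr[1]
  profiles$pos_5hmC <- profiles$i_5hmC > thr[2]
  profiles$stratum <- ifelse(profiles$pos_5mC & profiles$pos_5hmC, "hyper",
                             ifelse(!profiles$pos_5mC & !profiles$pos_5hmC,
                                    "hypo", "mixed"))
  attr(profiles, "thresholds") <- c(thr_5mC = thr[1], thr_5hmC = thr[2])
  profiles
}

#' Class frequency table with per-case mean and SD
#'
#' Percentages of each level of `field`, computed per case and then averaged
#' across cases (mean +/- SD), plus the pooled percentages. Per-case
#' percentages sum to 100 exactly.
#'
#' @param records data.frame with a `case` column and the categorical `field`.
#' @param field column name to tabulate.
#' @param min_n warn if any case has fewer records than this (the design
#'   scored at least 1000 cells per sample; default warns below 100 to suit
#'   scaled-down synthetic runs).
#' @return list with `per_case` (case x class %), `mean` and `sd` (named
#'   numeric per class), `pooled` (named numeric %), `n`.
#' @export
class_frequencies <- function(records, field, min_n = 100L) {
  if (nrow(records) == 0L) stp_data_error("class_frequencies: empty input")
  if (!field %in% names(records))
    stp_data_error("class_frequencies: no column '%s'", field)
  f <- factor(records[[field]])
  case <- factor(records$case)
  n_case <- table(case)
  if (any(n_case < min_n))
    warning(sprintf("class_frequencies: %d case(s) below n = %d",
                    sum(n_case < min_n), min_n))
  counts <- table(case, f)
  per_case <- 100 * sweep(counts, 1, rowSums(counts), "/")
  pooled <- 100 * as.numeric(table(f)) / length(f)
  names(pooled) <- levels(f)
  list(per_case = per_case,
       mean = colMeans(per_case),
       sd = apply(per_case, 2, stats::sd),
       pooled = pooled,
       n = length(f))
}
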