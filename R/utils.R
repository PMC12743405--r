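#' @keywords internal
"_PACKAGE"

## Condition helpers: config errors and data errors carry distinct classes so
## the CLI can map them to exit codes (2 and 3 respectively).
stp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "stp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stp_config_error <- function(msg, ...) stp_stop("stp_config_error", msg, ...)
stp_data_error   <- function(msg, ...) stp_stop("stp_data_error", msg, ...)

#' Round half away from zero
#'
#' Reporting rounding used for printed fold changes and percentages: ties go
#' away from zero (GraphPad-style), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Otsu's threshold
#'
#' Maximum between-class variance threshold on a histogram of values; used for
#' image binarization and as an alternative IF-positivity criterion.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value; values strictly above it are "foreground".
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stp_data_error("otsu_threshold: constant or empty input, threshold undefined")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  breaks[which.max(sb2) + 1L]
}

## Mean of a normal(mu, sd) truncated to [lo, hi].
.truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  out <- mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  ## when the location sits many SDs outside [lo, hi] the mass ratio is 0/0;
  ## the truncated mean then degenerates to the nearer bound
  deg <- !is.finite(out) | z < 1e-14
  if (any(deg)) out[deg] <- ifelse(rep(mu, length.out = length(out))[deg] < lo,
                                   lo, hi)
  out
}

## Location parameter mu' such that the [lo, hi]-truncated normal with sd has
## the requested mean. Used by the generator so preset means are realized
## exactly in expectation despite truncation.
.truncnorm_solve_location <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi)
    stp_config_error("infeasible preset: target mean %.3f outside truncation (%.3f, %.3f)",
                     target, lo, hi)
  f <- function(mu) .truncnorm_mean(mu, sd, lo, hi) - target
  stats::uniroot(f, lower = lo - 6 * sd, upper = hi + 6 * sd, tol = 1e-10)$root
}

## Draw from a [lo, hi]-truncated normal by inverse CDF (vectorized).
.rtruncnorm <- function(n, mu, sd, lo, hi) {
  pa <- stats::pnorm(lo, mu, sd)
  pb <- stats::pnorm(hi, mu, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sd)
}
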