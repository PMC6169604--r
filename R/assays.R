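#' Fit a qPCR standard curve from serially diluted input
#'
#' Least-squares line `Ct = slope * log10(quantity) + intercept`, where
#' quantity is the dilution factor of the chromatin input in relative
#' units (the undiluted input aliquot is quantity 1). A valid curve has a
#' negative slope — Ct decreases as template increases; at 100%
#' amplification efficiency the slope is `-1/log10(2) ~ -3.32` per decade.
#'
#' @param dilution numeric vector of dilution factors (quantity in
#'   relative units), at least 3 distinct values.
#' @param ct matching Ct values.
#' @param input_fraction fraction of the chromatin used as the input
#'   aliquot, default 0.10 (a 10% input sample).
#' @return A `qpcr_curve` list: `slope`, `intercept`, `r_squared`,
#'   `efficiency` (`10^(-1/slope) - 1`, diagnostic only), `input_fraction`
#'   and the fitted points.
#' @export
fit_standard_curve <- function(dilution, ct, input_fraction = 0.10) {
  stopifnot(length(dilution) == length(ct), all(dilution > 0),
            input_fraction > 0, input_fraction <= 1)
  if (length(base::unique(dilution)) < 3L) {
    stop("standard curve needs >= 3 distinct dilutions")
  }
  lq <- log10(dilution)
  if (stats::var(lq) == 0) stop("zero variance in log10 quantity")
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_,
         input_fraction = input_fraction,
         points = tibble::tibble(dilution = dilution, ct = ct)),
    class = "qpcr_curve"
  )
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf(
    "<qpcr_curve> slope %.4f, intercept %.2f, r2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Percent input of an IP sample from its Ct
#'
#' Interpolates the IP sample's quantity on the input standard curve,
#' `q_ip = 10^((ct_ip - intercept)/slope)`, and expresses it as a percent
#' of the total chromatin. The input aliquot (quantity 1 on the curve) is
#' `input_fraction` of the chromatin, so the total is `1/input_fraction`
#' and `percent = 100 * q_ip * input_fraction`. An IP whose Ct equals the
#' undiluted aliquot's therefore reads 10% input at the default 10%
#' aliquot.
#'
#' @param ct_ip Ct value(s) of the IP sample, vectorized.
#' @param curve a [fit_standard_curve()] result; a non-negative slope is a
#'   hard error.
#' @return Percent-input value(s).
#' @export
percent_input <- function(ct_ip, curve) {
  stopifnot(inherits(curve, "qpcr_curve"))
  if (curve$slope >= 0) stop("invalid standard curve: slope must be negative")
  q_ip <- 10^((ct_ip - curve$intercept) / curve$slope)
  100 * q_ip * curve$input_fraction
}

#' Forward-simulate qPCR Ct values
#'
#' The generative model inverted by [percent_input()]: with amplification
#' efficiency `E`, each cycle multiplies template by `(1 + E)`, so
#' `Ct = ct0 - log(quantity) / log(1 + E)` plus optional Gaussian
#' measurement noise. Used to exercise curve fitting and percent-input
#' recovery against known quantities.
#'
#' @param quantity template quantities in relative units.
#' @param efficiency amplification efficiency in (0, 1], default 1 (a
#'   perfect doubling per cycle).
#' @param ct0 Ct of quantity 1, default 20.
#' @param sigma Gaussian Ct noise SD, default 0 (noise-free).
#' @return Numeric Ct values.
#' @export
simulate_ct <- function(quantity, efficiency = 1, ct0 = 20, sigma = 0) {
  stopifnot(all(quantity > 0), efficiency > 0, efficiency <= 1, sigma >= 0)
  ct <- ct0 - log(quantity) / log(1 + efficiency)
  if (sigma > 0) ct <- ct + stats::rnorm(length(ct), 0, sigma)
  ct
}

#' Beta-galactosidase activity in Miller units
#'
#' `U = (A420 * 1000) / (A660 * t * v)`: ONPG cleavage product absorbance
#' normalized by culture density, incubation time and culture volume.
#'
#' @param a420 absorbance at 420 nm (reaction product).
#' @param a660 absorbance at 660 nm (culture density).
#' @param t incubation time, minutes.
#' @param v culture volume assayed, mL.
#' @return Miller units, vectorized.
#' @export
miller_units <- function(a420, a660, t, v) {
  if (any(c(a420, a660, t, v) <= 0)) {
    stop("all Miller-assay inputs must be positive")
  }
  (a420 * 1000) / (a660 * t * v)
}

#' Aggregate replicate measurements
#'
#' Mean and standard error (sample SD over sqrt(n)) of replicate assay
#' values, the summary reported for triplicate qPCR and Miller
#' measurements.
#'
#' @param values numeric vector, n >= 2.
#' @return List with `mean`, `se` and `n`.
#' @export
aggregate_replicates <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicates")
  list(mean = mean(values), se = stats::sd(values) / sqrt(n), n = n)
}
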