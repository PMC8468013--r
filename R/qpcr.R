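# Quantitative model of the real-time PCR assay: the standard curve
# Ct = slope * log10(concentration) + intercept fitted by ordinary least
# squares, the amplification efficiency derived from the slope, the
# high-efficiency qualification rule, and inverse quantification of unknowns.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 concentration. The returned object
#' behaves like a classical fitted model: `print`, `summary`, `coef`,
#' `predict`, `residuals`, `plot` and `simulate` methods are provided, plus
#' [quantify()] for the inverse map.
#'
#' Efficiency is `(10^(-1/slope) - 1) * 100` percent: the per-cycle
#' amplification factor minus one, 100% at the perfect-doubling slope
#' −3.3219. The fit qualifies as high-efficiency when `r_squared >= 0.98`
#' and the slope lies in `[-3.6, -3.1]` (bounds inclusive).
#'
#' @param observations data.frame with numeric columns `log10_conc`
#'   (log10 CFU/mL or copies) and `ct` (threshold cycles), or a numeric
#'   vector of log10 concentrations when `ct` is given separately.
#' @param ct optional numeric vector of Ct values.
#' @return object of class `standard_curve`: list with `slope` (cycles per
#'   log10 unit), `intercept` (cycles), `r_squared`, `efficiency_pct`
#'   (NA with a warning for non-negative slopes), `high_efficiency`,
#'   `n_points`, the `lm` fit and the data.
#' @examples
#' x <- 3:9
#' fit <- fit_standard_curve(data.frame(log10_conc = x,
#'                                      ct = -3.530 * x + 36.906))
#' coef(fit)
#' quantify(fit, 26.316)
#' @export
fit_standard_curve <- function(observations, ct = NULL) {
  if (!is.null(ct)) observations <- data.frame(log10_conc = observations, ct = ct)
  stopifnot(is.data.frame(observations),
            all(c("log10_conc", "ct") %in% names(observations)))
  obs <- observations[, c("log10_conc", "ct")]
  obs <- obs[stats::complete.cases(obs), ]
  if (nrow(obs) < 3L)
    stop("need at least 3 observations to fit a standard curve", call. = FALSE)
  if (!all(is.finite(obs$log10_conc)) || !all(is.finite(obs$ct)))
    stop("observations must be finite", call. = FALSE)
  span <- diff(range(obs$log10_conc))
  if (span == 0)
    stop("log10 concentrations have zero variance", call. = FALSE)
  if (span < 2)
    warning("standard curve spans less than 2 log10 units; ",
            "the fit may be poorly constrained")
  fit <- lm(ct ~ log10_conc, data = obs)
  slope <- unname(coef(fit)[["log10_conc"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  # squared Pearson correlation == OLS R^2 for a simple regression, without
  # summary.lm's perfect-fit warning on noiseless calibration data
  r2 <- if (sd(obs$ct) == 0) NA_real_ else stats::cor(obs$log10_conc, obs$ct)^2
  eff <- if (slope < 0) efficiency_from_slope(slope) else {
    warning("non-negative slope: amplification efficiency undefined")
    NA_real_
  }
  out <- list(slope = slope, intercept = intercept, r_squared = r2,
              efficiency_pct = eff,
              high_efficiency = qualify_high_efficiency(slope = slope,
                                                        r_squared = r2),
              n_points = nrow(obs), lm = fit, data = obs)
  class(out) <- "standard_curve"
  out
}

#' Amplification efficiency from a standard-curve slope
#'
#' `(10^(-1/slope) - 1) * 100` percent; the unrounded value is returned
#' (display rounds to one decimal).
#'
#' @param slope standard-curve slope in cycles per log10 unit; must be
#'   negative.
#' @return efficiency in percent.
#' @examples
#' round(efficiency_from_slope(-3.530), 1)   # 92.0
#' round(efficiency_from_slope(-3.3219), 1)  # 100.0
#' @export
efficiency_from_slope <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope >= 0)
    stop("standard-curve slope must be negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}

#' High-efficiency qualification of a standard curve
#'
#' A real-time PCR standard curve qualifies as high-efficiency when
#' `r_squared >= 0.98` and the slope lies within `[-3.6, -3.1]`, boundaries
#' inclusive.
#'
#' @param fit a `standard_curve` (or omit and give `slope`/`r_squared`).
#' @param slope,r_squared scalar alternatives to `fit`.
#' @return logical.
#' @export
qualify_high_efficiency <- function(fit = NULL, slope = NULL, r_squared = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "standard_curve"))
    slope <- fit$slope; r_squared <- fit$r_squared
  }
  stopifnot(is.numeric(slope), is.numeric(r_squared))
  isTRUE(r_squared >= 0.98 && slope >= -3.6 && slope <= -3.1)
}

#' Quantify an unknown from its Ct value
#'
#' Inverse of the standard curve: `log10_conc = (ct - intercept) / slope`.
#'
#' @param fit a `standard_curve`.
#' @param ct numeric vector of Ct values.
#' @return log10 concentrations.
#' @export
quantify <- function(fit, ct) {
  stopifnot(inherits(fit, "standard_curve"), is.numeric(ct), all(is.finite(ct)))
  if (fit$slope == 0) stop("slope is zero: curve not invertible", call. = FALSE)
  (ct - fit$intercept) / fit$slope
}

#' Simulate Ct observations along a known standard curve
#'
#' `ct = true_slope * x + true_intercept + N(0, noise_sd)` at the given
#' log10 concentrations; deterministic for a fixed seed.
#'
#' @param true_slope,true_intercept the generating line.
#' @param log10_concs numeric vector of log10 concentrations.
#' @param noise_sd Gaussian noise standard deviation in cycles (>= 0).
#' @param seed integer seed (optional; the caller's RNG state is preserved).
#' @return data.frame with columns `log10_conc`, `ct`.
#' @export
simulate_ct <- function(true_slope, true_intercept, log10_concs,
                        noise_sd = 0.1, seed = NULL) {
  stopifnot(noise_sd >= 0, is.numeric(log10_concs), length(log10_concs) >= 1L)
  ct <- with_seed(seed,
    true_slope * log10_concs + true_intercept +
      rnorm(length(log10_concs), 0, noise_sd))
  data.frame(log10_conc = log10_concs, ct = ct)
}

#' @export
print.standard_curve <- function(x, digits = 3L, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  ct = %.3f * log10(conc) %+.3f   (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  cat(sprintf("  R-squared: %.3f   efficiency: %s%%   high-efficiency: %s\n",
              x$r_squared,
              if (is.na(x$efficiency_pct)) "NA" else sprintf("%.1f", x$efficiency_pct),
              if (x$high_efficiency) "yes" else "no"))
  invisible(x)
}

#' @export
summary.standard_curve <- function(object, ...) {
  out <- list(curve = object, lm_summary = summary(object$lm))
  class(out) <- "summary.standard_curve"
  out
}

#' @export
print.summary.standard_curve <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  residual sd: %.4f cycles over %d points\n",
              stats::sigma(x$curve$lm), x$curve$n_points))
  printCoefmat(stats::coef(x$lm_summary), digits = 4)
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
#' @param object,newdata standard predict interface; `newdata` may be a
#'   data.frame with `log10_conc` or a bare numeric vector.
#' @rdname fit_standard_curve
predict.standard_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(predict(object$lm)))
  if (is.numeric(newdata)) newdata <- data.frame(log10_conc = newdata)
  unname(predict(object$lm, newdata = newdata))
}

#' @export
residuals.standard_curve <- function(object, ...) {
  unname(residuals(object$lm))
}

#' @export
simulate.standard_curve <- function(object, nsim = 1, seed = NULL, ...) {
  noise <- stats::sigma(object$lm)
  with_seed(seed, {
    out <- replicate(nsim, object$slope * object$data$log10_conc +
                       object$intercept +
                       rnorm(object$n_points, 0, noise), simplify = FALSE)
    as.data.frame(setNames(out, paste0("sim_", seq_len(nsim))))
  })
}

#' @export
plot.standard_curve <- function(x, ...) {
  plot(x$data$log10_conc, x$data$ct,
       xlab = expression(log[10] ~ "concentration"), ylab = "Ct (cycles)",
       pch = 19, ...)
  abline(x$intercept, x$slope, lty = 2)
  mtext(sprintf("ct = %.3f x %+.3f   R2 = %.3f   eff = %.1f%%",
                x$slope, x$intercept, x$r_squared, x$efficiency_pct),
        side = 3, line = 0.3, cex = 0.85)
  invisible(x)
}

#' Read / write qPCR observation and fit tables
#'
#' Observations are a two-column TSV (`log10_conc`, `ct`); the fit summary is
#' a one-row TSV with slope, intercept, R-squared, efficiency and the
#' high-efficiency flag.
#'
#' @param path TSV path.
#' @return data.frame of observations, or `path` invisibly for writers.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("log10_conc", "ct") %in% names(df)))
  df[, c("log10_conc", "ct")]
}

#' @rdname read_ct_table
#' @param fit a `standard_curve`.
#' @export
write_standard_curve <- function(fit, path) {
  df <- data.frame(slope = fit$slope, intercept = fit$intercept,
                   r_squared = fit$r_squared,
                   efficiency_pct = fit$efficiency_pct,
                   high_efficiency = fit$high_efficiency,
                   n_points = fit$n_points)
  write_tsv(df, path)
}
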