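# Uptake-rate calibration and time-weighted-average (TWA) concentration
# arithmetic. In the linear (integrative) phase of first-order uptake the
# accumulated mass is m = Rs * C * t, so C_TWA = m / (Rs * t).

#' Calibrate a sampler uptake rate from a laboratory time series
#'
#' Fits ordinary least squares of accumulated disk mass against deployment
#' time at a known, constant laboratory water concentration. The uptake rate
#' is the fitted slope divided by that concentration: `rs = slope / c_lab`
#' (L/day). The intercept is left free, so small time-zero offsets or lag
#' phases do not bias the rate. Linear-window selection is a deterministic
#' single pass: the series is fit without its last timepoint and the last
#' point's predictive residual compared against three times that fit's
#' residual standard deviation; if it falls outside (and at least three
#' points remain), the point is dropped — a guard against the curvilinear
#' approach to equilibrium at the longest deployment time.
#'
#' @param times numeric vector of deployment times in days (>= 3 points).
#' @param masses numeric vector of accumulated masses (ng/disk), same length.
#' @param c_lab constant laboratory water concentration (ng/L), > 0.
#' @param compound_id,sorbent optional labels carried into the result.
#' @return an object of class `rs_estimate`: a list with `rs`, `slope`,
#'   `intercept`, `fit_r2`, `n_points`, `linear_window` and `valid`
#'   (`FALSE` when the slope is non-positive, making `rs` unusable
#'   downstream). Use [generics::tidy()] for a one-row tibble.
#' @examples
#' calibrate_rs(1:4, 0.05 * 500 * 1:4, c_lab = 500)
#' @export
calibrate_rs <- function(times, masses, c_lab,
                         compound_id = NA_character_, sorbent = NA_character_) {
  if (length(times) != length(masses)) {
    rlang::abort("times and masses must have equal length")
  }
  if (length(times) < 3) rlang::abort("at least 3 calibration points required")
  if (!is.finite(c_lab) || c_lab <= 0) rlang::abort("c_lab must be positive")
  ord <- order(times)
  times <- times[ord]
  masses <- masses[ord]

  n_used <- length(times)
  if (n_used >= 4) {
    # predictive check of the last point against the trend of the others:
    # its out-of-window residual must stay within 3 residual sd of that fit
    fit_rest <- stats::lm(masses[-n_used] ~ times[-n_used])
    pred_last <- stats::coef(fit_rest)[1] + stats::coef(fit_rest)[2] * times[n_used]
    sd_rest <- stats::sd(stats::residuals(fit_rest))
    tol <- max(3 * sd_rest, 1e-8 * max(abs(masses)))
    if (abs(masses[n_used] - pred_last) > tol) {
      times <- times[-n_used]
      masses <- masses[-n_used]
      n_used <- n_used - 1
    }
  }
  fit <- stats::lm(masses ~ times)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((masses - mean(masses))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  out <- structure(list(
    compound_id = compound_id,
    sorbent = sorbent,
    rs = slope / c_lab,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    fit_r2 = r2,
    n_points = n_used,
    linear_window = c(t_start = min(times), t_end = max(times)),
    valid = is.finite(slope) && slope > 0
  ), class = "rs_estimate")
  out
}

#' @export
print.rs_estimate <- function(x, ...) {
  cat("<rs_estimate>", if (!is.na(x$compound_id)) x$compound_id else "",
      if (!is.na(x$sorbent)) paste0("[", x$sorbent, "]"), "\n")
  cat(sprintf("  rs = %.4g L/day (slope %.4g, R^2 %.3f, n = %d, window %g-%g d)%s\n",
              x$rs, x$slope, x$fit_r2, x$n_points,
              x$linear_window[1], x$linear_window[2],
              if (x$valid) "" else "  [INVALID: non-positive slope]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate_rs
#' @param x an `rs_estimate` object.
#' @param ... unused.
#' @method tidy rs_estimate
#' @export
tidy.rs_estimate <- function(x, ...) {
  tibble::tibble(
    compound_id = x$compound_id, sorbent = x$sorbent,
    rs_L_day = x$rs, slope = x$slope, intercept = x$intercept,
    fit_r2 = x$fit_r2, n_points = x$n_points,
    t_start = unname(x$linear_window[1]), t_end = unname(x$linear_window[2]),
    valid = x$valid
  )
}

#' Calibrate uptake rates for every compound x sorbent series in a table
#'
#' @param series calibration tibble as returned by
#'   [read_calibration_series()].
#' @return tibble with one row per compound x sorbent (the tidy form of each
#'   [calibrate_rs()] result).
#' @export
calibrate_rs_table <- function(series) {
  series |>
    dplyr::group_by(.data$compound_id, .data$sorbent) |>
    dplyr::group_map(function(df, key) {
      tidy(calibrate_rs(df$time_days, df$mass_ng, df$c_lab_ng_L[1],
                        compound_id = key$compound_id, sorbent = key$sorbent))
    }) |>
    dplyr::bind_rows()
}

#' Time-weighted-average water concentration from a disk mass
#'
#' `c_twa = mass_ng / (rs * duration_days)`; linear in mass and the exact
#' inverse of [theoretical_disk_mass()].
#'
#' @param mass_ng accumulated mass on the disk (ng), >= 0.
#' @param rs sampling rate (L/day), > 0.
#' @param duration_days deployment duration (days), > 0.
#' @return TWA concentration in ng/L.
#' @examples
#' twa_concentration(6.7, rs = 0.05, duration_days = 7)
#' @export
twa_concentration <- function(mass_ng, rs, duration_days) {
  if (any(!is.finite(rs)) || any(rs <= 0)) rlang::abort("rs must be positive")
  if (any(!is.finite(duration_days)) || any(duration_days <= 0)) {
    rlang::abort("duration_days must be positive")
  }
  if (any(mass_ng < 0, na.rm = TRUE)) rlang::abort("mass_ng must be >= 0")
  mass_ng / (rs * duration_days)
}

#' Theoretical disk mass accumulated from a known water concentration
#'
#' `mass = c_water * rs * duration_days`, the inverse of
#' [twa_concentration()]. Used to place literature water data on the sampler
#' scale when no deployment took place.
#'
#' @param c_water dissolved concentration (ng/L), >= 0.
#' @param rs sampling rate (L/day), >= 0.
#' @param duration_days deployment duration (days), >= 0.
#' @return accumulated mass in ng/disk.
#' @export
theoretical_disk_mass <- function(c_water, rs, duration_days) {
  if (any(c_water < 0, na.rm = TRUE) || any(rs < 0, na.rm = TRUE) ||
      any(duration_days < 0, na.rm = TRUE)) {
    rlang::abort("all inputs must be >= 0")
  }
  c_water * rs * duration_days
}

#' Agreement between TWA-derived and grab-sample water concentrations
#'
#' Pairs the two tables by compound and summarises the signed differences
#' `twa - grab`. With a single pair the standard deviation is reported as 0
#' by convention (a lone difference carries no spread information).
#'
#' @param twa tibble with columns `compound_id`, `value` (ng/L) of
#'   TWA-derived concentrations.
#' @param grab tibble with the same columns for grab samples.
#' @return list of class `twa_agreement` with `per_compound` (tibble:
#'   `compound_id`, `twa`, `grab`, `diff`), `mean_error`, `sd_error`, `n`.
#' @export
twa_agreement <- function(twa, grab) {
  pairs <- dplyr::inner_join(
    dplyr::rename(twa[, c("compound_id", "value")], twa = "value"),
    dplyr::rename(grab[, c("compound_id", "value")], grab = "value"),
    by = "compound_id"
  )
  if (nrow(pairs) == 0) rlang::abort("no overlapping compounds to pair")
  pairs$diff <- pairs$twa - pairs$grab
  structure(list(
    per_compound = pairs,
    mean_error = mean(pairs$diff),
    sd_error = if (nrow(pairs) > 1) stats::sd(pairs$diff) else 0,
    n = nrow(pairs)
  ), class = "twa_agreement")
}

#' @export
print.twa_agreement <- function(x, ...) {
  cat(sprintf("<twa_agreement> mean error = %.3g +/- %.3g ng/L (n = %d)\n",
              x$mean_error, x$sd_error, x$n))
  invisible(x)
}

#' @rdname twa_agreement
#' @param x a `twa_agreement` object.
#' @param ... unused.
#' @method glance twa_agreement
#' @export
glance.twa_agreement <- function(x, ...) {
  tibble::tibble(mean_error = x$mean_error, sd_error = x$sd_error, n = x$n)
}
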