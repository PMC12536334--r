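# Cross-matrix proxy model: calibrate sampler-derived effect units against
# biota-derived ones, validate with k-fold cross-validation, back-calculate
# internal tissue concentrations, and cross-check toxic-unit classification
# across measurement routes.

#' Calibrate sampler effect units against biota effect units
#'
#' Linear (OLS) model of biota log10 effect units on sampler log10 effect
#' units (the latter from [effect_unit()] fed with
#' [psd_pseudo_concentration()]), fitted separately per sorbent. The
#' in-sample mean error is `mean(predicted - observed)` — identically zero
#' (up to floating point) for an intercept-including OLS fit — with the
#' error spread and a normal-approximation 95% CI
#' (`mean +/- 1.96 sd / sqrt(n)`) reported alongside.
#'
#' @param eu_psd numeric vector of sampler-derived log10 effect units.
#' @param eu_biota numeric vector of biota-derived log10 effect units,
#'   paired with `eu_psd` (same compound x month).
#' @param sorbent optional sorbent label carried into the result.
#' @param labels optional character vector naming each pair (for the
#'   residual table).
#' @return object of class `calibration_fit` with `slope`, `intercept`,
#'   `r2`, `p_value`, `n`, `mean_error`, `error_sd`, `ci95`, `residuals`
#'   (tibble) and the underlying `lm` fit. [generics::tidy()] gives the
#'   coefficient table, [generics::glance()] the one-row model summary.
#' @export
eu_calibration <- function(eu_psd, eu_biota, sorbent = NA_character_,
                           labels = NULL) {
  if (length(eu_psd) != length(eu_biota)) {
    rlang::abort("eu_psd and eu_biota must have equal length")
  }
  ok <- is.finite(eu_psd) & is.finite(eu_biota)
  eu_psd <- eu_psd[ok]
  eu_biota <- eu_biota[ok]
  if (!is.null(labels)) labels <- labels[ok]
  n <- length(eu_psd)
  if (n < 3) rlang::abort("at least 3 pairs required")
  if (stats::var(eu_psd) == 0) {
    rlang::abort("sampler effect units are constant; no calibration possible")
  }
  fit <- stats::lm(eu_biota ~ eu_psd)
  s <- suppressWarnings(summary(fit)) # perfect fits are legitimate here
  err <- unname(stats::fitted(fit) - eu_biota)
  mean_error <- mean(err)
  error_sd <- stats::sd(err)
  ci95 <- mean_error + c(-1, 1) * 1.96 * error_sd / sqrt(n)
  structure(list(
    sorbent = sorbent,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = n,
    mean_error = mean_error,
    error_sd = error_sd,
    ci95 = ci95,
    residuals = tibble::tibble(
      label = if (is.null(labels)) as.character(seq_len(n)) else labels,
      eu_psd = eu_psd, eu_biota = eu_biota,
      predicted = unname(stats::fitted(fit)), error = err
    ),
    fit = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit%s> biota_EU = %.3f x psd_EU %+.3f\n",
              if (!is.na(x$sorbent)) paste0(" ", x$sorbent) else "",
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f, p = %.3g, n = %d\n", x$r2, x$p_value, x$n))
  cat(sprintf("  mean error = %.3g +/- %.3g log10 units (95%% CI [%.3g, %.3g])\n",
              x$mean_error, x$error_sd, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @rdname eu_calibration
#' @param x a `calibration_fit` object.
#' @param ... unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2]),
    statistic = unname(co[, 3]),
    p_value = unname(co[, 4])
  )
}

#' @rdname eu_calibration
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    sorbent = x$sorbent, slope = x$slope, intercept = x$intercept,
    r_squared = x$r2, p_value = x$p_value, n = x$n,
    mean_error = x$mean_error, error_sd = x$error_sd,
    ci95_lo = x$ci95[1], ci95_hi = x$ci95[2]
  )
}

#' Paired sampler/biota effect units from a campaign
#'
#' Runs [risk_table()] and joins the sampler-as-organism effect units of one
#' sorbent against the biota effect units by compound x month, carrying the
#' per-compound `pc_crit` and worst-case `bcf` along for back-calculation.
#'
#' @param measurements validated measurement tibble.
#' @param compounds compound table.
#' @param sorbent `"hlb"`, `"anion"` or `"cation"`.
#' @param thresholds a [risk_thresholds()] object.
#' @return tibble with `compound_id`, `month`, `eu_psd`, `eu_biota`,
#'   `pc_crit`, `bcf` — ready for [eu_calibration()] and
#'   [kfold_validate()].
#' @export
eu_pairs <- function(measurements, compounds, sorbent = "hlb",
                     thresholds = risk_thresholds()) {
  sorbent <- rlang::arg_match(sorbent, SORBENTS)
  rt <- risk_table(measurements, compounds, thresholds)
  eu <- rt[rt$metric == "EU", ]
  psd <- eu[eu$matrix == paste0("psd_", sorbent),
            c("compound_id", "month", "value")]
  bio <- eu[eu$matrix == "biota", c("compound_id", "month", "value")]
  cc <- compound_constants(compounds)
  dplyr::inner_join(
    dplyr::rename(psd, eu_psd = "value"),
    dplyr::rename(bio, eu_biota = "value"),
    by = c("compound_id", "month")
  ) |>
    dplyr::left_join(
      tibble::tibble(compound_id = cc$compound_id,
                     pc_crit = cc$pc_crit_mg_L, bcf = cc$bcf),
      by = "compound_id"
    )
}

#' k-fold cross-validation of the effect-unit calibration
#'
#' Shuffles the pairs with a recorded seed into `k` folds (sizes differing by
#' at most one, every pair in exactly one validation fold), fits the
#' calibration on the remaining folds and evaluates the signed mean error
#' (`predicted - observed`) on the held-out fold — in log10 effect units
#' and, when per-pair `pc_crit`/`bcf` columns are supplied, in
#' back-calculated tissue concentrations (ng/g) via
#' [predict_internal_concentration()]. Five folds suit the small campaign
#' datasets (tens of pairs).
#'
#' @param pairs tibble with columns `eu_psd`, `eu_biota` and optionally
#'   `pc_crit` (mg/L) and `bcf` (L/kg).
#' @param k number of folds (default 5), `k <= n`.
#' @param seed integer seed for the fold shuffle.
#' @param form effect-unit denominator form (see [eu_denominator_ng_g()]).
#' @param ci one of `"normal"` (default, `mean +/- 1.96 sd / sqrt(k)`) or
#'   `"t"` (Student-t quantile, for small k).
#' @return object of class `cv_report` with `per_fold` (tibble),
#'   `mean_error`, `error_sd`, `ci95` (log10 units), the `_ng_g`
#'   counterparts when back-calculation was possible, plus `k`, `seed`,
#'   `folds` (the assignment vector).
#' @export
kfold_validate <- function(pairs, k = 5, seed = 1,
                           form = c("pc_crit_times_bcf", "pc_crit_only"),
                           ci = c("normal", "t")) {
  form <- match.arg(form)
  ci <- match.arg(ci)
  n <- nrow(pairs)
  if (n < k) rlang::abort("need at least k pairs")
  if (k < 2) rlang::abort("k must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))

  back <- all(c("pc_crit", "bcf") %in% names(pairs)) ||
    ("pc_crit" %in% names(pairs) && form == "pc_crit_only")
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- pairs[folds != f, ]
    test <- pairs[folds == f, ]
    fit <- stats::lm(eu_biota ~ eu_psd, data = train)
    pred <- stats::predict(fit, newdata = test)
    row <- tibble::tibble(
      fold = f, n = nrow(test),
      mean_error_eu = mean(pred - test$eu_biota)
    )
    if (back) {
      bcf <- if ("bcf" %in% names(pairs)) test$bcf else NULL
      conc_pred <- predict_internal_concentration(pred, test$pc_crit, bcf, form)
      conc_obs <- predict_internal_concentration(test$eu_biota, test$pc_crit,
                                                 bcf, form)
      row$mean_error_ng_g <- mean(conc_pred - conc_obs)
    }
    row
  })

  pooled <- function(v) {
    m <- mean(v)
    s <- stats::sd(v)
    half <- if (ci == "normal") 1.96 * s / sqrt(k) else {
      stats::qt(0.975, df = k - 1) * s / sqrt(k)
    }
    list(mean = m, sd = s, ci = m + c(-1, 1) * half)
  }
  eu <- pooled(per_fold$mean_error_eu)
  out <- list(per_fold = per_fold, k = k, seed = seed, folds = folds,
              mean_error = eu$mean, error_sd = eu$sd, ci95 = eu$ci)
  if (back) {
    ng <- pooled(per_fold$mean_error_ng_g)
    out$mean_error_ng_g <- ng$mean
    out$error_sd_ng_g <- ng$sd
    out$ci95_ng_g <- ng$ci
  }
  structure(out, class = "cv_report")
}

# preserve caller RNG state around seeded internals
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (seed %d)\n", x$k, x$seed))
  cat(sprintf("  EU mean error = %.3g +/- %.3g log10 units (95%% CI [%.3g, %.3g])\n",
              x$mean_error, x$error_sd, x$ci95[1], x$ci95[2]))
  if (!is.null(x$mean_error_ng_g)) {
    cat(sprintf("  back-calculated = %.3g +/- %.3g ng/g (95%% CI [%.3g, %.3g])\n",
                x$mean_error_ng_g, x$error_sd_ng_g,
                x$ci95_ng_g[1], x$ci95_ng_g[2]))
  }
  invisible(x)
}

#' @rdname kfold_validate
#' @param x a `cv_report` object.
#' @param ... unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @rdname kfold_validate
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  out <- tibble::tibble(
    k = x$k, seed = x$seed,
    mean_error = x$mean_error, error_sd = x$error_sd,
    ci95_lo = x$ci95[1], ci95_hi = x$ci95[2]
  )
  if (!is.null(x$mean_error_ng_g)) {
    out$mean_error_ng_g <- x$mean_error_ng_g
    out$error_sd_ng_g <- x$error_sd_ng_g
    out$ci95_ng_g_lo <- x$ci95_ng_g[1]
    out$ci95_ng_g_hi <- x$ci95_ng_g[2]
  }
  out
}

#' Back-calculate an internal tissue concentration from an effect unit
#'
#' Inverts [effect_unit()]: `c = 10^eu * denominator(pc_crit, bcf)` in ng/g.
#'
#' @param eu_pred log10 effect unit (predicted or observed).
#' @param pc_crit critical environmental concentration (mg/L).
#' @param bcf bioconcentration factor (L/kg); ignored for `pc_crit_only`.
#' @param form effect-unit denominator form.
#' @return tissue concentration in ng/g, vectorised.
#' @export
predict_internal_concentration <- function(eu_pred, pc_crit, bcf = NULL,
                                           form = c("pc_crit_times_bcf",
                                                    "pc_crit_only")) {
  10^eu_pred * eu_denominator_ng_g(pc_crit, bcf, match.arg(form))
}

#' Toxic-unit classification across measurement routes
#'
#' Computes log10 internal toxic units for one pesticide along every
#' available route and reports which routes agree with the tissue-based
#' classification at the -3.0 threshold:
#' * `tissue`: tissue concentration over the internal EC50;
#' * `water`: dissolved concentration over the *unadjusted* EC50 (both on
#'   the ng/L scale) — the conventional water-based screen;
#' * `psd_measured`: measured disk mass via the sampler-as-organism
#'   pseudo-concentration, one row per sorbent;
#' * `psd_theoretical`: disk mass reconstructed from the water concentration
#'   via `Rs x t`, one row per sorbent with an uptake rate.
#'
#' Routes whose inputs are missing are omitted and listed in the
#' `"omitted"` attribute.
#'
#' @param disk_mass_ng named numeric vector of measured disk masses (ng) per
#'   sorbent (names among hlb/anion/cation), or `NULL`.
#' @param c_water_ng_L dissolved concentration (ng/L), or `NA`.
#' @param c_tissue_ng_g tissue concentration (ng/g).
#' @param ec50_ug_L EC50 in water (ug/L).
#' @param bcf_L_kg worst-case bioconcentration factor (L/kg).
#' @param rs_L_day named numeric vector of uptake rates per sorbent, or
#'   `NULL`.
#' @param duration_days deployment duration (days, default 7).
#' @param thresholds a [risk_thresholds()] object.
#' @return tibble with `route`, `sorbent`, `log_tu`, `exceeds`,
#'   `agrees_with_tissue`.
#' @export
tu_crosscheck <- function(disk_mass_ng = NULL, c_water_ng_L = NA,
                          c_tissue_ng_g, ec50_ug_L, bcf_L_kg,
                          rs_L_day = NULL, duration_days = 7,
                          thresholds = risk_thresholds()) {
  if (!is.finite(c_tissue_ng_g) || c_tissue_ng_g <= 0) {
    rlang::abort("a positive tissue concentration is required as the reference route")
  }
  ec50_int <- internal_ec50(ec50_ug_L, bcf_L_kg)
  thr <- thresholds$tu_log_threshold
  omitted <- character(0)
  rows <- list(tibble::tibble(
    route = "tissue", sorbent = NA_character_,
    log_tu = toxic_unit(c_tissue_ng_g, ec50_int)
  ))
  if (is.finite(c_water_ng_L) && c_water_ng_L > 0) {
    rows <- c(rows, list(tibble::tibble(
      route = "water", sorbent = NA_character_,
      log_tu = log10(c_water_ng_L / ec50_as_ng_L(ec50_ug_L))
    )))
  } else {
    omitted <- c(omitted, "water")
  }
  if (!is.null(disk_mass_ng) && length(disk_mass_ng) > 0) {
    ok <- is.finite(disk_mass_ng) & disk_mass_ng > 0
    rows <- c(rows, list(tibble::tibble(
      route = "psd_measured", sorbent = names(disk_mass_ng)[ok],
      log_tu = unname(toxic_unit(
        psd_pseudo_concentration(disk_mass_ng[ok], thresholds$disk_mass_g),
        ec50_int))
    )))
  } else {
    omitted <- c(omitted, "psd_measured")
  }
  if (!is.null(rs_L_day) && length(rs_L_day) > 0 &&
      is.finite(c_water_ng_L) && c_water_ng_L > 0) {
    ok <- is.finite(rs_L_day) & rs_L_day > 0
    mass <- theoretical_disk_mass(c_water_ng_L, rs_L_day[ok], duration_days)
    rows <- c(rows, list(tibble::tibble(
      route = "psd_theoretical", sorbent = names(rs_L_day)[ok],
      log_tu = unname(toxic_unit(
        psd_pseudo_concentration(mass, thresholds$disk_mass_g), ec50_int))
    )))
  } else {
    omitted <- c(omitted, "psd_theoretical")
  }
  out <- dplyr::bind_rows(rows)
  out$exceeds <- out$log_tu > thr
  tissue_exceeds <- out$exceeds[out$route == "tissue"]
  out$agrees_with_tissue <- out$exceeds == tissue_exceeds
  attr(out, "omitted") <- omitted
  out
}
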