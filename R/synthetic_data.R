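# Synthetic monitoring campaigns with known ground truth. The generator
# emulates the structure of a monthly multi-matrix study: monthly water
# concentrations with log-normal noise and an optional seasonal trend,
# first-order sampler accumulation over a 7-day deployment, biota
# concentrations proportional to water through an apparent BCF, LOD/LOQ
# censoring and sporadic blank contamination.

#' Configuration of a synthetic monitoring campaign
#'
#' All per-compound parameters may be scalars (recycled) or vectors of
#' length `n_compounds`. Noise standard deviations are on the natural-log
#' scale (multiplicative log-normal noise). Defaults describe a mid-sized
#' wastewater-impacted urban river campaign: six monthly deployments of
#' seven days, three replicates per matrix, water means log-spaced across
#' 10-1350 ng/L.
#'
#' @param n_compounds number of compounds.
#' @param months character vector of `YYYY-MM` months.
#' @param n_reps replicates per compound x matrix x month.
#' @param water_mean per-compound monthly mean water concentration (ng/L);
#'   default log-spaced over \[10, 1350\].
#' @param water_noise_sd log-scale sd of water observations.
#' @param seasonal_trend fractional linear change of the monthly mean from
#'   the first to the last month (0 = flat, -0.5 = 50% decline).
#' @param rs_true per-compound true uptake rates: a list with numeric
#'   vectors `hlb`, `anion`, `cation` (L/day; `NA` = sorbent not calibrated
#'   for that compound). Default: log-spaced base rates 0.02-0.08 L/day on
#'   HLB, x0.8 on the anion and x1.2 on the cation phase.
#' @param deployment_days sampler deployment length (days, default 7).
#' @param bcf_app per-compound apparent bioconcentration factor (L/kg)
#'   linking realized water concentration to tissue concentration.
#' @param bcf_noise_sd log-scale sd of biota observations.
#' @param psd_noise_sd log-scale sd of sampler masses.
#' @param lod,loq named numeric vectors with elements `water`, `psd`,
#'   `biota` (units ng/L, ng/disk, ng/g); observations below `lod` are
#'   `not_detected`, between `lod` and `loq` `detected_below_loq`.
#' @param blank_prob probability that a compound x month gets a contaminated
#'   field blank.
#' @param compounds optional compound table (as from
#'   [read_compound_table()]) overriding the generated default constants.
#' @param seed integer seed; the whole campaign is reproducible from it.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(n_compounds = 20,
                            months = sprintf("2021-%02d", 7:12),
                            n_reps = 3,
                            water_mean = NULL,
                            water_noise_sd = 0.3,
                            seasonal_trend = 0,
                            rs_true = NULL,
                            deployment_days = 7,
                            bcf_app = NULL,
                            bcf_noise_sd = 0.2,
                            psd_noise_sd = 0.1,
                            lod = c(water = 1, psd = 0.002, biota = 0.05),
                            loq = c(water = 3, psd = 0.006, biota = 0.15),
                            blank_prob = 0,
                            compounds = NULL,
                            seed = 1) {
  n <- n_compounds
  geomspace <- function(a, b, n) {
    if (n == 1) return(a)
    a * (b / a)^((seq_len(n) - 1) / (n - 1))
  }
  if (is.null(water_mean)) water_mean <- geomspace(10, 1350, n)
  water_mean <- rep_len(water_mean, n)
  if (is.null(rs_true)) {
    base <- geomspace(0.02, 0.08, n)
    rs_true <- list(hlb = base, anion = 0.8 * base, cation = 1.2 * base)
  }
  rs_true <- purrr::map(rs_true, rep_len, n)
  if (is.null(bcf_app)) bcf_app <- 2000 * rs_true$hlb
  bcf_app <- rep_len(bcf_app, n)

  problems <- c(
    if (n < 1) "n_compounds must be >= 1",
    if (length(months) < 1) "at least one month required",
    if (n_reps < 1) "n_reps must be >= 1",
    if (any(water_mean <= 0)) "water_mean must be positive",
    if (water_noise_sd < 0 || bcf_noise_sd < 0 || psd_noise_sd < 0)
      "noise sds must be >= 0",
    if (deployment_days <= 0) "deployment_days must be positive",
    if (any(unlist(rs_true) <= 0, na.rm = TRUE)) "rs_true must be positive",
    if (any(bcf_app <= 0)) "bcf_app must be positive",
    if (!all(c("water", "psd", "biota") %in% names(lod)) ||
        !all(c("water", "psd", "biota") %in% names(loq)))
      "lod and loq need elements water, psd, biota",
    if (any(loq[names(lod)] < lod)) "loq must be >= lod",
    if (blank_prob < 0 || blank_prob > 1) "blank_prob must be in [0, 1]"
  )
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid campaign config: ",
                        paste(problems, collapse = "; ")))
  }
  structure(list(
    n_compounds = n, months = months, n_reps = n_reps,
    water_mean = water_mean, water_noise_sd = water_noise_sd,
    seasonal_trend = seasonal_trend, rs_true = rs_true,
    deployment_days = deployment_days, bcf_app = bcf_app,
    bcf_noise_sd = bcf_noise_sd, psd_noise_sd = psd_noise_sd,
    lod = lod, loq = loq, blank_prob = blank_prob,
    compounds = compounds, seed = seed
  ), class = "campaign_config")
}

default_synthetic_compounds <- function(config) {
  n <- config$n_compounds
  ids <- sprintf("c%03d", seq_len(n))
  is_pest <- seq_len(n) %% 3 == 1
  tibble::tibble(
    compound_id = ids,
    name = ids,
    chem_class = ifelse(is_pest, "pesticide", "pharmaceutical"),
    pnec_ng_L = config$water_mean / 5,
    ec50_ug_L = ifelse(is_pest, 5, NA_real_),
    pc_crit_mg_L = ifelse(is_pest, NA_real_,
                          1e-5 * 10^((seq_len(n) - 1) / max(1, n - 1) * 2)),
    rs_hlb_L_day = config$rs_true$hlb,
    rs_anion_L_day = config$rs_true$anion,
    rs_cation_L_day = config$rs_true$cation,
    lod_water = unname(config$lod["water"]),
    loq_water = unname(config$loq["water"]),
    lod_psd = unname(config$lod["psd"]),
    loq_psd = unname(config$loq["psd"]),
    lod_biota = unname(config$lod["biota"]),
    loq_biota = unname(config$loq["biota"]),
    bcf_candidates = purrr::map(seq_len(n), ~ c(100, 80))
  )
}

censor_values <- function(value, lod, loq) {
  censor <- dplyr::case_when(
    value < lod ~ "not_detected",
    value < loq ~ "detected_below_loq",
    TRUE ~ "quantified"
  )
  value[censor != "quantified"] <- NA_real_
  list(value = value, censor = censor)
}

#' Generate a full synthetic campaign
#'
#' Simulates, reproducibly from the config seed, the three observation
#' streams of a monitoring campaign:
#' * water: `monthly mean x lognormal(water_noise_sd)` per replicate;
#' * sampler: `rs_true x (realized mean water over the deployment) x
#'   deployment_days x lognormal(psd_noise_sd)` per sorbent and replicate —
#'   uptake integrates the *realized* water series, so the TWA relation is
#'   exact in the noiseless limit;
#' * biota: `bcf_app x realized water / 1000 x lognormal(bcf_noise_sd)` in
#'   ng/g (instantaneous proportionality, no toxicokinetic lag).
#'
#' All observations are then censored against the per-matrix LOD/LOQ, and
#' contaminated field blanks are injected per compound x month with
#' probability `blank_prob`.
#'
#' @param config a [campaign_config()].
#' @return list of class `synthetic_campaign` with `measurements`
#'   (validated tibble), `compounds` (compound table) and `truth` (list:
#'   realized water series, true rates and factors, censoring and blank
#'   bookkeeping).
#' @export
generate_campaign <- function(config) {
  if (!inherits(config, "campaign_config")) {
    rlang::abort("config must be a campaign_config object")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_compounds
  M <- length(config$months)
  R <- config$n_reps
  ids <- sprintf("c%03d", seq_len(n))
  compounds <- if (is.null(config$compounds)) {
    default_synthetic_compounds(config)
  } else {
    config$compounds
  }
  if (nrow(compounds) != n) {
    rlang::abort("compound table must have n_compounds rows")
  }
  ids <- compounds$compound_id

  trend_factor <- if (M == 1) 1 else {
    1 + config$seasonal_trend * (seq_len(M) - 1) / (M - 1)
  }
  mean_cm <- outer(config$water_mean, trend_factor) # n x M
  lnoise <- function(sd, k) exp(stats::rnorm(k, 0, sd))

  grid <- tidyr::expand_grid(i = seq_len(n), m = seq_len(M), r = seq_len(R))
  w_obs <- mean_cm[cbind(grid$i, grid$m)] *
    lnoise(config$water_noise_sd, nrow(grid))
  # realized deployment-window water concentration: mean of realized obs
  w_real <- matrix(tapply(w_obs, list(grid$i, grid$m), mean), nrow = n)

  water_rows <- tibble::tibble(
    compound_id = ids[grid$i], matrix = "water",
    timepoint = config$months[grid$m], replicate = grid$r, raw = w_obs
  )

  psd_rows <- purrr::map_dfr(SORBENTS, function(s) {
    rs <- config$rs_true[[s]]
    keep <- grid[!is.na(rs[grid$i]), ]
    if (nrow(keep) == 0) return(NULL)
    mass <- rs[keep$i] * w_real[cbind(keep$i, keep$m)] *
      config$deployment_days * lnoise(config$psd_noise_sd, nrow(keep))
    tibble::tibble(
      compound_id = ids[keep$i], matrix = paste0("psd_", s),
      timepoint = config$months[keep$m], replicate = keep$r, raw = mass
    )
  })

  biota_raw <- config$bcf_app[grid$i] * w_real[cbind(grid$i, grid$m)] / 1000 *
    lnoise(config$bcf_noise_sd, nrow(grid))
  biota_rows <- tibble::tibble(
    compound_id = ids[grid$i], matrix = "biota",
    timepoint = config$months[grid$m], replicate = grid$r, raw = biota_raw
  )

  obs <- dplyr::bind_rows(water_rows, psd_rows, biota_rows)
  fam <- dplyr::case_when(
    obs$matrix == "water" ~ "water",
    obs$matrix == "biota" ~ "biota",
    TRUE ~ "psd"
  )
  cen <- censor_values(obs$raw, config$lod[fam], config$loq[fam])
  obs$value <- cen$value
  obs$censor <- cen$censor

  blank_grid <- tidyr::expand_grid(i = seq_len(n), m = seq_len(M))
  contaminated <- stats::runif(nrow(blank_grid)) < config$blank_prob
  blanks <- blank_grid[contaminated, ]
  blank_rows <- if (nrow(blanks) > 0) {
    tibble::tibble(
      compound_id = ids[blanks$i], matrix = "blank_field",
      timepoint = config$months[blanks$m], replicate = 1L,
      value = 2 * unname(config$loq["psd"]), censor = "quantified"
    )
  } else {
    NULL
  }

  measurements <- validate_measurements(dplyr::bind_rows(
    tibble::tibble(
      compound_id = obs$compound_id, matrix = obs$matrix,
      timepoint = obs$timepoint, replicate = as.integer(obs$replicate),
      value = obs$value, censor = obs$censor
    ),
    blank_rows
  ))

  truth <- list(
    config = config,
    water_monthly_mean = mean_cm,
    realized_water = w_real,
    rs_true = config$rs_true,
    bcf_app = config$bcf_app,
    censored = tibble::tibble(
      compound_id = obs$compound_id, matrix = obs$matrix,
      timepoint = obs$timepoint, replicate = obs$replicate,
      raw = obs$raw, censor = obs$censor
    ),
    blank_pairs = if (nrow(blanks) > 0) {
      tibble::tibble(compound_id = ids[blanks$i],
                     month = config$months[blanks$m])
    } else {
      tibble::tibble(compound_id = character(0), month = character(0))
    }
  )
  structure(list(measurements = measurements, compounds = compounds,
                 truth = truth),
            class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat(sprintf("<synthetic_campaign> %d compounds, %d months, %d measurement rows (seed %d)\n",
              x$truth$config$n_compounds, length(x$truth$config$months),
              nrow(x$measurements), x$truth$config$seed))
  invisible(x)
}

#' Generate a laboratory calibration time series
#'
#' `mass(t) = rs_true x c_lab x t x exp(eps)`, `eps ~ N(0, noise_sd)`;
#' timepoints are sorted before generation.
#'
#' @param rs_true true uptake rate (L/day), > 0.
#' @param c_lab constant lab water concentration (ng/L), > 0.
#' @param timepoints deployment times in days.
#' @param noise_sd log-scale noise sd.
#' @param seed integer seed.
#' @param compound_id,sorbent labels for the output table.
#' @return tibble with `compound_id`, `sorbent`, `time_days`, `mass_ng`,
#'   `c_lab_ng_L`.
#' @export
generate_calibration_series <- function(rs_true, c_lab,
                                        timepoints = c(1, 2, 3, 5, 7),
                                        noise_sd = 0, seed = 1,
                                        compound_id = "c001",
                                        sorbent = "hlb") {
  if (rs_true <= 0 || c_lab <= 0) {
    rlang::abort("rs_true and c_lab must be positive")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- sort(timepoints)
  tibble::tibble(
    compound_id = compound_id, sorbent = sorbent, time_days = t,
    mass_ng = rs_true * c_lab * t * exp(stats::rnorm(length(t), 0, noise_sd)),
    c_lab_ng_L = c_lab
  )
}

#' Named campaign scenario presets
#'
#' * `"wandle_like"`: 100 compounds over six monthly 7-day deployments,
#'   water means log-spaced across the 10-1350 ng/L range typical of a
#'   wastewater-impacted urban river, realistic noise and censoring and
#'   sporadic blank contamination.
#' * `"proxy_ideal"`: noiseless campaign whose apparent biota factors are
#'   proportional to the sampler uptake rates, so sampler- and
#'   biota-derived effect units are affinely related and the cross-matrix
#'   calibration is exact (R^2 = 1).
#' * `"misclassify"`: a single pesticide at a low water concentration where
#'   the tissue toxic unit exceeds the -3.0 threshold but the water-based
#'   toxic unit does not — the scenario in which only the sampler routes
#'   classify the risk correctly.
#'
#' @param name preset name.
#' @param seed integer seed stored in the config.
#' @return a [campaign_config()].
#' @export
scenario_presets <- function(name = c("wandle_like", "proxy_ideal",
                                      "misclassify"),
                             seed = 1) {
  name <- rlang::arg_match(name)
  switch(name,
    wandle_like = campaign_config(
      n_compounds = 100, n_reps = 3,
      water_noise_sd = 0.3, psd_noise_sd = 0.1, bcf_noise_sd = 0.2,
      seasonal_trend = -0.2, blank_prob = 0.02, seed = seed
    ),
    proxy_ideal = {
      n <- 24
      base <- 0.02 * (0.08 / 0.02)^((seq_len(n) - 1) / (n - 1))
      cfg <- campaign_config(
        n_compounds = n, n_reps = 1,
        water_mean = 20 * (500 / 20)^((seq_len(n) - 1) / (n - 1)),
        water_noise_sd = 0, psd_noise_sd = 0, bcf_noise_sd = 0,
        rs_true = list(hlb = base, anion = 0.8 * base, cation = 1.2 * base),
        bcf_app = 2000 * base,
        lod = c(water = 0, psd = 0, biota = 0),
        loq = c(water = 0, psd = 0, biota = 0),
        seed = seed
      )
      cfg$compounds <- default_synthetic_compounds(cfg)
      # all-pharmaceutical panel so every compound enters the EU calibration
      cfg$compounds$chem_class <- "pharmaceutical"
      cfg$compounds$ec50_ug_L <- NA_real_
      cfg$compounds$pc_crit_mg_L <-
        1e-5 * 10^(((seq_len(n) - 1) %% 8) / 4) # varied, repeating ladder
      cfg
    },
    misclassify = {
      cfg <- campaign_config(
        n_compounds = 1, n_reps = 1,
        water_mean = 5, water_noise_sd = 0, psd_noise_sd = 0,
        bcf_noise_sd = 0,
        rs_true = list(hlb = NA_real_, anion = 0.05, cation = 0.05),
        bcf_app = 1000,
        lod = c(water = 0, psd = 0, biota = 0),
        loq = c(water = 0, psd = 0, biota = 0),
        seed = seed
      )
      cfg$compounds <- tibble::tibble(
        compound_id = "c001", name = "pesticide_x", chem_class = "pesticide",
        pnec_ng_L = 6.8, ec50_ug_L = 20.9, pc_crit_mg_L = NA_real_,
        rs_hlb_L_day = NA_real_, rs_anion_L_day = 0.05,
        rs_cation_L_day = 0.05,
        lod_water = 0, loq_water = 0, lod_psd = 0, loq_psd = 0,
        lod_biota = 0, loq_biota = 0,
        bcf_candidates = list(9.5)
      )
      cfg
    }
  )
}
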