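# Risk scores across matrices: risk quotients (MEC/PNEC) with four-band
# classification, internal toxic units (pesticides, EC50-based) and internal
# effect units (pharmaceuticals, PC_crit-based), including the
# sampler-as-organism substitution where the disk load divided by the disk
# weight stands in for the tissue concentration.

RQ_CATEGORIES <- c("insignificant", "low", "medium", "high")
EU_FORMS <- c("pc_crit_times_bcf", "pc_crit_only")

#' Risk thresholds and classification constants
#'
#' Holds the risk-quotient band breakpoints (0.1, 1, 10), the log10 toxic
#' unit threshold above which pesticides can harm invertebrates (-3.0), the
#' sorbent disk weight used by the sampler-as-organism substitution
#' (0.0115 g per 9 mm disk) and the algebraic form of the effect-unit
#' denominator.
#'
#' @param rq_breaks strictly increasing breakpoints separating the
#'   insignificant/low/medium/high risk-quotient bands.
#' @param tu_log_threshold log10 toxic-unit threshold; exceedance is strict
#'   (`value > threshold`).
#' @param disk_mass_g sorbent disk weight in grams.
#' @param eu_form `"pc_crit_times_bcf"` (default: denominator is
#'   PC_crit x BCF internalised to ng/g, the analogue of the internal EC50)
#'   or `"pc_crit_only"` (denominator is PC_crit alone on the same scale,
#'   i.e. BCF taken as 1 L/kg).
#' @return list of class `risk_thresholds`.
#' @export
risk_thresholds <- function(rq_breaks = c(0.1, 1, 10),
                            tu_log_threshold = -3.0,
                            disk_mass_g = 0.0115,
                            eu_form = c("pc_crit_times_bcf", "pc_crit_only")) {
  eu_form <- match.arg(eu_form)
  if (length(rq_breaks) != 3 || any(diff(rq_breaks) <= 0)) {
    rlang::abort("rq_breaks must be three strictly increasing values")
  }
  if (disk_mass_g <= 0) rlang::abort("disk_mass_g must be positive")
  structure(list(rq_breaks = rq_breaks, tu_log_threshold = tu_log_threshold,
                 disk_mass_g = disk_mass_g, eu_form = eu_form),
            class = "risk_thresholds")
}

#' Risk quotient
#'
#' The ratio of a measured environmental concentration to the predicted
#' no-effect concentration, both in ng/L.
#'
#' @param mec measured environmental concentration (ng/L), >= 0.
#' @param pnec predicted no-effect concentration (ng/L), > 0.
#' @return unitless risk quotient, vectorised over `mec`.
#' @examples
#' risk_quotient(66, 6.8) # ~9.7, medium risk
#' @export
risk_quotient <- function(mec, pnec) {
  if (any(!is.finite(pnec)) || any(pnec <= 0)) rlang::abort("pnec must be positive")
  if (any(mec < 0, na.rm = TRUE)) rlang::abort("mec must be >= 0")
  mec / pnec
}

#' Classify a risk quotient into the four risk bands
#'
#' Bands form a partition of the non-negative line: insignificant
#' `[0, 0.1)`, low `[0.1, 1)`, medium `[1, 10]`, high `(10, Inf)`. Lower
#' bounds are inclusive for low and medium; 10 belongs to medium so that
#' "high" means strictly greater than 10.
#'
#' @param rq numeric vector of risk quotients, >= 0.
#' @param thresholds a [risk_thresholds()] object.
#' @return factor with levels insignificant < low < medium < high.
#' @export
classify_rq <- function(rq, thresholds = risk_thresholds()) {
  if (any(rq < 0, na.rm = TRUE)) rlang::abort("rq must be >= 0")
  b <- thresholds$rq_breaks
  out <- dplyr::case_when(
    is.na(rq) ~ NA_character_,
    rq < b[1] ~ "insignificant",
    rq < b[2] ~ "low",
    rq <= b[3] ~ "medium",
    TRUE ~ "high"
  )
  factor(out, levels = RQ_CATEGORIES, ordered = TRUE)
}

#' Internal EC50 on the tissue scale
#'
#' `EC50_int = EC50 x BCF`. With EC50 in ug/L and BCF in L/kg the product is
#' ug/kg, numerically ng/g, so no conversion factor appears.
#'
#' @param ec50 median effect concentration in water (ug/L), > 0.
#' @param bcf bioconcentration factor (L/kg), > 0.
#' @return internal EC50 in ng/g.
#' @export
internal_ec50 <- function(ec50, bcf) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) rlang::abort("ec50 must be positive")
  if (any(!is.finite(bcf)) || any(bcf <= 0)) rlang::abort("bcf must be positive")
  ec50 * bcf
}

#' Worst-case bioconcentration factor
#'
#' Several BCF estimates may exist per compound (different prediction
#' models); the largest is used so derived internal thresholds are the most
#' protective.
#'
#' @param bcf_candidates numeric vector of candidate BCFs (L/kg), all > 0.
#' @return the maximum candidate.
#' @export
select_worst_case_bcf <- function(bcf_candidates) {
  bcf_candidates <- bcf_candidates[!is.na(bcf_candidates)]
  if (length(bcf_candidates) == 0) rlang::abort("no BCF candidates supplied")
  if (any(bcf_candidates <= 0)) rlang::abort("BCF candidates must be positive")
  max(bcf_candidates)
}

#' Internal toxic unit (log10)
#'
#' `log10(c_invert / EC50_int)`, the tissue concentration over the internal
#' EC50. Values above the -3.0 threshold indicate a pesticide may elicit
#' adverse effects in the invertebrate; the comparison is strict
#' (`> threshold`), so -3.0 exactly does not exceed.
#'
#' @param c_invert tissue concentration (ng/g), > 0.
#' @param ec50_int internal EC50 (ng/g), > 0.
#' @return log10 toxic unit, vectorised.
#' @export
toxic_unit <- function(c_invert, ec50_int) {
  if (any(c_invert <= 0, na.rm = TRUE)) rlang::abort("c_invert must be positive")
  if (any(!is.finite(ec50_int)) || any(ec50_int <= 0)) {
    rlang::abort("ec50_int must be positive")
  }
  log10(c_invert / ec50_int)
}

#' Effect-unit denominator on the tissue scale
#'
#' For the default `pc_crit_times_bcf` form the denominator is
#' PC_crit \[mg/L\] x BCF \[L/kg\] = mg/kg, converted to ng/g (x 1000). The
#' `pc_crit_only` form omits the BCF (equivalent to BCF = 1 L/kg).
#'
#' @param pc_crit critical environmental concentration (mg/L), > 0.
#' @param bcf bioconcentration factor (L/kg), > 0 (ignored for
#'   `pc_crit_only`).
#' @param form one of `"pc_crit_times_bcf"`, `"pc_crit_only"`.
#' @return denominator in ng/g.
#' @export
eu_denominator_ng_g <- function(pc_crit, bcf = NULL,
                                form = c("pc_crit_times_bcf", "pc_crit_only")) {
  form <- match.arg(form)
  if (any(!is.finite(pc_crit)) || any(pc_crit <= 0)) {
    rlang::abort("pc_crit must be positive")
  }
  if (form == "pc_crit_times_bcf") {
    if (is.null(bcf) || any(!is.finite(bcf)) || any(bcf <= 0)) {
      rlang::abort("bcf must be positive for the pc_crit_times_bcf form")
    }
    pc_crit * bcf * MG_KG_TO_NG_G
  } else {
    pc_crit * MG_KG_TO_NG_G
  }
}

#' Internal effect unit (log10)
#'
#' The PC_crit-based analogue of [toxic_unit()] used to rank pharmaceuticals
#' lacking EC50 data: `log10(c_invert / denominator)` with the denominator
#' from [eu_denominator_ng_g()].
#'
#' @inheritParams eu_denominator_ng_g
#' @param c_invert tissue concentration (ng/g), > 0.
#' @return log10 effect unit, vectorised.
#' @export
effect_unit <- function(c_invert, pc_crit, bcf = NULL,
                        form = c("pc_crit_times_bcf", "pc_crit_only")) {
  if (any(c_invert <= 0, na.rm = TRUE)) rlang::abort("c_invert must be positive")
  log10(c_invert / eu_denominator_ng_g(pc_crit, bcf, form))
}

#' Sampler-as-organism pseudo-concentration
#'
#' Divides the contaminant mass accumulated on a sorbent disk by the disk
#' weight, yielding a ng/g value that can be substituted for the tissue
#' concentration in [toxic_unit()] and [effect_unit()] — treating the
#' sampler as if it were the organism.
#'
#' @param mass_ng mass on disk (ng), >= 0.
#' @param disk_mass_g disk weight in grams (default 0.0115 g for a 9 mm
#'   disk), > 0.
#' @return pseudo-concentration in ng/g.
#' @examples
#' psd_pseudo_concentration(6.7) # 6.7 ng on a 0.0115 g disk
#' @export
psd_pseudo_concentration <- function(mass_ng, disk_mass_g = 0.0115) {
  if (any(!is.finite(disk_mass_g)) || any(disk_mass_g <= 0)) {
    rlang::abort("disk_mass_g must be positive")
  }
  if (any(mass_ng < 0, na.rm = TRUE)) rlang::abort("mass_ng must be >= 0")
  mass_ng / disk_mass_g
}

.sorbent_of_matrix <- c(psd_hlb = "hlb", psd_anion = "anion", psd_cation = "cation")

compound_constants <- function(compounds) {
  tibble::tibble(
    compound_id = compounds$compound_id,
    chem_class = compounds$chem_class,
    pnec_ng_L = compounds$pnec_ng_L,
    ec50_ug_L = compounds$ec50_ug_L,
    pc_crit_mg_L = compounds$pc_crit_mg_L,
    bcf = purrr::map_dbl(compounds$bcf_candidates, function(b) {
      b <- b[!is.na(b) & b > 0]
      if (length(b) == 0) NA_real_ else max(b)
    }),
    rs_hlb = compounds$rs_hlb_L_day,
    rs_anion = compounds$rs_anion_L_day,
    rs_cation = compounds$rs_cation_L_day
  )
}

#' Monthly risk table across matrices
#'
#' For every quantifiable (compound, matrix, month) cell — replicates
#' averaged — computes the applicable risk metrics:
#' * `RQ` from water concentrations and from sampler TWA concentrations
#'   (sampler cells only where a sampling rate exists for that sorbent);
#' * `TU` (log10 internal toxic units) for pesticides with EC50 and BCF, from
#'   tissue concentrations and from sampler pseudo-concentrations;
#' * `EU` (log10 internal effect units) for pharmaceuticals with PC_crit,
#'   from tissue and sampler pseudo-concentrations.
#'
#' Censored observations contribute nothing. Compounds lacking the constants
#' for a metric are skipped and listed in the `"skipped"` attribute.
#'
#' @param measurements validated measurement tibble.
#' @param compounds compound table (see [read_compound_table()]).
#' @param thresholds a [risk_thresholds()] object.
#' @param deployment_days sampler deployment length in days (default 7).
#' @return tibble with columns `compound_id`, `matrix`, `month`, `metric`,
#'   `value`, `category` (RQ rows), `exceeds_tu_threshold` (TU rows), sorted
#'   by value descending within each metric.
#' @export
risk_table <- function(measurements, compounds, thresholds = risk_thresholds(),
                       deployment_days = 7) {
  cc <- compound_constants(compounds)
  cells <- measurements |>
    dplyr::filter(.data$censor == "quantified",
                  !.data$matrix %in% BLANK_MATRICES) |>
    dplyr::group_by(.data$compound_id, .data$matrix, .data$month) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::left_join(cc, by = "compound_id")
  if (nrow(cells) == 0) {
    out <- tibble::tibble(compound_id = character(0), matrix = character(0),
                          month = character(0), metric = character(0),
                          value = numeric(0),
                          category = factor(character(0), levels = RQ_CATEGORIES,
                                            ordered = TRUE),
                          exceeds_tu_threshold = logical(0))
    attr(out, "skipped") <- tibble::tibble(compound_id = character(0),
                                           matrix = character(0),
                                           reason = character(0))
    return(out)
  }

  skipped <- list()
  note_skip <- function(df, reason) {
    if (nrow(df) > 0) {
      skipped[[length(skipped) + 1]] <<- dplyr::distinct(
        tibble::tibble(compound_id = df$compound_id, matrix = df$matrix,
                       reason = reason))
    }
  }

  # aqueous concentration per cell: water directly, sampler via TWA
  aq <- cells |>
    dplyr::mutate(rs = dplyr::case_when(
      .data$matrix == "psd_hlb" ~ .data$rs_hlb,
      .data$matrix == "psd_anion" ~ .data$rs_anion,
      .data$matrix == "psd_cation" ~ .data$rs_cation,
      TRUE ~ NA_real_
    )) |>
    dplyr::filter(.data$matrix %in% c("water", PSD_MATRICES))
  note_skip(dplyr::filter(aq, .data$matrix %in% PSD_MATRICES, is.na(.data$rs)),
            "no Rs for sorbent")
  note_skip(dplyr::filter(aq, is.na(.data$pnec_ng_L)), "no PNEC")
  rq_rows <- aq |>
    dplyr::filter(!is.na(.data$pnec_ng_L),
                  .data$matrix == "water" | !is.na(.data$rs)) |>
    dplyr::mutate(
      conc = ifelse(.data$matrix == "water", .data$value,
                    .data$value / (.data$rs * deployment_days)),
      metric = "RQ",
      value = risk_quotient(.data$conc, .data$pnec_ng_L),
      category = classify_rq(.data$value, thresholds),
      exceeds_tu_threshold = NA
    )

  # tissue-scale concentration: biota directly, sampler via pseudo-conc
  tis <- cells |>
    dplyr::filter(.data$matrix %in% c("biota", PSD_MATRICES)) |>
    dplyr::mutate(conc = ifelse(.data$matrix == "biota", .data$value,
                                .data$value / thresholds$disk_mass_g)) |>
    dplyr::filter(.data$conc > 0)

  tu_in <- dplyr::filter(tis, .data$chem_class == "pesticide")
  note_skip(dplyr::filter(tu_in, is.na(.data$ec50_ug_L) | is.na(.data$bcf)),
            "no EC50/BCF for TU")
  tu_ok <- dplyr::filter(tu_in, !is.na(.data$ec50_ug_L), !is.na(.data$bcf))
  tu_rows <- tu_ok |>
    dplyr::mutate(
      metric = "TU",
      value = toxic_unit(.data$conc, internal_ec50(.data$ec50_ug_L, .data$bcf)),
      category = factor(NA_character_, levels = RQ_CATEGORIES, ordered = TRUE),
      exceeds_tu_threshold = .data$value > thresholds$tu_log_threshold
    )

  eu_in <- dplyr::filter(tis, .data$chem_class == "pharmaceutical")
  need_bcf <- thresholds$eu_form == "pc_crit_times_bcf"
  eu_bad <- dplyr::filter(eu_in, is.na(.data$pc_crit_mg_L) |
                            (need_bcf & is.na(.data$bcf)))
  note_skip(eu_bad, "no PC_crit/BCF for EU")
  eu_ok <- dplyr::filter(eu_in, !is.na(.data$pc_crit_mg_L),
                         !need_bcf | !is.na(.data$bcf))
  eu_rows <- eu_ok |>
    dplyr::mutate(
      metric = "EU",
      value = effect_unit(.data$conc, .data$pc_crit_mg_L, .data$bcf,
                          form = thresholds$eu_form),
      category = factor(NA_character_, levels = RQ_CATEGORIES, ordered = TRUE),
      exceeds_tu_threshold = NA
    )

  keep <- c("compound_id", "matrix", "month", "metric", "value", "category",
            "exceeds_tu_threshold")
  out <- dplyr::bind_rows(rq_rows[keep], tu_rows[keep], eu_rows[keep]) |>
    dplyr::mutate(metric = factor(.data$metric, levels = c("RQ", "TU", "EU"))) |>
    dplyr::arrange(.data$metric, dplyr::desc(.data$value))
  attr(out, "skipped") <- if (length(skipped) > 0) {
    dplyr::distinct(dplyr::bind_rows(skipped))
  } else {
    tibble::tibble(compound_id = character(0), matrix = character(0),
                   reason = character(0))
  }
  out
}

#' Summarise a risk table across months
#'
#' Mean and standard deviation of each metric per compound and matrix,
#' pooling the monthly values produced by [risk_table()].
#'
#' @param risk tibble from [risk_table()].
#' @return tibble with `compound_id`, `matrix`, `metric`, `mean`, `sd`, `n`.
#' @export
summarise_risk <- function(risk) {
  risk |>
    dplyr::group_by(.data$compound_id, .data$matrix, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     n = dplyr::n(), .groups = "drop")
}

#' Write a risk report as CSV plus a JSON summary
#'
#' @param risk tibble from [risk_table()].
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the summary list written to JSON.
#' @export
write_risk_report <- function(risk, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(risk, csv_path, progress = FALSE)
  summ <- summarise_risk(risk)
  payload <- list(
    n_results = nrow(risk),
    metrics = as.list(table(as.character(risk$metric))),
    rq_categories = as.list(table(as.character(risk$category[risk$metric == "RQ"]))),
    summary = summ
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(payload)
}
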