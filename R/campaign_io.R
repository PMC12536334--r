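# Reading, validation and writing of the tidy campaign tables. Every other
# module assumes the unit and censoring conventions enforced here.

MATRIX_LEVELS <- c(
  "water", "psd_hlb", "psd_anion", "psd_cation", "biota",
  "blank_field", "blank_extraction"
)

PSD_MATRICES <- c("psd_hlb", "psd_anion", "psd_cation")
BLANK_MATRICES <- c("blank_field", "blank_extraction")

CENSOR_LEVELS <- c("quantified", "detected_below_loq", "not_detected")

CHEM_CLASSES <- c(
  "pharmaceutical", "pesticide", "illicit", "transformation_product", "other"
)

SORBENTS <- c("hlb", "anion", "cation")

# alternate spellings accepted on read, mapped onto MATRIX_LEVELS
.matrix_aliases <- c(
  water = "water",
  hlb = "psd_hlb", psd_hlb = "psd_hlb", `mm-hlb` = "psd_hlb",
  anion = "psd_anion", psd_anion = "psd_anion", `mm-anion` = "psd_anion",
  mm_anion = "psd_anion",
  cation = "psd_cation", psd_cation = "psd_cation", `mm-cation` = "psd_cation",
  mm_cation = "psd_cation",
  biota = "biota", gammarus = "biota", g_pulex = "biota", invertebrate = "biota",
  blank_field = "blank_field", field_blank = "blank_field",
  blank_extraction = "blank_extraction", extraction_blank = "blank_extraction"
)

#' Measurement unit implied by a matrix label
#'
#' Water concentrations are ng/L, sorbent-disk loads ng/disk (blanks are disk
#' extracts and share that unit), and invertebrate tissue ng/g.
#'
#' @param matrix character vector of matrix labels (see [read_measurements()]).
#' @return character vector of unit strings.
#' @export
matrix_unit <- function(matrix) {
  unname(c(
    water = "ng/L",
    psd_hlb = "ng/disk", psd_anion = "ng/disk", psd_cation = "ng/disk",
    blank_field = "ng/disk", blank_extraction = "ng/disk",
    biota = "ng/g"
  )[matrix])
}

normalise_matrix <- function(x) {
  key <- stringr::str_replace_all(stringr::str_to_lower(stringr::str_trim(x)), " ", "_")
  out <- unname(.matrix_aliases[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    rlang::abort(paste0("unknown matrix label(s): ", paste(bad, collapse = ", ")))
  }
  out
}

parse_num_list <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(stringr::str_trim(s))) return(numeric(0))
    as.numeric(stringr::str_split_1(s, ";"))
  })
}

#' Read a compound-property table
#'
#' Reads the per-chemical constants that drive the risk computations: PNEC
#' (ng/L), EC50 (ug/L), candidate bioconcentration factors (L/kg,
#' semicolon-separated in one column), PC_crit (mg/L), per-sorbent sampling
#' rates Rs (L/day) and per-matrix LOD/LOQ. Expected columns (header row
#' mandatory, unknown columns ignored, all optional except `compound_id`):
#' `compound_id`, `name`, `chem_class`, `pnec_ng_L`, `ec50_ug_L`, `bcf_L_kg`,
#' `pc_crit_mg_L`, `rs_hlb_L_day`, `rs_anion_L_day`, `rs_cation_L_day`,
#' `lod_water`, `loq_water`, `lod_psd`, `loq_psd`, `lod_biota`, `loq_biota`
#' (LOD/LOQ in the unit of their matrix). Missing optional fields become `NA`
#' (empty `bcf_candidates`); they are tolerated here and handled downstream.
#'
#' @param path path to a UTF-8 comma-separated file.
#' @return a tibble with one row per compound; `bcf_candidates` is a
#'   list-column of numeric vectors.
#' @seealso [read_measurements()], [read_calibration_series()]
#' @export
read_compound_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"compound_id" %in% names(raw)) {
    rlang::abort("compound table must have a compound_id column")
  }
  if (nrow(raw) == 0) return(empty_compound_table())
  if (anyDuplicated(raw$compound_id)) {
    dup <- unique(raw$compound_id[duplicated(raw$compound_id)])
    rlang::abort(paste0("duplicate compound_id: ", paste(dup, collapse = ", ")))
  }

  num_cols <- c(
    "pnec_ng_L", "ec50_ug_L", "pc_crit_mg_L",
    "rs_hlb_L_day", "rs_anion_L_day", "rs_cation_L_day",
    "lod_water", "loq_water", "lod_psd", "loq_psd", "lod_biota", "loq_biota"
  )
  out <- tibble::tibble(
    compound_id = raw$compound_id,
    name = if ("name" %in% names(raw)) raw$name else raw$compound_id,
    chem_class = if ("chem_class" %in% names(raw)) raw$chem_class else "other"
  )
  bad_class <- setdiff(unique(out$chem_class[!is.na(out$chem_class)]), CHEM_CLASSES)
  if (length(bad_class) > 0) {
    rlang::abort(paste0("unknown chem_class: ", paste(bad_class, collapse = ", ")))
  }
  for (col in num_cols) {
    out[[col]] <- if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  out$bcf_candidates <- if ("bcf_L_kg" %in% names(raw)) {
    parse_num_list(raw$bcf_L_kg)
  } else {
    purrr::map(seq_len(nrow(raw)), ~ numeric(0))
  }

  # non-negativity of every concentration-like field, reported with row index
  for (col in num_cols) {
    bad <- which(!is.na(out[[col]]) & out[[col]] < 0)
    if (length(bad) > 0) {
      rlang::abort(paste0("negative ", col, " at row ", bad[1]))
    }
  }
  bad_bcf <- which(purrr::map_lgl(out$bcf_candidates, ~ any(.x < 0)))
  if (length(bad_bcf) > 0) {
    rlang::abort(paste0("negative bcf_L_kg at row ", bad_bcf[1]))
  }
  for (mx in c("water", "psd", "biota")) {
    lod <- out[[paste0("lod_", mx)]]
    loq <- out[[paste0("loq_", mx)]]
    bad <- which(!is.na(lod) & !is.na(loq) & loq < lod)
    if (length(bad) > 0) {
      rlang::abort(paste0("loq_", mx, " < lod_", mx, " at row ", bad[1]))
    }
  }
  out
}

empty_compound_table <- function() {
  tibble::tibble(
    compound_id = character(0), name = character(0), chem_class = character(0),
    pnec_ng_L = numeric(0), ec50_ug_L = numeric(0), pc_crit_mg_L = numeric(0),
    rs_hlb_L_day = numeric(0), rs_anion_L_day = numeric(0),
    rs_cation_L_day = numeric(0),
    lod_water = numeric(0), loq_water = numeric(0),
    lod_psd = numeric(0), loq_psd = numeric(0),
    lod_biota = numeric(0), loq_biota = numeric(0),
    bcf_candidates = list()
  )
}

#' Write a compound-property table
#'
#' Inverse of [read_compound_table()]: a written table read back reproduces
#' the records field for field (BCF candidates are re-joined with `;`).
#'
#' @param compounds tibble as returned by [read_compound_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(compounds, path) {
  out <- compounds
  out$bcf_L_kg <- purrr::map_chr(out$bcf_candidates, ~ paste(format(.x, digits = 15, scientific = FALSE, trim = TRUE), collapse = ";"))
  out$bcf_candidates <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a long-format measurement table
#'
#' One row per observation of a compound in a matrix at a timepoint. Expected
#' columns: `compound_id`, `matrix` (one of water, psd_hlb, psd_anion,
#' psd_cation, biota, blank_field, blank_extraction; common aliases and any
#' letter case accepted), `timepoint` (ISO `YYYY-MM` month or `YYYY-MM-DD`
#' date), `replicate` (integer), `value` (in the matrix unit: water ng/L,
#' sorbent disks ng/disk, tissue ng/g), and optionally `censor` (`quantified`,
#' `detected_below_loq`, `not_detected`; default `quantified`). A value must
#' be present if and only if the row is `quantified`. A derived `month`
#' column (`YYYY-MM`) is added.
#'
#' @param path path to a UTF-8 comma-separated file.
#' @return a tibble of validated measurements, in input order.
#' @export
read_measurements <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("compound_id", "matrix", "timepoint", "replicate", "value")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("measurement table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    compound_id = raw$compound_id,
    matrix = if (nrow(raw) > 0) normalise_matrix(raw$matrix) else character(0),
    timepoint = raw$timepoint,
    replicate = as.integer(raw$replicate),
    value = as.numeric(raw$value),
    censor = if ("censor" %in% names(raw)) {
      ifelse(is.na(raw$censor) | !nzchar(raw$censor), "quantified", raw$censor)
    } else {
      rep("quantified", nrow(raw))
    }
  )
  validate_measurements(tbl)
}

#' Validate a measurement tibble against the package conventions
#'
#' Applied automatically by [read_measurements()]; exported so synthetic or
#' hand-built tables can be checked the same way.
#'
#' @param tbl tibble with columns `compound_id`, `matrix`, `timepoint`,
#'   `replicate`, `value`, `censor`.
#' @return the validated tibble with a derived `month` column.
#' @export
validate_measurements <- function(tbl) {
  bad_censor <- setdiff(unique(tbl$censor), CENSOR_LEVELS)
  if (length(bad_censor) > 0) {
    rlang::abort(paste0("unknown censor flag(s): ", paste(bad_censor, collapse = ", ")))
  }
  bad_matrix <- setdiff(unique(tbl$matrix), MATRIX_LEVELS)
  if (length(bad_matrix) > 0) {
    rlang::abort(paste0("unknown matrix label(s): ", paste(bad_matrix, collapse = ", ")))
  }
  q <- tbl$censor == "quantified"
  if (any(q & is.na(tbl$value))) {
    rlang::abort(paste0("quantified measurement with missing value at row ",
                        which(q & is.na(tbl$value))[1]))
  }
  if (any(!q & !is.na(tbl$value))) {
    rlang::abort(paste0("censored measurement must not carry a value (row ",
                        which(!q & !is.na(tbl$value))[1], ")"))
  }
  if (any(!is.na(tbl$value) & tbl$value < 0)) {
    rlang::abort(paste0("negative value at row ",
                        which(!is.na(tbl$value) & tbl$value < 0)[1]))
  }
  tbl$month <- stringr::str_sub(tbl$timepoint, 1, 7)
  tbl
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]; the derived `month` column is dropped on
#' write and recomputed on read, so a round trip is the identity.
#'
#' @param measurements validated measurement tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements[, c("compound_id", "matrix", "timepoint", "replicate",
                          "value", "censor")]
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a laboratory calibration time series
#'
#' Expected columns: `compound_id`, `sorbent` (hlb/anion/cation),
#' `time_days`, `mass_ng`, `c_lab_ng_L` (the constant lab water
#' concentration).
#'
#' @param path path to a comma-separated file.
#' @return tibble of calibration points.
#' @export
read_calibration_series <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           compound_id = readr::col_character(),
                           sorbent = readr::col_character(),
                           time_days = readr::col_double(),
                           mass_ng = readr::col_double(),
                           c_lab_ng_L = readr::col_double()
                         ))
  bad <- setdiff(unique(tbl$sorbent), SORBENTS)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown sorbent: ", paste(bad, collapse = ", ")))
  }
  if (any(tbl$c_lab_ng_L <= 0)) rlang::abort("c_lab_ng_L must be positive")
  if (any(tbl$mass_ng < 0)) rlang::abort("negative mass_ng")
  tbl
}

#' Read a deployment record table
#'
#' Expected columns: `sorbent` (hlb/anion/cation), `start`, `end` (ISO
#' dates) and `duration_days`. The stated duration must be positive and
#' agree with `end - start`.
#'
#' @param path path to a comma-separated file.
#' @return tibble of deployment records with `Date` columns.
#' @export
read_deployments <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           sorbent = readr::col_character(),
                           start = readr::col_date(),
                           end = readr::col_date(),
                           duration_days = readr::col_double()
                         ))
  bad <- setdiff(unique(tbl$sorbent), SORBENTS)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown sorbent: ", paste(bad, collapse = ", ")))
  }
  if (any(tbl$duration_days <= 0)) rlang::abort("duration_days must be positive")
  mismatch <- which(as.numeric(tbl$end - tbl$start) != tbl$duration_days)
  if (length(mismatch) > 0) {
    rlang::abort(paste0("end - start disagrees with duration_days at row ",
                        mismatch[1]))
  }
  tbl
}

#' Remove compound-months affected by blank contamination
#'
#' Field or extraction blanks showing a quantified signal above the
#' compound's detection limit indicate contamination; the affected compound
#' is then removed from that month's dataset across all matrices. Blanks with
#' `detected_below_loq` or `not_detected` flags never trigger exclusion.
#' Field and extraction blanks are treated identically. The comparison uses
#' the compound's `lod_psd` when a compound table is supplied (blanks are
#' disk extracts); without a compound table (or without an LOD) any
#' quantified positive blank triggers exclusion, the most conservative
#' reading.
#'
#' @param measurements validated measurement tibble; may itself contain the
#'   blank rows.
#' @param blanks optional tibble of blank measurements (matrix `blank_field`
#'   or `blank_extraction`). If `NULL`, blank rows are taken from
#'   `measurements`.
#' @param compounds optional compound table providing `lod_psd`.
#' @return the filtered measurements (blank rows retained so the operation is
#'   idempotent), with the exclusion log as attribute `"exclusion_log"`; see
#'   [exclusion_log()].
#' @export
apply_blank_exclusion <- function(measurements, blanks = NULL, compounds = NULL) {
  if (is.null(blanks)) {
    blanks <- dplyr::filter(measurements, .data$matrix %in% BLANK_MATRICES)
  }
  if (!"month" %in% names(blanks) && nrow(blanks) > 0) {
    blanks$month <- stringr::str_sub(blanks$timepoint, 1, 7)
  }
  hits <- dplyr::filter(blanks, .data$censor == "quantified")
  if (nrow(hits) > 0 && !is.null(compounds)) {
    lods <- tibble::tibble(compound_id = compounds$compound_id,
                           .lod = compounds$lod_psd)
    hits <- dplyr::left_join(hits, lods, by = "compound_id")
    hits$.lod[is.na(hits$.lod)] <- 0
    hits <- dplyr::filter(hits, .data$value > .data$.lod)
  } else if (nrow(hits) > 0) {
    hits <- dplyr::filter(hits, .data$value > 0)
  }
  log <- dplyr::distinct(
    dplyr::select(hits, "compound_id", "month", blank_matrix = "matrix")
  )
  pairs <- dplyr::distinct(log[, c("compound_id", "month")])
  keep_blank <- measurements$matrix %in% BLANK_MATRICES
  flagged <- paste(measurements$compound_id, measurements$month) %in%
    paste(pairs$compound_id, pairs$month)
  out <- measurements[keep_blank | !flagged, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log left by [apply_blank_exclusion()]
#'
#' @param measurements tibble returned by [apply_blank_exclusion()].
#' @return tibble with columns `compound_id`, `month`, `blank_matrix` (empty
#'   if nothing was excluded).
#' @export
exclusion_log <- function(measurements) {
  log <- attr(measurements, "exclusion_log")
  if (is.null(log)) {
    log <- tibble::tibble(compound_id = character(0), month = character(0),
                          blank_matrix = character(0))
  }
  log
}
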