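# Canonical internal units used throughout the package:
#   aqueous concentration  ng/L      (water, TWA, PNEC, MEC)
#   disk load              ng/disk   (passive sampler sorbents)
#   tissue concentration   ng/g      (invertebrate biota)
#   EC50                   ug/L
#   PC_crit                mg/L
#   BCF                    L/kg
#   sampling rate Rs       L/day
# All conversions are exact powers of ten and live here, nowhere else.

#' Unit conversion constants
#'
#' Named powers-of-ten constants linking the canonical units used across the
#' package. `MG_L_TO_NG_L` converts mg/L to ng/L (x 1e6), `UG_L_TO_NG_L`
#' converts ug/L to ng/L (x 1e3), and `MG_KG_TO_NG_G` converts mg/kg to ng/g
#' (x 1e3; 1 mg/kg = 1 ug/g = 1000 ng/g). The product EC50 \[ug/L\] x BCF
#' \[L/kg\] is ug/kg, numerically equal to ng/g, so no constant is needed for
#' the internal EC50; the product PC_crit \[mg/L\] x BCF \[L/kg\] is mg/kg and
#' needs `MG_KG_TO_NG_G` to land on the tissue scale.
#'
#' @name unit-constants
#' @examples
#' 6.4e-6 * MG_L_TO_NG_L # PC_crit of 6.4e-6 mg/L expressed in ng/L
NULL

#' @rdname unit-constants
#' @export
MG_L_TO_NG_L <- 1e6

#' @rdname unit-constants
#' @export
UG_L_TO_NG_L <- 1e3

#' @rdname unit-constants
#' @export
MG_KG_TO_NG_G <- 1e3

#' Express a PC_crit value (mg/L) on the aqueous ng/L scale
#'
#' @param pc_crit_mg_L numeric, critical environmental concentration in mg/L.
#' @return numeric, the same concentration in ng/L.
#' @export
pc_crit_as_ng_L <- function(pc_crit_mg_L) pc_crit_mg_L * MG_L_TO_NG_L

#' Express an EC50 value (ug/L) on the aqueous ng/L scale
#'
#' @param ec50_ug_L numeric, median effect concentration in ug/L.
#' @return numeric, the same concentration in ng/L.
#' @export
ec50_as_ng_L <- function(ec50_ug_L) ec50_ug_L * UG_L_TO_NG_L
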