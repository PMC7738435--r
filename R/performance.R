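# Elemental composition of the supported fermentation products (CnHaOb).
# ThOD is derived from full-oxidation stoichiometry rather than hard-coded:
#   CnHaOb + (n + a/4 - b/2) O2 -> n CO2 + a/2 H2O
# using nominal atomic masses (C 12, H 1, O 16), the convention under which
# acetate's factor is exactly 64/60 g COD per g acid.
.vfa_formulas <- list(
  acetic      = c(C = 2, H = 4,  O = 2),
  propionic   = c(C = 3, H = 6,  O = 2),
  butyric     = c(C = 4, H = 8,  O = 2),
  isobutyric  = c(C = 4, H = 8,  O = 2),
  ethanol     = c(C = 2, H = 6,  O = 1),
  propanol    = c(C = 3, H = 8,  O = 1),
  isopropanol = c(C = 3, H = 8,  O = 1),
  butanol     = c(C = 4, H = 10, O = 1)
)

#' Theoretical oxygen demand factor of a fermentation product
#'
#' Grams of COD (O2) per gram of compound, from the balanced full-oxidation
#' reaction CnHaOb + (n + a/4 - b/2) O2 -> n CO2 + a/2 H2O.
#'
#' @param compound one of acetic, propionic, butyric, isobutyric, ethanol,
#'   propanol, isopropanol, butanol.
#' @return numeric factor \[g COD / g compound\].
#' @examples
#' thod_factor("acetic")     # 64/60
#' thod_factor("propionic")  # 112/74
#' @export
thod_factor <- function(compound) {
  f <- .vfa_formulas[[compound]]
  if (is.null(f))
    stop("unknown compound '", compound, "'; supported: ",
         paste(names(.vfa_formulas), collapse = ", "))
  mw <- 12 * f[["C"]] + 1 * f[["H"]] + 16 * f[["O"]]
  o2 <- f[["C"]] + f[["H"]] / 4 - f[["O"]] / 2
  32 * o2 / mw
}

#' Volatile fatty acids and alcohols as COD
#'
#' Converts per-component concentrations \[mg/L as the compound\] to COD
#' equivalents \[mg COD/L\] via theoretical oxygen demand, and totals them.
#' Measurements already expressed in COD units pass through unchanged with
#' `as_cod = TRUE`.
#'
#' @param components named numeric vector, names drawn from the compounds
#'   supported by [thod_factor]; concentrations in mg/L (or mg COD/L when
#'   `as_cod = TRUE`). May be empty.
#' @param as_cod if `TRUE`, inputs are already COD-based (factor 1).
#' @return list with `total` \[mg COD/L\] and `per_component` (named numeric,
#'   mg COD/L).
#' @examples
#' vfa_as_cod(c(acetic = 100))$total  # 106.67 mg COD/L
#' @export
vfa_as_cod <- function(components = numeric(), as_cod = FALSE) {
  if (length(components) == 0)
    return(list(total = 0, per_component = numeric()))
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be named by compound")
  if (any(components < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(components), names(.vfa_formulas))
  if (length(unknown) > 0)
    stop("unknown component(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(.vfa_formulas), collapse = ", "))
  factors <- if (as_cod) rep(1, length(components)) else
    vapply(names(components), thod_factor, numeric(1L))
  per <- components * factors
  list(total = sum(per), per_component = per)
}

#' Solid removal efficiency
#'
#' Fraction of feed volatile suspended solids removed across the reactor:
#' (VSS_in - VSS_out) / VSS_in. A net accumulation of solids (VSS_out >
#' VSS_in) yields a negative efficiency, which is reported with a warning
#' rather than clipped.
#'
#' @param vss_in feed VSS concentration \[g/L\]; must be > 0.
#' @param vss_out effluent VSS concentration \[g/L\].
#' @return fraction removed (may be negative).
#' @export
solid_removal <- function(vss_in, vss_out) {
  if (!is.numeric(vss_in) || vss_in <= 0)
    stop("vss_in must be > 0")
  if (vss_out < 0) stop("vss_out must be >= 0")
  eff <- (vss_in - vss_out) / vss_in
  if (eff < 0)
    warning("vss_out exceeds vss_in: negative solid removal ", signif(eff, 3))
  eff
}

#' Methane yield per gram of volatile solids fed
#'
#' @param ch4_cumulative cumulative CH4 produced \[mmol\].
#' @param vs_fed_total total volatile solids fed over the run \[g VS\];
#'   see [vs_fed_total] to derive it from the feeding schedule.
#' @return yield \[mmol CH4 / g VS fed\].
#' @export
ch4_yield <- function(ch4_cumulative, vs_fed_total) {
  if (!is.numeric(vs_fed_total) || vs_fed_total <= 0)
    stop("vs_fed_total must be > 0")
  if (ch4_cumulative < 0) stop("ch4_cumulative must be >= 0")
  ch4_cumulative / vs_fed_total
}

#' Total volatile solids fed by a semi-continuous schedule
#'
#' Sum over feeding events of event volume times feed VSS concentration:
#' n_events * exchange_volume \[mL\] * Cf \[g/L\] / 1000.
#'
#' @param cfg a [reactor_config] with `Cf` set.
#' @param n_events number of feeding events.
#' @return grams of volatile solids fed.
#' @examples
#' vs_fed_total(reactor_config(150, 3, 2, Cf = 6.2), 15)  # 0.279 g
#' @export
vs_fed_total <- function(cfg, n_events) {
  stopifnot(inherits(cfg, "reactor_config"), n_events >= 0)
  if (is.na(cfg$Cf)) stop("feed VSS concentration Cf is not set")
  n_events * cfg$exchange_volume * cfg$Cf / 1000
}
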