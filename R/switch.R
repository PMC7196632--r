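#' Parameters of the PII/NadE2 regulatory-switch model
#'
#' Collects the measured constants that drive the integrated model of
#' NadE2 activity: the PII-NadE2 complex dissociation constant, the
#' 2-oxoglutarate half-effect constants for the two regimes (blocking
#' complex formation versus dissociating a pre-formed complex), and the
#' NAD+ feedback-inhibition curves of the free enzyme (hyperbolic) and
#' the PII-bound enzyme (sigmoidal/Hill).
#'
#' Defaults are the constants measured for the GlnZ-AbNadE2 pair with
#' MgATP: `Kd_complex = 0.3` uM (0.15 with ADP), `K_OG_forming = 15.5`
#' uM, `K_OG_preformed = 1000` uM (1 mM), free-enzyme `Ki = 1` mM with
#' `Imax = 1`, complexed-enzyme `IC50 = 2.5` mM with Hill `n = 2.2`.
#'
#' @param Kd_complex PII-NadE2 dissociation constant, uM (trimer/dimer).
#' @param K_OG_forming 2-OG half-effect on complex formation, uM.
#' @param K_OG_preformed 2-OG half-effect on a pre-formed complex, uM.
#' @param Ki_free NAD+ half-inhibition constant of the free enzyme, mM.
#' @param Imax_free Maximum fractional inhibition of the free enzyme.
#' @param IC50_complex NAD+ IC50 of the PII-bound enzyme, mM.
#' @param n_complex Hill coefficient of the PII-bound enzyme.
#' @param Imax_complex Maximum fractional inhibition of the bound enzyme.
#' @return A `switch_params` list.
#' @export
switch_params <- function(Kd_complex = 0.3, K_OG_forming = 15.5,
                          K_OG_preformed = 1000, Ki_free = 1,
                          Imax_free = 1, IC50_complex = 2.5,
                          n_complex = 2.2, Imax_complex = 1) {
  stopifnot(
    Kd_complex > 0, K_OG_forming > 0, K_OG_preformed > 0,
    Ki_free > 0, IC50_complex > 0, n_complex > 0
  )
  if (!(K_OG_forming < K_OG_preformed)) {
    stop("K_OG_forming must be smaller than K_OG_preformed")
  }
  structure(
    list(
      Kd_complex = Kd_complex, K_OG_forming = K_OG_forming,
      K_OG_preformed = K_OG_preformed, Ki_free = Ki_free,
      Imax_free = Imax_free, IC50_complex = IC50_complex,
      n_complex = n_complex, Imax_complex = Imax_complex
    ),
    class = "switch_params"
  )
}

#' Metabolic state fed to the switch model
#'
#' @param NAD NAD+ concentration, mM.
#' @param PII_total Total PII, uM trimer.
#' @param NadE_total Total NadE2, uM dimer.
#' @param OG 2-oxoglutarate, uM.
#' @param urid_fraction Fraction of PII trimers uridylylated, in
#'   `[0, 1]`; uridylylated PII does not bind NadE2.
#' @param history `"forming"` (complex forms in the presence of the
#'   stated 2-OG) or `"preformed"` (complex assembled before 2-OG rose).
#' @return A `hub_state` list.
#' @export
hub_state <- function(NAD = 0, PII_total = 0, NadE_total = 0.1, OG = 0,
                      urid_fraction = 0,
                      history = c("forming", "preformed")) {
  history <- match.arg(history)
  stopifnot(
    NAD >= 0, PII_total >= 0, NadE_total >= 0, OG >= 0,
    urid_fraction >= 0, urid_fraction <= 1
  )
  structure(
    list(
      NAD = NAD, PII_total = PII_total, NadE_total = NadE_total,
      OG = OG, urid_fraction = urid_fraction, history = history
    ),
    class = "hub_state"
  )
}

#' PII available for NadE2 binding
#'
#' Uridylylation removes PII from the NadE2-binding pool:
#' `PII_total * (1 - urid_fraction)`.
#'
#' @param state A [hub_state()].
#' @return Available PII, uM trimer.
#' @export
available_pii <- function(state) {
  state$PII_total * (1 - state$urid_fraction)
}

#' History-dependent effective dissociation constant
#'
#' 2-oxoglutarate weakens the PII-NadE2 interaction as a competitive
#' effector: `Kd_eff = Kd_complex * (1 + OG / K_OG)`, where `K_OG` is the
#' formation-regime constant when the complex still has to assemble and
#' the (much larger) pre-formed-regime constant once it exists. This
#' asymmetry is the source of the model's memory effect.
#'
#' @param params A [switch_params()].
#' @param OG 2-oxoglutarate, uM (vectorized).
#' @param history `"forming"` or `"preformed"`.
#' @return Effective Kd in uM.
#' @export
effective_kd <- function(params, OG, history = c("forming", "preformed")) {
  history <- match.arg(history)
  stopifnot(all(OG >= 0))
  k_og <- if (history == "forming") {
    params$K_OG_forming
  } else {
    params$K_OG_preformed
  }
  params$Kd_complex * (1 + OG / k_og)
}

#' Fraction of NadE2 bound in the PII complex
#'
#' Exact tight-binding (quadratic) solution for 1 trimer : 1 dimer
#' binding, valid when concentrations are comparable to Kd:
#' `f = ((P + N + Kd) - sqrt((P + N + Kd)^2 - 4 P N)) / (2 N)`.
#'
#' @param PII_avail Available PII, uM trimer (vectorized).
#' @param NadE_total Total NadE2, uM dimer.
#' @param Kd_eff Effective dissociation constant, uM.
#' @return Complexed fraction of NadE2, in `[0, 1]`; 0 when
#'   `NadE_total = 0`.
#' @export
complex_fraction <- function(PII_avail, NadE_total, Kd_eff) {
  stopifnot(all(PII_avail >= 0), all(NadE_total >= 0), all(Kd_eff >= 0))
  s <- PII_avail + NadE_total + Kd_eff
  disc <- pmax(s^2 - 4 * PII_avail * NadE_total, 0)
  f <- ifelse(
    NadE_total == 0, 0,
    (s - sqrt(disc)) / (2 * NadE_total)
  )
  pmin(pmax(f, 0), 1)
}

#' Predicted NadE2 activity under the two-state switch model
#'
#' The enzyme population is split into a PII-bound fraction `f` (from the
#' tight-binding quadratic at the history-dependent effective Kd) and a
#' free fraction `1 - f`. Each state follows its measured NAD+
#' feedback-inhibition curve — sigmoidal (Hill) for the complex,
#' hyperbolic for the free enzyme — and the observed activity is the
#' linear mixture:
#' `activity = f * hill(NAD) + (1 - f) * hyperbola(NAD)`,
#' in percent of the NAD+-free activity.
#'
#' @param state A [hub_state()].
#' @param params A [switch_params()].
#' @return One-row tibble: `activity` (percent), `complex_fraction`,
#'   `Kd_eff` (uM), `PII_avail` (uM).
#' @examples
#' predicted_activity(
#'   hub_state(NAD = 2.5, PII_total = 2, NadE_total = 0.1),
#'   switch_params()
#' )
#' @export
predicted_activity <- function(state, params = switch_params()) {
  p_avail <- available_pii(state)
  kd <- effective_kd(params, state$OG, state$history)
  f <- complex_fraction(p_avail, state$NadE_total, kd)
  act_complex <- evaluate_model(
    "hill_inhibition",
    c(
      v0 = 100, Imax = params$Imax_complex,
      IC50 = params$IC50_complex, n = params$n_complex
    ),
    list(I = state$NAD)
  )
  act_free <- evaluate_model(
    "hyperbolic_inhibition",
    c(v0 = 100, Imax = params$Imax_free, Ki = params$Ki_free),
    list(I = state$NAD)
  )
  activity <- f * act_complex + (1 - f) * act_free
  tibble::tibble(
    activity = min(max(activity, 0), 100),
    complex_fraction = f, Kd_eff = kd, PII_avail = p_avail
  )
}

#' Hysteresis scan of activity versus 2-oxoglutarate
#'
#' Scans predicted activity over a 2-OG grid in both directions. The
#' ascending branch starts from a complex assembled at low 2-OG and uses
#' the pre-formed regime (complexes resist rising 2-OG); the descending
#' branch describes de novo complex formation at each 2-OG level and uses
#' the forming regime. The gap between the branches is the memory effect;
#' its enclosed area is positive for 2-OG between the two half-effect
#' constants.
#'
#' @param state A [hub_state()] template; its `OG` and `history` fields
#'   are overridden by the scan.
#' @param params A [switch_params()].
#' @param og_grid Ascending numeric grid of 2-OG concentrations, uM.
#' @return A tibble with columns `OG`, `branch` (`"ascending"` /
#'   `"descending"`), `activity`, `complex_fraction`.
#' @export
hysteresis_scan <- function(state, params = switch_params(),
                            og_grid = c(0, 10^seq(0, 4, length.out = 40))) {
  if (length(og_grid) == 0) stop("empty 2-OG grid")
  og_grid <- sort(og_grid)
  one <- function(og, hist, branch) {
    st <- state
    st$OG <- og
    st$history <- hist
    r <- predicted_activity(st, params)
    tibble::tibble(
      OG = og, branch = branch, activity = r$activity,
      complex_fraction = r$complex_fraction
    )
  }
  asc <- purrr::map_dfr(og_grid, one, hist = "preformed", branch = "ascending")
  desc <- purrr::map_dfr(
    rev(og_grid), one,
    hist = "forming", branch = "descending"
  )
  dplyr::bind_rows(asc, desc)
}

#' Area enclosed by a hysteresis loop
#'
#' Trapezoidal area between the ascending and descending activity
#' branches of a [hysteresis_scan()], on a log10 2-OG axis (zero points
#' dropped).
#'
#' @param scan Output of [hysteresis_scan()].
#' @return Non-negative scalar (percent-activity x log10-uM units).
#' @export
hysteresis_area <- function(scan) {
  asc <- scan[scan$branch == "ascending" & scan$OG > 0, ]
  desc <- scan[scan$branch == "descending" & scan$OG > 0, ]
  desc <- desc[order(desc$OG), ]
  stopifnot(nrow(asc) == nrow(desc), all(asc$OG == desc$OG))
  gap <- asc$activity - desc$activity
  x <- log10(asc$OG)
  sum(diff(x) * (gap[-1] + gap[-length(gap)]) / 2)
}
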