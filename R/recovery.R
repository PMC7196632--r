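#' Reference simulate-then-fit recovery studies
#'
#' Runs one of the package's reference parameter-recovery studies: data
#' are simulated at a fixed assay-like design from the measured constant
#' as ground truth, refit, and the median recovered values over
#' `n_seeds` seeded replicates are returned. These studies are how the
#' package demonstrates that each fitting route recovers the constants
#' the models are built around.
#'
#' Scenarios (constants in brackets are the generating truths):
#' \describe{
#'   \item{`ki_free`}{NAD+ feedback inhibition of the free enzyme:
#'     hyperbolic inhibition (v0 = 100, Imax = 1, Ki = 1 mM), 8 NAD+
#'     levels 0-10 mM, triplicate, 3% CV. Returns `Ki` (mM).}
#'   \item{`ic50_complex`}{NAD+ inhibition of the PII-bound enzyme:
#'     Hill model (IC50 = 2.5 mM, n = 2.2), same design. Returns `IC50`
#'     (mM) and `n`.}
#'   \item{`kact`}{Relief of NAD+ inhibition by PII titration:
#'     hyperbolic activation (floor 17%, ceiling 50%, Kact = 0.64 uM
#'     trimer) at 0, 0.25, 1, 2, 4, 10 uM, triplicate, 3% CV. Returns
#'     `Kact_nM`.}
#'   \item{`og_forming`}{2-OG blocking complex formation: effector
#'     model (B = 50, T = 100 percent inhibition, K_E = 15.5 uM), 8
#'     levels 0-480 uM, triplicate, 5% CV. Returns `K_OG_uM`.}
#'   \item{`og_preformed`}{2-OG dissociating a pre-formed complex:
#'     same model with K_E = 1000 uM over 0-5 mM. Returns `K_OG_uM`.}
#'   \item{`vmax_nad`}{Substrate saturation under 1 mM NAD+:
#'     Michaelis-Menten (Vmax = 0.04 umol/s, Km = 0.2 mM), 8 substrate
#'     levels 0.1-10x Km, triplicate, 3% CV. Returns `Vmax` (umol/s).}
#'   \item{`bli_rates`}{Global 1:1 sensorgram fit: kON = 9.09e4
#'     M-1 s-1, kOFF = 2.72e-2 s-1, Rmax = 2 nm, analyte 30-2000 nM,
#'     150 s association / 300 s dissociation, 0.02 nm noise. Returns
#'     `kON` and `kOFF`.}
#' }
#'
#' @param scenario Scenario name (see Details).
#' @param n_seeds Number of seeded replicates (default 50).
#' @param seed Global seed, fanned out by [substream_seed()].
#' @param n_starts Optimizer starts per fit.
#' @return Named numeric vector of median recovered values, with the
#'   generating truth attached as the `"truth"` attribute.
#' @export
recovery_study <- function(scenario = c(
                             "ki_free", "ic50_complex", "kact",
                             "og_forming", "og_preformed", "vmax_nad",
                             "bli_rates"
                           ),
                           n_seeds = 50, seed = 1, n_starts = 10) {
  scenario <- match.arg(scenario)
  nad_levels <- c(0, 0.25, 0.5, 1, 2, 4, 7, 10)
  run <- switch(scenario,
    ki_free = list(
      truth = c(Ki = 1),
      fn = function(s) {
        d <- sim_dose_response(
          "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
          nad_levels,
          noise_cv = 0.03, replicates = 3, seed = s
        )
        f <- fit_model(d, "hyperbolic_inhibition",
          fixed = c(Imax = 1), n_starts = n_starts, seed = s
        )
        c(Ki = unname(f$estimates[["Ki"]]))
      }
    ),
    ic50_complex = list(
      truth = c(IC50 = 2.5, n = 2.2),
      fn = function(s) {
        d <- sim_dose_response(
          "hill_inhibition",
          c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
          nad_levels,
          noise_cv = 0.03, replicates = 3, seed = s
        )
        f <- fit_model(d, "hill_inhibition",
          fixed = c(Imax = 1), n_starts = n_starts, seed = s
        )
        c(
          IC50 = unname(f$estimates[["IC50"]]),
          n = unname(f$estimates[["n"]])
        )
      }
    ),
    kact = list(
      truth = c(Kact_nM = 640),
      fn = function(s) {
        d <- sim_dose_response(
          "hyperbolic_activation",
          c(v_floor = 17, v_ceil = 50, Kact = 0.64),
          c(0, 0.25, 1, 2, 4, 10),
          noise_cv = 0.03, replicates = 3, seed = s
        )
        f <- fit_model(d, "hyperbolic_activation",
          n_starts = n_starts, seed = s
        )
        c(Kact_nM = unname(f$estimates[["Kact"]]) * 1000)
      }
    ),
    og_forming = list(
      truth = c(K_OG_uM = 15.5),
      fn = function(s) {
        d <- sim_dose_response(
          "effector_inhibition", c(B = 50, T = 100, K_E = 15.5),
          c(0, 5, 10, 20, 40, 80, 160, 480),
          noise_cv = 0.05, replicates = 3, seed = s
        )
        f <- fit_model(d, "effector_inhibition",
          n_starts = n_starts, seed = s
        )
        c(K_OG_uM = unname(f$estimates[["K_E"]]))
      }
    ),
    og_preformed = list(
      truth = c(K_OG_uM = 1000),
      fn = function(s) {
        d <- sim_dose_response(
          "effector_inhibition", c(B = 50, T = 100, K_E = 1000),
          c(0, 100, 250, 500, 1000, 2000, 3500, 5000),
          noise_cv = 0.05, replicates = 3, seed = s
        )
        f <- fit_model(d, "effector_inhibition",
          n_starts = n_starts, seed = s
        )
        c(K_OG_uM = unname(f$estimates[["K_E"]]))
      }
    ),
    vmax_nad = list(
      truth = c(Vmax = 0.04),
      fn = function(s) {
        km <- 0.2
        d <- sim_dose_response(
          "michaelis_menten", c(Vmax = 0.04, Km = km),
          km * c(0.1, 0.25, 0.5, 1, 2, 4, 7, 10),
          noise_cv = 0.03, replicates = 3, seed = s
        )
        f <- fit_model(d, "michaelis_menten",
          n_starts = n_starts, seed = s
        )
        c(Vmax = unname(f$estimates[["Vmax"]]))
      }
    ),
    bli_rates = list(
      truth = c(kON = 9.09e4, kOFF = 2.72e-2),
      fn = function(s) {
        sg <- sim_sensorgrams(
          binding_params(9.09e4, 2.72e-2, Rmax = 2),
          concentrations = c(30, 100, 300, 1000, 2000),
          noise_sd = 0.02, seed = s
        )
        f <- fit_binding_global(sg, "one_to_one",
          n_starts = min(n_starts, 4), seed = s
        )
        c(kON = f$params$kON, kOFF = f$params$kOFF)
      }
    )
  )
  out <- recovery_medians(run$fn, n_seeds = n_seeds, seed = seed)
  attr(out, "truth") <- run$truth
  out
}
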