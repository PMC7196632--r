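#' Rate and dose-response model specifications
#'
#' A `rate_model_spec` describes one of the closed-form rate / dose-response
#' models used throughout the kinetics analyses: its ordered parameter
#' names, default box bounds for fitting, and the predictor variables it
#' expects.
#'
#' Available models:
#' \describe{
#'   \item{`michaelis_menten`}{`v = Vmax * S / (Km + S)`; predictor `S`.}
#'   \item{`noncompetitive_mm`}{`v = Vmax / (1 + I/Ki) * S / (Km + S)`;
#'     predictors `S`, `I`. The noncompetitive form: inhibitor lowers the
#'     apparent Vmax, leaves Km untouched.}
#'   \item{`hyperbolic_inhibition`}{`v = v0 * (1 - Imax * I / (Ki + I))`;
#'     predictor `I`. `Imax` is the maximum fractional inhibition
#'     (`Imax = 1` means full inhibition at saturating inhibitor).}
#'   \item{`hill_inhibition`}{`v = v0 * (1 - Imax * I^n / (IC50^n + I^n))`;
#'     predictor `I`. Reduces exactly to the hyperbola at `n = 1`.}
#'   \item{`hyperbolic_activation`}{`v = v_floor + (v_ceil - v_floor) *
#'     A / (Kact + A)`; predictor `A`.}
#'   \item{`effector_inhibition`}{percent inhibition versus an effector:
#'     `f = B + (T - B) * E / (K_E + E)`; predictor `E`.}
#' }
#'
#' `Ki` and `IC50` are empirical half-effect constants of the respective
#' curve, not mechanistic dissociation constants.
#'
#' @param model_id One of `"michaelis_menten"`, `"noncompetitive_mm"`,
#'   `"hyperbolic_inhibition"`, `"hill_inhibition"`,
#'   `"hyperbolic_activation"`, `"effector_inhibition"`.
#' @param bounds Optional named list overriding default per-parameter
#'   `c(lo, hi)` bounds.
#' @return An object of class `rate_model_spec` with elements `model_id`,
#'   `parameter_names`, `predictor_names`, `bounds` and the model function.
#' @examples
#' spec <- rate_model("hyperbolic_inhibition")
#' evaluate_model(spec, c(v0 = 100, Imax = 1, Ki = 1), list(I = 1))
#' @export
rate_model <- function(model_id, bounds = NULL) {
  defs <- .rate_model_defs()
  model_id <- match.arg(model_id, names(defs))
  def <- defs[[model_id]]
  b <- def$bounds
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), def$parameter_names)
    if (length(bad) > 0) {
      stop("unknown parameter(s) in bounds: ", paste(bad, collapse = ", "))
    }
    b[names(bounds)] <- bounds
  }
  for (nm in names(b)) {
    lohi <- b[[nm]]
    if (length(lohi) != 2 || !all(is.finite(lohi)) || lohi[1] >= lohi[2]) {
      stop("bounds for ", nm, " must be finite with lo < hi")
    }
  }
  structure(
    list(
      model_id = model_id,
      parameter_names = def$parameter_names,
      predictor_names = def$predictor_names,
      bounds = b,
      fn = def$fn,
      positive = def$positive
    ),
    class = "rate_model_spec"
  )
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat("<rate_model_spec> ", x$model_id, "\n",
    "  parameters: ", paste(x$parameter_names, collapse = ", "), "\n",
    "  predictors: ", paste(x$predictor_names, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

.rate_model_defs <- function() {
  list(
    michaelis_menten = list(
      parameter_names = c("Vmax", "Km"),
      predictor_names = "S",
      positive = c("Vmax", "Km"),
      bounds = list(Vmax = c(1e-8, 1e4), Km = c(1e-6, 1e4)),
      fn = function(p, d) p[["Vmax"]] * d$S / (p[["Km"]] + d$S)
    ),
    noncompetitive_mm = list(
      parameter_names = c("Vmax", "Km", "Ki"),
      predictor_names = c("S", "I"),
      positive = c("Vmax", "Km", "Ki"),
      bounds = list(Vmax = c(1e-8, 1e4), Km = c(1e-6, 1e4), Ki = c(1e-6, 1e4)),
      fn = function(p, d) {
        p[["Vmax"]] / (1 + d$I / p[["Ki"]]) * d$S / (p[["Km"]] + d$S)
      }
    ),
    hyperbolic_inhibition = list(
      parameter_names = c("v0", "Imax", "Ki"),
      predictor_names = "I",
      positive = c("v0", "Ki"),
      bounds = list(v0 = c(1e-8, 1e4), Imax = c(0, 1), Ki = c(1e-6, 1e4)),
      fn = function(p, d) {
        p[["v0"]] * (1 - p[["Imax"]] * d$I / (p[["Ki"]] + d$I))
      }
    ),
    hill_inhibition = list(
      parameter_names = c("v0", "Imax", "IC50", "n"),
      predictor_names = "I",
      positive = c("v0", "IC50", "n"),
      bounds = list(
        v0 = c(1e-8, 1e4), Imax = c(0, 1),
        IC50 = c(1e-6, 1e4), n = c(0.2, 10)
      ),
      fn = function(p, d) {
        frac <- ifelse(
          d$I == 0, 0,
          d$I^p[["n"]] / (p[["IC50"]]^p[["n"]] + d$I^p[["n"]])
        )
        p[["v0"]] * (1 - p[["Imax"]] * frac)
      }
    ),
    hyperbolic_activation = list(
      parameter_names = c("v_floor", "v_ceil", "Kact"),
      predictor_names = "A",
      positive = "Kact",
      bounds = list(
        v_floor = c(0, 1e4), v_ceil = c(0, 1e4), Kact = c(1e-6, 1e4)
      ),
      fn = function(p, d) {
        p[["v_floor"]] +
          (p[["v_ceil"]] - p[["v_floor"]]) * d$A / (p[["Kact"]] + d$A)
      }
    ),
    effector_inhibition = list(
      parameter_names = c("B", "T", "K_E"),
      predictor_names = "E",
      positive = "K_E",
      bounds = list(B = c(0, 1e4), T = c(0, 1e4), K_E = c(1e-6, 1e6)),
      fn = function(p, d) {
        p[["B"]] + (p[["T"]] - p[["B"]]) * d$E / (p[["K_E"]] + d$E)
      }
    )
  )
}

#' Evaluate a rate model at given parameters and predictors
#'
#' @param spec A [rate_model()] specification (or a model id string).
#' @param params Named numeric vector or list, complete for the model.
#' @param predictors Named list (or data frame) of predictor vectors; all
#'   concentrations must be non-negative.
#' @return Numeric vector of responses, recycled over the predictors.
#' @examples
#' evaluate_model("hill_inhibition",
#'   c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
#'   list(I = c(0, 2.5, 10))
#' )
#' @export
evaluate_model <- function(spec, params, predictors) {
  if (is.character(spec)) spec <- rate_model(spec)
  stopifnot(inherits(spec, "rate_model_spec"))
  params <- unlist(params)
  missing <- setdiff(spec$parameter_names, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  predictors <- as.list(predictors)
  missing_p <- setdiff(spec$predictor_names, names(predictors))
  if (length(missing_p) > 0) {
    stop("missing predictor(s): ", paste(missing_p, collapse = ", "))
  }
  for (nm in spec$predictor_names) {
    if (any(predictors[[nm]] < 0, na.rm = TRUE)) {
      stop("negative concentration in predictor '", nm, "'")
    }
  }
  out <- spec$fn(params, predictors)
  if (any(!is.finite(out))) stop("model evaluation produced non-finite values")
  out
}
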