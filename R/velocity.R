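#' Reduce an assay time course to an initial velocity
#'
#' Detects the linear phase of a progress trace and returns the slope of
#' the least-squares line through it. Two assay read-outs are supported:
#' a discontinuous pyrophosphate assay (`signal` already in product
#' micromoles, slope reported directly) and the coupled photometric assay
#' that follows NADH at 340 nm (`signal` in absorbance units, slope
#' converted to a molar rate via Beer-Lambert: `rate = slope /
#' (epsilon * path_length)`).
#'
#' The linear phase is the longest prefix of at least 3 points whose
#' fitted slope changes by less than `linearity_tolerance` (relative) when
#' the last point of the prefix is dropped; the prefix stops growing at
#' the first violation.
#'
#' @param trace Data frame with columns `time` (s, strictly increasing)
#'   and `signal`.
#' @param assay_kind `"discontinuous_ppi"` or `"coupled_A340"`.
#' @param epsilon_NADH Molar extinction coefficient of NADH at 340 nm
#'   (M^-1 cm^-1); default 6220.
#' @param path_length Cuvette path length in cm; default 1.
#' @param linearity_tolerance Maximum relative slope drift tolerated while
#'   extending the linear phase (default 0.05).
#' @return One-row tibble: `rate`, `n_linear` (points retained),
#'   `assay_kind`.
#' @examples
#' tr <- data.frame(time = 0:5, signal = 2 * (0:5))
#' initial_velocity(tr) # rate 2, all 6 points
#' @export
initial_velocity <- function(trace,
                             assay_kind = c(
                               "discontinuous_ppi", "coupled_A340"
                             ),
                             epsilon_NADH = 6220, path_length = 1,
                             linearity_tolerance = 0.05) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(epsilon_NADH > 0, path_length > 0, linearity_tolerance > 0)
  t <- trace$time
  y <- trace$signal
  if (length(t) < 3) stop("need at least 3 time points")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")

  slope_of <- function(k) {
    stats::cov(t[1:k], y[1:k]) / stats::var(t[1:k])
  }
  k <- 3
  s_prev <- slope_of(3)
  while (k < length(t)) {
    s_next <- slope_of(k + 1)
    drift <- abs(s_next - s_prev) / max(abs(s_prev), .Machine$double.eps)
    if (drift >= linearity_tolerance) break
    k <- k + 1
    s_prev <- s_next
  }
  slope <- slope_of(k)
  rate <- if (assay_kind == "coupled_A340") {
    slope / (epsilon_NADH * path_length)
  } else {
    slope
  }
  tibble::tibble(
    rate = rate, n_linear = as.integer(k), assay_kind = assay_kind
  )
}
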