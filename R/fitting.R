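#' Fit a rate / dose-response model by multi-start nonlinear least squares
#'
#' Fits any [rate_model()] to tabular data by Levenberg-Marquardt least
#' squares with box bounds, restarted from `n_starts` seeded draws within
#' the bounds (the lowest residual sum of squares wins). Standard errors
#' come from the Gauss-Newton curvature (the Jacobian cross-product) at
#' the optimum. The fit is deterministic given `(data, model, options)`.
#'
#' The first start is a data-driven heuristic (e.g. `v0` from the response
#' at zero dose, half-effect constants from the median dose); the remaining
#' starts are drawn within the bounds — log-uniform for strictly positive
#' scale parameters, whose plausible ranges span decades, and uniform for
#' the rest.
#'
#' @param data Data frame with one column per model predictor (e.g. `I`
#'   for inhibition models, `S` and `I` for saturation data) and the
#'   response column.
#' @param model A [rate_model()] spec or model id string.
#' @param response Name of the response column (default `"response"`).
#' @param n_starts Number of seeded starts (default 20).
#' @param seed Integer seed for the start draws.
#' @param bounds Optional named list of `c(lo, hi)` overriding defaults.
#' @param fixed Named vector of parameters to hold fixed (e.g.
#'   `c(Imax = 1)`).
#' @param weights Optional numeric vector of observation weights.
#' @return A `nadreg_fit` object; see [tidy.nadreg_fit()] and
#'   [glance.nadreg_fit()].
#' @examples
#' d <- sim_dose_response("hyperbolic_inhibition",
#'   c(v0 = 100, Imax = 1, Ki = 1),
#'   concentrations = c(0, 0.25, 0.5, 1, 2, 4, 8), noise_cv = 0, seed = 1
#' )
#' fit <- fit_model(d, "hyperbolic_inhibition", fixed = c(Imax = 1), seed = 1)
#' coef(fit)
#' @export
fit_model <- function(data, model, response = "response", n_starts = 20,
                      seed = 1, bounds = NULL, fixed = NULL, weights = NULL) {
  spec <- if (is.character(model)) rate_model(model, bounds) else model
  stopifnot(inherits(spec, "rate_model_spec"))
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found")
  }
  y <- data[[response]]
  preds <- data[spec$predictor_names]
  keep <- stats::complete.cases(cbind(y, preds))
  y <- y[keep]
  preds <- preds[keep, , drop = FALSE]
  n <- length(y)

  free <- setdiff(spec$parameter_names, names(fixed))
  n_distinct <- nrow(unique(preds))
  if (n_distinct < length(free) + 1) {
    stop(
      "need at least ", length(free) + 1,
      " distinct predictor settings for ", length(free), " free parameters"
    )
  }
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)

  resid_fn <- function(theta) {
    p <- c(theta, fixed)
    sw * (y - spec$fn(as.list(p), preds))
  }

  lo <- vapply(spec$bounds[free], `[`, numeric(1), 1)
  hi <- vapply(spec$bounds[free], `[`, numeric(1), 2)
  starts <- .fit_starts(spec, free, lo, hi, y, preds, n_starts, seed)

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = lo, upper = hi, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-300 ||
      (abs(rss - best$rss) <= 1e-300 && !best$ok && ok)) {
      best <- list(par = res$par, rss = rss, ok = ok)
    }
    any_converged <- any_converged || ok
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for model ", spec$model_id)
  }

  est <- c(best$par, fixed)[spec$parameter_names]
  se <- .fit_se(resid_fn, best$par, best$rss, n)
  se_full <- stats::setNames(rep(NA_real_, length(est)), names(est))
  se_full[names(se)] <- se

  structure(
    list(
      model_id = spec$model_id,
      spec = spec,
      estimates = est,
      standard_errors = se_full,
      fixed = fixed,
      free = free,
      rss = best$rss,
      n_obs = n,
      converged = any_converged && best$ok,
      seed = seed,
      n_starts = n_starts,
      data = cbind(preds, response = y)
    ),
    class = "nadreg_fit"
  )
}

# heuristic first start + seeded draws (log-uniform for positive scales)
.fit_starts <- function(spec, free, lo, hi, y, preds, n_starts, seed) {
  heur <- .fit_heuristic(spec, y, preds)
  first <- pmin(pmax(heur[free], lo), hi)
  if (n_starts <= 1) {
    return(list(first))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  log_scaled <- free %in% spec$positive & lo > 0
  starts <- vector("list", n_starts - 1)
  for (i in seq_len(n_starts - 1)) {
    u <- stats::runif(length(free))
    s <- ifelse(log_scaled,
      10^(log10(lo) + u * (log10(hi) - log10(lo))),
      lo + u * (hi - lo)
    )
    starts[[i]] <- stats::setNames(s, free)
  }
  c(list(first), starts)
}

# save/restore global RNG state so fits do not perturb caller streams
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}

.fit_heuristic <- function(spec, y, preds) {
  pos <- function(v) v[v > 0]
  mid <- function(v) if (length(pos(v)) > 0) stats::median(pos(v)) else 1
  switch(spec$model_id,
    michaelis_menten = c(Vmax = max(y), Km = mid(preds$S)),
    noncompetitive_mm = c(
      Vmax = max(y), Km = mid(preds$S),
      Ki = mid(preds$I)
    ),
    hyperbolic_inhibition = c(
      v0 = max(y), Imax = 1 - min(y) / max(max(y), 1e-12),
      Ki = mid(preds$I)
    ),
    hill_inhibition = c(
      v0 = max(y), Imax = 1 - min(y) / max(max(y), 1e-12),
      IC50 = mid(preds$I), n = 1.5
    ),
    hyperbolic_activation = c(
      v_floor = min(y), v_ceil = max(y), Kact = mid(preds$A)
    ),
    effector_inhibition = c(B = min(y), T = max(y), K_E = mid(preds$E))
  )
}

# Gauss-Newton standard errors from a numeric Jacobian of the residuals
.fit_se <- function(resid_fn, par, rss, n) {
  p <- length(par)
  if (n <= p) {
    return(stats::setNames(rep(NA_real_, p), names(par)))
  }
  J <- .num_jacobian(resid_fn, par)
  jtj <- crossprod(J)
  s2 <- rss / (n - p)
  cov <- tryCatch(solve(jtj) * s2, error = function(e) NULL)
  if (is.null(cov)) {
    return(stats::setNames(rep(NA_real_, p), names(par)))
  }
  stats::setNames(sqrt(pmax(diag(cov), 0)), names(par))
}

.num_jacobian <- function(fn, par) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]), 1e-8) * 1e-6
    pp <- par
    pm <- par
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' @export
print.nadreg_fit <- function(x, ...) {
  cat("<nadreg_fit> ", x$model_id,
    if (!x$converged) "  [NOT CONVERGED]", "\n",
    sep = ""
  )
  est <- format(signif(x$estimates, 4))
  se <- format(signif(x$standard_errors, 3))
  for (i in seq_along(est)) {
    fx <- if (names(x$estimates)[i] %in% names(x$fixed)) " (fixed)" else
      paste0(" +/- ", se[i])
    cat("  ", names(x$estimates)[i], " = ", est[i], fx, "\n", sep = "")
  }
  cat("  rss = ", signif(x$rss, 4), " on n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}

#' @export
coef.nadreg_fit <- function(object, ...) object$estimates

#' Tidy a model fit into one row per parameter
#'
#' @param x A `nadreg_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `fixed`.
#' @export
tidy.nadreg_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$standard_errors),
    fixed = names(x$estimates) %in% names(x$fixed)
  )
}

#' One-row fit summary
#'
#' @param x A `nadreg_fit` object.
#' @param ... Unused.
#' @return A tibble with `model_id`, `rss`, `n_obs`, `df`, `AICc`,
#'   `converged`, `seed`, `n_starts`.
#' @export
glance.nadreg_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    rss = x$rss,
    n_obs = x$n_obs,
    df = length(x$free),
    AICc = .aicc(x$rss, x$n_obs, length(x$free)),
    converged = x$converged,
    seed = x$seed,
    n_starts = x$n_starts
  )
}

# AICc for least squares: k counts free parameters + the error variance
.aicc <- function(rss, n, p) {
  k <- p + 1
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

#' Compare two fits of the same data
#'
#' Model selection between two fits of the same observations, either by
#' corrected AIC or, for nested models, the extra-sum-of-squares F test
#' with `(df_full - df_reduced, n - df_full)` degrees of freedom. This is
#' how a hyperbolic and a sigmoidal (Hill) description of the same
#' dose-response data are discriminated.
#'
#' @param fit_a,fit_b `nadreg_fit` objects on the same data (`fit_b` is the
#'   fuller model for `f_test`).
#' @param criterion `"aicc"` or `"f_test"`.
#' @param alpha Significance level for the F test.
#' @return One-row tibble: `preferred`, `statistic`, `p.value` (F test) or
#'   `delta_aicc`.
#' @export
compare_models <- function(fit_a, fit_b, criterion = c("aicc", "f_test"),
                           alpha = 0.05) {
  criterion <- match.arg(criterion)
  if (fit_a$n_obs != fit_b$n_obs) {
    stop("fits have different numbers of observations; not comparable")
  }
  n <- fit_a$n_obs
  if (criterion == "aicc") {
    a <- .aicc(fit_a$rss, n, length(fit_a$free))
    b <- .aicc(fit_b$rss, n, length(fit_b$free))
    preferred <- if (a <= b) fit_a$model_id else fit_b$model_id
    return(tibble::tibble(
      criterion = "aicc", preferred = preferred,
      statistic = a - b, p.value = NA_real_
    ))
  }
  # order so that `full` has more free parameters
  if (length(fit_a$free) > length(fit_b$free)) {
    tmp <- fit_a
    fit_a <- fit_b
    fit_b <- tmp
  }
  df_r <- length(fit_a$free)
  df_f <- length(fit_b$free)
  if (df_f == df_r) {
    same <- abs(fit_a$rss - fit_b$rss) <= 1e-12 * max(fit_a$rss, 1e-300)
    return(tibble::tibble(
      criterion = "f_test",
      preferred = if (same) NA_character_ else
        c(fit_a$model_id, fit_b$model_id)[which.min(c(fit_a$rss, fit_b$rss))],
      statistic = 0, p.value = 1
    ))
  }
  num <- (fit_a$rss - fit_b$rss) / (df_f - df_r)
  den <- fit_b$rss / (n - df_f)
  f <- if (den <= 0) Inf else max(num / den, 0)
  p <- stats::pf(f, df_f - df_r, n - df_f, lower.tail = FALSE)
  tibble::tibble(
    criterion = "f_test",
    preferred = if (p < alpha) fit_b$model_id else fit_a$model_id,
    statistic = f, p.value = p
  )
}

#' Classify an inhibition mechanism from paired saturation fits
#'
#' Compares Michaelis-Menten fits of substrate-saturation data measured
#' without and with a fixed inhibitor concentration. A drop in Vmax with
#' unchanged Km is the signature of noncompetitive/allosteric inhibition;
#' an increased Km with unchanged Vmax indicates competition for the
#' substrate site; both shifted is mixed. "Changed" and "unchanged" are
#' judged by Wald confidence intervals at level `1 - alpha`.
#'
#' @param fit_no_inh,fit_with_inh Converged `nadreg_fit` objects from the
#'   Michaelis-Menten family.
#' @param alpha Confidence level parameter (default 0.05).
#' @return One-row tibble: `classification` (one of `"competitive"`,
#'   `"noncompetitive_allosteric"`, `"mixed"`, `"indeterminate"`),
#'   `km_changed`, `vmax_changed`, `reason`.
#' @export
classify_inhibition <- function(fit_no_inh, fit_with_inh, alpha = 0.05) {
  out <- function(cls, km, vmax, reason = NA_character_) {
    tibble::tibble(
      classification = cls, km_changed = km, vmax_changed = vmax,
      reason = reason
    )
  }
  if (!isTRUE(fit_no_inh$converged) || !isTRUE(fit_with_inh$converged)) {
    return(out("indeterminate", NA, NA, "non-converged input fit"))
  }
  z <- stats::qnorm(1 - alpha / 2)
  ci <- function(fit, term) {
    e <- fit$estimates[[term]]
    s <- fit$standard_errors[[term]]
    if (is.na(s)) s <- 0
    c(e - z * s, e + z * s)
  }
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  km0 <- ci(fit_no_inh, "Km")
  km1 <- ci(fit_with_inh, "Km")
  v0 <- ci(fit_no_inh, "Vmax")
  v1 <- ci(fit_with_inh, "Vmax")
  km_changed <- !overlap(km0, km1)
  vmax_changed <- !overlap(v0, v1)
  if (!km_changed && vmax_changed &&
    fit_with_inh$estimates[["Vmax"]] < fit_no_inh$estimates[["Vmax"]]) {
    out("noncompetitive_allosteric", km_changed, vmax_changed)
  } else if (km_changed && !vmax_changed &&
    fit_with_inh$estimates[["Km"]] > fit_no_inh$estimates[["Km"]]) {
    out("competitive", km_changed, vmax_changed)
  } else if (km_changed && vmax_changed) {
    out("mixed", km_changed, vmax_changed)
  } else {
    out("indeterminate", km_changed, vmax_changed, "no clear CI separation")
  }
}
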