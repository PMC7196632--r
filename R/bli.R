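#' Binding parameters for biolayer interferometry models
#'
#' Bundles the Langmuir 1:1 rate constants and sensor amplitude for one
#' binding site. Kd is always derived as `kOFF / kON`. For the 2:1
#' heterogeneous-ligand model pass a list of two such sites to the
#' simulation / fitting functions.
#'
#' @param kON Association rate constant, M^-1 s^-1.
#' @param kOFF Dissociation rate constant, s^-1.
#' @param Rmax Maximum response amplitude of the site, nm.
#' @return A `binding_params` object (list with `kON`, `kOFF`, `Rmax`,
#'   `Kd`).
#' @examples
#' binding_params(9.09e4, 2.72e-2, Rmax = 2)
#' @export
binding_params <- function(kON, kOFF, Rmax) {
  stopifnot(kON > 0, kOFF > 0, Rmax > 0)
  structure(
    list(kON = kON, kOFF = kOFF, Rmax = Rmax, Kd = kOFF / kON),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat("<binding_params> kON = ", signif(x$kON, 4), " M-1 s-1, kOFF = ",
    signif(x$kOFF, 4), " s-1, Rmax = ", signif(x$Rmax, 4),
    " nm, Kd = ", signif(x$Kd * 1e9, 4), " nM\n",
    sep = ""
  )
  invisible(x)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param kON Association rate constant, M^-1 s^-1 (> 0).
#' @param kOFF Dissociation rate constant, s^-1 (> 0).
#' @return Kd in M, exactly `kOFF / kON`.
#' @examples
#' kd_from_rates(9.09e4, 2.72e-2) # ~3e-7 M, i.e. ~300 nM
#' @export
kd_from_rates <- function(kON, kOFF) {
  if (any(kON <= 0) || any(kOFF <= 0)) {
    stop("rate constants must be strictly positive")
  }
  kOFF / kON
}

# deterministic association/dissociation curve for one or two sites;
# conc in M, times relative to phase start
.bli_curve <- function(sites, conc, t_assoc, t_diss) {
  assoc <- rep(0, length(t_assoc))
  end_by_site <- numeric(length(sites))
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    kobs <- s$kON * conc + s$kOFF
    req <- if (conc == 0) 0 else s$Rmax * conc / (conc + s$Kd)
    ri <- req * (1 - exp(-kobs * t_assoc))
    assoc <- assoc + ri
    end_by_site[i] <- if (length(t_assoc) > 0) ri[length(ri)] else 0
  }
  diss <- rep(0, length(t_diss))
  for (i in seq_along(sites)) {
    diss <- diss + end_by_site[i] * exp(-sites[[i]]$kOFF * t_diss)
  }
  list(assoc = assoc, diss = diss)
}

.as_sites <- function(params) {
  if (inherits(params, "binding_params")) list(params) else params
}

#' Simulate a biolayer-interferometry sensorgram
#'
#' Generates a phased sensor trace (baseline, association, dissociation)
#' at one analyte concentration from Langmuir 1:1 kinetics, or from the
#' sum of two independent sites (the 2:1 heterogeneous-ligand model).
#' Association follows `R(t) = Req (1 - exp(-(kON C + kOFF) t))` with
#' `Req = Rmax C / (C + Kd)`; dissociation decays exponentially from the
#' association end point at rate `kOFF`. Gaussian noise and a linear
#' drift are added after the deterministic curve; the trace is
#' deterministic given `seed`.
#'
#' @param params A [binding_params()] object, or a list of two for the
#'   heterogeneous model.
#' @param conc Analyte concentration in nM (dimer basis for NadE2).
#' @param phase_times Named numeric vector of phase durations in seconds:
#'   `baseline`, `association`, `dissociation`.
#' @param noise_sd Gaussian noise standard deviation in nm (>= 0).
#' @param drift Linear baseline drift in nm/s.
#' @param seed Integer seed (only used when `noise_sd > 0` or
#'   `drift != 0`).
#' @param dt Sampling interval in seconds.
#' @return A tibble with columns `time`, `response`, `phase`,
#'   `analyte_conc` (nM).
#' @export
simulate_sensorgram <- function(params, conc,
                                phase_times = c(
                                  baseline = 30, association = 150,
                                  dissociation = 300
                                ),
                                noise_sd = 0, drift = 0, seed = 1, dt = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (conc < 0) stop("analyte concentration must be non-negative")
  sites <- .as_sites(params)
  nb <- max(round(phase_times[["baseline"]] / dt), 0)
  na <- max(round(phase_times[["association"]] / dt), 1) + 1
  nd <- max(round(phase_times[["dissociation"]] / dt), 1)
  # association carries its own t = 0 origin point (response zero);
  # dissociation time is relative to the association end point
  t_assoc <- (seq_len(na) - 1) * dt
  t_diss <- seq_len(nd) * dt
  cm <- conc * 1e-9
  cur <- .bli_curve(sites, cm, t_assoc, t_diss)
  resp <- c(rep(0, nb), cur$assoc, cur$diss)
  time <- seq_along(resp) * dt
  phase <- c(
    rep("baseline", nb), rep("association", na), rep("dissociation", nd)
  )
  if (noise_sd > 0 || drift != 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    resp <- resp + drift * time + stats::rnorm(length(resp), 0, noise_sd)
    old()
  }
  tibble::tibble(
    time = time, response = resp, phase = phase, analyte_conc = conc
  )
}

#' Reference-subtract and smooth a sensorgram
#'
#' Subtracts a reference sensor trace recorded on the same time grid
#' (background of unspecific analyte binding), then applies
#' Savitzky-Golay smoothing. Phases are preserved.
#'
#' @param raw,reference Sensorgram tibbles sharing the same `time` grid.
#' @param sg_window Odd filter window length in points (default 11).
#' @param sg_polyorder Polynomial order, `< sg_window` (default 3).
#' @return The preprocessed sensorgram tibble.
#' @export
bli_preprocess <- function(raw, reference, sg_window = 11, sg_polyorder = 3) {
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_polyorder >= sg_window) stop("sg_polyorder must be < sg_window")
  if (nrow(raw) != nrow(reference) ||
    any(abs(raw$time - reference$time) > 1e-9)) {
    stop("raw and reference sensorgrams are not on the same time grid")
  }
  corrected <- raw$response - reference$response
  smoothed <- signal::sgolayfilt(corrected, p = sg_polyorder, n = sg_window)
  out <- raw
  out$response <- smoothed
  out
}

#' Globally fit binding kinetics across analyte concentrations
#'
#' Fits the association and dissociation phases of a set of sensorgrams
#' recorded at different analyte concentrations with shared rate
#' constants and amplitude (per site for the 2:1 heterogeneous model).
#' Each association phase is zeroed to its first point; baseline and
#' loading phases are carried through but not modelled. Optimization is
#' multi-start Levenberg-Marquardt on log-parameters (all parameters
#' strictly positive); Kd is derived from the fitted rates.
#'
#' @param sensorgrams A single tibble with an `analyte_conc` column
#'   covering several concentrations (rows from [simulate_sensorgram()]
#'   bound together), or a list of such tibbles.
#' @param model `"one_to_one"` or `"heterogeneous_2to1"`.
#' @param n_starts Seeded optimizer starts (default 8).
#' @param seed Integer seed for the start draws.
#' @return A list of class `bli_fit`: `params` ([binding_params()] or a
#'   list of two sites), `model`, `rss`, `n_obs`, `converged`, `seed`,
#'   `confounded` flag (single-concentration input), and the tibble
#'   `data` actually fitted.
#' @export
fit_binding_global <- function(sensorgrams,
                               model = c("one_to_one", "heterogeneous_2to1"),
                               n_starts = 8, seed = 1) {
  model <- match.arg(model)
  if (is.data.frame(sensorgrams)) sensorgrams <- list(sensorgrams)
  curves <- purrr::map(sensorgrams, function(sg) {
    split(sg, sg$analyte_conc)
  })
  curves <- purrr::flatten(curves)
  concs <- vapply(
    curves, function(sg) sg$analyte_conc[1], numeric(1)
  )
  confounded <- length(unique(concs[concs > 0])) < 2
  if (confounded) {
    warning("fewer than 2 nonzero analyte concentrations: ",
      "Kd and Rmax are confounded",
      call. = FALSE
    )
  }
  prep <- purrr::map(curves, function(sg) {
    a <- sg[sg$phase == "association", ]
    d <- sg[sg$phase == "dissociation", ]
    if (nrow(a) < 2 || nrow(d) < 2) {
      stop("each sensorgram needs association and dissociation phases")
    }
    z <- a$response[1]
    list(
      conc = sg$analyte_conc[1] * 1e-9,
      t_assoc = a$time - a$time[1],
      y_assoc = a$response - z,
      t_diss = d$time - a$time[nrow(a)],
      y_diss = d$response - z
    )
  })
  y_all <- unlist(purrr::map(prep, function(p) c(p$y_assoc, p$y_diss)))
  n_obs <- length(y_all)
  r_scale <- max(abs(y_all))

  n_sites <- if (model == "one_to_one") 1L else 2L
  resid_fn <- function(lpar) {
    sites <- .sites_from_log(lpar, n_sites)
    unlist(purrr::map(prep, function(p) {
      cur <- .bli_curve(sites, p$conc, p$t_assoc, p$t_diss)
      c(p$y_assoc - cur$assoc, p$y_diss - cur$diss)
    }))
  }

  starts <- .bli_starts(n_sites, r_scale, n_starts, seed)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = res$par, rss = rss, ok = res$info %in% 1:4)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  sites <- .sites_from_log(best$par, n_sites)
  params <- if (n_sites == 1) sites[[1]] else sites
  structure(
    list(
      params = params, model = model, rss = best$rss, n_obs = n_obs,
      converged = best$ok, seed = seed, n_starts = n_starts,
      confounded = confounded,
      data = dplyr::bind_rows(curves)
    ),
    class = "bli_fit"
  )
}

.sites_from_log <- function(lpar, n_sites) {
  purrr::map(seq_len(n_sites), function(i) {
    o <- (i - 1) * 3
    binding_params(
      kON = exp(lpar[o + 1]), kOFF = exp(lpar[o + 2]),
      Rmax = exp(lpar[o + 3])
    )
  })
}

.bli_starts <- function(n_sites, r_scale, n_starts, seed) {
  # heuristic centre: mid-range rates for protein-protein interactions
  centre <- rep(log(c(1e5, 1e-2, max(r_scale, 1e-3))), n_sites)
  if (n_sites == 2) {
    centre[4:6] <- log(c(1e4, 1e-3, max(r_scale / 2, 1e-3)))
  }
  out <- list(centre)
  if (n_starts > 1) {
    old <- .Random.seed_exists()
    set.seed(seed)
    for (i in seq_len(n_starts - 1)) {
      out[[i + 1]] <- centre + stats::rnorm(length(centre), 0, 1.5)
    }
    old()
  }
  out
}

#' @export
print.bli_fit <- function(x, ...) {
  cat("<bli_fit> ", x$model,
    if (!x$converged) "  [NOT CONVERGED]",
    if (x$confounded) "  [Kd/Rmax confounded]", "\n",
    sep = ""
  )
  sites <- .as_sites(x$params)
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    cat("  site ", i, ": kON = ", signif(s$kON, 4), " M-1 s-1, kOFF = ",
      signif(s$kOFF, 4), " s-1, Rmax = ", signif(s$Rmax, 3),
      " nm, Kd = ", signif(s$Kd * 1e9, 4), " nM\n",
      sep = ""
    )
  }
  cat("  rss = ", signif(x$rss, 4), " on n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bli_fit <- function(x, ...) {
  sites <- .as_sites(x$params)
  purrr::map_dfr(seq_along(sites), function(i) {
    s <- sites[[i]]
    tibble::tibble(
      site = i,
      term = c("kON", "kOFF", "Rmax", "Kd"),
      estimate = c(s$kON, s$kOFF, s$Rmax, s$Kd)
    )
  })
}

#' @export
glance.bli_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, rss = x$rss, n_obs = x$n_obs,
    converged = x$converged, confounded = x$confounded, seed = x$seed
  )
}

#' Half-effect constant of 2-oxoglutarate on complex formation
#'
#' Fits equilibrium (plateau) sensor responses measured at increasing
#' 2-oxoglutarate concentrations with a hyperbolic decay
#' `R(OG) = R0 * K / (K + OG)` (optionally with a floor, i.e. a residual
#' response at saturating effector) and returns the half-effect constant.
#' Plateau responses are used rather than observed rates or amplitudes.
#'
#' @param data Data frame with columns `OG` (effector concentration,
#'   include 0) and `response` (plateau response, nm).
#' @param floor If `TRUE`, frees a residual-response floor (fits the
#'   maximum fractional decrease as a parameter); default `FALSE`.
#' @param n_starts,seed Passed to [fit_model()].
#' @return A list: `K_OG` (half-effect constant, same unit as `OG`) and
#'   `fit` (the underlying `nadreg_fit`).
#' @export
og_inhibition_constant <- function(data, floor = FALSE, n_starts = 20,
                                   seed = 1) {
  if (length(unique(data$OG)) < 4 || !any(data$OG == 0)) {
    stop("need >= 4 effector levels including 0")
  }
  if (stats::sd(data$response) == 0) {
    stop("all responses equal: half-effect constant not identifiable")
  }
  d <- data.frame(I = data$OG, response = data$response)
  fixed <- if (floor) NULL else c(Imax = 1)
  fit <- fit_model(d, "hyperbolic_inhibition",
    fixed = fixed, n_starts = n_starts, seed = seed
  )
  list(K_OG = unname(fit$estimates[["Ki"]]), fit = fit)
}
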