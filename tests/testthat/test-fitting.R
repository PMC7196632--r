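test_that("noise-free parameter recovery is exact for every model", {
  cases <- list(
    list(
      "michaelis_menten", c(Vmax = 0.09, Km = 0.2),
      0.2 * c(0.1, 0.3, 0.7, 1, 2, 5, 10), NULL
    ),
    list(
      "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
      c(0, 0.25, 0.5, 1, 2, 4, 7, 10), c(Imax = 1)
    ),
    list(
      "hill_inhibition", c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
      c(0, 0.25, 0.5, 1, 2, 4, 7, 10), c(Imax = 1)
    ),
    list(
      "hyperbolic_activation", c(v_floor = 17, v_ceil = 50, Kact = 0.64),
      c(0, 0.25, 1, 2, 4, 10), NULL
    ),
    list(
      "effector_inhibition", c(B = 50, T = 100, K_E = 15.5),
      c(0, 5, 10, 20, 40, 80, 160, 480), NULL
    )
  )
  for (cs in cases) {
    d <- sim_dose_response(cs[[1]], cs[[2]], cs[[3]], noise_cv = 0, seed = 1)
    f <- fit_model(d, cs[[1]], fixed = cs[[4]], n_starts = 10, seed = 1)
    expect_true(f$converged)
    free <- setdiff(names(cs[[2]]), names(cs[[4]]))
    expect_equal(
      f$estimates[free], cs[[2]][free],
      tolerance = 1e-6
    )
  }
})

test_that("Hill n = 1 fit matches the hyperbolic fit on hyperbolic data", {
  d <- sim_dose_response(
    "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
    c(0, 0.25, 0.5, 1, 2, 4, 7, 10),
    noise_cv = 0, seed = 1
  )
  f_hyp <- fit_model(d, "hyperbolic_inhibition",
    fixed = c(Imax = 1), seed = 1
  )
  f_hill <- fit_model(d, "hill_inhibition",
    fixed = c(Imax = 1, n = 1), seed = 1
  )
  expect_lt(abs(f_hyp$rss - f_hill$rss), 1e-8)
  expect_equal(
    unname(f_hill$estimates[["IC50"]]),
    unname(f_hyp$estimates[["Ki"]]),
    tolerance = 1e-6
  )
})

test_that("fits are bit-reproducible given the same data and options", {
  d <- sim_dose_response(
    "hill_inhibition", c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
    c(0, 0.25, 0.5, 1, 2, 4, 7, 10),
    noise_cv = 0.03, seed = 11
  )
  f1 <- fit_model(d, "hill_inhibition", fixed = c(Imax = 1), seed = 7)
  f2 <- fit_model(d, "hill_inhibition", fixed = c(Imax = 1), seed = 7)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
})

test_that("fitting does not perturb the caller's RNG stream", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  d <- sim_dose_response(
    "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
    c(0, 0.5, 1, 2, 4),
    noise_cv = 0, seed = 1
  )
  invisible(fit_model(d, "hyperbolic_inhibition", fixed = c(Imax = 1)))
  expect_identical(runif(1), a)
})

test_that("fit_model demands enough distinct concentrations", {
  d <- data.frame(I = c(0, 0, 1, 1), response = c(100, 99, 50, 51))
  expect_error(
    fit_model(d, "hyperbolic_inhibition"),
    "distinct predictor settings"
  )
})

test_that("model comparison discriminates Hill from hyperbolic data", {
  conc <- c(0, 0.25, 0.5, 1, 2, 4, 7, 10)
  # data truly sigmoidal: hill wins the F test
  d_hill <- sim_dose_response(
    "hill_inhibition", c(v0 = 100, Imax = 1, IC50 = 2.5, n = 2.2),
    conc,
    noise_cv = 0.02, replicates = 3, seed = 3
  )
  fa <- fit_model(d_hill, "hyperbolic_inhibition",
    fixed = c(Imax = 1), seed = 1
  )
  fb <- fit_model(d_hill, "hill_inhibition", fixed = c(Imax = 1), seed = 1)
  cmp <- compare_models(fa, fb, "f_test", alpha = 0.05)
  expect_identical(cmp$preferred, "hill_inhibition")
  expect_lt(cmp$p.value, 0.05)
  # data truly hyperbolic: the simpler model wins by AICc
  d_hyp <- sim_dose_response(
    "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
    conc,
    noise_cv = 0.02, replicates = 3, seed = 4
  )
  fa2 <- fit_model(d_hyp, "hyperbolic_inhibition",
    fixed = c(Imax = 1), seed = 1
  )
  fb2 <- fit_model(d_hyp, "hill_inhibition", fixed = c(Imax = 1), seed = 1)
  cmp2 <- compare_models(fa2, fb2, "aicc")
  expect_identical(cmp2$preferred, "hyperbolic_inhibition")
  # identical fits: no preference, F = 0
  cmp3 <- compare_models(fa, fa, "f_test")
  expect_identical(cmp3$statistic, 0)
  expect_true(is.na(cmp3$preferred))
  expect_error(
    compare_models(fa, fit_model(
      d_hyp[1:12, ], "hyperbolic_inhibition",
      fixed = c(Imax = 1)
    )),
    "different numbers"
  )
})

test_that("inhibition classification separates allosteric from competitive", {
  km <- 0.2
  s_levels <- km * c(0.1, 0.25, 0.5, 1, 2, 4, 7, 10)
  fit_mm <- function(vmax, km_true, seed) {
    d <- sim_dose_response(
      "michaelis_menten", c(Vmax = vmax, Km = km_true), s_levels,
      noise_cv = 0.02, replicates = 3, seed = seed
    )
    fit_model(d, "michaelis_menten", seed = 1)
  }
  f0 <- fit_mm(0.09, km, 1)
  # Vmax drops, Km untouched: allosteric (noncompetitive) signature
  f_nc <- fit_mm(0.04, km, 2)
  expect_identical(
    classify_inhibition(f0, f_nc)$classification,
    "noncompetitive_allosteric"
  )
  # Km doubled, Vmax untouched: competitive signature
  f_comp <- fit_mm(0.09, 2 * km, 3)
  expect_identical(
    classify_inhibition(f0, f_comp)$classification,
    "competitive"
  )
  # identical fits are indeterminate
  expect_identical(
    classify_inhibition(f0, f0)$classification,
    "indeterminate"
  )
  # non-converged input flagged, with a reason
  f_bad <- f0
  f_bad$converged <- FALSE
  res <- classify_inhibition(f0, f_bad)
  expect_identical(res$classification, "indeterminate")
  expect_match(res$reason, "non-converged")
})

test_that("tidy and glance expose estimates and fit metadata", {
  d <- sim_dose_response(
    "hyperbolic_inhibition", c(v0 = 100, Imax = 1, Ki = 1),
    c(0, 0.5, 1, 2, 4, 8),
    noise_cv = 0.03, seed = 2
  )
  f <- fit_model(d, "hyperbolic_inhibition", fixed = c(Imax = 1), seed = 1)
  td <- tidy(f)
  expect_setequal(td$term, c("v0", "Imax", "Ki"))
  expect_true(td$fixed[td$term == "Imax"])
  expect_true(all(is.finite(td$std.error[!td$fixed])))
  gl <- glance(f)
  expect_identical(gl$n_obs, nrow(d))
  expect_true(gl$converged)
  expect_true(is.finite(gl$AICc))
})
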