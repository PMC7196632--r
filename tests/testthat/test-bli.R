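legend_params <- function() binding_params(9.09e4, 2.72e-2, Rmax = 2)

test_that("Kd from rates reproduces the measured equilibrium constant", {
  kd <- kd_from_rates(9.09e4, 2.72e-2)
  expect_equal(kd * 1e9, 300, tolerance = 0.01) # ~300 nM
  expect_identical(kd_from_rates(1, 1), 1)
  expect_lt(kd_from_rates(1e5, 1e-9), 1e-13)
  expect_error(kd_from_rates(0, 1), "strictly positive")
})

test_that("simulated association saturates and respects equilibrium", {
  p <- legend_params()
  # zero analyte: flat zero before noise
  sg0 <- simulate_sensorgram(p, 0, noise_sd = 0)
  expect_true(all(sg0$response == 0))
  # saturation: Req -> Rmax at C = 1000 Kd
  kd_nm <- p$Kd * 1e9
  sg_sat <- simulate_sensorgram(p, 1000 * kd_nm,
    phase_times = c(baseline = 0, association = 600, dissociation = 10),
    noise_sd = 0
  )
  plateau <- max(sg_sat$response)
  expect_lt(abs(plateau - p$Rmax) / p$Rmax, 0.001)
  # half-saturation at C = Kd (association long enough to equilibrate)
  sg_half <- simulate_sensorgram(p, kd_nm,
    phase_times = c(baseline = 0, association = 400, dissociation = 10),
    noise_sd = 0
  )
  expect_lt(abs(max(sg_half$response) - p$Rmax / 2) / (p$Rmax / 2), 0.01)
  # equilibrium consistency across a concentration grid:
  # plateau / Rmax = C / (C + Kd) once association >= 5 / kobs
  for (c_nm in c(30, 100, 300, 1000)) {
    kobs <- p$kON * c_nm * 1e-9 + p$kOFF
    sg <- simulate_sensorgram(p, c_nm,
      phase_times = c(
        baseline = 0, association = ceiling(5 / kobs) + 1,
        dissociation = 5
      ),
      noise_sd = 0
    )
    frac <- max(sg$response) / p$Rmax
    expect_lt(abs(frac - c_nm / (c_nm + p$Kd * 1e9)), 0.01)
  }
})

test_that("noise-free phases are monotone and dissociation decays", {
  sg <- simulate_sensorgram(legend_params(), 300, noise_sd = 0)
  a <- sg$response[sg$phase == "association"]
  d <- sg$response[sg$phase == "dissociation"]
  expect_true(all(diff(a) >= -1e-12))
  expect_true(all(diff(d) <= 1e-12))
  expect_error(simulate_sensorgram(legend_params(), 300, noise_sd = -1))
})

test_that("preprocessing subtracts the reference and smooths noise", {
  p <- legend_params()
  raw <- simulate_sensorgram(p, 300, noise_sd = 0)
  # reference identical to raw: all-zero output
  out <- bli_preprocess(raw, raw)
  expect_true(all(abs(out$response) < 1e-10))
  # a cubic signal is reproduced exactly by an order-3 filter (interior)
  poly <- raw
  poly$response <- 1e-4 * poly$time^3 - 0.01 * poly$time + 2
  zero_ref <- raw
  zero_ref$response <- 0
  sm <- bli_preprocess(poly, zero_ref, sg_window = 11, sg_polyorder = 3)
  interior <- 6:(nrow(poly) - 6)
  expect_equal(
    sm$response[interior], poly$response[interior],
    tolerance = 1e-8
  )
  # smoothing reduces the residual SD against the clean curve >= 2x
  noisy <- simulate_sensorgram(p, 300, noise_sd = 0.05, seed = 9)
  sm2 <- bli_preprocess(noisy, zero_ref, sg_window = 11, sg_polyorder = 3)
  clean <- raw$response
  expect_gt(
    sd(noisy$response - clean) / sd(sm2$response - clean), 2
  )
  expect_error(bli_preprocess(raw, raw, sg_window = 10), "odd")
  short <- raw[1:10, ]
  expect_error(bli_preprocess(raw, short), "time grid")
})

test_that("global 1:1 fit recovers rates from noise-free data", {
  p <- legend_params()
  sg <- sim_sensorgrams(p, noise_sd = 0, seed = 1)
  f <- fit_binding_global(sg, "one_to_one", n_starts = 4, seed = 1)
  expect_true(f$converged)
  expect_equal(f$params$kON, p$kON, tolerance = 1e-4)
  expect_equal(f$params$kOFF, p$kOFF, tolerance = 1e-4)
  # internal consistency: reported Kd equals kOFF / kON of the fit
  expect_equal(
    f$params$Kd, kd_from_rates(f$params$kON, f$params$kOFF),
    tolerance = 1e-12
  )
})

test_that("global fit under noise recovers rates within 10%", {
  p <- legend_params()
  sg <- sim_sensorgrams(p, noise_sd = 0.02, seed = 21)
  f <- fit_binding_global(sg, "one_to_one", n_starts = 4, seed = 1)
  expect_lt(abs(f$params$kON - p$kON) / p$kON, 0.1)
  expect_lt(abs(f$params$kOFF - p$kOFF) / p$kOFF, 0.1)
  # seed-reproducible
  f2 <- fit_binding_global(sg, "one_to_one", n_starts = 4, seed = 1)
  expect_identical(f$params$kON, f2$params$kON)
})

test_that("2:1 heterogeneous data fit 1:1 leaves structure behind", {
  sites <- list(
    binding_params(9.09e4, 2.72e-2, Rmax = 1.2),
    binding_params(5e3, 2e-3, Rmax = 0.8)
  )
  sg <- sim_sensorgrams(sites, noise_sd = 0, seed = 2)
  f1 <- fit_binding_global(sg, "one_to_one", n_starts = 4, seed = 1)
  f2 <- fit_binding_global(sg, "heterogeneous_2to1", n_starts = 8, seed = 1)
  expect_gt(f1$rss, f2$rss)
})

test_that("single-concentration input warns about confounded Kd/Rmax", {
  sg <- simulate_sensorgram(legend_params(), 300, noise_sd = 0)
  expect_warning(
    f <- fit_binding_global(sg, "one_to_one", n_starts = 2, seed = 1),
    "confounded"
  )
  expect_true(f$confounded)
})

test_that("2-OG half-effect constant is recovered from plateau responses", {
  r0 <- 1.8
  k <- 15.5
  og <- c(0, 5, 10, 20, 40, 80, 160, 480)
  d <- data.frame(OG = og, response = r0 * k / (k + og))
  res <- og_inhibition_constant(d, seed = 1)
  expect_equal(res$K_OG, 15.5, tolerance = 1e-6)
  # half-response at OG = K
  expect_equal(
    evaluate_model(
      "hyperbolic_inhibition",
      c(v0 = r0, Imax = 1, Ki = k), list(I = k)
    ),
    r0 / 2
  )
  expect_error(
    og_inhibition_constant(data.frame(OG = og, response = 1)),
    "not identifiable"
  )
  expect_error(
    og_inhibition_constant(data.frame(OG = c(1, 2, 3), response = 1:3)),
    ">= 4"
  )
})
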