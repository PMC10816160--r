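# Parameter estimation: goodness statistics, linearized and nonlinear
# kinetic fits, piecewise diffusion fits, SLMRG multistart least squares.

test_that("goodness-of-fit statistics match hand arithmetic and flag degeneracy", {
  g <- goodness(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r2, 1)
  expect_equal(g$rmse, 0)

  g <- goodness(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$r2, 0.5)            # SSE = 1, SST = 2
  expect_equal(g$rmse, sqrt(1 / 3))  # sqrt(SSE/N), no dof correction

  obs <- c(4, 7, 1, 9)
  g <- goodness(obs, rep(mean(obs), 4))
  expect_equal(g$r2, 0)

  g <- goodness(c(5, 5, 5), c(5, 4, 6))
  expect_true(g$degenerate)
  expect_true(is.na(g$r2))
  expect_gt(g$rmse, 0)
})

test_that("r2 is invariant under affine unit changes applied to both series", {
  set.seed(11)
  obs <- runif(25, 10, 60)
  pred <- obs + rnorm(25, 0, 2)
  base <- goodness(obs, pred)$r2
  for (scale in c(0.001, 1000)) {
    shifted <- goodness(scale * obs + 7, scale * pred + 7)$r2
    expect_equal(shifted, base, tolerance = 1e-10)
  }
})

test_that("PSO linearization is lossless on exact second-order data", {
  tr <- gen_kinetics("pso", list(qe = 40, k2 = 0.001))
  fit <- fit_pso_linear(tr)
  expect_equal(fit$linearization$slope, 1 / 40, tolerance = 1e-12)
  expect_equal(fit$linearization$intercept, 1 / (0.001 * 40^2),
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(40, 0.001), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant trace: degenerate, k2 unidentified
  flat <- kinetic_trace(c(10, 20, 30, 40), rep(25, 4))
  expect_warning(fd <- fit_pso_linear(flat), "degenerate|unidentified")
  expect_true(fd$linearization$degenerate)
  expect_equal(fd$linearization$slope, 1 / 25, tolerance = 1e-12)
  expect_error(fit_pso_linear(kinetic_trace(c(0, 10), c(0, 5))), "t > 0")
})

test_that("PFO linearization recovers the rate from the log-linear slope", {
  tr <- gen_kinetics("pfo", list(qe = 40, k1 = 0.0115),
                     grid = seq(10, 300, by = 20))
  fit <- fit_pfo_linear(tr, qe_exp = 40)
  expect_equal(fit$linearization$slope, -0.0115 / log(10), tolerance = 1e-10)
  expect_equal(fit$linearization$slope, -0.004994, tolerance = 1e-4)
  expect_equal(unname(coef(fit)), c(40, 0.0115), tolerance = 1e-8)
  expect_error(fit_pfo_linear(tr, qe_exp = max(tr$qt)), "qe_exp")
})

test_that("nonlinear kinetic fits agree with the linearized estimates on noiseless data", {
  pso_tr <- gen_kinetics("pso", list(qe = 47.2, k2 = 3.5e-4))
  nl <- fit_kinetics("pso", pso_tr)
  lin <- fit_pso_linear(pso_tr)
  expect_equal(coef(nl), coef(lin), tolerance = 1e-6)

  pfo_tr <- gen_kinetics("pfo", list(qe = 39.8, k1 = 0.012))
  nl <- fit_kinetics("pfo", pfo_tr)
  expect_equal(unname(coef(nl)), c(39.8, 0.012), tolerance = 1e-6)

  # with noise the statistics stay sane
  noisy <- gen_kinetics("pso", list(qe = 47.2, k2 = 3.5e-4),
                        noise_sd = 0.05, seed = 4)
  nf <- fit_kinetics("pso", noisy)
  expect_true(nf$r2 > 0 && nf$r2 < 1)
  expect_gt(nf$rmse, 0)
})

test_that("single-segment diffusion fit reproduces an exact line in sqrt(t)", {
  t <- seq(4, 100, by = 8)
  tr <- kinetic_trace(t, 2 * sqrt(t) + 5)
  fit <- fit_ipd_segments(tr, n_segments = 1)
  expect_equal(fit$segments$kid, 2, tolerance = 1e-10)
  expect_equal(fit$segments$c, 5, tolerance = 1e-10)
  expect_false(fit$through_origin)

  through <- fit_ipd_segments(kinetic_trace(t, 2 * sqrt(t) + 0.1),
                              n_segments = 1)
  expect_true(through$through_origin)
})

test_that("three-regime diffusion traces give back the planted breakpoints", {
  segs <- list(list(kid = 4, c = 0.2),      # film diffusion, near origin
               list(kid = 1.2, c = 18),     # intra-particle
               list(kid = 0, c = 40))       # equilibrium plateau
  grid <- c(1, 4, 9, 16, 25, 36, 64, 100, 144, 196, 256, 324, 400, 484)
  tr <- gen_kinetics("ipd", list(segments = segs, breaks = c(40, 330)),
                     grid = grid)
  fit <- fit_ipd_segments(tr, n_segments = 3)
  # breakpoints recovered at data resolution: planted after t=36 and t=324
  expect_equal(fit$breakpoints, c(36, 324))
  expect_equal(fit$segments$kid, c(4, 1.2, 0), tolerance = 1e-8)
  expect_equal(fit$segments$c[3], 40, tolerance = 1e-8)
  expect_true(fit$through_origin)
  expect_lt(fit$sse, 1e-16)
  expect_error(fit_ipd_segments(kinetic_trace(1:6, sqrt(1:6)), 3),
               "at least 7")
})

test_that("SLMRG fit recovers generating parameters exactly from noiseless data", {
  rec <- ref_params_list()[["OWP_293"]]
  d <- gen_isotherm(rec$params, rec$temperature, n_points = 15)
  fit <- fit_slmrg(d, seed = 7)
  tru <- param_vec(rec$params)
  expect_lt(max(abs(coef(fit) - tru) / tru), 0.01)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  expect_true(fit$converged)
  expect_gte(fit$starts_tried, 1)
})

test_that("SLMRG objective at the solution never exceeds it at the truth on noisy data", {
  rec <- ref_params_list()[["OWPSA_293"]]
  for (s in c(3, 17)) {
    d <- gen_isotherm(rec$params, rec$temperature, n_points = 15,
                      noise_sd = 0.02, seed = s)
    fit <- fit_slmrg(d, seed = s)
    sse_truth <- sum((d$qe - slmrg_capacity(d$ce, rec$params,
                                            rec$temperature))^2)
    expect_lte(fit$sse, sse_truth + 1e-10)
  }
})

test_that("fit objects expose the standard modelling methods", {
  rec <- ref_params_list()[["OWP_293"]]
  d <- gen_isotherm(rec$params, rec$temperature, n_points = 15,
                    noise_sd = 0.02, seed = 2)
  fit <- fit_slmrg(d, seed = 2)
  expect_named(coef(fit), c("n", "nm", "a", "b", "w"))
  expect_equal(fitted(fit) + residuals(fit), d$qe, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(predict(fit, newdata = d$ce), fitted(fit))
  expect_output(print(fit), "SLMRG")
  expect_output(summary(fit), "Qsat")
  sim <- simulate(fit, seed = 9)
  expect_s3_class(sim, "isotherm_data")
  expect_identical(sim$ce, d$ce)
  # simulate is seed-reproducible
  expect_identical(simulate(fit, seed = 9)$qe, sim$qe)
})
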