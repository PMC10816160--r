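# Closed-form equilibrium and kinetic forward models.

test_that("effective concentration reduces to ce in the ideal limit and matches hand evaluation", {
  ideal <- slmrg_params(n = 1, nm = 10, a = 0, b = 0, w = 5)
  expect_equal(effective_concentration(10, ideal, 293), 10)
  expect_equal(effective_concentration(0, ideal, 293), 0)

  # b = 0.008 L/mg and a chosen so 2*a*beta = 0.04 L/mg:
  # f(10) = 10/0.92 * exp(0.08/0.92) * exp(-0.4), hand-evaluated
  a_for <- 0.04 * 1.380649 * 293 / 2
  p <- slmrg_params(n = 1, nm = 10, a = a_for, b = 0.008, w = 5)
  expect_equal(effective_concentration(10, p, 293),
               10 / 0.92 * exp(0.08 / 0.92) * exp(-0.4), tolerance = 1e-12)
  expect_equal(effective_concentration(10, p, 293), 7.948023,
               tolerance = 1e-6)
})

test_that("co-volume singularity is rejected with a domain error", {
  p <- slmrg_params(n = 1, nm = 10, a = 0, b = 0.01, w = 5)
  expect_error(effective_concentration(100, p, 293), "co-volume|1/b")
  expect_error(slmrg_capacity(150, p, 293), "co-volume|1/b")
  # inside the domain the correction stays finite and grows toward the bound
  f <- effective_concentration(c(80, 90, 95), p, 293)
  expect_true(all(is.finite(f)) && all(diff(f) > 0))
})

test_that("SLMRG capacity has the right limits and special cases", {
  p <- slmrg_params(n = 1, nm = 30, a = 0, b = 0, w = 12)
  expect_equal(slmrg_capacity(0, p, 293), 0)
  # Langmuir half-saturation: n = 1, ce = w
  expect_equal(slmrg_capacity(12, p, 293), 30 / 2)
  # approaches but never reaches n*Nm
  q <- slmrg_capacity(c(1, 10, 100, 1e4), p, 293)
  expect_true(all(q < saturation_capacity(p)))
  expect_true(all(diff(q) > 0))
})

test_that("SLMRG reduces exactly to Hill and Langmuir at a = b = 0", {
  ce <- seq(0.5, 120, length.out = 40)
  p_hill <- slmrg_params(n = 2.3, nm = 47, a = 0, b = 0, w = 9.5)
  hill <- p_hill$n * p_hill$nm / (1 + (p_hill$w / ce)^p_hill$n)
  expect_equal(slmrg_capacity(ce, p_hill, 293), hill, tolerance = 1e-12)

  p_lang <- slmrg_params(n = 1, nm = 47, a = 0, b = 0, w = 9.5)
  lang <- p_lang$nm * ce / (p_lang$w + ce)
  expect_equal(slmrg_capacity(ce, p_lang, 303), lang, tolerance = 1e-12)
})

test_that("capacity is bounded by Qsat and tracks the effective concentration", {
  # qe = Qsat/(1 + (w/f)^n) is strictly increasing in f, so on any grid the
  # capacity must rise and fall exactly where f does; for strongly cohesive
  # parameter sets f itself turns over at high ce (the real-gas correction
  # leaves its validity range), so monotonicity in ce is not universal.
  for (rec in ref_params_list()) {
    p <- rec$params
    hi <- 0.9 / p$b
    ce <- seq(hi / 500, hi, length.out = 300)
    f <- effective_concentration(ce, p, rec$temperature)
    q <- slmrg_capacity(ce, p, rec$temperature)
    lab <- sprintf("%s %g K", rec$adsorbent, rec$temperature)
    expect_true(all(q >= 0 & q < saturation_capacity(p)), label = lab)
    expect_true(all(diff(q)[diff(f) > 0] > 0), label = lab)
    expect_true(all(diff(q)[diff(f) < 0] < 0), label = lab)
  }
  # at experimentally mild corrections the isotherm is monotone in ce itself
  for (key in c("OWP_293", "OWPSA_293", "OWPSA_303", "alginate_293")) {
    rec <- ref_params_list()[[key]]
    ce <- seq(0.2, 0.9 / rec$params$b, length.out = 300)
    expect_true(all(diff(slmrg_capacity(ce, rec$params,
                                        rec$temperature)) > 0), label = key)
  }
})

test_that("saturation capacity is the steric product n * Nm", {
  expect_equal(saturation_capacity(slmrg_params(1, 88, w = 1)), 88)
  expect_equal(saturation_capacity(slmrg_params(2.037, 50.391, w = 1)),
               102.647, tolerance = 0.01 / 102.647)
  expect_equal(saturation_capacity(slmrg_params(2.860, 44.712, w = 1)),
               127.869, tolerance = 0.01 / 127.869)
})

test_that("energetic parameter and adsorption energy are inverse maps", {
  # analytic cases
  expect_equal(energetic_parameter(cs = 100, ea = 0, temperature = 300), 100)
  expect_equal(energetic_parameter(100, 8.314 * 300 * log(10), 300), 10,
               tolerance = 1e-12)
  # reference-scale case, hand arithmetic: 8.314 * 293 * ln(100/9.283)
  expect_equal(adsorption_energy(w = 9.283, cs = 100, temperature = 293),
               5790.341, tolerance = 1e-6)
  # round-trip identity across magnitudes
  for (ea in c(-2e3, 0, 1e3, 2e4)) {
    w <- suppressWarnings(energetic_parameter(150, ea, 310))
    expect_equal(suppressWarnings(adsorption_energy(w, 150, 310)), ea,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # negative energy is flagged, not an error
  expect_warning(ea <- adsorption_energy(w = 200, cs = 100, temperature = 293),
                 "negative")
  expect_identical(attr(ea, "flag"), "negative_energy")
})

test_that("integrated kinetic models match their closed forms", {
  # PSO half-saturation at t = 1/(k2*qe)
  expect_equal(pso_capacity(25, qe = 40, k2 = 0.001), 20)
  # PFO at t = 1/k1 reaches qe*(1 - 1/e)
  expect_equal(pfo_capacity(100, qe = 40, k1 = 0.01), 40 * (1 - exp(-1)))
  expect_equal(pfo_capacity(100, qe = 40, k1 = 0.01), 25.28482,
               tolerance = 1e-6)
  expect_equal(ipd_capacity(25, kid = 2, c = 5), 15)
  # both start at zero and saturate at qe
  expect_equal(pfo_capacity(0, 40, 0.01), 0)
  expect_equal(pso_capacity(0, 40, 0.001), 0)
  expect_equal(pfo_capacity(1e7, 40, 0.01), 40, tolerance = 1e-8)
  expect_equal(pso_capacity(1e9, 40, 0.001), 40, tolerance = 1e-4)
  expect_error(pfo_capacity(-1, 40, 0.01), ">= 0")
})

test_that("PFO and PSO agree to first order at small t when initial rates match", {
  qe <- 40
  k1 <- 0.01
  k2 <- k1 / qe  # makes qe*k1 = qe^2*k2
  t <- 10^seq(-4, -1, length.out = 10)
  ratio <- pfo_capacity(t, qe, k1) / pso_capacity(t, qe, k2)
  expect_equal(ratio[1], 1, tolerance = 1e-4)
  expect_true(all(abs(ratio - 1) < 1e-2))
})

test_that("batch mass balance and removal efficiency are consistent", {
  # dose m/V = 1 g/L, qe = 39.77 mg/g from c0 = 50 mg/L
  expect_equal(removal_efficiency(qe = 39.77, c0 = 50, volume = 0.02,
                                  mass = 0.02), 79.54)
  expect_equal(batch_capacity(ce = 50, c0 = 50, volume = 0.02, mass = 0.02), 0)
  expect_equal(removal_efficiency(0, 50, 0.02, 0.02), 0)
  # mass-balance inversion: ce implied by the published capacity
  qe <- 39.77
  ce <- 50 - qe * 0.02 / 0.02
  expect_equal(ce, 10.23)
  expect_equal(batch_capacity(ce, 50, 0.02, 0.02), qe)
  expect_error(batch_capacity(ce = 60, c0 = 50, volume = 0.02, mass = 0.02),
               "exceeds")
})
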