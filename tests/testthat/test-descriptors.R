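# Conceptual-DFT descriptors, sigma-profile regions, QTAIM classification.

test_that("every derivable descriptor cell is reproduced from the orbital energies", {
  ref <- ref_orbitals()
  d <- global_descriptors(ref$e_homo, ref$e_lumo, ref$species)
  # the published energies carry 3 decimals, so derived cells can differ
  # from the tabulated (unrounded-input) values by one unit in the last digit
  ulp <- 0.001 + 1e-12
  expect_true(all(abs(d$gap - ref$gap) <= ulp))
  expect_true(all(abs(d$mu - ref$mu) <= ulp))
  expect_true(all(abs(d$chi - ref$chi) <= ulp))
  expect_true(all(abs(d$eta - ref$eta) <= ulp))
  expect_equal(d$omega, ref$omega, tolerance = 0.003 / min(ref$omega))
  expect_equal(d$dn_max, ref$dn_max, tolerance = 0.003)
})

test_that("descriptor identities hold for arbitrary orbital pairs", {
  set.seed(5)
  eh <- runif(30, -20, -1)
  el <- eh + runif(30, 0.1, 10)
  d <- global_descriptors(eh, el)
  expect_equal(d$gap, 2 * d$eta, tolerance = 1e-12)
  expect_equal(d$chi, -d$mu, tolerance = 1e-12)
  expect_true(all(d$omega >= 0))
  # symmetric orbitals: mu = 0 hence omega = 0
  sym <- global_descriptors(-3, 3)
  expect_equal(sym$mu, 0)
  expect_equal(sym$omega, 0)
  expect_error(global_descriptors(-5, -5, "degenerate"), "degenerate")
})

test_that("frontier-gap reactivity ordering is lignin < hemicellulose < alginate < cellulose", {
  ref <- ref_orbitals()
  d <- global_descriptors(ref$e_homo, ref$e_lumo, ref$species)
  gaps <- setNames(d$gap, d$species)
  expect_true(gaps[["lignin"]] < gaps[["hemicellulose"]] &&
              gaps[["hemicellulose"]] < gaps[["alginate"]] &&
              gaps[["alginate"]] < gaps[["cellulose"]])
})

test_that("charge-transfer index supports both conventions", {
  ref <- ref_orbitals()
  d <- global_descriptors(ref$e_homo, ref$e_lumo, ref$species)
  cu <- d[d$species == "Cu2+", ]
  alg <- d[d$species == "alginate", ]
  hemi <- d[d$species == "hemicellulose", ]
  expect_equal(charge_transfer(hemi, variant = "table_single"), 1.517,
               tolerance = 0.003)
  expect_equal(charge_transfer(cu, variant = "table_single"), 3.415,
               tolerance = 0.003)
  # pairwise form, hand arithmetic: (13.811 - 2.727)/(2*(4.044 + 2.201))
  expect_equal(charge_transfer(cu, alg, variant = "pairwise"),
               (13.811 - 2.727) / (2 * (4.044 + 2.201)), tolerance = 1e-3)
  expect_equal(charge_transfer(cu, alg, variant = "pairwise"), 0.8874,
               tolerance = 1e-3)
  expect_error(charge_transfer(cu, variant = "pairwise"), "donor")
})

test_that("sigma-profile regions partition the area and handle edge cases", {
  # profile entirely inside the nonpolar window
  r <- sigma_regions(seq(-0.006, 0.006, by = 0.001),
                     rep(2, 13))
  expect_equal(unname(r$fractions[["nonpolar"]]), 1)
  # single spike in the acceptor region
  r <- sigma_regions(c(0.018, 0.02, 0.022), c(0, 5, 0))
  expect_equal(unname(r$fractions[["hba"]]), 1)
  # two equal spikes at +-0.02 split evenly between donor and acceptor
  r <- sigma_regions(c(-0.022, -0.02, -0.018, 0.018, 0.02, 0.022),
                     c(0, 5, 0, 0, 5, 0))
  expect_equal(unname(r$fractions[["hbd"]]), 0.5)
  expect_equal(unname(r$fractions[["hba"]]), 0.5)
  # fractions are a partition for a generic smooth profile
  sg <- seq(-0.03, 0.03, by = 0.0005)
  r <- sigma_regions(sg, exp(-(sg / 0.01)^2) + 0.3 * exp(-((sg - 0.015) / 0.004)^2))
  expect_true(all(r$fractions >= 0))
  expect_equal(sum(r$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(r$areas), r$total, tolerance = 1e-12)
  # zero profile flagged degenerate
  r0 <- sigma_regions(c(-0.01, 0, 0.01), c(0, 0, 0))
  expect_true(r0$degenerate)
  expect_true(all(is.na(r0$fractions)))
})

test_that("bond-critical-point classification follows the G/|V| and Laplacian rules", {
  r <- classify_bcp(rho = 0.05, lap_rho = 0.2, g = 0.05, v = -0.08)
  expect_equal(r$ratio, 0.625)
  expect_equal(r$h, -0.03)
  expect_identical(r$class, "partially_covalent")
  # boundary ratio of one is weak/noncovalent
  r <- classify_bcp(0.02, 0.15, g = 0.05, v = -0.05)
  expect_equal(r$ratio, 1)
  expect_identical(r$class, "noncovalent_weak")
  # negative Laplacian means shared-shell covalency
  r <- classify_bcp(0.3, -0.8, g = 0.1, v = -0.4)
  expect_identical(r$class, "covalent")
  # identity: v = -2g gives h = -g
  g <- c(0.03, 0.11)
  r <- classify_bcp(c(0.1, 0.2), c(0.5, 0.5), g, -2 * g)
  expect_equal(r$h, -g)
  expect_error(classify_bcp(0.1, 0.2, 0.05, 0), "undefined")
})
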