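# Seeded generators producing data with the statistical structure each
# analysis stage assumes, so the full pipeline is testable without external
# measurements. Noise is multiplicative Gaussian by default: batch sorption
# capacities span an order of magnitude across datasets, so a constant
# relative error is the defensible default; an additive option is available.

apply_noise <- function(y, noise_sd, seed, noise_model) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd == 0) return(y)
  draw <- function() {
    eps <- stats::rnorm(length(y), 0, noise_sd)
    switch(noise_model,
           multiplicative = y * (1 + eps),
           additive = y + eps,
           stop("unknown noise model: ", noise_model))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Generate a synthetic SLMRG isotherm dataset
#'
#' Evaluates the SLMRG forward model on a concentration grid and perturbs it
#' with seeded multiplicative Gaussian noise:
#' `qe_i = slmrg_capacity(ce_i) * (1 + eps_i)`, `eps_i ~ N(0, noise_sd^2)`.
#' The default grid is `n_points` log-spaced concentrations in
#' `[1, 0.8/b]` mg/L (or `[1, 100]` when `b = 0`), mimicking batch isotherm
#' designs that crowd points at low concentration.
#'
#' @param params an [slmrg_params()] object or named list.
#' @param temperature absolute temperature, K.
#' @param grid optional explicit Ce grid, mg/L, inside `(0, 1/b)`.
#' @param n_points grid size when `grid` is not given (default 12).
#' @param noise_sd relative noise standard deviation (default 0, i.e.
#'   noiseless).
#' @param noise_model `"multiplicative"` or `"additive"` (`noise_sd` is then
#'   in mg/g).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param adsorbent label for the dataset.
#' @return An [isotherm_data()] object.
#' @export
gen_isotherm <- function(params, temperature, grid = NULL, n_points = 12,
                         noise_sd = 0, noise_model = "multiplicative",
                         seed = NULL, adsorbent = "synthetic") {
  params <- as_slmrg_params(params)
  if (is.null(grid)) {
    ce_max <- if (params$b > 0) 0.8 / params$b else 100
    grid <- exp(seq(log(1), log(ce_max), length.out = n_points))
  }
  if (any(grid <= 0)) stop("the Ce grid must be > 0")
  if (params$b > 0 && any(grid >= 1 / params$b))
    stop(sprintf("Ce grid exceeds the model domain (0, 1/b = %g mg/L)",
                 1 / params$b))
  qe <- slmrg_capacity(grid, params, temperature)
  qe <- pmax(apply_noise(qe, noise_sd, seed, noise_model), 0)
  isotherm_data(grid, qe, temperature, adsorbent)
}

#' Generate a synthetic kinetic trace
#'
#' Evaluates the integrated pseudo-first-order, pseudo-second-order or
#' Weber-Morris forward model on a time grid, optionally with seeded noise.
#' For `"ipd"`, `params` may also be a list of up to three
#' `list(kid, c)` records with a `breaks` vector of times, producing a
#' piecewise multi-regime trace (values are taken from the regime the time
#' falls in).
#'
#' @param model `"pfo"`, `"pso"` or `"ipd"`.
#' @param params named list: `qe, k1` (pfo); `qe, k2` (pso); `kid, c` or
#'   `list(segments = list(list(kid, c), ...), breaks = c(...))` (ipd).
#' @param grid time grid, min; strictly increasing, >= 0. Default 14 points
#'   from 5 to 600 min.
#' @inheritParams gen_isotherm
#' @return A [kinetic_trace()] object.
#' @export
gen_kinetics <- function(model = c("pfo", "pso", "ipd"), params, grid = NULL,
                         noise_sd = 0, noise_model = "multiplicative",
                         seed = NULL) {
  model <- match.arg(model)
  if (is.null(grid))
    grid <- c(5, 10, 20, 30, 45, 60, 90, 120, 180, 240, 300, 360, 480, 600)
  qt <- switch(model,
    pfo = pfo_capacity(grid, params$qe, params$k1),
    pso = pso_capacity(grid, params$qe, params$k2),
    ipd = {
      if (!is.null(params$segments)) {
        breaks <- params$breaks
        if (length(breaks) != length(params$segments) - 1)
          stop("'breaks' must have one fewer entry than 'segments'")
        regime <- findInterval(grid, breaks, left.open = TRUE) + 1
        vapply(seq_along(grid), function(i) {
          s <- params$segments[[regime[i]]]
          ipd_capacity(grid[i], s$kid, s$c)
        }, numeric(1))
      } else ipd_capacity(grid, params$kid, params$c)
    })
  qt <- pmax(apply_noise(qt, noise_sd, seed, noise_model), 0)
  kinetic_trace(grid, qt)
}

#' Generate a thermodynamically consistent equilibrium-constant series
#'
#' Inverts the van't Hoff relation: `K(T) = exp(dS/R - dH/(R*T))` with the
#' inputs in kJ, so [vant_hoff()] on the output recovers `(dh, ds)` exactly.
#'
#' @param dh standard enthalpy, kJ/mol.
#' @param ds standard entropy, kJ/(mol K).
#' @param temperatures absolute temperatures, K, strictly increasing.
#' @return A data.frame with columns `temperature` (K) and `kads`.
#' @export
gen_vant_hoff_series <- function(dh, ds, temperatures) {
  stopifnot(is.finite(dh), is.finite(ds))
  if (any(temperatures <= 0)) stop("temperatures must be > 0 (kelvin)")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  data.frame(temperature = temperatures,
             kads = exp(ds * 1000 / .Rgas - dh * 1000 / (.Rgas * temperatures)))
}

#' Generate a pH-drift titration curve
#'
#' A smooth, monotone-decreasing drift curve with its unique zero planted at
#' the requested point of zero charge:
#' `delta_pH = amplitude * tanh((true_pzc - pH)/width)`, optionally with
#' seeded additive noise.
#'
#' @param true_pzc the planted point of zero charge; must lie inside the
#'   grid range.
#' @param grid initial-pH grid, strictly increasing (default 2 to 12 in 0.5
#'   steps).
#' @param amplitude saturation drift, pH units (default 1.5).
#' @param width transition width, pH units (default 2).
#' @param noise_sd additive noise SD in pH units (default 0).
#' @param seed integer seed.
#' @return A data.frame with columns `ph_initial`, `delta_ph`.
#' @export
gen_pzc_curve <- function(true_pzc, grid = seq(2, 12, by = 0.5),
                          amplitude = 1.5, width = 2,
                          noise_sd = 0, seed = NULL) {
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (true_pzc <= min(grid) || true_pzc >= max(grid))
    stop(sprintf("true_pzc = %g lies outside the grid range [%g, %g]",
                 true_pzc, min(grid), max(grid)))
  delta <- amplitude * tanh((true_pzc - grid) / width)
  delta <- apply_noise(delta, noise_sd, seed, "additive")
  data.frame(ph_initial = grid, delta_ph = delta)
}
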