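# Integrated forward models for sorption kinetics and batch mass-balance
# quantities.

#' Kinetic trace constructor
#'
#' A validated (t, qt) record of instantaneous adsorbed amount against
#' contact time.
#'
#' @param t contact times, min; strictly increasing, all >= 0.
#' @param qt instantaneous capacities, mg/g; all >= 0, same length as `t`.
#' @return A data.frame of class `"kinetic_trace"` with columns `t`, `qt`.
#' @export
kinetic_trace <- function(t, qt) {
  stopifnot(is.numeric(t), is.numeric(qt))
  if (length(t) != length(qt))
    stop("'t' and 'qt' must have the same length")
  if (any(t < 0)) stop("'t' must be >= 0")
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (any(qt < 0)) stop("'qt' must be >= 0")
  structure(data.frame(t = t, qt = qt),
            class = c("kinetic_trace", "data.frame"))
}

as_kinetic_trace <- function(x) {
  if (inherits(x, "kinetic_trace")) return(x)
  if (is.data.frame(x) && all(c("t", "qt") %in% names(x)))
    return(kinetic_trace(x$t, x$qt))
  stop("expected a kinetic_trace or a data.frame with columns t, qt")
}

#' Pseudo-first-order kinetic model
#'
#' Integrated Lagergren form `qt = qe * (1 - exp(-k1 * t))`.
#'
#' @param t time(s), min; >= 0.
#' @param qe equilibrium capacity, mg/g (> 0).
#' @param k1 first-order rate constant, 1/min (> 0).
#' @return Capacity value(s), mg/g.
#' @export
pfo_capacity <- function(t, qe, k1) {
  stopifnot(qe > 0, k1 > 0)
  if (any(t < 0)) stop("'t' must be >= 0")
  qe * (1 - exp(-k1 * t))
}

#' Pseudo-second-order kinetic model
#'
#' Integrated Ho-McKay form `qt = qe^2 * k2 * t / (1 + qe * k2 * t)`.
#'
#' @param t time(s), min; >= 0.
#' @param qe equilibrium capacity, mg/g (> 0).
#' @param k2 second-order rate constant, g/(mg*min) (> 0).
#' @return Capacity value(s), mg/g.
#' @export
pso_capacity <- function(t, qe, k2) {
  stopifnot(qe > 0, k2 > 0)
  if (any(t < 0)) stop("'t' must be >= 0")
  qe^2 * k2 * t / (1 + qe * k2 * t)
}

#' Weber-Morris intra-particle diffusion model
#'
#' `qt = kid * sqrt(t) + c`; a nonzero intercept `c` is read as the
#' thickness of the boundary layer.
#'
#' @param t time(s), min; >= 0.
#' @param kid intra-particle diffusion rate constant, mg/(g*min^0.5) (>= 0).
#' @param c boundary-layer intercept, mg/g.
#' @return Capacity value(s), mg/g.
#' @export
ipd_capacity <- function(t, kid, c = 0) {
  stopifnot(kid >= 0)
  if (any(t < 0)) stop("'t' must be >= 0")
  kid * sqrt(t) + c
}

#' Batch mass balance: capacity and removal efficiency
#'
#' `batch_capacity()` converts an equilibrium concentration into a capacity
#' by mass balance, `qe = (c0 - ce) * volume / mass`.
#' `removal_efficiency()` expresses an achieved capacity as the percentage of
#' the initial load removed, `100 * qe * (mass/volume) / c0`.
#'
#' @param ce equilibrium concentration, mg/L; `0 <= ce <= c0`.
#' @param c0 initial concentration, mg/L (>= 0).
#' @param volume solution volume, L (> 0).
#' @param mass adsorbent mass, g (> 0).
#' @return `batch_capacity()`: mg adsorbate per g adsorbent.
#'   `removal_efficiency()`: percent removed, in `[0, 100]`.
#' @export
batch_capacity <- function(ce, c0, volume, mass) {
  stopifnot(c0 >= 0, volume > 0, mass > 0)
  if (any(ce < 0)) stop("'ce' must be >= 0")
  if (any(ce > c0))
    stop("'ce' exceeds the initial concentration 'c0'; negative uptake signals an input mistake")
  (c0 - ce) * volume / mass
}

#' @rdname batch_capacity
#' @param qe equilibrium capacity, mg/g.
#' @export
removal_efficiency <- function(qe, c0, volume, mass) {
  stopifnot(c0 > 0, volume > 0, mass > 0)
  if (any(qe < 0)) stop("'qe' must be >= 0")
  eff <- 100 * qe * (mass / volume) / c0
  if (any(eff > 100 + 1e-9))
    stop("implied removal above 100%; check qe against the mass balance")
  pmin(eff, 100)
}
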