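# Single-layer statistical-physics isotherm coupled to a real-gas (van der
# Waals) description of the dissolved adsorbate: forward model and closed-form
# quantities derived from its parameters.

# Physical constants used throughout: Boltzmann constant in J/K and the molar
# gas constant in J/(mol K).
.kB <- 1.380649e-23
.Rgas <- 8.314

#' SLMRG parameter set
#'
#' Bundles and validates the five parameters of the single-layer
#' statistical-physics isotherm with real-gas (van der Waals) corrections:
#' the grand-canonical occupation of `nm` receptor sites per gram, each
#' binding `n` adsorbate units, with the solution phase corrected for
#' molecular cohesion (`a`) and co-volume (`b`).
#'
#' @param n sites-per-molecule exponent (dimensionless, > 0). Values below 1
#'   mean one ion spans several sites; values above 1 mean several ions share
#'   one site.
#' @param nm receptor-site density, mg/g (> 0).
#' @param a cohesion pressure in units of 1e-23 J*L/mg (>= 0), the convention
#'   in which fitted values for aqueous metal uptake are O(10).
#' @param b co-volume, L/mg (>= 0). The model is only defined for
#'   `ce < 1/b`.
#' @param w energetic parameter, mg/L (> 0): the concentration scale at which
#'   half the saturation capacity is reached in the ideal limit.
#' @return An object of class `"slmrg_params"` (a named list).
#' @seealso [slmrg_capacity()], [saturation_capacity()], [fit_slmrg()]
#' @export
slmrg_params <- function(n, nm, a = 0, b = 0, w) {
  vals <- c(n = n, nm = nm, a = a, b = b, w = w)
  if (!all(is.finite(vals)))
    stop("SLMRG parameters must all be finite, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (n <= 0) stop("'n' must be > 0")
  if (nm <= 0) stop("'nm' must be > 0")
  if (a < 0) stop("'a' must be >= 0")
  if (b < 0) stop("'b' must be >= 0")
  if (w <= 0) stop("'w' must be > 0")
  structure(list(n = n, nm = nm, a = a, b = b, w = w),
            class = "slmrg_params")
}

#' @export
print.slmrg_params <- function(x, digits = 4, ...) {
  cat("SLMRG parameters:\n")
  cat(sprintf("  n  = %-10.4g (sites per molecule)\n", x$n))
  cat(sprintf("  Nm = %-10.4g mg/g (receptor-site density)\n", x$nm))
  cat(sprintf("  a  = %-10.4g x 1e-23 J*L/mg (cohesion pressure)\n", x$a))
  cat(sprintf("  b  = %-10.4g L/mg (co-volume)\n", x$b))
  cat(sprintf("  w  = %-10.4g mg/L (energetic parameter)\n", x$w))
  cat(sprintf("  Qsat = n*Nm = %.4g mg/g\n", x$n * x$nm))
  invisible(x)
}

as_slmrg_params <- function(p) {
  if (inherits(p, "slmrg_params")) return(p)
  if (is.list(p) || (is.numeric(p) && !is.null(names(p)))) {
    p <- as.list(p)
    need <- c("n", "nm", "w")
    if (!all(need %in% names(p)))
      stop("SLMRG parameters need at least named components n, nm, w")
    return(slmrg_params(n = p$n, nm = p$nm,
                        a = if (is.null(p$a)) 0 else p$a,
                        b = if (is.null(p$b)) 0 else p$b,
                        w = p$w))
  }
  stop("cannot interpret 'params' as SLMRG parameters")
}

#' Van der Waals effective (corrected) concentration
#'
#' Maps the measured equilibrium concentration onto the effective
#' concentration seen by the adsorption equilibrium once the dissolved phase
#' is treated as a van der Waals fluid:
#' `f = ce/(1 - b*ce) * exp(b*ce/(1 - b*ce)) * exp(-2*a*beta*ce)` with
#' `beta = 1/(kB*T)`. The co-volume factors inflate the activity as solute
#' crowding grows; the cohesion factor deflates it. With `a = b = 0` the
#' correction vanishes and `f = ce`.
#'
#' @param ce equilibrium concentration(s), mg/L; must satisfy
#'   `0 <= ce < 1/b`.
#' @param params an [slmrg_params()] object (or named list coercible to one).
#' @param temperature absolute temperature, K.
#' @return Effective concentration(s), mg/L.
#' @export
effective_concentration <- function(ce, params, temperature) {
  params <- as_slmrg_params(params)
  stopifnot(is.numeric(ce), is.numeric(temperature), temperature > 0)
  if (any(ce < 0)) stop("'ce' must be >= 0")
  if (params$b > 0 && any(ce >= 1 / params$b))
    stop(sprintf(
      "ce = %g reaches the co-volume singularity at 1/b = %g mg/L; the model is undefined there",
      max(ce), 1 / params$b))
  # a is stored in 1e-23 J*L/mg, so the 1e-23 cancels against kB
  two_a_beta <- 2 * params$a / (1.380649 * temperature)
  bC <- params$b * ce
  ce / (1 - bC) * exp(bC / (1 - bC)) * exp(-two_a_beta * ce)
}

#' SLMRG equilibrium adsorption capacity
#'
#' Forward model for the adsorbed amount at equilibrium:
#' `qe = n*Nm / (1 + (w/f)^n)`, where `f` is the van der Waals effective
#' concentration of [effective_concentration()]. At `a = b = 0` this is the
#' Hill isotherm, and additionally at `n = 1` the Langmuir isotherm.
#' `qe(0)` is defined as 0 by continuous extension.
#'
#' @inheritParams effective_concentration
#' @return Capacity value(s), mg/g, in `[0, n*Nm)`.
#' @export
slmrg_capacity <- function(ce, params, temperature) {
  params <- as_slmrg_params(params)
  f <- effective_concentration(ce, params, temperature)
  qe <- params$n * params$nm / (1 + (params$w / f)^params$n)
  qe[ce == 0] <- 0
  qe
}

#' Saturation capacity of an SLMRG isotherm
#'
#' The plateau (maximum monolayer) capacity is the product of the two steric
#' parameters, `Qsat = n * Nm`.
#'
#' @param params an [slmrg_params()] object or named list.
#' @return Saturation capacity, mg/g.
#' @export
saturation_capacity <- function(params) {
  params <- as_slmrg_params(params)
  params$n * params$nm
}

#' Energetic parameter from an adsorption energy, and its inverse
#'
#' The energetic parameter of the SLMRG model factorizes as
#' `w = cs * exp(-Ea/(R*T))`, with `cs` a reference concentration (commonly
#' the solubility, mg/L) and `Ea` the molar adsorption energy (J/mol).
#' `adsorption_energy()` inverts the relation: `Ea = R*T*log(cs/w)`.
#'
#' @param cs reference concentration, mg/L (> 0).
#' @param ea adsorption energy, J/mol.
#' @param temperature absolute temperature, K.
#' @return `energetic_parameter()`: `w` in mg/L. `adsorption_energy()`:
#'   `Ea` in J/mol; when `w > cs` the energy is negative and carries
#'   attribute `flag = "negative_energy"` (with a warning) since a
#'   user-supplied `cs` below the fitted `w` usually signals a questionable
#'   reference concentration rather than a hard error.
#' @export
energetic_parameter <- function(cs, ea, temperature) {
  stopifnot(cs > 0, temperature > 0, is.finite(ea))
  cs * exp(-ea / (.Rgas * temperature))
}

#' @rdname energetic_parameter
#' @param w energetic parameter, mg/L (> 0).
#' @export
adsorption_energy <- function(w, cs, temperature) {
  stopifnot(w > 0, cs > 0, temperature > 0)
  ea <- .Rgas * temperature * log(cs / w)
  if (any(ea < 0)) {
    warning("w > cs gives a negative adsorption energy; check the reference concentration 'cs'")
    attr(ea, "flag") <- "negative_energy"
  }
  ea
}
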