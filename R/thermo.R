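# Equilibrium thermodynamics of adsorption: Gibbs energy from the
# equilibrium constant, van't Hoff regression for enthalpy/entropy, sorption
# regime classification, and point-of-zero-charge determination.

#' Standard Gibbs energy of adsorption
#'
#' `dG = -R*T*ln(K)` with R = 8.314 J/(mol K), reported in kJ/mol. Negative
#' values (K > 1) indicate a spontaneous process.
#'
#' @param k dimensionless equilibrium adsorption constant(s), > 0.
#' @param temperature absolute temperature(s), K.
#' @return Gibbs energy, kJ/mol.
#' @export
gibbs_energy <- function(k, temperature) {
  if (any(k <= 0)) stop("'k' must be > 0")
  if (any(temperature <= 0)) stop("'temperature' must be > 0 (kelvin)")
  -.Rgas * temperature * log(k) / 1000
}

#' Van't Hoff analysis of an equilibrium-constant series
#'
#' Ordinary least squares of `ln K` on `1/T`:
#' `ln K = dS/R - dH/(R*T)`, so the slope gives the standard enthalpy
#' (`dH = -R*slope`) and the intercept the standard entropy
#' (`dS = R*intercept`). Per-temperature Gibbs energies are computed from the
#' input constants via [gibbs_energy()], and the enthalpy is classified into
#' a sorption regime by [classify_sorption()].
#'
#' @param temperatures absolute temperatures, K; strictly increasing,
#'   length >= 2.
#' @param kads dimensionless equilibrium constants, same length, all > 0.
#' @param adsorbent label stored on the result.
#' @param threshold chemisorption enthalpy threshold, kJ/mol (default 40).
#' @return An object of class `"vant_hoff"`: list with `dh` (kJ/mol), `ds`
#'   (kJ/(mol K)), `dg` (kJ/mol, one per temperature), `r2`, `regime`,
#'   `temperatures`, `kads`, `coefficients` (`dh`, `ds`). Supports `print()`,
#'   `coef()`, `predict()` (K at new temperatures) and `plot()`.
#' @examples
#' vh <- vant_hoff(c(293, 303, 313), c(1.6829, 2.0825, 2.5422))
#' coef(vh)
#' @export
vant_hoff <- function(temperatures, kads, adsorbent = "adsorbent",
                      threshold = 40) {
  stopifnot(is.numeric(temperatures), is.numeric(kads))
  if (length(temperatures) != length(kads))
    stop("'temperatures' and 'kads' must have the same length")
  if (length(temperatures) < 2)
    stop("van't Hoff regression needs at least 2 temperatures")
  if (any(temperatures <= 0)) stop("temperatures must be > 0 (kelvin)")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing (duplicates make the design singular)")
  if (any(kads <= 0)) stop("'kads' must be > 0")
  reg <- stats::lm(lnk ~ invT,
                   data = data.frame(invT = 1 / temperatures, lnk = log(kads)))
  slope <- unname(stats::coef(reg)[2])
  intercept <- unname(stats::coef(reg)[1])
  dh <- -.Rgas * slope / 1000
  ds <- .Rgas * intercept / 1000
  r2 <- if (length(temperatures) == 2) 1 else reg_r2(reg)
  structure(list(dh = dh, ds = ds,
                 dg = gibbs_energy(kads, temperatures),
                 r2 = r2,
                 regime = classify_sorption(dh, threshold),
                 temperatures = temperatures, kads = kads,
                 adsorbent = adsorbent,
                 coefficients = c(dh = dh, ds = ds)),
            class = "vant_hoff")
}

#' @export
coef.vant_hoff <- function(object, ...) object$coefficients

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf("Van't Hoff analysis: %s, %d temperatures (%g-%g K)\n",
              x$adsorbent, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  cat(sprintf("  dH = %.4f kJ/mol, dS = %.4f kJ/(mol K), R2 = %.5f\n",
              x$dh, x$ds, x$r2))
  cat("  dG (kJ/mol):",
      paste(sprintf("%.3f (%g K)", x$dg, x$temperatures), collapse = ", "),
      "\n")
  cat(sprintf("  Regime: %s\n", x$regime))
  invisible(x)
}

#' @export
predict.vant_hoff <- function(object, temperatures = NULL, ...) {
  if (is.null(temperatures)) temperatures <- object$temperatures
  exp(object$ds * 1000 / .Rgas - object$dh * 1000 / (.Rgas * temperatures))
}

#' @export
plot.vant_hoff <- function(x, ...) {
  graphics::plot(1 / x$temperatures, log(x$kads),
                 xlab = "1/T (1/K)", ylab = "ln K",
                 main = sprintf("Van't Hoff plot: %s", x$adsorbent), ...)
  graphics::abline(a = x$ds * 1000 / .Rgas, b = -x$dh * 1000 / .Rgas)
  invisible(x)
}

#' Sorption regime from the standard enthalpy
#'
#' Classifies an adsorption enthalpy against the conventional
#' chemisorption threshold: `"chemisorption"` iff `dh` strictly exceeds the
#' threshold (40 kJ/mol by default), else `"physisorption"`.
#'
#' @param dh standard adsorption enthalpy, kJ/mol (finite).
#' @param threshold threshold, kJ/mol.
#' @return `"physisorption"` or `"chemisorption"` (vectorized over `dh`).
#' @export
classify_sorption <- function(dh, threshold = 40) {
  if (any(!is.finite(dh))) stop("'dh' must be finite")
  ifelse(dh > threshold, "chemisorption", "physisorption")
}

#' Point of zero charge from a pH-drift titration
#'
#' Locates the zero crossing of the drift curve `delta_pH = f(pH_initial)`
#' by linear interpolation between the first bracketing pair of points. The
#' crossing pH is the point of zero charge: below it the surface is
#' positively charged, above it negatively.
#'
#' @param ph_initial initial pH values, strictly increasing, length >= 2.
#' @param delta_ph observed drifts `pH_final - pH_initial`, same length.
#' @return The pH of zero charge (scalar).
#' @export
pzc_from_titration <- function(ph_initial, delta_ph) {
  stopifnot(is.numeric(ph_initial), is.numeric(delta_ph))
  if (length(ph_initial) != length(delta_ph))
    stop("'ph_initial' and 'delta_ph' must have the same length")
  if (length(ph_initial) < 2) stop("at least 2 titration points are needed")
  if (any(diff(ph_initial) <= 0))
    stop("'ph_initial' must be strictly increasing")
  exact <- which(delta_ph == 0)
  sgn <- sign(delta_ph)
  cross <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  if (length(exact) && (!length(cross) || exact[1] <= cross[1]))
    return(ph_initial[exact[1]])
  if (!length(cross))
    stop("no zero crossing in titration range; widen the initial-pH grid")
  i <- cross[1]
  ph_initial[i] + delta_ph[i] * (ph_initial[i + 1] - ph_initial[i]) /
    (delta_ph[i] - delta_ph[i + 1])
}
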