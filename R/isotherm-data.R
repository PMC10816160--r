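#' Equilibrium isotherm dataset
#'
#' A validated set of (Ce, qe) pairs measured at a single temperature for one
#' adsorbent.
#'
#' @param ce equilibrium concentrations, mg/L; all >= 0, length >= 3.
#' @param qe equilibrium capacities, mg/g; all >= 0, same length.
#' @param temperature absolute temperature, K (> 0).
#' @param adsorbent adsorbent label (e.g. `"OWP"`).
#' @return A data.frame of class `"isotherm_data"` with columns `ce`, `qe`
#'   and attributes `temperature`, `adsorbent`.
#' @export
isotherm_data <- function(ce, qe, temperature, adsorbent = "adsorbent") {
  stopifnot(is.numeric(ce), is.numeric(qe))
  if (length(ce) != length(qe))
    stop("'ce' and 'qe' must have the same length")
  if (length(ce) < 3)
    stop("an isotherm needs at least 3 points")
  if (any(ce < 0)) stop("'ce' must be >= 0")
  if (any(qe < 0)) stop("'qe' must be >= 0")
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be a positive number (kelvin)")
  structure(data.frame(ce = ce, qe = qe),
            temperature = temperature,
            adsorbent = as.character(adsorbent),
            class = c("isotherm_data", "data.frame"))
}

as_isotherm_data <- function(x, temperature = NULL, adsorbent = "adsorbent") {
  if (inherits(x, "isotherm_data")) return(x)
  if (is.data.frame(x) && all(c("ce", "qe") %in% names(x))) {
    if (is.null(temperature))
      stop("'temperature' must be supplied when 'data' is a plain data.frame")
    return(isotherm_data(x$ce, x$qe, temperature, adsorbent))
  }
  stop("expected an isotherm_data object or a data.frame with columns ce, qe")
}

#' @export
print.isotherm_data <- function(x, ...) {
  cat(sprintf("Isotherm: %s at %g K, %d points (Ce %.3g-%.3g mg/L)\n",
              attr(x, "adsorbent"), attr(x, "temperature"), nrow(x),
              min(x$ce), max(x$ce)))
  print.data.frame(x, ...)
  invisible(x)
}
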