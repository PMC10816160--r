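# Multi-start nonlinear least-squares estimation of the SLMRG isotherm.

#' Default parameter bounds for the SLMRG fit
#'
#' Box constraints used by [fit_slmrg()]: `n` in \[0.1, 10\] (the exponent is
#' usually quoted between 1 and 10, relaxed downward because polymeric
#' adsorbents can show n < 1), `Nm` in (0, 1e4\] mg/g, `a` in \[0, 1e3\]
#' (units of 1e-23 J*L/mg), `b` in \[0, 0.9/max(ce)\] L/mg so the co-volume
#' singularity stays outside the data range, and `w` in (0, 1e4\] mg/L.
#'
#' @param ce_max largest equilibrium concentration in the data, mg/L.
#' @return A list with numeric vectors `lower` and `upper` named
#'   `n, nm, a, b, w`.
#' @export
slmrg_bounds <- function(ce_max) {
  stopifnot(ce_max > 0)
  list(lower = c(n = 0.1, nm = 1e-3, a = 0, b = 0, w = 1e-3),
       upper = c(n = 10, nm = 1e4, a = 1e3, b = 0.9 / ce_max, w = 1e4))
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# Latin-hypercube starting points over the bounds; nm and w are sampled
# log-uniformly (they span decades), a on a square-root scale (large a kills
# the model and its gradient), n and b linearly. The hypercube is drawn much
# larger than the number of local searches and screened by residual sum of
# squares: the model surface has several basins, and local searches are only
# worth spending on the most promising candidates.
slmrg_starts <- function(n_starts, bounds, ce, qe, temperature,
                         pool_factor = 64) {
  lo <- bounds$lower
  hi <- bounds$upper
  heur <- c(n = 1,
            nm = min(max(1.2 * max(qe), lo["nm"]), hi["nm"]),
            a = 0,
            b = 0,
            w = min(max(stats::median(ce), lo["w"]), hi["w"]))
  names(heur) <- names(lo)
  if (n_starts <= 1) return(list(heur))
  u <- lhs::randomLHS(pool_factor * (n_starts - 1), 5)
  colnames(u) <- names(lo)
  log_lo <- function(x) max(x, 1e-3)
  pool <- lapply(seq_len(nrow(u)), function(i) {
    s <- c(n = lo[["n"]] + u[i, "n"] * (hi[["n"]] - lo[["n"]]),
           nm = exp(log(log_lo(lo[["nm"]])) +
                      u[i, "nm"] * (log(hi[["nm"]]) - log(log_lo(lo[["nm"]])))),
           a = (sqrt(lo[["a"]]) +
                  u[i, "a"] * (sqrt(hi[["a"]]) - sqrt(lo[["a"]])))^2,
           b = lo[["b"]] + u[i, "b"] * (hi[["b"]] - lo[["b"]]),
           w = exp(log(log_lo(lo[["w"]])) +
                     u[i, "w"] * (log(hi[["w"]]) - log(log_lo(lo[["w"]])))))
    stats::setNames(s, names(lo))
  })
  sse <- vapply(pool, function(s) {
    pred <- slmrg_capacity(ce, as.list(s), temperature)
    sum((qe - pred)^2)
  }, numeric(1))
  keep <- order(sse)[seq_len(n_starts - 1)]
  c(list(heur), pool[keep])
}

#' Fit the SLMRG isotherm by multi-start nonlinear least squares
#'
#' Estimates the five SLMRG parameters (n, Nm, a, b, w) by bounded
#' Levenberg-Marquardt least squares, restarted from a Latin-hypercube of
#' seeded starting points plus one data-driven heuristic start, keeping the
#' solution with the lowest residual sum of squares.
#'
#' @param data an [isotherm_data()] object, or a data.frame with columns
#'   `ce`, `qe` (then `temperature` is required).
#' @param temperature absolute temperature, K; taken from `data` when it is
#'   an `isotherm_data` object.
#' @param n_starts number of starting points (>= 1; default 32).
#' @param seed integer seed controlling the Latin-hypercube draw.
#' @param bounds parameter box as returned by [slmrg_bounds()]; defaults to
#'   `slmrg_bounds(max(ce))`.
#' @param adsorbent label stored on the result (taken from `data` when
#'   available).
#' @return An object of class `c("slmrg_fit", "sorption_fit")` with
#'   components `params` ([slmrg_params()]), `r2`, `rmse`, `sse`, `n_obs`,
#'   `converged`, `starts_tried`, `temperature`, `data`, `bounds`, `seed`.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `fitted()`,
#'   `residuals()`, `plot()` and `simulate()`.
#' @examples
#' p <- slmrg_params(n = 2.037, nm = 50.391, a = 8.46, b = 0.008, w = 9.283)
#' d <- gen_isotherm(p, temperature = 293, n_points = 15)
#' f <- fit_slmrg(d, seed = 7)
#' coef(f)
#' @export
fit_slmrg <- function(data, temperature = NULL, n_starts = 32, seed = 1L,
                      bounds = NULL, adsorbent = NULL) {
  data <- as_isotherm_data(data, temperature = temperature,
                           adsorbent = if (is.null(adsorbent)) "adsorbent" else adsorbent)
  temperature <- attr(data, "temperature")
  adsorbent <- attr(data, "adsorbent")
  ce <- data$ce
  qe <- data$qe
  if (length(ce) < 6)
    stop("fitting five parameters needs at least 6 isotherm points")
  if (n_starts < 1) stop("'n_starts' must be >= 1")
  if (is.null(bounds)) bounds <- slmrg_bounds(max(ce))

  model_fun <- function(ce, n, nm, a, b, w)
    slmrg_capacity(ce, list(n = n, nm = nm, a = a, b = b, w = w), temperature)

  starts <- with_local_seed(seed,
                            slmrg_starts(n_starts, bounds, ce, qe, temperature))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  best <- NULL
  best_sse <- Inf
  tried <- 0L
  failures <- character(0)
  for (st in starts) {
    tried <- tried + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(qe ~ model_fun(ce, n, nm, a, b, w),
                        data = data.frame(ce = ce, qe = qe),
                        start = as.list(st),
                        lower = bounds$lower, upper = bounds$upper,
                        control = ctrl),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit
    }
  }
  if (is.null(best))
    stop("SLMRG fit failed to converge from any of ", tried,
         " starting points; last error: ", utils::tail(failures, 1))

  cf <- stats::coef(best)
  params <- slmrg_params(n = cf[["n"]], nm = cf[["nm"]], a = cf[["a"]],
                         b = cf[["b"]], w = cf[["w"]])
  pred <- slmrg_capacity(ce, params, temperature)
  gof <- goodness(qe, pred, n_params = 5)
  structure(list(params = params,
                 coefficients = cf,
                 r2 = gof$r2, rmse = gof$rmse, sse = best_sse,
                 n_obs = length(ce),
                 converged = TRUE,
                 starts_tried = tried,
                 temperature = temperature,
                 adsorbent = adsorbent,
                 data = data,
                 fitted = pred,
                 residuals = qe - pred,
                 bounds = bounds,
                 seed = seed,
                 model = "slmrg"),
            class = c("slmrg_fit", "sorption_fit"))
}

#' @export
coef.sorption_fit <- function(object, ...) object$coefficients

#' @export
fitted.sorption_fit <- function(object, ...) object$fitted

#' @export
residuals.sorption_fit <- function(object, ...) object$residuals

#' @export
print.sorption_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (%d points%s)\n",
              toupper(x$model), x$n_obs,
              if (!is.null(x$temperature))
                sprintf(", %g K", x$temperature) else ""))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.4f, RMSE = %.4g\n", x$r2, x$rmse))
  invisible(x)
}

#' @export
summary.sorption_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Converged after %d start(s); SSE = %.6g\n",
              object$starts_tried, object$sse))
  if (inherits(object, "slmrg_fit"))
    cat(sprintf("Saturation capacity Qsat = n*Nm = %.4f mg/g\n",
                saturation_capacity(object$params)))
  invisible(object)
}

#' @export
predict.slmrg_fit <- function(object, newdata = NULL, ...) {
  ce <- if (is.null(newdata)) object$data$ce
        else if (is.data.frame(newdata)) newdata$ce
        else newdata
  slmrg_capacity(ce, object$params, object$temperature)
}

#' @export
plot.slmrg_fit <- function(x, n_grid = 200, ...) {
  ce <- x$data$ce
  grid <- seq(0, max(ce), length.out = n_grid)
  graphics::plot(ce, x$data$qe, xlab = "Ce (mg/L)", ylab = "qe (mg/g)",
                 main = sprintf("SLMRG fit, %s at %g K", x$adsorbent,
                                x$temperature), ...)
  graphics::lines(grid, slmrg_capacity(grid, x$params, x$temperature))
  invisible(x)
}

#' @export
simulate.slmrg_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.02, ...) {
  grids <- lapply(seq_len(nsim), function(i)
    gen_isotherm(object$params, object$temperature, grid = object$data$ce,
                 noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else seed + i - 1,
                 adsorbent = object$adsorbent))
  if (nsim == 1) grids[[1]] else grids
}
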