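# Estimation of kinetic model parameters: classical linearizations, nonlinear
# least squares on the integrated forms, and piecewise Weber-Morris fits.

kinetic_fit <- function(model, coefficients, trace, fitted, extra = list()) {
  gof <- goodness(trace$qt, fitted, n_params = length(coefficients))
  structure(c(list(model = model,
                   coefficients = coefficients,
                   r2 = gof$r2, rmse = gof$rmse,
                   sse = sum((trace$qt - fitted)^2),
                   n_obs = nrow(trace),
                   converged = TRUE,
                   starts_tried = 1L,
                   data = trace,
                   fitted = fitted,
                   residuals = trace$qt - fitted,
                   temperature = NULL),
              extra),
            class = c("kinetic_fit", "sorption_fit"))
}

#' Linearized pseudo-first-order fit
#'
#' Lagergren linearization: regress `log10(qe_exp - qt)` on `t`; the slope is
#' `-k1/ln(10)` and the intercept `log10(qe)`. The experimental plateau
#' `qe_exp` must be supplied, as in standard practice (the nonlinear route of
#' [fit_kinetics()] does not need it).
#'
#' @param trace a [kinetic_trace()] or data.frame with columns `t`, `qt`.
#' @param qe_exp experimental equilibrium capacity, mg/g; must exceed every
#'   `qt`.
#' @return A `kinetic_fit` object with coefficients `qe`, `k1` and, in
#'   `$linearization`, the slope/intercept and r2 of the regression in the
#'   transformed coordinates.
#' @export
fit_pfo_linear <- function(trace, qe_exp) {
  trace <- as_kinetic_trace(trace)
  stopifnot(qe_exp > 0)
  bad <- which(trace$qt >= qe_exp)
  if (length(bad))
    stop(sprintf("qt at point %d (t = %g) reaches qe_exp = %g; the PFO linearization needs qt < qe_exp",
                 bad[1], trace$t[bad[1]], qe_exp))
  y <- log10(qe_exp - trace$qt)
  reg <- stats::lm(y ~ t, data = data.frame(t = trace$t, y = y))
  slope <- unname(stats::coef(reg)[2])
  intercept <- unname(stats::coef(reg)[1])
  k1 <- -slope * log(10)
  qe <- 10^intercept
  if (k1 <= 0)
    warning("non-positive k1 from the PFO linearization; the trace does not look first-order")
  cf <- c(qe = qe, k1 = k1)
  fitted <- if (k1 > 0) pfo_capacity(trace$t, qe, k1) else rep(NA_real_, nrow(trace))
  out <- kinetic_fit("pfo_linear", cf, trace, fitted,
                     extra = list(linearization = list(
                       slope = slope, intercept = intercept,
                       r2 = reg_r2(reg)),
                       qe_exp = qe_exp))
  out
}

#' Linearized pseudo-second-order fit
#'
#' Ho-McKay linearization: regress `t/qt` on `t`; `qe = 1/slope` and
#' `k2 = slope^2/intercept`. Exact second-order data linearize losslessly.
#' A constant trace gives a zero intercept; the fit is then flagged
#' degenerate (`k2` infinite).
#'
#' @inheritParams fit_pfo_linear
#' @return A `kinetic_fit` object with coefficients `qe`, `k2` and the
#'   regression diagnostics in `$linearization` (including a `degenerate`
#'   flag).
#' @export
fit_pso_linear <- function(trace) {
  trace <- as_kinetic_trace(trace)
  bad <- which(trace$qt <= 0 | trace$t <= 0)
  if (length(bad))
    stop(sprintf("point %d (t = %g, qt = %g) is not usable: the PSO linearization needs t > 0 and qt > 0",
                 bad[1], trace$t[bad[1]], trace$qt[bad[1]]))
  y <- trace$t / trace$qt
  reg <- stats::lm(y ~ t, data = data.frame(t = trace$t, y = y))
  slope <- unname(stats::coef(reg)[2])
  intercept <- unname(stats::coef(reg)[1])
  degenerate <- abs(intercept) < 1e-10 * max(abs(y))
  qe <- 1 / slope
  k2 <- if (degenerate) Inf else slope^2 / intercept
  if (degenerate)
    warning("zero intercept in the PSO linearization (constant qt?); k2 is unidentified")
  cf <- c(qe = qe, k2 = k2)
  fitted <- if (is.finite(k2) && k2 > 0 && qe > 0)
    pso_capacity(trace$t, qe, k2) else rep(mean(trace$qt), nrow(trace))
  kinetic_fit("pso_linear", cf, trace, fitted,
              extra = list(linearization = list(
                slope = slope, intercept = intercept,
                r2 = reg_r2(reg), degenerate = degenerate)))
}

#' Nonlinear kinetic fits on the integrated forms
#'
#' Least-squares fit of the integrated pseudo-first-order, pseudo-second-order
#' or Weber-Morris intra-particle diffusion model. PFO/PSO use bounded
#' Levenberg-Marquardt started from the linearized estimates (with fallbacks);
#' the diffusion model is linear in `sqrt(t)` and solved by ordinary least
#' squares.
#'
#' @param model one of `"pfo"`, `"pso"`, `"ipd"`.
#' @inheritParams fit_pfo_linear
#' @param qe_exp optional plateau passed to the PFO linearization used for
#'   starting values; defaults to `1.05 * max(qt)`.
#' @return A `kinetic_fit` object; coefficients are `qe, k1` (pfo),
#'   `qe, k2` (pso) or `kid, c` (ipd).
#' @export
fit_kinetics <- function(model = c("pfo", "pso", "ipd"), trace,
                         qe_exp = NULL) {
  model <- match.arg(model)
  trace <- as_kinetic_trace(trace)
  if (nrow(trace) < 4)
    stop("a nonlinear kinetic fit needs at least 4 points")
  t <- trace$t
  qt <- trace$qt
  if (model == "ipd") {
    reg <- stats::lm(qt ~ sqrt(t), data = data.frame(t = t, qt = qt))
    cf <- c(kid = unname(stats::coef(reg)[2]), c = unname(stats::coef(reg)[1]))
    return(kinetic_fit("ipd", cf, trace,
                       ipd_capacity(t, max(cf[["kid"]], 0), cf[["c"]])))
  }
  qmax <- max(qt)
  start <- tryCatch({
    lin <- if (model == "pfo")
      fit_pfo_linear(trace[trace$qt < 0.999 * (if (is.null(qe_exp)) 1.05 * qmax else qe_exp), ,
                           drop = FALSE],
                     if (is.null(qe_exp)) 1.05 * qmax else qe_exp)
    else suppressWarnings(fit_pso_linear(trace[trace$t > 0 & trace$qt > 0, , drop = FALSE]))
    cf <- stats::coef(lin)
    if (!all(is.finite(cf)) || any(cf <= 0)) stop("bad linearized start")
    as.list(cf)
  }, error = function(e) {
    if (model == "pfo") list(qe = qmax, k1 = 1 / stats::median(t[t > 0]))
    else list(qe = qmax, k2 = 1 / (qmax * stats::median(t[t > 0])))
  })
  form <- if (model == "pfo") qt ~ pfo_capacity(t, qe, k1)
          else qt ~ pso_capacity(t, qe, k2)
  fit <- minpack.lm::nlsLM(
    form, data = data.frame(t = t, qt = qt), start = start,
    lower = c(1e-8, 1e-10), upper = c(1e6, 1e3),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  fitted <- if (model == "pfo") pfo_capacity(t, cf[["qe"]], cf[["k1"]])
            else pso_capacity(t, cf[["qe"]], cf[["k2"]])
  kinetic_fit(model, cf, trace, fitted)
}

#' Piecewise Weber-Morris diffusion fit
#'
#' Fits `qt` as a piecewise-linear function of `sqrt(t)` with 1-3 segments,
#' choosing the segment boundaries by exhaustive search over contiguous
#' partitions of the observed points (each segment keeps at least
#' `min_points` observations) to minimize the total sum of squared errors;
#' ties are broken in favour of the earliest breakpoints. Successive segments
#' are conventionally read as film diffusion, intra-particle diffusion and
#' the equilibrium plateau; a first segment whose intercept is not within
#' `origin_tol` of zero indicates boundary-layer resistance.
#'
#' @inheritParams fit_pfo_linear
#' @param n_segments number of linear regimes, 1, 2 or 3.
#' @param min_points minimum observations per segment (default 2).
#' @param origin_tol tolerance (mg/g) on the first-segment intercept for the
#'   through-the-origin diagnosis (default 0.5).
#' @return An object of class `"ipd_segments"`: a list with `segments` (a
#'   data.frame with one row per segment: `kid`, `c`, `t_start`, `t_end`,
#'   `n_points`, `r2`), `breakpoints` (times separating the segments),
#'   `through_origin` (logical, first segment), `sse`, and the trace.
#' @export
fit_ipd_segments <- function(trace, n_segments = 3, min_points = 2,
                             origin_tol = 0.5) {
  trace <- as_kinetic_trace(trace)
  if (!n_segments %in% 1:3) stop("'n_segments' must be 1, 2 or 3")
  n <- nrow(trace)
  if (n < 2 * n_segments + 1)
    stop(sprintf("%d segments need at least %d points, got %d",
                 n_segments, 2 * n_segments + 1, n))
  s <- sqrt(trace$t)
  q <- trace$qt

  seg_fit <- function(idx) {
    reg <- stats::lm(qq ~ ss, data = data.frame(ss = s[idx], qq = q[idx]))
    list(kid = unname(stats::coef(reg)[2]), c = unname(stats::coef(reg)[1]),
         sse = sum(stats::residuals(reg)^2),
         r2 = reg_r2(reg))
  }

  # all contiguous partitions of 1..n into n_segments blocks of >= min_points
  cuts <- if (n_segments == 1) list(integer(0))
  else if (n_segments == 2)
    lapply(seq(min_points, n - min_points), function(i) i)
  else {
    out <- list()
    for (i in seq(min_points, n - 2 * min_points))
      for (j in seq(i + min_points, n - min_points))
        out[[length(out) + 1]] <- c(i, j)
    out
  }

  best <- NULL
  best_sse <- Inf
  for (cut in cuts) {
    edges <- c(0, cut, n)
    fits <- lapply(seq_len(n_segments), function(k)
      seg_fit((edges[k] + 1):edges[k + 1]))
    sse <- sum(vapply(fits, `[[`, numeric(1), "sse"))
    if (sse < best_sse - 1e-12) {  # strict improvement; earliest cut wins ties
      best_sse <- sse
      best <- list(cut = cut, fits = fits, edges = edges)
    }
  }

  seg <- do.call(rbind, lapply(seq_len(n_segments), function(k) {
    idx <- (best$edges[k] + 1):best$edges[k + 1]
    data.frame(segment = k,
               kid = best$fits[[k]]$kid,
               c = best$fits[[k]]$c,
               t_start = trace$t[idx[1]],
               t_end = trace$t[idx[length(idx)]],
               n_points = length(idx),
               r2 = best$fits[[k]]$r2)
  }))
  structure(list(segments = seg,
                 breakpoints = if (length(best$cut)) trace$t[best$cut] else numeric(0),
                 breakpoint_index = best$cut,
                 through_origin = abs(seg$c[1]) <= origin_tol,
                 origin_tol = origin_tol,
                 sse = best_sse,
                 n_segments = n_segments,
                 data = trace),
            class = "ipd_segments")
}

#' @export
print.ipd_segments <- function(x, digits = 4, ...) {
  cat(sprintf("Weber-Morris piecewise fit: %d segment(s), total SSE = %.4g\n",
              x$n_segments, x$sse))
  print(format(x$segments, digits = digits), row.names = FALSE)
  if (length(x$breakpoints))
    cat("Breakpoints after t =", paste(signif(x$breakpoints, 5), collapse = ", "),
        "min\n")
  cat(sprintf("First segment %s through the origin (|c| %s %g mg/g)\n",
              if (x$through_origin) "passes" else "does not pass",
              if (x$through_origin) "<=" else ">", x$origin_tol))
  invisible(x)
}

#' @export
plot.kinetic_fit <- function(x, n_grid = 200, ...) {
  t <- x$data$t
  graphics::plot(t, x$data$qt, xlab = "t (min)", ylab = "qt (mg/g)",
                 main = sprintf("%s kinetic fit", toupper(x$model)), ...)
  grid <- seq(min(t), max(t), length.out = n_grid)
  cf <- x$coefficients
  pred <- switch(sub("_linear", "", x$model),
                 pfo = pfo_capacity(grid, cf[["qe"]], cf[["k1"]]),
                 pso = pso_capacity(grid, cf[["qe"]], cf[["k2"]]),
                 ipd = ipd_capacity(grid, max(cf[["kid"]], 0), cf[["c"]]))
  graphics::lines(grid, pred)
  invisible(x)
}
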