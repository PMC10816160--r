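# r2 of a fitted lm without going through summary.lm (which warns on
# perfect fits — common here, where linearizations are exact by design)
reg_r2 <- function(reg) {
  y <- stats::model.frame(reg)[[1]]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) NA_real_ else 1 - sum(stats::residuals(reg)^2) / sst
}

#' Goodness-of-fit statistics
#'
#' Coefficient of determination and root-mean-square error of a fitted curve
#' against observations: `r2 = 1 - SSE/SST` with SST about the observed mean,
#' and `rmse = sqrt(SSE/N)` (no degrees-of-freedom correction).
#'
#' @param observed observed values.
#' @param predicted model values, same length.
#' @param n_params number of free parameters of the model (recorded, not used
#'   in the statistics).
#' @return A list with `r2`, `rmse`, `n_obs`, `n_params` and a logical
#'   `degenerate` flag: when the observations are constant, SST is zero and
#'   `r2` is returned as `NA` with `degenerate = TRUE`.
#' @export
goodness <- function(observed, predicted, n_params = 0) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have the same length")
  if (length(observed) < 2)
    stop("at least 2 observations are needed")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  degenerate <- sst == 0
  list(r2 = if (degenerate) NA_real_ else 1 - sse / sst,
       rmse = sqrt(sse / length(observed)),
       n_obs = length(observed),
       n_params = n_params,
       degenerate = degenerate)
}
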