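#' Fit a GM(1,1) grey forecasting model
#'
#' Standard construction: first-order accumulated generating operation (AGO)
#' of the positive series, least squares on the grey difference equation
#' `x0(k) + a * z1(k) = b` where `z1` is the adjacent mean of the AGO
#' series, giving the development coefficient `a` and grey action quantity
#' `b`.
#'
#' Prediction ([gm11_predict()]) iterates the fitted difference equation
#' forward, `x0(k) = (b - a * x1(k-1)) / (1 + a/2)`, rather than evaluating
#' the continuous exponential response: the discrete form reproduces exact
#' geometric (noiseless exponential) series without the small discretization
#' bias of `e^{-a}` versus the true ratio, and degrades gracefully to a
#' constant forecast as `a -> 0`.
#'
#' @param x numeric series, length >= 4, all values > 0 (the AGO model is
#'   undefined otherwise).
#' @return object of class `gm11` with fields `a`, `b`, `x0_1` (initial
#'   value), `n` (fitted length), `fitted` (one-step in-sample fit) and
#'   `series`.
#' @export
gm11_fit <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("GM(1,1) needs at least 4 observations")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("GM(1,1) requires strictly positive values (AGO undefined)")
  n <- length(x)
  x1 <- cumsum(x)
  z1 <- 0.5 * (x1[-1] + x1[-n])
  B <- cbind(-z1, 1)
  Y <- x[-1]
  ab <- solve(crossprod(B), crossprod(B, Y))
  a <- ab[1]; b <- ab[2]
  ## one-step in-sample fit via the same discrete recursion used to predict
  fitted <- c(x[1], (b - a * x1[-n]) / (1 + a / 2))
  structure(list(a = a, b = b, x0_1 = x[1], n = n, fitted = fitted,
                 series = x),
            class = "gm11")
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("<gm11> a = %.6g, b = %.6g, fitted on %d points\n",
              x$a, x$b, x$n))
  invisible(x)
}

#' Forecast from a fitted GM(1,1) model
#'
#' @param model a [gm11_fit()] object.
#' @param horizon number of steps beyond the training series (>= 1).
#' @return numeric vector of `horizon` forecasts on the original scale.
#' @export
gm11_predict <- function(model, horizon = 1) {
  stopifnot(inherits(model, "gm11"), horizon >= 1)
  x1 <- sum(model$series)         # AGO value at the training endpoint
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    x0 <- (model$b - model$a * x1) / (1 + model$a / 2)
    out[h] <- x0
    x1 <- x1 + x0
  }
  out
}

#' Fit-and-forecast a socioeconomic series
#'
#' Convenience wrapper: fits GM(1,1) to a [socio_series()] and returns the
#' value forecast for `target_year` (stepping one year per model step).
#'
#' @param series a `socio_series`.
#' @param target_year year beyond the series end.
#' @return forecast value.
#' @export
gm11_forecast_year <- function(series, target_year) {
  stopifnot(inherits(series, "socio_series"))
  last <- max(series$years)
  if (target_year <= last) return(series_at(series, target_year))
  m <- gm11_fit(series$values)
  p <- gm11_predict(m, target_year - last)
  p[length(p)]
}
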