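#' Sliding-window configuration for just-in-time forecasting
#'
#' @param train_seconds training window length, s (default 30, so a
#'   window holds `30 * f` timepoints at rate f).
#' @param horizon_steps forecast horizon in frames (default 10).
#' @param step window advance per prediction, frames (default 1).
#' @return object of class `sliding_window_config`.
#' @export
sliding_window_config <- function(train_seconds = 30, horizon_steps = 10,
                                  step = 1) {
  if (horizon_steps < 1) stop_invalid("horizon_steps must be >= 1")
  if (step < 1) stop_invalid("step must be >= 1")
  structure(list(train_seconds = train_seconds,
                 horizon_steps = as.integer(horizon_steps),
                 step = as.integer(step)),
            class = "sliding_window_config")
}

#' Fit an autoregressive model by ordinary least squares
#'
#' Regresses each value on its previous `order` values plus an
#' intercept, minimizing the squared one-step error over the window. A
#' rank-deficient lag matrix (e.g. a constant window) falls back to a
#' ridge solution (lambda = 1e-8, scaled), flagged in the result.
#'
#' @param window numeric vector of at least `2 * order + 1` finite
#'   positions.
#' @param order AR order p (default 10).
#' @return object of class `ar_model` with `order`, `coefficients`
#'   (lag 1..p), `intercept`, `ridge` flag.
#' @export
fit_ar <- function(window, order = 10) {
  if (any(!is.finite(window))) stop_invalid("window must be finite")
  n <- length(window)
  if (n < 2 * order + 1) {
    stop_invalid(sprintf("window of %d points is too short for AR(%d); need >= %d",
                         n, order, 2 * order + 1))
  }
  lags <- stats::embed(window, order + 1)
  y <- lags[, 1]
  X <- cbind(1, lags[, -1, drop = FALSE])
  qr_x <- qr(X)
  ridge <- qr_x$rank < ncol(X)
  beta <- if (!ridge) {
    qr.coef(qr_x, y)
  } else {
    lambda <- 1e-8 * max(1, mean(X^2))
    A <- crossprod(X) + diag(lambda, ncol(X))
    drop(solve(A, crossprod(X, y)))
  }
  structure(list(order = as.integer(order),
                 coefficients = unname(beta[-1]),
                 intercept = unname(beta[1]), ridge = ridge),
            class = "ar_model")
}

#' Recursive multi-step AR forecast
#'
#' Feeds each prediction back as an input to produce `horizon` values
#' ahead of the window.
#'
#' @param model an [fit_ar()] model.
#' @param window numeric vector (length >= model order) supplying the
#'   initial lags.
#' @param horizon number of steps (>= 1).
#' @return numeric vector of `horizon` forecasts.
#' @export
predict_ar <- function(model, window, horizon = 1) {
  if (horizon < 1) stop_invalid("horizon must be >= 1")
  p <- model$order
  if (length(window) < p) stop_invalid("window shorter than the AR order")
  state <- rev(tail(window, p))  # newest first: x[t-1], x[t-2], ...
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    out[h] <- model$intercept + sum(model$coefficients * state)
    state <- c(out[h], state[-p])
  }
  out
}

#' Sliding-window just-in-time forecasting over a waveform
#'
#' Emulates the treatment-time loop: a `train_seconds` window (30 s by
#' default, i.e. `30 * f` points) is fitted and the next frame is
#' predicted; the window then advances one timepoint (drop oldest, add
#' newest) and the fit repeats. The first held-out point seeds the first
#' window advance, so a 40-s waveform yields `10 * f - 1` first-step
#' predictions, with truth taken from the held-out tail. Multi-step
#' (horizon) forecasts are recursive.
#'
#' @param w a [breathing_waveform()].
#' @param method `"ar"`, `"lstm"`, or `"oracle"` (truth passed through,
#'   for end-to-end identity checks).
#' @param swc a [sliding_window_config()].
#' @param order AR order (method `"ar"`).
#' @param lstm an [lstm_config()] (method `"lstm"`).
#' @return object of class `prediction_series`: a list with `results`
#'   (data frame: `frame_index`, `horizon`, `predicted`, `truth`,
#'   `abs_error`), `first_step` (the horizon-1 rows), `method`, `rate`.
#' @export
run_sliding_forecast <- function(w, method = c("ar", "lstm", "oracle"),
                                 swc = sliding_window_config(),
                                 order = 10, lstm = lstm_config()) {
  method <- match.arg(method)
  f <- w$rate
  train_n <- swc$train_seconds * f
  if (abs(train_n - round(train_n)) > 1e-9) {
    stop_invalid("train_seconds * rate must be an integer")
  }
  train_n <- as.integer(round(train_n))
  N <- length(w$positions)
  if (N < train_n + 2) {
    stop_invalid(sprintf("waveform of %d points is too short; need >= %d (%g s at %g Hz)",
                         N, train_n + 2, (train_n + 2) / f, f))
  }
  H <- swc$horizon_steps
  ks <- seq(1L, N - train_n - 1L, by = swc$step)
  rows <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    idx <- (1 + k):(train_n + k)
    window <- w$positions[idx]
    pred <- switch(method,
      ar = predict_ar(fit_ar(window, order = order), window, horizon = H),
      lstm = fit_predict_lstm(window, cfg = lstm, horizon = H),
      oracle = {
        ti <- train_n + k + seq_len(H)
        ifelse(ti <= N, w$positions[pmin(ti, N)], NA_real_)
      })
    ti <- train_n + k + seq_len(H)
    truth <- ifelse(ti <= N, w$positions[pmin(ti, N)], NA_real_)
    rows[[j]] <- data.frame(frame_index = ti, horizon = seq_len(H),
                            predicted = pred, truth = truth,
                            abs_error = abs(pred - truth))
  }
  results <- do.call(rbind, rows)
  results$method <- method
  structure(list(results = results,
                 first_step = results[results$horizon == 1, ],
                 method = method, rate = f, train_n = train_n,
                 n_predictions = length(ks)),
            class = "prediction_series")
}

#' @export
print.prediction_series <- function(x, ...) {
  fs <- x$first_step
  cat(sprintf("<prediction_series> %s @ %g Hz: %d predictions, mean first-step |error| = %.3f mm\n",
              x$method, x$rate, x$n_predictions,
              mean(fs$abs_error, na.rm = TRUE)))
  invisible(x)
}
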