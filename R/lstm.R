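#' LSTM forecaster configuration
#'
#' A single-recurrent-layer LSTM (sequence-to-one-step regression) with
#' a dense linear head, trained from scratch on each sliding window with
#' the Adam optimizer under a squared-error loss. The window is z-score
#' normalized before training (with a constant-window guard) and
#' forecasts are de-normalized and fed back recursively for multi-step
#' horizons.
#'
#' @param hidden_units LSTM state size (default 20).
#' @param max_epochs training epochs per window (default 150).
#' @param learning_rate Adam step size (default 0.005).
#' @param optimizer only `"Adam"` is implemented.
#' @param seed integer seed for weight initialization.
#' @return object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 20, max_epochs = 150,
                        learning_rate = 0.005, optimizer = "Adam",
                        seed = 1L) {
  if (hidden_units < 1) stop_invalid("hidden_units must be >= 1")
  if (max_epochs < 1) stop_invalid("max_epochs must be >= 1")
  if (!identical(optimizer, "Adam")) stop_invalid("only the Adam optimizer is available")
  structure(list(hidden_units = as.integer(hidden_units),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Parameter vector layout for hidden size H (gate order i, f, g, o):
## Wx (4H) | Wh (4H*H) | b (4H) | wy (H) | by (1)
lstm_init <- function(H) {
  r <- 1 / sqrt(H)
  G <- 4L * H
  theta <- runif(G + G * H + G + H + 1, -r, r)
  b_off <- G + G * H
  theta[b_off + H + seq_len(H)] <- 1  # forget-gate bias starts open
  theta
}

lstm_unpack <- function(theta, H) {
  G <- 4L * H
  o <- 0L
  Wx <- theta[o + seq_len(G)]; o <- o + G
  Wh <- matrix(theta[o + seq_len(G * H)], G, H); o <- o + G * H
  b <- theta[o + seq_len(G)]; o <- o + G
  wy <- theta[o + seq_len(H)]; o <- o + H
  by <- theta[o + 1L]
  list(Wx = Wx, Wh = Wh, b = b, wy = wy, by = by)
}

## Forward pass over inputs x (scalar sequence); returns outputs and,
## if keep = TRUE, the cached activations needed for BPTT.
lstm_forward <- function(par, x, H, keep = FALSE) {
  T_ <- length(x)
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  h <- numeric(H); cc <- numeric(H)
  y <- numeric(T_)
  cache <- if (keep) {
    list(i = matrix(0, H, T_), f = matrix(0, H, T_),
         g = matrix(0, H, T_), o = matrix(0, H, T_),
         tc = matrix(0, H, T_), h_prev = matrix(0, H, T_),
         c_prev = matrix(0, H, T_), h = matrix(0, H, T_))
  }
  for (t in seq_len(T_)) {
    z <- par$Wx * x[t] + drop(par$Wh %*% h) + par$b
    i_t <- sigmoid(z[ii]); f_t <- sigmoid(z[fi])
    g_t <- tanh(z[gi]); o_t <- sigmoid(z[oi])
    if (keep) {
      cache$h_prev[, t] <- h
      cache$c_prev[, t] <- cc
    }
    cc <- f_t * cc + i_t * g_t
    tc <- tanh(cc)
    h <- o_t * tc
    y[t] <- sum(par$wy * h) + par$by
    if (keep) {
      cache$i[, t] <- i_t; cache$f[, t] <- f_t
      cache$g[, t] <- g_t; cache$o[, t] <- o_t
      cache$tc[, t] <- tc; cache$h[, t] <- h
    }
  }
  list(y = y, h = h, c = cc, cache = cache)
}

## Mean-squared loss and analytic gradient (full BPTT).
lstm_loss_grad <- function(theta, x, target, H) {
  par <- lstm_unpack(theta, H)
  fw <- lstm_forward(par, x, H, keep = TRUE)
  ca <- fw$cache
  T_ <- length(x)
  loss <- mean((fw$y - target)^2)
  G <- 4L * H
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  dWx <- numeric(G); dWh <- matrix(0, G, H); db <- numeric(G)
  dwy <- numeric(H); dby <- 0
  dh_carry <- numeric(H); dc_carry <- numeric(H)
  for (t in rev(seq_len(T_))) {
    dy <- 2 * (fw$y[t] - target[t]) / T_
    dwy <- dwy + dy * ca$h[, t]
    dby <- dby + dy
    dh <- dy * par$wy + dh_carry
    do_ <- dh * ca$tc[, t]
    dc <- dh * ca$o[, t] * (1 - ca$tc[, t]^2) + dc_carry
    di <- dc * ca$g[, t]
    dg <- dc * ca$i[, t]
    df <- dc * ca$c_prev[, t]
    dc_carry <- dc * ca$f[, t]
    dz <- numeric(G)
    dz[ii] <- di * ca$i[, t] * (1 - ca$i[, t])
    dz[fi] <- df * ca$f[, t] * (1 - ca$f[, t])
    dz[gi] <- dg * (1 - ca$g[, t]^2)
    dz[oi] <- do_ * ca$o[, t] * (1 - ca$o[, t])
    dWx <- dWx + dz * x[t]
    dWh <- dWh + dz %o% ca$h_prev[, t]
    db <- db + dz
    dh_carry <- drop(crossprod(par$Wh, dz))
  }
  list(loss = loss, grad = c(dWx, as.vector(dWh), db, dwy, dby))
}

#' Train an LSTM on a window and forecast ahead
#'
#' Trains the recurrent forecaster from scratch on the z-score
#' normalized window (inputs `x[t]`, targets `x[t+1]`) for
#' `cfg$max_epochs` full-batch Adam steps, then forecasts recursively
#' for `horizon` steps, feeding each prediction back as the next input.
#' A (near-)constant window skips training and returns the last value.
#'
#' @param window numeric vector of at least 10 positions.
#' @param cfg an [lstm_config()].
#' @param horizon number of steps ahead (>= 1).
#' @return numeric vector of `horizon` forecasts, mm.
#' @export
fit_predict_lstm <- function(window, cfg = lstm_config(), horizon = 1) {
  if (horizon < 1) stop_invalid("horizon must be >= 1")
  if (length(window) < 10) stop_invalid("window must have >= 10 points")
  mu <- mean(window)
  s <- sd(window)
  if (!is.finite(s) || s < 1e-8 * max(1, abs(mu))) {
    return(rep(tail(window, 1), horizon))  # constant-window guard
  }
  z <- (window - mu) / s
  T_ <- length(z)
  x <- z[-T_]
  target <- z[-1]
  H <- cfg$hidden_units
  theta <- with_seed(cfg$seed, lstm_init(H))
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(cfg$max_epochs)) {
    lg <- lstm_loss_grad(theta, x, target, H)
    if (!is.finite(lg$loss)) {
      stop("training-failure: non-finite LSTM loss at epoch ", ep,
           call. = FALSE)
    }
    m <- b1 * m + (1 - b1) * lg$grad
    v <- b2 * v + (1 - b2) * lg$grad^2
    mh <- m / (1 - b1^ep)
    vh <- v / (1 - b2^ep)
    theta <- theta - cfg$learning_rate * mh / (sqrt(vh) + eps)
  }
  par <- lstm_unpack(theta, H)
  fw <- lstm_forward(par, z, H)  # state after consuming the full window
  preds <- numeric(horizon)
  preds[1] <- fw$y[T_]
  h <- fw$h; cc <- fw$c
  ii <- seq_len(H); fi <- H + ii; gi <- 2L * H + ii; oi <- 3L * H + ii
  if (horizon > 1) {
    for (k in 2:horizon) {
      zt <- par$Wx * preds[k - 1] + drop(par$Wh %*% h) + par$b
      i_t <- sigmoid(zt[ii]); f_t <- sigmoid(zt[fi])
      g_t <- tanh(zt[gi]); o_t <- sigmoid(zt[oi])
      cc <- f_t * cc + i_t * g_t
      h <- o_t * tanh(cc)
      preds[k] <- sum(par$wy * h) + par$by
    }
  }
  preds * s + mu
}
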