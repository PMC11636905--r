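# Independent brute-force re-implementations used as oracles. These are
# written as explicit scalar loops, deliberately sharing no code with the
# package's vectorized paths.

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

oracle_smooth <- function(values, span) {
  n <- length(values)
  half <- (span - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    acc <- 0
    for (j in (i - h):(i + h)) acc <- acc + values[j]
    out[i] <- acc / (2 * h + 1)
  }
  out
}

# Explicit per-neuron forward pass: scale, two tanh layers, linear output,
# unscale.
oracle_forward <- function(model, taps) {
  sc <- model$scaler
  x <- 2 * (taps - sc$lo) / (sc$hi - sc$lo) - 1
  w <- model$weights
  a1 <- numeric(nrow(w$W1))
  for (i in seq_along(a1)) a1[i] <- tanh(sum(w$W1[i, ] * x) + w$b1[i])
  a2 <- numeric(nrow(w$W2))
  for (i in seq_along(a2)) a2[i] <- tanh(sum(w$W2[i, ] * a1) + w$b2[i])
  y <- sum(w$W3[1, ] * a2) + w$b3
  (y + 1) / 2 * (sc$hi - sc$lo) + sc$lo
}

# Naive recursion: explicit shifting buffer around oracle_forward.
oracle_recursive <- function(model, seed_window, n_steps) {
  buf <- seed_window
  out <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    p <- oracle_forward(model, buf)
    out[k] <- p
    buf <- c(buf[-1], p)
  }
  out
}

oracle_rmse <- function(g, ghat) {
  acc <- 0
  for (i in seq_along(g)) acc <- acc + (g[i] - ghat[i])^2
  sqrt(acc / length(g))
}

oracle_fit <- function(g, ghat) {
  gbar <- sum(g) / length(g)
  num <- 0; den <- 0
  for (i in seq_along(g)) {
    num <- num + (g[i] - ghat[i])^2
    den <- den + (g[i] - gbar)^2
  }
  (1 - sqrt(num) / sqrt(den)) * 100
}

oracle_npe <- function(g, ghat) {
  num <- 0; den <- 0
  for (i in seq_along(g)) {
    num <- num + (g[i] - ghat[i])^2
    den <- den + g[i]^2
  }
  sqrt(num / den) * 100
}

# Independent scalar evaluation of the Clarke grid rules, written as a
# precedence chain of if-clauses rather than vectorized masks.
oracle_clarke <- function(R, P) {
  if ((R <= 70 && P <= 70) || (P >= 0.8 * R && P <= 1.2 * R)) return("A")
  if ((R >= 180 && P <= 70) || (R <= 70 && P >= 180)) return("E")
  if ((R >= 70 && R <= 290 && P >= R + 110) ||
      (R >= 130 && R <= 180 && P <= 1.4 * R - 182)) return("C")
  if ((R >= 240 && P >= 70 && P <= 180) ||
      (R <= 175 / 3 && P >= 70 && P <= 180) ||
      (R >= 175 / 3 && R <= 70 && P >= 1.2 * R)) return("D")
  "B"
}

# A random small model with a fitted scaler, for forward/recursion checks.
random_model <- function(seed, n_taps = 20, hidden = c(20, 13),
                         lo = 3, hi = 16) {
  m <- narx_model(narx_config(n_taps = n_taps, hidden = hidden,
                              seed = seed))
  m$scaler <- structure(list(lo = lo, hi = hi), class = "glucose_scaler")
  m
}

# A model whose every prediction is the constant `value`: zero weights,
# output bias set so the unscaled output equals `value`.
constant_model <- function(value, lo = 0, hi = 10, n_taps = 20) {
  m <- narx_model(narx_config(n_taps = n_taps))
  m$scaler <- structure(list(lo = lo, hi = hi), class = "glucose_scaler")
  m$weights <- lapply(m$weights, function(p) p * 0)
  m$weights$b3 <- 2 * (value - lo) / (hi - lo) - 1
  m
}

sine_series <- function(n, amplitude = 3, offset = 9, period = 24,
                        phase = 0) {
  glucose_series((seq_len(n) - 1) * 5,
                 offset + amplitude * sin(2 * pi * ((seq_len(n) - 1) +
                                                      phase) / period))
}
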