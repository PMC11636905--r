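#' Architecture of the NARX glucose predictor
#'
#' The network maps a tapped delay line of the `n_taps` most recent glucose
#' readings through two tanh hidden layers (default 20 and 13 neurons) to a
#' single linear output, the next reading. Glucose serves as both the
#' autoregressive series and the exogenous input, so the two tap lines of
#' the general NARX form merge into one delay line of `n_taps` inputs.
#'
#' @param n_taps Number of delayed glucose inputs (default 20; also the
#'   default cap on recursive prediction depth, i.e. 100 min at 5-min
#'   sampling).
#' @param hidden Sizes of the two hidden layers (default `c(20, 13)`).
#' @param seed RNG seed for weight initialization.
#' @return A `narx_config` list.
#' @export
narx_config <- function(n_taps = 20, hidden = c(20, 13), seed = 1) {
  if (n_taps < 1) stop("n_taps must be >= 1")
  if (length(hidden) != 2 || any(hidden < 1))
    stop("hidden must give two positive layer sizes")
  structure(list(n_taps = as.integer(n_taps), hidden = as.integer(hidden),
                 activation_hidden = "tanh", activation_output = "identity",
                 seed = as.integer(seed)),
            class = "narx_config")
}

#' Initialize a NARX glucose prediction network
#'
#' Weights are drawn uniformly from `(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' under `config$seed`; biases start at zero. Identical seeds give
#' bit-identical models. The model starts in open-loop (series-parallel)
#' mode, the training configuration; [close_loop()] switches it to the
#' parallel mode used for recursive multi-step prediction.
#'
#' @param config A [narx_config()].
#' @param scaler Optional fitted [fit_scaler()] mapping glucose to the
#'   `[-1, 1]` working range of the tanh units; if `NULL`,
#'   [train_open_loop()] fits one from the training windows.
#' @return A `narx_model`.
#' @export
narx_model <- function(config = narx_config(), scaler = NULL) {
  stopifnot(inherits(config, "narx_config"))
  if (!is.null(scaler)) stopifnot(inherits(scaler, "glucose_scaler"))
  h1 <- config$hidden[1]; h2 <- config$hidden[2]; nt <- config$n_taps
  init <- function(nrow, ncol) {
    r <- 1 / sqrt(ncol)
    matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
  }
  w <- with_seed(config$seed, list(
    W1 = init(h1, nt), b1 = numeric(h1),
    W2 = init(h2, h1), b2 = numeric(h2),
    W3 = init(1, h2), b3 = numeric(1)))
  structure(list(config = config, weights = w, scaler = scaler,
                 mode = "open_loop"),
            class = "narx_model")
}

#' @export
print.narx_model <- function(x, ...) {
  cat(sprintf("<narx_model> %d taps -> %d -> %d -> 1 (tanh/linear), %s mode, scaler %s\n",
              x$config$n_taps, x$config$hidden[1], x$config$hidden[2],
              x$mode, if (is.null(x$scaler)) "unfitted" else
                sprintf("[%.3g, %.3g] mmol/L", x$scaler$lo, x$scaler$hi)))
  invisible(x)
}

# Forward pass on a matrix of scaled tap vectors (rows). Returns the
# activations needed for backpropagation.
narx_forward_scaled <- function(w, X) {
  A1 <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  A2 <- tanh(sweep(A1 %*% t(w$W2), 2, w$b2, "+"))
  yhat <- drop(A2 %*% t(w$W3)) + w$b3
  list(A1 = A1, A2 = A2, yhat = yhat)
}

#' One-step glucose prediction from a tap vector
#'
#' Evaluates the network on the `n_taps` most recent glucose values (mmol/L,
#' oldest first / newest last) and returns the predicted next value. This is
#' the series-parallel prediction: all taps hold true measurements.
#'
#' @param model A `narx_model` with a fitted scaler.
#' @param taps Numeric vector of length `n_taps`, newest value last.
#' @return Predicted next glucose value (mmol/L).
#' @export
forward_one_step <- function(model, taps) {
  stopifnot(inherits(model, "narx_model"))
  if (is.null(model$scaler)) stop("model has no fitted scaler")
  if (length(taps) != model$config$n_taps)
    stop("expected ", model$config$n_taps, " taps, got ", length(taps))
  x <- matrix(apply_scaler(model$scaler, taps), nrow = 1)
  invert_scaler(model$scaler, narx_forward_scaled(model$weights, x)$yhat)
}

#' Training settings for open-loop teacher-forced fitting
#'
#' @param max_epochs Maximum full-batch gradient epochs (default 4000).
#' @param mse_tolerance Stop early once training MSE (scaled units) drops
#'   below this (default 1e-7).
#' @param learn_rate Adam step size (default 0.005; a conservative rate
#'   that converges reliably on smoothed CGM windows).
#' @param validation_fraction Share of windows held out to monitor
#'   generalization (default 0.15); the returned model carries the weights
#'   of the best validation epoch.
#' @param patience Epochs without validation improvement before stopping
#'   (default 200).
#' @param objective `"teacher_forced"` (default): every one-step pair
#'   unrolled from each 40-sample window, true values in the taps.
#'   `"direct"`: one pair per window regressing the taps directly onto the
#'   value `n_out` steps ahead, for comparison.
#' @param seed RNG seed for the validation split.
#' @return A `narx_train_config` list.
#' @export
train_config <- function(max_epochs = 4000, mse_tolerance = 1e-7,
                         learn_rate = 0.005, validation_fraction = 0.15,
                         patience = 200,
                         objective = c("teacher_forced", "direct"),
                         seed = 1) {
  stopifnot(max_epochs >= 1, validation_fraction >= 0,
            validation_fraction < 1, patience >= 1, learn_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 mse_tolerance = mse_tolerance, learn_rate = learn_rate,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 objective = match.arg(objective), seed = as.integer(seed)),
            class = "narx_train_config")
}

# Unroll windows into (tap vector -> next value) training pairs.
# Teacher forcing: a 40-sample window (20 in + 20 out) yields 20 pairs,
# pair k using samples [k, k+19] as taps and sample k+20 as target.
unroll_pairs <- function(windows, n_taps, objective) {
  rows <- lapply(windows, function(w) {
    full <- c(w$inputs, w$targets)
    if (objective == "direct") {
      list(X = matrix(full[seq_len(n_taps)], nrow = 1),
           y = full[length(full)])
    } else {
      ks <- seq_len(length(full) - n_taps)
      X <- t(vapply(ks, function(k) full[k:(k + n_taps - 1)],
                    numeric(n_taps)))
      list(X = X, y = full[ks + n_taps])
    }
  })
  list(X = do.call(rbind, lapply(rows, `[[`, "X")),
       y = unlist(lapply(rows, `[[`, "y")))
}

# MSE and gradient of the scaled one-step loss, standard backprop.
narx_loss_grad <- function(w, X, y) {
  f <- narx_forward_scaled(w, X)
  r <- f$yhat - y
  n <- length(y)
  d3 <- matrix(2 * r / n, ncol = 1)
  gW3 <- t(d3) %*% f$A2
  gb3 <- sum(d3)
  d2 <- (d3 %*% w$W3) * (1 - f$A2^2)
  gW2 <- t(d2) %*% f$A1
  gb2 <- colSums(d2)
  d1 <- (d2 %*% w$W2) * (1 - f$A1^2)
  gW1 <- t(d1) %*% X
  gb1 <- colSums(d1)
  list(mse = mean(r^2),
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3))
}

#' Train the network open-loop (series-parallel, teacher-forced)
#'
#' Minimizes the mean-squared one-step error over every (taps -> next value)
#' pair unrolled from the training windows, with true measurements filling
#' the taps (teacher forcing). Optimization is full-batch Adam with early
#' stopping on a held-out fraction of windows; everything is deterministic
#' given the seeds. The input model is not modified; a newly trained copy is
#' returned.
#'
#' @param model An open-loop `narx_model`.
#' @param windows Training windows from [make_windows()].
#' @param tc A [train_config()].
#' @return `list(model, report)` where `report` has `epochs_run`,
#'   `final_train_mse`, `final_val_mse` (scaled units) and `converged`.
#' @export
train_open_loop <- function(model, windows, tc = train_config()) {
  stopifnot(inherits(model, "narx_model"), inherits(tc, "narx_train_config"))
  if (model$mode != "open_loop") stop("model must be in open-loop mode")
  if (length(windows) == 0) stop("no training windows supplied")

  if (is.null(model$scaler))
    model$scaler <- fit_scaler(unlist(lapply(windows, function(w)
      c(w$inputs, w$targets))))

  n_val <- floor(tc$validation_fraction * length(windows))
  val_idx <- if (n_val > 0)
    with_seed(tc$seed, sample.int(length(windows), n_val)) else integer(0)
  train_w <- if (n_val > 0) windows[-val_idx] else windows
  val_w <- windows[val_idx]
  if (length(train_w) == 0) stop("validation split left no training windows")

  sc <- function(v) apply_scaler(model$scaler, v)
  tp <- unroll_pairs(train_w, model$config$n_taps, tc$objective)
  X <- sc(tp$X); y <- sc(tp$y)
  if (n_val > 0) {
    vp <- unroll_pairs(val_w, model$config$n_taps, tc$objective)
    Xv <- sc(vp$X); yv <- sc(vp$y)
  }

  w <- model$weights
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_w <- w; best_val <- Inf; best_train <- Inf; stall <- 0
  epochs_run <- 0L; converged <- FALSE; train_mse <- Inf; val_mse <- NA_real_

  for (ep in seq_len(tc$max_epochs)) {
    lg <- narx_loss_grad(w, X, y)
    if (!is.finite(lg$mse))
      stop("training diverged: non-finite loss at epoch ", ep)
    train_mse <- lg$mse
    epochs_run <- ep
    for (nm in names(w)) {
      g <- lg$grad[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
      mh <- m[[nm]] / (1 - b1^ep)
      vh <- v[[nm]] / (1 - b2^ep)
      w[[nm]] <- w[[nm]] - tc$learn_rate * mh / (sqrt(vh) + eps)
    }
    if (n_val > 0) {
      fv <- narx_forward_scaled(w, Xv)
      val_mse <- mean((fv$yhat - yv)^2)
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse; best_w <- w; best_train <- train_mse; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= tc$patience) { converged <- TRUE; break }
      }
    } else {
      best_w <- w; best_train <- train_mse
    }
    if (train_mse < tc$mse_tolerance) { converged <- TRUE; break }
  }

  model$weights <- if (n_val > 0) best_w else w
  report <- list(epochs_run = epochs_run,
                 final_train_mse = if (n_val > 0) best_train else train_mse,
                 final_val_mse = if (n_val > 0) best_val else NA_real_,
                 converged = converged)
  list(model = model, report = report)
}

#' Close the loop: switch to the parallel prediction architecture
#'
#' Re-tags the trained open-loop network as closed-loop (parallel): the same
#' mapping, but the delay taps are fed from the model's own past predictions
#' during recursive forecasting. No weight changes.
#'
#' @param model An open-loop `narx_model`.
#' @return The same model in closed-loop mode.
#' @export
close_loop <- function(model) {
  stopifnot(inherits(model, "narx_model"))
  if (model$mode != "open_loop") stop("loop is already closed")
  model$mode <- "closed_loop"
  model
}

#' Recursive multi-step glucose prediction
#'
#' Starting from a seed window of `n_taps` true glucose values, the closed
#' network predicts the next value, shifts it into the tap buffer in place
#' of the oldest measurement, and repeats; after `k` steps the buffer's `k`
#' newest entries are the model's own predictions. All intermediate steps
#' are returned, so the forecast at horizon `PH = k * sampling_period`
#' minutes is element `k`.
#'
#' @param model A closed-loop `narx_model`.
#' @param seed_window The `n_taps` most recent true glucose values (mmol/L),
#'   newest last.
#' @param n_steps Number of recursive steps, between 1 and `max_steps`.
#' @param max_steps Cap on recursion depth (default `n_taps`: beyond that
#'   every tap is a self-prediction).
#' @return Numeric vector of `n_steps` predictions (mmol/L).
#' @export
predict_recursive <- function(model, seed_window, n_steps,
                              max_steps = model$config$n_taps) {
  stopifnot(inherits(model, "narx_model"))
  if (model$mode != "closed_loop")
    stop("model must be closed-loop; call close_loop() first")
  if (length(seed_window) != model$config$n_taps)
    stop("seed window must hold ", model$config$n_taps, " values")
  if (n_steps < 1 || n_steps > max_steps)
    stop("n_steps must be in [1, ", max_steps, "]")
  buf <- as.numeric(seed_window)
  out <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    p <- forward_one_step_unchecked(model, buf)
    out[k] <- p
    buf <- c(buf[-1], p)
  }
  out
}

# forward_one_step without the mode check, shared by both architectures:
# closing the loop changes where the taps come from, not the mapping.
forward_one_step_unchecked <- function(model, taps) {
  x <- matrix(apply_scaler(model$scaler, taps), nrow = 1)
  invert_scaler(model$scaler, narx_forward_scaled(model$weights, x)$yhat)
}

NARX_SCHEMA <- "glynarx-model/1"

#' Save / load a model as versioned JSON
#'
#' Text serialization at 17 significant digits, which round-trips IEEE
#' doubles exactly: a reloaded model reproduces every prediction bit for
#' bit. The file carries a schema tag, the architecture config, the scaler
#' bounds and row-major weight/bias arrays.
#'
#' @param model A `narx_model` with fitted scaler.
#' @param path File path.
#' @return `save_narx` invisibly returns `path`; `load_narx` returns the
#'   reconstructed `narx_model`.
#' @export
save_narx <- function(model, path) {
  stopifnot(inherits(model, "narx_model"))
  if (is.null(model$scaler)) stop("refusing to save a model without scaler")
  obj <- list(
    schema = NARX_SCHEMA,
    config = list(n_taps = model$config$n_taps, hidden = model$config$hidden,
                  activation_hidden = model$config$activation_hidden,
                  activation_output = model$config$activation_output,
                  seed = model$config$seed),
    scaler = list(lo = model$scaler$lo, hi = model$scaler$hi),
    mode = model$mode,
    weights = lapply(model$weights, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(t(p)))
      else list(dim = length(p), data = as.numeric(p))))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_narx
#' @export
load_narx <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$schema)) stop("model file is missing the schema tag")
  if (!identical(obj$schema, NARX_SCHEMA))
    stop("unsupported model schema '", obj$schema, "' (expected ",
         NARX_SCHEMA, ")")
  for (f in c("config", "scaler", "mode", "weights"))
    if (is.null(obj[[f]])) stop("model file is missing field '", f, "'")
  for (f in c("lo", "hi"))
    if (is.null(obj$scaler[[f]])) stop("model file scaler is missing '", f, "'")
  cfg <- narx_config(n_taps = obj$config$n_taps, hidden = obj$config$hidden,
                     seed = obj$config$seed)
  weights <- list()
  for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    wf <- obj$weights[[nm]]
    if (is.null(wf)) stop("model file is missing weight array '", nm, "'")
    weights[[nm]] <- if (length(wf$dim) == 2)
      matrix(wf$data, nrow = wf$dim[1], ncol = wf$dim[2], byrow = TRUE)
    else as.numeric(wf$data)
  }
  structure(list(config = cfg, weights = weights,
                 scaler = structure(list(lo = as.numeric(obj$scaler$lo),
                                         hi = as.numeric(obj$scaler$hi)),
                                    class = "glucose_scaler"),
                 mode = obj$mode),
            class = "narx_model")
}
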