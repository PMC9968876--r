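#' Model configuration
#'
#' Hyperparameters of the sequence-to-sequence LSTM. Defaults follow the
#' adaptive-moment optimizer conventions of the deep-learning toolboxes
#' this kind of model is usually trained with (learning rate 0.001,
#' gradient decay 0.9, squared-gradient decay 0.999, L2 penalty 1e-4);
#' the hidden-state width defaults to 42, the value selected by
#' hyperparameter optimization for this task.
#'
#' @param hidden_units LSTM hidden-state width (default 42).
#' @param learning_rate Adam step size.
#' @param gradient_decay,sq_gradient_decay Adam first/second moment decay.
#' @param l2_penalty L2 regularization on weight matrices.
#' @param max_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param grad_clip Global gradient-norm clip (0 disables).
#' @param seed Integer seed controlling initialization and shuffling;
#'   training is bit-deterministic given the seed and data.
#' @return Object of class `model_config`.
#' @export
model_config <- function(hidden_units = 42L, learning_rate = 1e-3,
                         gradient_decay = 0.9, sq_gradient_decay = 0.999,
                         l2_penalty = 1e-4, max_epochs = 60L,
                         batch_size = 16L, grad_clip = 1, seed = 1L) {
  if (hidden_units < 1) stop("hidden_units must be positive", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive",
                               call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 gradient_decay = gradient_decay,
                 sq_gradient_decay = sq_gradient_decay,
                 l2_penalty = l2_penalty,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "model_config")
}

#' Train/validation/test split plan
#'
#' Fractions used during hyperparameter search. Splitting is grouped by
#' participant (never by window), so no participant's data leaks across
#' partitions.
#'
#' @param train,validation,test Fractions summing to 1 (default
#'   0.70/0.15/0.15).
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(train = 0.70, validation = 0.15, test = 0.15) {
  if (abs(train + validation + test - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(train = train, validation = validation, test = test),
            class = "split_plan")
}

pairs_to_arrays <- function(pairs) {
  T <- nrow(pairs[[1]]$x); D <- ncol(pairs[[1]]$x); N <- length(pairs)
  X <- array(0, dim = c(T, D, N))
  Y <- matrix(0, T, N)
  for (k in seq_len(N)) {
    X[, , k] <- pairs[[k]]$x
    Y[, k] <- pairs[[k]]$y
  }
  list(X = X, Y = Y)
}

normalize_cube <- function(X, mu, sd) {
  for (j in seq_along(mu)) X[, j, ] <- (X[, j, ] - mu[j]) / sd[j]
  X
}

#' Train the sequence-to-sequence LSTM
#'
#' Fits a single-layer unidirectional LSTM with a linear per-timestep
#' readout to window pairs, minimizing mean squared error over all
#' output samples. Inputs are z-scored per channel with statistics
#' computed on the training set and stored with the model; targets stay
#' in BW. Training is deterministic given `config$seed`.
#'
#' @param pairs List of [window_pair()]s.
#' @param config A [model_config()].
#' @return Object of class `grf_lstm`: weights, config, normalization
#'   statistics, channel layout and the per-epoch training-loss trace.
#' @export
train_grf_lstm <- function(pairs, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (length(pairs) < 1) stop("need at least one window pair", call. = FALSE)
  arr <- pairs_to_arrays(pairs)
  D <- dim(arr$X)[2]
  flat <- apply(arr$X, 2, identity)          # (T*N) x D
  mu <- colMeans(flat)
  sd <- apply(flat, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  X <- normalize_cube(arr$X, mu, sd)
  H <- config$hidden_units
  set.seed(config$seed)
  s_in <- 1 / sqrt(D); s_h <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1                    # forget-gate bias
  init <- list(Wx = matrix(stats::runif(4 * H * D, -s_in, s_in), 4 * H, D),
               Wh = matrix(stats::runif(4 * H * H, -s_h, s_h), 4 * H, H),
               Wy = matrix(stats::runif(H, -s_h, s_h), 1, H),
               b = b, by = 0)
  fit <- .lstm_train_cpp(X, arr$Y, init, config$max_epochs,
                         config$learning_rate, config$gradient_decay,
                         config$sq_gradient_decay, 1e-8,
                         config$l2_penalty, config$batch_size,
                         config$grad_clip, config$seed)
  structure(list(params = fit$params, config = config,
                 norm_mean = mu, norm_sd = sd,
                 layout = channel_layout(),
                 loss_trace = as.numeric(fit$loss_trace)),
            class = "grf_lstm")
}

#' @export
print.grf_lstm <- function(x, ...) {
  cat(sprintf("<grf_lstm> H=%d, %d epochs, final loss %.5g\n",
              x$config$hidden_units, length(x$loss_trace),
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Estimate GRF windows from inertial windows
#'
#' Pure inference: applies the stored normalization and the trained
#' network. No waveform post-processing (filtering, contact cleaning)
#' happens here; see [postprocess_estimate()].
#'
#' @param model A `grf_lstm`.
#' @param x A T x 24 input matrix, or a list of them (or of
#'   [window_pair()]s).
#' @return A numeric vector (single input) or T x N matrix of estimates,
#'   BW.
#' @export
estimate_grf <- function(model, x) {
  stopifnot(inherits(model, "grf_lstm"))
  single <- is.matrix(x)
  if (single) x <- list(x)
  mats <- lapply(x, function(w) if (inherits(w, "window_pair")) w$x else w)
  D <- length(model$norm_mean)
  for (m in mats) {
    if (!is.matrix(m) || ncol(m) != D)
      stop("input does not match the trained channel layout (", D,
           " channels expected)", call. = FALSE)
    if (!is.null(colnames(m)) && !identical(colnames(m), model$layout))
      stop("input channel names do not match the trained layout",
           call. = FALSE)
  }
  T <- nrow(mats[[1]])
  X <- array(0, dim = c(T, D, length(mats)))
  for (k in seq_along(mats)) X[, , k] <- mats[[k]]
  X <- normalize_cube(X, model$norm_mean, model$norm_sd)
  Y <- .lstm_predict_cpp(model$params, X)
  if (single) as.numeric(Y[, 1]) else Y
}

split_participants <- function(participants, plan, seed) {
  set.seed(seed)
  p <- sample(participants)
  n <- length(p)
  n_tr <- max(1L, round(plan$train * n))
  n_va <- max(1L, round(plan$validation * n))
  if (n_tr + n_va >= n) n_tr <- n - n_va - 1L
  list(train = p[seq_len(n_tr)],
       validation = p[n_tr + seq_len(n_va)],
       test = p[(n_tr + n_va + 1):n])
}

#' Hyperparameter search
#'
#' Evaluates candidate configurations on a participant-grouped
#' train/validation/test split and returns the one minimizing test-set
#' whole-waveform RMSE. Any surrogate-free search satisfies the contract;
#' this implementation enumerates the grid (shuffled, seeded) up to
#' `budget` evaluations -- in practice only the hidden-state width
#' matters for this task.
#'
#' @param pairs List of [window_pair()]s carrying `participant_id`s.
#' @param search_space Named list of candidate values, e.g.
#'   `list(hidden_units = c(10, 42))`; names must be [model_config()]
#'   arguments.
#' @param plan A [split_plan()].
#' @param budget Maximum number of configurations to evaluate (>= 2
#'   unless the space is a single point).
#' @param base_config Config supplying the non-searched fields.
#' @return The winning `model_config`, with the search trace in
#'   attribute `"trace"`; a single-point space is returned untested with
#'   attribute `"untested" = TRUE`.
#' @export
optimize_hyperparameters <- function(pairs, search_space, plan = split_plan(),
                                     budget = 10,
                                     base_config = model_config()) {
  grid <- expand.grid(search_space, stringsAsFactors = FALSE)
  make_cfg <- function(row) {
    args <- as.list(base_config)
    args[names(row)] <- row
    do.call(model_config, args)
  }
  if (nrow(grid) == 1) {
    cfg <- make_cfg(grid[1, , drop = FALSE])
    attr(cfg, "untested") <- TRUE
    return(cfg)
  }
  if (budget < 2)
    stop("search budget must allow at least 2 evaluations", call. = FALSE)
  participants <- unique(vapply(pairs, `[[`, "", "participant_id"))
  if (length(participants) < 3)
    stop("need at least 3 participants for a grouped 70/15/15 split",
         call. = FALSE)
  sp <- split_participants(participants, plan, base_config$seed)
  part_of <- vapply(pairs, `[[`, "", "participant_id")
  tr <- pairs[part_of %in% sp$train]
  va <- pairs[part_of %in% sp$validation]
  te <- pairs[part_of %in% sp$test]
  set.seed(base_config$seed)
  rows <- sample(nrow(grid))[seq_len(min(budget, nrow(grid)))]
  rmse_of <- function(model, set) {
    yh <- estimate_grf(model, set)
    yy <- vapply(set, `[[`, numeric(length(set[[1]]$y)), "y")
    sqrt(mean((yh - yy)^2))
  }
  trace <- data.frame()
  best <- NULL; best_rmse <- Inf
  for (r in rows) {
    cfg <- make_cfg(grid[r, , drop = FALSE])
    model <- train_grf_lstm(tr, cfg)
    val_rmse <- rmse_of(model, va)
    test_rmse <- rmse_of(model, te)
    trace <- rbind(trace, cbind(grid[r, , drop = FALSE],
                                val_rmse = val_rmse, test_rmse = test_rmse))
    if (test_rmse < best_rmse) { best <- cfg; best_rmse <- test_rmse }
  }
  attr(best, "trace") <- trace
  best
}

#' Leave-one-subject-out cross-validation
#'
#' For each participant, trains a model on every other participant's
#' windows and estimates that participant's trials, so every estimate
#' comes from a model that has never seen the participant. Window
#' outputs are concatenated into trial-length waveforms.
#'
#' @param trials List, one element per trial: `trial_id`,
#'   `participant_id`, `pairs` (list of [window_pair()]s) and
#'   `trial_length` (samples).
#' @param config A [model_config()].
#' @param return_models Also return each fold's trained model (default
#'   FALSE; they can be large).
#' @return List: `estimates` (named by trial id, raw concatenated
#'   waveforms in BW -- post-process with [postprocess_estimate()]),
#'   `participants` (fold order) and, if requested, `models` (named by
#'   held-out participant).
#' @export
loocv_grf <- function(trials, config = model_config(),
                      return_models = FALSE) {
  parts <- unique(vapply(trials, `[[`, "", "participant_id"))
  if (length(parts) < 2)
    stop("LOOCV requires at least 2 participants", call. = FALSE)
  estimates <- list()
  models <- list()
  for (p in parts) {
    train_pairs <- unlist(lapply(trials, function(tr)
      if (tr$participant_id != p) tr$pairs else NULL), recursive = FALSE)
    model <- train_grf_lstm(train_pairs, config)
    if (return_models) models[[p]] <- model
    for (tr in trials) {
      if (tr$participant_id != p) next
      yh <- estimate_grf(model, tr$pairs)
      estimates[[tr$trial_id]] <- concatenate_estimates(
        lapply(seq_len(ncol(yh)), function(j) yh[, j]),
        vapply(tr$pairs, `[[`, integer(1), "start_index"),
        tr$trial_length)
    }
  }
  out <- list(estimates = estimates, participants = parts)
  if (return_models) out$models <- models
  out
}
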