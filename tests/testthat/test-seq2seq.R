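small_cfg <- function(...) model_config(hidden_units = 8, max_epochs = 30,
                                        learning_rate = 0.008,
                                        batch_size = 8, seed = 7, ...)

test_that("training is seed-deterministic with a finite loss trace", {
  pairs <- learnable_windows(8)
  m1 <- train_grf_lstm(pairs, small_cfg())
  m2 <- train_grf_lstm(pairs, small_cfg())
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params$Wx, m2$params$Wx)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
})

test_that("a constant-target window is memorized to within 0.01", {
  set.seed(1)
  x <- matrix(rnorm(400 * 24), 400, 24)
  pair <- window_pair(x, rep(0.8, 400), "T1", 1L, "P1")
  # no L2: the shrinkage penalty would bias an exact-interpolation check
  m <- train_grf_lstm(list(pair), model_config(hidden_units = 16,
                                               max_epochs = 1500,
                                               learning_rate = 0.01,
                                               l2_penalty = 0,
                                               batch_size = 1, seed = 3))
  expect_lt(max(abs(estimate_grf(m, x) - 0.8)), 0.01)
})

test_that("a noiseless learnable mapping generalizes below 0.05 BW RMSE", {
  pairs <- learnable_windows(24)
  m <- train_grf_lstm(pairs, model_config(hidden_units = 16,
                                          max_epochs = 80,
                                          learning_rate = 0.008,
                                          batch_size = 8, seed = 7))
  held <- learnable_windows(6, seed = 99)
  yh <- estimate_grf(m, held)
  yy <- vapply(held, `[[`, numeric(400), "y")
  expect_lt(sqrt(mean((yh - yy)^2)), 0.05)
})

test_that("estimation is pure, shape-checked and finite on zeros", {
  pairs <- learnable_windows(4)
  m <- train_grf_lstm(pairs, model_config(hidden_units = 4, max_epochs = 2,
                                          seed = 1))
  z <- matrix(0, 400, 24)
  y1 <- estimate_grf(m, z)
  expect_length(y1, 400L)
  expect_true(all(is.finite(y1)))
  expect_identical(y1, estimate_grf(m, z))
  expect_error(estimate_grf(m, matrix(0, 400, 23)), "channel layout")
})

test_that("hyperparameter search prefers the better capacity", {
  pairs <- learnable_windows(24)
  best <- optimize_hyperparameters(pairs, list(hidden_units = c(2L, 16L)),
                                   budget = 2,
                                   base_config = small_cfg())
  expect_equal(best$hidden_units, 16L)
  tr <- attr(best, "trace")
  expect_equal(nrow(tr), 2L)
  expect_true(all(c("val_rmse", "test_rmse") %in% names(tr)))

  expect_error(optimize_hyperparameters(pairs,
                                        list(hidden_units = c(2L, 16L)),
                                        budget = 1), "at least 2")
  one <- optimize_hyperparameters(pairs, list(hidden_units = 42L),
                                  budget = 5)
  expect_equal(one$hidden_units, 42L)
  expect_true(isTRUE(attr(one, "untested")))
})

test_that("LOOCV partitions by participant and never leaks held-out data", {
  pairs <- learnable_windows(12)            # participants P1..P4
  trials <- lapply(c("P1", "P2"), function(p) {
    ps <- pairs[vapply(pairs, `[[`, "", "participant_id") == p]
    for (i in seq_along(ps)) ps[[i]]$start_index <- (i - 1L) * 400L + 1L
    list(trial_id = paste0(p, "_T1"), participant_id = p, pairs = ps,
         trial_length = length(ps) * 400L)
  })
  cfg <- model_config(hidden_units = 4, max_epochs = 3, seed = 2)
  cv <- loocv_grf(trials, cfg, return_models = TRUE)
  expect_length(cv$estimates, 2L)
  expect_setequal(cv$participants, c("P1", "P2"))

  # perturb P1 wildly; the fold-P1 model (trained on P2 only) is unchanged
  trials2 <- trials
  for (i in seq_along(trials2[[1]]$pairs))
    trials2[[1]]$pairs[[i]]$x <- trials2[[1]]$pairs[[i]]$x * 100
  cv2 <- loocv_grf(trials2, cfg, return_models = TRUE)
  expect_identical(cv2$models$P1$params, cv$models$P1$params)

  expect_error(loocv_grf(trials[1], cfg), "at least 2")
})
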