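fake_imu_set <- function(T = 20) {
  t <- (0:(T - 1)) / 100
  mk <- function(site, a, g)
    imu_recording(site, t, matrix(a, T, 3, byrow = TRUE),
                  matrix(g, T, 3, byrow = TRUE), 100)
  list(left_foot = mk("left_foot", c(3, 4, 0), c(0, 0, 0)),
       right_foot = mk("right_foot", c(1, 0, 0), c(0, 2, 0)),
       sacrum = mk("sacrum", c(0, 0, -9.81), c(1, 1, 1)))
}

test_that("channel assembly produces the 24-column layout with magnitudes", {
  m <- assemble_channels(fake_imu_set())
  expect_equal(ncol(m), 24L)
  expect_identical(colnames(m), channel_layout())
  expect_equal(unique(m[, "left_foot.amag"]), 5)       # |(3,4,0)|
  expect_equal(unique(m[, "left_foot.gmag"]), 0)       # zero gyro
  expect_equal(unique(m[, "sacrum.gmag"]), sqrt(3))
  expect_error(assemble_channels(fake_imu_set()[1:2]), "must contain")
})

test_that("bilateral force sums, normalizes and applies the 5% BW rule", {
  t <- (0:9) / 100
  f <- force_recording(t, c(360.5, 20, 0, rep(100, 7)),
                       c(360.5, 10, 0, rep(100, 7)), 100, 721.0)
  y <- sum_bilateral_force(f)
  expect_equal(y[1], 1.0, tolerance = 1e-12)
  expect_equal(y[2], 0)      # 30/721 < 5% BW
  expect_equal(y[3], 0)      # flight
})

test_that("window cutting counts, drops remainders and tiles the trial", {
  ch <- matrix(rnorm(4000 * 24), 4000, 24)
  f <- abs(rnorm(4000))
  w <- make_windows(ch, f, "T1", "P1")
  expect_length(w, 10L)
  expect_true(all(vapply(w, function(p) nrow(p$x) == 400 &&
                           ncol(p$x) == 24, logical(1))))
  recon <- do.call(rbind, lapply(w, `[[`, "x"))
  expect_identical(recon, unname(ch[1:4000, ]))

  w2 <- make_windows(ch[1:450, ], f[1:450], "T1", "P1")
  expect_length(w2, 1L)
  expect_warning(w0 <- make_windows(ch[1:399, ], f[1:399], "T1", "P1"),
                 "shorter")
  expect_length(w0, 0L)
})

test_that("concatenation inverts windowing on the covered prefix", {
  f <- abs(rnorm(950))
  ch <- matrix(0, 950, 24)
  w <- make_windows(ch, f, "T1", "P1")
  y <- concatenate_estimates(lapply(w, `[[`, "y"),
                             vapply(w, `[[`, integer(1), "start_index"),
                             950)
  expect_equal(as.numeric(y)[1:800], f[1:800])
  expect_equal(attr(y, "tail_filled"), 150L)
  expect_true(all(y[801:950] == 0))

  expect_error(concatenate_estimates(lapply(rev(w), `[[`, "y"),
                                     rev(vapply(w, `[[`, integer(1),
                                                "start_index")), 950),
               "out of order")
  one <- concatenate_estimates(list(f[1:400]), 1L, 400)
  expect_equal(as.numeric(one), f[1:400])
})
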