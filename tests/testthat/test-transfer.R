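test_that("transfer constants hit their threshold limits", {
  tc <- transfer_constants(np_high$V_T, np_high, hp_high)
  expect_equal(tc$c0, 1)
  expect_equal(tc$K_EIF0, -1)
  expect_equal(abs(tc$K_LIF0), hp_high$K + 1)

  tc3 <- transfer_constants(np_high$V_T - 3, np_high, hp_high)
  expect_equal(tc3$c0, exp(1))

  # structural invariants across a baseline range
  for (V0 in seq(-65, np_high$V_T, length.out = 10)) {
    tc <- transfer_constants(V0, np_high, hp_high)
    expect_gte(tc$c0, 1)
    expect_lt(tc$K_LIF0, 0)
    expect_gt(tc$K_EIF0, -hp_high$K * tc$c0)
    expect_lte(tc$K_EIF0, hp_high$K - 1)
  }
})

test_that("the transfer function is the identity for zero feedback and at high f", {
  expect_equal(transfer_function(c(0, 1, 50, 1e4), 7.2, 0),
               rep(1 + 0i, 4))
  tc <- transfer_constants(-51.4, np_high, hp_high)
  Tf <- transfer_function(1e6, tc$h0, tc$K_EIF0)
  expect_equal(Mod(Tf), 1, tolerance = 1e-6)
  expect_equal(Arg(Tf), 0, tolerance = 1e-3)
})

test_that("the gain at 50 Hz matches an independent algebraic evaluation", {
  tc <- transfer_constants(-51.4, np_high, hp_high)
  w <- 2 * pi * 50
  gain <- Mod(transfer_function(50, tc$h0, tc$K_EIF0))
  # modulus computed without complex arithmetic
  expected <- sqrt((w^2 + tc$h0^2) / (w^2 + (tc$h0 * (1 + tc$K_EIF0))^2))
  expect_equal(gain, expected, tolerance = 1e-12)
})

test_that("evaluation at the real pole is flagged singular", {
  expect_error(transfer_function(0, 10, -1), "singular")
})

test_that("deep baselines make the EIF and LIF feedback weights coincide", {
  tc <- transfer_constants(-65, np_high, hp_high)
  expect_lt(abs(tc$K_EIF0 - tc$K_LIF0) / abs(tc$K_LIF0), 0.01)
})

test_that("EIF curves dominate LIF curves at every frequency and baseline", {
  for (hp_np in list(list(np_high, hp_high), list(np_low, hp_low))) {
    b <- bode(neuron = hp_np[[1]], hazard = hp_np[[2]])
    e <- b[b$model == "eif", ]
    l <- b[b$model == "lif", ]
    expect_true(all(b$gain > 0))
    expect_true(all(abs(1 - e$gain) <= abs(1 - l$gain) + 1e-9))
    expect_true(all(abs(e$phase_deg) <= abs(l$phase_deg) + 0.1))
  }
})

test_that("EIF gain approaches unity as the baseline nears threshold", {
  b <- bode(frequencies = c(5, 20, 80), neuron = np_high, hazard = hp_high)
  e <- b[b$model == "eif", ]
  l <- b[b$model == "lif", ]
  for (f in c(5, 20, 80)) {
    by_v0 <- e[e$frequency_hz == f, ]
    by_v0 <- by_v0[order(by_v0$V0_mV), ]
    expect_true(all(diff(abs(1 - by_v0$gain)) <= 1e-9))
    # LIF gain is virtually flat in V0 by comparison
    lg <- l[l$frequency_hz == f, "gain"]
    expect_lt(diff(range(lg)), 0.1 * diff(range(by_v0$gain)) + 1e-6)
  }
})

test_that("the low-conductance regime depends less on the baseline voltage", {
  spread <- function(np, hp) {
    b <- bode(neuron = np, hazard = hp)
    e <- b[b$model == "eif", ]
    c(gain = mean(tapply(e$gain, e$frequency_hz, function(g) diff(range(g)))),
      phase = mean(tapply(e$phase_deg, e$frequency_hz,
                          function(g) diff(range(g)))))
  }
  s_high <- spread(np_high, hp_high)
  s_low <- spread(np_low, hp_low)
  expect_lt(s_low["gain"], s_high["gain"])
  expect_lt(s_low["phase"], s_high["phase"])
})

test_that("the log-modulation prediction is the identity for zero feedback", {
  g <- grid_coarse(t_max = 0.5)
  lm <- make_log_modulation(modulation_spec(10, 10, 60, 0.2, seed = 3), g)
  # V0 slightly above threshold makes c0 = (K-1)/K, i.e. K_EIF0 = 0
  K <- hp_high$K
  V0_id <- np_high$V_T - 3 * log((K - 1) / K)
  tc <- transfer_constants(V0_id, np_high, hp_high)
  expect_equal(tc$K_EIF0, 0, tolerance = 1e-12)
  pred <- predict_logmod(lm, tc, "eif")
  # anchored at the zero initial condition: identity up to the start value
  expect_equal(pred$values, lm$values - lm$values[1], tolerance = 1e-9)
  # FFT route on the stripped signal agrees up to the untransduced offset
  lm_tab <- sampled_fun(lm$values, g, "1")
  pred_fft <- predict_logmod(lm_tab, tc, "eif")
  expect_equal(pred_fft$values, lm$values, tolerance = 1e-9)
})

test_that("a high-frequency sinusoid passes nearly undistorted near threshold", {
  g <- grid_coarse(t_max = 0.5, dt = 2e-4)
  lm <- make_log_modulation(modulation_spec(1, 150, 150, 0.1, seed = 4), g)
  tc <- transfer_constants(np_high$V_T - 1, np_high, hp_high)
  pred <- predict_logmod(lm, tc, "eif", transient = FALSE)
  Tf <- transfer_function(150, tc$h0, tc$K_EIF0)
  expect_gt(Mod(Tf), 0.95)
  expect_lt(abs(Arg(Tf)) * 180 / pi, 15)
  mp <- attr(lm, "mod_params")
  centred <- lm$values - mp$beta
  expect_lt(rel_l2(pred$values, centred), 0.25)
})
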