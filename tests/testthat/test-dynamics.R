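test_that("the reference state is a fixed point of every sampled instance", {
  b <- lactis()
  model <- compile_model(b$network)
  set.seed(31)
  ps <- sample_parameter_set(model, b$state, sampling_config(1, 1, 31))
  tr <- integrate_timecourse(model, ps$values, b$state, events = NULL,
                             t_end = 100, times = c(10, 50, 100))
  expect_false(tr$failed)
  c0 <- b$state$concentrations[colnames(tr$concentrations)]
  for (i in seq_along(tr$time))
    expect_lt(max(abs(tr$concentrations[i, ] - c0) / c0), 1e-6)
})

test_that("moiety sums stay constant along a starvation trajectory", {
  b <- lactis()
  model <- compile_model(b$network)
  cons <- find_conservation_relations(b$network)
  set.seed(32)
  ps <- sample_parameter_set(model, b$state, sampling_config(1, 1, 32))
  ev <- lactokin:::glucose_events(starvation_protocol())
  tr <- integrate_timecourse(model, ps$values, b$state, ev, t_end = 100)
  expect_false(tr$failed)
  for (m in cons$moiety_vectors) {
    tot <- drop(tr$concentrations[, names(m)] %*% m)
    expect_lt(max(abs(tot - tot[1])) / abs(tot[1]), 1e-6)
  }
  # glucose drop: intermediates fall quickly
  fbp <- tr$concentrations[, "FBP"]
  i_drop <- which.min(abs(tr$time - 1))
  i_mid <- which.min(abs(tr$time - 9.9))
  expect_lt(fbp[i_mid], 0.5 * fbp[i_drop])
})

test_that("ATP typically shows a transient rise after glucose withdrawal", {
  b <- lactis()
  model <- compile_model(b$network)
  ev <- lactokin:::glucose_events(starvation_protocol())
  grid <- sort(unique(c(1, 1 + 10 ^ seq(-3, log10(3), length.out = 60))))
  traces <- sapply(1:10, function(seed) {
    ps <- with_seed_local(seed, sample_parameter_set(model, b$state,
                                                     sampling_config(1, 1, seed)))
    tr <- integrate_timecourse(model, ps$values, b$state, ev, t_end = 4,
                               times = grid)
    tr$concentrations[, "ATP"]
  })
  bump <- apply(traces, 2, function(a) max(a[-1]) > a[1])
  expect_gte(mean(bump), 0.5)   # a typical instance shows the transient rise
})

test_that("protocol and event validation", {
  expect_error(starvation_protocol(t_drop = 10, t_restore = 5), "t_drop")
  b <- lactis()
  model <- compile_model(b$network)
  ps <- exact_params(model, b$state)
  bad_ev <- data.frame(time = 1, species = "ATP", value = 1)
  expect_error(integrate_timecourse(model, ps$values, b$state, bad_ev),
               "not a fixed species")
})

test_that("classify_recovery: exact, collapsed and failure outcomes", {
  b <- lactis()
  model <- compile_model(b$network)
  ps <- exact_params(model, b$state)
  tr <- integrate_timecourse(model, ps$values, b$state, NULL, t_end = 1,
                             times = c(0.5, 1))
  oc <- classify_recovery(tr, b$state, b$network)
  expect_true(oc$recovered)
  expect_lt(oc$distance, 1e-6)
  expect_false(oc$collapsed)
  # scripted collapsed vector: ATP near zero is far from the reference
  tr2 <- tr
  tr2$concentrations[nrow(tr2$concentrations), ] <-
    rep(0.01, ncol(tr2$concentrations))
  oc2 <- classify_recovery(tr2, b$state, b$network)
  expect_false(oc2$recovered)
  expect_true(oc2$collapsed)
  expect_gt(oc2$distance, 0.9)
  # NaN trajectory -> numerical failure, never counted as recovered
  tr3 <- tr
  tr3$concentrations[nrow(tr3$concentrations), 1] <- NaN
  oc3 <- classify_recovery(tr3, b$state, b$network)
  expect_true(oc3$numerical_failure)
  expect_false(oc3$recovered)
})

test_that("a null starvation protocol recovers every instance", {
  b <- lactis()
  pr <- starvation_protocol(glucose_high = 20, glucose_low = 20,
                            t_drop = 1, t_restore = 2, t_eval = 10)
  res <- run_starvation_experiment(b$network, b$state,
                                   sampling_config(1, 8, seed = 33), pr)
  expect_equal(res$recovered_fraction, 1)
  expect_equal(res$counts[["numerical_failure"]], 0L)
})

test_that("recovery classification is robust to the tolerance choice", {
  b <- lactis()
  res <- run_starvation_experiment(b$network, b$state,
                                   sampling_config(1, 60, seed = 34))
  d <- vapply(res$outcomes, `[[`, 0, "distance")
  fr <- vapply(c(0.01, 0.05, 0.10), function(tol) mean(d <= tol), 0)
  expect_lt(max(fr) - min(fr), 0.05)  # < 5 percentage points over the sweep
})

test_that("the pinned bistable toy shows hysteresis; the monostable variant does not", {
  bt <- make_bistable_toy(TRUE)
  expect_true(validate_steady_state(bt$network, bt$state)$pass)
  expect_true(all(check_thermodynamic_feasibility(bt$network, bt$state)$feasible))
  hs <- hysteresis_scan(bt$model, bt$par, bt$state, glucose_high = 10,
                        glucose_low = 0.1, glucose_id = "S", atp_id = "X")
  expect_true(hs$bistable)
  expect_false(hs$indeterminate)
  mt <- make_bistable_toy(FALSE)
  expect_true(validate_steady_state(mt$network, mt$state)$pass)
  hm <- hysteresis_scan(mt$model, mt$par, mt$state, glucose_high = 10,
                        glucose_low = 0.1, glucose_id = "S", atp_id = "X")
  expect_false(hm$bistable)
})

test_that("a 1x1 recovery surface reduces to the starvation experiment", {
  b <- lactis()
  cfg <- sampling_config(1, 12, seed = 35)
  surf <- recovery_surface(b$network, b$state, cfg,
                           starvation_durations = 9, recovery_durations = 90)
  pr <- starvation_protocol(t_drop = 1, t_restore = 10, t_eval = 100)
  res <- run_starvation_experiment(b$network, b$state, cfg, pr)
  expect_equal(dim(surf), c(1L, 1L))
  expect_equal(surf[1, 1], res$recovered_fraction)
})
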