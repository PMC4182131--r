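test_that("Michaelis-constant sampling respects the log-uniform interval", {
  tc <- toy_chain()
  model <- compile_model(tc$network)
  cfg <- sampling_config(lambda = 1, n_samples = 1, seed = 1)
  set.seed(1)
  draws <- replicate(200, sample_michaelis_constants(tc$state, cfg, model))
  ref <- lactokin:::param_references(model, tc$state)
  ref <- ref[!is.na(ref)]
  for (i in seq_along(ref)) {
    expect_true(all(draws[i, ] >= ref[i] / 10 - 1e-12))
    expect_true(all(draws[i, ] <= ref[i] * 10 + 1e-12))
  }
  # lambda = 0 degenerates to the concentration itself
  cfg0 <- sampling_config(lambda = 0, n_samples = 1, seed = 1)
  set.seed(1)
  expect_equal(unname(sample_michaelis_constants(tc$state, cfg0, model)),
               unname(ref))
  expect_error(sampling_config(lambda = -1), "lambda")
})

test_that("log10 of draws is uniform: mean near the reference decade", {
  tc <- toy_chain(conc = c(EXT = 5, S = 1, P = 1),
                  flux = c(IN = 1, R = 1, OUT = 1))
  model <- compile_model(tc$network)
  cfg <- sampling_config(lambda = 1, n_samples = 1, seed = 1)
  set.seed(42)
  draws <- replicate(2e4, sample_michaelis_constants(tc$state, cfg, model)[["km|R|S"]])
  expect_lt(abs(mean(log10(draws))), 0.02)  # LLN on U(-1, 1)
  expect_gt(sd(log10(draws)), 0.5)          # spread consistent with uniform
})

test_that("uni-uni rate law matches its closed form and the Haldane condition", {
  r <- reaction("R", c(S = -1, P = 1), TRUE, keq = 10)
  rl <- build_rate_law(r, list(km = c(S = 2, P = 4), vmax = 1))
  # S = KS, P = 0, effectively irreversible at P = 0
  expect_equal(rl(c(S = 2, P = 0)), 0.5)
  # equilibrium: gamma = keq -> rate 0 regardless of km
  expect_equal(rl(c(S = 1, P = 10)), 0)
  for (km in list(c(S = 0.3, P = 9), c(S = 5, P = 0.1))) {
    rl2 <- build_rate_law(r, list(km = km, vmax = 2.7))
    expect_equal(rl2(c(S = 2, P = 20)), 0)
  }
  # explicit convenience-kinetics value
  rl3 <- build_rate_law(r, list(km = c(S = 2, P = 4), vmax = 3))
  S <- 1; P <- 2
  expect_equal(rl3(c(S = S, P = P)),
               3 * (S / 2) * (1 - (P / S) / 10) / (1 + S / 2 + P / 4))
  expect_error(build_rate_law(r, list(km = c(S = 2), vmax = 1)), "missing km")
})

test_that("regulation multipliers have the right limits and monotonicity", {
  r <- reaction("R", c(S = -1), FALSE,
                regulations = list(regulation("I", "inhibitor", 1),
                                   regulation("A", "activator", 1)))
  rl <- build_rate_law(r, list(km = c(S = 1), vmax = 1,
                               reg = list(I = 1, A = 1)))
  base <- function(I, A) rl(c(S = 1e9, I = I, A = A)) # saturate the core
  expect_lt(base(1e9, 1), 1e-6)            # inhibitor -> infinity kills rate
  # activator -> infinity restores the unregulated rate; at zero it is off
  expect_equal(base(0, 1e9), 1, tolerance = 1e-6)
  expect_equal(base(0, 0), 0)
  # strict monotonicity over a grid
  xs <- 10 ^ seq(-2, 2, length.out = 20)
  vi <- vapply(xs, function(x) base(x, 1e9), 0)
  va <- vapply(xs, function(x) base(0, x), 0)
  expect_true(all(diff(vi) < 0))
  expect_true(all(diff(va) > 0))
})

test_that("R closure and compiled rates agree on random parameter draws", {
  co <- toy_cofactor()
  model <- compile_model(co$network)
  set.seed(7)
  for (rep in 1:5) {
    ps <- sample_parameter_set(model, co$state,
                               sampling_config(1, 1, seed = rep))
    conc <- co$state$concentrations * runif(6, 0.3, 3)
    vC <- lactokin:::model_rates(model, conc[model$met_ids], ps$values)
    for (j in seq_along(co$network$reactions)) {
      r <- co$network$reactions[[j]]
      st <- r$stoichiometry
      need <- names(st)[if (r$reversible) TRUE else st < 0]
      km <- ps$values[paste("km", r$id, need, sep = "|")]
      names(km) <- need
      rl <- build_rate_law(r, list(km = km,
                                   vmax = ps$values[[paste0("vmax|", r$id)]]))
      expect_equal(unname(vC[[r$id]]), rl(conc), tolerance = 1e-12)
    }
  }
})

test_that("Vmax rescaling makes the state an exact fixed point, repeatably", {
  b <- lactis()
  model <- compile_model(b$network)
  c0 <- b$state$concentrations[model$met_ids]
  J0 <- b$state$fluxes[model$rxn_ids]
  N <- stoichiometry_matrix(b$network, dynamic_only = TRUE)
  for (seed in 1:20) {
    ps <- sample_parameter_set(model, b$state, sampling_config(1, 1, seed))
    expect_false(ps$rejected)
    v <- lactokin:::model_rates(model, c0, ps$values)
    expect_lt(max(abs(v - J0)), 1e-12 * max(abs(J0)))
    expect_lt(max(abs(N %*% v)), 1e-9 * max(abs(J0)))
  }
  # trivial division example: reduced rate 0.5, J0 = 1 -> vmax = 2
  tc <- toy_chain()
  m2 <- compile_model(tc$network)
  par <- setNames(numeric(nrow(m2$pspec)), m2$pspec$name)
  par["km|IN|EXT"] <- 5   # EXT = 5 -> half saturation, reduced rate 0.5
  par["km|R|S"] <- 2; par["km|R|P"] <- 1
  par["km|OUT|P"] <- 1
  rs <- rescale_vmax(m2, tc$state, par)
  expect_equal(unname(rs$vmax[["IN"]]), 2)
})

test_that("thermodynamically blocked instances are rejected with names", {
  tc <- toy_chain(keq = 10)
  st_blocked <- metabolic_state(tc$state$concentrations,
                                c(IN = 1, R = -1, OUT = 1)) # backward flux
  model <- compile_model(tc$network)
  par <- setNames(rep(1, nrow(model$pspec)), model$pspec$name)
  rs <- rescale_vmax(model, st_blocked, par)
  expect_true(rs$rejected)
  expect_true("R" %in% rs$blocked)
})

test_that("sampling is seed-reproducible", {
  b <- lactis()
  model <- compile_model(b$network)
  cfg <- sampling_config(1, 1, seed = 99)
  p1 <- with(list(), {set.seed(99); sample_parameter_set(model, b$state, cfg)})
  p2 <- with(list(), {set.seed(99); sample_parameter_set(model, b$state, cfg)})
  expect_identical(p1$values, p2$values)
})

test_that("analytic elasticities match a finite-difference oracle", {
  co <- toy_cofactor()
  model <- compile_model(co$network)
  ps <- sample_parameter_set(model, co$state, sampling_config(1, 1, 5))
  c0 <- co$state$concentrations[model$met_ids]
  E <- lactokin:::model_dvdc(model, c0, ps$values)
  E_fd <- fd_dvdc(model, c0, ps$values)
  expect_equal(E, E_fd, tolerance = 1e-6)
  # same on the full fixture with all regulation types (incl. NADH/NAD ratio)
  b <- lactis()
  mb <- compile_model(b$network)
  pb <- sample_parameter_set(mb, b$state, sampling_config(1, 1, 6))
  cb <- b$state$concentrations[mb$met_ids]
  expect_equal(lactokin:::model_dvdc(mb, cb, pb$values),
               fd_dvdc(mb, cb, pb$values), tolerance = 1e-5)
})

test_that("scaled elasticities: half-saturation value and consistency", {
  # irreversible uni-uni at S = KS: d log v / d log S = 1/(1 + S/KS) = 0.5
  mets <- list(metabolite("X", concentration = 2))
  net <- metabolic_network(list(metabolite("EXT", fixed = TRUE,
                                           concentration = 2),
                                metabolite("X", concentration = 1)),
                           list(reaction("R", c(EXT = -1, X = 1), FALSE),
                                reaction("D", c(X = -1), FALSE)))
  st <- metabolic_state(c(EXT = 2, X = 1), c(R = 1, D = 1))
  model <- compile_model(net)
  par <- setNames(numeric(nrow(model$pspec)), model$pspec$name)
  par["km|R|EXT"] <- 2; par["km|D|X"] <- 1
  rs <- rescale_vmax(model, st, par)
  el <- compute_elasticities(model, st, rs$par)
  expect_equal(el$scaled["R", "EXT"], 0.5, tolerance = 1e-12)
  expect_equal(el$unscaled * outer(1 / el$v0, st$concentrations[model$met_ids]),
               el$scaled, tolerance = 1e-12)
})

test_that("product elasticity magnitude grows as rho approaches 1", {
  # rho sweep on the reversible uni-uni step of the toy chain
  mags <- vapply(c(0.1, 0.5, 0.9, 0.99), function(rho) {
    keq <- 0.5 / rho                  # gamma fixed at 0.5 (S=2, P=1)
    tc <- toy_chain(keq = keq)
    model <- compile_model(tc$network)
    ps <- exact_params(model, tc$state)
    el <- compute_elasticities(model, tc$state, ps$values)
    abs(el$scaled["R", "P"])
  }, 0)
  expect_true(all(diff(mags) > 0))
  expect_lt(mags[1], 1)
  expect_gt(mags[4], 10)
})
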