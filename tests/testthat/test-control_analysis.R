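test_that("reduced Jacobian agrees with a finite-difference linearization", {
  co <- toy_cofactor()
  model <- compile_model(co$network)
  cons <- find_conservation_relations(co$network)
  ps <- sample_parameter_set(model, co$state, sampling_config(1, 1, 3))
  el <- compute_elasticities(model, co$state, ps$values)
  jr <- assemble_jacobian(cons, el$unscaled)
  # oracle: numerically linearize the full ODE over dynamic species
  c0 <- co$state$concentrations[model$met_ids]
  dyn <- which(!model$fixed)
  y0 <- c0[dyn]
  f <- function(y) {
    ct <- c0; ct[dyn] <- y
    drop(stoichiometry_matrix(co$network, TRUE) %*%
           lactokin:::model_rates(model, ct, ps$values))
  }
  Jfd <- matrix(0, length(y0), length(y0))
  for (j in seq_along(y0)) {
    h <- 1e-6 * max(abs(y0[j]), 1e-3)
    yp <- y0; ym <- y0; yp[j] <- y0[j] + h; ym[j] <- y0[j] - h
    Jfd[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  # nonzero spectrum of the full FD Jacobian matches the reduced one,
  # plus one zero mode per conservation relation
  ev_full <- sort(Re(eigen(Jfd, only.values = TRUE)$values))
  ev_red <- sort(Re(jr$eigenvalues))
  expect_equal(sum(abs(ev_full) < 1e-7), length(cons$moiety_vectors))
  nz <- ev_full[abs(ev_full) >= 1e-7]
  expect_equal(nz, ev_red, tolerance = 1e-5)
})

test_that("conservation removes the zero mode of a closed cycle", {
  cl <- toy_closed()
  model <- compile_model(cl$network)
  cons <- find_conservation_relations(cl$network)
  par <- setNames(c(1, 2, 1), model$pspec$name) # km A, km B, vmax
  el <- lactokin:::model_dvdc(model, c(1, 2), par)
  N <- stoichiometry_matrix(cl$network, TRUE)
  full <- N %*% el
  expect_lt(min(abs(eigen(full, only.values = TRUE)$values)), 1e-12)
  jr <- assemble_jacobian(cons, el)
  expect_true(all(abs(jr$eigenvalues) > 1e-12))
  expect_true(jr$stable)
})

test_that("two-step pathway control matches the closed-form MCA solution", {
  # EXT -> S -> (sink): C^J_1 = e2/(e2 - e1), C^J_2 = -e1/(e2 - e1) where
  # e1, e2 are the unscaled elasticities of the two steps w.r.t. S
  net <- metabolic_network(
    list(metabolite("EXT", fixed = TRUE, concentration = 4),
         metabolite("S", concentration = 2)),
    list(reaction("R1", c(EXT = -1, S = 1), TRUE, keq = 3),
         reaction("R2", c(S = -1), FALSE)))
  st <- metabolic_state(c(EXT = 4, S = 2), c(R1 = 1, R2 = 1))
  model <- compile_model(net)
  cons <- find_conservation_relations(net)
  for (seed in 1:10) {
    ps <- sample_parameter_set(model, st, sampling_config(1, 1, seed))
    el <- compute_elasticities(model, st, ps$values)
    e1 <- el$unscaled["R1", "S"]
    e2 <- el$unscaled["R2", "S"]
    cc <- control_coefficients(cons, el$unscaled, st, net)
    expect_equal(cc$cj["R1", "R1"], e2 / (e2 - e1), tolerance = 1e-10)
    expect_equal(cc$cj["R1", "R2"], -e1 / (e2 - e1), tolerance = 1e-10)
    expect_equal(sum(cc$cj["R1", ]), 1, tolerance = 1e-10)
  }
})

test_that("summation theorems hold per sampled instance on the fixture", {
  b <- lactis()
  ens <- sample_control_ensemble(b$network, b$state,
                                 sampling_config(1, 60, seed = 4))
  expect_gt(length(ens$cj), 20)
  for (i in seq_along(ens$cj)) {
    expect_lt(max(abs(rowSums(ens$cj[[i]]) - 1)), 1e-8)
    expect_lt(max(abs(rowSums(ens$cs[[i]]))), 1e-8)
  }
})

test_that("control coefficients match a steady-state perturbation oracle", {
  co <- toy_cofactor()
  model <- compile_model(co$network)
  cons <- find_conservation_relations(co$network)
  ps <- sample_parameter_set(model, co$state, sampling_config(0.5, 1, 11))
  el <- compute_elasticities(model, co$state, ps$values)
  jr <- assemble_jacobian(cons, el$unscaled)
  expect_true(jr$stable)
  cc <- control_coefficients(cons, el$unscaled, co$state, co$network)
  # oracle: modulate one Vmax by 0.1%, re-relax to steady state by long
  # integration, and measure the relative flux changes
  c0 <- co$state$concentrations[model$met_ids]
  dyn <- which(!model$fixed)
  solver <- list(rtol = 1e-10, atol = 1e-12, maxsteps = 400000L)
  steady_flux <- function(par) {
    r <- lactokin:::integrate_segment(model, par, c0[dyn], c0, 0, 2000,
                                      numeric(0), solver, relax_ftol = 1e-11)
    expect_true(r$relaxed)
    ct <- c0; ct[dyn] <- r$y
    lactokin:::model_rates(model, ct, par)
  }
  for (enz in c("R1", "R2", "R4")) {
    slot <- paste0("vmax|", enz)
    eps <- 1e-3
    up <- ps$values; up[slot] <- up[slot] * (1 + eps)
    dn <- ps$values; dn[slot] <- dn[slot] * (1 - eps)
    Jup <- steady_flux(up); Jdn <- steady_flux(dn)
    cj_num <- (Jup - Jdn) / (2 * eps) / co$state$fluxes[model$rxn_ids]
    expect_equal(unname(cj_num), unname(cc$cj[, enz]), tolerance = 1e-3)
  }
})

test_that("scaled control coefficients are invariant under common flux rescaling", {
  co <- toy_cofactor()
  model <- compile_model(co$network)
  cons <- find_conservation_relations(co$network)
  cfg <- sampling_config(1, 1, 8)
  set.seed(8)
  km <- sample_michaelis_constants(co$state, cfg, model)
  par <- setNames(numeric(nrow(model$pspec)), model$pspec$name)
  par[names(km)] <- km
  cc_of <- function(state) {
    rs <- rescale_vmax(model, state, par)
    el <- compute_elasticities(model, state, rs$par)
    control_coefficients(cons, el$unscaled, state, co$network)$cj
  }
  st2 <- metabolic_state(co$state$concentrations, co$state$fluxes * 7.3)
  expect_equal(cc_of(co$state), cc_of(st2), tolerance = 1e-9)
})

test_that("stability filter counts and errors behave", {
  expect_error(stability_filter(logical(0)), "no instances")
  sf <- stability_filter(c(TRUE, TRUE, FALSE, NA))
  expect_equal(sf$fraction, 2 / 3)
  expect_equal(sf$n_tested, 3)
})

test_that("ensemble profile: degenerate ensemble gives zero widths", {
  b <- lactis()
  ens <- sample_control_ensemble(b$network, b$state,
                                 sampling_config(1, 10, seed = 2))
  one <- ens
  one$cj <- rep(ens$cj[1], 30)  # identical matrices
  prof <- ensemble_control_profile(one, min_instances = 1)
  expect_true(all(prof$sd == 0))
  expect_true(all(prof$frac_positive %in% c(0, 1)))
  expect_equal(prof$median, ens$cj[[1]])
  empty <- ens; empty$cj <- list()
  expect_error(ensemble_control_profile(empty), "empty")
})

test_that("width-vs-disequilibrium flags degenerate single-instance input", {
  b <- lactis()
  th <- check_thermodynamic_feasibility(b$network, b$state)
  ens <- sample_control_ensemble(b$network, b$state,
                                 sampling_config(1, 3, seed = 3))
  ens$cj <- ens$cj[1]
  wd <- width_vs_disequilibrium(ens, th)
  expect_true(wd$degenerate)
  expect_error(width_vs_disequilibrium(ens, th[1:2, ]), "3 reactions")
})

test_that("a constructed near-equilibrium step has minimal control width", {
  # 4-reaction chain with one near-equilibrium step
  net <- metabolic_network(
    list(metabolite("EXT", fixed = TRUE, concentration = 5),
         metabolite("A", concentration = 2),
         metabolite("B", concentration = 1.9),
         metabolite("C", concentration = 0.5)),
    list(reaction("R1", c(EXT = -1, A = 1), FALSE),
         reaction("R2", c(A = -1, B = 1), TRUE, keq = 0.96), # rho ~ 0.99
         reaction("R3", c(B = -1, C = 1), TRUE, keq = 50),   # far from eq
         reaction("R4", c(C = -1), FALSE)))
  st <- metabolic_state(c(EXT = 5, A = 2, B = 1.9, C = 0.5),
                        c(R1 = 1, R2 = 1, R3 = 1, R4 = 1))
  ens <- sample_control_ensemble(net, st, sampling_config(1, 150, seed = 12))
  th <- check_thermodynamic_feasibility(net, st)
  wd <- width_vs_disequilibrium(ens, th)
  widths <- setNames(wd$table$avg_sd, wd$table$reaction_id)
  expect_equal(names(which.min(widths)), "R2")
  expect_gt(wd$rank_correlation, 0)
})
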