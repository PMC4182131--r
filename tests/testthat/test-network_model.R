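test_that("validate_steady_state accepts balanced states and zero flux", {
  tc <- toy_chain()
  expect_true(validate_steady_state(tc$network, tc$state)$pass)
  zero <- metabolic_state(tc$state$concentrations,
                          setNames(rep(0, 3), names(tc$state$fluxes)))
  expect_true(validate_steady_state(tc$network, zero)$pass)
})

test_that("validate_steady_state localizes a perturbed flux", {
  tc <- toy_chain()
  bad <- tc$state
  bad$fluxes[["R"]] <- bad$fluxes[["R"]] + 1
  # oracle: direct matrix multiply
  N <- stoichiometry_matrix(tc$network, dynamic_only = TRUE)
  res_oracle <- drop(N %*% bad$fluxes[colnames(N)])
  vs <- validate_steady_state(tc$network, bad)
  expect_false(vs$pass)
  expect_equal(vs$residuals, res_oracle)
  expect_setequal(vs$offending, c("S", "P"))
})

test_that("validate_steady_state errors on structural problems", {
  tc <- toy_chain()
  short <- metabolic_state(tc$state$concentrations[-2], tc$state$fluxes)
  expect_error(validate_steady_state(tc$network, short), "missing metabolite")
  neg <- tc$state
  neg$concentrations[["S"]] <- -1
  expect_error(validate_steady_state(tc$network, neg), "negative")
})

test_that("conservation analysis: closed system, cofactor pair, factorization", {
  cl <- toy_closed()
  ca <- find_conservation_relations(cl$network)
  expect_length(ca$moiety_vectors, 1)
  expect_equal(unname(ca$moiety_vectors[[1]]), c(1, 1))

  co <- toy_cofactor()
  cc <- find_conservation_relations(co$network)
  # the cofactor cycle creates two relations: the pair itself and a pool
  # spanning the chain species the cycle is coupled to
  expect_length(cc$moiety_vectors, 2)
  # the cofactor-pair invariant Ca + Cb lies in the span of the basis
  B <- do.call(rbind, cc$moiety_vectors)
  target <- as.numeric(colnames(B) %in% c("Ca", "Cb"))
  resid <- target - drop(t(B) %*% qr.solve(t(B), target))
  expect_lt(max(abs(resid)), 1e-9)
  # factorization N = L N_R and left-null property
  N <- stoichiometry_matrix(co$network, dynamic_only = TRUE)
  expect_equal(cc$link_matrix %*% cc$reduced_stoichiometry, N,
               tolerance = 1e-12)
  for (m in cc$moiety_vectors)
    expect_lt(max(abs(m %*% N)), 1e-9)
})

test_that("conservation count matches an independent rank oracle on random networks", {
  for (seed in 1:5) {
    g <- generate_network_and_state(synthetic_spec(6, 8, n_moieties = 1,
                                                   seed = seed))
    N <- stoichiometry_matrix(g$network, dynamic_only = TRUE)
    rank_oracle <- qr(N)$rank
    ca <- find_conservation_relations(g$network)
    expect_equal(length(ca$moiety_vectors), nrow(N) - rank_oracle)
    expect_equal(ca$rank, rank_oracle)
  }
})

test_that("mass-action ratio and rho follow the displacement definition", {
  tc <- toy_chain(keq = 10)
  r <- tc$network$reactions[[2]]
  mar <- mass_action_ratio(r, tc$state) # S=2, P=1
  expect_equal(mar$gamma, 0.5)
  expect_equal(mar$rho, 0.05)
  # equilibrium limit rho = 1
  st_eq <- metabolic_state(c(EXT = 5, S = 1, P = 10), tc$state$fluxes)
  expect_equal(mass_action_ratio(r, st_eq)$rho, 1)
  # irreversible reaction: rho = 0 by definition
  expect_equal(mass_action_ratio(tc$network$reactions[[1]], tc$state)$rho, 0)
  # zero concentration is a domain error
  st_bad <- metabolic_state(c(EXT = 5, S = 0, P = 1), tc$state$fluxes)
  expect_error(mass_action_ratio(r, st_bad), "positive")
  # rho > 1 is reported, not truncated
  st_over <- metabolic_state(c(EXT = 5, S = 0.1, P = 100), tc$state$fluxes)
  over <- mass_action_ratio(r, st_over)
  expect_gt(over$rho, 1)
  expect_true(isTRUE(attr(over, "clipped")))
})

test_that("thermodynamic feasibility implements the sign test", {
  tc <- toy_chain(keq = 10) # gamma = 0.5 < keq, flux +1 -> feasible
  th <- check_thermodynamic_feasibility(tc$network, tc$state)
  expect_true(all(th$feasible))
  # gamma > keq with positive flux -> infeasible
  tc2 <- toy_chain(keq = 0.2)
  th2 <- check_thermodynamic_feasibility(tc2$network, tc2$state)
  expect_false(th2$feasible[th2$reaction_id == "R"])
  # reversed flux makes it feasible again
  st_rev <- metabolic_state(tc2$state$concentrations,
                            c(IN = 0, R = -1, OUT = 0))
  th3 <- check_thermodynamic_feasibility(tc2$network, st_rev)
  expect_true(all(th3$feasible))
})

test_that("keq from formation energies: inverse, multiplicativity, errors", {
  RT <- 8.314462618e-3 * 298.15
  r1 <- reaction("X1", c(A = -1, B = 1), TRUE, keq = 1)
  dg <- c(A = -10, B = -10, C = -4)
  expect_equal(keq_from_formation_energies(dg, r1), 1)       # dG0 = 0
  dg2 <- c(A = 0, B = -RT * log(10))
  expect_equal(keq_from_formation_energies(dg2, r1), 10)
  # additivity: keq(A->C) = keq(A->B) * keq(B->C)
  r2 <- reaction("X2", c(B = -1, C = 1), TRUE, keq = 1)
  r3 <- reaction("X3", c(A = -1, C = 1), TRUE, keq = 1)
  expect_equal(keq_from_formation_energies(dg, r3),
               keq_from_formation_energies(dg, r1) *
                 keq_from_formation_energies(dg, r2))
  expect_error(keq_from_formation_energies(dg[-3], r2), "C")
})

test_that("rho lies in [0,1] for every accepted state (fixture and synthetic)", {
  b <- lactis()
  th <- check_thermodynamic_feasibility(b$network, b$state)
  expect_true(all(th$feasible))
  expect_true(all(th$rho >= 0 & th$rho <= 1))
  for (seed in 1:3) {
    g <- generate_network_and_state(synthetic_spec(5, 7, seed = seed))
    tg <- check_thermodynamic_feasibility(g$network, g$state)
    expect_true(all(tg$feasible))
    expect_true(all(tg$rho >= 0 & tg$rho <= 1))
  }
})
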