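# Small fixture-free networks used across the suite.

# Reversible uni-uni reaction S <-> P with an external feed and drain, so a
# nonzero steady flux exists: EXT -> S -> P -> (sink).
toy_chain <- function(keq = 10, conc = c(EXT = 5, S = 2, P = 1),
                      flux = c(IN = 1, R = 1, OUT = 1)) {
  mets <- list(metabolite("EXT", fixed = TRUE, concentration = conc[["EXT"]]),
               metabolite("S", concentration = conc[["S"]]),
               metabolite("P", concentration = conc[["P"]]))
  rxns <- list(reaction("IN", c(EXT = -1, S = 1), FALSE),
               reaction("R", c(S = -1, P = 1), TRUE, keq),
               reaction("OUT", c(P = -1), FALSE))
  list(network = metabolic_network(mets, rxns, "toy_chain"),
       state = metabolic_state(conc, flux))
}

# Three-species linear pathway with a conserved cofactor pair, for
# conservation/Jacobian/control tests: EXT -> A -> B -> C -> out, where
# A -> B consumes Ca/produces Cb and C -> out regenerates Ca.
toy_cofactor <- function() {
  conc <- c(EXT = 10, A = 2, B = 1, C = 0.5, Ca = 1.5, Cb = 0.8)
  flux <- c(R1 = 1, R2 = 1, R3 = 1, R4 = 1)
  mets <- list(metabolite("EXT", fixed = TRUE, concentration = 10),
               metabolite("A", concentration = 2),
               metabolite("B", concentration = 1),
               metabolite("C", concentration = 0.5),
               metabolite("Ca", concentration = 1.5),
               metabolite("Cb", concentration = 0.8))
  rxns <- list(reaction("R1", c(EXT = -1, A = 1), FALSE),
               reaction("R2", c(A = -1, Ca = -1, B = 1, Cb = 1), TRUE,
                        keq = 4),
               reaction("R3", c(B = -1, C = 1), TRUE, keq = 8),
               reaction("R4", c(C = -1, Cb = -1, Ca = 1), FALSE))
  list(network = metabolic_network(mets, rxns, "toy_cofactor"),
       state = metabolic_state(conc, flux))
}

# closed two-species system A <-> B (no steady flux, one conservation)
toy_closed <- function() {
  mets <- list(metabolite("A", concentration = 1),
               metabolite("B", concentration = 2))
  rxns <- list(reaction("RAB", c(A = -1, B = 1), TRUE, keq = 2))
  list(network = metabolic_network(mets, rxns, "toy_closed"),
       state = metabolic_state(c(A = 1, B = 2), c(RAB = 0)))
}

# deterministic state-consistent parameter set at lambda = 0 (km = conc)
exact_params <- function(model, state) {
  cfg <- sampling_config(lambda = 0, n_samples = 1, seed = 1)
  sample_parameter_set(model, state, cfg)
}

# central finite-difference dv/dc oracle (relative step)
fd_dvdc <- function(model, conc, par, h = 1e-6) {
  E <- matrix(0, length(model$rxn_ids), length(model$met_ids),
              dimnames = list(model$rxn_ids, model$met_ids))
  for (j in seq_along(conc)) {
    dp <- max(abs(conc[j]), 1e-4) * h
    cp <- conc; cm <- conc
    cp[j] <- conc[j] + dp; cm[j] <- conc[j] - dp
    E[, j] <- (lactokin:::model_rates(model, cp, par) -
                 lactokin:::model_rates(model, cm, par)) / (2 * dp)
  }
  E
}

lactis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_lactis_model()
    cache
  }
})

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}
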