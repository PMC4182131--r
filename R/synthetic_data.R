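#' Specification of a random synthetic network
#'
#' Synthetic networks are connected chains with random branch reactions, an
#' input from a fixed external species and a terminal sink, plus optional
#' conserved cofactor pairs and random regulatory edges. They exist so every
#' pipeline stage is testable without the bundled fixture.
#'
#' @param n_metabolites dynamic species count (including 2 per moiety for
#'   cofactor pairs)
#' @param n_reactions total reactions
#' @param fraction_reversible fraction of eligible reactions made reversible
#' @param n_regulations random activator/inhibitor edges
#' @param n_moieties conserved cofactor pairs
#' @param conc_range log-uniform concentration range (mM)
#' @param flux_scale flux magnitude scale (mM/min)
#' @param seed integer seed
#' @export
synthetic_spec <- function(n_metabolites = 6, n_reactions = 8,
                           fraction_reversible = 0.5, n_regulations = 0,
                           n_moieties = 0, conc_range = c(0.1, 10),
                           flux_scale = 1, seed = 1) {
  if (n_moieties * 2 >= n_metabolites)
    stopf("need n_metabolites > 2 * n_moieties")
  if (n_reactions < n_metabolites - n_moieties + 1)
    stopf("need n_reactions >= n_metabolites - n_moieties + 1 for a nonzero steady flux through the backbone")
  structure(list(n_metabolites = n_metabolites, n_reactions = n_reactions,
                 fraction_reversible = fraction_reversible,
                 n_regulations = n_regulations, n_moieties = n_moieties,
                 conc_range = conc_range, flux_scale = flux_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random network with a mass-balanced, feasible state
#'
#' Builds a chain-with-branches stoichiometry, draws a strictly positive
#' steady flux from the null space by rejection sampling (retry cap 1000),
#' draws concentrations log-uniformly, and forces thermodynamic feasibility
#' by setting `Keq = Gamma * 10^u` with `u ~ U[0.3, 2]` decades for every
#' reversible reaction. The returned state always passes
#' [validate_steady_state()] and [check_thermodynamic_feasibility()].
#'
#' @param spec a [synthetic_spec()]
#' @return list(network, state)
#' @export
generate_network_and_state <- function(spec) {
  with_seed(spec$seed, {
    n_core <- spec$n_metabolites - 2 * spec$n_moieties
    core <- paste0("M", seq_len(n_core))
    ext_in <- "EXT"
    mets_ids <- c(core, ext_in)
    # backbone: EXT -> M1 -> ... -> Mn -> sink
    sto <- list()
    sto[["R_in"]] <- setNames(c(-1, 1), c(ext_in, core[1]))
    for (i in seq_len(n_core - 1))
      sto[[paste0("R", i)]] <- setNames(c(-1, 1), c(core[i], core[i + 1]))
    sto[["R_out"]] <- setNames(-1, core[n_core])
    # conserved cofactor pairs: each pair is consumed by the input reaction
    # and regenerated by a dedicated cycle reaction, so any positive
    # backbone flux admits a balanced cofactor turnover
    for (m in seq_len(spec$n_moieties)) {
      a <- paste0("C", m, "a"); b <- paste0("C", m, "b")
      mets_ids <- c(mets_ids, a, b)
      sto[["R_in"]] <- c(sto[["R_in"]], setNames(c(-1, 1), c(a, b)))
      sto[[paste0("RC", m)]] <- setNames(c(-1, 1), c(b, a))
    }
    # random branches Mi -> Mj until n_reactions reached
    k <- 0
    while (length(sto) < spec$n_reactions) {
      k <- k + 1
      ij <- sample(n_core, 2)
      sto[[paste0("B", k)]] <- setNames(c(-1, 1), core[ij])
    }
    rids <- names(sto)
    # positive flux by rejection sampling over the null space
    N <- matrix(0, length(mets_ids), length(rids),
                dimnames = list(mets_ids, rids))
    for (j in seq_along(rids)) N[names(sto[[j]]), j] <- sto[[j]]
    dynN <- N[setdiff(mets_ids, ext_in), , drop = FALSE]
    s <- svd(dynN, nv = ncol(dynN))
    rank <- sum(s$d > 1e-10 * max(s$d))
    if (rank >= ncol(dynN))
      stopf("network admits no nonzero steady flux; infeasible spec")
    nullsp <- s$v[, (rank + 1):ncol(dynN), drop = FALSE]
    J <- NULL
    for (try in seq_len(1000)) {
      z <- rnorm(ncol(nullsp))
      cand <- drop(nullsp %*% z)
      if (all(cand > 1e-6)) { J <- cand; break }
      if (all(-cand > 1e-6)) { J <- -cand; break }
    }
    if (is.null(J))
      stopf("no strictly positive steady flux found after 1000 tries; infeasible spec")
    J <- J / max(J) * spec$flux_scale
    conc <- 10 ^ runif(length(mets_ids), log10(spec$conc_range[1]),
                       log10(spec$conc_range[2]))
    names(conc) <- mets_ids
    # reversibility + forced-feasible Keq (only where products are species)
    mets <- lapply(mets_ids, function(id)
      metabolite(id, id, conc[[id]], fixed = id == ext_in,
                 provenance = "synthetic"))
    state0 <- metabolic_state(conc, setNames(J, rids))
    rxns <- lapply(seq_along(rids), function(j) {
      st <- sto[[j]]
      rev_ok <- any(st > 0)
      rev <- rev_ok && runif(1) < spec$fraction_reversible
      keq <- Inf
      if (rev) {
        gamma <- prod(conc[names(st)[st > 0]] ^ st[st > 0]) /
          prod(conc[names(st)[st < 0]] ^ (-st[st < 0]))
        keq <- gamma * 10 ^ runif(1, 0.3, 2)
      }
      reaction(rids[j], st, rev, keq, provenance = "synthetic")
    })
    # random regulations
    if (spec$n_regulations > 0) {
      for (g in seq_len(spec$n_regulations)) {
        j <- sample(length(rxns), 1)
        eff <- sample(core, 1)
        mode <- sample(c("inhibitor", "activator"), 1)
        rxns[[j]]$regulations <- c(rxns[[j]]$regulations,
                                   list(regulation(eff, mode, conc[[eff]],
                                                   provenance = "synthetic")))
      }
    }
    network <- metabolic_network(mets, rxns, name = sprintf("synthetic_%d", spec$seed))
    list(network = network, state = metabolic_state(conc, setNames(J, rids)))
  })
}

#' A pinned bistable toy model (and a monostable variant)
#'
#' A two-reaction positive-feedback switch: an input reaction `R1: S -> X`
#' autocatalytically activated by its product X (Hill coefficient 2) and a
#' removal reaction `R2: X -> (sink)`. With the pinned parameters the system
#' has a stable high-X state (the reference state of the returned bundle), a
#' stable zero state, and shows hysteresis under a quasi-static sweep of the
#' fixed substrate S. The monostable variant lacks the activation and has a
#' unique steady state.
#'
#' @param bistable build the bistable (TRUE) or monostable (FALSE) variant
#' @return list(network, state, par, model): a compiled model plus the
#'   pinned parameter vector
#' @export
make_bistable_toy <- function(bistable = TRUE) {
  mets <- list(metabolite("S", "substrate", 10, fixed = TRUE,
                          provenance = "synthetic"),
               metabolite("X", "autocatalytic product", 2,
                          provenance = "synthetic"))
  regs <- if (bistable)
    list(regulation("X", "activator", half_saturation = 1, hill = 2,
                    provenance = "synthetic")) else list()
  rxns <- list(reaction("R1", c(S = -1, X = 1), FALSE, regulations = regs,
                        provenance = "synthetic"),
               reaction("R2", c(X = -1), FALSE, provenance = "synthetic"))
  network <- metabolic_network(mets, rxns, name = "bistable_toy")
  state <- metabolic_state(c(S = 10, X = 2), c(R1 = 1, R2 = 1))
  model <- compile_model(network)
  par <- numeric(nrow(model$pspec))
  names(par) <- model$pspec$name
  par["km|R1|S"] <- 10
  par["km|R2|X"] <- 20
  if (bistable) par["reg|R1|X"] <- 1
  rs <- rescale_vmax(model, state, par)
  stopifnot(!rs$rejected)
  list(network = network, state = state, par = rs$par, model = model)
}
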