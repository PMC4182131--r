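#' Metabolic network and state containers
#'
#' A `metabolic_network` couples an ordered metabolite table with an ordered
#' reaction list (stoichiometry, reversibility, equilibrium constants and
#' allosteric regulations). A `metabolic_state` is the observed phenotype the
#' whole analysis conditions on: a steady-state flux vector (mM/min) and a
#' thermodynamically consistent concentration vector (mM) aligned to the
#' network ordering.
#'
#' @param id short metabolite identifier
#' @param name human-readable name
#' @param concentration reference concentration in mM (> 0 for dynamic species)
#' @param fixed logical; TRUE for clamped/external species
#' @param provenance free-text provenance note for fixture values
#' @return `metabolite()` returns a one-row metabolite record (list).
#' @export
metabolite <- function(id, name = id, concentration = NA_real_, fixed = FALSE,
                       provenance = NA_character_) {
  stopifnot(is.character(id), nchar(id) > 0)
  if (!fixed && (!is.finite(concentration) || concentration <= 0))
    stopf("dynamic metabolite '%s' needs a positive concentration", id)
  structure(list(id = id, name = name, concentration = concentration,
                 fixed = isTRUE(fixed), provenance = provenance),
            class = "lk_metabolite")
}

#' Allosteric regulation of a reaction by an effector
#'
#' Regulations enter the rate laws as multiplicative Hill-type factors:
#' inhibitors contribute \eqn{1/(1+(x/K)^h)} (always in (0,1]); activators
#' contribute \eqn{(x/K)^h/(1+(x/K)^h)} (in [0,1), rising to 1 at saturating
#' effector). An effector written as a ratio `"A/B"` (e.g. `"NADH/NAD"`) is
#' evaluated in the ratio variable.
#'
#' @param effector metabolite id, or `"A/B"` for a concentration ratio
#' @param mode `"activator"` or `"inhibitor"`
#' @param half_saturation reference half-saturation constant (mM, or
#'   dimensionless for a ratio effector); resampled around the state value
#'   during Monte-Carlo sampling
#' @param hill Hill coefficient (>= 1, default 1)
#' @param provenance provenance note
#' @export
regulation <- function(effector, mode = c("inhibitor", "activator"),
                       half_saturation = NA_real_, hill = 1,
                       provenance = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(hill >= 1)
  structure(list(effector = effector, mode = mode,
                 half_saturation = half_saturation, hill = hill,
                 provenance = provenance),
            class = "lk_regulation")
}

#' @param stoichiometry named numeric vector, negative for substrates
#' @param reversible logical
#' @param keq equilibrium constant (concentration units consistent with mM);
#'   `Inf` (or NA) for irreversible reactions
#' @param regulations list of [regulation()] records
#' @rdname metabolite
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE, keq = Inf,
                     regulations = list(), provenance = NA_character_) {
  stopifnot(is.character(id), is.numeric(stoichiometry),
            !is.null(names(stoichiometry)))
  if (!any(stoichiometry < 0))
    stopf("reaction '%s' must have at least one substrate", id)
  if (reversible && (!is.finite(keq) || keq <= 0))
    stopf("reversible reaction '%s' needs a finite positive keq", id)
  if (!reversible) keq <- Inf
  structure(list(id = id, stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible), keq = keq,
                 regulations = regulations, provenance = provenance),
            class = "lk_reaction")
}

#' @param metabolites list of [metabolite()] records (order defines the
#'   concentration vector)
#' @param reactions list of [reaction()] records (order defines the flux
#'   vector)
#' @rdname metabolite
#' @export
metabolic_network <- function(metabolites, reactions, name = "network") {
  ids <- vapply(metabolites, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("duplicate metabolite ids")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) stopf("duplicate reaction ids")
  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), ids)
    if (length(unknown))
      stopf("reaction '%s' references unknown metabolite(s): %s", r$id,
            paste(unknown, collapse = ", "))
    for (g in r$regulations) {
      eff <- strsplit(g$effector, "/", fixed = TRUE)[[1]]
      if (!all(eff %in% ids))
        stopf("regulation of '%s': unknown effector '%s'", r$id, g$effector)
    }
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 name = name),
            class = "metabolic_network")
}

#' @param concentrations named numeric vector (mM) covering every metabolite
#' @param fluxes named numeric vector (mM/min) covering every reaction
#' @rdname metabolite
#' @export
metabolic_state <- function(concentrations, fluxes) {
  structure(list(concentrations = concentrations, fluxes = fluxes),
            class = "metabolic_state")
}

#' @export
print.metabolic_network <- function(x, ...) {
  nfix <- sum(vapply(x$metabolites, `[[`, TRUE, "fixed"))
  nreg <- sum(lengths(lapply(x$reactions, `[[`, "regulations")))
  cat(sprintf("<metabolic_network '%s': %d metabolites (%d fixed), %d reactions, %d regulations>\n",
              x$name, length(x$metabolites), nfix, length(x$reactions), nreg))
  invisible(x)
}

#' @export
print.metabolic_state <- function(x, ...) {
  cat(sprintf("<metabolic_state: %d concentrations, %d fluxes, |J| in [%.3g, %.3g] mM/min>\n",
              length(x$concentrations), length(x$fluxes),
              min(abs(x$fluxes)), max(abs(x$fluxes))))
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

met_ids <- function(network) vapply(network$metabolites, `[[`, "", "id")
rxn_ids <- function(network) vapply(network$reactions, `[[`, "", "id")
met_fixed <- function(network) vapply(network$metabolites, `[[`, TRUE, "fixed")

#' Stoichiometric matrix of a network
#'
#' @param network a [metabolic_network()]
#' @param dynamic_only drop rows of fixed (clamped/external) species
#' @return numeric matrix, metabolites x reactions
#' @export
stoichiometry_matrix <- function(network, dynamic_only = FALSE) {
  ids <- met_ids(network)
  N <- matrix(0, length(ids), length(network$reactions),
              dimnames = list(ids, rxn_ids(network)))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoichiometry
    N[names(st), j] <- st
  }
  if (dynamic_only) N <- N[!met_fixed(network), , drop = FALSE]
  N
}

# align a state to network ordering, with structural error messages
align_state <- function(network, state) {
  ids <- met_ids(network); rids <- rxn_ids(network)
  if (!all(ids %in% names(state$concentrations)))
    stopf("state concentrations missing metabolite(s): %s",
          paste(setdiff(ids, names(state$concentrations)), collapse = ", "))
  if (!all(rids %in% names(state$fluxes)))
    stopf("state fluxes missing reaction(s): %s",
          paste(setdiff(rids, names(state$fluxes)), collapse = ", "))
  list(conc = state$concentrations[ids], flux = state$fluxes[rids])
}

# ---- operations ------------------------------------------------------------

#' Verify that a state satisfies the steady-state mass balance N J = 0
#'
#' @param network a [metabolic_network()]
#' @param state a [metabolic_state()]
#' @param tol relative tolerance; the check passes when
#'   `max |N J0| <= tol * max |J0|` over dynamic species
#' @return list with per-species residuals, the offending species and a
#'   `pass` flag
#' @export
validate_steady_state <- function(network, state, tol = 1e-9) {
  al <- align_state(network, state)
  dyn <- !met_fixed(network)
  if (any(!is.finite(al$conc[dyn])) || any(al$conc[dyn] <= 0))
    stopf("negative or non-finite dynamic concentration: %s",
          paste(names(al$conc[dyn])[!is.finite(al$conc[dyn]) | al$conc[dyn] <= 0],
                collapse = ", "))
  N <- stoichiometry_matrix(network, dynamic_only = TRUE)
  res <- drop(N %*% al$flux)
  thr <- tol * max(abs(al$flux), 1e-300)
  list(residuals = res, max_residual = max(abs(res)),
       offending = names(res)[abs(res) > thr],
       pass = max(abs(res)) <= thr)
}

#' Conservation relations, link matrix and reduced stoichiometry
#'
#' Finds the conserved moieties (left null space of the dynamic
#' stoichiometry), a set of independent species, the link matrix L and the
#' reduced stoichiometry N_R with `N_dyn = L N_R`. Moiety vectors are
#' presented with integer entries when a small-denominator rational
#' reconstruction exists.
#'
#' @param network a [metabolic_network()]
#' @param tol rank threshold relative to the largest singular value
#' @return object of class `conservation_analysis`
#' @export
find_conservation_relations <- function(network, tol = 1e-9) {
  N <- stoichiometry_matrix(network, dynamic_only = TRUE)
  if (nrow(N) < 1) stopf("network has no dynamic species")
  sv <- svd(N)$d
  rank <- sum(sv > tol * max(sv, 0) , na.rm = TRUE)
  # independent species via column-pivoted QR of t(N)
  qrt <- qr(t(N))
  ind <- sort(qrt$pivot[seq_len(rank)])
  dep <- setdiff(seq_len(nrow(N)), ind)
  N_R <- N[ind, , drop = FALSE]
  L <- t(qr.solve(t(N_R), t(N)))
  dimnames(L) <- list(rownames(N), rownames(N_R))
  # left null space via RREF of t(N) (exact structure for integer N)
  rr <- rref(t(N))
  free <- setdiff(seq_len(nrow(N)), rr$pivots)
  moi <- lapply(free, function(f) {
    v <- numeric(nrow(N))
    v[f] <- 1
    v[rr$pivots] <- -rr$R[seq_along(rr$pivots), f]
    v <- integerize(v)
    names(v) <- rownames(N)
    v
  })
  structure(list(link_matrix = L, reduced_stoichiometry = N_R,
                 moiety_vectors = moi,
                 independent_species = rownames(N)[ind],
                 dependent_species = rownames(N)[dep],
                 rank = rank),
            class = "conservation_analysis")
}

#' @export
print.conservation_analysis <- function(x, ...) {
  cat(sprintf("<conservation_analysis: rank %d, %d conserved moieties>\n",
              x$rank, length(x$moiety_vectors)))
  for (v in x$moiety_vectors) {
    nz <- v[v != 0]
    cat("  ", paste(sprintf("%+g %s", nz, names(nz)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Mass-action ratio and displacement from equilibrium
#'
#' \eqn{\Gamma} is the product-over-substrate concentration ratio raised to
#' stoichiometric powers; \eqn{\rho = \Gamma/K_{eq}} is zero for irreversible
#' reactions and approaches one at equilibrium. For forward-flux feasible
#' reactions \eqn{\rho \in [0, 1]}; values above 1 are reported (attribute
#' `clipped`), never silently truncated.
#'
#' @param reaction a [reaction()]
#' @param state a [metabolic_state()] providing concentrations
#' @return list with `gamma` and `rho`
#' @export
mass_action_ratio <- function(reaction, state) {
  st <- reaction$stoichiometry
  conc <- state$concentrations[names(st)]
  if (any(!is.finite(conc)) || any(conc <= 0))
    stopf("mass_action_ratio('%s'): all participating concentrations must be positive",
          reaction$id)
  gamma <- prod(conc[st > 0] ^ st[st > 0]) / prod(conc[st < 0] ^ (-st[st < 0]))
  if (!reaction$reversible || !is.finite(reaction$keq))
    return(list(gamma = gamma, rho = 0))
  rho <- gamma / reaction$keq
  out <- list(gamma = gamma, rho = rho)
  if (rho > 1) attr(out, "clipped") <- TRUE
  out
}

#' Thermodynamic feasibility of a metabolic state
#'
#' A flux-carrying reversible reaction is feasible when its Gibbs free energy
#' is negative in the flux direction, i.e. `flux > 0 & gamma < keq` or
#' `flux < 0 & gamma > keq`; zero-flux reactions are feasible, irreversible
#' reactions must not carry negative flux.
#'
#' @inheritParams validate_steady_state
#' @return data.frame (class `thermo_report`) with columns
#'   `reaction_id, gamma, rho, feasible`
#' @export
check_thermodynamic_feasibility <- function(network, state) {
  al <- align_state(network, state)
  st2 <- metabolic_state(al$conc, al$flux)
  rows <- lapply(seq_along(network$reactions), function(j) {
    r <- network$reactions[[j]]
    flux <- al$flux[[j]]
    if (r$reversible && !is.finite(r$keq) && flux != 0)
      stopf("flux-carrying reversible reaction '%s' has no keq", r$id)
    mar <- mass_action_ratio(r, st2)
    feasible <- if (flux == 0) TRUE
      else if (!r$reversible) flux > 0
      else if (flux > 0) mar$gamma < r$keq
      else mar$gamma > r$keq
    data.frame(reaction_id = r$id, gamma = mar$gamma, rho = mar$rho,
               feasible = feasible, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("thermo_report", "data.frame")
  out
}

#' Equilibrium constant from Gibbs formation energies
#'
#' `Keq = exp(-dG0/RT)` with `dG0 = sum(coeff * dGf)` over the reaction
#' stoichiometry. Multiplicative under reaction addition.
#'
#' @param formation_energies named vector of formation energies (kJ/mol)
#' @param reaction a [reaction()]
#' @param RT gas constant times temperature (kJ/mol), default 298.15 K
#' @export
keq_from_formation_energies <- function(formation_energies, reaction,
                                        RT = 8.314462618e-3 * 298.15) {
  st <- reaction$stoichiometry
  missing <- setdiff(names(st), names(formation_energies))
  if (length(missing))
    stopf("missing formation energy for metabolite(s): %s",
          paste(missing, collapse = ", "))
  dG0 <- sum(st * formation_energies[names(st)])
  exp(-dG0 / RT)
}

#' Write a thermodynamic report as TSV
#' @param report a `thermo_report`
#' @param path output file
#' @export
write_thermo_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
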