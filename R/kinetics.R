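#' Monte-Carlo sampling configuration
#'
#' @param lambda sampling spread in orders of magnitude around each reference
#'   concentration (default 1: one order of magnitude above and below)
#' @param n_samples ensemble size
#' @param seed master seed; every substream is derived from it
#' @param include_regulation TRUE (all), FALSE (none), or a character vector
#'   of regulation ids `"reaction|effector"` to keep
#' @return a `sampling_config`
#' @export
sampling_config <- function(lambda = 1, n_samples = 10000L, seed = 1L,
                            include_regulation = TRUE) {
  if (lambda < 0) stopf("sampling spread lambda must be >= 0")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  structure(list(lambda = lambda, n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 include_regulation = include_regulation),
            class = "sampling_config")
}

regulation_ids <- function(network) {
  unlist(lapply(network$reactions, function(r)
    vapply(r$regulations, function(g) paste(r$id, g$effector, sep = "|"), "")))
}

#' Drop regulations from a network
#'
#' @param network a [metabolic_network()]
#' @param keep TRUE (keep all), FALSE/empty (drop all) or regulation ids
#'   `"reaction|effector"` to retain
#' @export
strip_regulations <- function(network, keep = FALSE) {
  if (isTRUE(keep)) return(network)
  keep <- if (isFALSE(keep)) character(0) else keep
  known <- regulation_ids(network)
  bad <- setdiff(keep, known)
  if (length(bad)) stopf("unknown regulation id(s): %s", paste(bad, collapse = ", "))
  network$reactions <- lapply(network$reactions, function(r) {
    r$regulations <- Filter(function(g)
      paste(r$id, g$effector, sep = "|") %in% keep, r$regulations)
    r
  })
  network
}

# reference value for every sampled parameter slot: the state concentration
# of the associated compound (a ratio effector uses the state's ratio)
param_references <- function(model, state) {
  conc <- setNames(full_conc(model, state), model$met_ids)
  vapply(seq_len(nrow(model$pspec)), function(i) {
    p <- model$pspec[i, ]
    if (p$kind == "vmax") return(NA_real_)
    eff <- parse_effector(p$target)
    if (eff$ratio) conc[[eff$num]] / conc[[eff$den]] else conc[[eff$num]]
  }, 0)
}

#' Sample Michaelis and regulation constants around the metabolic state
#'
#' Each constant is drawn log-uniformly from
#' \eqn{[c/10^\lambda,\; c\,10^\lambda]} around the state concentration `c`
#' of its associated compound, i.e. `log10` of the draw is uniform on
#' `[log10 c - lambda, log10 c + lambda]`. Uses the current RNG stream.
#'
#' @param state a [metabolic_state()]
#' @param config a [sampling_config()]
#' @param model a compiled model ([compile_model()]); determines the slots
#' @return named vector of draws for every non-Vmax parameter slot
#' @export
sample_michaelis_constants <- function(state, config, model) {
  refs <- param_references(model, state)
  samp <- model$pspec$kind != "vmax"
  draws <- 10 ^ (log10(refs[samp]) + runif(sum(samp), -config$lambda, config$lambda))
  setNames(draws, model$pspec$name[samp])
}

#' Rescale maximal velocities so the state is an exact fixed point
#'
#' With all Michaelis/regulation constants fixed, the forward velocity of
#' every reaction is adjusted so that `rate(c0) = J0` exactly. An instance
#' whose reduced rate at `c0` has the wrong sign (thermodynamically blocked)
#' is a rejection: `rejected` is set and the offending reactions named.
#'
#' @param model compiled model
#' @param state the metabolic state
#' @param par parameter vector with Vmax slots unset (they are overwritten)
#' @return list(par, vmax, rejected, blocked)
#' @export
rescale_vmax <- function(model, state, par) {
  al <- align_state(model$network, state)
  c0 <- full_conc(model, state)
  vslots <- which(model$pspec$kind == "vmax")
  par[vslots] <- 1
  red <- model_rates(model, c0, par)
  J0 <- al$flux
  vmax <- ifelse(J0 == 0, 0, J0 / red)
  blocked <- model$rxn_ids[J0 != 0 & (!is.finite(vmax) | vmax <= 0)]
  par[vslots] <- ifelse(is.finite(vmax) & vmax > 0, vmax, 0)
  list(par = par, vmax = setNames(par[vslots], model$rxn_ids),
       rejected = length(blocked) > 0, blocked = blocked)
}

#' Draw one state-consistent parameter set
#'
#' Samples every Michaelis and regulation constant (log-uniform around the
#' associated state concentration), then rescales Vmax so the observed state
#' is an exact fixed point of the resulting kinetic model.
#'
#' @inheritParams sample_michaelis_constants
#' @return object of class `parameter_set`: named parameter vector `values`,
#'   `rejected` flag, and the seed provenance
#' @export
sample_parameter_set <- function(model, state, config) {
  par <- numeric(nrow(model$pspec))
  samp <- model$pspec$kind != "vmax"
  par[samp] <- sample_michaelis_constants(state, config, model)
  rs <- rescale_vmax(model, state, par)
  structure(list(values = setNames(rs$par, model$pspec$name),
                 rejected = rs$rejected, blocked = rs$blocked,
                 seed = config$seed),
            class = "parameter_set")
}

#' Single-reaction rate law (reference implementation)
#'
#' Builds the regulated reversible Michaelis-Menten rate law as an R closure:
#' the convenience-kinetics core
#' \deqn{v = V_{max}\, f(x)\, \frac{\prod_s (s/K_s)^{a_s}\,(1 - \Gamma/K_{eq})}
#'       {\prod_s (1+s/K_s)^{a_s} + \prod_p (1+p/K_p)^{b_p} - 1}}
#' times Hill-type regulation multipliers. For a uni-uni reaction this is
#' exactly `Vmax (S/KS)(1 - Gamma/Keq) / (1 + S/KS + P/KP)`. Slower than the
#' compiled path but independent of it; the two are cross-checked in the
#' test-suite.
#'
#' @param reaction a [reaction()]
#' @param params list with `km` (named by species), `vmax`, and optionally
#'   `reg` (named by effector string) half-saturations
#' @return function(conc) -> rate, where `conc` is a named concentration
#'   vector covering substrates, products and effectors
#' @export
build_rate_law <- function(reaction, params) {
  st <- reaction$stoichiometry
  subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
  need <- c(subs, if (reaction$reversible) prods)
  missing <- setdiff(need, names(params$km))
  if (length(missing))
    stopf("rate law '%s': missing km for %s", reaction$id,
          paste(missing, collapse = ", "))
  if (is.null(params$vmax)) stopf("rate law '%s': missing vmax", reaction$id)
  for (g in reaction$regulations)
    if (is.null(params$reg[[g$effector]]))
      stopf("rate law '%s': missing regulation constant for %s", reaction$id,
            g$effector)
  force(reaction); force(params)
  function(conc) {
    a <- -st[subs]; b <- st[prods]
    s <- conc[subs]; km_s <- params$km[subs]
    A <- prod((s / km_s) ^ a)
    PS <- prod((1 + s / km_s) ^ a)
    if (reaction$reversible) {
      p <- conc[prods]; km_p <- params$km[prods]
      B <- prod((p / km_p) ^ b)
      PP <- prod((1 + p / km_p) ^ b)
      q <- reaction$keq * prod(km_s ^ a) / prod(km_p ^ b)
      core <- (A - B / q) / (PS + PP - 1)
    } else {
      core <- A / PS
    }
    f <- 1
    for (g in reaction$regulations) {
      eff <- parse_effector(g$effector)
      x <- if (eff$ratio) conc[[eff$num]] / conc[[eff$den]] else conc[[eff$num]]
      r <- (x / params$reg[[g$effector]]) ^ g$hill
      f <- f * if (g$mode == "activator") r / (1 + r) else 1 / (1 + r)
    }
    unname(params$vmax * f * core)
  }
}

#' Elasticity matrices at the metabolic state
#'
#' Unscaled elasticities are the partial derivatives \eqn{\partial v/\partial c}
#' of every rate with respect to every species (including regulation
#' effector columns); scaled elasticities are
#' \eqn{(c_j/v_i)\,\partial v_i/\partial c_j}. Reactions with zero rate are
#' reported unscaled only and flagged.
#'
#' @param model compiled model
#' @param state metabolic state (evaluation point)
#' @param par parameter vector (e.g. from [sample_parameter_set()])
#' @return list(unscaled, scaled, v0, zero_rate_reactions); matrices are
#'   reactions x species over all species columns
#' @export
compute_elasticities <- function(model, state, par) {
  c0 <- full_conc(model, state)
  E <- model_dvdc(model, c0, par)
  v0 <- model_rates(model, c0, par)
  zero <- model$rxn_ids[v0 == 0]
  scl <- E * outer(ifelse(v0 == 0, NA_real_, 1 / v0), c0)
  dimnames(scl) <- dimnames(E)
  list(unscaled = E, scaled = scl, v0 = v0, zero_rate_reactions = zero)
}
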