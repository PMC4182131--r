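# Bridge between the R-level network description and the compiled C++ model
# (rate evaluation, analytic elasticities, stiff integration).

parse_effector <- function(effector) {
  parts <- strsplit(effector, "/", fixed = TRUE)[[1]]
  if (length(parts) == 2) list(ratio = TRUE, num = parts[1], den = parts[2])
  else list(ratio = FALSE, num = parts[1], den = NA_character_)
}

#' Compile a network into a fast evaluation object
#'
#' Builds the C++ representation used for rate, elasticity and ODE
#' evaluation, plus the parameter layout (`pspec`): one Michaelis constant
#' per reactant (products only for reversible reactions), one half-saturation
#' constant per regulation, one Vmax per reaction.
#'
#' @param network a [metabolic_network()]
#' @return object of class `lk_model`
#' @export
compile_model <- function(network) {
  ids <- met_ids(network)
  fixed <- met_fixed(network)
  N_dyn <- stoichiometry_matrix(network, dynamic_only = TRUE)

  pspec <- list()
  rx <- list()
  idx <- 0L
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    st <- r$stoichiometry
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    km_sub <- integer(0)
    for (s in subs) {
      pspec[[length(pspec) + 1L]] <- list(name = paste("km", r$id, s, sep = "|"),
                                          kind = "km", reaction = r$id,
                                          target = s)
      km_sub <- c(km_sub, idx); idx <- idx + 1L
    }
    km_prod <- integer(0)
    if (r$reversible) {
      for (p in prods) {
        pspec[[length(pspec) + 1L]] <- list(name = paste("km", r$id, p, sep = "|"),
                                            kind = "km", reaction = r$id,
                                            target = p)
        km_prod <- c(km_prod, idx); idx <- idx + 1L
      }
    }
    regs <- lapply(r$regulations, function(g) {
      eff <- parse_effector(g$effector)
      pspec[[length(pspec) + 1L]] <<- list(name = paste("reg", r$id, g$effector, sep = "|"),
                                           kind = "reg", reaction = r$id,
                                           target = g$effector)
      pi <- idx; idx <<- idx + 1L
      list(mode = if (eff$ratio) 2L else if (g$mode == "activator") 1L else 0L,
           eff1 = match(eff$num, ids) - 1L,
           eff2 = if (eff$ratio) match(eff$den, ids) - 1L else -1L,
           hill = g$hill, par_idx = pi)
    })
    pspec[[length(pspec) + 1L]] <- list(name = paste("vmax", r$id, sep = "|"),
                                        kind = "vmax", reaction = r$id,
                                        target = NA_character_)
    vmax_idx <- idx; idx <- idx + 1L
    rx[[j]] <- list(sub_idx = as.integer(match(subs, ids) - 1L),
                    sub_st = as.numeric(-st[subs]),
                    prod_idx = as.integer(match(prods, ids) - 1L),
                    prod_st = as.numeric(st[prods]),
                    reversible = r$reversible,
                    keq = if (is.finite(r$keq)) r$keq else 0,
                    km_sub_idx = as.integer(km_sub),
                    km_prod_idx = as.integer(km_prod),
                    vmax_idx = as.integer(vmax_idx),
                    regs = regs)
  }
  pspec <- do.call(rbind, lapply(pspec, function(p)
    data.frame(name = p$name, kind = p$kind, reaction = p$reaction,
               target = p$target, stringsAsFactors = FALSE)))
  spec <- list(n_met = length(ids), n_rxn = length(network$reactions),
               n_par = idx, dyn_idx = as.integer(which(!fixed) - 1L),
               N_dyn = N_dyn, reactions = rx)
  structure(list(network = network, ptr = .model_build(spec), pspec = pspec,
                 met_ids = ids, rxn_ids = rxn_ids(network), fixed = fixed),
            class = "lk_model")
}

#' @export
print.lk_model <- function(x, ...) {
  cat(sprintf("<lk_model: %d reactions, %d species (%d dynamic), %d parameters>\n",
              length(x$rxn_ids), length(x$met_ids), sum(!x$fixed),
              nrow(x$pspec)))
  invisible(x)
}

# full concentration vector in network order from a state
full_conc <- function(model, state) {
  conc <- state$concentrations[model$met_ids]
  if (any(is.na(conc))) stopf("state does not cover all metabolites")
  unname(conc)
}

# Evaluate all reaction rates at a concentration vector.
model_rates <- function(model, conc, par) {
  v <- .model_rates(model$ptr, as.numeric(conc), as.numeric(par))
  setNames(drop(v), model$rxn_ids)
}

# Unscaled derivative matrix dv/dc over all species (reactions x species).
model_dvdc <- function(model, conc, par) {
  E <- .model_elasticities(model$ptr, as.numeric(conc), as.numeric(par))
  dimnames(E) <- list(model$rxn_ids, model$met_ids)
  E
}
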