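#' Read and write the JSON model format
#'
#' The on-disk schema couples network and state:
#' `{metabolites: [{id, name, concentration_mM, fixed}], reactions: [{id,
#' stoichiometry: {id: coeff}, reversible, keq, flux_mM_per_min,
#' regulations: [{effector, mode, half_saturation_mM, hill_coefficient}]}]}`.
#' `keq` is `null` for irreversible reactions. Validation is strict: unknown
#' keys are rejected. An optional `provenance` string is allowed on every
#' record, and `name`/`schema` at the top level.
#'
#' @param path JSON file
#' @return `read_model_json()`: list with elements `network` and `state`
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(doc, c("metabolites", "reactions"), c("name", "schema"), "top level")
  mets <- lapply(doc$metabolites, function(m) {
    check_keys(m, c("id", "concentration_mM", "fixed"),
               c("name", "provenance"), "metabolite")
    metabolite(m$id, m$name %||% m$id, as.numeric(m$concentration_mM),
               isTRUE(m$fixed), m$provenance %||% NA_character_)
  })
  rxns <- lapply(doc$reactions, function(r) {
    check_keys(r, c("id", "stoichiometry", "reversible", "flux_mM_per_min"),
               c("keq", "regulations", "provenance"), "reaction")
    st <- unlist(r$stoichiometry)
    regs <- lapply(r$regulations %||% list(), function(g) {
      check_keys(g, c("effector", "mode"),
                 c("half_saturation_mM", "hill_coefficient", "provenance"),
                 "regulation")
      regulation(g$effector, g$mode,
                 as.numeric(g$half_saturation_mM %||% NA_real_),
                 as.numeric(g$hill_coefficient %||% 1),
                 g$provenance %||% NA_character_)
    })
    keq <- if (isTRUE(r$reversible)) as.numeric(r$keq) else Inf
    reaction(r$id, st, isTRUE(r$reversible), keq, regs,
             r$provenance %||% NA_character_)
  })
  network <- metabolic_network(mets, rxns, doc$name %||% "model")
  conc <- setNames(vapply(mets, `[[`, 0, "concentration"),
                   vapply(mets, `[[`, "", "id"))
  flux <- setNames(vapply(doc$reactions, function(r) as.numeric(r$flux_mM_per_min), 0),
                   vapply(rxns, `[[`, "", "id"))
  list(network = network, state = metabolic_state(conc, flux))
}

check_keys <- function(x, required, optional, what) {
  ks <- names(x)
  miss <- setdiff(required, ks)
  if (length(miss))
    stopf("model JSON %s: missing required key(s) %s", what,
          paste(miss, collapse = ", "))
  unknown <- setdiff(ks, c(required, optional))
  if (length(unknown))
    stopf("model JSON %s: unknown key(s) %s rejected", what,
          paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' @param network a [metabolic_network()]
#' @param state a [metabolic_state()]
#' @rdname read_model_json
#' @export
write_model_json <- function(network, state, path) {
  al <- align_state(network, state)
  mets <- lapply(network$metabolites, function(m) {
    out <- list(id = m$id, name = m$name,
                concentration_mM = al$conc[[m$id]], fixed = m$fixed)
    if (!is.na(m$provenance)) out$provenance <- m$provenance
    out
  })
  rxns <- lapply(network$reactions, function(r) {
    out <- list(id = r$id, stoichiometry = as.list(r$stoichiometry),
                reversible = r$reversible,
                keq = if (r$reversible) r$keq else NULL,
                flux_mM_per_min = al$flux[[r$id]],
                regulations = lapply(r$regulations, function(g) {
                  gg <- list(effector = g$effector, mode = g$mode,
                             half_saturation_mM = g$half_saturation,
                             hill_coefficient = g$hill)
                  if (!is.na(g$provenance)) gg$provenance <- g$provenance
                  gg
                }))
    if (!r$reversible) out$keq <- NULL
    if (!is.na(r$provenance)) out$provenance <- r$provenance
    out
  })
  doc <- list(schema = "lactokin-model/1", name = network$name,
              metabolites = mets, reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialize sampled parameter sets
#'
#' A single instance is written as one JSON document (name/value pairs plus
#' seed provenance); a list of instances as a columnar TSV
#' `(instance_id, reaction_id, parameter_name, value)`.
#'
#' @param ps a `parameter_set` from [sample_parameter_set()]
#' @param path output file
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "parameter_set"))
  jsonlite::write_json(list(seed = ps$seed, rejected = ps$rejected,
                            values = as.list(ps$values)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param ensemble list of `parameter_set` objects
#' @rdname write_parameter_set
#' @export
write_parameter_ensemble <- function(ensemble, path) {
  rows <- do.call(rbind, lapply(seq_along(ensemble), function(i) {
    v <- ensemble[[i]]$values
    parts <- strsplit(names(v), "|", fixed = TRUE)
    data.frame(instance_id = i,
               reaction_id = vapply(parts, `[`, "", 2),
               parameter_name = names(v),
               value = unname(v), stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as TSV
#'
#' Columns: time, one per dynamic species (mM), then one per reaction flux
#' (mM/min, prefixed `flux.`). Optional down-sampling via `every`.
#'
#' @param trajectory a `trajectory` from [integrate_timecourse()]
#' @param path output file
#' @param every keep every `every`-th time point
#' @export
write_trajectory <- function(trajectory, path, every = 1L) {
  keep <- seq(1, length(trajectory$time), by = every)
  df <- data.frame(time = trajectory$time[keep],
                   trajectory$concentrations[keep, , drop = FALSE],
                   setNames(as.data.frame(trajectory$fluxes[keep, , drop = FALSE]),
                            paste0("flux.", colnames(trajectory$fluxes))),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
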