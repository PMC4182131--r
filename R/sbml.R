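#' Export the network skeleton as SBML Level 3
#'
#' Writes species, compartments and reactions (reversibility and
#' stoichiometry, plus regulations as modifier references); no rate laws.
#' Requires the suggested package `xml2`.
#'
#' @param network a [metabolic_network()]
#' @param state a [metabolic_state()] for initial concentrations
#' @param path output .xml path
#' @export
export_sbml <- function(network, state, path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stopf("SBML export needs the 'xml2' package")
  al <- align_state(network, state)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = network$name)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cytosol", constant = "true",
                      spatialDimensions = "3", size = "1")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in network$metabolites)
    xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
                        compartment = "cytosol",
                        initialConcentration = format(al$conc[[m$id]]),
                        constant = tolower(as.character(m$fixed)),
                        boundaryCondition = tolower(as.character(m$fixed)),
                        hasOnlySubstanceUnits = "false")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in network$reactions) {
    rn <- xml2::xml_add_child(lr, "reaction", id = r$id,
                              reversible = tolower(as.character(r$reversible)))
    st <- r$stoichiometry
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in names(st)[st < 0])
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = format(-st[[s]]),
                            constant = "true")
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(st)[st > 0])
        xml2::xml_add_child(lpr, "speciesReference", species = s,
                            stoichiometry = format(st[[s]]),
                            constant = "true")
    }
    if (length(r$regulations)) {
      lm <- xml2::xml_add_child(rn, "listOfModifiers")
      for (g in r$regulations) {
        eff <- parse_effector(g$effector)
        for (sp in unique(c(eff$num, if (eff$ratio) eff$den)))
          xml2::xml_add_child(lm, "modifierSpeciesReference", species = sp)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Command: SBML export of a model file
#' @param model_path model JSON
#' @param out output SBML path
#' @export
cmd_export_sbml <- function(model_path, out) {
  b <- load_bundle(model_path)
  export_sbml(b$network, b$state, out)
}
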