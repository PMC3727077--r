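.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export the assembled network to SBML Level 3
#'
#' Writes compartments, species and reactions (with kon/koff or
#' first-order rates recorded as local parameters) of an assembled
#' model as an SBML Level 3 Version 2 core document.  Species
#' identifiers are the enumeration ids with dots replaced by
#' underscores.
#'
#' @param model a `vegf_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "vegf_model"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = .sbml_id(model$config$name))
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cn in names(model$config$network$compartments)) {
    vol <- model$config$geometry[[cn]]$volume
    if (is.null(vol)) vol <- model$config$growth$V0
    xml2::xml_add_child(comps, "compartment", id = cn,
                        size = format(vol), constant = "true",
                        spatialDimensions = "3")
  }
  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(
      spl, "species", id = .sbml_id(model$species$id[i]),
      compartment = model$species$compartment[i],
      initialConcentration = format(unname(model$y0[model$species$id[i]])),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    rev <- rx$kind[i] %in% c("binding", "coupling")
    rnode <- xml2::xml_add_child(rxl, "reaction", id = rx$id[i],
                                 name = paste(rx$kind[i], rx$class[i]),
                                 reversible = if (rev) "true" else "false")
    rea <- stats::na.omit(c(rx$r1[i], rx$r2[i]))
    pro <- stats::na.omit(rx$p1[i])
    if (length(rea)) {
      lr <- xml2::xml_add_child(rnode, "listOfReactants")
      for (s in rea)
        xml2::xml_add_child(lr, "speciesReference", species = .sbml_id(s),
                            stoichiometry = "1", constant = "true")
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rnode, "listOfProducts")
      for (s in pro)
        xml2::xml_add_child(lp, "speciesReference", species = .sbml_id(s),
                            stoichiometry = "1", constant = "true")
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    lpars <- xml2::xml_add_child(kl, "listOfLocalParameters")
    if (rev) {
      xml2::xml_add_child(lpars, "localParameter", id = "kon",
                          value = format(rx$kon[i]))
      xml2::xml_add_child(lpars, "localParameter", id = "koff",
                          value = format(rx$koff[i]))
    } else {
      xml2::xml_add_child(lpars, "localParameter", id = "rate",
                          value = format(rx$rate[i]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an SBML document and recover the structural manifest
#'
#' Reads species and reactions back from an exported document and
#' returns the per-compartment species counts and the reaction count,
#' for round-trip verification against [enumerate_species()].
#'
#' @param path SBML file path.
#' @return list with `counts` (named integer per compartment),
#'   `total`, `n_reactions`, and the species id vector.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  comp <- xml2::xml_attr(spn, "compartment")
  rxn <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  counts <- table(factor(comp, levels = unique(comp)))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       total = length(spn),
       n_reactions = length(rxn),
       species = xml2::xml_attr(spn, "id"))
}
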