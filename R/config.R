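# ---------------------------------------------------------------------------
# Declarative model-definition config: constructs (states, rates, factors)
# serialize to YAML and reconstruct through the ordinary construct API, so a
# round-trip re-validates every invariant.  Numbers are written with full
# precision so round-trips are exact.
# ---------------------------------------------------------------------------

num_chr <- function(x) {
  if (is.null(x) || !length(x)) return(NULL)
  v <- vapply(unname(x), function(e) formatC(e, digits = 17, format = "g"),
              "")
  if (!is.null(names(x))) stats::setNames(as.list(v), names(x)) else
    as.list(v)
}

#' Write constructs to a model-definition config file
#'
#' @param constructs list of `Construct`s.
#' @param file YAML path.
#' @export
write_model_config <- function(constructs, file) {
  ser_rate <- function(r) {
    out <- list(k = formatC(r$k, digits = 17, format = "g"),
                law_kind = r$law_kind)
    if (length(r$reactants)) out$reactants <- as.list(r$reactants)
    if (length(r$modifiers)) out$modifiers <- as.list(r$modifiers)
    if (length(r$sources)) out$sources <- num_chr(r$sources)
    if (length(r$sinks)) out$sinks <- num_chr(r$sinks)
    sat <- Filter(function(fc) fc$kind == "sat", r$factors)
    inh <- Filter(function(fc) fc$kind == "inhib", r$factors)
    if (length(sat))
      out$sat <- stats::setNames(
        lapply(sat, function(fc) formatC(fc$K, digits = 17, format = "g")),
        vapply(sat, `[[`, "", "ref"))
    if (length(inh))
      out$inhib <- stats::setNames(
        lapply(inh, function(fc) formatC(fc$K, digits = 17, format = "g")),
        vapply(inh, `[[`, "", "ref"))
    if (!is.null(r$group)) {
      out$group <- r$group
      out$weight_const <- formatC(r$weight_const, digits = 17, format = "g")
      if (length(r$weight_states))
        out$weight_states <- as.list(r$weight_states)
    }
    if (!isTRUE(r$scale_size)) out$scale_size <- FALSE
    out
  }
  doc <- list(constructs = lapply(constructs, function(con) {
    list(name = con$name, kind = con$kind,
         exception = con$exception,
         states = lapply(con$states, function(s)
           list(initial_amount = formatC(s$initial_amount, digits = 17,
                                         format = "g"),
                compartment = s$compartment,
                is_sink = s$is_sink, dimensionless = s$dimensionless,
                halve = s$halve)),
         rates = lapply(con$rates, ser_rate))
  }))
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' Read a model-definition config file
#'
#' Reconstructs every construct through [new_construct()], [add_state()]
#' and [add_rate()], so all definition invariants are re-validated; the
#' round-trip is lossless.
#'
#' @param file YAML path written by [write_model_config()].
#' @return list of `Construct`s.
#' @export
read_model_config <- function(file) {
  doc <- yaml::read_yaml(file)
  nv <- function(x) {
    if (is.null(x)) return(character())
    stats::setNames(vapply(x, function(e) as.numeric(e), 0), names(x))
  }
  lapply(doc$constructs, function(cd) {
    con <- new_construct(cd$name, cd$kind)
    if (!is.null(cd$exception)) con <- flag_exception(con, cd$exception)
    for (sn in names(cd$states)) {
      s <- cd$states[[sn]]
      con <- add_state(con, sn, as.numeric(s$initial_amount),
                       s$compartment, is_sink = isTRUE(s$is_sink),
                       dimensionless = isTRUE(s$dimensionless),
                       halve = isTRUE(s$halve))
    }
    for (rn in names(cd$rates)) {
      r <- cd$rates[[rn]]
      con <- add_rate(con, rn, as.numeric(r$k),
                      reactants = as.character(unlist(r$reactants)),
                      sources = nv(r$sources), sinks = nv(r$sinks),
                      modifiers = as.character(unlist(r$modifiers)),
                      law_kind = r$law_kind,
                      sat = if (!is.null(r$sat)) nv(r$sat),
                      inhib = if (!is.null(r$inhib)) nv(r$inhib),
                      group = r$group,
                      weight_const = as.numeric(r$weight_const %||% 0),
                      weight_states = as.character(unlist(r$weight_states)),
                      scale_size = !isFALSE(r$scale_size))
    }
    con
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a compiled model as SBML Level 3
#'
#' States become species (with compartments), rates become reactions with
#' their stoichiometries, modifiers and mass-action / saturating kinetic
#' laws in MathML.  Allocation members are exported with their weight
#' definitions in an annotation (their flux is a global resource share, not
#' a local law).
#'
#' @param model a `CompiledModel`.
#' @param file output path.
#' @export
export_sbml <- function(model, file) {
  stopifnot(inherits(model, "CompiledModel"))
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "mitosim_model")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$states$compartment))
    xml2::xml_add_child(comps, "compartment", id = sid(cp),
                        constant = "false", spatialDimensions = "3")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$states))) {
    s <- model$states[i, ]
    xml2::xml_add_child(sp, "species", id = sid(s$qname),
                        compartment = sid(s$compartment),
                        initialAmount = formatC(s$x0, digits = 17,
                                                format = "g"),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (rn in names(model$rates))
    xml2::xml_add_child(pars, "parameter", id = paste0("k_", sid(rn)),
                        value = formatC(model$rates[[rn]]$k, digits = 17,
                                        format = "g"),
                        constant = "true")
  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (rn in names(model$rates)) {
    r <- model$rates[[rn]]
    rx <- xml2::xml_add_child(rxns, "reaction", id = sid(rn),
                              reversible = "false")
    if (length(r$sources)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_along(r$sources))
        xml2::xml_add_child(lr, "speciesReference",
                            species = sid(names(r$sources)[j]),
                            stoichiometry = as.character(r$sources[[j]]),
                            constant = "true")
    }
    if (length(r$sinks)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_along(r$sinks))
        xml2::xml_add_child(lp, "speciesReference",
                            species = sid(names(r$sinks)[j]),
                            stoichiometry = as.character(r$sinks[[j]]),
                            constant = "true")
    }
    mods <- setdiff(vapply(r$factors, `[[`, "", "ref"), names(r$sources))
    if (length(mods)) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (mref in mods)
        xml2::xml_add_child(lm, "modifierSpeciesReference",
                            species = sid(mref))
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    if (identical(r$law_kind, "allocation")) {
      xml2::xml_add_child(math, "ci", paste0("k_", sid(rn)))
      xml2::xml_add_child(
        rx, "notes",
        paste("allocation member; weight =", r$weight_const, "+ sum(",
              paste(r$weight_states, collapse = ", "), ")"))
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "ci", paste0("k_", sid(rn)))
      for (fc in r$factors) {
        if (fc$kind == "linear")
          xml2::xml_add_child(ap, "ci", sid(fc$ref))
        else {
          dv <- xml2::xml_add_child(ap, "apply")
          xml2::xml_add_child(dv, "divide")
          if (fc$kind == "sat")
            xml2::xml_add_child(dv, "ci", sid(fc$ref))
          else
            xml2::xml_add_child(dv, "cn", as.character(fc$K))
          pl <- xml2::xml_add_child(dv, "apply")
          xml2::xml_add_child(pl, "plus")
          xml2::xml_add_child(pl, "cn", as.character(fc$K))
          xml2::xml_add_child(pl, "ci", sid(fc$ref))
        }
      }
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}
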