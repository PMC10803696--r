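SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
SBML_NS_PREFIX <- "http://www.sbml.org/sbml/"

# XPath for an SBML-core element, excluding annotation-namespace nodes
sbml_xp <- function(name, prefix = "//") {
  paste0(prefix, "*[local-name()='", name,
         "' and starts-with(namespace-uri(),'", SBML_NS_PREFIX, "')]")
}
PBRPK_NS <- "https://pbrpk.r-lib.invalid/annotations"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

num_attr <- function(x) {
  # stable shortest round-trip representation
  s <- sprintf("%.17g", x)
  s2 <- sprintf("%.15g", x)
  if (as.numeric(s2) == x) s <- s2
  s
}

#' Export a reaction graph to SBML Level 3 Version 2 (core)
#'
#' Compartments, species (amount-based, `hasOnlySubstanceUnits`), global
#' parameters and reactions with explicit kinetic-law math are written in
#' insertion order, so re-exporting an imported document is byte-stable.
#' Species kinds, organ labels, subspaces, rate-law forms and provenance
#' tags travel in a package annotation namespace; the kinetic math itself
#' is plain MathML and self-contained. When an [injection_schedule()] is
#' given, boluses are exported as SBML events adding to the venous free
#' ligand amounts.
#'
#' @inheritParams add_compartment
#' @param path Output file path.
#' @param schedule Optional [injection_schedule()] exported as events.
#' @return Invisibly, the path; the document is consistency-checked before
#'   writing (see [validate_sbml()]).
#' @export
export_sbml <- function(graph, path, schedule = NULL) {
  stop_if_invalid(graph)
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:pbrpk" = PBRPK_NS,
                            level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "pbrpk_model",
                               substanceUnits = "item",
                               timeUnits = "second",
                               volumeUnits = "litre",
                               extentUnits = "item")

  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (i in seq_len(nrow(graph$compartments))) {
    cpi <- graph$compartments[i, ]
    node <- xml2::xml_add_child(loc, "compartment", id = cpi$id,
                                spatialDimensions = "3",
                                size = num_attr(cpi$volume),
                                constant = "true")
    ann <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(ann, "pbrpk:compartment", "xmlns:pbrpk" = PBRPK_NS,
                        organ = cpi$organ, subspace = cpi$subspace)
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(graph$species))) {
    spi <- graph$species[i, ]
    node <- xml2::xml_add_child(
      los, "species", id = spi$id, compartment = spi$compartment,
      initialAmount = num_attr(spi$initial_amount),
      hasOnlySubstanceUnits = "true", boundaryCondition = "false",
      constant = "false")
    ann <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(ann, "pbrpk:species", "xmlns:pbrpk" = PBRPK_NS,
                        kind = spi$kind)
  }

  if (length(graph$parameters)) {
    lop <- xml2::xml_add_child(model, "listOfParameters")
    for (nm in names(graph$parameters)) {
      xml2::xml_add_child(lop, "parameter", id = nm,
                          value = num_attr(graph$parameters[[nm]]),
                          constant = "true")
    }
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  comp_of <- stats::setNames(graph$species$compartment, graph$species$id)
  for (j in seq_len(nrow(graph$reactions))) {
    rx <- graph$reactions[j, ]
    node <- xml2::xml_add_child(lor, "reaction", id = rx$id,
                                reversible = "false")
    ann <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(ann, "pbrpk:reaction", "xmlns:pbrpk" = PBRPK_NS,
                        form = rx$form, tag = rx$tag,
                        volumeRefs = paste(rx$volume_refs[[1]],
                                           collapse = " "))
    r <- rx$reactants[[1]]
    p <- rx$products[[1]]
    if (length(r)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (s in names(r)) {
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = num_attr(r[[s]]),
                            constant = "true")
      }
    }
    if (length(p)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (s in names(p)) {
        xml2::xml_add_child(lp, "speciesReference", species = s,
                            stoichiometry = num_attr(p[[s]]),
                            constant = "true")
      }
    }
    kl <- xml2::xml_add_child(node, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    emit_kinetic_math(math, rx, comp_of)
    lol <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lol, "localParameter", id = "k",
                        value = num_attr(rx$rate_constant))
  }

  if (!is.null(schedule)) {
    emit_injection_events(model, graph, schedule)
  }

  diags <- validate_sbml(doc)
  if (nrow(diags)) {
    abort(paste0("refusing to export inconsistent SBML:\n",
                 paste0("  - ", diags$message, collapse = "\n")),
          class = "pbrpk_error_validation")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# canonical kinetic-law MathML:
#   mass_action:  k * (S1/C1) [* (S2/C2)] * VR   (VR = reaction volume)
#   transport:    k * S1 / C1
emit_kinetic_math <- function(math, rx, comp_of) {
  r <- rx$reactants[[1]]
  ap <- xml2::xml_add_child(math, "apply")
  xml2::xml_add_child(ap, "times")
  ci <- function(parent, name) {
    node <- xml2::xml_add_child(parent, "ci")
    xml2::xml_set_text(node, paste0(" ", name, " "))
  }
  ratio <- function(parent, s) {
    div <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(div, "divide")
    ci(div, s)
    ci(div, comp_of[[s]])
  }
  ci(ap, "k")
  if (rx$form == "mass_action") {
    for (s in names(r)) {
      for (dup in seq_len(r[[s]])) ratio(ap, s)
    }
    ci(ap, rx$volume_refs[[1]][1])
  } else {
    ratio(ap, names(r)[1])
  }
}

emit_injection_events <- function(model, graph, schedule) {
  tg <- bolus_targets(graph)
  loe <- xml2::xml_add_child(model, "listOfEvents")
  for (b in seq_len(schedule$n)) {
    ev <- xml2::xml_add_child(loe, "event",
                              id = sprintf("bolus_%02d", b),
                              useValuesFromTriggerTime = "true")
    ann <- xml2::xml_add_child(ev, "annotation")
    xml2::xml_add_child(ann, "pbrpk:bolus", "xmlns:pbrpk" = PBRPK_NS,
                        time = num_attr(schedule$times[b]),
                        hot = num_attr(schedule$hot_per_bolus[b]),
                        cold = num_attr(schedule$cold_per_bolus[b]))
    tr <- xml2::xml_add_child(ev, "trigger", initialValue = "false",
                              persistent = "true")
    math <- xml2::xml_add_child(tr, "math", xmlns = MATHML_NS)
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "geq")
    tnode <- xml2::xml_add_child(ap, "csymbol", encoding = "text",
      definitionURL = "http://www.sbml.org/sbml/symbols/time")
    xml2::xml_set_text(tnode, " t ")
    cn <- xml2::xml_add_child(ap, "cn")
    xml2::xml_set_text(cn, paste0(" ", num_attr(schedule$times[b]), " "))
    loa <- xml2::xml_add_child(ev, "listOfEventAssignments")
    for (target in c(tg$hot, tg$cold)) {
      amount <- if (target == tg$hot) schedule$hot_per_bolus[b] else
        schedule$cold_per_bolus[b]
      ea <- xml2::xml_add_child(loa, "eventAssignment", variable = target)
      math <- xml2::xml_add_child(ea, "math", xmlns = MATHML_NS)
      ap2 <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap2, "plus")
      cin <- xml2::xml_add_child(ap2, "ci")
      xml2::xml_set_text(cin, paste0(" ", target, " "))
      cn2 <- xml2::xml_add_child(ap2, "cn")
      xml2::xml_set_text(cn2, paste0(" ", num_attr(amount), " "))
    }
  }
}

#' Consistency-check an SBML document
#'
#' Structural checks applied both before writing and after reading:
#' unique compartment/species/reaction/parameter ids; every species placed
#' in a declared compartment; every species reference resolving; kinetic
#' math present and parseable; and absence of constructs outside the
#' supported core subset (rules, constraints, function definitions,
#' delays).
#'
#' @param doc An `xml_document`, or a path to an SBML file.
#' @return Tibble of diagnostics (empty when consistent).
#' @export
validate_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  msgs <- character(0)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    msgs <- c(msgs, "root element is not <sbml>")
  }
  comp_ids <- xml2::xml_attr(
    xml2::xml_find_all(doc, sbml_xp("compartment")), "id")
  sp_nodes <- xml2::xml_find_all(doc, sbml_xp("species"))
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  rx_nodes <- xml2::xml_find_all(doc, sbml_xp("reaction"))
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  for (lbl in list(list("compartment", comp_ids), list("species", sp_ids),
                   list("reaction", rx_ids))) {
    dups <- unique(lbl[[2]][duplicated(lbl[[2]])])
    if (length(dups)) {
      msgs <- c(msgs, paste0("duplicate ", lbl[[1]], " ids: ",
                             paste(dups, collapse = ", ")))
    }
  }
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  bad <- sp_ids[!sp_comp %in% comp_ids]
  if (length(bad)) {
    msgs <- c(msgs, paste0("species in undeclared compartments: ",
                           paste(bad, collapse = ", ")))
  }
  refs <- xml2::xml_attr(
    xml2::xml_find_all(doc, sbml_xp("speciesReference")), "species")
  bad <- setdiff(refs, sp_ids)
  if (length(bad)) {
    msgs <- c(msgs, paste0("unresolved species references: ",
                           paste(bad, collapse = ", ")))
  }
  for (construct in c("listOfRules", "algebraicRule", "assignmentRule",
                      "rateRule", "listOfConstraints",
                      "listOfFunctionDefinitions", "delay")) {
    if (length(xml2::xml_find_all(
      doc, sbml_xp(construct)))) {
      msgs <- c(msgs, paste0("unsupported construct: ", construct))
    }
  }
  no_math <- rx_ids[vapply(rx_nodes, function(n) {
    length(xml2::xml_find_all(
      n, paste0(sbml_xp("kineticLaw", ".//"), "//*[local-name()='math']"))) == 0L
  }, logical(1))]
  if (length(no_math)) {
    msgs <- c(msgs, paste0("reactions without kinetic math: ",
                           paste(no_math, collapse = ", ")))
  }
  if (length(msgs)) tibble(message = msgs) else tibble(message = character())
}

# ---- import ---------------------------------------------------------------

math_factors <- function(node) {
  # flatten a MathML product into multiplicative factors
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) {
      abort("unsupported construct: non-singular math element",
            class = "pbrpk_error_unsupported")
    }
    return(math_factors(kids[[1]]))
  }
  if (name == "ci" || name == "cn") {
    return(list(node))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    if (op == "times") {
      return(purrr::flatten(purrr::map(args, math_factors)))
    }
    if (op == "divide") {
      num <- math_factors(args[[1]])
      den <- args[[2]]
      if (xml2::xml_name(den) != "ci") {
        abort("unsupported construct: non-symbol divisor in kinetic math",
              class = "pbrpk_error_unsupported")
      }
      return(c(num, list(structure(list(den), divisor = TRUE))))
    }
    abort(paste0("unsupported construct: MathML operator <", op, ">"),
          class = "pbrpk_error_unsupported")
  }
  abort(paste0("unsupported construct: MathML element <", name, ">"),
        class = "pbrpk_error_unsupported")
}

#' Import an SBML file as a reaction graph
#'
#' Accepts SBML Level 3 core documents whose kinetic laws are products of
#' a rate constant, species/compartment-size ratios and an optional
#' reaction-volume factor (the mass-action and transport subset this
#' package emits). Package annotations, when present, restore organ
#' labels, subspaces, species kinds and rate-law forms; foreign documents
#' without annotations are imported with neutral metadata (organ =
#' compartment id, inferred rate-law form). Documents containing rules,
#' constraints, function definitions or delays are rejected with an
#' explicit unsupported-construct error.
#'
#' @param path SBML file path.
#' @return A `reaction_graph`; if the document carries injection events
#'   exported by this package, the reconstructed [injection_schedule()] is
#'   attached as attribute `"schedule"`.
#' @export
import_sbml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "pbrpk_error_reference")
  }
  doc <- xml2::read_xml(path)
  diags <- validate_sbml(doc)
  if (nrow(diags)) {
    unsupported <- grepl("unsupported", diags$message)
    abort(paste0("SBML consistency check failed:\n",
                 paste0("  - ", diags$message, collapse = "\n")),
          class = if (any(unsupported)) "pbrpk_error_unsupported" else
            "pbrpk_error_validation")
  }

  params <- xml2::xml_find_all(
    doc, paste0(sbml_xp("listOfParameters"), "/", substring(sbml_xp("parameter"), 3)))
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  if (!length(pvals)) pvals <- c(lambda_phys = 0)
  g <- reaction_graph(parameters = pvals)

  for (node in xml2::xml_find_all(doc, sbml_xp("compartment"))) {
    ann <- xml2::xml_find_first(
      node, ".//*[local-name()='compartment' and namespace-uri()='" %+%
        PBRPK_NS %+% "']")
    id <- xml2::xml_attr(node, "id")
    organ <- if (!inherits(ann, "xml_missing")) xml2::xml_attr(ann, "organ")
      else id
    subspace <- if (!inherits(ann, "xml_missing"))
      xml2::xml_attr(ann, "subspace") else "interstitial"
    g <- add_compartment(g, id, organ = organ, subspace = subspace,
                         volume = as.numeric(xml2::xml_attr(node, "size")))
  }
  for (node in xml2::xml_find_all(doc, sbml_xp("species"))) {
    ann <- xml2::xml_find_first(
      node, ".//*[local-name()='species' and namespace-uri()='" %+%
        PBRPK_NS %+% "']")
    kind <- if (!inherits(ann, "xml_missing")) xml2::xml_attr(ann, "kind")
      else "cold_ligand"
    amt <- xml2::xml_attr(node, "initialAmount")
    g <- add_species(g, xml2::xml_attr(node, "id"),
                     compartment = xml2::xml_attr(node, "compartment"),
                     kind = kind,
                     initial_amount = if (is.na(amt)) 0 else as.numeric(amt))
  }

  comp_vol <- stats::setNames(g$compartments$volume, g$compartments$id)
  comp_of <- stats::setNames(g$species$compartment, g$species$id)
  for (node in xml2::xml_find_all(doc, sbml_xp("reaction"))) {
    g <- import_reaction(g, node, comp_vol, comp_of)
  }

  sched <- import_schedule(doc)
  if (!is.null(sched)) attr(g, "schedule") <- sched
  stop_if_invalid(g)
  g
}

`%+%` <- function(a, b) paste0(a, b)

import_reaction <- function(g, node, comp_vol, comp_of) {
  id <- xml2::xml_attr(node, "id")
  get_refs <- function(which) {
    refs <- xml2::xml_find_all(
      node, paste0(sbml_xp(which, ".//"), "/",
                   substring(sbml_xp("speciesReference"), 3)))
    if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
    st <- xml2::xml_attr(refs, "stoichiometry")
    st[is.na(st)] <- "1"
    stats::setNames(as.numeric(st), xml2::xml_attr(refs, "species"))
  }
  reactants <- get_refs("listOfReactants")
  products <- get_refs("listOfProducts")

  lp <- xml2::xml_find_all(node, sbml_xp("localParameter", ".//"))
  lpv <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                         xml2::xml_attr(lp, "id"))

  math <- xml2::xml_find_first(
    node, paste0(sbml_xp("kineticLaw", ".//"), "/*[local-name()='math']"))
  factors <- math_factors(math)

  k <- 1
  num_species <- character(0)
  denominators <- character(0)
  extra_comps <- character(0)
  for (f in factors) {
    if (is.list(f) && isTRUE(attr(f, "divisor"))) {
      denominators <- c(denominators, trimws(xml2::xml_text(f[[1]])))
      next
    }
    nm <- xml2::xml_name(f)
    txt <- trimws(xml2::xml_text(f))
    if (nm == "cn") {
      k <- k * as.numeric(txt)
    } else if (txt %in% names(lpv)) {
      k <- k * lpv[[txt]]
    } else if (txt %in% names(comp_of)) {
      num_species <- c(num_species, txt)
    } else if (txt %in% names(comp_vol)) {
      extra_comps <- c(extra_comps, txt)
    } else {
      abort(paste0("unsupported construct: unknown symbol `", txt,
                   "` in kinetic law of ", id),
            class = "pbrpk_error_unsupported")
    }
  }

  ann <- xml2::xml_find_first(
    node, ".//*[local-name()='reaction' and namespace-uri()='" %+%
      PBRPK_NS %+% "']")
  if (!inherits(ann, "xml_missing")) {
    form <- xml2::xml_attr(ann, "form")
    tag <- xml2::xml_attr(ann, "tag")
    vrefs <- strsplit(xml2::xml_attr(ann, "volumeRefs"), " ")[[1]]
  } else {
    # infer: a trailing compartment multiplier marks mass action
    form <- if (length(extra_comps)) "mass_action" else "flow_transport"
    tag <- "imported"
    vrefs <- if (length(extra_comps)) extra_comps[1] else
      comp_of[[num_species[1]]]
  }
  add_reaction(g, id, reactants = reactants, products = products,
               law = rate_law(form, unname(k), volume_refs = vrefs),
               tag = tag)
}

import_schedule <- function(doc) {
  boluses <- xml2::xml_find_all(
    doc, paste0("//*[local-name()='bolus' and namespace-uri()='",
                PBRPK_NS, "']"))
  if (!length(boluses)) return(NULL)
  times <- as.numeric(xml2::xml_attr(boluses, "time"))
  hot <- as.numeric(xml2::xml_attr(boluses, "hot"))
  cold <- as.numeric(xml2::xml_attr(boluses, "cold"))
  ord <- order(times)
  n <- length(times)
  tau <- if (n > 1L) times[ord][2] - times[ord][1] else 0
  injection_schedule(hot_total = sum(hot), cold_total = sum(cold), n = n,
                     tau = tau, hot_per_bolus = hot[ord],
                     cold_per_bolus = cold[ord])
}
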