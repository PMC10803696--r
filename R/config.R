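#' Write a reaction graph to a human-editable YAML config
#'
#' One document holding compartments, species, reactions (with rate-law
#' form, rate constant, volume references and tag) and global parameters;
#' [read_graph_config()] restores an identical graph.
#'
#' @inheritParams add_compartment
#' @param path Output file path.
#' @export
write_graph_config <- function(graph, path) {
  stop_if_invalid(graph)
  doc <- list(
    parameters = as.list(graph$parameters),
    compartments = purrr::pmap(graph$compartments, function(...) list(...)),
    species = purrr::pmap(graph$species, function(...) list(...)),
    reactions = purrr::pmap(graph$reactions, function(id, reactants,
                                                      products, form,
                                                      rate_constant,
                                                      volume_refs, tag) {
      list(id = id, reactants = as.list(reactants),
           products = as.list(products), form = form,
           rate_constant = rate_constant,
           volume_refs = as.list(volume_refs), tag = tag)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a reaction graph from a YAML config
#' @param path Config file written by [write_graph_config()].
#' @export
read_graph_config <- function(path) {
  doc <- yaml::read_yaml(path)
  g <- reaction_graph(parameters = unlist(doc$parameters))
  for (cp in doc$compartments) {
    g <- add_compartment(g, cp$id, organ = cp$organ, subspace = cp$subspace,
                         volume = cp$volume)
  }
  for (sp in doc$species) {
    g <- add_species(g, sp$id, compartment = sp$compartment, kind = sp$kind,
                     initial_amount = sp$initial_amount)
  }
  for (rx in doc$reactions) {
    g <- add_reaction(
      g, rx$id,
      reactants = unlist(rx$reactants) %||% character(0),
      products = unlist(rx$products) %||% character(0),
      law = rate_law(rx$form, rx$rate_constant,
                     volume_refs = unlist(rx$volume_refs)),
      tag = rx$tag
    )
  }
  stop_if_invalid(g)
  g
}

#' Write per-organ time-activity curves as a tidy table
#'
#' @param result A `pbrpk_result`.
#' @param path Output file (tab-separated).
#' @param organs Organs to include; default all non-excreta organs.
#' @export
write_tac_table <- function(result, path, organs = NULL) {
  all_organs <- setdiff(unique(result$graph$compartments$organ), "excreta")
  organs <- organs %||% all_organs
  tab <- purrr::map_dfr(organs, function(org) activity_tac(result, org))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
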