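#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

SUBSPACES <- c("vascular", "interstitial", "membrane", "intracellular",
               "excreta", "blood_pool")

SPECIES_KINDS <- c("hot_ligand", "cold_ligand", "albumin",
                   "hot_albumin_complex", "cold_albumin_complex",
                   "receptor", "hot_bound", "cold_bound",
                   "hot_internal", "cold_internal")

RATE_LAW_FORMS <- c("mass_action", "flow_transport",
                    "permeability_transport", "clearance")

#' Create an empty reaction graph
#'
#' A reaction graph is the package's single source of truth for a
#' compartmental model: compartments (containers with a volume), species
#' (amount-valued state variables living in a compartment), and reactions
#' (mass-action conversions, flow/permeability transports, clearances).
#' State variables are amounts in nmol; rate laws convert to concentrations
#' through compartment volumes where the kinetics require it.
#'
#' @param parameters Named numeric vector of global scalar parameters
#'   (e.g. `lambda_phys`, the physical decay constant in 1/min).
#' @return An object of class `reaction_graph` with tibble fields
#'   `compartments`, `species`, `reactions` and a named `parameters` vector.
#' @examples
#' g <- reaction_graph(parameters = c(lambda_phys = 0.01))
#' g <- add_compartment(g, "body", organ = "body",
#'                      subspace = "vascular", volume = 1)
#' @export
reaction_graph <- function(parameters = c(lambda_phys = 0)) {
  stopifnot(is.numeric(parameters))
  structure(
    list(
      compartments = tibble(
        id = character(), organ = character(),
        subspace = character(), volume = numeric()
      ),
      species = tibble(
        id = character(), compartment = character(),
        kind = character(), initial_amount = numeric()
      ),
      reactions = tibble(
        id = character(),
        reactants = list(), products = list(),
        form = character(), rate_constant = numeric(),
        volume_refs = list(), tag = character()
      ),
      parameters = parameters
    ),
    class = "reaction_graph"
  )
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat("<reaction_graph>\n")
  cat("  compartments:", nrow(x$compartments), "\n")
  cat("  species:     ", nrow(x$species), "\n")
  cat("  reactions:   ", nrow(x$reactions), "\n")
  cat("  parameters:  ", length(x$parameters), "\n")
  invisible(x)
}

#' Add a compartment to a reaction graph
#'
#' @param graph A `reaction_graph`.
#' @param id Unique short identifier.
#' @param organ Organ label the compartment belongs to (e.g. `"kidneys"`).
#' @param subspace One of `"vascular"`, `"interstitial"`, `"membrane"`,
#'   `"intracellular"`, `"excreta"`, `"blood_pool"`.
#' @param volume Compartment volume in liters; must be strictly positive.
#' @return The augmented graph (input is unchanged; graphs are immutable
#'   values).
#' @export
add_compartment <- function(graph, id, organ, subspace, volume) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort("compartment `id` must be a non-empty string",
          class = "pbrpk_error_validation")
  }
  if (id %in% graph$compartments$id) {
    abort(paste0("duplicate compartment id: ", id),
          class = "pbrpk_error_duplicate")
  }
  if (!subspace %in% SUBSPACES) {
    abort(paste0("unknown subspace: ", subspace),
          class = "pbrpk_error_validation")
  }
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0) {
    abort(paste0("compartment volume must be > 0 (got ", volume,
                 " for ", id, ")"),
          class = "pbrpk_error_validation")
  }
  graph$compartments <- dplyr::bind_rows(
    graph$compartments,
    tibble(id = id, organ = organ, subspace = subspace, volume = volume)
  )
  graph
}

#' Add a species to a reaction graph
#'
#' @inheritParams add_compartment
#' @param compartment Id of an existing compartment.
#' @param kind Species kind (see [reaction_graph()] internals); one of the
#'   ligand/albumin/receptor forms tracked by the model.
#' @param initial_amount Initial amount in nmol, non-negative.
#' @export
add_species <- function(graph, id, compartment, kind, initial_amount = 0) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (!compartment %in% graph$compartments$id) {
    abort(paste0("species `", id, "` references unknown compartment `",
                 compartment, "`"),
          class = "pbrpk_error_reference")
  }
  if (!kind %in% SPECIES_KINDS) {
    abort(paste0("unknown species kind: ", kind),
          class = "pbrpk_error_validation")
  }
  if (any(graph$species$id == id & graph$species$compartment == compartment)) {
    abort(paste0("duplicate species (", id, ", ", compartment, ")"),
          class = "pbrpk_error_duplicate")
  }
  if (!is.finite(initial_amount) || initial_amount < 0) {
    abort(paste0("initial_amount of `", id, "` must be >= 0"),
          class = "pbrpk_error_validation")
  }
  graph$species <- dplyr::bind_rows(
    graph$species,
    tibble(id = id, compartment = compartment, kind = kind,
           initial_amount = initial_amount)
  )
  graph
}

#' Construct a rate law
#'
#' Four forms are supported. `mass_action` evaluates
#' `k * prod(concentration^stoich) * V_reaction` where concentrations are
#' amount/compartment-volume and `V_reaction` is the volume of the (single)
#' compartment named in `volume_refs` (bimolecular `k` in L/(nmol min),
#' unimolecular `k` in 1/min). The three transport forms
#' (`flow_transport`, `permeability_transport`, `clearance`) evaluate
#' `k * amount_source / V_source` with `k` in L/min; they take exactly one
#' reactant. Bidirectional exchange is modeled as two one-way reactions so
#' every rate is non-negative at non-negative states.
#'
#' @param form One of `"mass_action"`, `"flow_transport"`,
#'   `"permeability_transport"`, `"clearance"`.
#' @param rate_constant Non-negative rate constant in units matching `form`.
#' @param volume_refs Character vector of compartment ids used to convert
#'   amounts to concentrations; `NULL` defaults to the first reactant's
#'   compartment.
#' @export
rate_law <- function(form, rate_constant, volume_refs = NULL) {
  if (!form %in% RATE_LAW_FORMS) {
    abort(paste0("unknown rate law form: ", form),
          class = "pbrpk_error_validation")
  }
  if (!is.finite(rate_constant) || rate_constant < 0) {
    abort("rate_constant must be finite and >= 0",
          class = "pbrpk_error_validation")
  }
  structure(list(form = form, rate_constant = rate_constant,
                 volume_refs = volume_refs),
            class = "pbrpk_rate_law")
}

# normalize a reactant/product spec: named numeric (stoich) or character
# (stoich 1) -> named numeric
as_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("stoichiometry vectors must be named by species id",
          class = "pbrpk_error_validation")
  }
  if (any(x < 1) || any(x != round(x))) {
    abort("stoichiometric coefficients must be positive integers",
          class = "pbrpk_error_validation")
  }
  x
}

#' Add a reaction to a reaction graph
#'
#' @inheritParams add_compartment
#' @param reactants,products Species ids, either as a character vector
#'   (unit stoichiometry) or a named numeric vector of positive integer
#'   stoichiometries. Reactants may be empty only for `tag = "injection"`
#'   (source), products only for `tag = "clearance"` (sink).
#' @param law A [rate_law()].
#' @param tag Free-text provenance tag (e.g. `"decay"`, `"binding"`,
#'   `"clearance"`, `"flow"`).
#' @export
add_reaction <- function(graph, id, reactants, products, law, tag = "") {
  stopifnot(inherits(graph, "reaction_graph"), inherits(law, "pbrpk_rate_law"))
  reactants <- as_stoich(reactants)
  products <- as_stoich(products)
  if (id %in% graph$reactions$id) {
    abort(paste0("duplicate reaction id: ", id),
          class = "pbrpk_error_duplicate")
  }
  unknown <- setdiff(c(names(reactants), names(products)), graph$species$id)
  if (length(unknown)) {
    abort(paste0("reaction `", id, "` references unknown species: ",
                 paste(unknown, collapse = ", ")),
          class = "pbrpk_error_reference")
  }
  if (length(reactants) == 0L && !identical(tag, "injection")) {
    abort(paste0("reaction `", id, "` has no reactants (only tag ",
                 "\"injection\" may be a source)"),
          class = "pbrpk_error_validation")
  }
  if (length(products) == 0L && !identical(tag, "clearance")) {
    abort(paste0("reaction `", id, "` has no products (only tag ",
                 "\"clearance\" may be a sink)"),
          class = "pbrpk_error_validation")
  }
  if (law$form != "mass_action" && length(reactants) != 1L) {
    abort(paste0("transport/clearance rate laws take exactly one reactant (",
                 id, ")"),
          class = "pbrpk_error_validation")
  }
  if (law$form == "mass_action" && sum(reactants) > 1 &&
      length(law$volume_refs %||% character(0)) > 1L) {
    abort("bimolecular mass action must reference exactly one reaction volume",
          class = "pbrpk_error_validation")
  }
  vrefs <- law$volume_refs
  if (is.null(vrefs)) {
    first <- names(reactants)[1]
    vrefs <- graph$species$compartment[match(first, graph$species$id)]
  }
  missing_v <- setdiff(vrefs, graph$compartments$id)
  if (length(missing_v)) {
    abort(paste0("reaction `", id, "` volume_refs reference unknown ",
                 "compartments: ", paste(missing_v, collapse = ", ")),
          class = "pbrpk_error_reference")
  }
  graph$reactions <- dplyr::bind_rows(
    graph$reactions,
    tibble(id = id, reactants = list(reactants), products = list(products),
           form = law$form, rate_constant = law$rate_constant,
           volume_refs = list(vrefs), tag = tag)
  )
  graph
}

#' Set or update global parameters on a graph
#' @inheritParams add_compartment
#' @param ... Named scalar parameters.
#' @export
set_parameters <- function(graph, ...) {
  vals <- c(...)
  stopifnot(is.numeric(vals), !is.null(names(vals)))
  graph$parameters[names(vals)] <- vals
  graph
}

#' Validate a reaction graph
#'
#' Checks referential integrity, positivity of volumes, non-negativity of
#' initial amounts and rate constants, uniqueness of ids, and source/sink
#' tagging rules. Returns a tibble of diagnostics; an empty tibble means
#' the graph is well formed.
#'
#' @inheritParams add_compartment
#' @return A tibble with columns `entity`, `rule`, `message`.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  diags <- list()
  note <- function(entity, rule, message) {
    diags[[length(diags) + 1L]] <<- tibble(entity = entity, rule = rule,
                                           message = message)
  }
  cp <- graph$compartments
  sp <- graph$species
  rx <- graph$reactions

  dup <- cp$id[duplicated(cp$id)]
  for (d in unique(dup)) note(d, "compartment_id_unique", "duplicate compartment id")
  bad <- cp$id[!is.finite(cp$volume) | cp$volume <= 0]
  for (d in bad) note(d, "volume_positive", "compartment volume must be > 0")

  key <- paste(sp$id, sp$compartment, sep = "@")
  for (d in unique(key[duplicated(key)])) {
    note(d, "species_unique", "duplicate (species, compartment) pair")
  }
  miss <- sp$id[!sp$compartment %in% cp$id]
  for (d in miss) note(d, "species_compartment_exists",
                       "species placed in missing compartment")
  neg <- sp$id[!is.finite(sp$initial_amount) | sp$initial_amount < 0]
  for (d in neg) note(d, "initial_amount_nonnegative",
                      "initial amount must be >= 0")

  if (nrow(rx)) {
    for (j in seq_len(nrow(rx))) {
      refs <- c(names(rx$reactants[[j]]), names(rx$products[[j]]))
      unknown <- setdiff(refs, sp$id)
      if (length(unknown)) {
        note(rx$id[j], "reaction_species_exist",
             paste("unknown species:", paste(unknown, collapse = ", ")))
      }
      ambig <- refs[refs %in% sp$id[duplicated(sp$id)]]
      if (length(ambig)) {
        note(rx$id[j], "reaction_reference_unambiguous",
             paste("species id not globally unique:",
                   paste(unique(ambig), collapse = ", ")))
      }
      if (!is.finite(rx$rate_constant[j]) || rx$rate_constant[j] < 0) {
        note(rx$id[j], "rate_constant_nonnegative",
             "rate constant must be >= 0")
      }
      if (length(rx$reactants[[j]]) == 0L && rx$tag[j] != "injection") {
        note(rx$id[j], "source_requires_injection_tag",
             "source reactions must be tagged \"injection\"")
      }
      if (length(rx$products[[j]]) == 0L && rx$tag[j] != "clearance") {
        note(rx$id[j], "sink_requires_clearance_tag",
             "sink reactions must be tagged \"clearance\"")
      }
      bad_v <- setdiff(rx$volume_refs[[j]], cp$id)
      if (length(bad_v)) {
        note(rx$id[j], "volume_refs_exist",
             paste("unknown volume compartments:",
                   paste(bad_v, collapse = ", ")))
      }
    }
  }
  if (length(diags)) dplyr::bind_rows(diags) else
    tibble(entity = character(), rule = character(), message = character())
}

#' Is a graph valid?
#' @inheritParams add_compartment
#' @export
is_valid_graph <- function(graph) nrow(validate_graph(graph)) == 0L

stop_if_invalid <- function(graph) {
  d <- validate_graph(graph)
  if (nrow(d)) {
    abort(paste0("invalid reaction graph:\n",
                 paste0("  - [", d$entity, "] ", d$rule, ": ", d$message,
                        collapse = "\n")),
          class = "pbrpk_error_validation")
  }
  invisible(graph)
}

#' Stoichiometry matrix of a reaction graph
#'
#' @inheritParams add_compartment
#' @return Integer matrix of net stoichiometries, species (rows, named by
#'   species id) by reactions (columns, named by reaction id), such that
#'   `d(state)/dt = S %*% rates(state)`.
#' @export
stoichiometry_matrix <- function(graph) {
  stop_if_invalid(graph)
  sp <- graph$species$id
  rx <- graph$reactions
  S <- matrix(0L, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$id))
  for (j in seq_len(nrow(rx))) {
    r <- rx$reactants[[j]]
    p <- rx$products[[j]]
    if (length(r)) S[names(r), j] <- S[names(r), j] - as.integer(r)
    if (length(p)) S[names(p), j] <- S[names(p), j] + as.integer(p)
  }
  S
}

#' Evaluate instantaneous reaction rates at a state
#'
#' @inheritParams add_compartment
#' @param state Named numeric vector of species amounts (nmol); names must
#'   cover all species of the graph. Unnamed vectors are taken in species
#'   order.
#' @return Named numeric vector of reaction rates in nmol/min.
#' @export
reaction_rates <- function(graph, state) {
  stop_if_invalid(graph)
  sp <- graph$species$id
  if (is.null(names(state))) {
    stopifnot(length(state) == length(sp))
    names(state) <- sp
  }
  vol <- stats::setNames(graph$compartments$volume, graph$compartments$id)
  comp <- stats::setNames(graph$species$compartment, graph$species$id)
  rx <- graph$reactions
  rates <- numeric(nrow(rx))
  for (j in seq_len(nrow(rx))) {
    r <- rx$reactants[[j]]
    k <- rx$rate_constant[j]
    if (rx$form[j] == "mass_action") {
      conc <- if (length(r)) prod((state[names(r)] / vol[comp[names(r)]])^r) else 1
      vr <- rx$volume_refs[[j]][1]
      rates[j] <- k * conc * vol[vr]
    } else {
      src <- names(r)[1]
      rates[j] <- k * state[src] / vol[comp[src]]
    }
  }
  stats::setNames(rates, rx$id)
}

#' Build small closed-form fixture models
#'
#' Three toy reaction graphs with known analytic behavior, used throughout
#' the test-suite as oracles for the simulation engine:
#' \describe{
#'   \item{`decay_only`}{one compartment, hot ligand decaying to cold at
#'     `lambda_phys`; `H(t) = H0 exp(-lambda t)`.}
#'   \item{`two_compartment_exchange`}{linear exchange `k12`/`k21` between
#'     two compartments plus decay; solution is a matrix exponential.}
#'   \item{`minimal_binding`}{a single interstitial compartment with a
#'     finite receptor pool and reversible hot/cold binding; at equilibrium
#'     `[L][R]/[LR] = K_D`.}
#' }
#'
#' @param kind One of `"decay_only"`, `"two_compartment_exchange"`,
#'   `"minimal_binding"`.
#' @param lambda_phys Physical decay constant, 1/min.
#' @param k12,k21 Exchange rates (1/min) for the two-compartment fixture.
#' @param k_on Association rate, L/(nmol min), for the binding fixture.
#' @param K_D Dissociation constant, nmol/L, for the binding fixture.
#' @param H0,C0 Initial hot/cold amounts (nmol).
#' @param R0 Initial receptor amount (nmol) for the binding fixture.
#' @param volume Compartment volume (L).
#' @export
build_toy_model <- function(kind = c("decay_only", "two_compartment_exchange",
                                     "minimal_binding"),
                            lambda_phys = 0.01, k12 = 0.05, k21 = 0.02,
                            k_on = 0.1, K_D = 2, H0 = 1, C0 = 0, R0 = 1,
                            volume = 1) {
  kind <- match.arg(kind)
  g <- reaction_graph(parameters = c(lambda_phys = lambda_phys))
  if (kind == "decay_only") {
    g <- g |>
      add_compartment("vein", organ = "vein", subspace = "blood_pool",
                      volume = volume) |>
      add_species("hot", "vein", "hot_ligand", H0) |>
      add_species("cold", "vein", "cold_ligand", C0) |>
      add_reaction("decay", reactants = "hot", products = "cold",
                   law = rate_law("mass_action", lambda_phys,
                                  volume_refs = "vein"),
                   tag = "decay")
  } else if (kind == "two_compartment_exchange") {
    g <- g |>
      add_compartment("vein", organ = "vein", subspace = "blood_pool",
                      volume = volume) |>
      add_compartment("tissue", organ = "tissue", subspace = "interstitial",
                      volume = volume) |>
      add_species("hot_vein", "vein", "hot_ligand", H0) |>
      add_species("cold_vein", "vein", "cold_ligand", C0) |>
      add_species("hot_tissue", "tissue", "hot_ligand", 0) |>
      add_species("cold_tissue", "tissue", "cold_ligand", 0) |>
      add_reaction("h12", "hot_vein", "hot_tissue",
                   rate_law("mass_action", k12, "vein"), tag = "flow") |>
      add_reaction("h21", "hot_tissue", "hot_vein",
                   rate_law("mass_action", k21, "tissue"), tag = "flow") |>
      add_reaction("c12", "cold_vein", "cold_tissue",
                   rate_law("mass_action", k12, "vein"), tag = "flow") |>
      add_reaction("c21", "cold_tissue", "cold_vein",
                   rate_law("mass_action", k21, "tissue"), tag = "flow") |>
      add_reaction("decay_vein", "hot_vein", "cold_vein",
                   rate_law("mass_action", lambda_phys, "vein"),
                   tag = "decay") |>
      add_reaction("decay_tissue", "hot_tissue", "cold_tissue",
                   rate_law("mass_action", lambda_phys, "tissue"),
                   tag = "decay")
  } else {
    k_off <- k_on * K_D
    g <- g |>
      add_compartment("int", organ = "tissue", subspace = "interstitial",
                      volume = volume) |>
      add_species("hot", "int", "hot_ligand", H0) |>
      add_species("cold", "int", "cold_ligand", C0) |>
      add_species("receptor", "int", "receptor", R0) |>
      add_species("hot_bound", "int", "hot_bound", 0) |>
      add_species("cold_bound", "int", "cold_bound", 0) |>
      add_reaction("hot_on", c(hot = 1, receptor = 1), "hot_bound",
                   rate_law("mass_action", k_on, "int"), tag = "binding") |>
      add_reaction("hot_off", "hot_bound", c(hot = 1, receptor = 1),
                   rate_law("mass_action", k_off, "int"), tag = "binding") |>
      add_reaction("cold_on", c(cold = 1, receptor = 1), "cold_bound",
                   rate_law("mass_action", k_on, "int"), tag = "binding") |>
      add_reaction("cold_off", "cold_bound", c(cold = 1, receptor = 1),
                   rate_law("mass_action", k_off, "int"), tag = "binding") |>
      add_reaction("decay_free", "hot", "cold",
                   rate_law("mass_action", lambda_phys, "int"),
                   tag = "decay") |>
      add_reaction("decay_bound", "hot_bound", "cold_bound",
                   rate_law("mass_action", lambda_phys, "int"),
                   tag = "decay")
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
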