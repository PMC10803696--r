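#' @title Whole-body model construction
#' @description Functions that turn a population physiology table and a
#'   virtual patient into the full PBRPK reaction graph for a
#'   Lu-177-labeled receptor-targeting ligand.
#' @name physiology
NULL

# unit conversion to the canonical internal units
# (L, min, nmol, L/min, nmol/L, L/(nmol*min), J, kg/L)
convert_unit <- function(value, unit, field) {
  u <- gsub("\\s+", "", unit)
  if (!nzchar(u)) u <- "dimensionless"
  fac <- switch(u,
    "L" = , "l" = , "liters" = 1,
    "mL" = , "ml" = 1e-3,
    "1/min" = , "/min" = 1,
    "1/h" = , "1/hour" = 1 / 60,
    "min" = 1,
    "h" = , "hours" = 60,
    "L/min" = , "l/min" = 1,
    "mL/min" = , "ml/min" = 1e-3,
    "L/h" = , "l/h" = 1 / 60,
    "nmol/L" = , "nmol/lit" = , "nM" = 1,
    "nmol/mL" = , "nmol/ml" = 1e3,
    "L/(nmol*min)" = , "1/(nM*min)" = 1,
    "nmol" = 1,
    "J" = 1,
    "kg/L" = 1,
    "dimensionless" = 1,
    NULL
  )
  if (is.null(fac)) {
    abort(paste0("unit mismatch for `", field, "`: unsupported unit \"",
                 unit, "\""),
          class = "pbrpk_error_validation")
  }
  value * fac
}

read_quantity <- function(doc, section, key) {
  entry <- doc[[section]][[key]]
  if (is.null(entry) || is.null(entry$value)) {
    abort(paste0("parameter table missing required key `", key, "`"),
          class = "pbrpk_error_validation")
  }
  v <- convert_unit(as.numeric(entry$value), entry$unit %||% "", key)
  if (!is.nan(v) && !is.na(v) && v < 0) {
    abort(paste0("parameter `", key, "` must be >= 0"),
          class = "pbrpk_error_validation")
  }
  v
}

#' Load a physiology parameter table
#'
#' Reads a YAML parameter document (global kinetic constants, dosimetry
#' constants, blood pool volumes and the per-organ physiology table),
#' applies declared unit conversions to the canonical internal units
#' (liters, minutes, nmol) and validates it.
#'
#' @param source Path to a YAML document, or an already-parsed list.
#' @return A `global_parameters` object: a list with the kinetic constants,
#'   dosimetry constants, blood volumes and an `organs` tibble.
#' @export
load_parameter_table <- function(source = pbrpk_parameter_file()) {
  doc <- if (is.character(source)) yaml::read_yaml(source) else source
  for (sec in c("global", "dosimetry", "blood", "organs", "organ_units")) {
    if (is.null(doc[[sec]])) {
      abort(paste0("parameter table missing section `", sec, "`"),
            class = "pbrpk_error_validation")
    }
  }
  glb <- list(
    lambda_phys = read_quantity(doc, "global", "lambda_phys"),
    k_on = read_quantity(doc, "global", "k_on"),
    K_D = read_quantity(doc, "global", "K_D"),
    lambda_int = read_quantity(doc, "global", "lambda_int"),
    lambda_rel = read_quantity(doc, "global", "lambda_rel"),
    GFR = read_quantity(doc, "global", "GFR"),
    albumin_conc = read_quantity(doc, "global", "albumin_conc"),
    k_on_alb = read_quantity(doc, "global", "k_on_alb"),
    K_D_alb = read_quantity(doc, "global", "K_D_alb"),
    mean_energy_per_decay = read_quantity(doc, "dosimetry",
                                          "mean_energy_per_decay"),
    tissue_density = read_quantity(doc, "dosimetry", "tissue_density"),
    arterial_volume = read_quantity(doc, "blood", "arterial_volume"),
    venous_volume = read_quantity(doc, "blood", "venous_volume")
  )
  if (glb$K_D_alb <= 0) {
    abort("K_D_alb must be in (0, Inf]", class = "pbrpk_error_validation")
  }
  units <- doc$organ_units
  fields <- c("volume", "vascular_fraction", "interstitial_fraction",
              "plasma_flow", "receptor_density", "permeability")
  organs <- purrr::map_dfr(doc$organs, function(o) {
    if (is.null(o$name)) {
      abort("organ entry missing `name`", class = "pbrpk_error_validation")
    }
    row <- list(name = o$name)
    for (f in fields) {
      if (is.null(o[[f]])) {
        abort(paste0("organ `", o$name, "` missing field `", f, "`"),
              class = "pbrpk_error_validation")
      }
      row[[f]] <- convert_unit(as.numeric(o[[f]]), units[[f]] %||% "", f)
    }
    as_tibble(row)
  })
  bad <- organs$name[organs$vascular_fraction + organs$interstitial_fraction >= 1]
  if (length(bad)) {
    abort(paste0("vascular + interstitial fraction must be < 1 for: ",
                 paste(bad, collapse = ", ")),
          class = "pbrpk_error_validation")
  }
  if (any(unlist(organs[fields]) < 0)) {
    abort("organ parameters must be non-negative",
          class = "pbrpk_error_validation")
  }
  structure(c(glb, list(organs = organs)), class = "global_parameters")
}

#' Path of the packaged synthetic parameter table
#' @export
pbrpk_parameter_file <- function() {
  system.file("extdata", "pbrpk_parameters_synthetic.yaml", package = "pbrpk",
              mustWork = TRUE)
}

#' Default parameter set
#'
#' Loads the packaged synthetic physiology table (see
#' [pbrpk_parameter_file()]).
#' @export
default_parameters <- function() load_parameter_table(pbrpk_parameter_file())

#' @export
print.global_parameters <- function(x, ...) {
  cat("<global_parameters>\n")
  cat("  lambda_phys:", x$lambda_phys, "/min;  K_D:", x$K_D, "nmol/L;",
      "K_D_alb:", x$K_D_alb, "nmol/L\n")
  cat("  organs:", nrow(x$organs), "\n")
  invisible(x)
}

#' Model structure options
#'
#' @param albumin_enabled Compile the plasma-albumin species and (for finite
#'   `K_D_alb`) the ligand-albumin binding reactions into the model.
#' @param tumor_present Include the tumor organ.
#' @param albumin_leaks_into_tumor_interstitium Allow albumin and
#'   albumin-ligand complexes to cross the (porous) tumor vascular wall into
#'   the tumor interstitium; organs at risk never receive interstitial
#'   albumin.
#' @export
model_options <- function(albumin_enabled = FALSE, tumor_present = TRUE,
                          albumin_leaks_into_tumor_interstitium = TRUE) {
  structure(list(
    albumin_enabled = isTRUE(albumin_enabled),
    tumor_present = isTRUE(tumor_present),
    albumin_leak = isTRUE(albumin_leaks_into_tumor_interstitium)
  ), class = "model_options")
}

#' Create a virtual patient
#'
#' A virtual patient is the population baseline with the tumor volume and
#' tumor receptor density overridden. Tumor plasma flow and vascular
#' permeability scale proportionally with tumor volume; vascular and
#' interstitial fractions are preserved.
#'
#' @param base A `global_parameters` object.
#' @param tumor_volume_ml Tumor volume in mL (> 0); values outside the
#'   studied range 40–2100 mL trigger a warning.
#' @param receptor_density Tumor receptor density in nmol/L (> 0); values
#'   outside 10–890 nmol/L trigger a warning.
#' @return A `virtual_patient` object.
#' @export
make_virtual_patient <- function(base, tumor_volume_ml = 20,
                                 receptor_density = 40) {
  stopifnot(inherits(base, "global_parameters"))
  if (tumor_volume_ml <= 0 || receptor_density <= 0) {
    abort("tumor volume and receptor density must be > 0",
          class = "pbrpk_error_validation")
  }
  in_sweep_range <- tumor_volume_ml >= 40 && tumor_volume_ml <= 2100 &&
    receptor_density >= 10 && receptor_density <= 890
  default_tumor_ml <- 20
  if (!in_sweep_range &&
      !(tumor_volume_ml == default_tumor_ml && receptor_density >= 10 &&
          receptor_density <= 890)) {
    warn(paste0("virtual patient outside the studied ranges ",
                "(40-2100 mL, 10-890 nmol/L): ",
                tumor_volume_ml, " mL, ", receptor_density, " nmol/L"))
  }
  structure(list(base = base, tumor_volume_ml = tumor_volume_ml,
                 receptor_density = receptor_density),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("<virtual_patient> tumor", x$tumor_volume_ml, "mL,",
      x$receptor_density, "nmol/L receptors\n")
  invisible(x)
}

#' Enumerate a Cartesian grid of virtual patients
#'
#' @param volumes_ml Tumor volumes, mL (non-empty).
#' @param densities Tumor receptor densities, nmol/L (non-empty).
#' @param base A `global_parameters` object.
#' @return List of `virtual_patient`, volume-major deterministic order.
#' @export
enumerate_patient_grid <- function(volumes_ml, densities,
                                   base = default_parameters()) {
  if (!length(volumes_ml) || !length(densities)) {
    abort("patient grids must be non-empty", class = "pbrpk_error_validation")
  }
  grid <- tidyr::expand_grid(volume = volumes_ml, density = densities)
  purrr::map2(grid$volume, grid$density,
              function(v, d) suppressWarnings(
                make_virtual_patient(base, v, d)))
}

# the patient's organ table: tumor row overridden, flow/permeability
# scaled with volume
patient_organs <- function(patient) {
  organs <- patient$base$organs
  i <- which(organs$name == "tumor")
  if (length(i)) {
    v_new <- patient$tumor_volume_ml / 1000
    scale <- v_new / organs$volume[i]
    organs$volume[i] <- v_new
    organs$plasma_flow[i] <- organs$plasma_flow[i] * scale
    organs$permeability[i] <- organs$permeability[i] * scale
    organs$receptor_density[i] <- patient$receptor_density
  }
  organs
}

#' Build the full PBRPK reaction graph
#'
#' Constructs the whole-body model: an arterial and a venous plasma pool;
#' per organ a vascular and an interstitial compartment (plus an
#' intracellular compartment for receptor-expressing organs); plasma flow
#' artery -> organ vasculature -> vein -> artery; vascular/interstitial
#' permeability exchange of free ligand; reversible receptor binding
#' (`k_on`, `k_off = k_on * K_D`) of free interstitial hot and cold ligand
#' to a shared finite receptor pool, internalization of the bound complex
#' (returning the receptor to the free pool) and intracellular
#' release/degradation; renal clearance of free vascular ligand from the
#' kidneys into an excreta compartment at GFR; and physical decay hot ->
#' cold in every compartment and every bound/internalized/complexed form.
#'
#' With albumin enabled, albumin circulates in all plasma compartments and
#' binds hot/cold ligand 1:1 (`k_on_alb`, `k_off_alb = k_on_alb *
#' K_D_alb`); complexes are never renally cleared, never bind receptors,
#' and cross the vascular wall only into the tumor interstitium (porous
#' tumor vasculature), using the ligand's permeability coefficient.
#' `K_D_alb = Inf` is a sentinel: albumin species still circulate but no
#' binding reactions are emitted, so ligand kinetics are identical to the
#' albumin-disabled model.
#'
#' @param patient A `virtual_patient`.
#' @param options A [model_options()].
#' @return A validated `reaction_graph`.
#' @export
build_pbrpk_model <- function(patient,
                              options = model_options()) {
  stopifnot(inherits(patient, "virtual_patient"),
            inherits(options, "model_options"))
  p <- patient$base
  organs <- patient_organs(patient)
  if (!options$tumor_present) {
    organs <- organs[organs$name != "tumor", , drop = FALSE]
  }
  alb_on <- options$albumin_enabled
  bind_alb <- alb_on && is.finite(p$K_D_alb)
  k_off <- p$k_on * p$K_D
  k_off_alb <- if (bind_alb) p$k_on_alb * p$K_D_alb else NA_real_

  g <- reaction_graph(parameters = c(
    lambda_phys = p$lambda_phys, k_on = p$k_on, K_D = p$K_D,
    lambda_int = p$lambda_int, lambda_rel = p$lambda_rel, GFR = p$GFR,
    k_on_alb = p$k_on_alb, K_D_alb = p$K_D_alb,
    mean_energy_per_decay = p$mean_energy_per_decay,
    tissue_density = p$tissue_density
  ))
  g <- g |>
    add_compartment("art", organ = "artery", subspace = "blood_pool",
                    volume = p$arterial_volume) |>
    add_compartment("vein", organ = "vein", subspace = "blood_pool",
                    volume = p$venous_volume) |>
    add_compartment("urine", organ = "excreta", subspace = "excreta",
                    volume = 1)

  add_ligand_pair <- function(g, comp) {
    g |>
      add_species(paste0(comp, "__hot"), comp, "hot_ligand", 0) |>
      add_species(paste0(comp, "__cold"), comp, "cold_ligand", 0)
  }
  add_albumin_trio <- function(g, comp, alb0 = 0) {
    g |>
      add_species(paste0(comp, "__alb"), comp, "albumin", alb0) |>
      add_species(paste0(comp, "__hotalb"), comp, "hot_albumin_complex", 0) |>
      add_species(paste0(comp, "__coldalb"), comp, "cold_albumin_complex", 0)
  }

  g <- g |> add_ligand_pair("art") |> add_ligand_pair("vein") |>
    add_ligand_pair("urine")
  if (alb_on) {
    g <- g |>
      add_albumin_trio("art", p$albumin_conc * p$arterial_volume) |>
      add_albumin_trio("vein", p$albumin_conc * p$venous_volume)
  }

  receptor_organs <- organs$name[organs$receptor_density > 0]
  for (i in seq_len(nrow(organs))) {
    o <- organs[i, ]
    vc <- paste0(o$name, "_vasc")
    ic <- paste0(o$name, "_int")
    g <- g |>
      add_compartment(vc, organ = o$name, subspace = "vascular",
                      volume = o$volume * o$vascular_fraction) |>
      add_compartment(ic, organ = o$name, subspace = "interstitial",
                      volume = o$volume * o$interstitial_fraction) |>
      add_ligand_pair(vc) |> add_ligand_pair(ic)
    if (alb_on) {
      g <- add_albumin_trio(g, vc,
                            p$albumin_conc * o$volume * o$vascular_fraction)
      if (o$name == "tumor" && options$albumin_leak) {
        g <- add_albumin_trio(g, ic, 0)
      }
    }
    if (o$name %in% receptor_organs) {
      cc <- paste0(o$name, "_cell")
      g <- g |>
        add_compartment(cc, organ = o$name, subspace = "intracellular",
                        volume = o$volume *
                          max(1e-6, 1 - o$vascular_fraction -
                                o$interstitial_fraction)) |>
        add_species(paste0(ic, "__rec"), ic, "receptor",
                    o$receptor_density * o$volume) |>
        add_species(paste0(ic, "__hotb"), ic, "hot_bound", 0) |>
        add_species(paste0(ic, "__coldb"), ic, "cold_bound", 0) |>
        add_species(paste0(cc, "__hoti"), cc, "hot_internal", 0) |>
        add_species(paste0(cc, "__coldi"), cc, "cold_internal", 0)
    }
  }

  # ---- transport reactions ------------------------------------------------
  mobile_suffixes <- c("hot", "cold")
  alb_suffixes <- c("alb", "hotalb", "coldalb")
  q_total <- sum(organs$plasma_flow)

  flow_rxn <- function(g, from, to, q, sfx, tag) {
    add_reaction(g, paste0("flow__", from, "__", to, "__", sfx),
                 reactants = paste0(from, "__", sfx),
                 products = paste0(to, "__", sfx),
                 law = rate_law("flow_transport", q), tag = tag)
  }

  for (i in seq_len(nrow(organs))) {
    o <- organs[i, ]
    vc <- paste0(o$name, "_vasc")
    ic <- paste0(o$name, "_int")
    sfx_flow <- mobile_suffixes
    if (alb_on) sfx_flow <- c(sfx_flow, alb_suffixes)
    for (s in sfx_flow) {
      g <- g |>
        flow_rxn("art", vc, o$plasma_flow, s, "flow") |>
        flow_rxn(vc, "vein", o$plasma_flow, s, "flow")
    }
    # vascular <-> interstitial permeability for free ligand
    for (s in mobile_suffixes) {
      g <- g |>
        add_reaction(paste0("perm__", vc, "__", ic, "__", s),
                     paste0(vc, "__", s), paste0(ic, "__", s),
                     rate_law("permeability_transport", o$permeability),
                     tag = "permeability") |>
        add_reaction(paste0("perm__", ic, "__", vc, "__", s),
                     paste0(ic, "__", s), paste0(vc, "__", s),
                     rate_law("permeability_transport", o$permeability),
                     tag = "permeability")
    }
    # porous tumor vasculature: albumin and complexes leak into the tumor
    # interstitium with the ligand's permeability coefficient
    if (alb_on && o$name == "tumor" && options$albumin_leak) {
      for (s in alb_suffixes) {
        g <- g |>
          add_reaction(paste0("perm__", vc, "__", ic, "__", s),
                       paste0(vc, "__", s), paste0(ic, "__", s),
                       rate_law("permeability_transport", o$permeability),
                       tag = "albumin_leak") |>
          add_reaction(paste0("perm__", ic, "__", vc, "__", s),
                       paste0(ic, "__", s), paste0(vc, "__", s),
                       rate_law("permeability_transport", o$permeability),
                       tag = "albumin_leak")
      }
    }
  }
  # venous return
  sfx_flow <- mobile_suffixes
  if (alb_on) sfx_flow <- c(sfx_flow, alb_suffixes)
  for (s in sfx_flow) g <- flow_rxn(g, "vein", "art", q_total, s, "flow")

  # renal clearance of free (never albumin-bound) vascular ligand
  for (s in mobile_suffixes) {
    g <- add_reaction(g, paste0("gfr__", s),
                      paste0("kidneys_vasc__", s), paste0("urine__", s),
                      rate_law("clearance", p$GFR), tag = "renal_clearance")
  }

  # ---- receptor kinetics --------------------------------------------------
  for (org in receptor_organs) {
    ic <- paste0(org, "_int")
    cc <- paste0(org, "_cell")
    rec <- paste0(ic, "__rec")
    for (lab in c("hot", "cold")) {
      free <- paste0(ic, "__", lab)
      bound <- paste0(ic, "__", lab, "b")
      internal <- paste0(cc, "__", lab, "i")
      on <- stats::setNames(c(1, 1), c(free, rec))
      g <- g |>
        add_reaction(paste0("bind__", org, "__", lab), on, bound,
                     rate_law("mass_action", p$k_on, ic), tag = "binding") |>
        add_reaction(paste0("unbind__", org, "__", lab), bound, on,
                     rate_law("mass_action", k_off, ic), tag = "binding") |>
        add_reaction(paste0("internalize__", org, "__", lab), bound,
                     stats::setNames(c(1, 1), c(internal, rec)),
                     rate_law("mass_action", p$lambda_int, ic),
                     tag = "internalization") |>
        add_reaction(paste0("release__", org, "__", lab), internal, free,
                     rate_law("mass_action", p$lambda_rel, cc),
                     tag = "release")
    }
  }

  # ---- albumin binding ----------------------------------------------------
  if (bind_alb) {
    alb_comps <- c("art", "vein", paste0(organs$name, "_vasc"))
    if (options$tumor_present && options$albumin_leak) {
      alb_comps <- c(alb_comps, "tumor_int")
    }
    for (comp in alb_comps) {
      alb <- paste0(comp, "__alb")
      for (lab in c("hot", "cold")) {
        free <- paste0(comp, "__", lab)
        cplx <- paste0(comp, "__", lab, "alb")
        on <- stats::setNames(c(1, 1), c(free, alb))
        g <- g |>
          add_reaction(paste0("albbind__", comp, "__", lab), on, cplx,
                       rate_law("mass_action", p$k_on_alb, comp),
                       tag = "albumin_binding") |>
          add_reaction(paste0("albunbind__", comp, "__", lab), cplx, on,
                       rate_law("mass_action", k_off_alb, comp),
                       tag = "albumin_binding")
      }
    }
  }

  # ---- physical decay: every hot form -> matching cold form ---------------
  decay_map <- c(hot_ligand = "cold", hot_bound = "coldb",
                 hot_internal = "coldi", hot_albumin_complex = "coldalb")
  hot_map <- c(hot_ligand = "hot", hot_bound = "hotb",
               hot_internal = "hoti", hot_albumin_complex = "hotalb")
  sp <- g$species
  hot_rows <- which(sp$kind %in% names(decay_map))
  for (i in hot_rows) {
    comp <- sp$compartment[i]
    hot_id <- sp$id[i]
    cold_id <- sub(paste0(hot_map[[sp$kind[i]]], "$"),
                   decay_map[[sp$kind[i]]], hot_id)
    g <- add_reaction(g, paste0("decay__", hot_id), hot_id, cold_id,
                      rate_law("mass_action", p$lambda_phys, comp),
                      tag = "decay")
  }

  stop_if_invalid(g)
  g
}
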