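test_that("compartments enforce uniqueness and positive volume", {
  g <- reaction_graph()
  g <- add_compartment(g, "tum_int", organ = "tumor",
                       subspace = "interstitial", volume = 0.02)
  expect_equal(nrow(g$compartments), 1L)
  expect_equal(g$compartments$volume, 0.02)

  expect_error(add_compartment(g, "tum_int", "tumor", "interstitial", 0.01),
               class = "pbrpk_error_duplicate")
  expect_error(add_compartment(g, "x", "tumor", "interstitial", 0),
               class = "pbrpk_error_validation")
  expect_error(add_compartment(g, "x", "tumor", "nowhere", 1),
               class = "pbrpk_error_validation")
})

test_that("species require an existing compartment and non-negative amount", {
  g <- add_compartment(reaction_graph(), "c1", "organ", "vascular", 1)
  expect_error(add_species(g, "s", "missing", "hot_ligand", 1),
               class = "pbrpk_error_reference")
  expect_error(add_species(g, "s", "c1", "hot_ligand", -1),
               class = "pbrpk_error_validation")
  g <- add_species(g, "s", "c1", "hot_ligand", 1)
  expect_error(add_species(g, "s", "c1", "cold_ligand", 0),
               class = "pbrpk_error_duplicate")
})

test_that("rate laws evaluate per their form", {
  # bimolecular mass action: rate = k [A][B] V
  g <- build_toy_model("minimal_binding", k_on = 2, K_D = 1,
                       H0 = 3, C0 = 0, R0 = 4, volume = 1)
  r <- reaction_rates(g, c(hot = 3, cold = 0, receptor = 4,
                           hot_bound = 0, cold_bound = 0))
  expect_equal(unname(r["hot_on"]), 2 * 3 * 4)

  # unimolecular decay: rate = lambda * H
  gd <- build_toy_model("decay_only", lambda_phys = 0.01, H0 = 10)
  rd <- reaction_rates(gd, c(hot = 10, cold = 0))
  expect_equal(unname(rd["decay"]), 0.1)

  # volume scaling of the bimolecular law
  gv <- build_toy_model("minimal_binding", k_on = 2, K_D = 1,
                        H0 = 3, R0 = 4, volume = 2)
  rv <- reaction_rates(gv, c(hot = 3, cold = 0, receptor = 4,
                             hot_bound = 0, cold_bound = 0))
  expect_equal(unname(rv["hot_on"]), 2 * (3 / 2) * (4 / 2) * 2)

  expect_error(rate_law("mass_action", -1), class = "pbrpk_error_validation")
  expect_error(rate_law("osmosis", 1), class = "pbrpk_error_validation")
})

test_that("reactions referencing absent species are rejected", {
  g <- build_toy_model("decay_only")
  expect_error(
    add_reaction(g, "bad", reactants = "X", products = "cold",
                 law = rate_law("mass_action", 1, "vein")),
    class = "pbrpk_error_reference"
  )
})

test_that("stoichiometry matrix has net coefficients per column", {
  g <- build_toy_model("decay_only")
  S <- stoichiometry_matrix(g)
  expect_identical(dim(S), c(2L, 1L))
  expect_equal(S[, "decay"], c(hot = -1L, cold = 1L))

  gb <- build_toy_model("minimal_binding")
  Sb <- stoichiometry_matrix(gb)
  expect_equal(Sb[c("hot", "receptor", "hot_bound"), "hot_on"],
               c(hot = -1L, receptor = -1L, hot_bound = 1L))

  g0 <- add_compartment(reaction_graph(), "c", "o", "vascular", 1)
  expect_identical(ncol(stoichiometry_matrix(g0)), 0L)
})

test_that("validate_graph reports referential violations as diagnostics", {
  g <- build_toy_model("decay_only")
  expect_identical(nrow(validate_graph(g)), 0L)
  expect_true(is_valid_graph(g))

  g_bad <- g
  g_bad$species$compartment[1] <- "nowhere"
  d <- validate_graph(g_bad)
  expect_true(any(d$rule == "species_compartment_exists"))

  g_neg <- g
  g_neg$species$initial_amount[1] <- -1
  d <- validate_graph(g_neg)
  expect_true(any(d$rule == "initial_amount_nonnegative"))
})

test_that("toy fixtures match their closed forms", {
  # decay: H(100) = exp(-1) for lambda 0.01, H0 = 1
  g <- build_toy_model("decay_only", lambda_phys = 0.01, H0 = 1)
  res <- simulate_model(g, injection_schedule(0, 0),
                        solver_settings(t_end = 100, grid = c(0, 100)))
  expect_equal(unname(res$amounts[2, "hot"]), exp(-1), tolerance = 1e-8)

  # two-compartment exchange vs independent matrix-exponential oracle
  g2 <- build_toy_model("two_compartment_exchange", lambda_phys = 0.01,
                        k12 = 0.05, k21 = 0.02, H0 = 1)
  res2 <- simulate_model(g2, injection_schedule(0, 0),
                         solver_settings(t_end = 100,
                                         grid = c(0, 1, 10, 100)))
  for (tt in c(1, 10, 100)) {
    want <- two_compartment_hot_oracle(tt, 0.05, 0.02, 0.01)
    got <- res2$amounts[res2$times == tt, c("hot_vein", "hot_tissue")]
    expect_lt(max_rel_err(got, want), 1e-8)
  }

  # binding equilibrium (decay off): [L][R]/[LR] = K_D
  gb <- build_toy_model("minimal_binding", lambda_phys = 0, k_on = 0.1,
                        K_D = 2, H0 = 1, R0 = 1, volume = 0.5)
  resb <- simulate_model(gb, injection_schedule(0, 0),
                         solver_settings(t_end = 5000, grid = c(0, 5000)))
  a <- resb$amounts[2, ]
  v <- 0.5
  kd_obs <- (a[["hot"]] / v) * (a[["receptor"]] / v) / (a[["hot_bound"]] / v)
  expect_equal(unname(kd_obs), 2, tolerance = 1e-4)

  expect_error(build_toy_model("cyclotron"))
})

test_that("moiety conservation is encoded in the stoichiometry left null space", {
  g <- full_model(albumin = TRUE, kd_alb = 100)
  S <- stoichiometry_matrix(g)
  kinds <- g$species$kind
  moieties <- list(
    ligand = c("hot_ligand", "cold_ligand", "hot_bound", "cold_bound",
               "hot_internal", "cold_internal", "hot_albumin_complex",
               "cold_albumin_complex"),
    albumin = c("albumin", "hot_albumin_complex", "cold_albumin_complex"),
    receptor = c("receptor", "hot_bound", "cold_bound")
  )
  for (m in names(moieties)) {
    w <- as.numeric(kinds %in% moieties[[m]])
    expect_equal(max(abs(t(w) %*% S)), 0,
                 info = paste("moiety:", m))
  }
})

test_that("reaction rates are non-negative at non-negative states", {
  g <- full_model(albumin = TRUE, kd_alb = 100)
  set.seed(42)
  for (i in 1:5) {
    state <- stats::runif(nrow(g$species), 0, 10)
    names(state) <- g$species$id
    expect_true(all(reaction_rates(g, state) >= 0))
  }
})
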