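test_that("injection schedules split totals and place bolus times", {
  s <- injection_schedule(10, 100, n = 5, tau = 100)
  expect_equal(s$times, c(0, 100, 200, 300, 400))
  expect_equal(s$hot_per_bolus, rep(2, 5))
  expect_equal(sum(s$cold_per_bolus), 100)

  custom <- injection_schedule(10, 100, n = 2, tau = 50,
                               hot_per_bolus = c(7, 3),
                               cold_per_bolus = c(60, 40))
  expect_equal(custom$hot_per_bolus, c(7, 3))
  expect_error(injection_schedule(10, 100, n = 0),
               class = "pbrpk_error_validation")
  expect_error(injection_schedule(10, 100, n = 2, hot_per_bolus = c(1, 2)),
               class = "pbrpk_error_validation")
})

test_that("assembled derivative matches the rate laws", {
  g <- build_toy_model("decay_only", lambda_phys = 0.01)
  sys <- assemble_rhs(g)
  d <- sys$rhs(0, c(hot = 10, cold = 0), NULL)[[1]]
  expect_equal(d, c(-0.1, 0.1))
  expect_equal(sys$rhs(0, c(hot = 0, cold = 0), NULL)[[1]], c(0, 0))

  # full-model derivative finite at a post-bolus state
  gf <- full_model(albumin = TRUE, kd_alb = 100)
  sysf <- assemble_rhs(gf)
  y0 <- stats::setNames(gf$species$initial_amount, gf$species$id)
  y0["vein__hot"] <- 10
  y0["vein__cold"] <- 100
  expect_true(all(is.finite(sysf$rhs(0, y0, NULL)[[1]])))
})

test_that("analytic Jacobian agrees with finite differences", {
  g <- build_toy_model("minimal_binding", k_on = 0.3, K_D = 1.5,
                       H0 = 2, C0 = 1, R0 = 1)
  sys <- assemble_rhs(g)
  y <- c(hot = 1.2, cold = 0.4, receptor = 0.6, hot_bound = 0.3,
         cold_bound = 0.2)
  J <- sys$jac(0, y, NULL)
  h <- 1e-7
  for (i in seq_along(y)) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    num <- (sys$rhs(0, yp, NULL)[[1]] - sys$rhs(0, ym, NULL)[[1]]) / (2 * h)
    expect_equal(unname(J[, i]), num, tolerance = 1e-6)
  }
})

test_that("single-bolus decay matches the closed form", {
  g <- build_toy_model("decay_only", lambda_phys = 0.01, H0 = 0)
  res <- simulate_model(g, injection_schedule(1, 0),
                        solver_settings(t_end = 500))
  expect_lt(max_rel_err(res$amounts[, "hot"], exp(-0.01 * res$times)), 1e-8)
})

test_that("multi-bolus trajectories superpose in the linear regime", {
  g <- build_toy_model("two_compartment_exchange", lambda_phys = 0.01,
                       k12 = 0.05, k21 = 0.02, H0 = 0)
  grid <- seq(0, 1000, by = 10)
  st <- solver_settings(t_end = 1000, grid = grid)
  two <- simulate_model(g, injection_schedule(1, 0, n = 2, tau = 100), st)

  one_a <- simulate_model(g, injection_schedule(0.5, 0), st)
  # second bolus: same response shifted by 100 min
  shifted <- matrix(0, length(grid), ncol(one_a$amounts))
  keep <- grid > 100
  shifted[keep, ] <- apply(one_a$amounts, 2, function(a) {
    stats::approx(grid, a, xout = grid[keep] - 100)$y
  })
  combined <- one_a$amounts + shifted
  expect_lt(max(abs(two$amounts - combined)) / max(two$amounts), 1e-6)
})

test_that("bolus events inject exactly the scheduled totals", {
  g <- full_model(albumin = FALSE)
  res <- simulate_model(g, injection_schedule(10, 100, n = 7, tau = 50),
                        solver_settings(t_end = 5000))
  lig <- moiety_totals(res, "ligand")
  # after the last bolus every ligand molecule is accounted for
  expect_equal(lig[length(lig)], 110, tolerance = 1e-9)
})

test_that("conservation holds on the full model under random schedules", {
  g <- full_model(albumin = TRUE, kd_alb = 1000)
  set.seed(7)
  for (i in 1:5) {
    n <- sample(1:10, 1)
    tau <- sample(c(10, 100, 500, 1000), 1)
    res <- simulate_model(g, injection_schedule(10, 100, n = n, tau = tau),
                          solver_settings(t_end = n * tau + 2000))
    after_last <- res$times > max(res$schedule$times)
    lig <- moiety_totals(res, "ligand")[after_last]
    expect_lt(max(abs(lig - 110)) / 110, 1e-6)
    alb <- moiety_totals(res, "albumin")
    expect_lt(max(abs(alb - alb[1])) / alb[1], 1e-6)
    rec <- moiety_totals(res, "receptor", organ = "tumor")
    expect_lt(max(abs(rec - rec[1])) / rec[1], 1e-6)
  }
})

test_that("hot moiety decays purely physically after the last bolus", {
  g <- full_model(albumin = TRUE, kd_alb = 1000)
  res <- simulate_model(g, injection_schedule(10, 100, n = 3, tau = 100),
                        solver_settings(t_end = 20000))
  lambda <- unname(g$parameters["lambda_phys"])
  after <- res$times > 200
  hot <- moiety_totals(res, "hot")[after]
  tt <- res$times[after]
  want <- hot[1] * exp(-lambda * (tt - tt[1]))
  expect_lt(max_rel_err(hot, want), 1e-6)
})

test_that("resampling is exact on the original grid and bounded off it", {
  g <- build_toy_model("decay_only", lambda_phys = 0.01, H0 = 1)
  res <- simulate_model(g, injection_schedule(0, 0),
                        solver_settings(t_end = 100, grid = seq(0, 100, 5)))
  same <- resample(res, res$times)
  expect_equal(same$amounts, res$amounts)

  mid <- resample(res, seq(2.5, 97.5, 5))
  expect_lt(max(abs(mid$amounts[, "hot"] - exp(-0.01 * mid$times))), 5e-4)

  expect_error(resample(res, c(0, 200)), class = "pbrpk_error_validation")
})

test_that("solver failure surfaces as a structured error", {
  g <- build_toy_model("decay_only")
  expect_error(
    simulate_model(g, injection_schedule(1, 0, n = 2, tau = 100),
                   solver_settings(t_end = 50)),
    class = "pbrpk_error_validation"
  )
})
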