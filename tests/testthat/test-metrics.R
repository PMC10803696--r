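make_surface <- function(f, hot = seq(5, 100, length.out = 12),
                         cold = seq(25, 800, length.out = 12),
                         organ = "tumor") {
  dose_grid(hot, cold, outer(hot, cold, f), organ = organ)
}

test_that("dose grids validate their axes and payload", {
  expect_error(dose_grid(c(2, 1), 1:3, matrix(0, 2, 3)),
               class = "pbrpk_error_validation")
  expect_error(dose_grid(1:2, 1:3, matrix(-1, 2, 3)),
               class = "pbrpk_error_validation")
  expect_error(dose_grid(1:2, 1:3, matrix(0, 3, 2)),
               class = "pbrpk_error_validation")
})

test_that("contours of analytic surfaces have the known geometry", {
  # dose depends on hot only -> vertical iso-lines at 90 degrees
  g1 <- make_surface(function(h, c) h)
  cts <- extract_isodose_contours(g1, c(30, 70))
  expect_length(cts, 2)
  for (ct in cts) expect_equal(fit_contour_line(ct), 90, tolerance = 1e-6)

  # additive surface: slope -1 in raw axes
  g2 <- make_surface(function(h, c) h + c)
  ct2 <- extract_isodose_contours(g2, 400)[[1]]
  slope <- stats::coef(stats::lm(cold ~ hot, data = ct2$points))[2]
  expect_equal(unname(slope), -1, tolerance = 1e-6)

  # out-of-range level is skipped with a warning
  expect_warning(cts3 <- extract_isodose_contours(g1, c(30, 1e6)),
                 "outside")
  expect_length(cts3, 1)
})

test_that("orthogonal line fits recover generating angles", {
  # vertical segment
  vert <- tibble::tibble(hot = rep(5, 10), cold = seq(0, 1, length.out = 10))
  expect_equal(fit_contour_line(vert, hot_range = c(0, 10),
                                cold_range = c(0, 1)), 90)
  # diagonal of the standardized unit square
  diag_pts <- tibble::tibble(hot = seq(0, 1, length.out = 10),
                             cold = seq(0, 1, length.out = 10))
  expect_equal(fit_contour_line(diag_pts, hot_range = c(0, 1),
                                cold_range = c(0, 1)), 45)

  # noisy line recovered within 1 degree
  set.seed(11)
  for (ang_deg in c(20, 60, 120)) {
    t <- seq(-1, 1, length.out = 200)
    x <- 0.5 + t * cos(ang_deg * pi / 180) + stats::rnorm(200, 0, 0.01)
    y <- 0.5 + t * sin(ang_deg * pi / 180) + stats::rnorm(200, 0, 0.01)
    got <- fit_contour_line(tibble::tibble(hot = x, cold = y),
                            hot_range = c(0, 1), cold_range = c(0, 1))
    expect_lt(abs(got - ang_deg), 1)
  }

  expect_error(fit_contour_line(tibble::tibble(hot = 1, cold = 1),
                                hot_range = c(0, 1), cold_range = c(0, 1)),
               class = "pbrpk_error_validation")
})

test_that("twist is zero for parallel contours and matches hand geometry", {
  g_lin <- make_surface(function(h, c) h)
  tw <- compute_twist(g_lin)
  expect_true(all(tw$twist_deg < 1e-6))
  expect_equal(tw$twist_deg[which.min(tw$level)], 0)

  # saturating surface h/(h+c+s): iso-line of level L is h = L/(1-L) (c+s);
  # hand-derived standardized angle from the slope
  h <- seq(5, 100, length.out = 25)
  c_ <- seq(25, 800, length.out = 25)
  s <- 50
  gs <- dose_grid(h, c_, outer(h, c_, function(h, c) h / (h + c + s)))
  levels <- c(0.05, 0.1, 0.2, 0.3)
  expected_angle <- function(L) {
    m <- L / (1 - L) # dh/dc in raw axes
    atan2(1, m * diff(range(c_)) / diff(range(h))) * 180 / pi
  }
  tw2 <- compute_twist(gs, levels = levels)
  want <- abs(vapply(levels, expected_angle, numeric(1)) -
                expected_angle(levels[1]))
  expect_true(all(abs(tw2$twist_deg - want) < 1))
})

test_that("twist is invariant to dose units and axis rescaling", {
  f <- function(h, c) h / (h + c + 50)
  g1 <- make_surface(f)
  g2 <- dose_grid(g1$hot, g1$cold, g1$dose * 1000, organ = "tumor") # Gy->mGy
  lv1 <- range(g1$dose) %*% c(0.7, 0.3)
  tw1 <- compute_twist(g1)
  tw2 <- compute_twist(g2)
  expect_equal(tw1$twist_deg, tw2$twist_deg, tolerance = 1e-9)

  # rescale the cold axis by a common factor
  g3 <- dose_grid(g1$hot, g1$cold * 10,
                  outer(g1$hot, g1$cold, f), organ = "tumor")
  tw3 <- compute_twist(g3)
  expect_equal(tw1$twist_deg, tw3$twist_deg, tolerance = 1e-9)
})

test_that("MRDC follows its defining formula with deterministic ties", {
  tab <- tibble::tibble(n = c(1, 2, 5), tau = c(0, 100, 100),
                        dose = c(10, 12, 12))
  m <- compute_mrdc(tab, baseline = 10)
  expect_equal(m$mrdc, 0.2)
  expect_equal(m$n_star, 2) # tie broken toward smaller n

  # optimum equals the baseline -> MRDC 0
  m0 <- compute_mrdc(tibble::tibble(n = 1, tau = 0, dose = 10), 10)
  expect_equal(m0$mrdc, 0)

  # all fractionated schedules below the included baseline
  m2 <- compute_mrdc(tibble::tibble(n = c(1, 4), tau = c(0, 100),
                                    dose = c(10, 8)), 10)
  expect_equal(m2$mrdc, 0)
  expect_equal(m2$n_star, 1)

  expect_error(compute_mrdc(tab, 0), class = "pbrpk_error_validation")
})

test_that("MRDC is invariant to the dose/TIA multiplicative constant", {
  tab <- tibble::tibble(n = c(1, 3, 6), tau = c(0, 50, 200),
                        dose = c(10, 11, 11.5))
  m1 <- compute_mrdc(tab, 10)
  tab2 <- tab; tab2$dose <- tab2$dose * 3.7
  m2 <- compute_mrdc(tab2, 37)
  expect_equal(m1$mrdc, m2$mrdc)
  expect_equal(m1$n_star, m2$n_star)
})

test_that("enhancement factors follow the ratio-of-ratios definition", {
  ef <- compute_ef(c(100, Inf), c(40, 10), c(10, 10), 10, 10)
  expect_equal(ef$ef, c(4, 1))

  # common rescaling of both organs leaves EF unchanged
  ef2 <- compute_ef(c(100), c(80), c(20), 10, 10)
  expect_equal(ef2$ef, 4)

  # separate multiplicative constants cancel entirely
  efa <- compute_ef(c(5, 50), c(12, 9), c(3, 4), 10, 5)
  efb <- compute_ef(c(5, 50), c(12, 9) * 2.5, c(3, 4) * 0.3, 25, 1.5)
  expect_equal(efa$ef, efb$ef)

  expect_error(compute_ef(1, 1, 0, 1, 1), class = "pbrpk_error_validation")
  expect_error(compute_ef(c(1, 2), 1, 1, 1, 1),
               class = "pbrpk_error_validation")
})
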