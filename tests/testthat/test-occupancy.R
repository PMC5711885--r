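pop <- vesicle_population()

test_that("end-point normalization rescales between baseline and maximum", {
  expect_equal(normalize_reduction(45, pop), 0)
  expect_equal(normalize_reduction(82.5, pop), 1)
  expect_equal(normalize_reduction(63.75, pop), 0.5)
  expect_warning(p <- normalize_reduction(40, pop), "clamped")
  expect_equal(p, 0)
  expect_equal(normalize_reduction(90, pop), 1)  # above F_max clamps
  expect_error(
    normalize_reduction(50, vesicle_population(f_o = 45, f_max = 45.0001)),
    NA)
  bad <- pop; bad$f_max <- 40
  expect_error(normalize_reduction(50, structure(bad,
                                                 class = "vesicle_population")),
               "f_max")
})

test_that("PPR* rescales the protein load by the reconstitutable fraction", {
  expect_equal(ppr_star(0, pop), 0)
  expect_equal(ppr_star(0.65, pop), 1)
  expect_equal(ppr_star(1.3, vesicle_population(refractory_fraction = 0.35)),
               2)
  expect_error(vesicle_population(refractory_fraction = 1), "\\[0, 1\\)")
  expect_error(ppr_star(-1, pop), ">= 0")
})

test_that("mean occupancy matches the explicit lipid-count route", {
  expect_equal(mean_occupancy(c(10, 88), 8e-4, 0), c(0, 0))
  # reciprocal cancellation: alpha = 16/(M eps^2), x = M/16 * eps^2
  eps <- 0.472; M <- 41700
  expect_equal(mean_occupancy(1, 16 / (M * eps^2), M * eps^2 / 16), 0.5)
  # independent route: lipids per vesicle (8 r^2 / eps^2, two leaflets of
  # area 4 pi r^2 at pi eps^2 per lipid) times protein:lipid molar ratio
  alpha <- 8.17e-4; x <- 1; r <- 88
  M <- 16 / (alpha * eps^2)
  lipid_route <- (8 * r^2 / eps^2) * (x / M)
  expect_equal(mean_occupancy(r, alpha, x), lipid_route, tolerance = 1e-12)
  expect_equal(mean_occupancy(2 * r, alpha, x),
               4 * mean_occupancy(r, alpha, x))
})

test_that("ensemble coefficients reduce to 784 and 3872 at the defaults", {
  cf <- occupancy_coefficients(pop)
  expect_identical(unname(cf["sqrt_coef"]), 784)
  expect_identical(unname(cf["exp_coef"]), 3872)
  cf2 <- occupancy_coefficients(vesicle_population(mean_radius = 100,
                                                   sd_radius = 10))
  expect_equal(unname(cf2), c(100, 5000))
})

test_that("closed-form occupancy agrees with the Monte-Carlo ensemble", {
  expect_equal(predict_p_at_least_one(8.17e-4, 0, pop), 0)
  for (alpha in c(2e-4, 8.17e-4)) {
    for (x in c(0.5, 2)) {
      p_cf <- predict_p_at_least_one(alpha, x, pop)
      p_mc <- mc_occupancy(alpha, x, n = 2e5, seed = 7)
      expect_lt(abs(p_cf - p_mc), mc_tol(p_cf, 2e5))
    }
  }
  expect_error(predict_p_at_least_one(8.17e-4, -1, pop), "domain")
})

test_that("occupancy curve is monotone in load and alpha, with no inflection", {
  xs <- seq(0, 5, by = 0.1)
  for (alpha in c(2e-4, 8e-4, 2e-3)) {
    p <- predict_p_at_least_one(alpha, xs, pop)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
    # concave over the assay range: second differences negative for x > 0
    expect_true(all(diff(diff(p)) < 0))
  }
  for (x in c(0.5, 2, 5))
    expect_true(all(diff(vapply(c(2e-4, 5e-4, 1e-3, 2e-3), function(a)
      predict_p_at_least_one(a, x, pop), numeric(1))) > 0))
})

test_that("alpha-mass conversion reproduces the published constants", {
  expect_equal(signif(alpha_to_mass(8.17e-4, 0.472), 5), 87905)
  expect_equal(signif(alpha_to_mass(18.90e-4, 0.472), 3), 38000)
  expect_equal(mass_to_alpha(41700, 0.472), 16 / (41700 * 0.472^2))
  # round trip to machine precision
  for (a in c(1e-4, 8.17e-4, 5e-3))
    expect_equal(mass_to_alpha(alpha_to_mass(a)), a, tolerance = 1e-15)
  expect_error(alpha_to_mass(0), "domain")
  expect_error(mass_to_alpha(-5), "domain")
})

test_that("oligomer order assignment flags masses above an integer multiple", {
  expect_equal(oligomer_order(38000, 41700)$label, "1")
  expect_equal(oligomer_order(87905, 41700)$label, ">=2")
  o <- oligomer_order(41700, 41700)
  expect_equal(o$order, 1L)
  expect_false(o$at_least)
  expect_equal(oligomer_order(41700 * 2.04, 41700)$label, "2")
  expect_equal(oligomer_order(41700 * 2.06, 41700)$label, ">=2")
})

test_that("fitting noiseless model data recovers alpha to machine precision", {
  x <- c(0.2, 0.5, 1, 2, 4)
  p <- predict_p_at_least_one(1e-3, x, pop)
  fit <- fit_alpha(data.frame(ppr_star = x, p_active = p), pop)
  expect_equal(fit$alpha, 1e-3, tolerance = 1e-6)
  expect_equal(fit$molar_mass, alpha_to_mass(1e-3), tolerance = 1e-6)
})

test_that("fit errors on degenerate input", {
  expect_error(fit_alpha(data.frame(ppr_star = c(0, 1, 2),
                                    p_active = c(0, 0, 0)), pop),
               "degenerate")
  expect_error(fit_alpha(data.frame(ppr_star = c(1, 1, 1),
                                    p_active = c(0.5, 0.6, 0.7)), pop),
               "distinct")
  expect_error(fit_alpha(data.frame(ppr_star = 1, p_active = 0.5), pop),
               ">= 3")
})

test_that("fit recovers alpha from a noisy series within 2 SE", {
  ser <- simulate_assay_series(assay_ppr_grid, alpha_to_mass(quad_alpha),
                               pop, noise_sd = 0.03, on = "p",
                               method = "closed_form", seed = 1)
  fit <- fit_alpha(ser, pop)
  expect_lt(abs(fit$alpha - quad_alpha), 2 * fit$alpha_se)
  # molar-mass SE propagates first order
  expect_equal(fit$molar_mass_se / fit$molar_mass,
               fit$alpha_se / fit$alpha, tolerance = 1e-10)
})

test_that("prediction band straddles the fitted curve and widens the CI", {
  ser <- simulate_assay_series(assay_ppr_grid, 41700, pop,
                               noise_sd = 0.03, on = "p",
                               method = "closed_form", seed = 5)
  fit <- fit_alpha(ser, pop)
  pr <- predict(fit, data.frame(x = c(0.5, 1, 2)))
  expect_true(all(pr$lwr <= pr$p & pr$p <= pr$upr))
  expect_true(all(pr$upr - pr$lwr > 0))
})
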