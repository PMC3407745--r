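test_that("city generation is deterministic and respects its configuration", {
  cfg <- city_config(extent = 12000, n_radial = 6, n_ring = 1,
                     block_grid = 10)
  a <- generate_city(cfg, seed = 7)
  b <- generate_city(cfg, seed = 7)
  expect_identical(a$roads, b$roads)
  expect_identical(a$blocks, b$blocks)
  gx <- seq(0, 12000, length.out = 20)
  expect_identical(a$altitude_field(gx, rev(gx)), b$altitude_field(gx, rev(gx)))

  # geometry inside the extent, counts follow the representation rules
  expect_true(all(a$roads$x1 >= 0 & a$roads$x1 <= cfg$extent))
  expect_true(all(a$roads$y2 >= 0 & a$roads$y2 <= cfg$extent))
  expect_true(all(a$blocks$cx >= 0 & a$blocks$cx <= cfg$extent))
  expect_true(all(a$roads$vehicles_per_day >= 4000))
  expect_true(any(a$roads$vehicles_per_day > 10000))
  expect_true(any(a$roads$vehicles_per_day <= 10000))
  expect_true(all(a$blocks$area > 0))
  expect_equal(nrow(a$blocks), 100)
  # radial roads are split into 5 segments each; rings into 20
  expect_equal(nrow(a$roads), 6 * 5 + 1 * 20)

  expect_error(generate_city(city_config(extent = -1)), "extent")
})

test_that("block population density decays from the centre", {
  city <- generate_city(city_config(block_grid = 23), seed = 11)  # 529 blocks
  d <- sqrt((city$blocks$cx - city$centre[1])^2 +
              (city$blocks$cy - city$centre[2])^2)
  dens <- city$blocks$residents / city$blocks$area
  expect_lt(cor(dens, d, method = "spearman"), 0)
})

test_that("latent surface reduces to the exact linear form without noise", {
  city <- fixture_city()
  # all betas zero: constant surface exp(beta0)
  flat <- simulate_true_surface(
    city, surface_params(beta0 = log(45), betas = c(dist_centre = 0),
                         noise_sd = 0, drift = list(shift = 0, traffic_coef = 0)),
    seed = 1)
  pts <- data.frame(x = c(4000, 15000, 26000), y = c(21000, 9000, 14000))
  expect_equal(exp(surface_log_no2(flat, pts)), rep(45, 3))
  expect_equal(surface_log_no2(flat, pts, campaign = 2),
               surface_log_no2(flat, pts, campaign = 1))

  # hand evaluation of the linear form at one point
  pars <- surface_params(noise_sd = 0)
  surf <- simulate_true_surface(city, pars, seed = 1)
  pt <- assemble_predictor_table(pts, city)
  want <- pars$beta0 +
    as.numeric(as.matrix(pt[, lur_predictors()]) %*% pars$betas)
  expect_equal(surface_log_no2(surf, pts, predictor_table = pt), want)

  expect_error(
    simulate_true_surface(city, surface_params(betas = c(bogus = 1))),
    "unknown predictor")
})

test_that("spatial noise correlation decays with distance", {
  city <- fixture_city()
  surf <- simulate_true_surface(
    city, surface_params(noise_sd = 0.1, noise_range = 1000), seed = 5)
  set.seed(42)
  n <- 10000
  base <- data.frame(x = runif(n, 3000, 27000), y = runif(n, 3000, 27000))
  near <- base; far <- base
  ang <- runif(n, 0, 2 * pi)
  near$x <- base$x + 200 * cos(ang);  near$y <- base$y + 200 * sin(ang)
  far$x <- base$x + 2000 * cos(ang); far$y <- base$y + 2000 * sin(ang)
  z0 <- surf$noise_fun(base$x, base$y)
  r_near <- cor(z0, surf$noise_fun(near$x, near$y))
  r_far <- cor(z0, surf$noise_fun(far$x, far$y))
  expect_gt(r_near, r_far)
  expect_gt(r_near, 0.5)
})

test_that("campaign simulation honours sampler, drift, floor and conservation", {
  city <- fixture_city()
  surf <- fixture_surface(noise_sd = 0)
  sites <- fixture_sites()
  ident <- sampler_spec("ident")
  c1 <- simulate_campaign(city, surf, sites, periods = 3, sampler = ident,
                          campaign_index = 1, seed = 3,
                          period_effects = c(0, 0, 0))
  truth <- exp(surface_log_no2(surf, sites, 1))
  expect_equal(c1$records$value,
               rep(truth, each = 3), tolerance = 1e-12)
  expect_equal(nrow(c1$records), nrow(sites) * 3)

  # negative drift lowers campaign-2 site means
  c2 <- simulate_campaign(city, surf, sites, periods = 3, sampler = ident,
                          campaign_index = 2, seed = 3,
                          period_effects = c(0, 0, 0))
  m1 <- site_period_mean(c1)$values$value
  m2 <- site_period_mean(c2)$values$value
  expect_gt(length(m1), 50)
  expect_lt(mean(m2), mean(m1))

  # conservation under missingness: records = sites*periods - missing cells
  cm <- simulate_campaign(city, surf, sites, periods = 3, sampler = ident,
                          campaign_index = 1, seed = 9,
                          missing_rate = 3 / 70)
  n_missing <- nrow(sites) * 3 - nrow(cm$records)
  expect_equal(length(site_period_mean(cm)$dropped), n_missing)

  # expected number of incomplete sites ~ rate * n_sites
  incomplete <- vapply(1:20, function(s) {
    cc <- simulate_campaign(city, surf, sites, periods = 3, sampler = ident,
                            campaign_index = 1, seed = s,
                            missing_rate = 3 / 70)
    length(site_period_mean(cc)$dropped)
  }, numeric(1))
  expect_gt(mean(incomplete), 1.5)
  expect_lt(mean(incomplete), 4.5)

  expect_error(
    simulate_campaign(city, surf, data.frame(site_id = "bad", x = -10, y = 10,
                                             site_type = "background"),
                      sampler = ident),
    "extent")
})

test_that("co-located pairs invert the calibration equation algebraically", {
  city <- fixture_city()
  surf <- fixture_surface(noise_sd = 0)
  sites <- fixture_sites()[1:27, ]
  ident <- sampler_spec("a")
  same <- simulate_colocated_pairs(sites, surf, ident, sampler_spec("b"),
                                   seed = 1)
  expect_equal(same$value_a, same$value_b)

  # sampler B distorted by the inverse affine map: regressing A on B
  # recovers slope 0.68 and intercept 13.53 exactly in the noiseless case
  bad <- sampler_spec("b", gain = 1 / 0.68, offset = -13.53 / 0.68)
  pr <- simulate_colocated_pairs(sites, surf, ident, bad, seed = 1)
  cal <- fit_calibration(data.frame(value_source = pr$value_b,
                                    value_target = pr$value_a))
  expect_equal(cal$slope, 0.68, tolerance = 1e-9)
  expect_equal(cal$intercept, 13.53, tolerance = 1e-6)

  expect_error(simulate_colocated_pairs(sites[1:2, ], surf, ident, ident),
               "3")
})

test_that("cohort generator enforces censoring, confounding control and nulls", {
  city <- fixture_city()
  surf <- fixture_surface()
  coh <- simulate_cohort(city, surf, n = 2000, horizon_years = 5.2, seed = 21)
  expect_lte(max(coh$followup_time), 5.2)
  expect_true(all(coh$followup_time > 0))
  expect_true(all(coh$followup_time[coh$event] <= 5.2))
  expect_error(simulate_cohort(city, surf, n = 50), "100")
  expect_error(simulate_cohort(city, surf, n = 200, horizon_years = -1),
               "positive")

  # confounding_strength = 0 decouples SEP from exposure
  coh0 <- simulate_cohort(city, surf, n = 20000, confounding_strength = 0,
                          seed = 22)
  expect_lt(abs(cor(coh0$no2_true, as.integer(coh0$sep))), 0.05)

  # null model: event proportions flat across exposure quintiles
  null <- simulate_cohort(city, surf, n = 10000, beta_no2_per10 = 0,
                          covariate_effects = list(),
                          confounding_strength = 0, seed = 23)
  q <- categorize_exposure(null$no2_true, "quintiles")
  p <- chisq.test(table(q, null$event))$p.value
  expect_gt(p, 0.001)
})
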