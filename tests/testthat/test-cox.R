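test_that("the toy partial likelihood has its closed-form root", {
  # times 1..4 all events, x = (1,0,1,0): score equation u^2 - u - 4 = 0
  # with u = exp(beta), so beta = log((1 + sqrt(17)) / 2)
  df <- data.frame(followup_time = 1:4, event = TRUE)
  x <- c(1, 0, 1, 0)
  fit <- cox_fit(df, exposure = x * 10, exposure_coding = "linear",
                 covariates = character(0))
  beta_hat <- unname(coef(fit)["no2_per10"])
  expect_equal(beta_hat, log((1 + sqrt(17)) / 2), tolerance = 1e-8)
  expect_equal(unname(fit$hr["no2_per10"]), (1 + sqrt(17)) / 2,
               tolerance = 1e-8)
  expect_equal(unname(fit$hr), unname(exp(fit$coefficients)),
               tolerance = 1e-12)

  oracle <- cox_grid_oracle(df$followup_time, df$event, x)
  expect_lt(abs(beta_hat - oracle), 1e-4)
})

test_that("the Cox fitter matches an established implementation", {
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.4)
    t_true <- rexp(n, 0.08 * exp(0.4 * x1 - 0.25 * x2))
    cens <- quantile(t_true, 0.7)   # ~30% administrative censoring
    time <- pmin(t_true, cens)
    ev <- t_true <= cens
    for (tie_method in c("efron", "breslow")) {
      # discretize times so ties genuinely occur
      tt <- if (s %% 2 == 0) ceiling(time * 2) / 2 else time
      df <- data.frame(followup_time = tt, event = ev,
                       x2 = factor(x2))
      fit <- cox_fit(df, exposure = x1 * 10, exposure_coding = "linear",
                     covariates = "x2", ties = tie_method)
      ref <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2,
                             data = data.frame(tt, ev, x2 = factor(x2)),
                             ties = tie_method)
      expect_lt(abs(unname(coef(fit)["no2_per10"]) - unname(coef(ref)["x1"])),
                1e-4)
      ci_ref <- exp(confint(ref))["x1", ]
      expect_equal(unname(fit$ci_lower["no2_per10"]), unname(ci_ref[1]),
                   tolerance = 1e-3)
      expect_equal(unname(fit$ci_upper["no2_per10"]), unname(ci_ref[2]),
                   tolerance = 1e-3)
    }
  }
})

test_that("null exposure gives HR near 1 and separation errors out", {
  set.seed(42)
  n <- 4000
  x <- rnorm(n, 45, 6)
  t_true <- rexp(n, 0.05)
  df <- data.frame(followup_time = pmin(t_true, 10), event = t_true <= 10)
  fit <- cox_fit(df, exposure = x, exposure_coding = "linear",
                 covariates = character(0))
  expect_lt(fit$ci_lower["no2_per10"], 1)
  expect_gt(fit$ci_upper["no2_per10"], 1)
  expect_equal(unname(fit$hr["no2_per10"]), 1, tolerance = 0.15)

  sep <- data.frame(followup_time = c(1, 2), event = c(TRUE, FALSE))
  expect_error(cox_fit(sep, exposure = c(10, 0), exposure_coding = "linear",
                       covariates = character(0)),
               "monotone|diverging")
  zero_ev <- data.frame(followup_time = c(1, 2, 3), event = FALSE)
  expect_error(cox_fit(zero_ev, exposure = c(1, 2, 3) * 10,
                       exposure_coding = "linear",
                       covariates = character(0)), "no events")
  const <- data.frame(followup_time = 1:5,
                      event = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_error(cox_fit(const, exposure = rep(45, 5),
                       exposure_coding = "linear",
                       covariates = character(0)), "degenerate|constant")
})

test_that("per-increment hazard ratios are log-linear in the increment", {
  set.seed(42)
  n <- 3000
  x <- rnorm(n, 45, 8)
  t_true <- rexp(n, 0.04 * exp(log(1.06) * x / 10))
  df <- data.frame(followup_time = pmin(t_true, 8), event = t_true <= 8)
  fit <- cox_fit(df, exposure = x, exposure_coding = "linear",
                 covariates = character(0))

  h10 <- hr_for_increment(fit, 10)
  h20 <- hr_for_increment(fit, 20)
  expect_equal(h20$hr, h10$hr^2, tolerance = 1e-10)
  expect_equal(hr_for_increment(fit, 0)$hr, 1)

  hiqr <- hr_for_increment(fit, iqr = TRUE)
  expect_equal(hiqr$delta,
               unname(diff(quantile(x, c(0.25, 0.75)))),
               tolerance = 1e-12)
  expect_equal(hiqr$hr, h10$hr^(hiqr$delta / 10), tolerance = 1e-10)
  expect_true(hiqr$lower <= hiqr$hr && hiqr$hr <= hiqr$upper)

  # rescaling the exposure rescales the coefficient, not per-delta HRs
  fit2 <- cox_fit(df, exposure = x * 2, exposure_coding = "linear",
                  covariates = character(0))
  expect_equal(unname(coef(fit2)), unname(coef(fit)) / 2, tolerance = 1e-6)
  expect_equal(hr_for_increment(fit2, 20)$hr, hr_for_increment(fit, 10)$hr,
               tolerance = 1e-6)

  qfit <- cox_fit(df, exposure = x, exposure_coding = "quintiles",
                  covariates = character(0))
  expect_error(hr_for_increment(qfit, 10), "linear")
})

test_that("rescaling printed hazard ratios reproduces per-IQR values", {
  # per-10 HR 1.06 with quartiles 42.6 and 49.8: per-IQR HR prints 1.04
  out <- scale_hr(1.06, delta_to = 49.8 - 42.6, lower = 1.04, upper = 1.08)
  expect_equal(round(out$hr, 2), 1.04)
  expect_true(out$lower < out$hr && out$hr < out$upper)
})

test_that("ordinal trend refit is consistent with the category fit", {
  city <- fixture_city()
  surf <- fixture_surface()
  coh <- simulate_cohort(city, surf, n = 8000, seed = 31)
  q <- categorize_exposure(coh$no2_true, "quintiles")
  tr <- trend_across_categories(coh, q)
  qfit <- cox_fit(coh, coh$no2_true, exposure_coding = "quintiles")
  # the ordinal slope points the same way as the top-category log-HR
  top <- qfit$coefficients[grep("quintiles_5", names(qfit$coefficients))]
  expect_equal(sign(tr$coef), sign(unname(top)))
  expect_error(trend_across_categories(coh, rep(1:2, length.out = nrow(coh))),
               "3")
})

test_that("a strongly increasing category hazard yields p_trend < 0.001", {
  set.seed(42)
  n <- 20000
  cat5 <- sample(1:5, n, TRUE)
  t_true <- rexp(n, 0.012 * exp(0.15 * (cat5 - 1)))
  df <- data.frame(followup_time = pmin(t_true, 5.2),
                   event = t_true <= 5.2)
  tr <- trend_across_categories(df, cat5, covariates = character(0))
  expect_lt(tr$p_trend, 0.001)
  expect_gt(tr$coef, 0)
})

test_that("shuffled exposure labels give a calibrated trend test", {
  city <- fixture_city()
  surf <- fixture_surface()
  coh <- simulate_cohort(city, surf, n = 400, beta_no2_per10 = 0,
                         covariate_effects = list(),
                         confounding_strength = 0, event_rate = 0.2,
                         seed = 33)
  set.seed(42)
  rej <- vapply(1:200, function(i) {
    q <- sample(categorize_exposure(coh$no2_true, "quintiles"))
    trend_across_categories(coh, q, covariates = character(0))$p_trend < 0.05
  }, logical(1))
  # 5% nominal level: binomial(200, 0.05) comfortably within [1, 22]
  expect_gte(sum(rej), 1)
  expect_lte(sum(rej), 22)
})
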