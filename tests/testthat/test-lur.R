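# exhaustive-subset oracle: among all predictor subsets whose OLS fit
# satisfies the sign rule and the p <= p_remove rule, the one with maximal
# adjusted R-squared
stepwise_oracle <- function(data, no2, candidates, p_remove = 0.20,
                            signs = expected_signs()) {
  y <- log(no2)
  best <- character(0)
  best_adj <- -Inf
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(candidates)))
  for (i in seq_len(nrow(subsets))) {
    S <- candidates[unlist(subsets[i, ])]
    if (length(S) == 0) {
      adj <- 0
    } else {
      df <- data[S]; df$.y <- y
      fit <- lm(.y ~ ., data = df)
      cf <- summary(fit)$coefficients
      ok <- TRUE
      for (p in S) {
        sl <- cf[make.names(p), 1]
        pv <- cf[make.names(p), 4]
        expct <- signs[p]
        if (!is.na(expct) && expct != "unconstrained" &&
            sign(sl) != ifelse(expct == "positive", 1, -1)) ok <- FALSE
        if (pv > p_remove) ok <- FALSE
      }
      if (!ok) next
      adj <- summary(fit)$adj.r.squared
    }
    if (adj > best_adj) {
      best_adj <- adj
      best <- S
    }
  }
  best
}

test_that("site annual means apply the completeness rule", {
  rec <- data.frame(site_id = "s1", period = 1:3, value = c(40, 50, 60))
  out <- site_period_mean(rec, 3)
  expect_equal(out$values$value, 50)

  # 70 sites, 3 with one missing period: 67 retained
  rec70 <- expand.grid(period = 1:3, site_id = sprintf("s%02d", 1:70))
  rec70$value <- 40 + seq_len(nrow(rec70)) %% 7
  drop_rows <- paste(rec70$site_id, rec70$period) %in%
    c("s05 2", "s21 1", "s66 3")
  out70 <- site_period_mean(rec70[!drop_rows, ], 3)
  expect_equal(nrow(out70$values), 67)
  expect_setequal(out70$dropped, c("s05", "s21", "s66"))

  # single required period passes values through
  one <- site_period_mean(data.frame(site_id = "a", period = 1, value = 42), 1)
  expect_equal(one$values$value, 42)

  empty <- site_period_mean(data.frame(site_id = character(0),
                                       period = integer(0),
                                       value = numeric(0)))
  expect_equal(nrow(empty$values), 0)
})

test_that("univariate screening returns closed-form OLS slopes", {
  tab <- data.frame(a = c(0, 1, 2), b = c(1, 1, 1))
  # ln(y) = 1.5 * a exactly
  out <- univariate_screen(tab, exp(1.5 * tab$a), predictors = c("a", "b"))
  expect_equal(out$slope[out$predictor == "a"], 1.5)
  expect_true(out$constant[out$predictor == "b"])
  expect_true(is.na(out$slope[out$predictor == "b"]))

  # constant response: zero slope for any predictor
  out2 <- univariate_screen(data.frame(a = c(1, 5, 9)), rep(45, 3),
                            predictors = "a")
  expect_equal(out2$slope, 0)

  # binary 0/1 regressor is handled like any numeric column
  set.seed(42)
  g <- rep(0:1, each = 10)
  y <- exp(0.2 + 0.5 * g + rnorm(20, 0, 0.01))
  out3 <- univariate_screen(data.frame(g = g), y, predictors = "g")
  expect_equal(out3$slope, 0.5, tolerance = 0.02)
})

test_that("backward stepwise removes noise and matches the all-subsets oracle", {
  for (s in 1:5) {
    dat <- random_design(80, 3, seed = s)
    set.seed(s + 100)
    y <- 1 + 0.5 * dat$v1 - 0.3 * dat$v2 + rnorm(80, 0, 0.3)
    fit <- lur_fit(dat, exp(y), predictors = c("v1", "v2", "v3"))
    expect_false("v3" %in% fit$selected)
    oracle <- stepwise_oracle(dat, exp(y), c("v1", "v2", "v3"))
    expect_setequal(fit$selected, oracle)
  }
})

test_that("a single informative predictor with the right sign is retained", {
  set.seed(42)
  x <- runif(40, 0, 5000)
  y <- 4 - 1e-4 * x + rnorm(40, 0, 0.05)
  dat <- data.frame(dist_centre = x)
  fit <- lur_fit(dat, exp(y), predictors = "dist_centre")
  expect_equal(fit$selected, "dist_centre")
  expect_lt(fit$coefficients[["dist_centre"]], 0)
})

test_that("the coordinate pairing rule keeps the weak coordinate", {
  set.seed(42)
  n <- 80
  dat <- data.frame(x_coord = runif(n, 0, 30000),
                    y_coord = runif(n, 0, 30000))
  y <- 3 + 2e-5 * dat$x_coord + rnorm(n, 0, 0.1)  # y_coord pure noise
  fit <- lur_fit(dat, exp(y), predictors = c("x_coord", "y_coord"))
  pv <- fit$p_values
  expect_lt(pv[["x_coord"]], 0.20)
  expect_true(all(c("x_coord", "y_coord") %in% fit$selected))
})

test_that("noiseless log-linear campaigns are recovered exactly", {
  city <- fixture_city()
  pars <- surface_params(noise_sd = 0)
  surf <- simulate_true_surface(city, pars, seed = 1)
  sites <- fixture_sites()
  camp <- simulate_campaign(city, surf, sites, periods = 3,
                            sampler = sampler_spec("ident"),
                            campaign_index = 1, seed = 1,
                            period_effects = c(0, 0, 0))
  means <- site_period_mean(camp, 3)
  pt <- fixture_site_predictors()
  rows <- match(means$values$site_id, pt$id)
  fit <- lur_fit(pt[rows, , drop = FALSE], means$values$value)
  active <- names(pars$betas)[pars$betas != 0]
  expect_setequal(fit$selected, active)
  expect_equal(fit$coefficients[["(Intercept)"]], pars$beta0,
               tolerance = 1e-6)
  for (p in active) {
    expect_equal(fit$coefficients[[p]], unname(pars$betas[p]),
                 tolerance = 1e-6)
  }
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_lt(fit$rmse_log, 1e-8)
})

test_that("with no constraints and p_remove = 1 the full OLS fit is returned", {
  dat <- random_design(50, 4, seed = 9)
  set.seed(10)
  y <- 2 + 0.3 * dat$v1 + rnorm(50, 0.2)
  fit <- lur_fit(dat, exp(y), predictors = names(dat), p_remove = 1)
  expect_setequal(fit$selected, names(dat))
  full <- lm(y ~ ., data = dat)
  expect_equal(unname(fit$coefficients),
               unname(coef(full)[c("(Intercept)", paste0(fit$selected))]),
               tolerance = 1e-10)
  expect_equal(length(fit$trace), 0)
})

test_that("no retained constrained coefficient contradicts its expected sign", {
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    dat <- data.frame(
      dist_centre = runif(n, 0, 20000),
      altitude = runif(n, 0, 120),
      traffic_density_150 = pmax(rnorm(n, 10, 15), 0),
      hi_road_len_150 = pmax(rnorm(n, 50, 100), 0))
    y <- 3.8 + rnorm(n, 0, 0.2)  # pure noise response
    fit <- suppressWarnings(lur_fit(dat, exp(y), predictors = names(dat)))
    for (p in fit$selected) {
      expct <- expected_signs()[p]
      if (expct == "positive") expect_gt(fit$coefficients[[p]], 0)
      if (expct == "negative") expect_lt(fit$coefficients[[p]], 0)
    }
    # adjusted R2 of the final model cannot exceed the full model's R2
    df_full <- dat; df_full$.y <- y
    expect_lte(fit$adjusted_r2, summary(lm(.y ~ ., df_full))$r.squared + 1e-12)
  }
})

test_that("LUR predictions are the exponentiated linear form", {
  int_only <- structure(list(coefficients = c("(Intercept)" = log(45)),
                             selected = character(0)), class = "lur")
  expect_equal(predict(int_only, data.frame(x = 1:3)), rep(45, 3))

  m <- structure(list(coefficients = c("(Intercept)" = 3.5,
                                       dist_centre = -2e-5),
                      selected = "dist_centre"), class = "lur")
  expect_equal(predict(m, data.frame(dist_centre = 10000)), exp(3.3))
  # moving a negatively-signed predictor up lowers the prediction
  expect_lt(predict(m, data.frame(dist_centre = 12000)),
            predict(m, data.frame(dist_centre = 10000)))
  expect_error(predict(m, data.frame(altitude = 1)), "dist_centre")
})
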