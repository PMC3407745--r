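#' Default configuration for the synthetic city
#'
#' A radial city on a 30 km square: population density decays from the
#' centre, radial arterials and ring roads carry traffic counts that fall
#' off towards the suburbs, census blocks are a regular grid with about 470
#' residents on average, and altitude rises gently towards the north-east
#' with smooth local relief.
#'
#' @param extent side of the square study area (m).
#' @param n_radial number of radial arterial roads.
#' @param n_ring number of ring roads.
#' @param block_grid blocks per side (total blocks = `block_grid`^2).
#' @param mean_residents average residents per block.
#' @param pop_decay_range e-folding distance (m) of the population-density
#'   decay from the centre.
#' @param green_frac fraction of blocks adjacent to green urban areas.
#' @return Named list of configuration values.
#' @export
city_config <- function(extent = 30000, n_radial = 8, n_ring = 2,
                        block_grid = 40, mean_residents = 470,
                        pop_decay_range = 9000, green_frac = 0.2) {
  if (extent <= 0) stop("`extent` must be positive")
  if (block_grid < 2) stop("`block_grid` must be at least 2")
  list(extent = extent, n_radial = n_radial, n_ring = n_ring,
       block_grid = block_grid, mean_residents = mean_residents,
       pop_decay_range = pop_decay_range, green_frac = green_frac)
}

#' Generate a synthetic radial city
#'
#' Builds the full geographic scene: road segments with daily vehicle counts
#' (only roads above 4,000 vehicles/day are represented; counts decay with
#' distance from the centre so that both high-traffic (>10,000) and
#' moderate roads exist), a grid of census blocks whose resident counts
#' decay exponentially from the centre, a smooth altitude field, and the
#' city centre.
#'
#' @param config list from [city_config()].
#' @param seed integer seed; the scene is a pure function of
#'   `(config, seed)`.
#' @return Object of class `city_scene`.
#' @export
generate_city <- function(config = city_config(), seed = 1) {
  if (config$extent <= 0) stop("`extent` must be positive")
  set.seed(seed)
  ext <- config$extent
  ctr <- c(ext / 2, ext / 2)

  ## --- roads -------------------------------------------------------------
  n_seg_per_radial <- 5L
  roads <- list()
  rmax <- 0.48 * ext
  for (k in seq_len(config$n_radial)) {
    ang <- 2 * pi * (k - 1) / config$n_radial + 0.15
    radii <- seq(0.02 * ext, rmax, length.out = n_seg_per_radial + 1)
    for (s in seq_len(n_seg_per_radial)) {
      mid <- (radii[s] + radii[s + 1]) / 2
      # counts fall from ~45k near the centre to ~4.5k at the edge
      veh <- round(45000 * exp(-mid / (0.21 * ext)) * exp(rnorm(1, 0, 0.08)))
      veh <- max(veh, 4100)
      roads[[length(roads) + 1]] <- c(
        ctr[1] + radii[s] * cos(ang), ctr[2] + radii[s] * sin(ang),
        ctr[1] + radii[s + 1] * cos(ang), ctr[2] + radii[s + 1] * sin(ang),
        veh)
    }
  }
  n_ring_edges <- 20L
  for (k in seq_len(config$n_ring)) {
    rr <- rmax * k / (config$n_ring + 0.5)
    veh_ring <- round(28000 * exp(-rr / (0.25 * ext)))
    angs <- seq(0, 2 * pi, length.out = n_ring_edges + 1)
    for (s in seq_len(n_ring_edges)) {
      veh <- max(round(veh_ring * exp(rnorm(1, 0, 0.06))), 4100)
      roads[[length(roads) + 1]] <- c(
        ctr[1] + rr * cos(angs[s]), ctr[2] + rr * sin(angs[s]),
        ctr[1] + rr * cos(angs[s + 1]), ctr[2] + rr * sin(angs[s + 1]),
        veh)
    }
  }
  roads <- as.data.frame(do.call(rbind, roads))
  names(roads) <- c("x1", "y1", "x2", "y2", "vehicles_per_day")
  roads$id <- seq_len(nrow(roads))

  ## --- census blocks -----------------------------------------------------
  g <- config$block_grid
  side <- ext / g
  cx <- rep((seq_len(g) - 0.5) * side, times = g)
  cy <- rep((seq_len(g) - 0.5) * side, each = g)
  d_ctr <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2)
  dens_shape <- exp(-d_ctr / config$pop_decay_range)
  # strong block-to-block heterogeneity around the radial trend, as in real
  # census geographies (mean-one lognormal dispersion)
  hetero <- exp(rnorm(g * g, -0.5 * 0.7^2, 0.7))
  lambda <- config$mean_residents * dens_shape / mean(dens_shape) * hetero
  residents <- rpois(g * g, lambda)
  green <- runif(g * g) < config$green_frac

  ## altitude: mild SW-NE gradient (sea to hills) plus smooth relief
  altitude_field <- local({
    e <- ext
    function(x, y) {
      20 + 60 * (x + y) / (2 * e) +
        18 * sin(2.3 * pi * x / e) * cos(1.7 * pi * y / e) +
        12 * sin(3.1 * pi * y / e)
    }
  })

  blocks <- data.frame(
    id = seq_len(g * g),
    cx = cx, cy = cy,
    residents = residents,
    area = rep(side^2, g * g),
    altitude = altitude_field(cx, cy),
    green_adjacent = green
  )
  half <- side / 2
  block_polygons <- lapply(seq_len(g * g), function(i) {
    list(x = c(cx[i] - half, cx[i] + half, cx[i] + half, cx[i] - half),
         y = c(cy[i] - half, cy[i] - half, cy[i] + half, cy[i] + half))
  })

  structure(
    list(extent = ext, centre = ctr, roads = roads, blocks = blocks,
         block_polygons = block_polygons, altitude_field = altitude_field,
         grid = list(g = g, side = side), config = config, seed = seed),
    class = "city_scene")
}

#' @export
print.city_scene <- function(x, ...) {
  cat("Synthetic city scene\n")
  cat(sprintf("  extent: %.0f m square, centre (%.0f, %.0f)\n",
              x$extent, x$centre[1], x$centre[2]))
  cat(sprintf("  roads: %d segments (%d high-traffic >10,000 veh/day)\n",
              nrow(x$roads), sum(x$roads$vehicles_per_day > 10000)))
  cat(sprintf("  census blocks: %d, mean residents %.0f\n",
              nrow(x$blocks), mean(x$blocks$residents)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Gaussian random field with exponential covariance, grid + bilinear interp
## ---------------------------------------------------------------------------

.simulate_grf <- function(extent, sd, range, ngrid = 31) {
  gx <- seq(0, extent, length.out = ngrid)
  gy <- seq(0, extent, length.out = ngrid)
  pts <- expand.grid(x = gx, y = gy)
  d <- as.matrix(stats::dist(pts))
  cov <- sd^2 * exp(-d / range)
  diag(cov) <- diag(cov) + 1e-10
  L <- chol(cov)
  z <- as.numeric(crossprod(L, stats::rnorm(nrow(pts))))
  zmat <- matrix(z, nrow = ngrid, ncol = ngrid)  # [ix, iy]
  local({
    gx <- gx; gy <- gy; zmat <- zmat; ngrid <- ngrid
    function(x, y) {
      x <- pmin(pmax(x, gx[1]), gx[ngrid])
      y <- pmin(pmax(y, gy[1]), gy[ngrid])
      hx <- gx[2] - gx[1]
      hy <- gy[2] - gy[1]
      ix <- pmin(pmax(floor((x - gx[1]) / hx) + 1, 1), ngrid - 1)
      iy <- pmin(pmax(floor((y - gy[1]) / hy) + 1, 1), ngrid - 1)
      tx <- (x - gx[ix]) / hx
      ty <- (y - gy[iy]) / hy
      z11 <- zmat[cbind(ix, iy)]
      z21 <- zmat[cbind(ix + 1, iy)]
      z12 <- zmat[cbind(ix, iy + 1)]
      z22 <- zmat[cbind(ix + 1, iy + 1)]
      (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
        (1 - tx) * ty * z12 + tx * ty * z22
    }
  })
}

#' Default parameters of the latent log-linear concentration surface
#'
#' Coefficients are on the log \eqn{\mu g/m^3} scale per predictor unit.
#' The active set (distance to centre, altitude, both coordinates, traffic
#' density in the 150 m buffer, distance to the nearest high-traffic road)
#' mirrors the structure of an urban NO2 field: concentrations fall away
#' from the centre, with altitude and with distance from major roads, and
#' rise with nearby traffic. Spatial noise has sd 0.1 (log scale) and an
#' exponential correlation range of 1,000 m. The between-campaign drift is
#' a small overall decline plus an extra decline where traffic density is
#' high.
#'
#' @param beta0 intercept, log scale.
#' @param betas named numeric vector of coefficients; names must belong to
#'   [lur_predictors()]. Missing predictors get coefficient 0.
#' @param noise_sd sd of the spatially correlated noise, log scale.
#' @param noise_range exponential correlation range (m).
#' @param drift list with `shift` (additive log-scale change applied in
#'   campaign 2) and `traffic_coef` (additional log change per unit traffic
#'   density in campaign 2).
#' @return Named list of surface parameters.
#' @export
surface_params <- function(beta0 = 4.40,
                           betas = c(x_coord = 8e-6, y_coord = -8e-6,
                                     dist_centre = -2.5e-5,
                                     altitude = -3.5e-3,
                                     traffic_density_150 = 3e-3,
                                     dist_hi_road = -8e-5),
                           noise_sd = 0.1, noise_range = 1000,
                           drift = list(shift = -0.06, traffic_coef = -8e-4)) {
  unknown <- setdiff(names(betas), lur_predictors())
  if (length(unknown)) {
    stop("unknown predictor(s) in `betas`: ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(lur_predictors())), lur_predictors())
  full[names(betas)] <- betas
  list(beta0 = beta0, betas = full, noise_sd = noise_sd,
       noise_range = noise_range, drift = drift)
}

#' Realize the latent concentration surface over a city
#'
#' Realizes the spatially correlated Gaussian noise field and packages the
#' log-linear surface: at any point, the log concentration equals
#' `beta0 + sum(betas * predictors(point)) + noise(point)`. Campaign 2
#' additionally applies the drift terms.
#'
#' @param city a `city_scene`.
#' @param params list from [surface_params()].
#' @param seed integer seed for the noise field.
#' @return Object of class `no2_surface`.
#' @export
simulate_true_surface <- function(city, params = surface_params(), seed = 1) {
  unknown <- setdiff(names(params$betas), lur_predictors())
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  noise_fun <- if (params$noise_sd > 0) {
    .simulate_grf(city$extent, params$noise_sd, params$noise_range)
  } else {
    function(x, y) rep(0, length(x))
  }
  structure(
    list(city = city, beta0 = params$beta0, betas = params$betas,
         noise_sd = params$noise_sd, noise_range = params$noise_range,
         drift = params$drift, noise_fun = noise_fun, seed = seed),
    class = "no2_surface")
}

#' True log-scale surface value at points
#'
#' @param surface a `no2_surface`.
#' @param points data frame with `x`, `y` columns.
#' @param campaign 1 or 2; campaign 2 applies the drift terms.
#' @param predictor_table optional precomputed result of
#'   [assemble_predictor_table()] for `points` (saves recomputation).
#' @return Numeric vector of log concentrations.
#' @export
surface_log_no2 <- function(surface, points, campaign = 1,
                            predictor_table = NULL) {
  stopifnot(campaign %in% c(1, 2))
  pt <- predictor_table %||% assemble_predictor_table(points, surface$city)
  X <- as.matrix(pt[, lur_predictors(), drop = FALSE])
  lg <- surface$beta0 + as.numeric(X %*% surface$betas) +
    surface$noise_fun(points$x, points$y)
  if (campaign == 2) {
    lg <- lg + surface$drift$shift +
      surface$drift$traffic_coef * pt$traffic_density_150
  }
  lg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Passive sampler specification
#'
#' @param name sampler label.
#' @param gain multiplicative response distortion (> 0).
#' @param offset additive distortion (\eqn{\mu g/m^3}).
#' @param noise_sd measurement noise sd (\eqn{\mu g/m^3}).
#' @return Object of class `sampler_spec`.
#' @export
sampler_spec <- function(name, gain = 1, offset = 0, noise_sd = 0) {
  if (gain <= 0) stop("`gain` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(name = name, gain = gain, offset = offset,
                 noise_sd = noise_sd), class = "sampler_spec")
}

#' Draw a monitoring-site list over the city
#'
#' Background sites are placed away from high-traffic roads (more than
#' 300 m), traffic sites within 10-80 m of one, and regional-background
#' sites in the outer belt of the city. Site ids are stable so that
#' campaigns share locations by id.
#'
#' @param city a `city_scene`.
#' @param n_background,n_traffic,n_regional site counts by type.
#' @param seed integer seed.
#' @param id_start first numeric id (for extending an existing list with
#'   new sites under fresh ids).
#' @return data frame `site_id, x, y, site_type`.
#' @export
make_site_list <- function(city, n_background = 44, n_traffic = 23,
                           n_regional = 0, seed = 1, id_start = 1) {
  set.seed(seed)
  ext <- city$extent
  ctr <- city$centre
  hi <- city$roads[city$roads$vehicles_per_day > 10000, , drop = FALSE]
  draw_background <- function(n, rmin, rmax, dmin) {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      r <- sqrt(runif(1, rmin^2, rmax^2))
      a <- runif(1, 0, 2 * pi)
      x <- ctr[1] + r * cos(a)
      y <- ctr[2] + r * sin(a)
      if (x < 0 || x > ext || y < 0 || y > ext) next
      d <- tryCatch(distance_to_nearest_major_road(c(x, y), city$roads),
                    error = function(e) Inf)
      if (d > dmin) out <- rbind(out, c(x, y))
    }
    out
  }
  bg <- draw_background(n_background, 0.02 * ext, 0.42 * ext, 300)
  tr <- matrix(NA_real_, 0, 2)
  while (nrow(tr) < n_traffic) {
    i <- sample.int(nrow(hi), 1)
    t <- runif(1)
    px <- hi$x1[i] + t * (hi$x2[i] - hi$x1[i])
    py <- hi$y1[i] + t * (hi$y2[i] - hi$y1[i])
    nx <- -(hi$y2[i] - hi$y1[i]); ny <- hi$x2[i] - hi$x1[i]
    nl <- sqrt(nx^2 + ny^2)
    off <- runif(1, 10, 80) * sample(c(-1, 1), 1)
    x <- px + off * nx / nl
    y <- py + off * ny / nl
    if (x < 0 || x > ext || y < 0 || y > ext) next
    tr <- rbind(tr, c(x, y))
  }
  rg <- if (n_regional > 0) {
    draw_background(n_regional, 0.42 * ext, 0.49 * ext, 1000)
  } else matrix(NA_real_, 0, 2)
  xy <- rbind(bg, tr, rg)
  data.frame(
    site_id = sprintf("site%03d", seq(id_start, length.out = nrow(xy))),
    x = xy[, 1], y = xy[, 2],
    site_type = rep(c("background", "traffic", "regional_background"),
                    c(nrow(bg), nrow(tr), nrow(rg))),
    stringsAsFactors = FALSE)
}

#' Simulate one measurement campaign
#'
#' Produces one value per site and one-week period. On the concentration
#' scale, a measurement is
#' `gain * (true + period_effect + noise) + offset`, truncated below at the
#' concentration floor of 1 \eqn{\mu g/m^3}; campaign 2 applies the
#' surface's drift. An optional missingness mechanism removes random
#' site-periods: each site independently loses one randomly chosen period
#' with probability `missing_rate` (so the expected number of incomplete
#' sites is `missing_rate * n_sites`).
#'
#' @param city a `city_scene`.
#' @param surface a `no2_surface`.
#' @param site_list data frame from [make_site_list()].
#' @param periods number of one-week periods (default 3).
#' @param sampler a [sampler_spec()].
#' @param campaign_index 1 or 2.
#' @param seed integer seed.
#' @param period_effects additive seasonal offsets per period
#'   (\eqn{\mu g/m^3}); default a symmetric seasonal pattern summing to 0.
#' @param missing_rate per-site probability of an incomplete record.
#' @return Object of class `measurement_set` with elements `campaign`,
#'   `sampler`, `records` (site_id, period, value), `sites`.
#' @export
simulate_campaign <- function(city, surface, site_list, periods = 3,
                              sampler = sampler_spec("reference"),
                              campaign_index = 1, seed = 1,
                              period_effects = NULL, missing_rate = 0) {
  stopifnot(periods >= 1, campaign_index %in% c(1, 2))
  if (any(site_list$x < 0 | site_list$x > city$extent |
          site_list$y < 0 | site_list$y > city$extent)) {
    stop("site outside the city extent")
  }
  set.seed(seed)
  if (is.null(period_effects)) {
    period_effects <- if (periods == 1) 0 else {
      pe <- seq(3, -3, length.out = periods)
      pe - mean(pe)
    }
  }
  stopifnot(length(period_effects) == periods)
  true_conc <- exp(surface_log_no2(surface, site_list, campaign_index))
  n <- nrow(site_list)
  rec <- expand.grid(period = seq_len(periods), row = seq_len(n))
  value <- sampler$gain *
    (true_conc[rec$row] + period_effects[rec$period] +
       stats::rnorm(nrow(rec), 0, sampler$noise_sd)) + sampler$offset
  value <- pmax(value, 1)
  records <- data.frame(site_id = site_list$site_id[rec$row],
                        period = rec$period, value = value,
                        stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    lose <- stats::runif(n) < missing_rate
    if (any(lose)) {
      drop_period <- sample.int(periods, sum(lose), replace = TRUE)
      key_drop <- paste(site_list$site_id[lose], drop_period)
      records <- records[!(paste(records$site_id, records$period) %in%
                             key_drop), , drop = FALSE]
    }
  }
  structure(list(campaign = campaign_index, sampler = sampler$name,
                 records = records, sites = site_list),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement campaign %d (%s sampler): %d records at %d sites\n",
              x$campaign, x$sampler, nrow(x$records), nrow(x$sites)))
  invisible(x)
}

#' Simulate co-located dual-sampler pairs
#'
#' At each site both samplers measure the same underlying true
#' concentration with independent noise, mimicking the co-location exercise
#' used to derive a between-sampler correction factor.
#'
#' @param sites data frame of at least 3 sites (`site_id, x, y`).
#' @param surface a `no2_surface`.
#' @param sampler_a,sampler_b two [sampler_spec()] objects.
#' @param campaign campaign whose surface the pairs sample (default 2, when
#'   co-location historically happened).
#' @param seed integer seed.
#' @return data frame `site_id, value_a, value_b`.
#' @export
simulate_colocated_pairs <- function(sites, surface, sampler_a, sampler_b,
                                     campaign = 2, seed = 1) {
  if (nrow(sites) < 3) {
    stop("at least 3 co-located sites are required (calibration unidentifiable)")
  }
  set.seed(seed)
  true_conc <- exp(surface_log_no2(surface, sites, campaign))
  n <- length(true_conc)
  va <- sampler_a$gain * (true_conc + stats::rnorm(n, 0, sampler_a$noise_sd)) +
    sampler_a$offset
  vb <- sampler_b$gain * (true_conc + stats::rnorm(n, 0, sampler_b$noise_sd)) +
    sampler_b$offset
  data.frame(site_id = sites$site_id, value_a = pmax(va, 1),
             value_b = pmax(vb, 1), stringsAsFactors = FALSE)
}

#' Default covariate log-hazard effects for the synthetic cohort
#'
#' Age dominates mortality; male gender carries a substantial excess;
#' the remaining socio-demographic covariates have modest effects; lower
#' area socioeconomic position raises mortality slightly.
#'
#' @return Named list: one named numeric vector of log-HRs per covariate
#'   (levels absent from a vector are at the reference, log-HR 0).
#' @export
cohort_effects <- function() {
  list(
    age_band = c("65-74" = 1.1, "75-80" = 1.9),
    gender = c("M" = 0.45),
    marital_status = c("single" = 0.15, "widowed" = 0.20),
    place_of_birth = c("elsewhere" = 0.05),
    education = c("medium" = -0.10, "high" = -0.20),
    occupation = c("retired" = 0.10, "other" = 0.15),
    sep = c("2" = -0.04, "3" = -0.08, "4" = -0.12, "5" = -0.16)
  )
}

#' Simulate the cohort with known exposure-mortality structure
#'
#' Addresses are drawn with probability proportional to block residents
#' (so the population concentrates towards the centre), true NO2 at each
#' address comes from the latent surface, and the 5-level area
#' socioeconomic category is built from a latent score
#' `confounding_strength * scale(NO2) + N(0,1)` cut at quintiles — a
#' positive association between socioeconomic position and exposure.
#' Survival times follow an exponential model whose log hazard is linear
#' in NO2 (per 10 \eqn{\mu g/m^3}) and in the categorical covariates, with
#' administrative censoring at the horizon. The baseline hazard is solved
#' numerically so the expected event fraction matches `event_rate`.
#'
#' @param city a `city_scene`.
#' @param surface a `no2_surface`.
#' @param n cohort size (>= 100).
#' @param beta_no2_per10 true log hazard ratio per 10 \eqn{\mu g/m^3}.
#' @param covariate_effects list as from [cohort_effects()].
#' @param confounding_strength weight of NO2 in the latent SEP score
#'   (0 = no confounding).
#' @param horizon_years administrative censoring horizon.
#' @param event_rate target overall event fraction.
#' @param campaign campaign surface used for the true exposure.
#' @param seed integer seed.
#' @return data frame of class `cohort_table` with one row per subject and
#'   attribute `ground_truth` holding the generating parameters.
#' @export
simulate_cohort <- function(city, surface, n = 20000,
                            beta_no2_per10 = log(1.06),
                            covariate_effects = cohort_effects(),
                            confounding_strength = 0.8,
                            horizon_years = 5.2, event_rate = 0.065,
                            campaign = 1, seed = 1) {
  if (n < 100) stop("`n` must be at least 100")
  if (horizon_years <= 0) stop("`horizon_years` must be positive")
  set.seed(seed)
  bl <- city$blocks
  pick <- sample.int(nrow(bl), n, replace = TRUE, prob = pmax(bl$residents, 0.01))
  half <- sqrt(bl$area[1]) / 2
  x <- bl$cx[pick] + stats::runif(n, -half, half)
  y <- bl$cy[pick] + stats::runif(n, -half, half)
  pts <- data.frame(x = x, y = y)
  no2 <- exp(surface_log_no2(surface, pts, campaign))

  sep_score <- confounding_strength * as.numeric(scale(no2)) + stats::rnorm(n)
  sep <- cut(sep_score, breaks = stats::quantile(sep_score, 0:5 / 5),
             labels = 1:5, include.lowest = TRUE)

  covs <- data.frame(
    age_band = sample(c("45-64", "65-74", "75-80"), n, TRUE,
                      prob = c(0.611, 0.273, 0.116)),
    gender = sample(c("F", "M"), n, TRUE, prob = c(0.553, 0.447)),
    marital_status = sample(c("married", "single", "widowed"), n, TRUE,
                            prob = c(0.65, 0.20, 0.15)),
    place_of_birth = sample(c("city", "elsewhere"), n, TRUE,
                            prob = c(0.6, 0.4)),
    education = sample(c("low", "medium", "high"), n, TRUE,
                       prob = c(0.40, 0.35, 0.25)),
    occupation = sample(c("employed", "retired", "other"), n, TRUE,
                        prob = c(0.50, 0.35, 0.15)),
    stringsAsFactors = FALSE)
  covs$sep <- as.character(sep)

  lp <- beta_no2_per10 * no2 / 10
  for (v in names(covariate_effects)) {
    eff <- covariate_effects[[v]]
    m <- match(covs[[v]], names(eff))
    lp <- lp + ifelse(is.na(m), 0, eff[m])
  }
  # baseline hazard giving the target expected event fraction
  f <- function(log_l0) {
    mean(1 - exp(-exp(log_l0 + lp) * horizon_years)) - event_rate
  }
  log_l0 <- stats::uniroot(f, c(-15, 2))$root
  lambda <- exp(log_l0 + lp)
  t_event <- stats::rexp(n, rate = lambda)
  followup <- pmin(t_event, horizon_years)
  event <- t_event <= horizon_years

  out <- data.frame(id = seq_len(n), x = x, y = y, no2_true = no2,
                    covs, followup_time = followup, event = event,
                    stringsAsFactors = FALSE)
  attr(out, "ground_truth") <- list(
    beta_no2_per10 = beta_no2_per10, covariate_effects = covariate_effects,
    confounding_strength = confounding_strength,
    horizon_years = horizon_years, log_baseline_hazard = log_l0,
    campaign = campaign, seed = seed)
  class(out) <- c("cohort_table", "data.frame")
  out
}
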