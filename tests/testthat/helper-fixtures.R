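# Shared fixtures, memoised so expensive objects are built once per run.
.fx <- new.env(parent = emptyenv())

fixture_city <- function() {
  if (is.null(.fx$city)) .fx$city <- generate_city(city_config(), seed = 42)
  .fx$city
}

fixture_surface <- function(noise_sd = 0.1) {
  key <- paste0("surface_", noise_sd)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_true_surface(
      fixture_city(), surface_params(noise_sd = noise_sd), seed = 42)
  }
  .fx[[key]]
}

fixture_sites <- function(n_background = 47, n_traffic = 23) {
  key <- paste0("sites_", n_background, "_", n_traffic)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- make_site_list(fixture_city(), n_background, n_traffic,
                                 seed = 42)
  }
  .fx[[key]]
}

fixture_site_predictors <- function(sites = fixture_sites()) {
  key <- paste0("pt_", nrow(sites))
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- assemble_predictor_table(
      data.frame(id = sites$site_id, x = sites$x, y = sites$y),
      fixture_city())
  }
  .fx[[key]]
}

# random predictor-like design for regression-level tests (no geography)
random_design <- function(n, p, seed) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(X) <- paste0("v", seq_len(p))
  X
}

# grid-search oracle for the partial likelihood of a single binary covariate
cox_grid_oracle <- function(time, status, x, grid = seq(-3, 3, by = 1e-5)) {
  ll <- vapply(grid, function(b) {
    eta <- b * x
    w <- exp(eta)
    sum(vapply(which(status), function(i) {
      eta[i] - log(sum(w[time >= time[i]]))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

# numeric-integration oracle for segment-in-disc length
chord_length_oracle <- function(x1, y1, x2, y2, cx, cy, r, m = 200001) {
  t <- seq(0, 1, length.out = m)
  px <- x1 + t * (x2 - x1)
  py <- y1 + t * (y2 - y1)
  inside <- (px - cx)^2 + (py - cy)^2 <= r^2
  ds <- sqrt((x2 - x1)^2 + (y2 - y1)^2) / (m - 1)
  sum(inside) * ds
}
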