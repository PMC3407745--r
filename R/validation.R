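#' Leave-one-out cross-validation of a LUR model
#'
#' Keeps the selected-predictor set fixed and, for each site in turn,
#' refits the OLS coefficients on the remaining sites, predicts the
#' held-out site, and back-transforms to the concentration scale. Summary
#' statistics (R-squared, adjusted R-squared of the measured-vs-predicted
#' regression, and RMSE) are computed on the original \eqn{\mu g/m^3}
#' scale.
#'
#' @param predictor_table data frame of predictor columns; when the first
#'   argument is a `lur` fit, table, response and selection are taken from
#'   it.
#' @param no2 measured concentrations.
#' @param selected predictor names held fixed across folds.
#' @param log model `log(no2)` and back-transform predictions with `exp`
#'   (default); `log = FALSE` runs the cross-validation on the raw scale.
#' @param reselect if `TRUE`, rerun the full stepwise selection inside
#'   every fold instead of refitting coefficients only.
#' @param ... passed to [lur_fit()] when `reselect = TRUE`.
#' @return Object of class `cv_result`: per-site `measured`/`predicted`,
#'   log-scale LOO residuals (`loo_residuals`), `r2`, `adjusted_r2`,
#'   `rmse`.
#' @export
loocv <- function(predictor_table, no2 = NULL, selected = NULL, log = TRUE,
                  reselect = FALSE, ...) {
  if (inherits(predictor_table, "lur")) {
    fit <- predictor_table
    no2 <- exp(fit$log_no2)
    selected <- fit$selected
    predictor_table <- fit$data
  }
  n <- length(no2)
  if (n < length(selected) + 2) stop("too few sites for leave-one-out")
  y <- if (log) base::log(no2) else no2
  X <- cbind(`(Intercept)` = 1,
             as.matrix(predictor_table[, selected, drop = FALSE]))
  pred_link <- numeric(n)
  for (i in seq_len(n)) {
    if (reselect) {
      f <- lur_fit(predictor_table[-i, , drop = FALSE], no2[-i], ...)
      pred_link[i] <- base::log(predict(f, predictor_table[i, , drop = FALSE]))
    } else {
      Xi <- X[-i, , drop = FALSE]
      qri <- qr(Xi)
      if (qri$rank < ncol(Xi)) {
        stop(sprintf("rank-deficient design when leaving out site %d", i))
      }
      beta <- qr.coef(qri, y[-i])
      pred_link[i] <- sum(X[i, ] * beta)
    }
  }
  predicted <- if (log) exp(pred_link) else pred_link
  measured <- no2
  r2 <- if (stats::sd(predicted) > 0) stats::cor(measured, predicted)^2 else NA_real_
  structure(list(
    measured = measured, predicted = predicted,
    loo_residuals = y - pred_link,
    r2 = r2,
    adjusted_r2 = if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(mean((measured - predicted)^2)),
    n = n), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("Leave-one-out cross-validation (%d sites)\n",
                     "  R2 = %.3f, adjusted R2 = %.3f, RMSE = %.3f\n"),
              x$n, x$r2, x$adjusted_r2, x$rmse))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from the OLS regression (with
#' intercept) of predictor `k` on the other selected predictors. Perfect
#' collinearity yields an infinite VIF rather than an error.
#'
#' @param predictor_table data frame of predictor columns (or a `lur` fit).
#' @param selected at least two predictor names.
#' @return List: `vif` (named vector), `mean_vif`, `max_vif`.
#' @export
vif <- function(predictor_table, selected = NULL) {
  if (inherits(predictor_table, "lur")) {
    selected <- predictor_table$selected
    predictor_table <- predictor_table$data
  }
  if (length(selected) < 2) stop("VIF needs at least 2 selected predictors")
  X <- as.matrix(predictor_table[, selected, drop = FALSE])
  v <- vapply(seq_along(selected), function(k) {
    yk <- X[, k]
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), yk)
    tss <- sum((yk - mean(yk))^2)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(v) <- selected
  list(vif = v, mean_vif = mean(v), max_vif = max(v))
}

#' Cook's distances of the LUR regression
#'
#' Classical Cook's D of each site in the OLS fit of log concentration on
#' the selected predictors; sites at leverage 1 get `NaN` and are flagged.
#'
#' @inheritParams loocv
#' @param threshold sites with D above it are reported (default 0.3).
#' @return List: `d` (per-site distances), `max_d`, `above_threshold`
#'   (indices), `undefined` (indices with leverage 1).
#' @export
cooks_distance <- function(predictor_table, no2 = NULL, selected = NULL,
                           log = TRUE, threshold = 0.3) {
  if (inherits(predictor_table, "lur")) {
    fit0 <- predictor_table
    no2 <- exp(fit0$log_no2)
    selected <- fit0$selected
    predictor_table <- fit0$data
  }
  y <- if (log) base::log(no2) else no2
  df <- predictor_table[, selected, drop = FALSE]
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  h <- stats::hatvalues(fit)
  d <- stats::cooks.distance(fit)
  # a numerically perfect fit has no influential points (0/0 above)
  if (sum(stats::residuals(fit)^2) <=
        1e-16 * max(sum((y - mean(y))^2), .Machine$double.eps)) {
    d[] <- 0
  }
  undefined <- which(h >= 1 - 1e-12)
  d[undefined] <- NaN
  list(d = as.numeric(d), max_d = max(d, na.rm = TRUE),
       above_threshold = which(!is.nan(d) & d > threshold),
       undefined = as.integer(undefined))
}

## spatial weight matrix from a specification
.moran_weights <- function(coords, weight_spec) {
  n <- nrow(coords)
  if (is.matrix(weight_spec)) {
    W <- weight_spec
  } else {
    d <- as.matrix(stats::dist(coords))
    type <- weight_spec$type %||% "idw"
    W <- switch(type,
      idw = {
        w <- 1 / d
        diag(w) <- 0
        w[!is.finite(w)] <- 0
        w
      },
      knn = {
        k <- weight_spec$k %||% 5
        w <- matrix(0, n, n)
        for (i in seq_len(n)) {
          nb <- order(d[i, ])[2:(k + 1)]
          w[i, nb] <- 1
        }
        w
      },
      band = {
        dmax <- weight_spec$dmax
        w <- (d > 0 & d <= dmax) * 1
        w
      },
      stop("unknown weight type: ", type))
  }
  diag(W) <- 0
  rs <- rowSums(W)
  if (isTRUE(weight_spec$row_standardize %||% TRUE)) {
    nz <- rs > 0
    W[nz, ] <- W[nz, ] / rs[nz]
  }
  W
}

#' Moran's I of regression residuals
#'
#' Computes \deqn{I = \frac{n}{\sum_{ij} w_{ij}}
#' \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}} with centred residuals
#' `z`, zero diagonal weights, and tests spatial autocorrelation either by
#' random permutation of the residuals over the locations (default;
#' two-sided p computed as `(count_extreme + 1) / (n_perm + 1)` with
#' extremeness measured as distance from the permutation expectation
#' `-1/(n-1)`) or by the normal approximation under the randomization
#' assumption.
#'
#' @param residuals numeric vector (non-constant).
#' @param coords two-column matrix or data frame of site coordinates.
#' @param weight_spec list describing the weights: `type` one of `"idw"`
#'   (inverse distance, default), `"knn"` (binary k-nearest, field `k`),
#'   `"band"` (binary within distance `dmax`); `row_standardize` (default
#'   `TRUE`). A full weight matrix may be supplied instead.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param method `"permutation"` (default) or `"analytic"`.
#' @return Object of class `moran_result`: `I`, `expected`
#'   (`-1/(n-1)`), `p`, `n_perm`, `method`, and `sd` for the analytic
#'   method.
#' @export
morans_i <- function(residuals, coords, weight_spec = list(type = "idw"),
                     n_perm = 999, seed = 1,
                     method = c("permutation", "analytic")) {
  method <- match.arg(method)
  n <- length(residuals)
  if (n < 4) stop("Moran's I needs at least 4 observations")
  if (stats::sd(residuals) == 0) stop("residuals have zero variance")
  coords <- as.matrix(coords)
  W <- .moran_weights(coords, weight_spec)
  s0 <- sum(W)
  if (sum(W != 0) < 2) stop("fewer than 2 nonzero weights")
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  I_obs <- (n / s0) * as.numeric(t(z) %*% W %*% z) / denom
  e_i <- -1 / (n - 1)

  if (method == "permutation") {
    set.seed(seed)
    Z <- vapply(seq_len(n_perm), function(j) z[sample.int(n)],
                numeric(n))
    I_perm <- (n / s0) * colSums(Z * (W %*% Z)) / denom
    extreme <- sum(abs(I_perm - e_i) >= abs(I_obs - e_i) - 1e-12)
    p <- (extreme + 1) / (n_perm + 1)
    structure(list(I = I_obs, expected = e_i, p = p, n_perm = n_perm,
                   method = "permutation", seed = seed),
              class = "moran_result")
  } else {
    s1 <- 0.5 * sum((W + t(W))^2)
    s2 <- sum((rowSums(W) + colSums(W))^2)
    b2 <- n * sum(z^4) / denom^2
    var_i <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - e_i^2
    zstat <- (I_obs - e_i) / sqrt(var_i)
    p <- 2 * stats::pnorm(-abs(zstat))
    structure(list(I = I_obs, expected = e_i, p = p, sd = sqrt(var_i),
                   z = zstat, method = "analytic"),
              class = "moran_result")
  }
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f), p = %.3f [%s]\n",
              x$I, x$expected, x$p, x$method))
  invisible(x)
}

#' Cross-period transportability of a LUR model
#'
#' Predicts another campaign's site concentrations with a fitted model and
#' correlates predictions with that campaign's measured annual values,
#' overall and by site type.
#'
#' @param model a `lur` fit from one campaign.
#' @param measurements_b data frame `site_id`, `value` of the other
#'   campaign's annual site means.
#' @param predictor_table_b predictor rows for the same sites (same order,
#'   or carrying a `site_id`/`id` column to match on).
#' @param site_types optional character vector of site types (same order
#'   as `measurements_b`).
#' @return List: `r` (overall Pearson), `r_by_type` (named), `table`
#'   (site_id, measured, predicted, site_type).
#' @export
cross_period_predict <- function(model, measurements_b, predictor_table_b,
                                 site_types = NULL) {
  if (nrow(measurements_b) < 3) stop("fewer than 3 overlapping sites")
  pred <- predict(model, predictor_table_b)
  tab <- data.frame(site_id = measurements_b$site_id,
                    measured = measurements_b$value,
                    predicted = pred,
                    site_type = site_types %||% NA_character_,
                    stringsAsFactors = FALSE)
  r <- stats::cor(tab$measured, tab$predicted)
  r_by_type <- if (!is.null(site_types)) {
    vapply(split(tab, tab$site_type), function(g) {
      if (nrow(g) >= 3) stats::cor(g$measured, g$predicted) else NA_real_
    }, numeric(1))
  } else NULL
  list(r = r, r_by_type = r_by_type, table = tab)
}
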