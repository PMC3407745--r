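#' Per-site annual means with the completeness rule
#'
#' The annual value of a site is the arithmetic mean of its per-period
#' measurements; sites missing any of the required periods are dropped and
#' reported, so that only sites with complete coverage enter the model.
#'
#' @param records a `measurement_set` or a data frame with columns
#'   `site_id`, `period`, `value`.
#' @param required_periods periods 1..`required_periods` must all be
#'   present for a site to be retained.
#' @return List: `values` (data frame `site_id`, `value`), `dropped`
#'   (character vector of incomplete site ids).
#' @export
site_period_mean <- function(records, required_periods = 3) {
  stopifnot(required_periods >= 1)
  if (inherits(records, "measurement_set")) records <- records$records
  if (nrow(records) == 0) {
    return(list(values = data.frame(site_id = character(0),
                                    value = numeric(0)),
                dropped = character(0)))
  }
  need <- seq_len(required_periods)
  sites <- unique(records$site_id)
  ok <- vapply(sites, function(s) {
    all(need %in% records$period[records$site_id == s])
  }, logical(1))
  keep <- records[records$site_id %in% sites[ok] &
                    records$period %in% need, , drop = FALSE]
  vals <- tapply(keep$value, keep$site_id, mean)
  list(values = data.frame(site_id = sites[ok],
                           value = as.numeric(vals[sites[ok]]),
                           stringsAsFactors = FALSE),
       dropped = sites[!ok])
}

#' Univariate screening of predictors against log concentration
#'
#' One simple OLS of `log(no2)` on each predictor; constant predictors are
#' flagged with `NA` slope.
#'
#' @param predictor_table data frame of predictor columns.
#' @param no2 positive concentrations (logged internally) unless
#'   `log = FALSE`, in which case the response is used as given.
#' @param predictors columns to screen (default all of [lur_predictors()]
#'   present in the table).
#' @param log take the log of `no2` first.
#' @return data frame `predictor`, `slope`, `p_value`, `constant`.
#' @export
univariate_screen <- function(predictor_table, no2,
                              predictors = intersect(lur_predictors(),
                                                     names(predictor_table)),
                              log = TRUE) {
  if (nrow(predictor_table) < 3) stop("at least 3 sites are required")
  if (log) {
    if (any(no2 <= 0)) stop("concentrations must be strictly positive")
    y <- base::log(no2)
  } else y <- no2
  rows <- lapply(predictors, function(p) {
    x <- predictor_table[[p]]
    if (stats::sd(x) == 0) {
      return(data.frame(predictor = p, slope = NA_real_,
                        p_value = NA_real_, constant = TRUE))
    }
    if (stats::sd(y) == 0) {
      return(data.frame(predictor = p, slope = 0,
                        p_value = 1, constant = FALSE))
    }
    fit <- stats::lm(y ~ x)
    cf <- suppressWarnings(summary(fit))$coefficients
    data.frame(predictor = p, slope = cf[2, 1], p_value = cf[2, 4],
               constant = FALSE)
  })
  do.call(rbind, rows)
}

## p-values of an OLS fit, robust to a numerically perfect fit: with zero
## residual variance a negligible coefficient gets p = 1 (so it is
## eliminated) and a real one p = 0.
.ols_pvalues <- function(fit, y) {
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- cf[, 4]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-16 * max(tss, .Machine$double.eps) || any(!is.finite(p))) {
    # numerically perfect fit: t statistics are noise; judge terms by the
    # magnitude of their standardized contribution instead
    co <- cf[, 1]
    scale_y <- max(stats::sd(y), .Machine$double.eps)
    X <- stats::model.matrix(fit)
    sx <- apply(X, 2, stats::sd)
    sx[1] <- 1  # intercept
    negligible <- abs(co * sx) <= 1e-8 * scale_y
    p <- ifelse(negligible, 1, 0)
    names(p) <- rownames(cf)
  }
  p
}

.coef_negligible <- function(coefs, x_sds, y_sd) {
  abs(coefs * x_sds) <= 1e-8 * max(y_sd, .Machine$double.eps)
}

#' Fit a land use regression model by sign-constrained backward stepwise
#' elimination
#'
#' Starting from the full OLS model of log concentration on all candidate
#' predictors, predictors are eliminated one by one: first any
#' sign-constrained predictor whose current coefficient contradicts its
#' expected direction (the violator with the largest p-value goes first),
#' then the predictor with the largest p-value above `p_remove`. The two
#' geographic coordinates are paired: while one coordinate holds a p-value
#' at or below `p_remove`, the other may not be eliminated. Ties in
#' p-values are broken by removing the predictor that comes later in the
#' canonical schema ordering. The final model is the OLS fit on the
#' retained predictors.
#'
#' @param predictor_table data frame containing the candidate columns.
#' @param no2 positive concentrations; modelled as `log(no2)`.
#' @param predictors candidate predictor names (canonical order taken from
#'   [lur_predictors()] where applicable).
#' @param signs named character vector of expected directions
#'   (`"positive"`, `"negative"`, `"unconstrained"`); default
#'   [expected_signs()].
#' @param p_remove elimination threshold (predictors with p above it are
#'   dropped; default 0.20).
#' @param sign_rule `"iterative"` re-checks signs at every step (default);
#'   `"prescreen"` instead drops, once and before the stepwise loop,
#'   constrained predictors whose univariate slope already has the wrong
#'   sign.
#' @param campaign optional campaign label carried into the object.
#' @return Object of class `lur`.
#' @export
lur_fit <- function(predictor_table, no2,
                    predictors = intersect(lur_predictors(),
                                           names(predictor_table)),
                    signs = expected_signs(), p_remove = 0.20,
                    sign_rule = c("iterative", "prescreen"),
                    campaign = NULL) {
  sign_rule <- match.arg(sign_rule)
  if (any(no2 <= 0)) stop("concentrations must be strictly positive")
  y <- log(no2)
  n <- length(y)
  if (n <= length(predictors) + 1) {
    stop("need more sites than candidate predictors + 1")
  }
  # canonical ordering for tie-breaks
  canon <- c(intersect(lur_predictors(), predictors),
             setdiff(predictors, lur_predictors()))
  current <- canon
  signs <- signs[intersect(names(signs), canon)]
  x_sds <- vapply(predictor_table[canon], stats::sd, numeric(1))
  y_sd <- stats::sd(y)
  trace <- list()

  # constant columns carry no information and would make the design singular
  for (p in canon[x_sds == 0]) {
    trace[[length(trace) + 1]] <- list(predictor = p, reason = "constant",
                                       p_value = NA_real_)
    current <- setdiff(current, p)
  }

  if (sign_rule == "prescreen") {
    uni <- univariate_screen(predictor_table, no2, predictors = current)
    for (p in current) {
      expct <- signs[p]
      if (is.na(expct) || expct == "unconstrained") next
      sl <- uni$slope[uni$predictor == p]
      if (!is.na(sl) && sign(sl) != ifelse(expct == "positive", 1, -1)) {
        trace[[length(trace) + 1]] <- list(predictor = p,
                                           reason = "sign_prescreen",
                                           p_value = uni$p_value[uni$predictor == p])
        current <- setdiff(current, p)
      }
    }
  }

  fit_current <- function(set) {
    if (length(set) == 0) return(stats::lm(y ~ 1))
    df <- predictor_table[set]
    df$.y <- y
    fit <- stats::lm(.y ~ ., data = df)
    if (any(is.na(stats::coef(fit)))) {
      stop("design matrix is rank-deficient for predictors: ",
           paste(set, collapse = ", "))
    }
    fit
  }

  repeat {
    if (length(current) == 0) break
    fit <- fit_current(current)
    co <- stats::coef(fit)[-1]
    names(co) <- current
    pv <- .ols_pvalues(fit, y)[-1]
    names(pv) <- current
    negl <- .coef_negligible(co, x_sds[current], y_sd)

    removed <- FALSE
    if (sign_rule == "iterative") {
      viol <- vapply(current, function(p) {
        expct <- signs[p]
        if (is.na(expct) || expct == "unconstrained") return(FALSE)
        if (negl[p]) return(FALSE)
        sign(co[p]) != ifelse(expct == "positive", 1, -1)
      }, logical(1))
      if (any(viol)) {
        cand <- current[viol]
        worst <- cand[order(-pv[cand], -match(cand, canon))][1]
        trace[[length(trace) + 1]] <- list(predictor = worst,
                                           reason = "sign_violation",
                                           p_value = unname(pv[worst]))
        current <- setdiff(current, worst)
        removed <- TRUE
      }
    }
    if (!removed) {
      protected <- character(0)
      if (all(c("x_coord", "y_coord") %in% current)) {
        if (pv["y_coord"] <= p_remove) protected <- c(protected, "x_coord")
        if (pv["x_coord"] <= p_remove) protected <- c(protected, "y_coord")
      }
      removable <- setdiff(current[pv[current] > p_remove], protected)
      if (length(removable)) {
        worst <- removable[order(-pv[removable], -match(removable, canon))][1]
        trace[[length(trace) + 1]] <- list(predictor = worst,
                                           reason = "p_value",
                                           p_value = unname(pv[worst]))
        current <- setdiff(current, worst)
        removed <- TRUE
      }
    }
    if (!removed) break
  }

  if (length(current) == 0) {
    warning("no predictor survived elimination; returning intercept-only model")
  }
  fit <- fit_current(current)
  sm <- suppressWarnings(summary(fit))
  res <- stats::residuals(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", current)
  pvals <- .ols_pvalues(fit, y)
  names(pvals) <- c("(Intercept)", current)

  structure(list(
    coefficients = coefs,
    p_values = pvals,
    selected = current,
    r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared,
    rmse_log = sqrt(mean(res^2)),
    n_sites = n,
    signs = signs,
    p_remove = p_remove,
    sign_rule = sign_rule,
    campaign = campaign,
    trace = trace,
    data = predictor_table,
    log_no2 = y,
    lm_fit = fit
  ), class = "lur")
}

#' @export
print.lur <- function(x, digits = 4, ...) {
  cat("Land use regression model")
  if (!is.null(x$campaign)) cat(sprintf(" (campaign %s)", x$campaign))
  cat(sprintf("\n  %d sites, %d selected predictors\n",
              x$n_sites, length(x$selected)))
  print(round(x$coefficients, 7))
  cat(sprintf("  adjusted R2 = %.3f, log-scale RMSE = %.3f\n",
              x$adjusted_r2, x$rmse_log))
  invisible(x)
}

#' @export
summary.lur <- function(object, ...) {
  tab <- data.frame(coefficient = object$coefficients,
                    p_value = object$p_values)
  steps <- if (length(object$trace)) {
    data.frame(
      step = seq_along(object$trace),
      predictor = vapply(object$trace, `[[`, character(1), "predictor"),
      reason = vapply(object$trace, `[[`, character(1), "reason"),
      p_value = vapply(object$trace, function(s) {
        v <- s$p_value
        if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
      }, numeric(1)))
  } else NULL
  out <- list(coefficients = tab, eliminations = steps,
              r2 = object$r2, adjusted_r2 = object$adjusted_r2,
              rmse_log = object$rmse_log, n_sites = object$n_sites)
  class(out) <- "summary.lur"
  out
}

#' @export
print.summary.lur <- function(x, ...) {
  cat(sprintf("LUR model on %d sites\n\nCoefficients (log scale):\n",
              x$n_sites))
  print(x$coefficients)
  if (!is.null(x$eliminations)) {
    cat("\nElimination steps:\n")
    print(x$eliminations, row.names = FALSE)
  }
  cat(sprintf("\nR2 = %.4f, adjusted R2 = %.4f, log RMSE = %.4f\n",
              x$r2, x$adjusted_r2, x$rmse_log))
  invisible(x)
}

#' @export
coef.lur <- function(object, ...) object$coefficients

#' @export
residuals.lur <- function(object, ...) stats::residuals(object$lm_fit)

#' @export
fitted.lur <- function(object, ...) exp(stats::fitted(object$lm_fit))

#' Predict concentrations from a LUR model
#'
#' @param object a `lur` fit.
#' @param newdata data frame containing every selected predictor column.
#' @param ... unused.
#' @return Predicted concentrations, `exp(intercept + sum(coef * value))`,
#'   strictly positive.
#' @export
predict.lur <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$selected, names(newdata))
  if (length(missing_cols)) {
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  }
  lp <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (p in object$selected) {
    lp <- lp + object$coefficients[[p]] * newdata[[p]]
  }
  exp(lp)
}

#' @export
plot.lur <- function(x, ...) {
  obs <- exp(x$log_no2)
  pred <- fitted(x)
  plot(pred, obs, xlab = expression(predicted ~ NO[2] ~ (mu * g / m^3)),
       ylab = expression(measured ~ NO[2] ~ (mu * g / m^3)),
       main = "LUR fit", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
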