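## ---------------------------------------------------------------------------
## Self-contained Cox proportional-hazards fitter (Newton-Raphson on the
## log partial likelihood, Efron or Breslow tie handling).
## ---------------------------------------------------------------------------

.revcumsum <- function(v) rev(cumsum(rev(v)))

## Log partial likelihood, score and information at beta.
.coxpl_eval <- function(beta, X, time, status, ties) {
  n <- nrow(X)
  p <- ncol(X)
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ev_times <- unique(time[status])           # time already sorted ascending
  G <- length(ev_times)
  pos <- match(ev_times, time)               # first at-risk index per group
  c0 <- .revcumsum(w)
  C1 <- apply(X * w, 2, .revcumsum)
  if (p == 1) C1 <- matrix(C1, ncol = 1)
  npair <- p * (p + 1) / 2
  # column-major upper-triangle order, matching `upper.tri(..., diag = TRUE)`
  pair_j <- integer(npair); pair_k <- integer(npair)
  idx <- 1L
  for (k in seq_len(p)) for (j in seq_len(k)) {
    pair_j[idx] <- j; pair_k[idx] <- k; idx <- idx + 1L
  }
  S2g <- matrix(0, G, npair)
  for (q in seq_len(npair)) {
    S2g[, q] <- .revcumsum(w * X[, pair_j[q]] * X[, pair_k[q]])[pos]
  }
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  Msym <- matrix(0, p, p)
  ut <- upper.tri(Msym, diag = TRUE)
  for (g in seq_len(G)) {
    rows <- which(time == ev_times[g] & status)
    d <- length(rows)
    Xd <- X[rows, , drop = FALSE]
    wd <- w[rows]
    S0 <- c0[pos[g]]
    S1 <- C1[pos[g], ]
    Msym[ut] <- S2g[g, ]
    S2 <- Msym + t(Msym) - diag(diag(Msym), p)
    ll <- ll + sum(eta[rows])
    grad <- grad + colSums(Xd)
    if (ties == "efron" && d > 1) {
      S0d <- sum(wd)
      S1d <- colSums(Xd * wd)
      S2d <- crossprod(Xd * sqrt(wd))
      for (l in 0:(d - 1)) {
        f <- l / d
        phi0 <- S0 - f * S0d
        mu <- (S1 - f * S1d) / phi0
        ll <- ll - log(phi0)
        grad <- grad - mu
        info <- info + (S2 - f * S2d) / phi0 - tcrossprod(mu)
      }
    } else {
      mu <- S1 / S0
      ll <- ll - d * log(S0)
      grad <- grad - d * mu
      info <- info + d * (S2 / S0 - tcrossprod(mu))
    }
  }
  list(loglik = ll, grad = grad, info = info)
}

.coxpl_newton <- function(X, time, status, ties = "efron", max_iter = 30) {
  p <- ncol(X)
  if (sum(status) == 0) stop("no events in the data")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate design: constant column(s) ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  ord <- order(time)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]
  ss <- as.logical(status)[ord]
  beta <- numeric(p)
  ev <- .coxpl_eval(beta, Xs, ts, ss, ties)
  ll <- ev$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) {
      stop("singular information matrix (collinear terms?)")
    })
    damp <- 1
    repeat {
      beta_new <- beta + damp * step
      ev_new <- .coxpl_eval(beta_new, Xs, ts, ss, ties)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ll - 1e-9) break
      damp <- damp / 2
      if (damp < 1e-10) stop("step halving failed; likelihood not improving")
    }
    if (any(abs(beta_new) > 20)) {
      stop("monotone likelihood: estimate diverging (|coef| > 20); ",
           "a term may perfectly separate events")
    }
    rel <- abs(ev_new$loglik - ll) / (abs(ll) + 0.1)
    step_size <- max(abs(damp * step))
    beta <- beta_new
    ll <- ev_new$loglik
    ev <- ev_new
    # a vanishing score alone is not enough: under a monotone likelihood the
    # score decays while the estimate still drifts, so also require the
    # Newton step to have become small
    if ((max(abs(ev$grad)) < 1e-8 && step_size < 1e-6) || rel < 1e-10) {
      converged <- TRUE
      break
    }
  }
  vcov <- solve(ev$info)
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov = vcov, loglik = ll, score = ev$grad, iter = it,
       converged = converged)
}

## reference-coded model matrix: reference level of each categorical
## covariate is its most frequent level
.cox_design <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  df <- data[, covariates, drop = FALSE]
  for (v in covariates) {
    if (!is.numeric(df[[v]])) {
      f <- factor(df[[v]])
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      df[[v]] <- stats::relevel(f, ref = ref)
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Fit a Cox proportional-hazards model of mortality on NO2 exposure
#'
#' Maximizes the log partial likelihood by Newton-Raphson (Efron tie
#' correction by default; Breslow optional), adjusting for the cohort's
#' socio-demographic covariates as reference-coded indicators (reference =
#' most frequent level). The exposure enters as a linear per-10
#' \eqn{\mu g/m^3} term, as quintile indicators, or as the four fixed
#' concentration classes (reference = lowest group). Time scale is time on
#' study, with age adjusted as a covariate.
#'
#' @param data data frame with follow-up time and event columns plus the
#'   covariates.
#' @param exposure numeric exposure vector (\eqn{\mu g/m^3}), or the name
#'   of a column of `data`.
#' @param exposure_coding `"linear"`, `"quintiles"`, or `"fixed4"`.
#' @param covariates names of adjustment columns (default: the synthetic
#'   cohort's covariate set).
#' @param time,event column names of follow-up time (years) and the
#'   event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `coxpl` with coefficients, covariance, hazard
#'   ratios and 95\% Wald confidence intervals.
#' @export
cox_fit <- function(data, exposure, exposure_coding = c("linear", "quintiles", "fixed4"),
                    covariates = c("age_band", "gender", "marital_status",
                                   "place_of_birth", "education",
                                   "occupation", "sep"),
                    time = "followup_time", event = "event",
                    ties = c("efron", "breslow")) {
  exposure_coding <- match.arg(exposure_coding)
  ties <- match.arg(ties)
  if (is.character(exposure) && length(exposure) == 1) {
    exposure <- data[[exposure]]
  }
  stopifnot(length(exposure) == nrow(data))
  categories <- NULL
  if (exposure_coding == "linear") {
    Xe <- matrix(exposure / 10, ncol = 1,
                 dimnames = list(NULL, "no2_per10"))
  } else {
    scheme <- if (exposure_coding == "quintiles") "quintiles" else "fixed4"
    categories <- categorize_exposure(exposure, scheme)
    f <- factor(categories, levels = sort(unique(categories)))
    mm <- stats::model.matrix(~ f)
    Xe <- mm[, -1, drop = FALSE]
    colnames(Xe) <- paste0("no2_", exposure_coding, "_",
                           levels(f)[-1])
  }
  Xc <- .cox_design(data, covariates)
  X <- if (is.null(Xc)) Xe else cbind(Xe, Xc)
  fit <- .coxpl_newton(X, data[[time]], data[[event]], ties = ties)
  se <- sqrt(diag(fit$vcov))
  zq <- stats::qnorm(0.975)
  structure(list(
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    se = stats::setNames(se, names(fit$coefficients)),
    hr = exp(fit$coefficients),
    ci_lower = exp(fit$coefficients - zq * se),
    ci_upper = exp(fit$coefficients + zq * se),
    p_values = 2 * stats::pnorm(-abs(fit$coefficients / se)),
    loglik = fit$loglik,
    n_subjects = nrow(data),
    n_events = sum(data[[event]]),
    ties = ties,
    iter = fit$iter,
    converged = fit$converged,
    exposure_coding = exposure_coding,
    exposure_terms = colnames(Xe),
    exposure_values = exposure,
    categories = categories
  ), class = "coxpl")
}

#' @export
print.coxpl <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d subjects, %d events\n",
              x$ties, x$n_subjects, x$n_events))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci_lower, upper95 = x$ci_upper,
                    p = x$p_values)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.coxpl <- function(object, ...) {
  object
}

#' @export
coef.coxpl <- function(object, ...) object$coefficients

#' @export
vcov.coxpl <- function(object, ...) object$vcov

#' @export
confint.coxpl <- function(object, parm = NULL, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Hazard ratio per exposure increment
#'
#' For a fit with a linear per-10 \eqn{\mu g/m^3} exposure term, transforms
#' the coefficient and its Wald interval to an arbitrary increment:
#' `HR(delta) = exp(coef * delta / 10)`. With `iqr = TRUE` the increment
#' is the inter-quartile range (Q75 - Q25) of the analysis population's
#' exposure.
#'
#' @param fit a `coxpl` fit with `exposure_coding = "linear"`.
#' @param delta increment in \eqn{\mu g/m^3} (ignored when `iqr = TRUE`).
#' @param iqr use the exposure IQR as the increment.
#' @return List: `hr`, `lower`, `upper`, `delta`.
#' @export
hr_for_increment <- function(fit, delta = 10, iqr = FALSE) {
  if (fit$exposure_coding != "linear") {
    stop("fit has no linear exposure term")
  }
  if (iqr) {
    q <- stats::quantile(fit$exposure_values, c(0.25, 0.75), type = 7)
    delta <- unname(q[2] - q[1])
  }
  if (delta < 0) stop("`delta` must be non-negative")
  b <- fit$coefficients["no2_per10"]
  s <- fit$se["no2_per10"]
  zq <- stats::qnorm(0.975)
  list(hr = unname(exp(b * delta / 10)),
       lower = unname(exp((b - zq * s) * delta / 10)),
       upper = unname(exp((b + zq * s) * delta / 10)),
       delta = delta)
}

#' Rescale a printed hazard ratio to another exposure increment
#'
#' Pure log-linear arithmetic on reported values:
#' `HR_to = HR_from^(delta_to / delta_from)`, applied identically to the
#' confidence bounds. Used to check the internal consistency of hazard
#' ratios reported per 10 \eqn{\mu g/m^3} against those reported per IQR.
#'
#' @param hr hazard ratio (with optional `lower`, `upper` bounds).
#' @param delta_to target increment; `delta_from` the increment `hr`
#'   refers to.
#' @param lower,upper optional confidence bounds on the same scale.
#' @return List: `hr`, and bounds when supplied.
#' @export
scale_hr <- function(hr, delta_to, delta_from = 10,
                     lower = NULL, upper = NULL) {
  e <- delta_to / delta_from
  out <- list(hr = hr^e)
  if (!is.null(lower)) out$lower <- lower^e
  if (!is.null(upper)) out$upper <- upper^e
  out
}

#' Trend test across ordered exposure categories
#'
#' Refits the Cox model with the category dummies replaced by a single
#' ordinal score (0, 1, 2, ...); the trend p-value is the two-sided Wald
#' p of the score coefficient.
#'
#' @param data cohort data frame as in [cox_fit()].
#' @param categories ordered category labels (integers or ordered factor).
#' @param covariates,time,event,ties as in [cox_fit()].
#' @return List: `p_trend`, `coef`, `z`, `fit` (the `coxpl` object).
#' @export
trend_across_categories <- function(data, categories,
                                    covariates = c("age_band", "gender",
                                                   "marital_status",
                                                   "place_of_birth",
                                                   "education", "occupation",
                                                   "sep"),
                                    time = "followup_time", event = "event",
                                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  lev <- sort(unique(categories))
  if (length(lev) < 3) stop("at least 3 ordered categories are required")
  score <- match(categories, lev) - 1
  Xe <- matrix(score, ncol = 1, dimnames = list(NULL, "no2_score"))
  Xc <- .cox_design(data, covariates)
  X <- if (is.null(Xc)) Xe else cbind(Xe, Xc)
  fit <- .coxpl_newton(X, data[[time]], data[[event]], ties = ties)
  se <- sqrt(diag(fit$vcov))
  z <- fit$coefficients["no2_score"] / se[1]
  list(p_trend = unname(2 * stats::pnorm(-abs(z))),
       coef = unname(fit$coefficients["no2_score"]),
       z = unname(z), fit = fit)
}
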