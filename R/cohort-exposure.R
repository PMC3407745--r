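#' Assign modelled exposure to cohort addresses
#'
#' Exposure at an address is the LUR model prediction at that address's
#' predictor row. Subjects whose predictor rows contain missing values are
#' excluded and counted.
#'
#' @param model a `lur` fit.
#' @param cohort data frame with one row per subject (an `id` column is
#'   carried through).
#' @param predictor_table predictor rows for the addresses, same order as
#'   `cohort`.
#' @return List: `exposure` (numeric, `NA` for excluded subjects),
#'   `n_assigned`, `n_excluded`, `excluded` (row indices).
#' @export
assign_exposure <- function(model, cohort, predictor_table) {
  stopifnot(nrow(cohort) == nrow(predictor_table))
  need <- model$selected
  miss <- setdiff(need, names(predictor_table))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  }
  ok <- stats::complete.cases(predictor_table[, need, drop = FALSE])
  exposure <- rep(NA_real_, nrow(cohort))
  exposure[ok] <- predict(model, predictor_table[ok, , drop = FALSE])
  list(exposure = exposure, n_assigned = sum(ok), n_excluded = sum(!ok),
       excluded = which(!ok))
}

#' Categorize exposure into quintiles or fixed classes
#'
#' `"quintiles"` cuts at the 20/40/60/80 empirical percentiles (linear
#' interpolation), with values equal to a cutpoint assigned to the lower
#' group; `"fixed4"` uses the pre-specified intervals
#' \eqn{(-\infty,35], (35,45], (45,50], (50,\infty)} \eqn{\mu g/m^3}.
#'
#' @param values exposure values.
#' @param scheme `"quintiles"` or `"fixed4"`.
#' @return Integer vector of group labels (1-5 or 1-4).
#' @export
categorize_exposure <- function(values, scheme = c("quintiles", "fixed4")) {
  scheme <- match.arg(scheme)
  if (length(values) == 0) stop("empty input")
  if (scheme == "quintiles") {
    cuts <- stats::quantile(values, c(0.2, 0.4, 0.6, 0.8), type = 7)
    as.integer(cut(values, breaks = c(-Inf, cuts, Inf), right = TRUE))
  } else {
    as.integer(cut(values, breaks = c(-Inf, 35, 45, 50, Inf), right = TRUE))
  }
}

#' Exposure summary stratified by population characteristics
#'
#' Per-stratum n, mean, sd, quartiles (linear-interpolation quantiles),
#' minimum and maximum, with an overall row first.
#'
#' @param exposures numeric exposure per subject.
#' @param strata factor/character stratum label per subject (or a data
#'   frame of several stratifying columns, summarised one after another).
#' @return data frame with columns `stratum`, `n`, `mean`, `sd`, `q25`,
#'   `q50`, `q75`, `min`, `max`.
#' @export
stratified_summary <- function(exposures, strata) {
  one <- function(v, label) {
    if (length(v) == 0) {
      return(data.frame(stratum = label, n = 0L, mean = NA_real_,
                        sd = NA_real_, q25 = NA_real_, q50 = NA_real_,
                        q75 = NA_real_, min = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(stratum = label, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               q25 = q[[1]], q50 = q[[2]], q75 = q[[3]],
               min = min(v), max = max(v))
  }
  if (is.data.frame(strata)) {
    out <- one(exposures, "overall")
    for (col in names(strata)) {
      g <- split(exposures, strata[[col]])
      for (lev in names(g)) {
        out <- rbind(out, one(g[[lev]], paste(col, lev, sep = ":")))
      }
    }
    rownames(out) <- NULL
    return(out)
  }
  g <- split(exposures, strata)
  out <- do.call(rbind, c(list(one(exposures, "overall")),
                          lapply(names(g), function(l) one(g[[l]], l))))
  rownames(out) <- NULL
  out
}

#' Cuzick's test for trend across ordered groups
#'
#' Rank-based trend test with integer group scores: with pooled midranks
#' \eqn{R_i} and scores \eqn{s_j}, the statistic is
#' \eqn{T = \sum_j s_j R_j} with
#' \eqn{E[T] = (N+1)/2 \sum_j n_j s_j} and variance
#' \eqn{Var(T) = c_t (N+1)/12 (N \sum n_j s_j^2 - (\sum n_j s_j)^2)}
#' where \eqn{c_t} is the usual tie-correction factor.
#'
#' @param values numeric observations.
#' @param groups ordered group labels (ordered factor, or sortable values;
#'   scores are 1, 2, ... in that order).
#' @return List: `z`, `p` (two-sided normal), `T`, `E_T`, `var_T`.
#' @export
cuzick_trend <- function(values, groups) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("at least 2 groups are required")
  if (stats::sd(values) == 0) stop("all values tied; trend undefined")
  N <- length(values)
  r <- rank(values)  # midranks
  s <- as.integer(groups)  # scores 1..k
  nj <- tabulate(s, nbins = k)
  sj <- seq_len(k)
  T_stat <- sum(s * r)
  L <- sum(nj * sj)
  E_T <- (N + 1) / 2 * L
  tie_tab <- table(values)
  ct <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  var_T <- ct * (N + 1) / 12 * (N * sum(nj * sj^2) - L^2)
  z <- (T_stat - E_T) / sqrt(var_T)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), T = T_stat, E_T = E_T,
       var_T = var_T)
}

#' Welch's t-test comparing exposure between two groups
#'
#' Thin wrapper over [stats::t.test()] with unequal variances, the
#' convention used for the gender comparison of exposure levels.
#'
#' @param values exposures.
#' @param group two-level factor.
#' @return The `htest` object.
#' @export
exposure_t_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly 2 levels")
  stats::t.test(values ~ group, var.equal = FALSE)
}
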