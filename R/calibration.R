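#' Fit a between-sampler calibration line
#'
#' Ordinary least squares of the target sampler's values on the source
#' sampler's values over co-located pairs, the standard way a correction
#' factor between passive sampler types is derived. The regression
#' direction is target-on-source so that `apply_calibration()` maps source
#' measurements onto the target scale.
#'
#' @param pairs data frame with the source values in the first numeric
#'   column and target values in the second (columns `value_source`,
#'   `value_target` if present, otherwise the first two numeric columns).
#' @return Object of class `calibration` with `slope`, `intercept`, `r`,
#'   `r2`, `n_pairs`.
#' @export
fit_calibration <- function(pairs) {
  v <- .calibration_columns(pairs)
  if (nrow(pairs) < 3) stop("at least 3 co-located pairs are required")
  if (stats::sd(v$source) == 0) {
    stop("degenerate design: source values are all equal")
  }
  fit <- stats::lm(v$target ~ v$source)
  r <- stats::cor(v$source, v$target)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, r2 = r^2, n_pairs = nrow(pairs)),
            class = "calibration")
}

.calibration_columns <- function(pairs) {
  if (all(c("value_source", "value_target") %in% names(pairs))) {
    list(source = pairs$value_source, target = pairs$value_target)
  } else {
    num <- pairs[vapply(pairs, is.numeric, logical(1))]
    if (ncol(num) < 2) stop("`pairs` needs two numeric columns")
    list(source = num[[1]], target = num[[2]])
  }
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Sampler calibration (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  target = %.4f * source + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.3f, R2 = %.3f\n", x$r, x$r2))
  invisible(x)
}

#' Apply a calibration model to raw values
#'
#' @param model a `calibration` object (or any list with `slope` and
#'   `intercept`).
#' @param values numeric vector on the source scale.
#' @return `slope * values + intercept`, elementwise.
#' @export
apply_calibration <- function(model, values) {
  model$slope * values + model$intercept
}

#' Bland-Altman agreement statistics
#'
#' Differences are first series minus second series; the limits of
#' agreement are mean difference \eqn{\pm} 1.96 times the sd of the
#' differences (n-1 denominator).
#'
#' @param pairs data frame; the two series are taken as in
#'   [fit_calibration()] (here difference = source - target, i.e. first
#'   minus second).
#' @return List with `mean_diff`, `sd_diff`, `loa` (length-2 limits),
#'   `n_pairs`, and the per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(pairs) {
  v <- .calibration_columns(pairs)
  if (length(v$source) < 2) stop("at least 2 pairs are required")
  d <- v$source - v$target
  m <- (v$source + v$target) / 2
  md <- mean(d)
  sdd <- if (length(d) > 1) stats::sd(d) else 0
  list(mean_diff = md, sd_diff = sdd,
       loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
       n_pairs = length(d), means = m, diffs = d)
}
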