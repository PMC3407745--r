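#' Two-campaign stability report
#'
#' Collects the four panel statistics of the cross-period comparison:
#' (A) correlation of measured annual values at shared sites (overall and
#' by site type) with Bland-Altman agreement statistics, (B) prospective
#' prediction (campaign-1 model vs campaign-2 measurements), (C)
#' retrospective prediction, and (D) correlation of the two models'
#' assigned exposures at the cohort addresses. Shared sites are matched by
#' site id.
#'
#' @param campaign1,campaign2 `measurement_set` objects (per-site annual
#'   values are formed with [site_period_mean()]).
#' @param model1,model2 `lur` fits for the two campaigns.
#' @param predictor_table1,predictor_table2 predictor rows for the two
#'   campaigns' sites (carrying `id` = site_id in the same order as the
#'   site lists).
#' @param assigned1,assigned2 exposure vectors at the cohort addresses
#'   from the two models (same subjects, same order).
#' @param required_periods completeness rule passed to
#'   [site_period_mean()].
#' @return Object of class `stability_report` (a named list; serializes
#'   losslessly to JSON).
#' @export
build_stability_report <- function(campaign1, campaign2, model1, model2,
                                   predictor_table1, predictor_table2,
                                   assigned1, assigned2,
                                   required_periods = 3) {
  m1 <- site_period_mean(campaign1, required_periods)$values
  m2 <- site_period_mean(campaign2, required_periods)$values
  shared <- intersect(m1$site_id, m2$site_id)
  if (length(shared) < 3) stop("fewer than 3 shared sites between campaigns")
  v1 <- m1$value[match(shared, m1$site_id)]
  v2 <- m2$value[match(shared, m2$site_id)]
  stype <- campaign1$sites$site_type[match(shared, campaign1$sites$site_id)]
  r_shared <- stats::cor(v1, v2)
  r_shared_by_type <- vapply(split(seq_along(shared), stype), function(ii) {
    if (length(ii) >= 3) stats::cor(v1[ii], v2[ii]) else NA_real_
  }, numeric(1))
  ba <- bland_altman(data.frame(value_source = v1, value_target = v2))

  pt2 <- predictor_table2[match(m2$site_id, predictor_table2$id), , drop = FALSE]
  prosp <- cross_period_predict(
    model1, m2, pt2,
    site_types = campaign2$sites$site_type[match(m2$site_id,
                                                 campaign2$sites$site_id)])
  pt1 <- predictor_table1[match(m1$site_id, predictor_table1$id), , drop = FALSE]
  retro <- cross_period_predict(
    model2, m1, pt1,
    site_types = campaign1$sites$site_type[match(m1$site_id,
                                                 campaign1$sites$site_id)])

  ok <- stats::complete.cases(cbind(assigned1, assigned2))
  structure(list(
    n_shared_sites = length(shared),
    r_measured_shared_sites = r_shared,
    r_measured_by_type = as.list(r_shared_by_type),
    bland_altman = list(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
                        loa = ba$loa),
    r_prospective = prosp$r,
    r_prospective_by_type = as.list(prosp$r_by_type),
    r_retrospective = retro$r,
    r_retrospective_by_type = as.list(retro$r_by_type),
    r_assigned_addresses = stats::cor(assigned1[ok], assigned2[ok]),
    n_addresses = sum(ok),
    model1 = list(adjusted_r2 = model1$adjusted_r2,
                  rmse_log = model1$rmse_log,
                  n_sites = model1$n_sites,
                  selected = model1$selected),
    model2 = list(adjusted_r2 = model2$adjusted_r2,
                  rmse_log = model2$rmse_log,
                  n_sites = model2$n_sites,
                  selected = model2$selected),
    panels = list(
      A = data.frame(site_id = shared, campaign1 = v1, campaign2 = v2,
                     site_type = stype),
      B = prosp$table,
      C = retro$table)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Cross-period stability report\n")
  cat(sprintf("  shared sites: %d, r(measured 1 vs 2) = %.3f\n",
              x$n_shared_sites, x$r_measured_shared_sites))
  cat(sprintf("  prospective r = %.3f, retrospective r = %.3f\n",
              x$r_prospective, x$r_retrospective))
  cat(sprintf("  r at %d cohort addresses = %.3f\n",
              x$n_addresses, x$r_assigned_addresses))
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' Scalar statistics go to JSON (the panel scatter tables are written as
#' separate CSVs by [run_pipeline()]).
#'
#' @param report a `stability_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(report, path) {
  keep <- report[setdiff(names(report), "panels")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
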