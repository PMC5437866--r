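#' Species-level binary false-positive table for one site
#'
#' One row per species observed at species rank at a site: outcome
#' \code{fp} = 1 if the species is a false positive there (not on the
#' accepted list), 0 if a true positive, joined with its regional 4 km^2
#' occupancy probability. This is the input of the rarity model, which is
#' always fitted per site, never pooled.
#'
#' @param detect output of \code{\link{detection_probabilities}} for the
#'   site.
#' @param attributes species attribute table with \code{species} and
#'   \code{occupancy}.
#' @param observed_only drop accepted species never actually recorded
#'   (default TRUE: the model describes observations, not the flora).
#' @return data.frame with columns \code{species, fp, occupancy}.
#' @export
fp_binary_table <- function(detect, attributes, observed_only = TRUE) {
  d <- detect
  if (observed_only) d <- d[d$n_detections > 0, , drop = FALSE]
  occ <- attributes$occupancy[match(d$species, attributes$species)]
  keep <- !is.na(occ)
  data.frame(species = d$species[keep],
             fp = as.integer(d$is_false_positive_species[keep]),
             occupancy = occ[keep], stringsAsFactors = FALSE)
}

#' Logit model of false-positive status against regional occupancy
#'
#' Fits, by maximum likelihood (iteratively reweighted least squares), the
#' Bernoulli GLM \eqn{logit P(fp = 1) = a + b \cdot occupancy} for one
#' site. Wald confidence intervals are reported on the logit scale and
#' back-transformed: the intercept through the inverse logit (the
#' probability that a species absent from the region — occupancy 0 — is
#' reported), the slope through the exponential (the multiplicative odds
#' factor per unit occupancy). Occupancy is used as a proportion in
#' [0, 1]; the scale is recorded in the fit.
#'
#' @param records data.frame with columns \code{fp} (0/1) and
#'   \code{occupancy}; >= 20 rows, both classes present.
#' @param site_id identifier carried into the result.
#' @param conf confidence level for the Wald intervals.
#' @return list of class \code{logit_fit} with logit-scale and
#'   back-transformed coefficients, intervals, \code{separation} flag and
#'   the underlying \code{glm} object.
#' @export
fit_fp_vs_occupancy <- function(records, site_id = NA_character_,
                                conf = 0.95) {
  if (nrow(records) < 20) stop("need at least 20 species rows")
  if (length(unique(records$fp)) < 2)
    stop("both outcome classes (true- and false-positive) must be present")
  if (any(records$occupancy < 0 | records$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fp ~ occupancy, family = stats::binomial("logit"),
               data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  if (sep)
    warning("possible complete separation; Wald intervals unreliable (effectively infinite)")
  structure(list(
    site_id = site_id, n_obs = nrow(records),
    intercept = cf[[1]], slope = cf[[2]],
    intercept_ci = ci[1, ], slope_ci = ci[2, ],
    intercept_bt = stats::plogis(cf[[1]]),
    intercept_bt_ci = stats::plogis(ci[1, ]),
    slope_bt = exp(cf[[2]]), slope_bt_ci = exp(ci[2, ]),
    occupancy_scale = "proportion [0,1]",
    separation = sep, df_residual = fit$df.residual, glm = fit
  ), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("site %s: n = %d, logit P(fp) = %.3f %+.3f * occupancy\n",
              x$site_id, x$n_obs, x$intercept, x$slope))
  cat(sprintf("  back-transformed intercept %.3f [%.3f, %.3f]; odds factor %.3g [%.3g, %.3g]\n",
              x$intercept_bt, x$intercept_bt_ci[1], x$intercept_bt_ci[2],
              x$slope_bt, x$slope_bt_ci[1], x$slope_bt_ci[2]))
  if (x$separation) cat("  warning: possible complete separation\n")
  invisible(x)
}

#' Central-third goodness-of-fit check
#'
#' Takes the middle third of the species by occupancy rank and compares
#' the observed false-positive proportion (with its binomial standard
#' error) to the model's predicted probability at the subgroup's mean
#' occupancy. A well-calibrated model has observed minus predicted within
#' about two standard errors.
#'
#' @param records data.frame with columns \code{fp} and \code{occupancy},
#'   >= 9 rows.
#' @param fit a \code{\link{fit_fp_vs_occupancy}} result.
#' @return list of class \code{central_third}: \code{observed, se,
#'   predicted, n, mean_occupancy, single_class}.
#' @export
central_third_check <- function(records, fit) {
  n <- nrow(records)
  if (n < 9) stop("need at least 9 rows for a central-third check")
  ord <- order(records$occupancy)
  idx <- ord[(floor(n / 3) + 1):floor(2 * n / 3)]
  sub <- records[idx, , drop = FALSE]
  p <- mean(sub$fp)
  se <- sqrt(p * (1 - p) / nrow(sub))
  single <- length(unique(sub$fp)) < 2
  if (single) warning("central third contains a single outcome class; SE is 0")
  structure(list(
    observed = p, se = se,
    predicted = stats::plogis(fit$intercept + fit$slope * mean(sub$occupancy)),
    n = nrow(sub), mean_occupancy = mean(sub$occupancy),
    single_class = single
  ), class = "central_third")
}

#' @export
print.central_third <- function(x, ...) {
  cat(sprintf("central third (n = %d): observed FP proportion %.3f +/- %.3f, model predicts %.3f\n",
              x$n, x$observed, x$se, x$predicted))
  invisible(x)
}
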