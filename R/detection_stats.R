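#' Per-species detection probabilities at a site
#'
#' Detection probability is the number of surveys in which a species was
#' recorded divided by the number of surveys conducted at the site. One
#' estimate is produced for every species either accepted at the site or
#' ever recorded there at species rank; species not on the accepted list
#' are flagged as false-positive species. Cautious (genus-only) and
#' mythical records never enter these estimates. The output supports the
#' classic two-group histogram of detection probability for true versus
#' false-positive observations.
#'
#' @param classified classified records of one site (see
#'   \code{\link{classify_records}}).
#' @param ref the site's \code{\link{site_reference}}.
#' @return data.frame with columns \code{species}, \code{site_id},
#'   \code{n_detections}, \code{n_surveys}, \code{p_detect},
#'   \code{is_false_positive_species}.
#' @export
detection_probabilities <- function(classified, ref) {
  classified <- classified[as.character(classified$site_id) == ref$site_id, ,
                           drop = FALSE]
  n_surveys <- length(unique(classified$survey_id))
  if (n_surveys < 1) stop("no surveys at site ", ref$site_id)
  sp <- classified[classified$category %in% c("true_positive", "false_positive"), ]
  # a species counts once per survey even if duplicated in the raw sheet
  det <- unique(sp[, c("survey_id", "matched_name")])
  counts <- table(det$matched_name)
  species <- sort(unique(c(ref$accepted_species, names(counts))))
  n_det <- as.integer(counts[species])
  n_det[is.na(n_det)] <- 0L
  data.frame(
    species = species,
    site_id = ref$site_id,
    n_detections = n_det,
    n_surveys = n_surveys,
    p_detect = n_det / n_surveys,
    is_false_positive_species = !(species %in% ref$accepted_species),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-survey false-positive rate of an observer
#'
#' The fraction of an observer's species-rank records that are false
#' positives: FP / (TP + FP). Cautious and mythical records are excluded
#' from the denominator. With no species-rank records the rate is
#' undefined and \code{NA} is returned with a warning.
#'
#' @param classified_survey classified records of a single survey.
#' @return a fraction in [0, 1], or \code{NA_real_} if undefined.
#' @export
observer_fp_rate <- function(classified_survey) {
  n_tp <- sum(classified_survey$category == "true_positive")
  n_fp <- sum(classified_survey$category == "false_positive")
  if (n_tp + n_fp == 0) {
    warning("no species-rank records; false-positive rate undefined")
    return(NA_real_)
  }
  n_fp / (n_tp + n_fp)
}

#' Cross-site correlation summary with a t confidence interval
#'
#' Computes one correlation coefficient per site from paired values, then
#' summarises across sites as the mean r with a t-distribution confidence
#' interval: mean +/- t(1 - alpha/2, n_sites - 1) * sd / sqrt(n_sites).
#' Sites where either variable is constant have an undefined r and are
#' excluded with a warning.
#'
#' @param pairs_per_site named list; each element a data.frame or list with
#'   numeric vectors \code{x} and \code{y} of equal length >= 3.
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param conf confidence level, default 0.95.
#' @return list of class \code{correlation_summary}: \code{per_site_r},
#'   \code{mean_r}, \code{ci_low}, \code{ci_high}, \code{n_sites}.
#' @export
cross_site_correlation <- function(pairs_per_site, method = "pearson",
                                   conf = 0.95) {
  if (length(pairs_per_site) < 2) stop("need pairs from at least 2 sites")
  rs <- vapply(names(pairs_per_site), function(s) {
    p <- pairs_per_site[[s]]
    x <- as.numeric(p$x); y <- as.numeric(p$y)
    if (length(x) != length(y) || length(x) < 3)
      stop("site ", s, ": need >= 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("site ", s, ": constant values, correlation undefined; excluded")
      return(NA_real_)
    }
    stats::cor(x, y, method = method)
  }, numeric(1))
  r <- rs[!is.na(rs)]
  n <- length(r)
  if (n < 2) stop("fewer than 2 sites with defined correlations")
  m <- mean(r)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(r) / sqrt(n)
  structure(list(per_site_r = rs, mean_r = m,
                 ci_low = m - half, ci_high = m + half, n_sites = n),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("mean R = %.2f (95%% CI [%.2f, %.2f], n = %d sites)\n",
              x$mean_r, x$ci_low, x$ci_high, x$n_sites))
  invisible(x)
}

#' Paired-value extractions for the four cross-site correlations
#'
#' Each extraction maps a classified record set (plus, where needed, a
#' species attribute table) to per-site \code{(x, y)} pairs suitable for
#' \code{\link{cross_site_correlation}}:
#' \describe{
#'   \item{fp_vs_correct}{per observer: number of false positives vs number
#'     of correct species;}
#'   \item{genus_fp_vs_size}{per genus: total false-positive observations
#'     vs number of species in the genus regionally;}
#'   \item{cautious_vs_size}{per genus: number of cautious observations vs
#'     genus size;}
#'   \item{cautious_vs_fp}{per observer: cautious count vs false-positive
#'     count.}
#' }
#'
#' @param classified classified records across sites.
#' @param which one of \code{"fp_vs_correct"}, \code{"genus_fp_vs_size"},
#'   \code{"cautious_vs_size"}, \code{"cautious_vs_fp"}.
#' @param attributes species attribute table (needed for the genus-size
#'   extractions); see \code{\link{read_species_attributes}}.
#' @return named list of per-site data.frames with columns \code{x, y}.
#' @export
correlation_pairs <- function(classified,
                              which = c("fp_vs_correct", "genus_fp_vs_size",
                                        "cautious_vs_size", "cautious_vs_fp"),
                              attributes = NULL) {
  which <- match.arg(which)
  per_observer <- function(df, cat_x, cat_y) {
    sv <- split(df, df$survey_id)
    data.frame(
      x = vapply(sv, function(s) sum(s$category == cat_x), numeric(1)),
      y = vapply(sv, function(s) sum(s$category == cat_y), numeric(1))
    )
  }
  per_genus <- function(df, cat) {
    if (is.null(attributes))
      stop("attributes table required for genus-size extraction")
    gsize <- attributes$genus_size[match(unique(attributes$genus),
                                         attributes$genus)]
    names(gsize) <- unique(attributes$genus)
    sub <- df[df$category == cat, , drop = FALSE]
    g <- if (cat == "cautious") sub$matched_name else genus_of(sub$matched_name)
    counts <- table(factor(g, levels = names(gsize)))
    data.frame(x = as.numeric(counts), y = as.numeric(gsize))
  }
  lapply(split(classified, as.character(classified$site_id)), function(df)
    switch(which,
           fp_vs_correct = per_observer(df, "false_positive", "true_positive"),
           cautious_vs_fp = per_observer(df, "cautious", "false_positive"),
           genus_fp_vs_size = per_genus(df, "false_positive"),
           cautious_vs_size = per_genus(df, "cautious")))
}
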