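#' Acceptance rule for combining surveys
#'
#' When k surveys are combined, a species is declared present if it was
#' recorded in all k of them (\code{all_of_k}), in at least m of them
#' (\code{at_least_m_of_k}), or in any of them (\code{union}).
#'
#' @param kind rule kind.
#' @param m agreement threshold, only for \code{at_least_m_of_k}.
#' @return object of class \code{acceptance_rule}.
#' @export
acceptance_rule <- function(kind = c("all_of_k", "at_least_m_of_k", "union"),
                            m = NULL) {
  kind <- match.arg(kind)
  if (kind == "at_least_m_of_k") {
    if (is.null(m) || m < 1) stop("at_least_m_of_k needs m >= 1")
  } else m <- NULL
  structure(list(kind = kind, m = m), class = "acceptance_rule")
}

rule_label <- function(rule)
  switch(rule$kind, all_of_k = "all", union = "union",
         at_least_m_of_k = paste0("atleast", rule$m))

rule_threshold <- function(rule, k) {
  m <- switch(rule$kind, all_of_k = k, union = 1L, at_least_m_of_k = rule$m)
  if (m > k) stop("agreement threshold m = ", m, " exceeds k = ", k)
  m
}

#' Species lists per survey
#'
#' Extracts, for each survey at a site, the set of species-rank records
#' (true positives and false positives); cautious and mythical records
#' never count toward agreement between surveys.
#'
#' @param classified classified records of one site.
#' @return named list of character vectors, one per survey.
#' @export
survey_species_sets <- function(classified) {
  if (length(unique(as.character(classified$site_id))) > 1)
    stop("records from more than one site; combine per site")
  sp <- classified[classified$category %in% c("true_positive", "false_positive"), ]
  sets <- lapply(split(sp$matched_name, factor(sp$survey_id)), unique)
  empty <- setdiff(unique(as.character(classified$survey_id)), names(sets))
  c(sets, setNames(replicate(length(empty), character(), simplify = FALSE), empty))
}

#' Combine k survey species sets under an acceptance rule
#'
#' @param sets list of character vectors (species per survey), all from one
#'   site.
#' @param rule an \code{\link{acceptance_rule}}.
#' @return character vector: the accepted species set.
#' @examples
#' sets <- list(c("A", "B", "C"), c("A", "B"), c("A", "D"))
#' combine_surveys(sets, acceptance_rule("all_of_k"))            # "A"
#' combine_surveys(sets, acceptance_rule("at_least_m_of_k", 2))  # "A" "B"
#' combine_surveys(sets, acceptance_rule("union"))
#' @export
combine_surveys <- function(sets, rule) {
  k <- length(sets)
  if (k < 1) stop("need at least one survey")
  m <- rule_threshold(rule, k)
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts >= m])
}

#' Bootstrap combination of k surveys at a site
#'
#' Each of \code{n_boot} resamples draws k distinct surveys uniformly
#' without replacement from the site's pool, combines them under the
#' acceptance rule, and scores the accepted set against the site's accepted
#' species list: TP = |accepted intersect reference|, FP = |accepted minus
#' reference|, FN = |reference minus accepted|. Means over resamples are
#' returned. Results are reproducible given the seed.
#'
#' @param classified classified records of one site.
#' @param ref the site's \code{\link{site_reference}}.
#' @param k number of surveys per combination.
#' @param rule an \code{\link{acceptance_rule}}.
#' @param n_boot number of resamples (the reference analysis uses 10,000).
#' @param seed integer seed.
#' @return list of class \code{combination_result} with fields
#'   \code{site_id, k, rule, n_boot, seed, mean_tp, mean_fp, mean_fn}.
#' @export
bootstrap_combination <- function(classified, ref, k, rule,
                                  n_boot = 10000, seed = 1) {
  sets <- survey_species_sets(classified)
  n <- length(sets)
  if (k > n) stop("k = ", k, " exceeds the pool of ", n, " surveys")
  if (n_boot < 1) stop("n_boot must be >= 1")
  m <- rule_threshold(rule, k)
  species <- sort(unique(c(ref$accepted_species,
                           unlist(sets, use.names = FALSE))))
  inc <- vapply(sets, function(s) species %in% s, logical(length(species)))
  inc <- matrix(inc, nrow = length(species))   # species x surveys
  in_ref <- species %in% ref$accepted_species
  n_ref <- length(ref$accepted_species)
  sums <- c(tp = 0, fp = 0, fn = 0)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, k, replace = FALSE)
      acc <- rowSums(inc[, idx, drop = FALSE]) >= m
      tp <- sum(acc & in_ref)
      sums <- sums + c(tp, sum(acc & !in_ref), n_ref - tp)
    }
  })
  means <- sums / n_boot
  structure(list(site_id = ref$site_id, k = k, rule = rule, n_boot = n_boot,
                 seed = seed, mean_tp = means[["tp"]], mean_fp = means[["fp"]],
                 mean_fn = means[["fn"]]),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("site %s, k = %d, rule %s: TP %.2f, FP %.2f, FN %.2f (%d resamples)\n",
              x$site_id, x$k, rule_label(x$rule), x$mean_tp, x$mean_fp,
              x$mean_fn, x$n_boot))
  invisible(x)
}

#' Sensitivity and specificity of a survey combination
#'
#' Sensitivity = TP / (TP + FN). Specificity = TN / (TN + FP), where the
#' true-negative pool is defined as the cumulative number of false-positive
#' species ever recorded at the site minus the mean number of false
#' positives in the combination; the absolute size of that pool is
#' acknowledged to be arbitrary — it shifts specificity's level, not the
#' comparison between acceptance thresholds.
#'
#' @param result a \code{\link{bootstrap_combination}} result.
#' @param ref the site's \code{\link{site_reference}} with \code{fp_pool}
#'   filled (see \code{\link{add_fp_pool}}).
#' @return list of class \code{confusion_summary}: \code{tp, fp, fn, tn,
#'   sensitivity, specificity}.
#' @export
confusion <- function(result, ref) {
  pool <- length(ref$fp_pool)
  if (result$mean_fp > pool + 1e-9)
    stop("integrity error: mean_fp (", result$mean_fp,
         ") exceeds the cumulative false-positive pool (", pool, ")")
  tn <- pool - result$mean_fp
  structure(list(
    tp = result$mean_tp, fp = result$mean_fp, fn = result$mean_fn, tn = tn,
    sensitivity = result$mean_tp / (result$mean_tp + result$mean_fn),
    specificity = tn / (tn + result$mean_fp)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %.2f FP %.2f FN %.2f TN %.2f | sensitivity %.3f specificity %.3f\n",
              x$tp, x$fp, x$fn, x$tn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Sweep acceptance thresholds over numbers of combined surveys
#'
#' Runs \code{\link{bootstrap_combination}} and \code{\link{confusion}} over
#' a grid of k values and rules, producing the long-format table behind the
#' false-positive reduction and sensitivity/specificity trade-off curves.
#' Each (site, k) cell gets its own derived seed, shared by all rules, so
#' the rules are compared on exactly the same survey selections (paired
#' comparison) and every cell is independently reproducible.
#'
#' @param classified classified records of one site.
#' @param ref site reference with \code{fp_pool}.
#' @param k_range integer vector of combination sizes.
#' @param rules list of \code{\link{acceptance_rule}} objects.
#' @param n_boot resamples per cell.
#' @param seed root integer seed.
#' @return data.frame with columns \code{site_id, k, rule, mean_tp, mean_fp,
#'   mean_fn, tn, sensitivity, specificity}.
#' @export
threshold_sweep <- function(classified, ref, k_range,
                            rules = list(acceptance_rule("all_of_k")),
                            n_boot = 10000, seed = 1) {
  rows <- list()
  for (rule in rules) for (k in k_range) {
    if (rule$kind == "at_least_m_of_k" && rule$m > k) next
    cell_seed <- derive_seed(seed, paste(ref$site_id, k))
    res <- bootstrap_combination(classified, ref, k, rule, n_boot, cell_seed)
    cs <- confusion(res, ref)
    rows[[length(rows) + 1]] <- data.frame(
      site_id = ref$site_id, k = k, rule = rule_label(rule),
      mean_tp = res$mean_tp, mean_fp = res$mean_fp, mean_fn = res$mean_fn,
      tn = cs$tn, sensitivity = cs$sensitivity, specificity = cs$specificity,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
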