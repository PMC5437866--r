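# Integer -> lower-case alphabetic code ("a", "b", ..., "aa", ...), used to
# build fake but well-formed Latin binomials whose epithets are globally
# unique, so any cross-genus recombination is guaranteed invalid.
int_to_alpha <- function(i) {
  vapply(i, function(k) {
    s <- ""
    repeat {
      s <- paste0(letters[(k - 1) %% 26 + 1], s)
      k <- (k - 1) %/% 26
      if (k == 0) return(s)
    }
  }, character(1))
}

#' Configuration of a synthetic survey world
#'
#' Defaults emulate the structure of a botanically rich temperate site
#' test: ~100-species sites drawn occupancy-weighted from a 1000-species
#' regional flora with genus structure; per-species detectability Beta(1,2)
#' — so exactly 75\% of species have detectability below 0.5 — spanning
#' 0 to 1; regional occupancy Beta(0.8, 2.5); observers of widely varying
#' skill (Beta(8,2)) and false-positive propensity (Gamma with mean
#' \code{fp_rate} records per survey, calibrated so false positives make up
#' roughly 3--4\% of a survey's species records); false-positive species
#' drawn preferentially from regionally rare species (\code{rarity_bias})
#' and species-rich genera (\code{genus_bias}); occasional genus-only
#' "cautious" records and corrupted non-existent names.
#'
#' @param n_species_regional regional species-pool size.
#' @param n_genera number of genera in the regional flora.
#' @param genus_nb_size,genus_nb_mu negative-binomial parameters for genus
#'   sizes (1 + NB), adjusted to sum exactly to the pool size.
#' @param occupancy_beta Beta(a, b) for regional 4 km^2 occupancy.
#' @param detectability_beta Beta(a, b) for per-species detectability.
#' @param site_size species per site.
#' @param n_sites number of sites.
#' @param n_observers observer roster size.
#' @param skill_beta Beta(a, b) for observer skill (fraction of detected
#'   species they can actually name).
#' @param fp_rate mean false-positive records per survey across observers.
#' @param fp_rate_shape Gamma shape of between-observer variation in
#'   false-positive propensity.
#' @param rarity_bias gamma >= 0: false-positive species weight includes
#'   (1 - occupancy)^gamma.
#' @param genus_bias delta >= 0: weight includes genus_size^delta.
#' @param cautious_rate probability a would-be species record degrades to
#'   its genus.
#' @param mythical_rate probability a false-positive record's name is
#'   corrupted to an invalid combination.
#' @param seed integer seed.
#' @return validated list of class \code{world_config}.
#' @export
world_config <- function(n_species_regional = 1000, n_genera = 250,
                         genus_nb_size = 0.6, genus_nb_mu = 3,
                         occupancy_beta = c(0.8, 2.5),
                         detectability_beta = c(1, 2),
                         site_size = 100, n_sites = 1, n_observers = 40,
                         skill_beta = c(8, 2),
                         fp_rate = 0.9, fp_rate_shape = 2,
                         rarity_bias = 1, genus_bias = 1,
                         cautious_rate = 0.05, mythical_rate = 0.05,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_species_regional >= n_genera, n_genera >= 2,
            site_size <= n_species_regional,
            all(c(occupancy_beta, detectability_beta, skill_beta) > 0),
            fp_rate >= 0, fp_rate_shape > 0,
            rarity_bias >= 0, genus_bias >= 0,
            cautious_rate >= 0, cautious_rate <= 1,
            mythical_rate >= 0, mythical_rate <= 1)
  structure(cfg, class = "world_config")
}

#' Generate a synthetic survey world with known ground truth
#'
#' Builds the regional flora (genus structure, occupancy, detectability),
#' the sites (occupancy-weighted species draws), the observer roster and
#' the reference objects the analysis pipeline consumes. Every quantity the
#' pipeline later estimates is stored as ground truth. Identical seeds give
#' identical worlds.
#'
#' @param config a \code{\link{world_config}}.
#' @return list of class \code{synthetic_world}: \code{species} (attribute
#'   table with true occupancy/detectability), \code{checklist},
#'   \code{sites} (named list of species-index vectors),
#'   \code{references} (named list of \code{\link{site_reference}}),
#'   \code{observers} (skill, fp_lambda), \code{config}.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, {
    sizes <- 1 + stats::rnbinom(config$n_genera, size = config$genus_nb_size,
                                mu = config$genus_nb_mu)
    diff <- config$n_species_regional - sum(sizes)
    while (diff != 0) {          # adjust to conserve the pool size exactly
      i <- sample.int(config$n_genera, 1)
      if (diff > 0) { sizes[i] <- sizes[i] + 1; diff <- diff - 1 }
      else if (sizes[i] > 1) { sizes[i] <- sizes[i] - 1; diff <- diff + 1 }
    }
    genus_names <- paste0("Genus", int_to_alpha(seq_len(config$n_genera)))
    genus <- rep(genus_names, sizes)
    species <- paste(genus, int_to_alpha(seq_len(config$n_species_regional)))
    occupancy <- stats::rbeta(config$n_species_regional,
                              config$occupancy_beta[1], config$occupancy_beta[2])
    detectability <- stats::rbeta(config$n_species_regional,
                                  config$detectability_beta[1],
                                  config$detectability_beta[2])
    sites <- lapply(seq_len(config$n_sites), function(s)
      sort(sample.int(config$n_species_regional, config$site_size,
                      prob = occupancy)))
    names(sites) <- paste0("site", seq_len(config$n_sites))
    observers <- data.frame(
      observer_id = paste0("obs", seq_len(config$n_observers)),
      skill = stats::rbeta(config$n_observers, config$skill_beta[1],
                           config$skill_beta[2]),
      fp_lambda = if (config$fp_rate == 0) rep(0, config$n_observers)
                  else stats::rgamma(config$n_observers,
                                     shape = config$fp_rate_shape,
                                     scale = config$fp_rate / config$fp_rate_shape),
      stringsAsFactors = FALSE)
  })
  spdf <- data.frame(species = species, genus = genus,
                     genus_size = rep(sizes, sizes),
                     occupancy = occupancy, detectability = detectability,
                     stringsAsFactors = FALSE)
  refs <- lapply(names(sites), function(s)
    site_reference(s, species[sites[[s]]]))
  structure(list(species = spdf, checklist = species, sites = sites,
                 references = setNames(refs, names(sites)),
                 observers = observers, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d regional species in %d genera, %d site(s) of %d species, %d observers\n",
              nrow(x$species), x$config$n_genera, length(x$sites),
              x$config$site_size, nrow(x$observers)))
  invisible(x)
}

#' Simulate one observer's survey of a site
#'
#' Each species present at the site is detected-and-named independently
#' with probability detectability x observer skill. A detected species
#' degrades to a genus-only cautious record with probability
#' \code{cautious_rate}. The observer then adds Poisson(lambda_observer)
#' false-positive records, drawn without replacement from the regional pool
#' outside the site with weight proportional to
#' (1 - occupancy)^rarity_bias x genus_size^genus_bias; with probability
#' \code{mythical_rate} such a record's name is corrupted into an invalid
#' genus-epithet combination.
#'
#' @param world a \code{\link{generate_world}} result.
#' @param site site id (name in \code{world$sites}).
#' @param observer observer id (row of \code{world$observers}).
#' @param seed integer seed.
#' @param survey_id optional explicit survey identifier.
#' @return list: \code{records} (canonical record data.frame) and
#'   \code{truth} (generative event log: detected / cautious /
#'   false-positive / mythical species index vectors).
#' @export
simulate_survey <- function(world, site, observer, seed,
                            survey_id = paste(site, observer, sep = "_")) {
  cfg <- world$config
  if (!site %in% names(world$sites)) stop("unknown site: ", site)
  orow <- world$observers[world$observers$observer_id == observer, ]
  if (nrow(orow) != 1) stop("unknown observer: ", observer)
  sp <- world$species
  present <- world$sites[[site]]
  with_seed(seed, {
    detected <- present[stats::runif(length(present)) <
                          sp$detectability[present] * orow$skill]
    cautious <- detected[stats::runif(length(detected)) < cfg$cautious_rate]
    named <- setdiff(detected, cautious)
    n_fp <- stats::rpois(1, orow$fp_lambda)
    pool <- setdiff(seq_len(nrow(sp)), present)
    wt <- (1 - sp$occupancy[pool])^cfg$rarity_bias *
      sp$genus_size[pool]^cfg$genus_bias
    n_fp <- min(n_fp, length(pool))
    fp <- if (n_fp > 0) sample(pool, n_fp, prob = wt) else integer()
    mythical <- fp[stats::runif(length(fp)) < cfg$mythical_rate]
    fp_named <- setdiff(fp, mythical)
    myth_names <- vapply(mythical, function(i) {
      other <- sample(which(sp$genus != sp$genus[i]), 1)
      paste(sp$genus[i], sub("^\\S+ ", "", sp$species[other]))
    }, character(1))
  })
  raw <- c(sp$species[named], sp$genus[cautious], sp$species[fp_named],
           myth_names)
  rank <- c(rep("species", length(named)), rep("genus", length(cautious)),
            rep("species", length(fp_named) + length(mythical)))
  records <- data.frame(
    site_id = site, survey_id = survey_id, observer_id = observer,
    date = "2010-07-01", raw_name = raw, rank = rank,
    stringsAsFactors = FALSE)
  list(records = records,
       truth = list(present = present, detected = detected,
                    cautious = cautious, false_positive = fp,
                    mythical = mythical))
}

#' Simulate a campaign of surveys across all sites
#'
#' One survey per (site, observer) pair, cycling through the roster, with
#' per-survey seeds derived from the root seed.
#'
#' @param world a \code{\link{generate_world}} result.
#' @param surveys_per_site surveys to simulate at each site.
#' @param seed root integer seed.
#' @return list: \code{records} (all surveys row-bound) and \code{truth}
#'   (named by survey_id).
#' @export
simulate_surveys <- function(world, surveys_per_site, seed = 1) {
  obs_ids <- world$observers$observer_id
  out <- list(); truth <- list()
  for (site in names(world$sites)) {
    who <- rep_len(obs_ids, surveys_per_site)
    for (j in seq_len(surveys_per_site)) {
      sid <- sprintf("%s_s%03d", site, j)
      sv <- simulate_survey(world, site, who[j],
                            seed = derive_seed(seed, sid), survey_id = sid)
      out[[sid]] <- sv$records
      truth[[sid]] <- sv$truth
    }
  }
  list(records = do.call(rbind, out), truth = truth)
}

#' Simulate a pure-birth (Yule) tree scaled to unit depth
#'
#' @param n_tips number of tips (>= 4).
#' @param seed integer seed.
#' @return an ultrametric \code{phylo} with maximum root-to-tip depth 1.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 4) stop("need at least 4 tips")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

#' Simulate a binary trait on a tree at fixed prevalence
#'
#' Under the \code{random} model the 1-state tips are a uniform random
#' subset; under \code{brownian_threshold} a continuous Brownian trait is
#' evolved along the branches and dichotomised at the order statistic
#' matching the prevalence. Either way exactly
#' \code{round(prevalence * n_tips)} tips carry state 1.
#'
#' @param tree a \code{phylo} object.
#' @param model \code{"random"} or \code{"brownian_threshold"}.
#' @param prevalence fraction of tips in state 1, strictly inside (0, 1).
#' @param seed integer seed.
#' @return named 0/1 vector over the tips.
#' @export
simulate_trait <- function(tree, model = c("random", "brownian_threshold"),
                           prevalence, seed = 1) {
  model <- match.arg(model)
  n <- ape::Ntip(tree)
  k <- round(prevalence * n)
  if (prevalence <= 0 || prevalence >= 1 || k == 0 || k == n)
    stop("prevalence must leave both states represented")
  with_seed(seed, {
    states <- if (model == "random") {
      s <- integer(n); s[sample.int(n, k)] <- 1L; s
    } else {
      as.integer(threshold_at_prevalence(bm_tips(tree, 1), k))
    }
  })
  setNames(states, tree$tip.label)
}
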