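#' surveyerr: false-positive errors in repeated species surveys
#'
#' Classification of survey records against a site reference, detection
#' probabilities, bootstrap multi-survey combination under acceptance
#' thresholds, sensitivity/specificity with a false-positive-pool
#' true-negative convention, the D statistic for binary-trait phylogenetic
#' signal, a logit rarity model, and a synthetic observer-world generator.
#'
#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-seed from a root seed and a character key.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Normalise a recorded plant name
#'
#' Reduces a raw field-recorded name to a comparable form: whitespace is
#' squashed, hybrid signs dropped, authorship strings removed, and
#' infraspecific records collapsed to the parent binomial. The genus is
#' title-cased and the epithet lower-cased. A name with no usable epithet
#' (e.g. \code{"Carex"}) normalises to a genus-rank name.
#'
#' Authorship is recognised heuristically: the specific epithet is the first
#' token after the genus that is purely lower-case alphabetic (hyphens
#' allowed) and contains no period; abbreviated authors ("L.", "(L.) Mill.")
#' and capitalised tokens are discarded. No fuzzy matching is performed —
#' a misspelling is simply a name that fails to match the checklist.
#'
#' @param x character vector of raw names.
#' @return data.frame with columns \code{name} (normalised name, \code{NA}
#'   if empty input), \code{genus} and \code{rank} ("species" or "genus").
#' @examples
#' normalise_name(c("Carex  flacca Schreb.", "Carex", "Trifolium pratense L."))
#' @export
normalise_name <- function(x) {
  x <- as.character(x)
  out <- data.frame(name = NA_character_, genus = NA_character_,
                    rank = NA_character_, stringsAsFactors = FALSE)[rep(1, length(x)), ]
  rownames(out) <- NULL
  for (i in seq_along(x)) {
    s <- gsub("\\s+", " ", trimws(x[i]))
    s <- gsub("(^|\\s)[x×](\\s)", "\\1", s)   # hybrid markers
    if (is.na(s) || !nzchar(s)) next
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    genus <- toks[1]
    genus <- paste0(toupper(substring(genus, 1, 1)),
                    tolower(substring(genus, 2)))
    if (!grepl("^[A-Z][a-z-]+$", genus)) next
    epithet <- NA_character_
    infra <- c("subsp.", "ssp.", "var.", "f.", "subvar.", "agg.", "s.l.", "s.s.")
    for (tok in toks[-1]) {
      if (tolower(tok) %in% infra) break  # infraspecifics collapse to the binomial
      if (grepl("^[a-z][a-z-]*$", tok) ||
          grepl("^[A-Z][A-Z-]+$", tok)) {  # all-caps data entry
        epithet <- tolower(tok)
        break
      }
      # otherwise an authorship fragment; keep scanning
    }
    if (is.na(epithet)) {
      out$name[i] <- genus
      out$genus[i] <- genus
      out$rank[i] <- "genus"
    } else {
      out$name[i] <- paste(genus, epithet)
      out$genus[i] <- genus
      out$rank[i] <- "species"
    }
  }
  out
}

genus_of <- function(names) vapply(strsplit(names, " ", fixed = TRUE),
                                   `[`, character(1), 1)

#' Construct a site reference
#'
#' The accepted species list for a site (the gold-standard observer's list
#' plus other reliable surveys) and, optionally, the cumulative pool of
#' species ever recorded at the site as false positives. The two sets are
#' required to be disjoint.
#'
#' @param site_id site identifier.
#' @param accepted_species character vector of accepted species names.
#' @param fp_pool character vector of cumulative false-positive species.
#' @return an object of class \code{site_reference}.
#' @export
site_reference <- function(site_id, accepted_species, fp_pool = character()) {
  accepted_species <- unique(normalise_name(accepted_species)$name)
  accepted_species <- accepted_species[!is.na(accepted_species)]
  fp_pool <- unique(normalise_name(fp_pool)$name)
  fp_pool <- fp_pool[!is.na(fp_pool)]
  if (length(intersect(accepted_species, fp_pool)))
    stop("accepted_species and fp_pool must be disjoint: ",
         paste(intersect(accepted_species, fp_pool), collapse = ", "))
  structure(list(site_id = as.character(site_id),
                 accepted_species = accepted_species,
                 fp_pool = fp_pool),
            class = "site_reference")
}

#' @export
print.site_reference <- function(x, ...) {
  cat("Site reference:", x$site_id, "\n",
      " accepted species:", length(x$accepted_species), "\n",
      " false-positive pool:", length(x$fp_pool), "\n")
  invisible(x)
}

#' Classify survey records into the four error categories
#'
#' Every record is assigned exactly one category:
#' \describe{
#'   \item{true_positive}{a valid species on the site's accepted list;}
#'   \item{false_positive}{a valid regional species not accepted at the
#'     site (misidentifications and "unreasonable" records are one class);}
#'   \item{cautious}{a record resolved only to genus, for a genus that
#'     exists in the regional flora;}
#'   \item{mythical}{a name matching no valid taxon — invalid combinations
#'     such as "Calystegia arvense" — for which \code{matched_name} is NA.}
#' }
#' Names are normalised (and infraspecifics collapsed to species) before
#' matching; an optional synonym table is applied after normalisation.
#'
#' @param records data.frame with columns \code{site_id}, \code{survey_id},
#'   \code{observer_id}, \code{date}, \code{raw_name} and optionally
#'   \code{rank}.
#' @param references a single \code{\link{site_reference}} or a list of them
#'   covering every \code{site_id} present.
#' @param checklist character vector of valid regional species names.
#' @param genus_index character vector of valid genus names; defaults to the
#'   genera of \code{checklist}.
#' @param synonyms optional data.frame with columns \code{from}, \code{to}
#'   mapping normalised names onto checklist names.
#' @return the records data.frame with added columns \code{matched_name},
#'   \code{rank} and \code{category}.
#' @export
classify_records <- function(records, references, checklist,
                             genus_index = NULL, synonyms = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("site_id", "survey_id", "observer_id", "raw_name")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(trimws(records$raw_name)) | is.na(records$raw_name)))
    stop("empty raw_name at row(s): ",
         paste(which(!nzchar(trimws(records$raw_name)) | is.na(records$raw_name)),
               collapse = ", "))
  if (inherits(references, "site_reference")) {
    refs <- setNames(list(references), references$site_id)
  } else {
    refs <- setNames(references, vapply(references, `[[`, "", "site_id"))
  }
  unknown <- setdiff(unique(as.character(records$site_id)), names(refs))
  if (length(unknown)) stop("no site reference for site(s): ",
                            paste(unknown, collapse = ", "))

  chk <- normalise_name(checklist)$name
  chk <- unique(chk[!is.na(chk)])
  if (is.null(genus_index)) genus_index <- unique(genus_of(chk))

  nm <- normalise_name(records$raw_name)
  if (!is.null(synonyms)) {
    idx <- match(nm$name, synonyms$from)
    hit <- !is.na(idx)
    nm$name[hit] <- synonyms$to[idx[hit]]
    nm$genus[hit] <- genus_of(nm$name[hit])
  }

  category <- character(nrow(records))
  matched <- nm$name
  for (i in seq_len(nrow(records))) {
    ref <- refs[[as.character(records$site_id[i])]]
    if (is.na(nm$name[i])) {
      category[i] <- "mythical"; matched[i] <- NA_character_
    } else if (nm$rank[i] == "genus") {
      if (nm$genus[i] %in% genus_index) category[i] <- "cautious"
      else { category[i] <- "mythical"; matched[i] <- NA_character_ }
    } else if (!(nm$name[i] %in% chk)) {
      category[i] <- "mythical"; matched[i] <- NA_character_
    } else if (nm$name[i] %in% ref$accepted_species) {
      category[i] <- "true_positive"
    } else {
      category[i] <- "false_positive"
    }
  }
  records$matched_name <- matched
  records$rank <- nm$rank
  records$category <- category
  records
}

#' Cumulative false-positive pool per site
#'
#' The set of species ever recorded as false positives at each site,
#' computed from a classified record set. It equals the union of the
#' per-survey false-positive species sets.
#'
#' @param classified output of \code{\link{classify_records}}.
#' @return named list (by site_id) of character vectors.
#' @export
fp_pool <- function(classified) {
  fp <- classified[classified$category == "false_positive", , drop = FALSE]
  lapply(split(fp$matched_name, as.character(fp$site_id)), unique)
}

#' Attach computed false-positive pools to site references
#'
#' @param references list of \code{\link{site_reference}} objects.
#' @param classified classified record set covering those sites.
#' @return the references with \code{fp_pool} filled in.
#' @export
add_fp_pool <- function(references, classified) {
  if (inherits(references, "site_reference")) references <- list(references)
  pools <- fp_pool(classified)
  out <- lapply(references, function(r) {
    p <- pools[[r$site_id]]
    if (!is.null(p)) r$fp_pool <- sort(unique(p))
    r
  })
  setNames(out, vapply(out, `[[`, "", "site_id"))
}

#' Score a survey against the gold-standard total
#'
#' The score is the number of correctly identified species plus half a mark
#' for each distinct cautiously recorded genus (a genus can earn its half
#' mark only once), expressed as a fraction of the gold-standard observer's
#' species total. False positives are counted and reported separately; the
#' penalty weight applied to them is configurable and defaults to zero
#' (reported but unweighted).
#'
#' @param classified_survey classified records of one survey.
#' @param gold_total number of species recorded by the gold-standard
#'   observer; must be positive.
#' @param fp_penalty marks deducted per false-positive record.
#' @return list of class \code{survey_score} with elements \code{score},
#'   \code{n_true_positive}, \code{n_cautious_genera},
#'   \code{n_false_positive}, \code{fp_penalty}.
#' @export
score_survey <- function(classified_survey, gold_total, fp_penalty = 0) {
  if (!is.numeric(gold_total) || gold_total <= 0)
    stop("gold_total must be a positive count")
  n_tp <- sum(classified_survey$category == "true_positive")
  caut <- classified_survey$matched_name[classified_survey$category == "cautious"]
  n_cg <- length(unique(caut))
  n_fp <- sum(classified_survey$category == "false_positive")
  structure(list(
    score = (n_tp + 0.5 * n_cg - fp_penalty * n_fp) / gold_total,
    n_true_positive = n_tp,
    n_cautious_genera = n_cg,
    n_false_positive = n_fp,
    fp_penalty = fp_penalty
  ), class = "survey_score")
}

#' @export
print.survey_score <- function(x, ...) {
  cat(sprintf("score %.3f (%d correct, %d cautious genera, %d false positives)\n",
              x$score, x$n_true_positive, x$n_cautious_genera,
              x$n_false_positive))
  invisible(x)
}

record_columns <- c("site_id", "survey_id", "observer_id", "date",
                    "raw_name", "rank")

delim_for <- function(path) if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","

#' Read a long-format survey table
#'
#' One row per observation with columns \code{site_id, survey_id,
#' observer_id, date, raw_name, rank} (comma- or tab-delimited by file
#' extension, UTF-8, header row). A column-mapping can adapt other layouts.
#' A \code{survey_id} appearing under more than one site, observer or date
#' is an integrity error.
#'
#' @param path file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{c(raw_name = "taxon")}.
#' @return data.frame of records.
#' @export
read_surveys <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                         quote = "\"", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", comment.char = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(x))
        stop("mapped column not in file: ", col_map[[canon]])
      names(x)[names(x) == col_map[[canon]]] <- canon
    }
  }
  miss <- setdiff(setdiff(record_columns, "rank"), names(x))
  if (length(miss))
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(x$site_id) | !nzchar(trimws(as.character(x$site_id))))
  if (length(bad))
    stop("missing site_id at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  key <- unique(x[, c("survey_id", "site_id", "observer_id", "date")])
  dup <- key$survey_id[duplicated(key$survey_id)]
  if (length(dup))
    stop("survey_id used inconsistently across surveys: ",
         paste(unique(dup), collapse = ", "))
  x
}

#' Write a long-format survey table
#'
#' Inverse of \code{\link{read_surveys}}: \code{read_surveys(write_surveys(x))}
#' returns the same records.
#'
#' @param records data.frame of records.
#' @param path destination path (.csv or .tsv).
#' @export
write_surveys <- function(records, path) {
  utils::write.table(records, path, sep = delim_for(path), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-site accepted species lists
#'
#' Two-column delimited text (\code{site_id, species}); one row per accepted
#' species.
#'
#' @param path file path.
#' @return named list of \code{\link{site_reference}} objects.
#' @export
read_site_references <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("site_id", "species") %in% names(x)))
    stop("reference list needs columns site_id, species")
  refs <- lapply(split(x$species, as.character(x$site_id)), function(sp) sp)
  out <- Map(function(id, sp) site_reference(id, sp), names(refs), refs)
  setNames(out, names(refs))
}

#' Read a species attribute table
#'
#' Four-column delimited text: \code{species, genus, genus_size, occupancy}.
#' \code{genus_size} is the number of congeneric species in the regional
#' flora (>= 1); \code{occupancy} is the regional 4 km^2 occupancy
#' probability in [0, 1].
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_species_attributes <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("species", "genus", "genus_size", "occupancy")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("attribute table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(x$genus_size < 1)) stop("genus_size must be >= 1")
  if (any(x$occupancy < 0 | x$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  x
}

#' Read a rooted phylogeny in Newick format
#'
#' Thin wrapper over \code{ape::read.tree} that validates what the signal
#' statistics require: unique tip labels and branch lengths present.
#'
#' @param path Newick file path.
#' @return an \code{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tr$tip.label)) stop("tree tip labels are not unique")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  tr
}
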