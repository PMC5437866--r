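# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A minimal regional checklist, site reference, and hand-written records
# covering all four record categories.
tiny_checklist <- function() {
  c("Carex flacca", "Carex nigra", "Trifolium pratense", "Trifolium repens",
    "Calystegia sepium", "Geranium pratense", "Plantago lanceolata",
    "Lotus corniculatus", "Salvia pratensis")
}

tiny_reference <- function() {
  site_reference("quarry",
                 c("Carex flacca", "Trifolium pratense",
                   "Plantago lanceolata", "Lotus corniculatus"))
}

tiny_records <- function() {
  data.frame(
    site_id = "quarry",
    survey_id = c("s1", "s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    observer_id = c(rep("alice", 5), rep("bob", 3)),
    date = "2012-07-04",
    raw_name = c("Carex flacca Schreb.", "Trifolium pratense",
                 "Salvia pratensis", "Carex", "Calystegia arvense",
                 "Plantago lanceolata", "Trifolium repens",
                 "Lotus corniculatus"),
    rank = "species",
    stringsAsFactors = FALSE)
}

tiny_classified <- function() {
  classify_records(tiny_records(), tiny_reference(), tiny_checklist())
}

# A small classified set with known per-survey species lists, for the
# combiner: survey lists {A,B,C}, {A,B}, {A,D} where A,B are accepted.
combiner_fixture <- function() {
  ref <- site_reference("s", c("Alpha one", "Beta two"))
  checklist <- c("Alpha one", "Beta two", "Gamma three", "Delta four")
  rec <- data.frame(
    site_id = "s",
    survey_id = c("v1", "v1", "v1", "v2", "v2", "v3", "v3"),
    observer_id = "o",
    date = "2010-01-01",
    raw_name = c("Alpha one", "Beta two", "Gamma three",
                 "Alpha one", "Beta two",
                 "Alpha one", "Delta four"),
    rank = "species", stringsAsFactors = FALSE)
  cl <- classify_records(rec, ref, checklist)
  list(classified = cl, ref = add_fp_pool(list(ref), cl)[["s"]],
       checklist = checklist)
}

# Random site fixture for property tests: n_surveys random species lists
# over a small pool, a random accepted list.
random_site_fixture <- function(n_surveys = 4, pool_size = 30, seed = 1) {
  set.seed(seed)
  pool <- paste("Genus", vapply(seq_len(pool_size), function(i)
    paste0(rep(letters[(i - 1) %% 26 + 1], (i - 1) %/% 26 + 1),
           collapse = ""), character(1)))
  accepted <- sample(pool, pool_size %/% 2)
  recs <- do.call(rbind, lapply(seq_len(n_surveys), function(j) {
    sp <- sample(pool, sample(5:15, 1))
    data.frame(site_id = "r", survey_id = sprintf("v%02d", j),
               observer_id = sprintf("o%02d", j), date = "2010-01-01",
               raw_name = sp, rank = "species", stringsAsFactors = FALSE)
  }))
  ref <- site_reference("r", accepted)
  cl <- classify_records(recs, ref, pool)
  list(classified = cl, ref = add_fp_pool(list(ref), cl)[["r"]])
}

# Exhaustive combinatorial average of TP/FP/FN over all k-subsets of the
# surveys, written independently of the package's bootstrap path (plain
# set operations over combn), for use as an enumeration oracle.
enumerate_combination <- function(classified, ref, k, m) {
  sp <- classified[classified$category %in% c("true_positive",
                                              "false_positive"), ]
  sets <- lapply(split(sp$matched_name, factor(sp$survey_id)), unique)
  ids <- unique(as.character(classified$survey_id))
  sets <- lapply(ids, function(i) if (i %in% names(sets)) sets[[i]] else character())
  combos <- utils::combn(length(sets), k, simplify = FALSE)
  per <- t(vapply(combos, function(idx) {
    tab <- table(unlist(sets[idx]))
    acc <- names(tab)[tab >= m]
    tp <- length(intersect(acc, ref$accepted_species))
    c(tp = tp, fp = length(setdiff(acc, ref$accepted_species)),
      fn = length(ref$accepted_species) - tp)
  }, c(tp = 0, fp = 0, fn = 0)))
  list(mean = colMeans(per), sd = apply(per, 2, function(x)
    sqrt(mean((x - mean(x))^2))), n_combos = length(combos))
}
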