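test_that("name normalisation strips authorship, collapses infraspecifics, detects rank", {
  nm <- normalise_name(c("Carex  flacca Schreb.", "Trifolium pratense L.",
                         "Carex", "Festuca rubra subsp. commutata",
                         "GALIUM APARINE", "x Festulolium loliaceum", ""))
  expect_equal(nm$name[1:6],
               c("Carex flacca", "Trifolium pratense", "Carex",
                 "Festuca rubra", "Galium aparine", "Festulolium loliaceum"))
  expect_equal(nm$rank[1:6],
               c("species", "species", "genus", "species", "species", "species"))
  expect_true(is.na(nm$name[7]))
})

test_that("records are classified into the four categories", {
  cl <- tiny_classified()
  expect_equal(cl$category[cl$raw_name == "Carex flacca Schreb."], "true_positive")
  # valid regional species not accepted at the site
  expect_equal(cl$category[cl$raw_name == "Salvia pratensis"], "false_positive")
  # genus-only record
  expect_equal(cl$category[cl$raw_name == "Carex"], "cautious")
  # invalid published combination
  expect_equal(cl$category[cl$raw_name == "Calystegia arvense"], "mythical")
  expect_true(is.na(cl$matched_name[cl$category == "mythical"]))
  expect_false(any(is.na(cl$matched_name[cl$category != "mythical"])))
})

test_that("classification is total and category counts partition the records", {
  cl <- tiny_classified()
  expect_true(all(cl$category %in% c("true_positive", "false_positive",
                                     "cautious", "mythical")))
  expect_equal(sum(table(cl$category)), nrow(cl))
  # a synonym table redirects an otherwise-mythical name
  syn <- data.frame(from = "Carex atrata", to = "Carex nigra",
                    stringsAsFactors = FALSE)
  rec <- tiny_records()[1, ]
  rec$raw_name <- "Carex atrata"
  cl2 <- classify_records(rec, tiny_reference(), tiny_checklist(),
                          synonyms = syn)
  expect_equal(cl2$category, "false_positive")
  expect_equal(cl2$matched_name, "Carex nigra")
})

test_that("empty names and unknown sites are input errors", {
  rec <- tiny_records()
  rec$raw_name[2] <- "  "
  expect_error(classify_records(rec, tiny_reference(), tiny_checklist()),
               "empty raw_name")
  rec2 <- tiny_records()
  rec2$site_id[1] <- "elsewhere"
  expect_error(classify_records(rec2, tiny_reference(), tiny_checklist()),
               "no site reference")
})

test_that("fp_pool equals the union of per-survey false-positive sets", {
  set.seed(42)
  fx <- random_site_fixture(n_surveys = 6, seed = 7)
  cl <- fx$classified
  pool <- fp_pool(cl)[["r"]]
  per_survey <- lapply(split(cl, cl$survey_id), function(s)
    unique(s$matched_name[s$category == "false_positive"]))
  expect_setequal(pool, unique(unlist(per_survey)))
  expect_length(intersect(pool, fx$ref$accepted_species), 0)
})

test_that("site_reference enforces disjoint accepted and fp pools", {
  expect_error(site_reference("x", c("Aa bb", "Cc dd"), fp_pool = "Aa bb"),
               "disjoint")
})

test_that("survey scoring applies half marks once per cautious genus", {
  mk <- function(tp, cautious_genera) {
    data.frame(category = c(rep("true_positive", tp),
                            rep("cautious", length(cautious_genera))),
               matched_name = c(sprintf("Sp %03d", seq_len(tp)),
                                cautious_genera),
               stringsAsFactors = FALSE)
  }
  expect_equal(score_survey(mk(50, character()), 100)$score, 0.50)
  expect_equal(score_survey(mk(10, "Carex"), 100)$score, 0.105)
  # the same genus recorded cautiously twice earns only one half mark
  expect_equal(score_survey(mk(10, c("Carex", "Carex")), 100)$score, 0.105)
  expect_error(score_survey(mk(10, "Carex"), 0), "positive")
  # the false-positive count is reported, and an explicit penalty applies
  sv <- mk(10, character())
  sv <- rbind(sv, data.frame(category = "false_positive",
                             matched_name = "Xx yy"))
  sc <- score_survey(sv, 100, fp_penalty = 1)
  expect_equal(sc$n_false_positive, 1)
  expect_equal(sc$score, 0.09)
})

test_that("survey tables round-trip through disk", {
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_surveys(rec, path)
  back <- read_surveys(path)
  expect_equal(back, rec)
  # tab-delimited round trip too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_surveys(rec, path2)
  expect_equal(read_surveys(path2), rec)
})

test_that("malformed survey tables are rejected with located errors", {
  rec <- tiny_records()
  rec$site_id[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(rec, path, sep = ",", row.names = FALSE, quote = TRUE)
  expect_error(read_surveys(path), "site_id at row")
  # same survey_id under two observers is an integrity error
  rec2 <- tiny_records()
  rec2$observer_id[1] <- "someone_else"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(rec2, path2, sep = ",", row.names = FALSE, quote = TRUE)
  expect_error(read_surveys(path2), "inconsistently")
  # column mapping adapts foreign layouts
  rec3 <- tiny_records()
  names(rec3)[names(rec3) == "raw_name"] <- "taxon"
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(rec3, path3, sep = ",", row.names = FALSE, quote = TRUE)
  expect_equal(read_surveys(path3, col_map = c(raw_name = "taxon"))$raw_name,
               tiny_records()$raw_name)
})

test_that("newick reader validates what the signal statistics need", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", path)
  tr <- read_newick(path)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  writeLines("((A,B),(C,D));", path)     # no branch lengths
  expect_error(read_newick(path), "branch lengths")
})

test_that("attribute tables are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(species = c("Aa bb", "Cc dd"), genus = c("Aa", "Cc"),
                   genus_size = c(3, 1), occupancy = c(0.2, 0.9))
  utils::write.csv(df, path, row.names = FALSE)
  expect_equal(read_species_attributes(path)$genus_size, c(3, 1))
  df$occupancy[1] <- 1.7
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_species_attributes(path), "occupancy")
})
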