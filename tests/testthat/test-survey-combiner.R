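test_that("combining species sets follows the acceptance rule", {
  sets <- list(c("A", "B", "C"), c("A", "B"), c("A", "D"))
  expect_equal(combine_surveys(sets, acceptance_rule("all_of_k")), "A")
  expect_equal(combine_surveys(sets, acceptance_rule("at_least_m_of_k", 2)),
               c("A", "B"))
  expect_equal(combine_surveys(sets, acceptance_rule("union")),
               c("A", "B", "C", "D"))
  expect_error(combine_surveys(sets[1:2], acceptance_rule("at_least_m_of_k", 3)),
               "exceeds")
})

test_that("survey species sets exclude cautious and mythical records and reject mixed sites", {
  cl <- tiny_classified()
  sets <- survey_species_sets(cl)
  expect_false("Carex" %in% unlist(sets))
  expect_setequal(sets[["s1"]],
                  c("Carex flacca", "Trifolium pratense", "Salvia pratensis"))
  cl2 <- cl
  cl2$site_id[1] <- "othersite"
  expect_error(survey_species_sets(cl2), "more than one site")
})

test_that("k = 1 bootstrap means equal per-survey averages; results are seed-reproducible", {
  fx <- combiner_fixture()
  res <- bootstrap_combination(fx$classified, fx$ref, k = 1,
                               rule = acceptance_rule("all_of_k"),
                               n_boot = 3000, seed = 9)
  # per-survey TP counts are 2, 2, 1 and FP counts 1, 0, 1
  expect_equal(res$mean_tp, mean(c(2, 2, 1)), tolerance = 0.05)
  expect_equal(res$mean_fp, mean(c(1, 0, 1)), tolerance = 0.05)
  res2 <- bootstrap_combination(fx$classified, fx$ref, k = 1,
                                rule = acceptance_rule("all_of_k"),
                                n_boot = 3000, seed = 9)
  expect_identical(res, res2)
  expect_error(bootstrap_combination(fx$classified, fx$ref, k = 4,
                                     rule = acceptance_rule("all_of_k"),
                                     n_boot = 10, seed = 1), "exceeds the pool")
})

test_that("bootstrap means converge on the exhaustive pair average", {
  fx <- combiner_fixture()
  ex <- enumerate_combination(fx$classified, fx$ref, k = 2, m = 2)
  res <- bootstrap_combination(fx$classified, fx$ref, k = 2,
                               rule = acceptance_rule("all_of_k"),
                               n_boot = 10000, seed = 4)
  for (q in c("tp", "fp", "fn")) {
    se <- ex$sd[[q]] / sqrt(res$n_boot)
    expect_lt(abs(res[[paste0("mean_", q)]] - ex$mean[[q]]),
              3 * se + 1e-12)
  }
})

test_that("independent false-positive draws almost never collide at k = 2", {
  # every observer draws FP species uniformly from a large pool, so the
  # chance two surveys share an FP species is tiny: mean_fp at k = 2 under
  # all_of_k must be far below mean_fp at k = 1
  w <- generate_world(world_config(n_species_regional = 1000, n_genera = 200,
                                   site_size = 80, fp_rate = 2,
                                   rarity_bias = 0, genus_bias = 0,
                                   mythical_rate = 0, cautious_rate = 0,
                                   seed = 31))
  sim <- simulate_surveys(w, 10, seed = 32)
  cl <- classify_records(sim$records, w$references, w$checklist)
  ref <- add_fp_pool(w$references, cl)[["site1"]]
  r1 <- bootstrap_combination(cl, ref, 1, acceptance_rule("all_of_k"),
                              n_boot = 2000, seed = 33)
  r2 <- bootstrap_combination(cl, ref, 2, acceptance_rule("all_of_k"),
                              n_boot = 2000, seed = 34)
  expect_gt(r1$mean_fp, 1)
  expect_lt(r2$mean_fp, 0.15 * r1$mean_fp)
})

test_that("confusion summary implements the false-positive-pool true-negative convention", {
  mk <- function(tp, fp, fn) structure(list(site_id = "x", mean_tp = tp,
                                            mean_fp = fp, mean_fn = fn),
                                       class = "combination_result")
  ref <- list(site_id = "x", fp_pool = sprintf("sp%02d", 1:86))
  cs <- confusion(mk(80, 3, 20), ref)
  expect_equal(cs$sensitivity, 0.80)
  expect_equal(cs$tn, 83)
  expect_equal(cs$specificity, 83 / 86)
  # zero false positives give perfect specificity
  expect_equal(confusion(mk(80, 0, 20), ref)$specificity, 1)
  expect_error(confusion(mk(1, 90, 1), ref), "integrity")
})

test_that("sweep tables respect conservation and the rule monotonicity chain", {
  for (seed in 1:5) {
    fx <- random_site_fixture(n_surveys = 4, seed = seed)
    n_acc <- length(fx$ref$accepted_species)
    sw <- threshold_sweep(fx$classified, fx$ref, k_range = 1:3,
                          rules = list(acceptance_rule("all_of_k"),
                                       acceptance_rule("at_least_m_of_k", 2),
                                       acceptance_rule("union")),
                          n_boot = 400, seed = seed)
    expect_equal(sw$mean_tp + sw$mean_fn, rep(n_acc, nrow(sw)))
    # all_of_k accepts a subset of at_least_2, which accepts a subset of union
    for (k in 2:3) {
      fp <- setNames(sw$mean_fp[sw$k == k], sw$rule[sw$k == k])
      expect_lte(fp[["all"]], fp[["atleast2"]] + 1e-9)
      expect_lte(fp[["atleast2"]], fp[["union"]] + 1e-9)
      tp <- setNames(sw$mean_tp[sw$k == k], sw$rule[sw$k == k])
      expect_lte(tp[["all"]], tp[["atleast2"]] + 1e-9)
      expect_lte(tp[["atleast2"]], tp[["union"]] + 1e-9)
    }
    # intersection rule: false positives cannot increase with k
    fp_all <- sw$mean_fp[sw$rule == "all"]
    expect_true(all(diff(fp_all) <= 1e-9))
    # union rule: sensitivity non-decreasing, specificity non-increasing in k
    expect_true(all(diff(sw$sensitivity[sw$rule == "union"]) >= -1e-9))
    expect_true(all(diff(sw$specificity[sw$rule == "union"]) <= 1e-9))
  }
})

test_that("agreement at two of three surveys restores single-survey sensitivity", {
  # on worlds with realistic detectabilities, the at-least-2-of-3 rule has
  # sensitivity close to a single survey while cutting false positives
  # detectability U-shaped (mass near 0 and 1, still 75% below 0.5), the
  # regime in which 2-of-3 agreement approximately preserves sensitivity
  w <- generate_world(world_config(n_sites = 1,
                                   detectability_beta = c(0.3, 0.766),
                                   seed = 41))
  sim <- simulate_surveys(w, 12, seed = 42)
  cl <- classify_records(sim$records, w$references, w$checklist)
  ref <- add_fp_pool(w$references, cl)[["site1"]]
  s1 <- confusion(bootstrap_combination(cl, ref, 1, acceptance_rule("all_of_k"),
                                        2000, 43), ref)
  s23 <- confusion(bootstrap_combination(cl, ref, 3,
                                         acceptance_rule("at_least_m_of_k", 2),
                                         2000, 44), ref)
  expect_equal(s23$sensitivity, s1$sensitivity, tolerance = 0.12)
  expect_lt(s23$fp, 0.5 * s1$fp)
})
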