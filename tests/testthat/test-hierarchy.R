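test_that("the first tier that fires wins", {
  # tetanus plus a lower-tier cause (prematurity): tetanus is tier 1
  rec <- set_yes(blank_records(1, age_days = 7L),
                 c("convulsions", "suckled_normally_after_birth",
                   "stopped_suckling", "born_early"))
  res <- assign_cause(rec)
  expect_equal(res$single_cause, "neonatal_tetanus")
  expect_equal(res$tier_index, 1L)
})

test_that("records firing nothing fall through to unspecified", {
  res <- assign_cause(blank_records(1, age_days = 50L))
  expect_equal(res$single_cause, "unspecified")
  expect_equal(res$tier_index, length(default_hierarchy()$tiers))
})

test_that("the simultaneous tier yields combination categories", {
  # measles + pneumonia co-firing
  r1 <- set_yes(blank_records(1, age_days = 200L),
                c("rash_3plus_days", "fever", "cough", "chest_indrawing"))
  expect_equal(assign_causes(r1)$cause, "measles_with_ari_or_diarrhea")
  # pneumonia + diarrhea co-firing (no measles)
  r2 <- set_yes(blank_records(1, age_days = 200L),
                c("cough", "chest_indrawing", "loose_stools",
                  "very_frequent_stools"))
  expect_equal(assign_causes(r2)$cause, "ari_and_diarrhea")
  # single causes stay single
  r3 <- set_yes(blank_records(1, age_days = 200L), c("rash_3plus_days", "fever"))
  expect_equal(assign_causes(r3)$cause, "measles")
})

test_that("co-firing possible pneumonia/diarrhea is held as the comorbid category", {
  r <- set_yes(blank_records(1, age_days = 200L),
               c("cough", "fever", "loose_stools"))
  expect_equal(assign_causes(r)$cause, "possible_ari_and_diarrhea")
})

test_that("multi-cause mode returns every firing cause", {
  rec <- set_yes(blank_records(1, age_days = 7L),
                 c("convulsions", "suckled_normally_after_birth",
                   "stopped_suckling", "fever"))
  causes <- assign_multicause(rec)
  expect_true(all(c("neonatal_tetanus", "other_possible_serious_infection")
                  %in% causes))
  expect_equal(assign_multicause(blank_records(1)), "unspecified")
})

test_that("resolve_multicause picks the smallest tier and honors promotions", {
  expect_equal(resolve_multicause(c("malnutrition", "neonatal_tetanus")),
               "neonatal_tetanus")
  expect_equal(resolve_multicause("pneumonia"), "pneumonia")
  # prematurity/LBW is deliberately ranked before other possible serious
  # infections in the standardized order
  expect_equal(resolve_multicause(c("prematurity_lbw",
                                    "other_possible_serious_infection")),
               "prematurity_lbw")
  expect_error(resolve_multicause("not_a_cause"), "hierarchy")
})

test_that("resolving the multi-cause set reproduces hierarchical assignment", {
  pop <- generate_population(synthetic_config(), seed = 55)
  rec <- harmonize_waves(pop$records)
  hier <- default_hierarchy()
  defs <- default_definitions()
  single <- assign_causes(rec, hier, defs)$cause
  multi <- assign_multicause(rec, defs)
  resolved <- vapply(multi, resolve_multicause, "", hierarchy = hier)
  expect_identical(unname(resolved), single)
})

test_that("assignment is invariant to cause order within a tier and to record order", {
  pop <- generate_population(synthetic_config(), seed = 66)
  rec <- harmonize_waves(pop$records)
  hier <- default_hierarchy()
  tiers <- hier$tiers
  tiers[[3]]$causes <- rev(tiers[[3]]$causes)  # simultaneous tier
  tiers[[6]]$causes <- rev(tiers[[6]]$causes)  # possible pair
  hier_rev <- va_hierarchy(tiers, version = "reordered-within")
  expect_identical(assign_causes(rec, hier)$cause,
                   assign_causes(rec, hier_rev)$cause)
  idx <- rev(seq_len(nrow(rec)))
  shuffled <- assign_causes(records_subset(rec, idx))
  expect_identical(shuffled$cause[order(match(shuffled$record_id,
                                              rec$record_id))],
                   assign_causes(rec)$cause)
})

test_that("reordering two tiers only affects records firing causes in both", {
  only_prem <- set_yes(blank_records(1, age_days = 20L), "born_early")
  only_opsi <- set_yes(blank_records(1, age_days = 20L),
                       c("fever", "convulsions"))
  both <- set_yes(blank_records(1, age_days = 20L),
                  c("born_early", "fever", "convulsions"))
  hier <- default_hierarchy()
  demoted <- swap_hierarchy_tiers(hier, "prematurity_lbw",
                                  "other_possible_serious_infection")
  for (r in list(only_prem, only_opsi)) {
    expect_equal(assign_causes(r, hier)$cause, assign_causes(r, demoted)$cause)
  }
  expect_equal(assign_causes(both, hier)$cause, "prematurity_lbw")
  expect_equal(assign_causes(both, demoted)$cause,
               "other_possible_serious_infection")
})

test_that("hierarchy construction rejects malformed tier structures", {
  expect_error(va_hierarchy(list(list(causes = "pneumonia"))), "unspecified")
  expect_error(va_hierarchy(list(list(causes = "pneumonia"),
                                 list(causes = "pneumonia"),
                                 list(causes = "unspecified"))),
               "more than one tier")
  expect_error(va_hierarchy(list(
    list(causes = c("measles", "pneumonia", "diarrhea"), mode = "simultaneous"),
    list(causes = c("possible_pneumonia", "possible_diarrhea"),
         mode = "simultaneous"),
    list(causes = "unspecified"))), "simultaneous")
  # a hierarchy cause without a definition fails at assignment construction
  defs <- va_definition_set(list(
    va_definition("injury", "both", va_sym("injury_accident"))))
  hier <- va_hierarchy(list(list(causes = "injury"),
                            list(causes = "malnutrition"),
                            list(causes = "unspecified")))
  expect_error(assign_causes(blank_records(1), hier, defs), "malnutrition")
})

test_that("hierarchy-insensitive share is 1 when no record fires twice", {
  # all records fire exactly one cause
  rec <- set_yes(blank_records(4, age_days = 300L), "injury_accident")
  expect_equal(fraction_hierarchy_insensitive(rec), 1)
  # no record fires anything: all unspecified singletons
  expect_equal(fraction_hierarchy_insensitive(blank_records(4)), 1)
})

test_that("hierarchy-insensitive share matches the generator's comorbidity rate", {
  # postneonatal-only noiseless population in which the only multi-diagnosis
  # mechanism is the ARI x diarrhea comorbidity
  cfg <- synthetic_config(
    psus_per_stratum = 8, deaths_per_psu = 60,
    neonatal_share = 0,
    cause_mix_postneonate = c(pneumonia = 0.35, diarrhea = 0.25,
                              injury = 0.2, malnutrition = 0.2),
    sensitivity = 1, fp_rate = 0, comorbidity_ari_diarrhea = 0.3,
    possible_fraction_postneonate = 0, oversample_factor = 1)
  pop <- generate_population(cfg, seed = 12)
  got <- fraction_hierarchy_insensitive(harmonize_waves(pop$records))
  p_multi <- 0.3 * (0.35 + 0.25)
  n <- nrow(pop$records)
  se <- sqrt(p_multi * (1 - p_multi) / n)
  expect_lt(abs(got - (1 - p_multi)), 4 * se)
})

test_that("hierarchies round-trip through YAML", {
  hier <- default_hierarchy()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hierarchy(hier, path)
  back <- read_hierarchy(path)
  expect_equal(back$version, hier$version)
  expect_equal(back$tiers, hier$tiers)
})
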