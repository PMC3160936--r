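test_that("read/write round-trip is lossless on valid files", {
  pop <- generate_population(synthetic_config(n_strata = 2,
                                              psus_per_stratum = 2,
                                              deaths_per_psu = 5), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_va_table(pop$records, path)
  back <- read_va_table(path, default_codebook())
  expect_equal(as.data.frame(back), as.data.frame(pop$records))
  # and again: write -> read of the re-read table is identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_va_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("tab-separated input is auto-detected", {
  rec <- blank_records(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_va_table(rec, path, sep = "\t")
  back <- read_va_table(path, default_codebook())
  expect_equal(nrow(back), 3L)
  expect_equal(back$fever, rep("no", 3))
})

test_that("malformed symptom values become missing with a warning", {
  rec <- blank_records(3)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(rec)
  df$fever[2] <- "9"
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_warning(back <- read_va_table(path, default_codebook()),
                 "missing")
  expect_equal(nrow(back), 3L)
  expect_equal(back$fever, c("no", "missing", "no"))
})

test_that("a missing design column is a hard error naming the column", {
  rec <- blank_records(2)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(rec)
  df$psu_id <- NULL
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_va_table(path, default_codebook()), "psu_id")
})

test_that("an unknown symptom column is a hard error", {
  rec <- blank_records(2)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(rec)
  df$not_a_symptom <- "yes"
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_va_table(path, default_codebook()), "not_a_symptom")
})

test_that("record validation enforces under-5 ages and positive weights", {
  rec <- as.data.frame(blank_records(2))
  bad_age <- rec; bad_age$age_days[1] <- 2000L
  expect_error(va_records(bad_age, default_codebook()), "age_days")
  bad_w <- rec; bad_w$weight[2] <- 0
  expect_error(va_records(bad_w, default_codebook()), "weight")
})

test_that("harmonization drops symptoms not asked in every wave present", {
  cb <- default_codebook()
  rec <- rbind(as.data.frame(blank_records(2, wave = "1993-1994")),
               as.data.frame(blank_records(2, wave = "1996-1997")),
               as.data.frame(blank_records(2, wave = "2004")))
  rec$record_id <- sprintf("M%03d", 1:6)
  rec <- va_records(rec, cb)
  harm <- harmonize_waves(rec)
  # a sign collected in 2004 alone disappears from every record
  expect_true("stiff_neck" %in% names(rec))
  expect_false("stiff_neck" %in% names(harm))
  expect_false("rapid_breathing" %in% names(harm))
  # all-wave signs survive
  expect_true(all(c("fever", "convulsions", "stopped_suckling") %in% names(harm)))
  # idempotent
  expect_equal(as.data.frame(harmonize_waves(harm)), as.data.frame(harm))
})

test_that("single-wave harmonization is the identity", {
  rec <- blank_records(3, wave = "2004")
  harm <- harmonize_waves(rec)
  expect_equal(as.data.frame(harm), as.data.frame(rec), ignore_attr = TRUE)
  expect_identical(names(harm), names(rec))
})

test_that("a 6th serious-infection sign missing from wave 1 leaves 5 after harmonization", {
  # purpose-built codebook: the 5 all-wave signs plus 'stopped_crying_si'
  # collected only in the later two waves
  waves_all <- c("w1", "w2", "w3")
  entry <- function(code, wv, si) {
    data.frame(code = code, label = code, age_group = "both",
               waves = I(list(wv)), serious_infection_sign = si,
               stringsAsFactors = FALSE)
  }
  cb <- va_codebook(rbind(
    entry("stopped_suckling", waves_all, TRUE),
    entry("difficult_breathing", waves_all, TRUE),
    entry("chest_indrawing", waves_all, TRUE),
    entry("convulsions", waves_all, TRUE),
    entry("fever", waves_all, TRUE),
    entry("stopped_crying_si", c("w2", "w3"), TRUE),
    entry("cough", waves_all, FALSE)
  ))
  df <- data.frame(record_id = c("a", "b", "c"), wave = c("w1", "w2", "w3"),
                   age_days = 10L, sex = "male", weight = 1,
                   stratum_id = "s", psu_id = "p",
                   stopped_suckling = "yes", difficult_breathing = "no",
                   chest_indrawing = "no", convulsions = "no", fever = "yes",
                   stopped_crying_si = "yes", cough = "no",
                   stringsAsFactors = FALSE)
  rec <- va_records(df, cb)
  harm <- harmonize_waves(rec)
  si_cols <- intersect(names(harm), cb$code[cb$serious_infection_sign])
  expect_setequal(si_cols, c("stopped_suckling", "difficult_breathing",
                             "chest_indrawing", "convulsions", "fever"))
  # sign counting uses only the common five
  expect_equal(count_serious_infection_signs(harm), c(2L, 2L, 2L))
})

test_that("harmonizing to an empty common symptom set errors", {
  waves_all <- c("wA", "wB")
  entry <- function(code, wv, si) {
    data.frame(code = code, label = code, age_group = "both",
               waves = I(list(wv)), serious_infection_sign = si,
               stringsAsFactors = FALSE)
  }
  cb <- va_codebook(rbind(
    entry("stopped_suckling", waves_all, TRUE),
    entry("difficult_breathing", waves_all, TRUE),
    entry("chest_indrawing", waves_all, TRUE),
    entry("convulsions", waves_all, TRUE),
    entry("fever", waves_all, TRUE),
    entry("only_in_a", "wA", FALSE)
  ))
  df <- data.frame(record_id = "x", wave = "wB", age_days = 5L, sex = "male",
                   weight = 1, stratum_id = "s", psu_id = "p",
                   only_in_a = "yes", stringsAsFactors = FALSE)
  rec <- va_records(df, cb)
  expect_error(harmonize_waves(rec), "drop")
})

test_that("codebook validation enforces unique codes and the 5 all-wave signs", {
  cb <- default_codebook()
  expect_error(va_codebook(rbind(as.data.frame(cb), as.data.frame(cb)[1, ])),
               "unique")
  entries <- as.data.frame(cb)
  entries$serious_infection_sign[entries$code == "fever"] <- FALSE
  expect_error(va_codebook(entries), "serious-infection")
})

test_that("codebook YAML round-trips", {
  cb <- default_codebook()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_equal(as.data.frame(back), as.data.frame(cb))
})
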