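test_that("a full study CSV yields the expected session-value cardinality", {
  truth <- seq(152, 186, length.out = 12)
  path <- write_fixture_csv(perfect_records(truth))
  ds <- read_measurements(path, schema = height_schema())
  sv <- session_values(ds, "height")
  expect_equal(nrow(sv), 12 * 3 * 2)
  expect_equal(sort(unique(ds$records$subject_id)),
               sprintf("S%02d", 1:12))
})

test_that("validation rejects duplicates and non-positive values with line numbers", {
  recs <- perfect_records(c(S1 = 170, S2 = 181), observers = "O1",
                          sessions = 1L)
  dup <- rbind(recs, recs[1, ])
  expect_error(read_measurements(write_fixture_csv(dup), height_schema()),
               "duplicated.*line")
  expect_error(reliability_dataset(dup, height_schema()), "duplicated")

  bad <- recs
  bad$value[2] <- -3
  # data row 2 sits on file line 3 (header = line 1)
  expect_error(read_measurements(write_fixture_csv(bad), height_schema()),
               "non-positive.*line\\(s\\) 3")

  txt <- bad
  txt$value <- c("170", "oops")
  expect_error(read_measurements(write_fixture_csv(txt), height_schema()),
               "malformed numeric value")
})

test_that("datasets round-trip through CSV unchanged", {
  ds <- simulate_reliability_study(synthetic_config(n_subjects = 5),
                                   seed = 3)
  path <- tempfile(fileext = ".csv")
  write_measurements(ds, path)
  back <- read_measurements(path, schema = ds$schema)
  key_order <- function(d) dplyr::arrange(d$records, variable, subject_id,
                                          observer_id, session, replicate)
  expect_equal(key_order(back), key_order(ds), tolerance = 1e-12)
  # writing the re-read dataset reproduces the file byte for byte
  path2 <- tempfile(fileext = ".csv")
  write_measurements(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("replicates average into session values, order-invariantly", {
  schema <- variable_descriptor("triceps_skinfold", "mm", "skinfold", 3L)
  recs <- data.frame(subject_id = "S1", observer_id = "O1", session = 1L,
                     replicate = 1:3, variable = "triceps_skinfold",
                     value = c(10, 11, 12))
  ds <- reliability_dataset(recs, schema)
  expect_equal(session_value(ds, "S1", "O1", 1, "triceps_skinfold"), 11)

  shuffled <- reliability_dataset(recs[c(3, 1, 2), ], schema)
  expect_equal(session_value(shuffled, "S1", "O1", 1, "triceps_skinfold"),
               11)

  # a single replicate is its own session value; absence is NA, not an error
  one <- reliability_dataset(recs[1, ], schema)
  expect_equal(session_value(one, "S1", "O1", 1, "triceps_skinfold"), 10)
  expect_true(is.na(session_value(one, "S2", "O1", 1, "triceps_skinfold")))
})

test_that("partial replicate sets are averaged with a warning", {
  schema <- variable_descriptor("triceps_skinfold", "mm", "skinfold", 3L)
  recs <- data.frame(subject_id = "S1", observer_id = "O1", session = 1L,
                     replicate = 1:2, variable = "triceps_skinfold",
                     value = c(4, 5))
  ds <- reliability_dataset(recs, schema)
  expect_warning(sv <- session_values(ds), "partial replicate")
  expect_equal(sv$value, 4.5)
  expect_equal(sv$n_replicates, 2L)
})

test_that("complete_cases applies per-variable listwise deletion", {
  truth <- seq(152, 186, length.out = 12)
  recs <- perfect_records(truth)
  # subject 12 misses all of session 2 (no-show on day two)
  recs <- recs[!(recs$subject_id == "S12" & recs$session == 2), ]
  ds <- reliability_dataset(recs, height_schema())
  cc <- complete_cases(ds, "height", quiet = TRUE)
  expect_equal(attr(cc, "n_retained"), 11L)
  expect_false("S12" %in% cc$records$subject_id)

  # idempotent, and never increases the subject count
  cc2 <- complete_cases(cc, "height", quiet = TRUE)
  expect_equal(attr(cc2, "n_retained"), 11L)
  expect_equal(cc2$records, cc$records)

  # an all-complete dataset is returned whole
  full <- reliability_dataset(perfect_records(truth), height_schema())
  expect_equal(attr(complete_cases(full, "height", quiet = TRUE),
                    "n_retained"), 12L)

  # a variable refused by some subjects shrinks only that variable's n
  wc_schema <- dplyr::bind_rows(
    height_schema(),
    variable_descriptor("waist_circumference", "cm", "trunk_girth"))
  wc <- perfect_records(truth[1:7], variable = "waist_circumference")
  both <- reliability_dataset(rbind(perfect_records(truth), wc), wc_schema)
  expect_equal(attr(complete_cases(both, "waist_circumference",
                                   quiet = TRUE), "n_retained"), 7L)
  expect_equal(attr(complete_cases(both, "height", quiet = TRUE),
                    "n_retained"), 12L)
})
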