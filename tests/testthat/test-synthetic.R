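test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(n_subjects = 6)
  a <- simulate_reliability_study(cfg, seed = 1)
  b <- simulate_reliability_study(cfg, seed = 1)
  expect_identical(a$records, b$records)
  expect_identical(attr(a, "truth")$observers, attr(b, "truth")$observers)

  c <- simulate_reliability_study(cfg, seed = 2)
  expect_equal(dim(c$records), dim(a$records))
  expect_false(isTRUE(all.equal(c$records$value, a$records$value)))
})

test_that("zero error SDs reproduce subject truth exactly", {
  vars <- synthetic_variable("height", "cm", "height", lo = 150, hi = 190,
                             bias_sd = 0, noise_sd = 0)
  ds <- simulate_reliability_study(
    synthetic_config(n_subjects = 8, variables = vars), seed = 5)
  truth <- attr(ds, "truth")$subjects
  merged <- merge(ds$records, truth, by = c("subject_id", "variable"))
  expect_equal(merged$value, merged$truth)
  expect_equal(inter_observer_table(ds, "height")$tem, c(0, 0))
  expect_equal(intra_observer_table(ds, "height")$tem, c(0, 0, 0))
})

test_that("defaults emulate the study design and respect truth ranges", {
  ds <- simulate_reliability_study(synthetic_config(), seed = 9)
  expect_equal(length(unique(ds$records$subject_id)), 12L)
  expect_equal(ds$observers, c("O1", "O2", "O3"))
  expect_equal(ds$sessions, 1:2)
  expect_setequal(unique(ds$records$variable), anthro_schema()$name)
  # triplicate skinfold, single replicate elsewhere
  reps <- tapply(ds$records$replicate, ds$records$variable, max)
  expect_equal(unname(reps[["triceps_skinfold"]]), 3L)
  expect_equal(unname(reps[["height"]]), 1L)
  expect_equal(nrow(ds$records), 12 * 3 * 2 * (4 + 3))
  # heights stay near the declared truth range (bias 0.8 + noise 0.5)
  h <- ds$records$value[ds$records$variable == "height"]
  expect_true(all(h > 152 - 8 & h < 186 + 8))
  expect_true(all(ds$records$value > 0))
})

test_that("adding an observer leaves existing observers' data unchanged", {
  cfg2 <- synthetic_config(n_subjects = 6, observers = 2L)
  cfg3 <- synthetic_config(n_subjects = 6, observers = 3L)
  a <- simulate_reliability_study(cfg2, seed = 4)$records
  b <- simulate_reliability_study(cfg3, seed = 4)$records
  b12 <- b[b$observer_id %in% c("O1", "O2"), ]
  ord <- function(d) dplyr::arrange(d, variable, observer_id, subject_id,
                                    session, replicate)
  expect_equal(ord(b12), ord(a))
})

test_that("missingness rules reproduce the no-show and refusal patterns", {
  miss <- list(
    subject_sessions = data.frame(subject_id = "S12", session = 2L),
    variable_subjects = data.frame(
      variable = "waist_circumference",
      subject_id = sprintf("S%02d", 8:12)))
  ds <- simulate_reliability_study(synthetic_config(missing = miss),
                                   seed = 6)
  expect_equal(attr(complete_cases(ds, "height", quiet = TRUE),
                    "n_retained"), 11L)
  # S12's day-2 no-show also hits the WC refusal set: 12 - 5 = 7 remain
  expect_equal(attr(complete_cases(ds, "waist_circumference",
                                   quiet = TRUE), "n_retained"), 7L)
})

test_that("recovery error shrinks as the subject count grows", {
  rel_err_intra <- function(n, seed) {
    ds <- simulate_reliability_study(one_var_config(n, noise_sd = 0.5),
                                     seed = seed)
    rep <- recovery_report(ds)
    mean(rep$relative_error[startsWith(rep$component, "intra")])
  }
  seeds <- 11:20
  small <- mean(vapply(seeds, function(s) rel_err_intra(40, s), numeric(1)))
  large <- mean(vapply(seeds, function(s) rel_err_intra(800, s), numeric(1)))
  expect_lt(large, small)
})

test_that("recovery report pairs estimators with their generator targets", {
  ds <- simulate_reliability_study(one_var_config(500, noise_sd = 0.5,
                                                  bias_sd = 1.0),
                                   seed = 8)
  rep <- recovery_report(ds)
  expect_setequal(unique(rep$component),
                  c("intra:O1", "intra:O2", "intra:O3",
                    "inter:s1", "inter:s2"))
  intra <- rep[startsWith(rep$component, "intra"), ]
  expect_equal(unique(intra$target), 0.5)
  inter <- rep[startsWith(rep$component, "inter"), ]
  # realized-panel target: sample SD of the drawn biases plus noise
  truth <- attr(ds, "truth")$observers
  expect_equal(unique(inter$target),
               sqrt(var(truth$bias) + 0.25), tolerance = 1e-12)
  expect_equal(unique(inter$nominal), sqrt(1 + 0.25), tolerance = 1e-12)

  # a noiseless generator is recovered exactly
  ds0 <- simulate_reliability_study(one_var_config(20, noise_sd = 0),
                                    seed = 8)
  rep0 <- recovery_report(ds0)
  expect_true(all(rep0$estimate == 0))
})
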