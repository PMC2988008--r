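# Fixture builders: all test data is constructed in code.

# Deterministic records for one variable with zero measurement error:
# every observer/session/replicate reading equals the subject's truth.
perfect_records <- function(truth, observers = c("O1", "O2", "O3"),
                            sessions = 1:2, variable = "height",
                            replicates = 1L) {
  subjects <- names(truth) %||% sprintf("S%02d", seq_along(truth))
  g <- expand.grid(subject_id = subjects, observer_id = observers,
                   session = sessions, replicate = seq_len(replicates),
                   stringsAsFactors = FALSE)
  g$variable <- variable
  g$value <- unname(truth[match(g$subject_id, subjects)])
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

height_schema <- function() variable_descriptor("height", "cm", "height")

# A single-variable synthetic study configuration.
one_var_config <- function(n_subjects, noise_sd, bias_sd = 0,
                           sessions = 2L, observers = 3L,
                           replicates = 1L, session_effect_sd = 0) {
  synthetic_config(
    n_subjects = n_subjects, observers = observers, sessions = sessions,
    variables = synthetic_variable("height", "cm", "height",
                                   replicates_per_session = replicates,
                                   lo = 150, hi = 190,
                                   bias_sd = bias_sd, noise_sd = noise_sd,
                                   session_effect_sd = session_effect_sd))
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
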