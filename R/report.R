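# Reporting layer: formatted TSV tables, a versioned JSON report, and
# the analyze / simulate / attribution drivers behind the command-line
# interface. Rendering adds no computation: every number in a rendered
# table is re-derivable from the JSON report.

REPORT_SCHEMA_VERSION <- "1"

#' Reporting precision
#'
#' Rounding applied only at the rendering layer: TEM, R and CV to two
#' decimals, %TEM to three significant figures.
#'
#' @param tem,r,cv Decimal places for TEM, R, CV.
#' @param percent Significant figures for %TEM.
#' @return A list of precision settings.
#' @export
reporting_precision <- function(tem = 2L, r = 2L, cv = 2L, percent = 3L) {
  list(tem = tem, r = r, cv = cv, percent = percent)
}

fmt_dec <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round(x, digits), format = "f",
                               digits = digits))
}

fmt_sig <- function(x, sig) {
  ifelse(is.na(x), "", as.character(signif(x, sig)))
}

format_reliability_table <- function(tab, precision = reporting_precision()) {
  out <- tab
  for (col in intersect(c("tem", "total_tem", "inter_tem", "mean", "sd",
                          "ci_halfwidth", "best_tem", "worst_tem"),
                        names(out)))
    out[[col]] <- fmt_dec(out[[col]], precision$tem)
  for (col in intersect(c("r", "r_raw"), names(out)))
    out[[col]] <- fmt_dec(out[[col]], precision$r)
  for (col in intersect("cv", names(out)))
    out[[col]] <- fmt_dec(out[[col]], precision$cv)
  for (col in intersect(c("percent_tem", "percent_total_tem",
                          "percent_of_gain"), names(out)))
    out[[col]] <- fmt_sig(out[[col]], precision$percent)
  if ("intra_tems" %in% names(out))
    out$intra_tems <- vapply(out$intra_tems, function(x)
      paste(sprintf("%s=%s", names(x), fmt_dec(x, precision$tem)),
            collapse = ";"), character(1))
  out
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Bundled reference reliability summary
#'
#' Summary statistics (CV, TEM, %TEM, R) from a published two-occasion
#' observer-reliability study of five anthropometric measures: 12 adult
#' volunteers measured by three newly trained observers on two
#' consecutive days, at the start (occasion A) and end (occasion B) of a
#' longitudinal cohort. The raw measurements were never deposited; these
#' per-cell summaries are the study's published inter-observer
#' (per-session) and intra-observer (per-observer) results, used in
#' examples and internal-consistency checks.
#'
#' @return A tibble with columns `analysis` (`inter`/`intra`),
#'   `occasion`, `session`, `observer`, `variable`, `cv`, `tem`,
#'   `percent_tem`, `r`. TEM is in the variable's natural unit (cm, kg
#'   or mm); CV is a fraction; R is the clamped reliability coefficient.
#' @export
#' @examples
#' head(reference_study_summary())
reference_study_summary <- function() {
  path <- system.file("extdata", "reliability_summary.csv",
                      package = "temrel", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

resolve_inputs <- function(inputs, schema) {
  if (inherits(inputs, "reliability_dataset")) inputs <- list(A = inputs)
  if (is.character(inputs)) {
    stems <- sub("\\.[^.]*$", "", basename(inputs))
    labels <- names(inputs) %||% make.unique(stems)
    labels[!nzchar(labels)] <- stems[!nzchar(labels)]
    inputs <- stats::setNames(
      lapply(inputs, read_measurements, schema = schema), labels)
  }
  if (!is.list(inputs) || !all(vapply(inputs, inherits, logical(1),
                                      "reliability_dataset")))
    stop("`inputs` must be CSV path(s) or reliability_dataset object(s)",
         call. = FALSE)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    names(inputs) <- LETTERS[seq_along(inputs)]
  inputs
}

#' Run the full reliability analysis and write a report bundle
#'
#' Reads one or more study occasions, builds the inter-observer,
#' intra-observer and (for the occasions jointly) total-TEM tables,
#' classifies every estimate against the acceptability thresholds and,
#' when hypothesized gains are supplied, derives best/worst-case change
#' attribution. Writes formatted TSV tables
#' (`table1_inter.tsv`, `table2_intra.tsv`, `table3_total.tsv`,
#' `table4_attribution.tsv`), a machine-readable `report.json` (schema
#' version 1, raw unrounded numbers, per-cell n, verdicts and the
#' collected warnings) and an `analyze.log`.
#'
#' @param inputs CSV path(s) (optionally named by occasion) or
#'   `reliability_dataset` object(s).
#' @param outdir Output directory (created if needed).
#' @param schema Variable schema, see [anthro_schema()].
#' @param thresholds [acceptability_thresholds()] object.
#' @param inter_session_policy Passed to [total_comparison_table()].
#' @param gains Optional named numeric vector of hypothesized
#'   longitudinal gains (units of each variable), e.g.
#'   `c(weight = 2.8, muac = 1)`; enables the attribution table.
#' @param precision [reporting_precision()] settings.
#' @param quiet Suppress progress messages.
#' @return The report bundle (a list), invisibly.
#' @export
run_analyze <- function(inputs, outdir, schema = anthro_schema(),
                        thresholds = acceptability_thresholds(),
                        inter_session_policy = "first", gains = NULL,
                        precision = reporting_precision(), quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  datasets <- withCallingHandlers(
    resolve_inputs(inputs, schema),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  variables <- schema$name

  inter_rows <- list(); intra_rows <- list(); class_rows <- list()
  withCallingHandlers({
    for (occ in names(datasets)) {
      ds <- datasets[[occ]]
      for (v in intersect(variables, unique(ds$records$variable))) {
        kind <- schema$kind[schema$name == v]
        it <- inter_observer_table(ds, v)
        it$occasion <- occ; it$variable <- v
        inter_rows[[length(inter_rows) + 1L]] <- it
        for (i in seq_len(nrow(it)))
          note("inter %s/%s session %s: n = %s", occ, v, it$session[i],
               it$n_subjects[i] %||% NA)
        ot <- intra_observer_table(ds, v)
        ot$occasion <- occ; ot$variable <- v
        intra_rows[[length(intra_rows) + 1L]] <- ot
        for (i in seq_len(nrow(ot)))
          note("intra %s/%s observer %s: n = %s", occ, v, ot$observer[i],
               ot$n_subjects[i] %||% NA)
        for (tab in list(it, ot)) {
          for (i in seq_len(nrow(tab))) {
            if (is.na(tab$tem[i])) next
            verd <- classify_acceptability(tab[i, ], kind, thresholds)
            verd$occasion <- occ; verd$variable <- v
            verd$analysis <- if ("session" %in% names(tab)) "inter"
            else "intra"
            verd$label <- as.character(
              if ("session" %in% names(tab)) tab$session[i]
              else tab$observer[i])
            class_rows[[length(class_rows) + 1L]] <- verd
          }
        }
      }
    }
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) invokeRestart("muffleMessage"))

  table1 <- dplyr::bind_rows(inter_rows)
  table2 <- dplyr::bind_rows(intra_rows)
  col1 <- c("occasion", "variable", "session", "n_subjects", "k_observers",
            "mean", "sd", "cv", "tem", "percent_tem", "r_raw", "r", "note")
  col2 <- c("occasion", "variable", "observer", "n_subjects", "mean", "sd",
            "cv", "tem", "percent_tem", "r_raw", "r", "note")
  table1 <- table1[intersect(col1, names(table1))]
  table2 <- table2[intersect(col2, names(table2))]

  table3 <- NULL
  withCallingHandlers({
    t3 <- list()
    for (v in variables) {
      have <- vapply(datasets, function(d) v %in% d$records$variable,
                     logical(1))
      if (!any(have)) next
      t3[[v]] <- tryCatch(
        total_comparison_table(datasets[have], v,
                               inter_session_policy = inter_session_policy),
        error = function(e) {
          warnings_seen <<- c(warnings_seen, paste0(
            "total TEM unavailable for ", v, ": ", conditionMessage(e)))
          NULL
        })
      if (!is.null(t3[[v]])) {
        verd_src <- t3[[v]]
        kind <- schema$kind[schema$name == v]
        for (i in seq_len(nrow(verd_src))) {
          verd <- classify_acceptability(
            list(tem = verd_src$total_tem[i],
                 percent_tem = verd_src$percent_total_tem[i],
                 r = verd_src$r[i]), kind, thresholds)
          verd$occasion <- verd_src$occasion[i]; verd$variable <- v
          verd$analysis <- "total"; verd$label <- verd_src$occasion[i]
          class_rows[[length(class_rows) + 1L]] <- verd
        }
      }
    }
    table3 <- dplyr::bind_rows(t3)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) invokeRestart("muffleMessage"))

  table4 <- NULL
  if (!is.null(gains)) {
    stopifnot(is.numeric(gains), !is.null(names(gains)), all(gains > 0))
    t4 <- list()
    for (v in names(gains)) {
      sub_i <- table2[table2$variable == v & !is.na(table2$tem), ]
      sub_e <- table1[table1$variable == v & !is.na(table1$tem), ]
      if (!nrow(sub_i) || !nrow(sub_e)) {
        warnings_seen <- c(warnings_seen, paste0(
          "attribution skipped for ", v, ": no usable TEM components"))
        next
      }
      ext <- scenario_extremes(
        intra = data.frame(observer = sub_i$observer,
                           occasion = sub_i$occasion, tem = sub_i$tem),
        inter = data.frame(occasion = sub_e$occasion,
                           session = sub_e$session, tem = sub_e$tem))
      t4[[v]] <- attribution_table(ext, gains[[v]], variable = v)
    }
    table4 <- dplyr::bind_rows(t4)
  }

  classification <- dplyr::bind_rows(class_rows)
  if (nrow(classification))
    classification <- classification[c("occasion", "variable", "analysis",
                                       "label", "criterion", "value",
                                       "threshold", "pass")]

  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    config = list(inter_session_policy = inter_session_policy,
                  thresholds = unclass(thresholds),
                  gains = as.list(gains %||% stats::setNames(list(),
                                                             character())),
                  precision = precision,
                  variables = schema,
                  occasions = names(datasets)),
    tables = list(inter = table1, intra = table2, total = table3,
                  attribution = table4),
    classification = classification,
    warnings = warnings_seen)

  write_tsv(format_reliability_table(table1, precision),
            file.path(outdir, "table1_inter.tsv"))
  write_tsv(format_reliability_table(table2, precision),
            file.path(outdir, "table2_intra.tsv"))
  if (!is.null(table3) && nrow(table3))
    write_tsv(format_reliability_table(table3, precision),
              file.path(outdir, "table3_total.tsv"))
  if (!is.null(table4) && nrow(table4))
    write_tsv(format_reliability_table(table4, precision),
              file.path(outdir, "table4_attribution.tsv"))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  for (w in warnings_seen) note("warning: %s", w)
  writeLines(log_lines, file.path(outdir, "analyze.log"))
  invisible(report)
}

#' Simulate a study and write it to disk
#'
#' Generates a synthetic reliability dataset
#' ([simulate_reliability_study()]), writes the long-format CSV that
#' [read_measurements()] ingests, and a truth sidecar JSON (per-subject
#' truths, per-observer realized biases) for parameter-recovery checks.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer master seed.
#' @param out Output CSV path.
#' @param truth_out Truth sidecar path (default `<out>.truth.json`).
#' @return The generated dataset, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), seed = 1L, out,
                         truth_out = paste0(out, ".truth.json")) {
  ds <- simulate_reliability_study(config, seed = seed)
  write_measurements(ds, out)
  truth <- attr(ds, "truth")
  jsonlite::write_json(
    list(seed = seed,
         subjects = truth$subjects,
         observers = truth$observers),
    truth_out, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(ds)
}

#' Change attribution from a saved JSON report
#'
#' Re-derives the best/worst-case attribution table for one variable
#' from the intra/inter TEM components stored in a `report.json`
#' written by [run_analyze()].
#'
#' @param report A report bundle (as returned by [run_analyze()]) or the
#'   path to its `report.json`.
#' @param gain Hypothesized longitudinal gain, `> 0`.
#' @param variable Variable name.
#' @return An [attribution_table()] tibble.
#' @export
run_attribution <- function(report, gain, variable) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  t1 <- tibble::as_tibble(report$tables$inter)
  t2 <- tibble::as_tibble(report$tables$intra)
  sub_i <- t2[t2$variable == variable & !is.na(t2$tem), ]
  sub_e <- t1[t1$variable == variable & !is.na(t1$tem), ]
  if (!nrow(sub_i) || !nrow(sub_e))
    stop("report holds no usable TEM components for ", variable,
         call. = FALSE)
  ext <- scenario_extremes(
    intra = data.frame(observer = sub_i$observer, occasion = sub_i$occasion,
                       tem = sub_i$tem),
    inter = data.frame(occasion = sub_e$occasion, session = sub_e$session,
                       tem = sub_e$tem))
  attribution_table(ext, gain, variable = variable)
}
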