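# Study-level orchestration: the per-session inter-observer table, the
# per-observer intra-observer table, the between-occasion total-TEM
# comparison, acceptability verdicts, best/worst scenarios and change
# attribution. Table builders are deterministic given a dataset.

tem_result_row <- function(res) {
  tibble::as_tibble(as.data.frame(res))
}

na_result_row <- function() {
  tibble::tibble(n_subjects = NA_integer_, k_observers = NA_integer_,
                 mean = NA_real_, sd = NA_real_, cv = NA_real_,
                 tem = NA_real_, percent_tem = NA_real_, r_raw = NA_real_,
                 r = NA_real_)
}

#' Per-session inter-observer reliability table
#'
#' For each session, subjects with a session value from every declared
#' observer enter a K-observer TEM estimate ([multi_observer_tem()]).
#' Sessions where fewer than two observers have complete data are
#' reported as absent rows with a reason, never dropped silently.
#'
#' @param dataset A `reliability_dataset`.
#' @param variable Variable name to analyse.
#' @return A tibble with one row per session: `session`, `n_subjects`,
#'   `k_observers`, `mean`, `sd`, `cv`, `tem`, `percent_tem`, `r_raw`,
#'   `r`, `note`.
#' @export
inter_observer_table <- function(dataset, variable) {
  stopifnot(inherits(dataset, "reliability_dataset"))
  sv <- suppressWarnings(session_values(dataset, variable))
  rows <- lapply(dataset$sessions, function(s) {
    cell <- sv[sv$session == s, ]
    wide <- tidyr::pivot_wider(cell[c("subject_id", "observer_id", "value")],
                               names_from = "observer_id",
                               values_from = "value")
    obs_present <- intersect(dataset$observers, names(wide))
    wide <- wide[stats::complete.cases(wide[obs_present]), , drop = FALSE]
    if (length(obs_present) < 2L || nrow(wide) < 1L) {
      out <- na_result_row()
      out$note <- "fewer than 2 observers with complete subjects"
    } else {
      m <- as.matrix(wide[obs_present])
      out <- tem_result_row(multi_observer_tem(m))
      out$note <- NA_character_
    }
    dplyr::bind_cols(tibble::tibble(session = s), out)
  })
  dplyr::bind_rows(rows)
}

#' Per-observer intra-observer reliability table
#'
#' For each observer, a subject's session-1 and session-2 values form a
#' measurement pair and enter the paired-difference TEM
#' ([intra_pair_tem()]). Subjects missing either session for that
#' observer are dropped from that observer's estimate (listwise, per
#' observer). Datasets with more than two sessions use the first two
#' declared sessions.
#'
#' @inheritParams inter_observer_table
#' @return A tibble with one row per observer: `observer`, the
#'   `tem_result` columns, and `note`.
#' @export
intra_observer_table <- function(dataset, variable) {
  stopifnot(inherits(dataset, "reliability_dataset"))
  if (length(dataset$sessions) < 2L)
    stop("intra-observer analysis needs at least 2 sessions", call. = FALSE)
  ses <- dataset$sessions[1:2]
  sv <- suppressWarnings(session_values(dataset, variable))
  rows <- lapply(dataset$observers, function(o) {
    cell <- sv[sv$observer_id == o & sv$session %in% ses, ]
    wide <- tidyr::pivot_wider(cell[c("subject_id", "session", "value")],
                               names_from = "session",
                               values_from = "value",
                               names_prefix = "s")
    cols <- paste0("s", ses)
    if (!all(cols %in% names(wide))) {
      out <- na_result_row()
      out$note <- "observer lacks data for a required session"
      return(dplyr::bind_cols(tibble::tibble(observer = o), out))
    }
    wide <- wide[stats::complete.cases(wide[cols]), , drop = FALSE]
    if (nrow(wide) < 2L) {
      out <- na_result_row()
      out$note <- "fewer than 2 subjects with both sessions"
    } else {
      out <- tem_result_row(intra_pair_tem(wide[[cols[1]]], wide[[cols[2]]]))
      out$note <- NA_character_
    }
    dplyr::bind_cols(tibble::tibble(observer = o), out)
  })
  dplyr::bind_rows(rows)
}

pick_inter_tem <- function(inter_tab, policy) {
  ok <- inter_tab[!is.na(inter_tab$tem), ]
  if (!nrow(ok)) return(list(tem = NA_real_, session = NA_integer_))
  switch(policy,
         first = {
           s <- min(ok$session)
           list(tem = ok$tem[ok$session == s], session = s)
         },
         last = {
           s <- max(ok$session)
           list(tem = ok$tem[ok$session == s], session = s)
         },
         pooled = list(tem = sqrt(mean(ok$tem^2)), session = NA_integer_),
         stop("unknown inter_session_policy: ", policy, call. = FALSE))
}

#' Between-occasion total-TEM comparison table
#'
#' For each study occasion, pools the per-observer intra-observer TEMs
#' with one inter-observer TEM into the total TEM ([total_tem()]),
#' expresses it as a percentage of the occasion's grand mean, and
#' derives the reliability coefficient from the occasion's
#' between-subject SD.
#'
#' @param datasets Named list of `reliability_dataset` objects, one per
#'   study occasion.
#' @param variable Variable name to analyse.
#' @param inter_session_policy Which session's inter-observer TEM enters
#'   the total: `"first"` (default), `"last"`, or `"pooled"` (root mean
#'   square over sessions).
#' @return A tibble with one row per occasion: `occasion`, `total_tem`,
#'   `percent_total_tem`, `r_raw`, `r`, `inter_tem`, `inter_session`,
#'   plus a list-column `intra_tems` of the per-observer components.
#' @export
total_comparison_table <- function(datasets, variable,
                                   inter_session_policy = c("first", "last",
                                                            "pooled")) {
  inter_session_policy <- match.arg(inter_session_policy)
  if (!is.list(datasets) || is.null(names(datasets)) ||
      any(!nzchar(names(datasets))))
    stop("`datasets` must be a named list of reliability datasets",
         call. = FALSE)
  rows <- lapply(names(datasets), function(occ) {
    ds <- datasets[[occ]]
    stopifnot(inherits(ds, "reliability_dataset"))
    intra <- intra_observer_table(ds, variable)
    inter <- inter_observer_table(ds, variable)
    intra_ok <- intra[!is.na(intra$tem), ]
    pick <- pick_inter_tem(inter, inter_session_policy)
    if (!nrow(intra_ok) || is.na(pick$tem))
      stop("occasion '", occ, "': missing intra components or the ",
           inter_session_policy, "-session inter-observer TEM",
           call. = FALSE)
    tt <- total_tem(intra_ok$tem, pick$tem)
    cc <- complete_cases(ds, variable, quiet = TRUE)
    sv <- suppressWarnings(session_values(cc, variable))
    grand_mean <- mean(sv$value)
    subj_means <- tapply(sv$value, sv$subject_id, mean)
    subj_sd <- stats::sd(subj_means)
    rel <- if (is.finite(subj_sd) && subj_sd > 0)
      reliability_coefficient(tem = tt$total, sd = subj_sd)
    else list(r_raw = NA_real_, r = NA_real_)
    tibble::tibble(occasion = occ, variable = variable,
                   n_subjects = attr(cc, "n_retained"),
                   total_tem = tt$total,
                   percent_total_tem = percent_tem(tt$total, grand_mean),
                   r_raw = rel$r_raw, r = rel$r,
                   inter_tem = pick$tem, inter_session = pick$session,
                   intra_tems = list(stats::setNames(intra_ok$tem,
                                                     intra_ok$observer)))
  })
  dplyr::bind_rows(rows)
}

#' Classify a TEM estimate against acceptability standards
#'
#' Issues pass/fail verdicts for the absolute TEM (where an absolute
#' cutoff exists for the variable's kind: weight, height, limb girth),
#' the relative TEM, and the reliability coefficient, plus an overall
#' flag (all available criteria pass).
#'
#' @param result A `tem_result`, or a list / one-row data frame with
#'   elements `tem`, `percent_tem`, `r`.
#' @param kind Variable kind (see [variable_descriptor()]); unknown
#'   kinds fall back to the default %TEM cutoff and receive no
#'   absolute-TEM verdict.
#' @param thresholds An [acceptability_thresholds()] object.
#' @return A tibble with columns `criterion`, `value`, `threshold`,
#'   `pass`, and attribute `overall`.
#' @export
#' @examples
#' classify_acceptability(list(tem = 0.05, percent_tem = 0.8, r = 0.99),
#'                        kind = "weight")
classify_acceptability <- function(result, kind,
                                   thresholds = acceptability_thresholds()) {
  stopifnot(inherits(thresholds, "acceptability_thresholds"))
  tem <- result$tem
  pct <- result$percent_tem
  r <- result$r
  rows <- list()
  if (kind %in% names(thresholds$abs_tem)) {
    thr <- unname(thresholds$abs_tem[[kind]])
    rows$abs <- tibble::tibble(criterion = "absolute_tem", value = tem,
                               threshold = thr, pass = tem <= thr)
  }
  pthr <- unname(thresholds$percent_tem[[
    if (kind %in% names(thresholds$percent_tem)) kind else "default"]])
  rows$pct <- tibble::tibble(criterion = "percent_tem", value = pct,
                             threshold = pthr, pass = pct <= pthr)
  rows$r <- tibble::tibble(criterion = "reliability", value = r,
                           threshold = thresholds$r_min,
                           pass = r > thresholds$r_min)
  out <- dplyr::bind_rows(rows)
  attr(out, "overall") <- all(out$pass) && !anyNA(out$pass)
  out
}

#' Best/worst TEM scenarios across study occasions
#'
#' Selects, for each error component, its best (minimum) and worst
#' (maximum) TEM across occasions: per-observer intra-observer TEMs
#' across occasions, the inter-observer TEM across all occasion/session
#' cells, and a total recomputed via [total_tem()] from the selected
#' per-component extremes (extremes are taken on components, never on
#' printed totals).
#'
#' @param intra Data frame with columns `observer`, `occasion`, `tem`
#'   (per-observer intra-observer TEMs, one row per occasion).
#' @param inter Data frame with columns `occasion`, `session`, `tem`
#'   (inter-observer TEMs, one row per occasion/session cell).
#' @return A tibble with columns `component`, `best_tem`, `worst_tem`;
#'   components are `"intra:<observer>"`, `"inter"`, `"total"`.
#' @export
scenario_extremes <- function(intra, inter) {
  req_i <- c("observer", "occasion", "tem")
  req_e <- c("occasion", "session", "tem")
  if (!is.data.frame(intra) || !all(req_i %in% names(intra)))
    stop("`intra` needs columns ", paste(req_i, collapse = ", "),
         call. = FALSE)
  if (!is.data.frame(inter) || !all(req_e %in% names(inter)))
    stop("`inter` needs columns ", paste(req_e, collapse = ", "),
         call. = FALSE)
  intra <- intra[!is.na(intra$tem), ]
  inter <- inter[!is.na(inter$tem), ]
  if (!nrow(intra) || !nrow(inter))
    stop("at least one occasion of intra and inter results is required",
         call. = FALSE)
  by_obs <- dplyr::summarise(dplyr::group_by(intra, .data$observer),
                             best = min(.data$tem), worst = max(.data$tem),
                             .groups = "drop")
  rows <- tibble::tibble(component = paste0("intra:", by_obs$observer),
                         best_tem = by_obs$best, worst_tem = by_obs$worst)
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(component = "inter", best_tem = min(inter$tem),
                   worst_tem = max(inter$tem)),
    tibble::tibble(component = "total",
                   best_tem = total_tem(by_obs$best, min(inter$tem))$total,
                   worst_tem = total_tem(by_obs$worst,
                                         max(inter$tem))$total))
  rows
}

#' Fraction of a longitudinal change attributable to measurement error
#'
#' Given a TEM and a hypothesized longitudinal gain, computes the 95%
#' confidence half-width of imprecision ([ci95_halfwidth()]) and
#' expresses it as a percentage of that gain. Percentages above 100%
#' mean the expected change is smaller than the measurement noise band.
#'
#' @param tem TEM estimate, `>= 0` (vectorized).
#' @param gain Hypothesized change, `> 0`, in the same unit.
#' @param variable,scenario Optional labels carried into the output.
#' @return A tibble with `variable`, `scenario`, `tem`, `ci_halfwidth`,
#'   `percent_of_gain`.
#' @export
#' @examples
#' change_attribution(0.51, gain = 2.8)  # ~50.5% of the gain
change_attribution <- function(tem, gain, variable = NA_character_,
                               scenario = NA_character_) {
  check_finite(tem, "`tem`")
  check_finite(gain, "`gain`")
  if (length(gain) != 1L || gain <= 0)
    stop("`gain` must be a single value > 0", call. = FALSE)
  if (any(tem < 0)) stop("`tem` must be >= 0", call. = FALSE)
  ci <- ci95_halfwidth(tem)
  tibble::tibble(variable = variable, scenario = scenario, tem = tem,
                 gain = gain, ci_halfwidth = ci,
                 percent_of_gain = 100 * ci / gain)
}

#' Best/worst attribution table for one variable
#'
#' Applies [change_attribution()] to every component of a
#' [scenario_extremes()] result, producing the best-case and worst-case
#' share of a hypothesized gain taken up by the 95% imprecision band.
#'
#' @param extremes Output of [scenario_extremes()].
#' @param gain Hypothesized longitudinal gain, `> 0`.
#' @param variable Variable label carried into the output.
#' @return A tibble with one row per component and scenario.
#' @export
attribution_table <- function(extremes, gain, variable = NA_character_) {
  stopifnot(is.data.frame(extremes),
            all(c("component", "best_tem", "worst_tem") %in%
                  names(extremes)))
  best <- change_attribution(extremes$best_tem, gain, variable, "best")
  worst <- change_attribution(extremes$worst_tem, gain, variable, "worst")
  best$component <- extremes$component
  worst$component <- extremes$component
  out <- dplyr::bind_rows(best, worst)
  out[c("variable", "component", "scenario", "tem", "gain",
        "ci_halfwidth", "percent_of_gain")]
}
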