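# Core TEM estimators. All computations are exact (no rounding);
# rounding happens only in the reporting layer.

new_tem_result <- function(tem, grand_mean, subject_sd, n_subjects,
                           k_observers) {
  percent <- if (is.finite(grand_mean) && grand_mean > 0)
    100 * tem / grand_mean else NA_real_
  cv <- if (is.finite(subject_sd) && is.finite(grand_mean) && grand_mean > 0)
    subject_sd / grand_mean else NA_real_
  if (is.finite(subject_sd) && subject_sd > 0) {
    rel <- reliability_coefficient(tem = tem, sd = subject_sd)
    r_raw <- rel$r_raw; r <- rel$r
  } else {
    r_raw <- NA_real_; r <- NA_real_
  }
  structure(list(tem = tem, mean = grand_mean, sd = subject_sd, cv = cv,
                 percent_tem = percent, r_raw = r_raw, r = r,
                 n_subjects = as.integer(n_subjects),
                 k_observers = as.integer(k_observers)),
            class = "tem_result")
}

#' @export
print.tem_result <- function(x, ...) {
  cat(sprintf(
    "<tem_result> TEM %.4g | %%TEM %.4g | R %.4g (raw %.4g) | CV %.4g\n",
    x$tem, x$percent_tem, x$r, x$r_raw, x$cv))
  cat(sprintf("  mean %.4g, between-subject SD %.4g, n = %d, k = %d\n",
              x$mean, x$sd, x$n_subjects, x$k_observers))
  invisible(x)
}

#' @export
as.data.frame.tem_result <- function(x, ...) {
  data.frame(n_subjects = x$n_subjects, k_observers = x$k_observers,
             mean = x$mean, sd = x$sd, cv = x$cv, tem = x$tem,
             percent_tem = x$percent_tem, r_raw = x$r_raw, r = x$r)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
    stop(what, " must be finite numeric values", call. = FALSE)
  invisible(x)
}

#' Paired-difference TEM (two determinations per subject)
#'
#' The technical error of measurement for duplicate determinations —
#' either the same observer measuring on two occasions (intra-observer
#' TEM) or two observers measuring once each:
#' \deqn{TEM = \sqrt{\sum_i D_i^2 / (2N)}}
#' where \eqn{D_i} is the difference between a subject's two
#' measurements and \eqn{N} the number of subjects.
#'
#' @param first,second Numeric vectors of the paired determinations, one
#'   element per subject.
#' @return A `tem_result` with the TEM, the grand mean of all `2N`
#'   values, the between-subject SD (sample SD of per-subject means),
#'   the CV, %TEM and the reliability coefficient. `k_observers` is 1:
#'   the pair is a repetition, not an observer panel.
#' @export
#' @examples
#' intra_pair_tem(c(10, 20, 30), c(12, 19, 30))  # TEM = sqrt(5/6)
intra_pair_tem <- function(first, second) {
  check_finite(first, "`first`"); check_finite(second, "`second`")
  if (length(first) != length(second))
    stop("`first` and `second` must have the same length", call. = FALSE)
  n <- length(first)
  if (n < 2L)
    stop("at least 2 measurement pairs are required", call. = FALSE)
  d <- second - first
  tem <- sqrt(sum(d^2) / (2 * n))
  new_tem_result(tem, grand_mean = mean(c(first, second)),
                 subject_sd = stats::sd((first + second) / 2),
                 n_subjects = n, k_observers = 1L)
}

#' Multi-observer TEM (one determination per observer)
#'
#' The K-observer technical error of measurement:
#' \deqn{TEM = \sqrt{ \sum_i \left( \sum_k M_{ik}^2 -
#'   (\sum_k M_{ik})^2 / K \right) / (N(K-1)) }}
#' i.e. the root of the mean within-subject sample variance across the
#' K observers. With K = 2 it coincides with [intra_pair_tem()] on the
#' same pairs.
#'
#' @param values Numeric matrix (or data frame / list of equal-length
#'   rows) with one row per subject and one column per observer.
#' @return A `tem_result`; the between-subject SD is the sample SD of
#'   the per-subject means (NA with a single subject).
#' @export
#' @examples
#' multi_observer_tem(rbind(c(1, 2, 3)))  # TEM = 1
multi_observer_tem <- function(values) {
  if (is.list(values) && !is.data.frame(values)) {
    len <- lengths(values)
    if (length(unique(len)) != 1L)
      stop("ragged rows: every subject needs the same number of observer ",
           "values", call. = FALSE)
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  check_finite(values, "observer values")
  k <- ncol(values); n <- nrow(values)
  if (k < 2L) stop("at least 2 observers are required", call. = FALSE)
  if (n < 1L) stop("at least 1 subject is required", call. = FALSE)
  # row-centred form of sum(M^2) - (sum M)^2 / K: algebraically identical,
  # immune to the catastrophic cancellation of the raw-moment expression
  ss <- rowSums((values - rowMeans(values))^2)
  tem <- sqrt(sum(ss) / (n * (k - 1)))
  subj_sd <- if (n >= 2L) stats::sd(rowMeans(values)) else NA_real_
  new_tem_result(tem, grand_mean = mean(values), subject_sd = subj_sd,
                 n_subjects = n, k_observers = k)
}

#' Relative TEM
#'
#' Expresses an absolute TEM as a percentage of the measurement mean,
#' `%TEM = 100 * TEM / mean`, so that error can be compared across
#' variables measured in different units.
#'
#' @param tem Absolute TEM (same unit as the measurement), `>= 0`.
#' @param mean Mean of the measurements the TEM was estimated from,
#'   `> 0`.
#' @return `%TEM` as a percentage.
#' @export
#' @examples
#' percent_tem(2, 80)  # 2.5
percent_tem <- function(tem, mean) {
  check_finite(tem, "`tem`"); check_finite(mean, "`mean`")
  if (any(tem < 0)) stop("`tem` must be >= 0", call. = FALSE)
  if (any(mean <= 0)) stop("`mean` must be > 0", call. = FALSE)
  100 * tem / mean
}

#' Coefficient of reliability
#'
#' The proportion of between-subject variance free of measurement
#' error, `R = 1 - TEM^2 / SD^2`. Because the mean cancels, R can be
#' computed equivalently from the relative quantities:
#' `R = 1 - (%TEM / (100 * CV))^2`, with CV the between-subject SD
#' divided by the mean (a fraction). The raw value can be negative when
#' the error variance exceeds the between-subject variance; the clamped
#' value is floored at 0 for reporting.
#'
#' @param tem,sd Absolute TEM and between-subject SD (`sd > 0`); or
#' @param percent_tem,cv Relative TEM (%) and coefficient of variability
#'   (fraction, `cv > 0`) — supply either pair.
#' @return A list with `r_raw` (may be negative) and `r` (clamped to
#'   `[0, 1]`).
#' @export
#' @examples
#' reliability_coefficient(percent_tem = 18.8, cv = 0.62)$r  # ~0.91
#' reliability_coefficient(percent_tem = 83.7, cv = 0.64)    # clamped to 0
reliability_coefficient <- function(tem = NULL, sd = NULL,
                                    percent_tem = NULL, cv = NULL) {
  if (!is.null(tem) && !is.null(sd)) {
    check_finite(tem, "`tem`"); check_finite(sd, "`sd`")
    if (any(tem < 0)) stop("`tem` must be >= 0", call. = FALSE)
    if (any(sd <= 0)) stop("`sd` must be > 0", call. = FALSE)
    ratio <- tem / sd
  } else if (!is.null(percent_tem) && !is.null(cv)) {
    check_finite(percent_tem, "`percent_tem`"); check_finite(cv, "`cv`")
    if (any(percent_tem < 0)) stop("`percent_tem` must be >= 0",
                                   call. = FALSE)
    if (any(cv <= 0)) stop("`cv` must be > 0", call. = FALSE)
    ratio <- percent_tem / (100 * cv)
  } else {
    stop("supply either (tem, sd) or (percent_tem, cv)", call. = FALSE)
  }
  r_raw <- 1 - ratio^2
  list(r_raw = r_raw, r = pmin(1, pmax(0, r_raw)))
}

#' 95% confidence half-width of measurement imprecision
#'
#' Half-width of the 95% confidence band around a difference of two
#' measurements, each carrying its own technical error:
#' `1.96 * sqrt(tem_a^2 + tem_b^2)`. With a single TEM estimate the two
#' errors are taken equal, giving `1.96 * sqrt(2) * tem` (~2.772 * tem).
#'
#' @param tem_a First TEM, `>= 0`.
#' @param tem_b Second TEM; defaults to `tem_a`.
#' @return The half-width, in measurement units.
#' @export
#' @examples
#' ci95_halfwidth(0.51)  # ~1.414
ci95_halfwidth <- function(tem_a, tem_b = tem_a) {
  check_finite(tem_a, "`tem_a`"); check_finite(tem_b, "`tem_b`")
  if (any(tem_a < 0) || any(tem_b < 0))
    stop("TEM values must be >= 0", call. = FALSE)
  1.96 * sqrt(tem_a^2 + tem_b^2)
}

#' Total TEM: pooled intra- and inter-observer error
#'
#' Combines the per-observer intra-observer TEMs with the
#' inter-observer TEM into one imprecision figure:
#' \deqn{Total\,TEM = \sqrt{ \overline{TEM_{intra}^2} + TEM_{inter}^2 }}
#' (the mean of the squared intra-observer TEMs plus the squared
#' inter-observer TEM, square-rooted). Written for a three-observer
#' panel, the form generalizes to any observer count.
#'
#' @param intra_tems Numeric vector of per-observer intra-observer TEMs
#'   (at least one, all `>= 0`).
#' @param inter_tem Inter-observer TEM, `>= 0`.
#' @return An object of class `total_tem`: list with `total`, `intra`,
#'   `inter`.
#' @export
#' @examples
#' total_tem(c(0.62, 0.90, 2.07), 0.90)  # ~1.62
total_tem <- function(intra_tems, inter_tem) {
  check_finite(intra_tems, "`intra_tems`")
  check_finite(inter_tem, "`inter_tem`")
  if (length(intra_tems) < 1L)
    stop("at least one intra-observer TEM is required", call. = FALSE)
  if (length(inter_tem) != 1L)
    stop("`inter_tem` must be a single value", call. = FALSE)
  if (any(intra_tems < 0) || inter_tem < 0)
    stop("TEM values must be >= 0", call. = FALSE)
  structure(list(total = sqrt(mean(intra_tems^2) + inter_tem^2),
                 intra = intra_tems, inter = inter_tem),
            class = "total_tem")
}

#' @export
print.total_tem <- function(x, ...) {
  cat(sprintf("<total_tem> %.4g  (intra: %s; inter: %.4g)\n", x$total,
              paste(sprintf("%.4g", x$intra), collapse = ", "), x$inter))
  invisible(x)
}
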