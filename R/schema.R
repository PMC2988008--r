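#' Variable descriptors and measurement schemas
#'
#' A variable descriptor declares a measured quantity: its name, unit,
#' kind (which acceptability standards apply) and how many replicate
#' readings are taken per session. Units are declared, never inferred;
#' all statistics are computed and reported in the declared unit.
#'
#' @param name Variable name (used in the `variable` column of the data).
#' @param unit Measurement unit, e.g. `"cm"`, `"kg"`, `"mm"`.
#' @param kind One of `"weight"`, `"height"`, `"limb_girth"`,
#'   `"trunk_girth"`, `"skinfold"`, `"other"`; selects the acceptability
#'   thresholds applied by [classify_acceptability()].
#' @param replicates_per_session Number of replicate readings taken in a
#'   single session; readings are averaged into one session value.
#' @return A one-row tibble (a schema row).
#' @seealso [anthro_schema()] for the default five-variable schema.
#' @export
#' @examples
#' variable_descriptor("calf_girth", "cm", "limb_girth")
variable_descriptor <- function(name, unit, kind = "other",
                                replicates_per_session = 1L) {
  kind <- match.arg(kind, variable_kinds())
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(unit), length(unit) == 1L)
  replicates_per_session <- as.integer(replicates_per_session)
  if (is.na(replicates_per_session) || replicates_per_session < 1L)
    stop("`replicates_per_session` must be an integer >= 1", call. = FALSE)
  tibble::tibble(name = name, unit = unit, kind = kind,
                 replicates_per_session = replicates_per_session)
}

variable_kinds <- function() {
  c("weight", "height", "limb_girth", "trunk_girth", "skinfold", "other")
}

#' Default anthropometric measurement schema
#'
#' The five measures of a standard adult anthropometric reliability
#' protocol: height (cm), weight (kg), mid-upper arm circumference
#' (MUAC, cm), triceps skinfold (mm, three caliper readings per session,
#' averaged) and waist circumference (cm).
#'
#' @return A tibble with one row per variable (columns `name`, `unit`,
#'   `kind`, `replicates_per_session`).
#' @export
#' @examples
#' anthro_schema()
anthro_schema <- function() {
  dplyr::bind_rows(
    variable_descriptor("height", "cm", "height"),
    variable_descriptor("weight", "kg", "weight"),
    variable_descriptor("muac", "cm", "limb_girth"),
    variable_descriptor("triceps_skinfold", "mm", "skinfold",
                        replicates_per_session = 3L),
    variable_descriptor("waist_circumference", "cm", "trunk_girth")
  )
}

validate_schema <- function(schema) {
  req <- c("name", "unit", "kind", "replicates_per_session")
  if (!is.data.frame(schema) || !all(req %in% names(schema)))
    stop("schema must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(schema$name))
    stop("schema declares duplicated variable names", call. = FALSE)
  bad <- setdiff(unique(schema$kind), variable_kinds())
  if (length(bad))
    stop("unknown variable kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(schema)
}

#' Acceptability thresholds for anthropometric measurement error
#'
#' Field standards against which TEM estimates are judged: absolute TEM
#' cutoffs of 0.1 kg for weight, 0.3 cm (3 mm) for height and 0.2 cm
#' (2 mm) for limb girths; relative TEM of at most 5% for skinfolds and
#' 1% for all other measures; and a coefficient of reliability above
#' 0.95. Absolute cutoffs exist only for weight, height and limb girth;
#' other kinds receive %TEM and R verdicts only.
#'
#' @param abs_tem Named numeric vector of absolute TEM cutoffs, in the
#'   variable's declared unit, keyed by variable kind.
#' @param percent_tem Named numeric vector of %TEM cutoffs keyed by kind;
#'   must contain a `"default"` entry used for kinds not listed.
#' @param r_min Minimum acceptable coefficient of reliability (a verdict
#'   passes when R is strictly greater than `r_min`).
#' @return An object of class `acceptability_thresholds`.
#' @export
#' @examples
#' acceptability_thresholds()
acceptability_thresholds <- function(abs_tem = c(weight = 0.1, height = 0.3,
                                                 limb_girth = 0.2),
                                     percent_tem = c(skinfold = 5, default = 1),
                                     r_min = 0.95) {
  stopifnot(is.numeric(abs_tem), all(abs_tem > 0),
            is.numeric(percent_tem), all(percent_tem > 0),
            "default" %in% names(percent_tem),
            is.numeric(r_min), length(r_min) == 1L, r_min > 0, r_min <= 1)
  structure(list(abs_tem = abs_tem, percent_tem = percent_tem,
                 r_min = r_min),
            class = "acceptability_thresholds")
}
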