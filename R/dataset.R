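#' Build a validated repeated-measurement dataset
#'
#' A reliability dataset collects individual measurement records — one
#' observed value per (subject, observer, session, replicate, variable)
#' — for a single reliability study occasion, together with the variable
#' schema and the ordered session and observer labels.
#'
#' @param records Data frame with columns `subject_id`, `observer_id`,
#'   `session`, `replicate`, `variable`, `value`.
#' @param schema Variable schema, see [anthro_schema()]. Every record
#'   must reference a declared variable.
#' @param sessions,observers Ordered session / observer labels; default
#'   the sorted unique values found in `records`.
#' @return An object of class `reliability_dataset`: a list with
#'   elements `records` (tibble), `schema`, `sessions`, `observers`.
#' @details Validation enforces positive finite values and uniqueness of
#'   the (subject, observer, session, replicate, variable) key. Row
#'   order never affects downstream results.
#' @export
#' @examples
#' recs <- expand.grid(subject_id = c("S1", "S2"), observer_id = "O1",
#'                     session = 1:2, replicate = 1L,
#'                     variable = "height", stringsAsFactors = FALSE)
#' recs$value <- c(170.0, 181.5, 170.4, 181.1)
#' reliability_dataset(recs)
reliability_dataset <- function(records, schema = anthro_schema(),
                                sessions = NULL, observers = NULL) {
  validate_schema(schema)
  req <- c("subject_id", "observer_id", "session", "replicate",
           "variable", "value")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  records <- tibble::as_tibble(records)[req]
  records$subject_id <- as.character(records$subject_id)
  records$observer_id <- as.character(records$observer_id)
  records$session <- as.integer(records$session)
  records$replicate <- as.integer(records$replicate)
  records$variable <- as.character(records$variable)
  records$value <- as.numeric(records$value)

  if (anyNA(records$session) || any(records$session < 1L))
    stop("`session` must be a 1-based integer index", call. = FALSE)
  if (anyNA(records$replicate) || any(records$replicate < 1L))
    stop("`replicate` must be a 1-based integer index", call. = FALSE)
  bad_val <- which(!is.finite(records$value) | records$value <= 0)
  if (length(bad_val))
    stop("non-positive or non-finite value(s) in records at row(s) ",
         paste(utils::head(bad_val, 5L), collapse = ", "), call. = FALSE)
  undeclared <- setdiff(unique(records$variable), schema$name)
  if (length(undeclared))
    stop("records reference undeclared variable(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  key <- do.call(paste, c(records[req[1:5]], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicated (subject, observer, session, replicate, variable) ",
         "key at row(s) ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }

  sessions <- as.integer(sessions %||% sort(unique(records$session)))
  observers <- as.character(observers %||% sort(unique(records$observer_id)))
  if (!all(records$session %in% sessions))
    stop("records reference undeclared session(s)", call. = FALSE)
  if (!all(records$observer_id %in% observers))
    stop("records reference undeclared observer(s)", call. = FALSE)

  structure(list(records = records, schema = tibble::as_tibble(schema),
                 sessions = sessions, observers = observers),
            class = "reliability_dataset")
}

#' @export
print.reliability_dataset <- function(x, ...) {
  cat("<reliability_dataset>\n")
  cat("  subjects:  ", length(unique(x$records$subject_id)), "\n")
  cat("  observers: ", paste(x$observers, collapse = ", "), "\n")
  cat("  sessions:  ", paste(x$sessions, collapse = ", "), "\n")
  cat("  variables: ", paste(x$schema$name, collapse = ", "), "\n")
  cat("  records:   ", nrow(x$records), "\n")
  invisible(x)
}

#' Read a long-format measurement CSV
#'
#' Reads a UTF-8 CSV with header
#' `subject_id,observer_id,session,replicate,variable,value`
#' (decimal point `.`) and returns a validated [reliability_dataset()].
#' Malformed or invalid rows are reported with their file line number
#' (header = line 1).
#'
#' @param path Path to the CSV file.
#' @inheritParams reliability_dataset
#' @return A `reliability_dataset`.
#' @export
read_measurements <- function(path, schema = anthro_schema(),
                              sessions = NULL, observers = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  req <- c("subject_id", "observer_id", "session", "replicate",
           "variable", "value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  line_of <- function(i) i + 1L  # header occupies line 1

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[col]])) |
                   !nzchar(trimws(raw[[col]])))
    if (length(bad))
      stop("malformed ", what, " at line(s) ",
           paste(line_of(utils::head(bad, 5L)), collapse = ", "),
           " of ", path, call. = FALSE)
    v
  }
  raw$session <- num("session", "session index")
  raw$replicate <- num("replicate", "replicate index")
  raw$value <- num("value", "numeric value")

  bad_val <- which(!is.finite(raw$value) | raw$value <= 0)
  if (length(bad_val))
    stop("non-positive value(s) at line(s) ",
         paste(line_of(utils::head(bad_val, 5L)), collapse = ", "),
         " of ", path, call. = FALSE)
  key <- do.call(paste, c(raw[req[1:5]], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated measurement key at line(s) ",
         paste(line_of(utils::head(dup, 5L)), collapse = ", "),
         " of ", path, call. = FALSE)

  reliability_dataset(raw, schema = schema, sessions = sessions,
                      observers = observers)
}

#' Write a dataset back to long-format CSV
#'
#' Records are written in a canonical order (variable, subject,
#' observer, session, replicate) so that a read/write cycle round-trips
#' to an identical dataset.
#'
#' @param dataset A `reliability_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  stopifnot(inherits(dataset, "reliability_dataset"))
  recs <- dplyr::arrange(dataset$records, .data$variable, .data$subject_id,
                         .data$observer_id, .data$session, .data$replicate)
  utils::write.csv(recs, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Reduce replicates to one value per measurement cell
#'
#' Computes the session value — the arithmetic mean of the replicate
#' readings — for every (subject, observer, session, variable) cell.
#' Replicated variables (e.g. skinfolds read in triplicate) are averaged;
#' a cell holding fewer replicates than its schema declares is averaged
#' over what exists, with a warning, because ragged field data still has
#' to yield one value per cell.
#'
#' @param dataset A `reliability_dataset`.
#' @param variable Optional variable name to restrict to.
#' @return A tibble with columns `subject_id`, `observer_id`, `session`,
#'   `variable`, `value`, `n_replicates`.
#' @export
session_values <- function(dataset, variable = NULL) {
  stopifnot(inherits(dataset, "reliability_dataset"))
  recs <- dataset$records
  if (!is.null(variable)) {
    if (!variable %in% dataset$schema$name)
      stop("undeclared variable: ", variable, call. = FALSE)
    recs <- recs[recs$variable == variable, ]
  }
  out <- dplyr::summarise(
    dplyr::group_by(recs, .data$subject_id, .data$observer_id,
                    .data$session, .data$variable),
    value = mean(.data$value), n_replicates = dplyr::n(), .groups = "drop")
  declared <- stats::setNames(dataset$schema$replicates_per_session,
                              dataset$schema$name)
  short <- out$n_replicates < declared[out$variable]
  if (any(short)) {
    tab <- table(out$variable[short])
    warning("partial replicate sets averaged over available readings: ",
            paste(sprintf("%s (%d cell%s)", names(tab), tab,
                          ifelse(tab > 1, "s", "")), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Look up one session value
#'
#' @inheritParams session_values
#' @param subject,observer Subject / observer identifier.
#' @param session Session index.
#' @param variable Variable name (must be declared).
#' @return The mean of the available replicates for that cell, or `NA`
#'   if no replicate is present (absence is a value, not an error).
#' @export
session_value <- function(dataset, subject, observer, session, variable) {
  sv <- suppressWarnings(session_values(dataset, variable))
  hit <- sv$subject_id == as.character(subject) &
    sv$observer_id == as.character(observer) &
    sv$session == as.integer(session)
  if (!any(hit)) return(NA_real_)
  sv$value[hit]
}

#' Restrict to subjects with complete measurement cells
#'
#' Listwise deletion per variable: keeps only the subjects holding a
#' session value for every required (observer, session) cell of the
#' given variable, mirroring the shifting per-variable n of field
#' reliability studies (a no-show drops a subject from every analysis of
#' that occasion; a refusal drops a subject from one variable only).
#'
#' @inheritParams session_values
#' @param variable Variable to assess completeness for.
#' @param sessions,observers Required sessions / observers (defaults:
#'   all declared).
#' @param quiet Suppress the retained-n message.
#' @return A `reliability_dataset` restricted to the complete subjects
#'   and to `variable`, with attribute `n_retained`.
#' @export
complete_cases <- function(dataset, variable, sessions = dataset$sessions,
                           observers = dataset$observers, quiet = FALSE) {
  stopifnot(inherits(dataset, "reliability_dataset"))
  if (!variable %in% dataset$schema$name)
    stop("undeclared variable: ", variable, call. = FALSE)
  sv <- suppressWarnings(session_values(dataset, variable))
  sv <- sv[sv$session %in% sessions & sv$observer_id %in% observers, ]
  need <- length(sessions) * length(observers)
  n_cells <- table(sv$subject_id)
  keep <- names(n_cells)[n_cells == need]
  recs <- dataset$records
  recs <- recs[recs$variable == variable & recs$subject_id %in% keep &
                 recs$session %in% sessions &
                 recs$observer_id %in% observers, ]
  if (!quiet)
    message(sprintf("complete_cases(%s): %d of %d subject(s) retained",
                    variable, length(keep),
                    length(unique(dataset$records$subject_id))))
  out <- reliability_dataset(recs,
                             schema = dataset$schema[dataset$schema$name ==
                                                       variable, ],
                             sessions = as.integer(sessions),
                             observers = observers)
  attr(out, "n_retained") <- length(keep)
  out
}
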