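# Delimited-table I/O and schema validation for the pipeline's published
# file formats.

#' Write a cohort to delimited text files
#'
#' Writes `persons.csv` (person_id, covariate columns, censor_time) and
#' `events.csv` (person_id, condition, onset_time) with header rows; times
#' are serialized as decimal years with full precision.
#'
#' @param cohort An `mm_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "persons.csv")
  pe <- file.path(dir, "events.csv")
  utils::write.csv(format_times(cohort$persons, "censor_time"), pp,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_times(cohort$events, "onset_time"), pe,
                   row.names = FALSE, quote = FALSE)
  invisible(c(persons = pp, events = pe))
}

format_times <- function(df, cols) {
  for (cc in intersect(cols, names(df)))
    df[[cc]] <- formatC(df[[cc]], digits = 9, format = "g")
  df
}

#' Read a cohort from delimited text files
#'
#' @param dir Directory containing `persons.csv` and `events.csv`, or
#'   `persons`/`events` file paths given explicitly.
#' @param persons,events Optional explicit file paths (override `dir`).
#' @return An `mm_cohort`.
#' @export
read_cohort <- function(dir = NULL, persons = NULL, events = NULL) {
  if (is.null(persons)) persons <- file.path(dir, "persons.csv")
  if (is.null(events)) events <- file.path(dir, "events.csv")
  for (f in c(persons, events))
    if (!file.exists(f)) stop("missing file: ", f)
  p <- utils::read.csv(persons, stringsAsFactors = FALSE)
  e <- utils::read.csv(events, stringsAsFactors = FALSE)
  structure(list(persons = p, events = e), class = "mm_cohort")
}

#' Validate persons and events tables
#'
#' Schema and integrity checks on the pipeline's input tables: required
#' columns, numeric types, uniqueness of person_id, foreign-key integrity of
#' events, condition vocabulary, finiteness of onset times, positivity of
#' censoring times and uniqueness of (person, condition) pairs. Every
#' violation is reported with its table and row number.
#'
#' @param persons Persons data frame or path to `persons.csv`.
#' @param events Events data frame or path to `events.csv`.
#' @return Data frame of class `mm_validation` with columns table, row,
#'   rule, message; zero rows when both tables are well-formed.
#' @export
validate_tables <- function(persons, events) {
  if (is.character(persons)) persons <- utils::read.csv(persons, stringsAsFactors = FALSE)
  if (is.character(events)) events <- utils::read.csv(events, stringsAsFactors = FALSE)
  v <- list()
  add <- function(table, row, rule, message)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)

  need_p <- c("person_id", "censor_time")
  for (cc in setdiff(need_p, names(persons)))
    add("persons", NA_integer_, "missing_column", paste("missing column", cc))
  need_e <- c("person_id", "condition", "onset_time")
  for (cc in setdiff(need_e, names(events)))
    add("events", NA_integer_, "missing_column", paste("missing column", cc))

  if ("person_id" %in% names(persons)) {
    dup <- which(duplicated(persons$person_id))
    for (i in dup) add("persons", i, "duplicate_person", "duplicate person_id")
  }
  if ("censor_time" %in% names(persons)) {
    bad <- which(!is.finite(persons$censor_time) | persons$censor_time <= 0)
    for (i in bad) add("persons", i, "censor_time", "censor_time must be > 0")
  }
  if (all(c("person_id", "condition") %in% names(events))) {
    dup <- which(duplicated(events[c("person_id", "condition")]))
    for (i in dup) add("events", i, "duplicate_event",
                       "duplicate (person_id, condition) pair")
  }
  if ("condition" %in% names(events)) {
    bad <- which(!events$condition %in% MM_CONDITIONS)
    for (i in bad) add("events", i, "unknown_condition",
                       paste("unknown condition", events$condition[i]))
  }
  if ("onset_time" %in% names(events)) {
    bad <- which(!is.finite(events$onset_time))
    for (i in bad) add("events", i, "onset_time", "onset_time must be finite")
  }
  if ("person_id" %in% names(events) && "person_id" %in% names(persons)) {
    bad <- which(!events$person_id %in% persons$person_id)
    for (i in bad) add("events", i, "foreign_key",
                       paste("person_id", events$person_id[i], "not in persons"))
  }

  out <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(0), row = integer(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  class(out) <- c("mm_validation", "data.frame")
  out
}

#' @export
print.mm_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Tables valid: no violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x)
  }
  invisible(x)
}

#' Write a pattern table to CSV
#'
#' @param x An `mm_pattern_table`.
#' @param file Output path.
#' @param public If TRUE (default) suppressed (small-count) rows are
#'   omitted, mirroring confidentiality suppression in published tables.
#' @return Invisibly, `file`.
#' @export
write_pattern_table <- function(x, file, public = TRUE) {
  stopifnot(inherits(x, "mm_pattern_table"))
  df <- as.data.frame(x)
  if (public) df <- df[!df$suppressed, setdiff(names(df), "suppressed"),
                       drop = FALSE]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
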