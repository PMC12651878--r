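#' Read a patient-level survival cohort from delimited text
#'
#' Reads a CSV or TSV file (dialect chosen by extension, overridable) with a
#' header row and maps its columns onto the fields the pipeline needs:
#' survival time in months, vital-status event indicator (1 = death observed,
#' 0 = censored), staging factor levels, and optionally age in years. Rows
#' with a missing or unparseable mapped value are dropped, never silently:
#' the returned audit counts them by reason.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named list (or path to a YAML/JSON file holding one)
#'   mapping field names to column names. Required: \code{time}, \code{event}.
#'   Optional: \code{age} plus one entry per staging factor (e.g.
#'   \code{T = "t_category"}).
#' @param sep Field separator; default \code{NULL} picks "," for \code{.csv}
#'   and tab otherwise.
#' @return A list with \code{records} (data.frame of kept rows: \code{time},
#'   \code{event}, factor columns, and \code{age}/\code{A} when age is
#'   mapped) and \code{audit} (rows read / kept / dropped, with a per-reason
#'   breakdown).
#' @export
read_cohort <- function(path, column_map, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  column_map <- load_column_map(column_map)
  for (req in c("time", "event"))
    if (is.null(column_map[[req]])) stop("column map must provide '", req, "'")
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  unmapped <- setdiff(unlist(column_map), names(raw))
  if (length(unmapped))
    stop("mapped columns absent from file: ", paste(unmapped, collapse = ", "))

  n_in <- nrow(raw)
  drop_reasons <- integer(0)
  keep <- rep(TRUE, n_in)
  flag <- function(bad, reason) {
    bad <- bad & keep
    if (any(bad)) drop_reasons[reason] <<- sum(bad)
    keep <<- keep & !bad
  }

  time <- suppressWarnings(as.numeric(raw[[column_map$time]]))
  flag(is.na(raw[[column_map$time]]), "missing time")
  flag(!is.na(raw[[column_map$time]]) & is.na(time), "unparseable time")
  flag(!is.na(time) & time < 0, "negative time")

  event <- suppressWarnings(as.numeric(raw[[column_map$event]]))
  flag(is.na(raw[[column_map$event]]), "missing event")
  flag(!is.na(raw[[column_map$event]]) & (is.na(event) | !event %in% c(0, 1)),
       "invalid event indicator")

  factor_fields <- setdiff(names(column_map), c("time", "event", "age"))
  for (f in factor_fields)
    flag(is.na(raw[[column_map[[f]]]]), paste("missing", f))

  age <- NULL
  if (!is.null(column_map$age)) {
    age <- suppressWarnings(as.numeric(raw[[column_map$age]]))
    flag(is.na(raw[[column_map$age]]), "missing age")
    flag(!is.na(raw[[column_map$age]]) & is.na(age), "unparseable age")
    flag(!is.na(age) & age < 0, "negative age")
  }

  records <- data.frame(time = time[keep], event = as.integer(event[keep]))
  for (f in factor_fields)
    records[[f]] <- as.character(raw[[column_map[[f]]]])[keep]
  if (!is.null(age)) {
    records$age <- age[keep]
    records$A <- dichotomize_age(records$age)
  }
  audit <- list(n_read = n_in, n_kept = nrow(records),
                n_dropped = n_in - nrow(records),
                reasons = drop_reasons)
  stopifnot(audit$n_read == audit$n_kept + audit$n_dropped)
  list(records = records, audit = audit)
}

load_column_map <- function(column_map) {
  if (is.character(column_map) && length(column_map) == 1L) {
    if (!file.exists(column_map)) stop("column map file not found: ", column_map)
    column_map <- if (grepl("\\.json$", column_map, ignore.case = TRUE))
      jsonlite::read_json(column_map, simplifyVector = TRUE)
    else yaml::read_yaml(column_map)
  }
  if (!is.list(column_map) || is.null(names(column_map)))
    stop("column_map must be a named list or a YAML/JSON file path")
  column_map
}

#' Write a cohort in the delimited format read_cohort() consumes
#'
#' @param records Data.frame with \code{time}, \code{event} and factor columns.
#' @param path Output path (.csv or .tsv).
#' @export
write_cohort <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(records, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dichotomize age at diagnosis at 50 years
#'
#' Returns \code{"A1"} for ages under 50 and \code{"A2"} for 50 and over,
#' the prognostic cut used for pancreatic neuroendocrine tumors.
#'
#' @param age_years Nonnegative numeric vector of ages in years.
#' @return Character vector of \code{"A1"}/\code{"A2"} levels.
#' @export
dichotomize_age <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 0))
    stop("age must be nonnegative and non-missing")
  ifelse(age_years < 50, "A1", "A2")
}

#' Group patient records into factor-level combinations
#'
#' Assigns every record to exactly one combination label (scheme-ordered
#' concatenation of its levels) and collects per-combination observation
#' lists. Combinations of the scheme with no records are reported, not kept.
#'
#' @param records Data.frame with \code{time}, \code{event}, and one column
#'   per scheme factor.
#' @param scheme A \code{factor_scheme}.
#' @return A \code{combination_cohort}: scheme, named list \code{groups} of
#'   \code{(time, event)} data.frames in enumeration order, \code{counts},
#'   total \code{n}, and \code{empty} (enumerated but unobserved labels).
#' @export
build_combinations <- function(records, scheme) {
  stopifnot(inherits(scheme, "factor_scheme"))
  if (!all(c("time", "event") %in% names(records)))
    stop("records need 'time' and 'event' columns")
  for (f in names(scheme$factors)) {
    if (is.null(records[[f]])) stop("records lack factor column '", f, "'")
    bad <- !records[[f]] %in% scheme$factors[[f]]
    if (any(bad)) {
      i <- which(bad)[1]
      stop("record ", i, " has level '", records[[f]][i],
           "' outside factor '", f, "'")
    }
  }
  labels <- combination_label(records, scheme)
  all_labels <- enumerate_combinations(scheme)
  observed <- all_labels[all_labels %in% labels]
  groups <- lapply(observed, function(lb) {
    idx <- which(labels == lb)
    data.frame(time = records$time[idx], event = as.integer(records$event[idx]))
  })
  names(groups) <- observed
  counts <- vapply(groups, nrow, integer(1))
  stopifnot(sum(counts) == nrow(records))
  structure(list(scheme = scheme, groups = groups, counts = counts,
                 n = nrow(records), empty = setdiff(all_labels, observed)),
            class = "combination_cohort")
}

#' @export
print.combination_cohort <- function(x, ...) {
  cat("Combination cohort: ", length(x$groups), " combinations, ",
      x$n, " patients\n", sep = "")
  print(x$counts)
  if (length(x$empty))
    cat("Empty combinations:", paste(x$empty, collapse = ", "), "\n")
  invisible(x)
}

#' Exclude combinations with too few patients
#'
#' Small combinations give unstable effect-size estimates; registry analyses
#' conventionally drop cells below a minimum size (default 15 patients)
#' before clustering.
#'
#' @param cohort A \code{combination_cohort}.
#' @param min_n Minimum patients per combination to keep (default 15).
#' @return List with the filtered \code{cohort} and \code{exclusions}, a
#'   data.frame of excluded labels and their patient counts.
#' @export
filter_small_combinations <- function(cohort, min_n = 15) {
  stopifnot(inherits(cohort, "combination_cohort"), min_n >= 1)
  drop <- cohort$counts < min_n
  excl <- data.frame(combination = names(cohort$counts)[drop],
                     n = unname(cohort$counts[drop]),
                     stringsAsFactors = FALSE)
  out <- cohort
  out$groups <- cohort$groups[!drop]
  out$counts <- cohort$counts[!drop]
  out$n <- sum(out$counts)
  if (length(out$groups) == 0L)
    warning("all combinations excluded at min_n = ", min_n)
  list(cohort = out, exclusions = excl)
}

#' Pool all observations of a combination cohort
#'
#' @param cohort A \code{combination_cohort}.
#' @return Data.frame with \code{combination}, \code{time}, \code{event}.
#' @export
pool_observations <- function(cohort) {
  stopifnot(inherits(cohort, "combination_cohort"))
  do.call(rbind, lapply(names(cohort$groups), function(lb) {
    g <- cohort$groups[[lb]]
    data.frame(combination = lb, time = g$time, event = g$event,
               stringsAsFactors = FALSE)
  }))
}
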