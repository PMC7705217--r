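# Descriptive layer: inclusion/exclusion filtering with a per-rule ledger,
# frequency/percentage tables with explicit denominators, and
# difference-score construction.

#' Apply inclusion filters with an exclusion ledger
#'
#' Filters a raw participant table in a fixed order, counting each excluded
#' row once, under the first rule it violates: (0) optional completion
#' filter if a logical `completed` column is present; (1) ambiguous
#' mental-health details (`mental_health_consistent == FALSE`); (2) age
#' below `min_age`; (3) participation after `cutoff_date`.  Re-applying the
#' filters to their own output changes nothing.
#'
#' @param raw_table data frame with columns `age`,
#'   `participation_date` (Date or parseable string),
#'   `mental_health_consistent` (logical), optionally `completed`.
#' @param cutoff_date last admissible participation date (inclusive).
#' @param min_age minimum age in years (inclusive).
#' @return list with `table` (the retained rows) and `exclusions` (a data
#'   frame of rule / n_excluded, in order of application).
#' @export
apply_inclusion_filters <- function(raw_table, cutoff_date = "2020-05-03",
                                    min_age = 18) {
  required <- c("age", "participation_date", "mental_health_consistent")
  missing_cols <- setdiff(required, names(raw_table))
  if (length(missing_cols)) {
    stop("raw table is missing filter column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cutoff <- as.Date(cutoff_date)
  tab <- raw_table
  log <- list()
  if ("completed" %in% names(tab)) {
    drop <- !tab$completed
    log[["incomplete"]] <- sum(drop)
    tab <- tab[!drop, , drop = FALSE]
  }
  drop <- !tab$mental_health_consistent
  log[["ambiguous_mental_health"]] <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  drop <- tab$age < min_age
  log[["under_age"]] <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  drop <- as.Date(tab$participation_date) > cutoff
  log[["after_cutoff"]] <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       exclusions = data.frame(rule = names(log),
                               n_excluded = unlist(log, use.names = FALSE),
                               stringsAsFactors = FALSE))
}

#' Frequency table against an explicit denominator
#'
#' Counts the levels of a stratum and reports percentages of a stated
#' denominator, rounded half-up to 2 decimals.  The denominator is always
#' an explicit argument — survey reports routinely switch denominators
#' (total sample, currently affected, subgroups in treatment, ...) and
#' inferring it silently is the classic descriptive-layer mistake.
#'
#' @param x data frame (with `stratum` naming a column) or a vector of
#'   stratum labels.
#' @param stratum column name when `x` is a data frame.
#' @param denominator positive integer the percentages refer to; defaults
#'   to the number of rows/elements counted.
#' @param denominator_definition free text recording what the denominator
#'   is (stored as an attribute).
#' @return a `frequency_table` data frame with columns `stratum`, `count`,
#'   `percentage`.
#' @export
frequency_table <- function(x, stratum = NULL, denominator = NULL,
                            denominator_definition = "all rows counted") {
  values <- if (is.data.frame(x)) {
    if (is.null(stratum) || !stratum %in% names(x)) {
      stop("stratum column not found in table", call. = FALSE)
    }
    x[[stratum]]
  } else {
    x
  }
  denominator <- denominator %||% length(values)
  assert_number(denominator, "denominator", lower = 1)
  counts <- table(values)
  if (sum(counts) > denominator) {
    stop("counts exceed the stated denominator", call. = FALSE)
  }
  out <- data.frame(stratum = names(counts),
                    count = as.integer(counts),
                    percentage = round_half_up(100 * as.integer(counts) /
                                                 denominator, 2),
                    stringsAsFactors = FALSE)
  structure(out, denominator = as.integer(denominator),
            denominator_definition = denominator_definition,
            class = c("frequency_table", "data.frame"))
}

#' Per-participant difference scores
#'
#' `T1 - T0` for one variable of a cohort table, in original score units.
#'
#' @param table a `cohort_table` (or any data frame with `<variable>_t0`
#'   and `<variable>_t1` columns).
#' @param variable variable name.
#' @return numeric vector of differences, one per row.
#' @export
difference_scores <- function(table, variable) {
  c0 <- paste0(variable, "_t0")
  c1 <- paste0(variable, "_t1")
  missing_cols <- setdiff(c(c0, c1), names(table))
  if (length(missing_cols)) {
    stop("missing timepoint column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(table[[c0]]) | is.na(table[[c1]]))
  if (length(bad)) {
    ids <- if ("participant_id" %in% names(table)) {
      table$participant_id[bad]
    } else bad
    stop("missing timepoint value for participant(s): ",
         paste(head(ids, 5), collapse = ", "), call. = FALSE)
  }
  table[[c1]] - table[[c0]]
}
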