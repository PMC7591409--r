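#' Assemble a longitudinal falls cohort
#'
#' A `falls_cohort` bundles one row per participant-visit with the deficit
#' specifications that interpret the raw deficit columns. Visits are keyed by
#' `(participant_id, visit_age)`; the default study design has three waves at
#' ages 75, 80 and 85.
#'
#' Required visit columns: `participant_id`, `visit_age`, `alive`,
#' `attended`, `falls_12m` (count of self-reported falls in the previous 12
#' months, `NA` when missing), the covariates `bmi` (kg/m^2), `s25ohd`
#' (serum 25(OH)D, nmol/L), `smoking` (`"never"`, `"previous"`,
#' `"current"`) and `prior_fracture` (any fracture between ages 50 and 75),
#' plus one column per deficit named in `deficit_specs`.
#'
#' @param visits A data.frame of participant-visit records.
#' @param deficit_specs Named list of [deficit_spec()] objects.
#' @param visit_ages Integer vector of permitted visit ages.
#' @return An object of class `falls_cohort`.
#' @export
falls_cohort <- function(visits, deficit_specs, visit_ages = c(75L, 80L, 85L)) {
  stopifnot(is.data.frame(visits))
  required <- c("participant_id", "visit_age", "alive", "attended",
                "falls_12m", "bmi", "s25ohd", "smoking", "prior_fracture")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dnames <- names(deficit_specs)
  missing_def <- setdiff(dnames, names(visits))
  if (length(missing_def)) {
    stop("cohort is missing deficit columns: ",
         paste(missing_def, collapse = ", "), call. = FALSE)
  }
  key <- paste(visits$participant_id, visits$visit_age, sep = "@")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate participant-visit key: ", dup, call. = FALSE)
  }
  visits <- visits[order(visits$participant_id, visits$visit_age), ,
                   drop = FALSE]
  rownames(visits) <- NULL
  structure(
    list(visits = visits, deficit_specs = deficit_specs,
         visit_ages = as.integer(visit_ages)),
    class = "falls_cohort"
  )
}

#' @export
print.falls_cohort <- function(x, ...) {
  v <- x$visits
  cat(sprintf("<falls_cohort> %d participants, %d visit records, %d deficits\n",
              length(unique(v$participant_id)), nrow(v),
              length(x$deficit_specs)))
  for (age in sort(unique(v$visit_age))) {
    sub <- v[v$visit_age == age, ]
    cat(sprintf("  age %d: %d records, %d attended, %d with falls data\n",
                age, nrow(sub), sum(sub$attended, na.rm = TRUE),
                sum(sub$attended & !is.na(sub$falls_12m), na.rm = TRUE)))
  }
  invisible(x)
}

#' Names of the deficit variables in a cohort
#' @param cohort A `falls_cohort`.
#' @return Character vector of deficit names.
#' @export
deficit_names <- function(cohort) {
  stopifnot(inherits(cohort, "falls_cohort"))
  names(cohort$deficit_specs)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks every participant-visit record against the cohort invariants:
#' falls counts are non-negative integers when present, attendance implies
#' vital status, visit ages belong to the configured waves, and smoking codes
#' are recognised. Structural problems (duplicate keys, missing columns) are
#' raised as errors by [falls_cohort()] itself; this function reports
#' record-level violations without mutating its input.
#'
#' @param cohort A `falls_cohort`.
#' @return A data.frame of findings with columns `participant_id`,
#'   `visit_age`, `rule` and `message`; zero rows when all invariants hold.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "falls_cohort"))
  v <- cohort$visits
  findings <- list()
  add <- function(idx, rule, msg) {
    if (!any(idx)) return()
    findings[[length(findings) + 1L]] <<- data.frame(
      participant_id = as.character(v$participant_id[idx]),
      visit_age = v$visit_age[idx],
      rule = rule, message = msg, stringsAsFactors = FALSE
    )
  }
  falls <- v$falls_12m
  bad_falls <- !is.na(falls) & (falls < 0 | falls != trunc(falls))
  add(bad_falls, "falls_non_negative_integer",
      "falls_12m must be a non-negative integer when present")
  add(!is.na(v$attended) & !is.na(v$alive) & v$attended & !v$alive,
      "attended_implies_alive", "a visit cannot be attended by a deceased participant")
  add(!v$visit_age %in% cohort$visit_ages, "visit_age_in_waves",
      sprintf("visit_age must be one of {%s}",
              paste(cohort$visit_ages, collapse = ", ")))
  add(!is.na(v$smoking) & !v$smoking %in% c("never", "previous", "current"),
      "smoking_levels", "smoking must be never/previous/current")
  for (nm in deficit_names(cohort)) {
    add(!is.na(v[[nm]]) & !is.finite(v[[nm]]),
        "deficit_finite", sprintf("deficit '%s' must be finite when present", nm))
  }
  if (length(findings) == 0L) {
    return(data.frame(participant_id = character(), visit_age = integer(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Read a cohort from a delimited text file
#'
#' Expects the CSV schema written by [write_cohort()]: one row per
#' participant-visit, missing values as empty fields, logical columns coded
#' TRUE/FALSE.
#'
#' @param path Path to the cohort CSV.
#' @param deficit_specs Named list of [deficit_spec()] objects, or a path to
#'   a YAML spec file readable by [read_deficit_specs()].
#' @param visit_ages Permitted visit ages.
#' @return A `falls_cohort`.
#' @export
read_cohort <- function(path, deficit_specs, visit_ages = c(75L, 80L, 85L)) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  if (is.character(deficit_specs)) {
    deficit_specs <- read_deficit_specs(deficit_specs)
  }
  v <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  v$participant_id <- as.character(v$participant_id)
  v$visit_age <- as.integer(v$visit_age)
  v$alive <- as.logical(v$alive)
  v$attended <- as.logical(v$attended)
  v$falls_12m <- as.integer(v$falls_12m)
  v$prior_fracture <- as.logical(v$prior_fracture)
  falls_cohort(v, deficit_specs, visit_ages = visit_ages)
}

#' Write a cohort to a delimited text file
#'
#' @param cohort A `falls_cohort`.
#' @param path Output path for the CSV (missing values as empty fields).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "falls_cohort"))
  utils::write.csv(cohort$visits, path, row.names = FALSE, na = "")
  invisible(path)
}
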