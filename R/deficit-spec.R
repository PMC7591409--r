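#' Define one health-deficit variable
#'
#' A deficit specification describes how one raw health variable is turned
#' into a deficit score on \[0, 1\]. Binary deficits are dichotomised at a
#' cut-point; continuous deficits are min-max rescaled between `v_min` and
#' `v_max` (the observed range after excluding extreme outliers). The
#' `direction` states which end of the scale is unhealthy, so that a score
#' near 0 always means a healthier state.
#'
#' @param name Identifier for the variable (used as the cohort column name).
#' @param kind `"binary"` or `"continuous"`.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @param cutpoint Dichotomisation cut-point (binary kind only). Values at or
#'   beyond the cut-point on the unhealthy side score 1.
#' @param v_min,v_max Rescaling range (continuous kind only). May be left
#'   `NA` and filled later from cohort data with [determine_range()].
#' @param outlier_rule Length-2 numeric, the lower/upper quantile band used to
#'   exclude extreme outliers before fixing `v_min`/`v_max` from data.
#'
#' @return An object of class `deficit_spec`.
#' @seealso [read_deficit_specs()], [rescale_continuous()], [score_binary()]
#' @examples
#' # number of steps taken to walk 30 m: fewer steps = longer stride = healthier
#' deficit_spec("steps_30m", "continuous", "higher_is_worse",
#'              v_min = 21, v_max = 160)
#' @export
deficit_spec <- function(name,
                         kind = c("continuous", "binary"),
                         direction = c("higher_is_worse", "lower_is_worse"),
                         cutpoint = NA_real_,
                         v_min = NA_real_,
                         v_max = NA_real_,
                         outlier_rule = c(0.005, 0.995)) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(outlier_rule), length(outlier_rule) == 2L,
            outlier_rule[1] < outlier_rule[2],
            outlier_rule[1] >= 0, outlier_rule[2] <= 1)
  if (kind == "binary") {
    if (is.na(cutpoint)) {
      stop("binary deficit '", name, "' requires a cutpoint", call. = FALSE)
    }
    if (!is.na(v_min) || !is.na(v_max)) {
      stop("binary deficit '", name, "' must not carry v_min/v_max",
           call. = FALSE)
    }
  } else {
    if (!is.na(cutpoint)) {
      stop("continuous deficit '", name, "' must not carry a cutpoint",
           call. = FALSE)
    }
    if (!is.na(v_min) && !is.na(v_max) && v_min >= v_max) {
      stop("continuous deficit '", name, "' requires v_min < v_max",
           call. = FALSE)
    }
    if (is.na(v_min) != is.na(v_max)) {
      stop("continuous deficit '", name,
           "': v_min and v_max must be given together", call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, direction = direction,
         cutpoint = as.numeric(cutpoint),
         v_min = as.numeric(v_min), v_max = as.numeric(v_max),
         outlier_rule = as.numeric(outlier_rule)),
    class = "deficit_spec"
  )
}

#' @export
print.deficit_spec <- function(x, ...) {
  det <- if (x$kind == "binary") {
    sprintf("cutpoint %s", format(x$cutpoint))
  } else if (is.na(x$v_min)) {
    "range unset (determine from data)"
  } else {
    sprintf("range [%s, %s]", format(x$v_min), format(x$v_max))
  }
  cat(sprintf("<deficit_spec> %s: %s, %s, %s\n",
              x$name, x$kind, x$direction, det))
  invisible(x)
}

#' Read deficit specifications from a YAML config
#'
#' The config is a YAML list with one entry per deficit; each entry carries
#' the fields of [deficit_spec()]. The file may either be a bare list or hold
#' the list under a top-level `deficits` key.
#'
#' @param path Path to the YAML file.
#' @return A named list of `deficit_spec` objects, in file order.
#' @export
read_deficit_specs <- function(path) {
  if (!file.exists(path)) {
    stop("deficit spec file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$deficits)) raw <- raw$deficits
  if (length(raw) == 0L) stop("no deficits defined in ", path, call. = FALSE)
  specs <- lapply(raw, function(d) {
    deficit_spec(
      name = d$name,
      kind = d$kind,
      direction = d$direction,
      cutpoint = if (is.null(d$cutpoint)) NA_real_ else d$cutpoint,
      v_min = if (is.null(d$v_min)) NA_real_ else d$v_min,
      v_max = if (is.null(d$v_max)) NA_real_ else d$v_max,
      outlier_rule = if (is.null(d$outlier_rule)) c(0.005, 0.995)
                     else unlist(d$outlier_rule)
    )
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) {
    stop("duplicate deficit names in ", path, call. = FALSE)
  }
  specs
}

#' Write deficit specifications to a YAML config
#'
#' @param specs Named list of `deficit_spec` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deficit_specs <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    e <- list(name = s$name, kind = s$kind, direction = s$direction)
    if (s$kind == "binary") e$cutpoint <- s$cutpoint
    if (s$kind == "continuous" && !is.na(s$v_min)) {
      e$v_min <- s$v_min
      e$v_max <- s$v_max
    }
    e$outlier_rule <- s$outlier_rule
    e
  })
  yaml::write_yaml(list(deficits = unname(entries)), path)
  invisible(path)
}
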