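#' Configure frailty-index construction and classification
#'
#' @param cutoff Frailty cutoff on the index scale (default 0.25, the
#'   empirical value at which 10-year mortality starts to rise steeply).
#' @param min_completeness Minimum fraction of the deficit items that must be
#'   non-missing for the index to be defined (default 0.8, i.e. at least 11
#'   of 13 items).
#' @param frail_boundary `"ge"` (frail when index >= cutoff, the default) or
#'   `"gt"` (frail only strictly above the cutoff).
#' @return An object of class `index_config`.
#' @export
index_config <- function(cutoff = 0.25, min_completeness = 0.8,
                         frail_boundary = c("ge", "gt")) {
  frail_boundary <- match.arg(frail_boundary)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff < 1)
  stopifnot(is.numeric(min_completeness), length(min_completeness) == 1L,
            min_completeness > 0, min_completeness <= 1)
  structure(list(cutoff = cutoff, min_completeness = min_completeness,
                 frail_boundary = frail_boundary),
            class = "index_config")
}

#' Min-max rescale a continuous deficit to a unit score
#'
#' Computes `(value - v_min) / (v_max - v_min)`, clamped to \[0, 1\]. When
#' the deficit's direction is `lower_is_worse` the complement is returned, so
#' a score near 0 always denotes the healthier state.
#'
#' @param value Numeric vector of raw values (non-missing).
#' @param spec A continuous [deficit_spec()] with a populated range.
#' @return Numeric vector of unit deficit scores in \[0, 1\].
#' @examples
#' steps <- deficit_spec("steps_30m", "continuous", "higher_is_worse",
#'                       v_min = 21, v_max = 160)
#' rescale_continuous(54, steps)  # (54 - 21) / 139 = 0.2374
#' @export
rescale_continuous <- function(value, spec) {
  stopifnot(inherits(spec, "deficit_spec"))
  if (spec$kind != "continuous") {
    stop("rescale_continuous requires a continuous deficit spec",
         call. = FALSE)
  }
  if (is.na(spec$v_min) || is.na(spec$v_max)) {
    stop("deficit '", spec$name, "' has no rescaling range; call ",
         "determine_range() first", call. = FALSE)
  }
  if (spec$v_min == spec$v_max) {
    stop("degenerate rescaling range for '", spec$name, "' (v_min == v_max)",
         call. = FALSE)
  }
  s <- (value - spec$v_min) / (spec$v_max - spec$v_min)
  s <- pmin(pmax(s, 0), 1)
  if (spec$direction == "lower_is_worse") s <- 1 - s
  s
}

#' Dichotomise a deficit at its cut-point
#'
#' Scores 1 when the value lies on the unhealthy side of the cut-point
#' (inclusive), 0 otherwise. For `higher_is_worse` deficits the unhealthy
#' side is `value >= cutpoint`; for `lower_is_worse`, `value <= cutpoint`.
#' Logical values are accepted for presence/absence deficits.
#'
#' @param value Numeric or logical vector (non-missing).
#' @param spec A binary [deficit_spec()].
#' @return Numeric vector of 0/1 deficit scores.
#' @export
score_binary <- function(value, spec) {
  stopifnot(inherits(spec, "deficit_spec"))
  if (spec$kind != "binary") {
    stop("score_binary requires a binary deficit spec", call. = FALSE)
  }
  value <- as.numeric(value)
  if (spec$direction == "higher_is_worse") {
    as.numeric(value >= spec$cutpoint)
  } else {
    as.numeric(value <= spec$cutpoint)
  }
}

#' Fix a rescaling range from observed values
#'
#' Implements the range-setting step of the continuous refinement: extreme
#' outliers are excluded and the highest and lowest remaining values become
#' `v_max` and `v_min`. Outliers are values outside the closed empirical
#' quantile band given by `outlier_rule`; quantiles are order statistics
#' (no interpolation), so the band always lies on observed values.
#'
#' @param values Numeric vector of raw observations (at least 20 non-missing).
#' @param outlier_rule Length-2 quantile band, default the 0.5th/99.5th
#'   percentiles.
#' @return Named numeric vector `c(v_min = ..., v_max = ...)`.
#' @export
determine_range <- function(values, outlier_rule = c(0.005, 0.995)) {
  values <- values[!is.na(values)]
  if (length(values) < 20L) {
    stop("determine_range requires at least 20 non-missing values",
         call. = FALSE)
  }
  band <- stats::quantile(values, probs = outlier_rule, type = 3,
                          names = FALSE)
  kept <- values[values >= band[1] & values <= band[2]]
  v_min <- min(kept)
  v_max <- max(kept)
  if (v_min == v_max) {
    stop("degenerate range: all retained values identical (", v_min, ")",
         call. = FALSE)
  }
  c(v_min = v_min, v_max = v_max)
}

#' Fill unset continuous ranges in a cohort's deficit specs from its data
#'
#' For every continuous deficit whose `v_min`/`v_max` are unset, the range is
#' determined from the pooled observed values across all visits using the
#' spec's own outlier rule.
#'
#' @param cohort A `falls_cohort`.
#' @return The cohort with completed deficit specs.
#' @export
determine_ranges <- function(cohort) {
  stopifnot(inherits(cohort, "falls_cohort"))
  for (nm in deficit_names(cohort)) {
    s <- cohort$deficit_specs[[nm]]
    if (s$kind == "continuous" && is.na(s$v_min)) {
      rng <- determine_range(cohort$visits[[nm]], s$outlier_rule)
      s$v_min <- rng[["v_min"]]
      s$v_max <- rng[["v_max"]]
      cohort$deficit_specs[[nm]] <- s
    }
  }
  cohort
}

# score one deficit column under its spec; NAs propagate
score_deficit <- function(value, spec) {
  out <- rep(NA_real_, length(value))
  ok <- !is.na(value)
  if (any(ok)) {
    out[ok] <- if (spec$kind == "binary") {
      score_binary(value[ok], spec)
    } else {
      rescale_continuous(value[ok], spec)
    }
  }
  out
}

#' Compute the frailty index for one participant-visit
#'
#' The index is the mean of the per-item deficit scores over non-missing
#' items — the proportion of accumulated health deficits, 0 (none) to 1
#' (all). Records scoring fewer than `min_completeness` of the items get an
#' undefined index (`NA`) and are flagged for downstream exclusion.
#'
#' @param visit A one-row data.frame (or named list) holding the raw deficit
#'   values, plus `participant_id` and `visit_age`.
#' @param specs Named list of [deficit_spec()] objects.
#' @param config An [index_config()].
#' @return A one-row data.frame with `participant_id`, `visit_age`, `index`,
#'   `n_items_scored`, `complete` and `frail`.
#' @export
compute_frailty_index <- function(visit, specs, config = index_config()) {
  visit <- as.data.frame(as.list(visit), stringsAsFactors = FALSE)
  scores <- vapply(specs, function(s) {
    val <- visit[[s$name]]
    if (is.null(val)) NA_real_ else score_deficit(val, s)
  }, numeric(1))
  n_scored <- sum(!is.na(scores))
  complete <- n_scored >= config$min_completeness * length(specs)
  idx <- if (complete) mean(scores, na.rm = TRUE) else NA_real_
  data.frame(
    participant_id = as.character(visit$participant_id),
    visit_age = as.integer(visit$visit_age),
    index = idx,
    n_items_scored = as.integer(n_scored),
    complete = complete,
    frail = if (is.na(idx)) NA else classify_frailty(idx, config) == "frail",
    stringsAsFactors = FALSE
  )
}

#' Build frailty indices for every attended visit of a cohort
#'
#' Vectorised equivalent of [compute_frailty_index()]: scores each deficit
#' column under its spec and averages over non-missing items per record.
#' Non-attended visits have no measurements and get `NA` throughout.
#'
#' @param cohort A `falls_cohort` (continuous ranges must be populated; see
#'   [determine_ranges()]).
#' @param config An [index_config()].
#' @return A data.frame with one row per attended visit: `participant_id`,
#'   `visit_age`, `index`, `n_items_scored`, `complete`, `frail` and a
#'   `quintile` placeholder (`NA`; quintiles are assigned per analysis
#'   subsample, see [assign_quintiles()]).
#' @export
build_frailty_index <- function(cohort, config = index_config()) {
  stopifnot(inherits(cohort, "falls_cohort"),
            inherits(config, "index_config"))
  v <- cohort$visits[cohort$visits$attended %in% TRUE, , drop = FALSE]
  specs <- cohort$deficit_specs
  score_mat <- vapply(specs, function(s) score_deficit(v[[s$name]], s),
                      numeric(nrow(v)))
  score_mat <- matrix(score_mat, nrow = nrow(v),
                      dimnames = list(NULL, names(specs)))
  n_scored <- rowSums(!is.na(score_mat))
  complete <- n_scored >= config$min_completeness * length(specs)
  idx <- ifelse(complete, rowMeans(score_mat, na.rm = TRUE), NA_real_)
  out <- data.frame(
    participant_id = as.character(v$participant_id),
    visit_age = as.integer(v$visit_age),
    index = idx,
    n_items_scored = as.integer(n_scored),
    complete = complete,
    frail = ifelse(is.na(idx), NA,
                   classify_frailty(idx, config) == "frail"),
    quintile = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify an index value as frail or non-frail
#'
#' @param index Numeric vector of frailty-index values in \[0, 1\].
#' @param config An [index_config()]; the default classifies frail at
#'   index >= 0.25.
#' @return Character vector `"frail"` / `"non_frail"`.
#' @export
classify_frailty <- function(index, config = index_config()) {
  stopifnot(all(is.na(index) | (index >= 0 & index <= 1)))
  frail <- if (config$frail_boundary == "ge") {
    index >= config$cutoff
  } else {
    index > config$cutoff
  }
  ifelse(frail, "frail", "non_frail")
}

#' Bin index values of an analysis subsample into equal-sized quintiles
#'
#' Partitions the supplied values into five groups whose sizes differ by at
#' most one; label 1 is the lowest-frailty fifth. Quintiles are always
#' computed on the analysis subsample at hand (e.g. attendees with valid
#' falls data at the outcome visit), never on the full baseline cohort.
#'
#' @param values Numeric vector (no missing values; at least 5).
#' @param ties `"stable"` (default) breaks ties by input order, which
#'   guarantees the size balance; `"lower"` assigns ties that span a
#'   boundary to the lower quintile, which can unbalance group sizes.
#' @return Integer vector of quintile labels 1-5, aligned with `values`.
#' @export
assign_quintiles <- function(values, ties = c("stable", "lower")) {
  ties <- match.arg(ties)
  if (anyNA(values)) {
    stop("assign_quintiles requires non-missing values", call. = FALSE)
  }
  n <- length(values)
  if (n < 5L) {
    stop("assign_quintiles requires at least 5 values", call. = FALSE)
  }
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  lab_by_rank <- rep.int(1:5, sizes)
  ord <- order(values)                 # stable: ties keep input order
  labels <- integer(n)
  labels[ord] <- lab_by_rank
  if (ties == "lower") {
    labels <- stats::ave(labels, values, FUN = min)
  }
  as.integer(labels)
}

#' Compare two frailty indices on paired participants
#'
#' Used to check a refined index against an alternative construction (e.g. a
#' larger all-dichotomous index): Pearson correlation on complete pairs plus
#' the location of each distribution.
#'
#' @param fi_a,fi_b Numeric vectors of index values, paired by participant.
#' @return An object of class `index_comparison`: `r`, `n_pairs`, and mean
#'   and median of each index over complete pairs.
#' @export
compare_indices <- function(fi_a, fi_b) {
  stopifnot(length(fi_a) == length(fi_b))
  ok <- !is.na(fi_a) & !is.na(fi_b)
  if (sum(ok) < 3L) {
    stop("compare_indices requires at least 3 complete pairs", call. = FALSE)
  }
  a <- fi_a[ok]; b <- fi_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: one index has zero variance", call. = FALSE)
  }
  structure(
    list(r = stats::cor(a, b), n_pairs = sum(ok),
         mean_a = mean(a), mean_b = mean(b),
         median_a = stats::median(a), median_b = stats::median(b)),
    class = "index_comparison"
  )
}

#' @export
print.index_comparison <- function(x, ...) {
  cat(sprintf("<index_comparison> r = %.3f on %d pairs\n", x$r, x$n_pairs))
  cat(sprintf("  index A: mean %.3f, median %.3f\n", x$mean_a, x$median_a))
  cat(sprintf("  index B: mean %.3f, median %.3f\n", x$mean_b, x$median_b))
  invisible(x)
}
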