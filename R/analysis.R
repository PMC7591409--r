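# Orchestrates the full frailty-falls analysis: baseline characteristics,
# quintile gradients, fall-frailty groups, frailty-status ORs and falls
# incidence, with analysis n and exclusion counts recorded at every step.

four_fall_groups <- function(n_falls) {
  out <- ifelse(is.na(n_falls), NA_character_,
                ifelse(n_falls >= 3, "three_plus",
                       ifelse(n_falls == 2, "two",
                              ifelse(n_falls == 1, "one", "none"))))
  factor(out, levels = c("none", "one", "two", "three_plus"))
}

est_row <- function(est) {
  data.frame(term = est$term, odds_ratio = est$odds_ratio,
             ci_low = est$ci_low, ci_high = est$ci_high,
             p_value = est$p_value, model = est$model,
             adjusted_for = paste(est$adjusted_for, collapse = "+"),
             n_used = if (is.null(attr(est, "n_used"))) NA_integer_
                      else attr(est, "n_used"),
             stringsAsFactors = FALSE)
}

# one analysis frame per participant: index/frail at the exposure visit,
# falls at the outcome visit, baseline covariates
pairing_frame <- function(cohort, fi, exposure_age, outcome_age) {
  v <- cohort$visits
  base <- v[v$visit_age == min(cohort$visit_ages),
            c("participant_id", "bmi", "s25ohd", "smoking", "prior_fracture")]
  exp_fi <- fi[fi$visit_age == exposure_age & fi$complete,
               c("participant_id", "index", "frail")]
  exp_falls <- v[v$visit_age == exposure_age & v$attended %in% TRUE,
                 c("participant_id", "falls_12m")]
  names(exp_falls)[2] <- "falls_exposure"
  out_falls <- v[v$visit_age == outcome_age & v$attended %in% TRUE,
                 c("participant_id", "falls_12m")]
  names(out_falls)[2] <- "falls_outcome"
  d <- merge(exp_fi, out_falls, by = "participant_id")
  d <- merge(d, exp_falls, by = "participant_id", all.x = TRUE)
  d <- merge(d, base, by = "participant_id", all.x = TRUE)
  d$any_fall <- ifelse(is.na(d$falls_outcome), NA, d$falls_outcome >= 1)
  d$recurrent <- ifelse(is.na(d$falls_outcome), NA, d$falls_outcome >= 2)
  d
}

baseline_characteristics <- function(cohort, fi, config) {
  age0 <- min(cohort$visit_ages)
  v <- cohort$visits[cohort$visits$visit_age == age0, , drop = FALSE]
  f0 <- fi[fi$visit_age == age0 & fi$complete, ]
  d <- merge(f0, v, by = c("participant_id", "visit_age"))
  d$status <- factor(ifelse(d$frail, "frail", "non_frail"),
                     levels = c("non_frail", "frail"))
  num_sum <- function(x, g) {
    t(vapply(split(x, g), function(z) {
      z <- z[!is.na(z)]
      c(n = length(z), mean = mean(z), sd = stats::sd(z),
        median = stats::median(z), iqr = stats::IQR(z))
    }, numeric(5)))
  }
  falls_valid <- d[!is.na(d$falls_12m), ]
  falls_tab <- cross_tabulate(
    data.frame(status = falls_valid$status,
               falls = classify_falls(falls_valid$falls_12m)),
    "status", "falls")
  list(
    n_by_status = table(d$status),
    index = num_sum(d$index, d$status),
    bmi = num_sum(d$bmi, d$status),
    s25ohd = num_sum(d$s25ohd, d$status),
    falls = falls_tab,
    n_falls_valid = nrow(falls_valid),
    prior_fracture = cross_tabulate(d, "status", "prior_fracture"),
    smoking = cross_tabulate(d, "status", "smoking")
  )
}

quintile_table <- function(cohort, fi, exposure_age, outcome_age) {
  d <- pairing_frame(cohort, fi, exposure_age, outcome_age)
  d <- d[!is.na(d$falls_outcome), , drop = FALSE]
  if (nrow(d) < 5L) stop("too few records for quintile analysis (",
                         exposure_age, " -> ", outcome_age, ")", call. = FALSE)
  d$quintile <- assign_quintiles(d$index)
  d$fall_group <- four_fall_groups(d$falls_outcome)
  tab <- cross_tabulate(d, "quintile", "fall_group")
  bounds <- t(vapply(split(d$index, d$quintile), range, numeric(2)))
  colnames(bounds) <- c("min_index", "max_index")
  list(exposure_age = exposure_age, outcome_age = outcome_age,
       n = nrow(d), table = tab, chi_square = chi_square(tab),
       quintile_bounds = bounds)
}

fall_frailty_section <- function(cohort, fi, exposure_age, outcome_age,
                                 adjustment) {
  d <- pairing_frame(cohort, fi, exposure_age, outcome_age)
  d$group <- fall_frailty_group(classify_falls(d$falls_exposure), d$frail)
  d <- d[!is.na(d$group), , drop = FALSE]
  out <- list(exposure_age = exposure_age, outcome_age = outcome_age)
  for (oc in c("any_fall", "recurrent")) {
    dd <- d[!is.na(d[[oc]]), , drop = FALSE]
    props <- cross_tabulate(
      data.frame(group = dd$group, outcome = dd[[oc]]), "group", "outcome")
    pair_p <- function(g1, g2) {
      sub <- dd[dd$group %in% c(g1, g2), ]
      tab <- table(droplevels(sub$group), sub[[oc]])
      if (any(dim(tab) < 2)) return(NA_real_)
      chi_square(tab)$p_value
    }
    # frail vs non-frail within each faller stratum
    strat_or <- function(stratum) {
      sub <- dd[dd$group %in% stratum, , drop = FALSE]
      sub$frail_num <- as.numeric(sub$frail)
      unadj <- logistic_or(sub, oc, "frail_num")[[1]]
      adj <- tryCatch(
        logistic_or(sub, oc, "frail_num", adjustment)[["frail_num"]],
        error = function(e) NULL)
      list(unadjusted = unadj, adjusted = adj)
    }
    faller <- strat_or(c("faller_frail", "faller_nonfrail"))
    nonfaller <- strat_or(c("nonfaller_frail", "nonfaller_nonfrail"))
    # four-group model against the robust (non-faller, non-frail) reference
    dd$group_rev <- stats::relevel(droplevels(dd$group),
                                   ref = "nonfaller_nonfrail")
    four_unadj <- logistic_or(dd, oc, "group_rev")
    four_adj <- tryCatch(logistic_or(dd, oc, "group_rev", adjustment),
                         error = function(e) NULL)
    out[[oc]] <- list(
      n = nrow(dd),
      proportions = props,
      p_faller_frail_vs_nonfrail = pair_p("faller_frail", "faller_nonfrail"),
      p_nonfaller_frail_vs_nonfrail = pair_p("nonfaller_frail",
                                             "nonfaller_nonfrail"),
      p_extremes = pair_p("faller_frail", "nonfaller_nonfrail"),
      or_faller = faller, or_nonfaller = nonfaller,
      or_four_group = list(unadjusted = four_unadj, adjusted = four_adj)
    )
  }
  out
}

frailty_status_section <- function(cohort, fi, exposure_age, outcome_age,
                                   adjustment) {
  d <- pairing_frame(cohort, fi, exposure_age, outcome_age)
  d$frail_num <- as.numeric(d$frail)
  res <- list(exposure_age = exposure_age, outcome_age = outcome_age)
  for (oc in c("any_fall", "recurrent")) {
    dd <- d[!is.na(d[[oc]]), , drop = FALSE]
    res[[oc]] <- list(
      n = nrow(dd),
      or_status_unadjusted = logistic_or(dd, oc, "frail_num")[[1]],
      or_status_adjusted = tryCatch(
        logistic_or(dd, oc, "frail_num", adjustment)[["frail_num"]],
        error = function(e) NULL),
      or_per_001_unadjusted = frailty_increment_or(dd, oc, "index"),
      or_per_001_adjusted = tryCatch(
        frailty_increment_or(dd, oc, "index", adjustment),
        error = function(e) NULL)
    )
  }
  res
}

falls_incidence <- function(cohort) {
  v <- cohort$visits
  do.call(rbind, lapply(sort(unique(v$visit_age)), function(age) {
    sub <- v[v$visit_age == age & v$attended %in% TRUE, ]
    falls <- sub$falls_12m
    valid <- falls[!is.na(falls)]
    g <- four_fall_groups(valid)
    data.frame(
      visit_age = age, n_attended = nrow(sub), n_falls_valid = length(valid),
      n_falls_missing = sum(is.na(falls)),
      n_none = sum(g == "none"), n_one = sum(g == "one"),
      n_two = sum(g == "two"), n_three_plus = sum(g == "three_plus"),
      pct_any_fall = 100 * mean(valid >= 1),
      pct_recurrent = 100 * mean(valid >= 2)
    )
  }))
}

#' Run the complete frailty-falls analysis on a cohort
#'
#' Builds the frailty index for every attended visit (determining any unset
#' continuous ranges from the data), then produces: (a) baseline
#' characteristics split by frailty status, (b) quintile-by-falls tables for
#' each visit pairing with chi-square tests, (c) combined fall-frailty group
#' proportions and odds ratios (frail vs non-frail within faller strata, and
#' all four groups against the robust reference), unadjusted and
#' covariate-adjusted, (d) frailty-status and per-0.01-increment odds ratios
#' for falls at later visits, and (e) falls incidence per visit. Every table
#' records its analysis n; records with missing falls data are excluded at
#' analysis time only.
#'
#' @param cohort A `falls_cohort`.
#' @param config An [index_config()].
#' @param adjustment Covariate columns for the adjusted models (default
#'   serum 25(OH)D, BMI, smoking and prior fracture, all at baseline).
#' @param pairings List of `c(exposure_age, outcome_age)` visit pairs for
#'   the longitudinal sections; defaults to 75->80, 75->85 and 80->85.
#' @return An object of class `falls_report`.
#' @export
run_full_analysis <- function(cohort, config = index_config(),
                              adjustment = c("s25ohd", "bmi", "smoking",
                                             "prior_fracture"),
                              pairings = list(c(75, 80), c(75, 85),
                                              c(80, 85))) {
  stopifnot(inherits(cohort, "falls_cohort"))
  if (nrow(cohort$visits) == 0L) stop("empty cohort", call. = FALSE)
  findings <- validate_cohort(cohort)
  if (nrow(findings)) {
    stop("cohort fails validation (", nrow(findings),
         " findings); see validate_cohort()", call. = FALSE)
  }
  cohort <- determine_ranges(cohort)
  fi <- build_frailty_index(cohort, config)
  age0 <- min(cohort$visit_ages)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  quintile_pairings <- c(list(c(age0, age0)), pairings)
  report <- list(
    config = config,
    adjustment = adjustment,
    frailty_index = fi,
    baseline = wrap("baseline_characteristics",
                    baseline_characteristics(cohort, fi, config)),
    quintiles = wrap("quintile_tables", lapply(quintile_pairings, function(p)
      quintile_table(cohort, fi, p[1], p[2]))),
    fall_frailty = wrap("fall_frailty_groups", lapply(pairings, function(p)
      fall_frailty_section(cohort, fi, p[1], p[2], adjustment))),
    frailty_status = wrap("frailty_status_ors", lapply(pairings, function(p)
      frailty_status_section(cohort, fi, p[1], p[2], adjustment))),
    incidence = wrap("falls_incidence", falls_incidence(cohort))
  )
  class(report) <- "falls_report"
  report
}

#' @export
print.falls_report <- function(x, ...) {
  cat("<falls_report>\n")
  inc <- x$incidence
  cat("Falls incidence per visit:\n")
  print(inc[, c("visit_age", "n_falls_valid", "pct_any_fall",
                "pct_recurrent")], row.names = FALSE, digits = 3)
  cat("\nFrailty-status odds ratios for recurrent falls:\n")
  for (s in x$frailty_status) {
    est <- s$recurrent$or_status_unadjusted
    cat(sprintf("  frail at %d -> recurrent falls at %d: OR %.2f (%.2f-%.2f), n = %d\n",
                s$exposure_age, s$outcome_age, est$odds_ratio, est$ci_low,
                est$ci_high, s$recurrent$n))
  }
  invisible(x)
}

#' Write a falls report to disk as CSV tables plus a JSON summary
#'
#' @param report A `falls_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "falls_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$frailty_index,
                   file.path(dir, "frailty_index.csv"), row.names = FALSE)
  utils::write.csv(report$incidence,
                   file.path(dir, "falls_incidence.csv"), row.names = FALSE)
  for (q in report$quintiles) {
    base <- sprintf("quintiles_%d_to_%d", q$exposure_age, q$outcome_age)
    counts <- as.data.frame.matrix(q$table$counts)
    counts <- cbind(quintile = rownames(counts), counts)
    utils::write.csv(counts, file.path(dir, paste0(base, ".csv")),
                     row.names = FALSE)
  }
  ors <- list()
  for (s in report$frailty_status) {
    for (oc in c("any_fall", "recurrent")) {
      sec <- s[[oc]]
      for (nm in c("or_status_unadjusted", "or_status_adjusted",
                   "or_per_001_unadjusted", "or_per_001_adjusted")) {
        if (is.null(sec[[nm]])) next
        row <- est_row(sec[[nm]])
        row$exposure_age <- s$exposure_age
        row$outcome_age <- s$outcome_age
        row$outcome <- oc
        row$estimate <- nm
        ors[[length(ors) + 1L]] <- row
      }
    }
  }
  for (s in report$fall_frailty) {
    for (oc in c("any_fall", "recurrent")) {
      sec <- s[[oc]]
      for (stratum in c("or_faller", "or_nonfaller")) {
        for (kind in c("unadjusted", "adjusted")) {
          est <- sec[[stratum]][[kind]]
          if (is.null(est)) next
          row <- est_row(est)
          row$exposure_age <- s$exposure_age
          row$outcome_age <- s$outcome_age
          row$outcome <- oc
          row$estimate <- paste(stratum, kind, sep = "_")
          ors[[length(ors) + 1L]] <- row
        }
      }
    }
  }
  utils::write.csv(do.call(rbind, ors),
                   file.path(dir, "odds_ratios.csv"), row.names = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(dir)
}

# plain-list rendering of a report for JSON serialisation
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "effect_estimate")) {
      return(list(term = x$term, odds_ratio = x$odds_ratio,
                  ci_low = x$ci_low, ci_high = x$ci_high,
                  p_value = x$p_value, model = x$model,
                  adjusted_for = x$adjusted_for,
                  corrected = isTRUE(x$corrected),
                  n_used = attr(x, "n_used")))
    }
    if (inherits(x, "contingency_table")) {
      return(list(counts = as.data.frame.matrix(x$counts),
                  row_pct = as.data.frame.matrix(x$row_pct),
                  n = x$n, n_excluded = x$n_excluded))
    }
    if (inherits(x, "index_config")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(report))
}
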