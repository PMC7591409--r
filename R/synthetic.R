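# Synthetic longitudinal cohort generator. The design is latent-index-first:
# a latent frailty trajectory is sampled for each woman, raw deficit values
# are then constructed so the index builder reproduces the latent index, and
# falls, mortality and attrition are drawn conditional on the latent index.
# Default calibration constants live in inst/extdata/generator_calibration.yaml.

#' Deficit specifications used by the synthetic cohort generator
#'
#' Thirteen synthetic deficit variables spanning the physiological domains
#' of the 13-item index: nine continuous (daily physical activity, time
#' outdoors, walking speed, steps to walk 30 m, balance sway, grip strength,
#' CRP, creatinine, medication count) and four binary (diabetes, cancer,
#' disease affecting balance, self-rated fall risk). Ranges other than the
#' published 21-160 steps are plausible synthetic defaults.
#'
#' @return Named list of 13 [deficit_spec()] objects.
#' @export
synthetic_deficit_specs <- function() {
  cont <- function(name, dir, lo, hi) {
    deficit_spec(name, "continuous", dir, v_min = lo, v_max = hi)
  }
  bin <- function(name) {
    deficit_spec(name, "binary", "higher_is_worse", cutpoint = 0.5)
  }
  specs <- list(
    cont("physical_activity", "lower_is_worse", 0, 14),   # h/week
    cont("time_outdoors", "lower_is_worse", 0, 40),       # h/week
    cont("walking_speed", "lower_is_worse", 0.2, 2.0),    # m/s
    cont("steps_30m", "higher_is_worse", 21, 160),        # published range
    cont("balance_sway", "higher_is_worse", 2, 40),       # mm
    cont("grip_strength", "lower_is_worse", 4, 40),       # kg
    cont("crp", "higher_is_worse", 0, 40),                # mg/L
    cont("creatinine", "higher_is_worse", 40, 160),       # umol/L
    cont("medication_count", "higher_is_worse", 0, 12),
    bin("diabetes"),
    bin("cancer"),
    bin("balance_disease"),
    bin("self_rated_fall_risk")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Configure the synthetic cohort generator
#'
#' Defaults come from the packaged calibration file (see
#' `system.file("extdata", "generator_calibration.yaml", package =
#' "frailtyfalls")`), which targets a right-skewed baseline index (median
#' 0.16, IQR 0.14), baseline falls incidence of 28.4% (>= 1 fall) and 14.7%
#' (recurrent), and frailty-dependent attrition thinning 1044 -> 715 -> 382.
#' Any element can be overridden through `...` (e.g.
#' `falls = list(log_or_recurrent_per_001 = 0)` for a null falls model).
#'
#' @param n_baseline Number of women at baseline (default 1044).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   seed.
#' @param visit_ages The three visit ages.
#' @param ... Named overrides of calibration entries (lists are merged
#'   element-wise).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_baseline = 1044L, seed = 1L,
                             visit_ages = c(75L, 80L, 85L), ...) {
  path <- system.file("extdata", "generator_calibration.yaml",
                      package = "frailtyfalls")
  cal <- yaml::read_yaml(path)
  overrides <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  bad <- setdiff(names(overrides), names(cal))
  if (length(bad)) {
    stop("unknown generator_config entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cal <- merge_in(cal, overrides)
  stopifnot(n_baseline >= 1, length(visit_ages) == 3L)
  probs <- c(unlist(cal$missingness_falls), cal$deficit_missingness,
             unlist(cal$attendance$target), unlist(cal$falls$target_any),
             unlist(cal$falls$target_recurrent), cal$mortality$base,
             cal$mortality$first_interval_share)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(c(list(n_baseline = as.integer(n_baseline),
                   seed = as.integer(seed),
                   visit_ages = as.integer(visit_ages)), cal),
            class = "generator_config")
}

# distribute a row-wise total over k unit-bounded scores: s_i = min(c*w_i, 1)
# with c solved per row by bisection so that sum_i s_i = total (exact when
# 0 <= total <= k)
waterfill_scores <- function(total, weights) {
  n <- nrow(weights); k <- ncol(weights)
  lo <- rep(0, n)
  hi <- rep(k / min(weights) + 1, n)
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    s <- pmin(weights * mid, 1)
    too_low <- rowSums(s) < total
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
  }
  pmin(weights * (lo + hi) / 2, 1)
}

# solve a logistic intercept so that mean(plogis(a + slope)) over the given
# offsets hits the target rate
solve_intercept <- function(offset, target, label) {
  if (length(offset) == 0L) {
    stop("infeasible calibration: no records for ", label, call. = FALSE)
  }
  f <- function(a) mean(stats::plogis(a + offset)) - target
  if (f(35) < 0 || f(-35) > 0) {
    stop("infeasible calibration for ", label, " (target ", target, ")",
         call. = FALSE)
  }
  stats::uniroot(f, c(-35, 35), tol = 1e-10)$root
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces a full three-visit cohort with raw deficit values, falls counts,
#' vital status, attendance and covariates, plus a generator-truth sidecar.
#' Per woman: a latent frailty trajectory over the three visits (Beta
#' baseline plus calibrated drift and noise); 13 raw deficit values
#' constructed so that the configured index builder reproduces the latent
#' index (exactly, except for the rare trajectories where the binary-deficit
#' draw makes the item total infeasible and the rebuilt index is clamped);
#' 12-month falls counts with log-odds linear in the latent index (counts
#' above two from a truncated negative-binomial tail); 10-year mortality
#' flat below the 0.25 knee and rising linearly above it; attendance
#' decreasing in frailty, with per-visit intercepts solved at generation
#' time to hit the configured expected attendee counts; and falls-data
#' missingness per visit. Identical config and seed give an identical
#' cohort.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_cohort`: `cohort` (a
#'   [falls_cohort()]), `truth` (per-visit latent index and falls
#'   probabilities, per-woman mortality, and the realised model intercepts)
#'   and `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_baseline
  ages <- config$visit_ages
  ids <- sprintf("P%04d", seq_len(n))

  ## latent frailty trajectory
  shape <- config$frailty_shape
  drift <- unlist(config$frailty_drift)
  nsd <- unlist(config$frailty_noise_sd)
  fi <- matrix(NA_real_, n, 3)
  fi[, 1] <- stats::rbeta(n, shape$alpha, shape$beta)
  fi[, 2] <- pmin(pmax(fi[, 1] + drift[1] + stats::rnorm(n, 0, nsd[1]), 0), 1)
  fi[, 3] <- pmin(pmax(fi[, 1] + drift[2] + stats::rnorm(n, 0, nsd[2]), 0), 1)

  ## mortality: 10-year death risk piecewise-linear in baseline index
  mort <- config$mortality
  p_die10 <- pmin(mort$base + mort$slope * pmax(fi[, 1] - mort$knee, 0), 1)
  die10 <- stats::rbinom(n, 1, p_die10) == 1
  die_first <- die10 & (stats::runif(n) < mort$first_interval_share)
  alive <- cbind(TRUE, !die_first, !die10)

  ## attendance: monotone dropout, log-odds decreasing in current index
  att_slope <- config$attendance$slope_per_001 * 100
  target <- unlist(config$attendance$target)
  attended <- matrix(FALSE, n, 3)
  attended[, 1] <- TRUE
  intercepts <- list()
  for (v in 2:3) {
    eligible <- alive[, v] & attended[, v - 1]
    n_target <- target[v] * n
    if (sum(eligible) < n_target) {
      stop("infeasible calibration: attendance target at visit ", v,
           " exceeds the number of eligible survivors", call. = FALSE)
    }
    # solve over eligible women for the expected attendee count
    f <- function(a) sum(stats::plogis(a - att_slope * fi[eligible, v])) -
      n_target
    a_v <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
    attended[eligible, v] <-
      stats::runif(sum(eligible)) < stats::plogis(a_v - att_slope * fi[eligible, v])
    intercepts[[paste0("attendance_", ages[v])]] <- a_v
  }

  ## falls: nested logistic draws, intercepts solved per visit on attendees
  fm <- config$falls
  b_any <- fm$log_or_any_per_001 * 100
  b_rec <- fm$log_or_recurrent_per_001 * 100
  falls <- matrix(NA_integer_, n, 3)
  p_any_m <- p_rec_m <- matrix(NA_real_, n, 3)
  for (v in 1:3) {
    att <- attended[, v]
    a_any <- solve_intercept(b_any * fi[att, v], fm$target_any[[v]],
                             paste0("falls(any) at visit ", v))
    a_rec <- solve_intercept(b_rec * fi[att, v], fm$target_recurrent[[v]],
                             paste0("falls(recurrent) at visit ", v))
    p_any <- stats::plogis(a_any + b_any * fi[, v])
    p_rec <- pmin(stats::plogis(a_rec + b_rec * fi[, v]), p_any)
    u <- stats::runif(n)
    extra <- stats::rnbinom(n, size = fm$extra_falls$dispersion,
                            mu = fm$extra_falls$mu_base +
                              fm$extra_falls$mu_slope * fi[, v])
    cnt <- ifelse(u < p_rec, 2L + extra, ifelse(u < p_any, 1L, 0L))
    cnt[!att] <- NA_integer_
    # falls-data missingness among attendees
    miss <- att & (stats::runif(n) < config$missingness_falls[[v]])
    cnt[miss] <- NA_integer_
    falls[, v] <- cnt
    p_any_m[att, v] <- p_any[att]
    p_rec_m[att, v] <- p_rec[att]
    intercepts[[paste0("falls_any_", ages[v])]] <- a_any
    intercepts[[paste0("falls_recurrent_", ages[v])]] <- a_rec
  }

  ## covariates (baseline values, carried forward)
  cv <- config$covariates
  fi_c <- fi[, 1] - shape$alpha / (shape$alpha + shape$beta)
  bmi <- cv$bmi$mean + cv$bmi$fi_slope * fi_c + stats::rnorm(n, 0, cv$bmi$sd)
  s25 <- pmax(cv$s25ohd$mean + cv$s25ohd$fi_slope * fi_c +
                stats::rnorm(n, 0, cv$s25ohd$sd), 5)
  sm <- cv$smoking
  w_never <- rep(1, n)
  w_prev <- (sm$p_previous / sm$p_never) * exp(sm$fi_slope * fi_c)
  w_curr <- (sm$p_current / sm$p_never) * exp(sm$fi_slope * fi_c)
  tot <- w_never + w_prev + w_curr
  u_sm <- stats::runif(n)
  smoking <- ifelse(u_sm < w_never / tot, "never",
                    ifelse(u_sm < (w_never + w_prev) / tot,
                           "previous", "current"))
  fx <- cv$prior_fracture
  prior_fracture <- stats::runif(n) <
    stats::plogis(stats::qlogis(fx$p) + fx$fi_logit_slope * fi_c)

  ## raw deficits per attended visit, reproducing the latent index
  specs <- synthetic_deficit_specs()
  kinds <- vapply(specs, `[[`, character(1), "kind")
  bin_names <- names(specs)[kinds == "binary"]
  cont_names <- names(specs)[kinds == "continuous"]
  n_bin <- length(bin_names); n_cont <- length(cont_names)
  n_items <- length(specs)
  deficit_cols <- stats::setNames(
    replicate(n_items, rep(NA_real_, n * 3), simplify = FALSE), names(specs))
  for (v in 1:3) {
    att <- which(attended[, v])
    m <- length(att)
    if (m == 0L) next
    f <- fi[att, v]
    bin_scores <- matrix(
      stats::rbinom(m * n_bin, 1, pmin(config$binary_prevalence_scale *
                                         rep(f, n_bin), 1)),
      nrow = m)
    total <- pmin(pmax(n_items * f - rowSums(bin_scores), 0), n_cont)
    weights <- matrix(stats::runif(m * n_cont, 0.1, 1.1), nrow = m)
    cont_scores <- waterfill_scores(total, weights)
    rows <- (v - 1L) * n + att
    for (j in seq_len(n_cont)) {
      s <- specs[[cont_names[j]]]
      sc <- cont_scores[, j]
      raw <- if (s$direction == "higher_is_worse") {
        s$v_min + sc * (s$v_max - s$v_min)
      } else {
        s$v_max - sc * (s$v_max - s$v_min)
      }
      deficit_cols[[cont_names[j]]][rows] <- raw
    }
    for (j in seq_len(n_bin)) {
      deficit_cols[[bin_names[j]]][rows] <- bin_scores[, j]
    }
    # sporadic item missingness
    if (config$deficit_missingness > 0) {
      for (nm in names(specs)) {
        drop <- rows[stats::runif(m) < config$deficit_missingness]
        deficit_cols[[nm]][drop] <- NA_real_
      }
    }
  }

  visits <- data.frame(
    participant_id = rep(ids, 3),
    visit_age = rep(ages, each = n),
    alive = as.vector(alive),
    attended = as.vector(attended),
    falls_12m = as.vector(falls),
    bmi = rep(round(bmi, 1), 3),
    s25ohd = rep(round(s25, 1), 3),
    smoking = rep(smoking, 3),
    prior_fracture = rep(prior_fracture, 3),
    stringsAsFactors = FALSE
  )
  for (nm in names(deficit_cols)) {
    visits[[nm]] <- round(deficit_cols[[nm]], 4)
  }
  cohort <- falls_cohort(visits, specs, visit_ages = ages)

  truth_visits <- data.frame(
    participant_id = rep(ids, 3),
    visit_age = rep(ages, each = n),
    latent_index = as.vector(fi),
    attended = as.vector(attended),
    p_any_fall = as.vector(p_any_m),
    p_recurrent = as.vector(p_rec_m),
    stringsAsFactors = FALSE
  )
  truth_women <- data.frame(
    participant_id = ids, p_die10 = p_die10, died_within_10y = die10,
    died_first_interval = die_first, stringsAsFactors = FALSE
  )
  structure(list(cohort = cohort,
                 truth = list(visits = truth_visits, women = truth_women,
                              intercepts = intercepts),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> seed", x$config$seed, "\n")
  print(x$cohort)
  invisible(x)
}

#' Write the generator-truth sidecar to JSON
#'
#' @param sim A `synthetic_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  jsonlite::write_json(
    list(config = unclass(sim$config), intercepts = sim$truth$intercepts,
         visits = sim$truth$visits, women = sim$truth$women),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# implied population odds ratio, frail vs non-frail, for a logistic-in-index
# outcome model evaluated over the latent baseline sample
implied_group_or <- function(latent, p, frail) {
  p_f <- mean(p[frail]); p_n <- mean(p[!frail])
  (p_f / (1 - p_f)) / (p_n / (1 - p_n))
}

#' Generate-analyse-summarise parameter recovery experiment
#'
#' Repeatedly generates a synthetic cohort, rebuilds the frailty index from
#' the raw deficits through the package pipeline, and fits the baseline
#' falls models, summarising bias, Wald-CI coverage and rejection rate for
#' (i) the per-0.01-index odds ratio and (ii) the frail vs non-frail odds
#' ratio for the chosen outcome. The truth for (i) is the configured
#' per-0.01 log-odds; for (ii) it is the population odds ratio implied by
#' the latent model, computed per replicate from the generator truth.
#'
#' @param config A [generator_config()] (its seed is replaced per replicate).
#' @param index_cfg An [index_config()].
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param outcome `"recurrent"` (default) or `"any_fall"`.
#' @return An object of class `recovery_summary`: per-replicate estimates
#'   and the aggregate bias/coverage summary (no coverage claim is made for
#'   a single replicate).
#' @export
recovery_experiment <- function(config = generator_config(),
                                index_cfg = index_config(),
                                n_replicates = 100L, seed = 1L,
                                outcome = c("recurrent", "any_fall")) {
  outcome <- match.arg(outcome)
  stopifnot(n_replicates >= 1L)
  b_per001 <- if (outcome == "recurrent") {
    config$falls$log_or_recurrent_per_001
  } else {
    config$falls$log_or_any_per_001
  }
  true_or <- exp(b_per001)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(seed) * 100003 + r) %% 2147483647)
    sim <- generate_cohort(cfg)
    fi <- build_frailty_index(sim$cohort, index_cfg)
    age0 <- min(cfg$visit_ages)
    base <- merge(
      fi[fi$visit_age == age0 & fi$complete, ],
      sim$cohort$visits[sim$cohort$visits$visit_age == age0,
                        c("participant_id", "falls_12m")],
      by = "participant_id")
    base <- base[!is.na(base$falls_12m), ]
    base$outcome_flag <- if (outcome == "recurrent") {
      base$falls_12m >= 2
    } else {
      base$falls_12m >= 1
    }
    inc <- frailty_increment_or(base, "outcome_flag", "index")
    base$frail_num <- as.numeric(base$frail)
    grp <- logistic_or(base, "outcome_flag", "frail_num")[[1]]
    tv <- sim$truth$visits
    tb <- tv[tv$visit_age == age0, ]
    p_true <- if (outcome == "recurrent") tb$p_recurrent else tb$p_any_fall
    frail_true <- classify_frailty(tb$latent_index, index_cfg) == "frail"
    or_grp_true <- implied_group_or(tb$latent_index, p_true, frail_true)
    rows[[r]] <- data.frame(
      replicate = r, n_analysed = nrow(base),
      or_per001 = inc$odds_ratio, ci_low = inc$ci_low, ci_high = inc$ci_high,
      p_value = inc$p_value,
      covered = inc$ci_low <= true_or & true_or <= inc$ci_high,
      or_group = grp$odds_ratio, group_ci_low = grp$ci_low,
      group_ci_high = grp$ci_high, or_group_true = or_grp_true,
      group_covered = grp$ci_low <= or_grp_true & or_grp_true <= grp$ci_high
    )
  }
  reps <- do.call(rbind, rows)
  summary <- list(
    outcome = outcome, true_or_per001 = true_or,
    n_replicates = n_replicates,
    mean_or_per001 = mean(reps$or_per001),
    bias_log_or = mean(log(reps$or_per001)) - log(true_or),
    rejection_rate = mean(reps$p_value < 0.05),
    mean_or_group = mean(reps$or_group),
    mean_or_group_true = mean(reps$or_group_true)
  )
  if (n_replicates > 1L) {
    summary$coverage <- mean(reps$covered)
    summary$group_coverage <- mean(reps$group_covered)
  }
  structure(list(replicates = reps, summary = summary),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery_summary> %s, %d replicates\n", s$outcome,
              s$n_replicates))
  cat(sprintf("  per-0.01 OR: true %.3f, mean estimate %.3f", s$true_or_per001,
              s$mean_or_per001))
  if (!is.null(s$coverage)) cat(sprintf(", coverage %.2f", s$coverage))
  cat("\n")
  cat(sprintf("  frail vs non-frail OR: implied true %.2f, mean estimate %.2f",
              s$mean_or_group_true, s$mean_or_group))
  if (!is.null(s$group_coverage)) {
    cat(sprintf(", coverage %.2f", s$group_coverage))
  }
  cat("\n")
  cat(sprintf("  rejection rate at alpha = 0.05: %.3f\n", s$rejection_rate))
  invisible(x)
}
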