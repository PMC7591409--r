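#' Classify a 12-month falls count
#'
#' Deterministic mapping of the self-reported falls count in the 12 months
#' before a visit: 0 falls, exactly one fall, or recurrent falls (2 or
#' more). Recurrent falling is treated as the marker of an intrinsic
#' falling phenotype, in contrast with the more arbitrary single fall.
#'
#' @param n_falls Integer vector of falls counts; `NA` propagates (such
#'   records are excluded from falls analyses).
#' @return Factor with levels `no_falls`, `one_fall`, `recurrent`.
#' @export
classify_falls <- function(n_falls) {
  bad <- !is.na(n_falls) & (n_falls < 0 | n_falls != trunc(n_falls))
  if (any(bad)) {
    stop("falls counts must be non-negative integers", call. = FALSE)
  }
  out <- ifelse(is.na(n_falls), NA_character_,
                ifelse(n_falls >= 2, "recurrent",
                       ifelse(n_falls == 1, "one_fall", "no_falls")))
  factor(out, levels = c("no_falls", "one_fall", "recurrent"))
}

#' Combine faller status and frailty status into the four study groups
#'
#' A faller is a participant reporting at least one fall in the 12 months
#' before the classifying visit (no carry-forward of earlier falls).
#'
#' @param fall_status Factor from [classify_falls()] (or falls counts).
#' @param frail Logical vector: frail at the classifying visit.
#' @return Factor with levels `faller_frail`, `faller_nonfrail`,
#'   `nonfaller_frail`, `nonfaller_nonfrail`.
#' @export
fall_frailty_group <- function(fall_status, frail) {
  if (!is.factor(fall_status)) fall_status <- classify_falls(fall_status)
  stopifnot(length(fall_status) == length(frail))
  faller <- fall_status %in% c("one_fall", "recurrent")
  out <- ifelse(is.na(fall_status) | is.na(frail), NA_character_,
                ifelse(faller,
                       ifelse(frail, "faller_frail", "faller_nonfrail"),
                       ifelse(frail, "nonfaller_frail", "nonfaller_nonfrail")))
  factor(out, levels = c("faller_frail", "faller_nonfrail",
                         "nonfaller_frail", "nonfaller_nonfrail"))
}

#' Cross-tabulate two variables with row percentages
#'
#' Builds the contingency table of two discrete variables over an analysis
#' slice, reporting counts and row percentages and the number of records
#' excluded for missingness in either variable.
#'
#' @param data A data.frame.
#' @param row_var,col_var Column names of the row and column variables.
#' @return An object of class `contingency_table`: `counts` (matrix),
#'   `row_pct`, `n`, `n_excluded`.
#' @export
cross_tabulate <- function(data, row_var, col_var) {
  stopifnot(is.data.frame(data), row_var %in% names(data),
            col_var %in% names(data))
  r <- data[[row_var]]
  c <- data[[col_var]]
  keep <- !is.na(r) & !is.na(c)
  if (!any(keep)) stop("no complete records to tabulate", call. = FALSE)
  counts <- table(r[keep], c[keep], dnn = c(row_var, col_var))
  counts <- unclass(counts)
  row_tot <- rowSums(counts)
  row_pct <- sweep(counts, 1, ifelse(row_tot == 0, 1, row_tot), "/") * 100
  structure(
    list(counts = counts, row_pct = row_pct, n = sum(counts),
         n_excluded = sum(!keep), row_var = row_var, col_var = col_var),
    class = "contingency_table"
  )
}

#' Build a contingency table directly from a counts matrix
#'
#' Convenience constructor for working with published summary counts.
#'
#' @param counts Numeric matrix of non-negative counts (dimnames kept).
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(counts == trunc(counts)))
  row_tot <- rowSums(counts)
  row_pct <- sweep(counts, 1, ifelse(row_tot == 0, 1, row_tot), "/") * 100
  structure(list(counts = counts, row_pct = row_pct, n = sum(counts),
                 n_excluded = 0L, row_var = NA_character_,
                 col_var = NA_character_),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, digits = 1, ...) {
  cat(sprintf("<contingency_table> n = %d (%d excluded)\n", x$n, x$n_excluded))
  disp <- matrix(sprintf("%d (%.*f)", x$counts, digits, x$row_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Pearson chi-square test of independence for a contingency table
#'
#' @param tab A `contingency_table` (or a counts matrix).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_square <- function(tab) {
  counts <- if (inherits(tab, "contingency_table")) tab$counts else as.matrix(tab)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    stop("zero expected count; merge sparse categories before testing",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` with a 95% CI on the
#' log scale, `log(OR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)` (Woolf). When
#' any cell is zero, 0.5 is added to every cell (Haldane-Anscombe) and the
#' estimate is flagged as corrected.
#'
#' @param a,b Events and non-events among the exposed.
#' @param c,d Events and non-events among the unexposed.
#' @param conf_level Confidence level (default 0.95).
#' @return An `effect_estimate`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value` (Wald), `model = "table_2x2"`, `corrected`.
#' @examples
#' odds_ratio_2x2(72, 149, 62, 631)  # recurrent falls, frail vs non-frail
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("odds ratio undefined: an entire table margin is zero",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(term = "exposure",
         odds_ratio = exp(log_or),
         ci_low = exp(log_or - z * se),
         ci_high = exp(log_or + z * se),
         p_value = 2 * stats::pnorm(-abs(log_or / se)),
         model = "table_2x2", adjusted_for = character(),
         corrected = corrected,
         counts = c(a = a, b = b, c = c, d = d)),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: OR %.2f (%.2f-%.2f), p = %.3g [%s%s]\n",
              x$term, x$odds_ratio, x$ci_low, x$ci_high, x$p_value, x$model,
              if (isTRUE(x$corrected)) ", Haldane-Anscombe corrected" else ""))
  if (length(x$adjusted_for)) {
    cat("  adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Odds ratios from binary logistic regression
#'
#' Fits a maximum-likelihood logistic model of a binary outcome on an
#' exposure plus optional adjustment covariates (complete-case analysis;
#' exclusion counts are recorded). Coefficients are exponentiated to odds
#' ratios with Wald confidence intervals.
#'
#' @param data A data.frame.
#' @param outcome Name of the binary outcome column (logical or 0/1).
#' @param exposure Name of the exposure column (numeric, logical or factor).
#' @param covariates Character vector of adjustment covariate columns
#'   (factors expand to their non-reference levels).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of `effect_estimate` objects, one per fitted term
#'   (exposure first), with attributes `n_used` and `n_excluded`.
#' @export
logistic_or <- function(data, outcome, exposure, covariates = character(),
                        conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[vars]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (sum(y) == 0 || sum(y) == nrow(d)) {
    stop("degenerate outcome: no variation in ", outcome, call. = FALSE)
  }
  for (v in c(exposure, covariates)) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.numeric(d[[v]]) && stats::var(d[[v]]) == 0) {
      stop("zero variance in predictor '", v, "'", call. = FALSE)
    }
  }
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  d[[outcome]] <- y
  n_par <- length(c(exposure, covariates)) + 1L
  if (nrow(d) < 10L * n_par) {
    warning("fewer than 10 complete cases per parameter (n = ", nrow(d), ")",
            call. = FALSE)
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  coefs <- summary(fit)$coefficients
  big <- abs(coefs[-1, "Estimate"]) > 15
  if (!fit$converged || any(big)) {
    culprit <- if (any(big)) rownames(coefs)[-1][big][1] else "model"
    stop("separation or non-convergence detected for '", culprit, "'",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- rownames(coefs)[-1]
  ests <- lapply(terms, function(tm) {
    est <- coefs[tm, "Estimate"]
    se <- coefs[tm, "Std. Error"]
    structure(
      list(term = tm, odds_ratio = exp(est),
           ci_low = exp(est - z * se), ci_high = exp(est + z * se),
           p_value = coefs[tm, "Pr(>|z|)"],
           model = if (length(covariates)) "logistic_adjusted"
                   else "logistic_unadjusted",
           adjusted_for = covariates, corrected = FALSE, counts = NULL),
      class = "effect_estimate"
    )
  })
  names(ests) <- terms
  attr(ests, "n_used") <- nrow(d)
  attr(ests, "n_excluded") <- sum(!keep)
  ests
}

#' Odds ratio per 0.01 increment of the frailty index
#'
#' The index is multiplied by 100 before fitting so the exponentiated
#' coefficient is the odds ratio per 0.01 increase in the index, the scale
#' on which continuous-frailty effects are conventionally reported.
#'
#' @param data A data.frame containing the outcome, index and covariates.
#' @param outcome Name of the binary outcome column.
#' @param index Name of the frailty-index column (on the 0-1 scale).
#' @param covariates Optional adjustment covariates.
#' @param conf_level Confidence level.
#' @return An `effect_estimate` for the per-0.01 index term, with `n_used` /
#'   `n_excluded` attributes carried over.
#' @export
frailty_increment_or <- function(data, outcome, index,
                                 covariates = character(),
                                 conf_level = 0.95) {
  d <- data
  d[[".fi100"]] <- d[[index]] * 100
  ests <- logistic_or(d, outcome, ".fi100", covariates, conf_level)
  out <- ests[[".fi100"]]
  out$term <- paste0(index, " (per 0.01)")
  attr(out, "n_used") <- attr(ests, "n_used")
  attr(out, "n_excluded") <- attr(ests, "n_excluded")
  out
}
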