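# Small in-code fixtures shared across the test files.

# two deficits: one continuous (the published steps-to-walk-30m range), one
# binary disease indicator
tiny_specs <- function() {
  list(
    steps_30m = deficit_spec("steps_30m", "continuous", "higher_is_worse",
                             v_min = 21, v_max = 160),
    diabetes = deficit_spec("diabetes", "binary", "higher_is_worse",
                            cutpoint = 0.5)
  )
}

# a well-formed three-participant cohort over two visits
tiny_cohort <- function() {
  visits <- data.frame(
    participant_id = c("A", "A", "B", "B", "C"),
    visit_age = c(75L, 80L, 75L, 80L, 75L),
    alive = TRUE,
    attended = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    falls_12m = c(0L, 2L, 1L, NA, NA),
    bmi = c(24.1, 24.5, 28.0, NA, 26.2),
    s25ohd = c(60, 65, 55, NA, 70),
    smoking = c("never", "never", "current", "current", "previous"),
    prior_fracture = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    steps_30m = c(40, 60, 90, NA, 54),
    diabetes = c(0, 0, 1, NA, 0),
    stringsAsFactors = FALSE
  )
  falls_cohort(visits, tiny_specs())
}

# a cheap generator configuration for tests that loop over replicates
small_config <- function(n = 400L, seed = 1L, ...) {
  generator_config(n_baseline = n, seed = seed, ...)
}

# a synthetic two-segment mortality curve packaged as a cutoff_scan
make_scan <- function(knee = 0.24, base = 0.30, slope = 1.5,
                      grid_max = 0.6, step = 0.02, noise_sd = 0,
                      n = 1000L) {
  grid <- seq(0, grid_max, by = step)
  mort <- base + slope * pmax(grid - knee, 0) + rnorm(length(grid), 0, noise_sd)
  scan <- data.frame(cutoff = grid, n_at_or_above = n, mortality = mort,
                     stable = TRUE)
  attr(scan, "step") <- step
  attr(scan, "mode") <- "at_or_above"
  attr(scan, "n_deaths") <- 1L
  class(scan) <- c("cutoff_scan", "data.frame")
  scan
}

# independent brute-force Pearson chi-square used as the oracle
bruteforce_chisq <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  list(statistic = stat, df = (nrow(counts) - 1) * (ncol(counts) - 1))
}
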