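#' Scan 10-year mortality over a grid of candidate frailty cutoffs
#'
#' For each candidate cutoff `c` on an ascending grid (default step 0.02),
#' records the 10-year mortality among participants with baseline index at
#' or above `c` (`mode = "at_or_above"`), or the difference in mortality
#' between those at/above and those below (`mode = "difference"`).
#' Candidates supported by fewer than `min_n` participants (on either side,
#' for the difference mode) are marked unstable and excluded from
#' changepoint fitting.
#'
#' @param index Numeric vector of baseline frailty-index values.
#' @param died_within_10y Logical vector, paired with `index`.
#' @param step Grid step (default 0.02).
#' @param grid_max Upper end of the candidate grid; defaults to the largest
#'   grid point not exceeding the maximum observed index.
#' @param min_n Minimum group size for a candidate to be considered stable.
#' @param mode Mortality summary per candidate, see above.
#' @return An object of class `cutoff_scan`: a data.frame with columns
#'   `cutoff`, `n_at_or_above`, `mortality`, `stable`, plus attributes
#'   `step` and `mode`.
#' @export
scan_mortality <- function(index, died_within_10y, step = 0.02,
                           grid_max = NULL, min_n = 10L,
                           mode = c("at_or_above", "difference")) {
  mode <- match.arg(mode)
  stopifnot(length(index) == length(died_within_10y), step > 0)
  ok <- !is.na(index) & !is.na(died_within_10y)
  index <- index[ok]
  died <- as.logical(died_within_10y[ok])
  if (length(index) == 0L) stop("no paired index/vital-status data", call. = FALSE)
  if (is.null(grid_max)) grid_max <- floor(max(index) / step + 1e-9) * step
  grid <- seq(0, grid_max, by = step)
  n_hi <- vapply(grid, function(c) sum(index >= c), integer(1))
  mort_hi <- vapply(grid, function(c) {
    hi <- index >= c
    if (any(hi)) mean(died[hi]) else NA_real_
  }, numeric(1))
  if (mode == "at_or_above") {
    mortality <- mort_hi
    stable <- n_hi >= min_n
  } else {
    n_lo <- length(index) - n_hi
    mort_lo <- vapply(grid, function(c) {
      lo <- index < c
      if (any(lo)) mean(died[lo]) else NA_real_
    }, numeric(1))
    mortality <- mort_hi - mort_lo
    stable <- n_hi >= min_n & n_lo >= min_n
  }
  out <- data.frame(cutoff = grid, n_at_or_above = n_hi,
                    mortality = mortality, stable = stable & !is.na(mortality))
  attr(out, "step") <- step
  attr(out, "mode") <- mode
  attr(out, "n_deaths") <- sum(died)
  class(out) <- c("cutoff_scan", "data.frame")
  out
}

#' Locate the beginning of a steeper slope in a mortality scan
#'
#' Formalises the visual "knee" of the mortality curve as a continuous
#' two-segment piecewise-linear least-squares fit with the breakpoint
#' restricted to the stable candidate grid: for each admissible breakpoint a
#' hinge regression `mortality ~ cutoff + max(cutoff - b, 0)` is fitted and
#' the breakpoint minimising the residual sum of squares is returned (ties
#' go to the smaller cutoff). The changepoint is only reported as distinct
#' when the upper slope exceeds the lower one clearly: by a factor of at
#' least `min_slope_ratio` when the lower slope is positive, or by at least
#' `min_slope_diff` (per unit of index) otherwise.
#'
#' @param scan A `cutoff_scan` from [scan_mortality()].
#' @param min_slope_ratio Minimum upper/lower slope ratio (default 2).
#' @param min_slope_diff Minimum absolute slope increase when the lower
#'   slope is zero or negative (default 0.1 mortality per unit index).
#' @param weighted When `TRUE`, candidates are weighted by the number of
#'   participants supporting each mortality proportion, which is appropriate
#'   for scans of real cohorts where group sizes shrink rapidly at high
#'   cutoffs. The default (unweighted) treats all stable candidates equally.
#' @return An object of class `slope_change`: `cutoff` (NA when no distinct
#'   changepoint), `distinct`, `slope_lower`, `slope_upper`, `rss`, and the
#'   per-candidate RSS profile.
#' @export
detect_slope_change <- function(scan, min_slope_ratio = 2,
                                min_slope_diff = 0.1, weighted = FALSE) {
  stopifnot(inherits(scan, "cutoff_scan"))
  pts <- scan[scan$stable, , drop = FALSE]
  if (nrow(pts) < 6L) {
    stop("detect_slope_change requires at least 6 stable candidates",
         call. = FALSE)
  }
  if (attr(scan, "n_deaths") == 0L) {
    stop("no deaths observed; changepoint undefined", call. = FALSE)
  }
  x <- pts$cutoff
  y <- pts$mortality
  w <- if (weighted) pts$n_at_or_above else rep(1, nrow(pts))
  m <- length(x)
  # breakpoint must leave at least 2 points strictly on each side
  cand_idx <- 3:(m - 2)
  profile <- data.frame(breakpoint = x[cand_idx], rss = NA_real_,
                        slope_lower = NA_real_, slope_upper = NA_real_)
  for (k in seq_along(cand_idx)) {
    b <- x[cand_idx[k]]
    hinge <- pmax(x - b, 0)
    fit <- stats::lm.wfit(cbind(1, x, hinge), y, w)
    profile$rss[k] <- sum(w * fit$residuals^2)
    profile$slope_lower[k] <- fit$coefficients[2]
    profile$slope_upper[k] <- fit$coefficients[2] + fit$coefficients[3]
  }
  # ties (numerically equal RSS) break toward the smaller cutoff
  best <- which(profile$rss <= min(profile$rss) + 1e-12)[1]
  s1 <- profile$slope_lower[best]
  s2 <- profile$slope_upper[best]
  distinct <- if (s1 > 0) s2 >= min_slope_ratio * s1 else s2 - s1 >= min_slope_diff
  structure(
    list(cutoff = if (distinct) profile$breakpoint[best] else NA_real_,
         distinct = distinct,
         breakpoint = profile$breakpoint[best],
         slope_lower = s1, slope_upper = s2,
         rss = profile$rss[best], profile = profile),
    class = "slope_change"
  )
}

#' @export
print.slope_change <- function(x, ...) {
  if (x$distinct) {
    cat(sprintf("<slope_change> changepoint at %.3f (slopes %.3f -> %.3f)\n",
                x$cutoff, x$slope_lower, x$slope_upper))
  } else {
    cat(sprintf(
      "<slope_change> no distinct changepoint (best candidate %.3f, slopes %.3f -> %.3f)\n",
      x$breakpoint, x$slope_lower, x$slope_upper))
  }
  invisible(x)
}
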