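#' Reference summary counts from the OPRA cohort
#'
#' Published summary tables of the motivating cohort (the OPRA study of 1044
#' community-dwelling women aged 75 at baseline), shipped as plain-text
#' counts. Person-level OPRA data are not deposited; these aggregate counts
#' are the level at which the pipeline's cross-tabulation and odds-ratio
#' arithmetic can be validated.
#'
#' Available tables:
#' \describe{
#'   \item{`baseline_falls`}{Baseline falls in the previous 12 months (no
#'     falls / one fall / recurrent) among the 914 women with valid falls
#'     data, split by baseline frailty status, plus the full baseline group
#'     sizes (799 non-frail, 245 frail).}
#'   \item{`quintile_falls`}{Frailty-quintile by falls-count tables for four
#'     visit pairings (baseline and the 5- and 10-year follow-ups).}
#'   \item{`group_falls`}{Combined fall-frailty groups at one visit and
#'     falls outcomes (at least one fall, recurrent falls) at the following
#'     visits: event counts, percentages and total analysed n.}
#' }
#'
#' @param table One of `"baseline_falls"`, `"quintile_falls"`,
#'   `"group_falls"`.
#' @return A data.frame of counts.
#' @export
reference_counts <- function(table = c("baseline_falls", "quintile_falls",
                                       "group_falls")) {
  table <- match.arg(table)
  path <- system.file("extdata",
                      paste0("reference_", table, ".csv"),
                      package = "frailtyfalls")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
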