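# Packaged concordance tables. The development tables carry the full
# 3x3 category cross-tabulation; the validation cohort is available only
# as dichotomized screening counts, so its tables are built with
# dichotomous_concordance().

#' Packaged concordance tables
#'
#' Cross-tabulations of quantitative versus semi-quantitative uACR
#' category used throughout the package:
#' \describe{
#'   \item{development_all_table()}{all diabetic patients in the
#'     development cohort (n = 1881).}
#'   \item{development_subgroup_table()}{development patients with eGFR
#'     >= 60 ml/min/1.73m2 and a negative dipstick (n = 1110) — the
#'     subgroup whose proportions parameterize the baseline cost model.}
#'   \item{validation_overall_table()}{external validation cohort
#'     (n = 431), dichotomized counts.}
#'   \item{validation_subgroup_table()}{validation patients with eGFR >=
#'     60 and negative dipstick (n = 301), dichotomized counts.}
#' }
#'
#' @return A [concordance_table()].
#' @name packaged_tables
NULL

#' @rdname packaged_tables
#' @export
development_all_table <- function() {
  concordance_table(matrix(c(664, 408, 9,
                             52, 350, 78,
                             0, 17, 303), nrow = 3, byrow = TRUE),
                    label = "development, all diabetes")
}

#' @rdname packaged_tables
#' @export
development_subgroup_table <- function() {
  concordance_table(matrix(c(579, 333, 5,
                             36, 142, 8,
                             0, 2, 5), nrow = 3, byrow = TRUE),
                    label = "development, eGFR >= 60 & dipstick negative")
}

#' @rdname packaged_tables
#' @export
validation_overall_table <- function() {
  dichotomous_concordance(tp = 93, fn = 18, fp = 106, tn = 214,
                          label = "validation, all diabetes")
}

#' @rdname packaged_tables
#' @export
validation_subgroup_table <- function() {
  dichotomous_concordance(tp = 38, fn = 8, fp = 68, tn = 187,
                          label = "validation, eGFR >= 60 & dipstick negative")
}
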