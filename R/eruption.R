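#' Reference eruption ages for the permanent dentition
#'
#' Median eruption ages (years) per tooth position and arch, compiled from
#' standard pediatric-dentistry reference tables (Lunt & Law-style values).
#' This is reference data shipped with the package, not study data; it is
#' consulted only by the synthetic cohort generator's age bounds and by the
#' advisory helper [flag_unexpected_eruption()] — never by the scorer,
#' where age-appropriate eruption remains a rater judgment.
#'
#' @param path optional path to a user-supplied replacement table with the
#'   same columns (`position`, `tooth`, `maxillary_eruption_years`,
#'   `mandibular_eruption_years`).
#' @return A data frame with one row per tooth position 1..7.
#' @export
eruption_age_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eruption_ages_reference.csv",
                        package = "dentale")
  }
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "tooth", "maxillary_eruption_years",
            "mandibular_eruption_years")
  if (!all(need %in% names(ref)) || !identical(sort(ref$position), 1:7)) {
    stop("eruption reference table must cover positions 1..7 with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ref
}

#' Advisory check of eruption flags against reference ages
#'
#' Lists teeth whose recorded eruption flag looks surprising given the
#' survivor's age and the reference table: a tooth flagged as not
#' age-appropriately erupted although the survivor is well past (by
#' `slack_years`) its reference eruption age is expected; the advisory
#' flags the opposite case — an eruption finding on a tooth whose reference
#' age the survivor has not yet reached, where delayed eruption may simply
#' be normal development. Advisory only; never affects the score.
#'
#' @param a a `dentale_assessment`.
#' @param reference a reference table from [eruption_age_reference()].
#' @param slack_years tolerance around the reference age.
#' @return Data frame of advisory rows (`fdi`, `reference_age`, `note`);
#'   zero rows when nothing looks surprising.
#' @export
flag_unexpected_eruption <- function(a,
                                     reference = eruption_age_reference(),
                                     slack_years = 1.5) {
  stopifnot(inherits(a, "dentale_assessment"))
  chart <- tooth_chart()
  ref_age <- ifelse(chart$quadrant %in% 1:2,
                    reference$maxillary_eruption_years[chart$position],
                    reference$mandibular_eruption_years[chart$position])
  teeth <- a$teeth[match(chart$fdi, a$teeth$fdi), ]
  flagged <- teeth$eruption_not_age_appropriate &
    a$age_at_opg_years < ref_age - slack_years
  if (!any(flagged, na.rm = TRUE)) {
    return(data.frame(fdi = integer(0), reference_age = numeric(0),
                      note = character(0)))
  }
  data.frame(
    fdi = chart$fdi[which(flagged)],
    reference_age = ref_age[which(flagged)],
    note = paste0("eruption flagged but survivor age ", a$age_at_opg_years,
                  " y is below the reference eruption age"),
    stringsAsFactors = FALSE
  )
}
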