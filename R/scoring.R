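#' Score a DENTALE assessment
#'
#' Computes the itemized score breakdown, the localized-pathology sextant
#' adjustment, and the referral decision.
#'
#' Item contributions: a missing tooth scores its presence weight; a
#' present tooth scores `aspect_point` per abnormal aspect (crown, root,
#' crown-root ratio >= 1:1, eruption not age-appropriate) — never both.
#' Reduced alveolar bone and tooth wear each score per sextant; condyles
#' score `condyle_point` per abnormal side and rami `ramus_point`. Teeth
#' with an `exclusion_note` (e.g. orthodontic extraction) contribute
#' nothing and are left out of sextant totals.
#'
#' A sextant's total for the adjustment rule is the presence points of its
#' missing teeth plus the aspect points of its present teeth plus its
#' alveolar and wear points; condyle and ramus points belong to no sextant.
#' If any sextant total strictly exceeds `sextant_adjustment_threshold`
#' (default 10), `sextant_adjustment_bonus` (default 5) is added once to
#' the base total. Referral is flagged when the final total reaches
#' `referral_threshold` (default 16, inclusive).
#'
#' @param a a `dentale_assessment`; must pass [validate_assessment()].
#' @param weights a `dentale_weights` configuration.
#' @return An object of class `dentale_score`: a list with
#'   `presence_points`, `aspect_points`, `alveolar_points`, `wear_points`,
#'   `condyle_points`, `ramus_points`, `per_sextant_totals` (named, 1..6),
#'   `base_total`, `adjustment_points`, `final_total`, `refer`, plus the
#'   subject and rater ids.
#' @examples
#' a <- new_assessment("S01")
#' a <- set_tooth(a, c(13, 11), status = "missing") # 8 + 6 = 14 in sextant 2
#' s <- score_assessment(a)
#' s$final_total # 19 (14 base + 5 adjustment), refer TRUE
#' @export
score_assessment <- function(a, weights = default_weights()) {
  validate_weights(weights)
  v <- validate_assessment(a)
  if (length(v)) {
    stop("invalid assessment:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  teeth <- a$teeth
  ord <- match(fdi_codes(), teeth$fdi)
  teeth <- teeth[ord, , drop = FALSE]
  chart <- tooth_chart()
  excluded <- !is.na(teeth$exclusion_note) & nzchar(teeth$exclusion_note)
  missing <- teeth$status == "missing" & !excluded
  present <- teeth$status == "present" & !excluded

  presence_per_tooth <- ifelse(missing,
                               unname(weights$presence_weights[chart$class]),
                               0)
  n_aspects <- rowSums(teeth[aspect_cols()])
  aspect_per_tooth <- ifelse(present, n_aspects * weights$aspect_point, 0)

  sx <- a$sextants[match(1:6, a$sextants$sextant), , drop = FALSE]
  alveolar_per_sext <- sx$alveolar_reduced * weights$alveolar_point
  wear_per_sext <- sx$tooth_wear * weights$wear_point

  tooth_pts_by_sext <- as.numeric(tapply(presence_per_tooth + aspect_per_tooth,
                                         factor(chart$sextant, levels = 1:6),
                                         sum))
  per_sextant <- tooth_pts_by_sext + alveolar_per_sext + wear_per_sext
  names(per_sextant) <- paste0("s", 1:6)

  condyle_points <- weights$condyle_point *
    sum(a$bony[c("condyle_left_abnormal", "condyle_right_abnormal")])
  ramus_points <- weights$ramus_point *
    sum(a$bony[c("ramus_left_abnormal", "ramus_right_abnormal")])

  base_total <- sum(presence_per_tooth) + sum(aspect_per_tooth) +
    sum(alveolar_per_sext) + sum(wear_per_sext) +
    condyle_points + ramus_points

  n_over <- sum(per_sextant > weights$sextant_adjustment_threshold)
  adjustment <- if (weights$adjustment_per_sextant) {
    weights$sextant_adjustment_bonus * n_over
  } else {
    weights$sextant_adjustment_bonus * (n_over > 0)
  }
  final_total <- base_total + adjustment

  out <- list(
    subject_id = a$subject_id,
    rater_id = a$rater_id,
    presence_points = sum(presence_per_tooth),
    aspect_points = sum(aspect_per_tooth),
    alveolar_points = sum(alveolar_per_sext),
    wear_points = sum(wear_per_sext),
    condyle_points = condyle_points,
    ramus_points = ramus_points,
    per_sextant_totals = per_sextant,
    base_total = base_total,
    adjustment_points = adjustment,
    final_total = final_total,
    refer = referral_decision(final_total, weights)
  )
  class(out) <- "dentale_score"
  out
}

#' Referral decision for a DENTALE total
#'
#' Inclusive comparison: a survivor is flagged for specialized dental care
#' when the final total is at or above the referral threshold (default 16).
#'
#' @param total final DENTALE total(s), non-negative.
#' @param weights a `dentale_weights` configuration.
#' @return Logical vector.
#' @export
referral_decision <- function(total, weights = default_weights()) {
  stopifnot(all(is.finite(total)), all(total >= 0))
  total >= weights$referral_threshold
}

#' Score a cohort of assessments
#'
#' Vectorized wrapper over [score_assessment()], one row per assessment in
#' input order.
#'
#' @param assessments list of `dentale_assessment` objects.
#' @param weights a `dentale_weights` configuration.
#' @return A data frame with columns `subject_id`, `rater_id`,
#'   `base_total`, `adjustment_points`, `final_total`, `refer`.
#' @export
score_cohort <- function(assessments, weights = default_weights()) {
  empty <- data.frame(subject_id = character(0), rater_id = character(0),
                      base_total = numeric(0), adjustment_points = numeric(0),
                      final_total = numeric(0), refer = logical(0),
                      stringsAsFactors = FALSE)
  if (length(assessments) == 0L) return(empty)
  rows <- lapply(seq_along(assessments), function(i) {
    s <- tryCatch(score_assessment(assessments[[i]], weights),
                  error = function(e) {
                    stop("assessment ", i, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
    data.frame(subject_id = s$subject_id, rater_id = s$rater_id,
               base_total = s$base_total,
               adjustment_points = s$adjustment_points,
               final_total = s$final_total, refer = s$refer,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.dentale_score <- function(x, ...) {
  cat("DENTALE score for subject ", x$subject_id, " (rater ", x$rater_id,
      ")\n", sep = "")
  cat("  presence ", x$presence_points, " + aspects ", x$aspect_points,
      " + alveolar ", x$alveolar_points, " + wear ", x$wear_points,
      " + condyle ", x$condyle_points, " + ramus ", x$ramus_points,
      " = base ", x$base_total, "\n", sep = "")
  cat("  per-sextant:", paste(names(x$per_sextant_totals),
                              x$per_sextant_totals, sep = "=",
                              collapse = " "), "\n")
  cat("  adjustment +", x$adjustment_points, " -> final ", x$final_total,
      "; refer: ", if (x$refer) "YES" else "no", "\n", sep = "")
  invisible(x)
}
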