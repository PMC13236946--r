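#' Construct a DENTALE assessment
#'
#' One rater's complete radiographic reading of one survivor's
#' orthopantomogram: per-tooth findings for the 28 permanent teeth
#' (third molars excluded), per-sextant findings, bilateral condyle and
#' ramus findings, and the survivor's age at the radiograph. The default
#' is an all-normal reading (score 0); use [set_tooth()], [set_sextant()]
#' and [set_bony()] to record findings.
#'
#' Tooth status is `"present"` or `"missing"`; a missing tooth's four
#' aspect flags must be `FALSE` (aspects are unscorable on an absent
#' tooth). A non-empty `exclusion_note` (e.g. "orthodontic extraction")
#' removes the tooth from scoring entirely: such losses are not late
#' effects of treatment.
#'
#' @param subject_id,rater_id identifier strings.
#' @param age_at_opg_years survivor age when the radiograph was taken.
#' @param teeth data frame with columns `fdi`, `status`, `crown_abnormal`,
#'   `root_abnormal`, `crown_root_ratio_abnormal`,
#'   `eruption_not_age_appropriate`, `exclusion_note`; one row per tooth.
#'   Defaults to all teeth present and normal.
#' @param sextants data frame with columns `sextant` (1..6),
#'   `alveolar_reduced`, `tooth_wear`. Defaults to all normal.
#' @param bony named logical vector with elements `condyle_left_abnormal`,
#'   `condyle_right_abnormal`, `ramus_left_abnormal`,
#'   `ramus_right_abnormal`.
#' @return An object of class `dentale_assessment`.
#' @examples
#' a <- new_assessment("S01", "R1", age_at_opg_years = 12)
#' a <- set_tooth(a, 13, status = "missing")
#' score_assessment(a)$base_total # 8
#' @export
new_assessment <- function(subject_id,
                           rater_id = "R1",
                           age_at_opg_years = 12,
                           teeth = NULL,
                           sextants = NULL,
                           bony = NULL) {
  if (is.null(teeth)) {
    teeth <- data.frame(
      fdi = fdi_codes(),
      status = "present",
      crown_abnormal = FALSE,
      root_abnormal = FALSE,
      crown_root_ratio_abnormal = FALSE,
      eruption_not_age_appropriate = FALSE,
      exclusion_note = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(sextants)) {
    sextants <- data.frame(sextant = 1:6,
                           alveolar_reduced = FALSE,
                           tooth_wear = FALSE)
  }
  if (is.null(bony)) {
    bony <- c(condyle_left_abnormal = FALSE, condyle_right_abnormal = FALSE,
              ramus_left_abnormal = FALSE, ramus_right_abnormal = FALSE)
  }
  a <- list(subject_id = as.character(subject_id),
            rater_id = as.character(rater_id),
            age_at_opg_years = as.numeric(age_at_opg_years),
            teeth = teeth, sextants = sextants, bony = bony)
  class(a) <- "dentale_assessment"
  a
}

aspect_cols <- function() {
  c("crown_abnormal", "root_abnormal", "crown_root_ratio_abnormal",
    "eruption_not_age_appropriate")
}

#' Record findings on one or more teeth
#'
#' Setting `status = "missing"` clears the aspect flags automatically,
#' since aspects cannot be read on an absent tooth; if the update leaves a
#' sextant with no present tooth, that sextant's wear flag is cleared too
#' (wear is unscorable there).
#'
#' @param a a `dentale_assessment`.
#' @param fdi FDI code(s) of the teeth to update.
#' @param status,crown_abnormal,root_abnormal,crown_root_ratio_abnormal,eruption_not_age_appropriate,exclusion_note
#'   fields to set; omitted fields are left unchanged.
#' @return The updated assessment.
#' @export
set_tooth <- function(a, fdi, status = NULL, crown_abnormal = NULL,
                      root_abnormal = NULL,
                      crown_root_ratio_abnormal = NULL,
                      eruption_not_age_appropriate = NULL,
                      exclusion_note = NULL) {
  stopifnot(inherits(a, "dentale_assessment"))
  fdi <- check_fdi(fdi)
  i <- match(fdi, a$teeth$fdi)
  if (anyNA(i)) stop("tooth not in assessment: ",
                     paste(fdi[is.na(i)], collapse = ", "), call. = FALSE)
  if (!is.null(status)) a$teeth$status[i] <- status
  for (col in aspect_cols()) {
    val <- get(col)
    if (!is.null(val)) a$teeth[[col]][i] <- val
  }
  if (!is.null(exclusion_note)) a$teeth$exclusion_note[i] <- exclusion_note
  miss <- i[a$teeth$status[i] == "missing"]
  if (length(miss)) a$teeth[miss, aspect_cols()] <- FALSE
  # wear cannot stand in a sextant left without any present tooth
  tooth_sext <- sextant_of(a$teeth$fdi)
  for (s in unique(tooth_sext[i])) {
    if (!any(a$teeth$status[tooth_sext == s] == "present")) {
      a$sextants$tooth_wear[a$sextants$sextant == s] <- FALSE
    }
  }
  a
}

#' Record findings on one or more sextants
#' @param a a `dentale_assessment`.
#' @param sextant sextant id(s) in 1..6.
#' @param alveolar_reduced,tooth_wear flags to set; omitted fields are left
#'   unchanged. Tooth wear is only applicable while at least one tooth in
#'   the sextant is present ([validate_assessment()] enforces this).
#' @return The updated assessment.
#' @export
set_sextant <- function(a, sextant, alveolar_reduced = NULL,
                        tooth_wear = NULL) {
  stopifnot(inherits(a, "dentale_assessment"), all(sextant %in% 1:6))
  i <- match(sextant, a$sextants$sextant)
  if (!is.null(alveolar_reduced)) a$sextants$alveolar_reduced[i] <- alveolar_reduced
  if (!is.null(tooth_wear)) a$sextants$tooth_wear[i] <- tooth_wear
  a
}

#' Record condyle / ramus findings
#' @param a a `dentale_assessment`.
#' @param condyle_left_abnormal,condyle_right_abnormal,ramus_left_abnormal,ramus_right_abnormal
#'   flags to set; omitted fields are left unchanged.
#' @return The updated assessment.
#' @export
set_bony <- function(a, condyle_left_abnormal = NULL,
                     condyle_right_abnormal = NULL,
                     ramus_left_abnormal = NULL,
                     ramus_right_abnormal = NULL) {
  stopifnot(inherits(a, "dentale_assessment"))
  for (nm in names(a$bony)) {
    val <- get(nm)
    if (!is.null(val)) a$bony[[nm]] <- val
  }
  a
}

#' Validate a DENTALE assessment
#'
#' Checks every structural invariant of the form: a complete,
#' duplicate-free 28-tooth chart in FDI notation with third molars
#' rejected, valid status values, logical aspect flags that are `FALSE` on
#' missing teeth, exactly six sextant records, tooth wear only in sextants
#' with at least one present tooth, four named bony flags, and a
#' non-negative age.
#'
#' @param a a `dentale_assessment`.
#' @return A character vector of violation messages; `character(0)` when
#'   the assessment is valid. Violations are returned, not raised.
#' @export
validate_assessment <- function(a) {
  v <- character(0)
  if (!inherits(a, "dentale_assessment")) {
    return("not a dentale_assessment object")
  }
  if (!is.finite(a$age_at_opg_years) || a$age_at_opg_years < 0) {
    v <- c(v, "age_at_opg_years: must be a non-negative number")
  }
  teeth <- a$teeth
  need <- c("fdi", "status", aspect_cols(), "exclusion_note")
  if (!all(need %in% names(teeth))) {
    return(c(v, paste("teeth: missing column(s)",
                      paste(setdiff(need, names(teeth)), collapse = ", "))))
  }
  third <- teeth$fdi %% 10L == 8L
  if (any(third)) {
    v <- c(v, paste0("teeth: code(s) ",
                     paste(teeth$fdi[third], collapse = ", "),
                     " are third molars, excluded from DENTALE"))
  }
  unknown <- !teeth$fdi %in% fdi_codes() & !third
  if (any(unknown)) {
    v <- c(v, paste0("teeth: unknown FDI code(s) ",
                     paste(teeth$fdi[unknown], collapse = ", ")))
  }
  if (anyDuplicated(teeth$fdi)) {
    v <- c(v, paste0("teeth: duplicate FDI code(s) ",
                     paste(unique(teeth$fdi[duplicated(teeth$fdi)]),
                           collapse = ", ")))
  }
  absent <- setdiff(fdi_codes(), teeth$fdi)
  if (length(absent)) {
    v <- c(v, paste0("teeth: incomplete chart, missing code(s) ",
                     paste(absent, collapse = ", ")))
  }
  if (!all(teeth$status %in% c("present", "missing"))) {
    v <- c(v, "teeth: status must be 'present' or 'missing'")
  }
  for (col in aspect_cols()) {
    if (!is.logical(teeth[[col]]) || anyNA(teeth[[col]])) {
      v <- c(v, paste0("teeth: ", col, " must be TRUE/FALSE without NA"))
    }
  }
  miss <- teeth$status == "missing"
  if (any(miss)) {
    flagged <- miss & Reduce(`|`, teeth[aspect_cols()])
    if (any(flagged, na.rm = TRUE)) {
      v <- c(v, paste0("teeth: aspect flag(s) set on missing tooth/teeth ",
                       paste(teeth$fdi[which(flagged)], collapse = ", "),
                       " (aspects are unscorable on an absent tooth)"))
    }
  }
  sx <- a$sextants
  if (!identical(sort(sx$sextant), 1:6) && !identical(sort(sx$sextant), as.numeric(1:6))) {
    v <- c(v, "sextants: must contain exactly sextants 1..6")
  } else if (all(teeth$fdi %in% fdi_codes()) && !anyDuplicated(teeth$fdi) &&
             length(absent) == 0L) {
    tooth_sext <- sextant_of(teeth$fdi)
    for (s in 1:6) {
      any_present <- any(teeth$status[tooth_sext == s] == "present")
      wear <- sx$tooth_wear[match(s, sx$sextant)]
      if (isTRUE(wear) && !any_present) {
        v <- c(v, paste0("sextants: tooth_wear flagged in sextant ", s,
                         " but all its teeth are missing ",
                         "(tooth wear scoring is inapplicable)"))
      }
    }
  }
  for (col in c("alveolar_reduced", "tooth_wear")) {
    if (!is.logical(sx[[col]]) || anyNA(sx[[col]])) {
      v <- c(v, paste0("sextants: ", col, " must be TRUE/FALSE without NA"))
    }
  }
  bony_names <- c("condyle_left_abnormal", "condyle_right_abnormal",
                  "ramus_left_abnormal", "ramus_right_abnormal")
  if (!all(bony_names %in% names(a$bony)) ||
      !is.logical(a$bony[bony_names]) || anyNA(a$bony[bony_names])) {
    v <- c(v, "bony: needs logical condyle_left/right and ramus_left/right flags")
  }
  v
}

#' @export
print.dentale_assessment <- function(x, ...) {
  nmiss <- sum(x$teeth$status == "missing")
  nflag <- sum(unlist(x$teeth[aspect_cols()]))
  cat("DENTALE assessment: subject ", x$subject_id, ", rater ", x$rater_id,
      ", age ", x$age_at_opg_years, " y\n", sep = "")
  cat("  teeth: ", nmiss, " missing, ", nflag, " aspect finding(s)\n", sep = "")
  cat("  sextants: ", sum(x$sextants$alveolar_reduced), " alveolar, ",
      sum(x$sextants$tooth_wear), " wear\n", sep = "")
  cat("  bony: ", sum(x$bony), " of 4 flags abnormal\n", sep = "")
  invisible(x)
}
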