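#' Read and write DENTALE assessment files
#'
#' JSON is the canonical interchange format: an array of records, one per
#' subject-rater pair, each with `subject_id`, `rater_id`,
#' `age_at_opg_years`, a `teeth` array of 28 objects (`fdi`, `status`,
#' `crown_abnormal`, `root_abnormal`, `crown_root_ratio_abnormal`,
#' `eruption_not_age_appropriate`, optional `exclusion_note`), a
#' `sextants` array of 6 objects (`sextant`, `alveolar_reduced`,
#' `tooth_wear`) and a `bony` object with the four condyle/ramus flags.
#'
#' The CSV dialect is a lossy-free flattening with a fixed column order:
#' `subject_id`, `rater_id`, `age_at_opg_years`, then for each tooth in
#' canonical FDI order the columns `t<fdi>_status` (`present`/`missing`),
#' `t<fdi>_crown`, `t<fdi>_root`, `t<fdi>_ratio`, `t<fdi>_eruption` (0/1)
#' and `t<fdi>_note`, then `s<1..6>_alveolar`, `s<1..6>_wear` (0/1), then
#' `condyle_L`, `condyle_R`, `ramus_L`, `ramus_R` (0/1). Columns for third
#' molars (e.g. `t18_status`) are rejected by name.
#'
#' Every record must pass [validate_assessment()]; otherwise the read
#' aborts listing all violations with their record indices. Duplicate
#' subject-rater pairs are rejected.
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; the default guesses from the file
#'   extension.
#' @return `read_assessments()` returns a list of `dentale_assessment`
#'   objects; `write_assessments()` returns `path` invisibly.
#' @export
read_assessments <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  if (file.size(path) == 0L) {
    stop("empty assessment file: ", path, call. = FALSE)
  }
  assessments <- if (format == "json") read_assessments_json(path)
                 else read_assessments_csv(path)
  if (length(assessments) == 0L) {
    stop("no assessment records in ", path, call. = FALSE)
  }
  keys <- vapply(assessments,
                 function(a) paste(a$subject_id, a$rater_id, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1]
    stop("duplicate subject-rater pair: ",
         gsub("\r", " / ", dup, fixed = TRUE), call. = FALSE)
  }
  problems <- character(0)
  for (i in seq_along(assessments)) {
    v <- validate_assessment(assessments[[i]])
    if (length(v)) {
      problems <- c(problems, paste0("record ", i, ": ", v))
    }
  }
  if (length(problems)) {
    stop("invalid assessment record(s):\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  assessments
}

read_assessments_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    need <- c("subject_id", "rater_id", "age_at_opg_years", "teeth",
              "sextants", "bony")
    if (!all(need %in% names(r))) {
      stop("record ", i, ": missing field(s) ",
           paste(setdiff(need, names(r)), collapse = ", "), call. = FALSE)
    }
    teeth <- do.call(rbind, lapply(r$teeth, function(t) {
      data.frame(
        fdi = as.integer(t$fdi),
        status = as.character(t$status),
        crown_abnormal = isTRUE(t$crown_abnormal),
        root_abnormal = isTRUE(t$root_abnormal),
        crown_root_ratio_abnormal = isTRUE(t$crown_root_ratio_abnormal),
        eruption_not_age_appropriate = isTRUE(t$eruption_not_age_appropriate),
        exclusion_note = if (is.null(t$exclusion_note)) NA_character_
                         else as.character(t$exclusion_note),
        stringsAsFactors = FALSE)
    }))
    sextants <- do.call(rbind, lapply(r$sextants, function(s) {
      data.frame(sextant = as.integer(s$sextant),
                 alveolar_reduced = isTRUE(s$alveolar_reduced),
                 tooth_wear = isTRUE(s$tooth_wear))
    }))
    bony <- c(condyle_left_abnormal = isTRUE(r$bony$condyle_left_abnormal),
              condyle_right_abnormal = isTRUE(r$bony$condyle_right_abnormal),
              ramus_left_abnormal = isTRUE(r$bony$ramus_left_abnormal),
              ramus_right_abnormal = isTRUE(r$bony$ramus_right_abnormal))
    new_assessment(r$subject_id, r$rater_id, r$age_at_opg_years,
                   teeth = teeth, sextants = sextants, bony = bony)
  })
}

csv_columns <- function() {
  tooth_cols <- as.vector(t(outer(fdi_codes(),
                                  c("status", "crown", "root", "ratio",
                                    "eruption", "note"),
                                  function(f, s) paste0("t", f, "_", s))))
  c("subject_id", "rater_id", "age_at_opg_years", tooth_cols,
    paste0("s", rep(1:6, each = 2), "_", c("alveolar", "wear")),
    "condyle_L", "condyle_R", "ramus_L", "ramus_R")
}

read_assessments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  third <- grepl("^t[1-4]8_", names(df))
  if (any(third)) {
    stop("column(s) ", paste(names(df)[third], collapse = ", "),
         " refer to third molars, which are excluded from DENTALE",
         call. = FALSE)
  }
  expected <- csv_columns()
  if (!identical(names(df), expected)) {
    extra <- setdiff(names(df), expected)
    missing <- setdiff(expected, names(df))
    stop("CSV columns do not match the fixed schema",
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5),
                                           collapse = ", "),
                                     if (length(missing) > 5) " ..."),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    getv <- function(cols) unlist(row[cols], use.names = FALSE)
    as01 <- function(cols) getv(cols) %in% c("1", "TRUE", "true")
    teeth <- data.frame(
      fdi = fdi_codes(),
      status = getv(paste0("t", fdi_codes(), "_status")),
      crown_abnormal = as01(paste0("t", fdi_codes(), "_crown")),
      root_abnormal = as01(paste0("t", fdi_codes(), "_root")),
      crown_root_ratio_abnormal = as01(paste0("t", fdi_codes(), "_ratio")),
      eruption_not_age_appropriate =
        as01(paste0("t", fdi_codes(), "_eruption")),
      exclusion_note = {
        notes <- getv(paste0("t", fdi_codes(), "_note"))
        ifelse(!is.na(notes) & nzchar(notes), notes, NA_character_)
      },
      stringsAsFactors = FALSE)
    sextants <- data.frame(
      sextant = 1:6,
      alveolar_reduced = as01(paste0("s", 1:6, "_alveolar")),
      tooth_wear = as01(paste0("s", 1:6, "_wear")))
    bony <- c(condyle_left_abnormal = as01("condyle_L"),
              condyle_right_abnormal = as01("condyle_R"),
              ramus_left_abnormal = as01("ramus_L"),
              ramus_right_abnormal = as01("ramus_R"))
    new_assessment(row[["subject_id"]], row[["rater_id"]],
                   as.numeric(row[["age_at_opg_years"]]),
                   teeth = teeth, sextants = sextants, bony = bony)
  })
}

#' @rdname read_assessments
#' @param assessments list of `dentale_assessment` objects.
#' @export
write_assessments <- function(assessments, path,
                              format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  stopifnot(length(assessments) >= 1L)
  for (a in assessments) {
    v <- validate_assessment(a)
    if (length(v)) stop("refusing to write invalid assessment (subject ",
                        a$subject_id, "): ", v[1], call. = FALSE)
  }
  if (format == "json") {
    recs <- lapply(assessments, function(a) {
      teeth <- lapply(seq_len(nrow(a$teeth)), function(j) {
        t <- a$teeth[j, ]
        rec <- list(fdi = t$fdi, status = t$status,
                    crown_abnormal = t$crown_abnormal,
                    root_abnormal = t$root_abnormal,
                    crown_root_ratio_abnormal = t$crown_root_ratio_abnormal,
                    eruption_not_age_appropriate =
                      t$eruption_not_age_appropriate)
        if (!is.na(t$exclusion_note)) rec$exclusion_note <- t$exclusion_note
        rec
      })
      sextants <- lapply(seq_len(nrow(a$sextants)), function(j) {
        s <- a$sextants[j, ]
        list(sextant = s$sextant, alveolar_reduced = s$alveolar_reduced,
             tooth_wear = s$tooth_wear)
      })
      list(subject_id = a$subject_id, rater_id = a$rater_id,
           age_at_opg_years = a$age_at_opg_years,
           teeth = teeth, sextants = sextants,
           bony = as.list(a$bony))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    rows <- lapply(assessments, function(a) {
      teeth <- a$teeth[match(fdi_codes(), a$teeth$fdi), ]
      vals <- c(a$subject_id, a$rater_id,
                format(a$age_at_opg_years, trim = TRUE),
                as.vector(t(cbind(
                  teeth$status,
                  as.integer(teeth$crown_abnormal),
                  as.integer(teeth$root_abnormal),
                  as.integer(teeth$crown_root_ratio_abnormal),
                  as.integer(teeth$eruption_not_age_appropriate),
                  ifelse(is.na(teeth$exclusion_note), "",
                         teeth$exclusion_note)))),
                as.vector(t(cbind(
                  as.integer(a$sextants$alveolar_reduced[match(1:6, a$sextants$sextant)]),
                  as.integer(a$sextants$tooth_wear[match(1:6, a$sextants$sextant)])))),
                as.integer(a$bony[c("condyle_left_abnormal",
                                    "condyle_right_abnormal",
                                    "ramus_left_abnormal",
                                    "ramus_right_abnormal")]))
      vals
    })
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- csv_columns()
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Build and serialize a DENTALE report document
#'
#' A report bundles the tool version, the weight configuration in force,
#' the per-subject score rows, and optionally a validation block
#' (confusion counts with diagnostic accuracy, and/or an ICC result).
#' Serialization is deterministic: fixed key order, percentages rendered
#' to one decimal; `read_report()` restores the identical content.
#'
#' @param scores data frame from [score_cohort()].
#' @param weights the `dentale_weights` configuration used.
#' @param accuracy optional `dentale_accuracy` object.
#' @param icc optional `dentale_icc` object.
#' @param timestamp report timestamp string; pass a fixed value for
#'   byte-stable output.
#' @return `dentale_report()` returns a `dentale_report` list;
#'   `write_report()` writes JSON and returns `path` invisibly;
#'   `read_report()` returns the parsed report list.
#' @export
dentale_report <- function(scores, weights = default_weights(),
                           accuracy = NULL, icc = NULL,
                           timestamp = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(is.data.frame(scores))
  doc <- list(
    tool = "dentale",
    version = as.character(utils::packageVersion("dentale")),
    timestamp = timestamp,
    weights = unclass(weights),
    n_subjects = nrow(scores),
    n_referrals = sum(scores$refer),
    scores = scores
  )
  if (!is.null(accuracy)) {
    counts <- attr(accuracy, "counts")
    doc$validation <- list(
      counts = unclass(counts)[c("tp", "fp", "fn", "tn", "n")],
      accuracy = lapply(seq_len(nrow(accuracy)), function(i) {
        list(metric = accuracy$metric[i],
             estimate = accuracy$estimate[i],
             percent = accuracy$percent[i],
             rendered = if (is.na(accuracy$percent[i])) "n/a"
                        else sprintf("%.1f%%", accuracy$percent[i]),
             ci_low = accuracy$ci_low[i],
             ci_high = accuracy$ci_high[i])
      })
    )
  }
  if (!is.null(icc)) {
    doc$icc <- unclass(icc)
  }
  class(doc) <- "dentale_report"
  doc
}

#' @rdname dentale_report
#' @param report a `dentale_report` object.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "dentale_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname dentale_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
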