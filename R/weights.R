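#' Default DENTALE weight configuration
#'
#' The weighting system behind the 0-158 score range. A missing tooth scores
#' its presence weight (canine 8, incisor 6, premolar/molar 4); each abnormal
#' tooth-specific aspect on a present tooth scores `aspect_point`; reduced
#' alveolar bone and tooth wear score one point per sextant; an abnormal
#' condylar contour scores 3 per side and an abnormal ascending ramus 1 per
#' side. If more than `sextant_adjustment_threshold` points (strictly)
#' accumulate within one sextant, `sextant_adjustment_bonus` points are
#' added once to the total, so that localized single-sextant pathology is
#' not missed. A final total at or above `referral_threshold` flags the
#' survivor for specialized dental care.
#'
#' @param presence_weights named numeric, points per missing tooth by class.
#' @param aspect_point points per abnormal tooth-specific aspect.
#' @param condyle_point points per abnormal condyle side.
#' @param ramus_point points per abnormal ramus side.
#' @param alveolar_point points per sextant with reduced alveolar bone.
#' @param wear_point points per sextant with tooth wear.
#' @param sextant_adjustment_threshold strict threshold for the per-sextant
#'   adjustment (a sextant total must exceed it).
#' @param sextant_adjustment_bonus points added when any sextant exceeds the
#'   threshold.
#' @param adjustment_per_sextant if `TRUE`, the bonus is added once per
#'   qualifying sextant instead of at most once per assessment (sensitivity
#'   analysis switch; the default mirrors the published rule).
#' @param referral_threshold inclusive referral cutoff on the final total.
#' @return An object of class `dentale_weights`.
#' @examples
#' w <- default_weights()
#' max_base_score(w) # 158
#' @export
default_weights <- function(presence_weights = c(central_incisor = 6,
                                                 lateral_incisor = 6,
                                                 canine = 8,
                                                 first_premolar = 4,
                                                 second_premolar = 4,
                                                 first_molar = 4,
                                                 second_molar = 4),
                            aspect_point = 1,
                            condyle_point = 3,
                            ramus_point = 1,
                            alveolar_point = 1,
                            wear_point = 1,
                            sextant_adjustment_threshold = 10,
                            sextant_adjustment_bonus = 5,
                            adjustment_per_sextant = FALSE,
                            referral_threshold = 16) {
  w <- list(
    presence_weights = presence_weights,
    aspect_point = aspect_point,
    condyle_point = condyle_point,
    ramus_point = ramus_point,
    alveolar_point = alveolar_point,
    wear_point = wear_point,
    sextant_adjustment_threshold = sextant_adjustment_threshold,
    sextant_adjustment_bonus = sextant_adjustment_bonus,
    adjustment_per_sextant = isTRUE(adjustment_per_sextant),
    referral_threshold = referral_threshold
  )
  class(w) <- "dentale_weights"
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  need <- c("central_incisor", "lateral_incisor", "canine", "first_premolar",
            "second_premolar", "first_molar", "second_molar")
  if (!all(need %in% names(w$presence_weights))) {
    stop("presence_weights must name all seven tooth classes", call. = FALSE)
  }
  num <- c(w$presence_weights, w$aspect_point, w$condyle_point,
           w$ramus_point, w$alveolar_point, w$wear_point,
           w$sextant_adjustment_threshold, w$sextant_adjustment_bonus,
           w$referral_threshold)
  if (!all(is.finite(num)) || any(num < 0)) {
    stop("all weights and thresholds must be finite and non-negative",
         call. = FALSE)
  }
  invisible(w)
}

#' Maximum achievable base score under a weight configuration
#'
#' The base-score ceiling is reached when all 28 teeth are missing (their
#' presence weights sum), both condyles and both rami are abnormal, and all
#' six sextants show alveolar reduction; tooth wear is then unscorable
#' because no tooth is visible. Under default weights this is
#' 144 + 6 + 2 + 6 = 158.
#'
#' @param weights a `dentale_weights` object.
#' @return A single number.
#' @export
max_base_score <- function(weights = default_weights()) {
  chart <- tooth_chart()
  sum(weights$presence_weights[chart$class]) +
    2 * weights$condyle_point + 2 * weights$ramus_point +
    6 * weights$alveolar_point
}

#' @export
print.dentale_weights <- function(x, ...) {
  cat("DENTALE weight configuration\n")
  cat("  presence:",
      paste(names(x$presence_weights), x$presence_weights, sep = "=",
            collapse = ", "), "\n")
  cat("  aspect", x$aspect_point, "| condyle", x$condyle_point,
      "| ramus", x$ramus_point, "| alveolar", x$alveolar_point,
      "| wear", x$wear_point, "\n")
  cat("  sextant adjustment: +", x$sextant_adjustment_bonus, " if > ",
      x$sextant_adjustment_threshold, " in one sextant",
      if (x$adjustment_per_sextant) " (per sextant)" else " (at most once)",
      "\n", sep = "")
  cat("  referral at total >=", x$referral_threshold, "\n")
  cat("  maximum base score:", max_base_score(x), "\n")
  invisible(x)
}

#' Read / write a weight configuration file
#'
#' Plain `key = value` text. Presence weights use keys
#' `presence.<class>` (e.g. `presence.canine = 8`);
#' `adjustment_per_sextant` is `true`/`false`. Unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_weights()` returns a `dentale_weights` object;
#'   `write_weights()` returns `path` invisibly.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE))) {
    stop("weights file must contain 'key = value' lines", call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  w <- default_weights()
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    if (startsWith(key, "presence.")) {
      cls <- sub("^presence\\.", "", key)
      if (!cls %in% names(w$presence_weights)) {
        stop("unknown tooth class in weights file: ", cls, call. = FALSE)
      }
      w$presence_weights[[cls]] <- as.numeric(val)
    } else if (key == "adjustment_per_sextant") {
      w$adjustment_per_sextant <- tolower(val) %in% c("true", "1", "yes")
    } else if (key %in% c("aspect_point", "condyle_point", "ramus_point",
                          "alveolar_point", "wear_point",
                          "sextant_adjustment_threshold",
                          "sextant_adjustment_bonus", "referral_threshold")) {
      w[[key]] <- as.numeric(val)
    } else {
      stop("unknown key in weights file: ", key, call. = FALSE)
    }
  }
  validate_weights(w)
  w
}

#' @rdname read_weights
#' @param weights a `dentale_weights` object.
#' @export
write_weights <- function(weights, path) {
  validate_weights(weights)
  lines <- c(
    paste0("presence.", names(weights$presence_weights), " = ",
           weights$presence_weights),
    paste("aspect_point =", weights$aspect_point),
    paste("condyle_point =", weights$condyle_point),
    paste("ramus_point =", weights$ramus_point),
    paste("alveolar_point =", weights$alveolar_point),
    paste("wear_point =", weights$wear_point),
    paste("sextant_adjustment_threshold =",
          weights$sextant_adjustment_threshold),
    paste("sextant_adjustment_bonus =", weights$sextant_adjustment_bonus),
    paste("adjustment_per_sextant =",
          tolower(weights$adjustment_per_sextant)),
    paste("referral_threshold =", weights$referral_threshold)
  )
  writeLines(lines, path)
  invisible(path)
}
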