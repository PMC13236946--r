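#' The permanent-dentition chart in FDI notation
#'
#' DENTALE scores the 28 permanent teeth, excluding third molars. Teeth are
#' identified by two-digit FDI codes: the first digit is the quadrant
#' (1 upper right, 2 upper left, 3 lower left, 4 lower right), the second
#' the position from the midline (1 central incisor .. 7 second molar).
#' Position 8 (third molars) is rejected everywhere in the package.
#'
#' Each tooth belongs to exactly one of six sextants, using the standard
#' periodontal convention: two anterior sextants run canine-to-canine
#' (6 teeth each), four posterior sextants cover first premolar to second
#' molar (4 teeth each).
#'
#' @return A data frame with one row per tooth in canonical order
#'   (11..17, 21..27, 31..37, 41..47) and columns `fdi`, `quadrant`,
#'   `position`, `class`, `presence_weight`, `sextant`.
#' @examples
#' chart <- tooth_chart()
#' sum(chart$presence_weight) # 144
#' table(chart$sextant)       # 4 4 4 4 6 6 across sextants 1..6
#' @export
tooth_chart <- function() {
  if (!is.null(.chart_cache$chart)) return(.chart_cache$chart)
  quadrant <- rep(1:4, each = 7L)
  position <- rep(1:7, times = 4L)
  classes <- c("central_incisor", "lateral_incisor", "canine",
               "first_premolar", "second_premolar",
               "first_molar", "second_molar")
  weights <- c(6L, 6L, 8L, 4L, 4L, 4L, 4L)
  sextant <- ifelse(position >= 4L,
                    c(1L, 3L, 4L, 6L)[quadrant],
                    c(2L, 2L, 5L, 5L)[quadrant])
  .chart_cache$chart <- data.frame(
    fdi = as.integer(quadrant * 10L + position),
    quadrant = quadrant,
    position = position,
    class = classes[position],
    presence_weight = weights[position],
    sextant = sextant,
    stringsAsFactors = FALSE
  )
  .chart_cache$chart
}

.chart_cache <- new.env(parent = emptyenv())

#' All 28 valid FDI codes in canonical order
#' @return Integer vector of length 28.
#' @export
fdi_codes <- function() tooth_chart()$fdi

check_fdi <- function(fdi) {
  if (length(fdi) == 0L) stop("no FDI codes supplied", call. = FALSE)
  bad <- !is.finite(fdi) | fdi != as.integer(fdi)
  if (any(bad)) {
    stop("invalid FDI code(s): ", paste(fdi[bad], collapse = ", "),
         call. = FALSE)
  }
  fdi <- as.integer(fdi)
  pos8 <- fdi %% 10L == 8L & fdi %/% 10L %in% 1:4
  if (any(pos8)) {
    stop("FDI code(s) ", paste(fdi[pos8], collapse = ", "),
         " denote third molars, which are excluded from DENTALE ",
         "(the tool scores the 28 other permanent teeth only)",
         call. = FALSE)
  }
  ok <- fdi %in% fdi_codes()
  if (!all(ok)) {
    stop("invalid FDI code(s): ", paste(fdi[!ok], collapse = ", "),
         " (valid codes are 11-17, 21-27, 31-37, 41-47)", call. = FALSE)
  }
  fdi
}

#' Tooth class of an FDI code
#'
#' Maps position digits to tooth classes: 1 central incisor, 2 lateral
#' incisor, 3 canine, 4/5 premolars, 6/7 molars.
#'
#' @param fdi integer vector of FDI codes.
#' @return Character vector of class names.
#' @examples
#' tooth_class_of(c(13, 41)) # canine, central_incisor
#' @export
tooth_class_of <- function(fdi) {
  fdi <- check_fdi(fdi)
  chart <- tooth_chart()
  chart$class[match(fdi, chart$fdi)]
}

#' Presence weight of an FDI code
#'
#' The points a missing tooth contributes: canines 8, incisors 6, premolars
#' and molars 4.
#'
#' @inheritParams tooth_class_of
#' @param weights a weight configuration, see [default_weights()].
#' @return Numeric vector of presence weights.
#' @export
presence_weight_of <- function(fdi, weights = default_weights()) {
  unname(weights$presence_weights[tooth_class_of(fdi)])
}

#' Sextant of an FDI code
#'
#' Sextant 1 is upper right posterior (14-17), 2 upper anterior (13-23),
#' 3 upper left posterior (24-27), 4 lower left posterior (34-37),
#' 5 lower anterior (33-43), 6 lower right posterior (44-47).
#'
#' @inheritParams tooth_class_of
#' @return Integer vector of sextant ids in 1..6.
#' @examples
#' sextant_of(c(16, 23, 35)) # 1, 2, 4
#' @export
sextant_of <- function(fdi) {
  fdi <- check_fdi(fdi)
  chart <- tooth_chart()
  chart$sextant[match(fdi, chart$fdi)]
}
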