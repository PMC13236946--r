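#' Parameters for a synthetic survivor cohort
#'
#' The generator emulates the kind of cohort the tool was piloted on:
#' childhood head-and-neck cancer survivors whose orthopantomograms range
#' from near-normal dentition to multi-item pathology. Each subject draws a
#' latent severity `s` in \[0, 1\] from a two-component Beta mixture (a
#' low-severity mode and a high-severity mode); every scorable item is then
#' abnormal with probability `plogis(a + b * s)` using item-class specific
#' intercepts `a` and slopes `b`. With probability `localization_prob` a
#' subject's pathology is concentrated in one randomly chosen sextant
#' (severity boosted there, suppressed elsewhere, bony items quiet) — the
#' single-sextant regime that motivated the +5 adjustment rule. The expert
#' referral label is `s > expert_cutoff`, flipped with probability
#' `label_noise`, so labels track severity rather than the score itself and
#' threshold selection is a genuine recovery problem.
#'
#' @param n_subjects cohort size (default 83, the pilot cohort size).
#' @param mix_weight_high probability a subject comes from the
#'   high-severity mode (default 0.6; roughly two-thirds of the pilot
#'   cohort needed referral).
#' @param sev_low_shape,sev_high_shape Beta shape pairs for the two
#'   severity modes.
#' @param item_intercepts,item_slopes named numeric vectors over the item
#'   classes `missing`, `crown`, `root`, `ratio`, `eruption`, `alveolar`,
#'   `wear`, `condyle`, `ramus`.
#' @param localization_prob probability of the single-sextant regime.
#' @param localization_boost severity added inside the focal sextant.
#' @param expert_cutoff severity above which the expert refers.
#' @param label_noise probability the expert label is flipped.
#' @param age_range survivor age range (years) at the radiograph; the
#'   default lower bound of 8 keeps all 28 permanent-tooth germs
#'   radiographically assessable per the shipped eruption reference table.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 83,
                          mix_weight_high = 0.6,
                          sev_low_shape = c(2, 10),
                          sev_high_shape = c(5, 3),
                          item_intercepts = c(missing = -4.5, crown = -4,
                                              root = -4, ratio = -4.5,
                                              eruption = -4.5,
                                              alveolar = -3.5, wear = -4,
                                              condyle = -4.5, ramus = -5),
                          item_slopes = c(missing = 5.5, crown = 4.5,
                                          root = 4.5, ratio = 4.5,
                                          eruption = 4, alveolar = 5,
                                          wear = 3.5, condyle = 5.5,
                                          ramus = 5),
                          localization_prob = 0.15,
                          localization_boost = 0.3,
                          expert_cutoff = 0.4,
                          label_noise = 0.02,
                          age_range = c(8, 18)) {
  classes <- c("missing", "crown", "root", "ratio", "eruption",
               "alveolar", "wear", "condyle", "ramus")
  if (!all(classes %in% names(item_intercepts)) ||
      !all(classes %in% names(item_slopes))) {
    stop("item_intercepts and item_slopes must name all item classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  probs <- c(mix_weight_high, localization_prob, label_noise)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("mix_weight_high, localization_prob and label_noise must lie in ",
         "[0, 1]", call. = FALSE)
  }
  stopifnot(n_subjects >= 1, all(sev_low_shape > 0), all(sev_high_shape > 0),
            expert_cutoff >= 0, expert_cutoff <= 1,
            length(age_range) == 2L, age_range[1] >= 0,
            age_range[2] >= age_range[1])
  p <- list(n_subjects = as.integer(n_subjects),
            mix_weight_high = mix_weight_high,
            sev_low_shape = sev_low_shape, sev_high_shape = sev_high_shape,
            item_intercepts = item_intercepts[classes],
            item_slopes = item_slopes[classes],
            localization_prob = localization_prob,
            localization_boost = localization_boost,
            expert_cutoff = expert_cutoff, label_noise = label_noise,
            age_range = age_range)
  class(p) <- "cohort_params"
  p
}

#' Rater observation-noise parameters
#'
#' @param flip_prob probability a rater records the opposite of the latent
#'   truth for any binary finding; must lie in \[0, 0.5) (at 0.5 ratings
#'   carry no signal).
#' @param bias optional numeric vector of per-rater additive tendencies on
#'   the aspect flags: rater `r`'s probability of calling a truly normal
#'   aspect abnormal is `flip_prob + bias[r]` (clamped to \[0, 0.5\]).
#' @return An object of class `rater_noise`.
#' @export
rater_noise <- function(flip_prob = 0.05, bias = NULL) {
  if (!is.finite(flip_prob) || flip_prob < 0 || flip_prob >= 0.5) {
    stop("flip_prob must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is.null(bias) && (any(!is.finite(bias)) || any(bias < 0))) {
    stop("bias must be non-negative", call. = FALSE)
  }
  structure(list(flip_prob = flip_prob, bias = bias),
            class = "rater_noise")
}

item_prob <- function(p, class, s) {
  stats::plogis(p$item_intercepts[[class]] + p$item_slopes[[class]] * s)
}

# severity seen by items in sextant sx; in the localized regime pathology
# is confined to the focal sextant (outside probabilities are forced to 0)
effective_severity <- function(s, localized, focal, sx, boost) {
  if (!localized) return(rep(s, length(sx)))
  ifelse(sx == focal, min(1, s + boost), NA_real_)
}

masked_prob <- function(p, class, s_eff) {
  pr <- item_prob(p, class, ifelse(is.na(s_eff), 0, s_eff))
  ifelse(is.na(s_eff), 0, pr)
}

#' Generate a synthetic survivor cohort
#'
#' Draws `p$n_subjects` latent severities, expert labels, and complete
#' DENTALE assessments. Every generated assessment satisfies the model
#' invariants by construction (wear is only flagged in sextants that keep
#' at least one present tooth). Identical `(p, seed)` give identical
#' output.
#'
#' @param p a `cohort_params` object.
#' @param seed integer seed; all randomness flows from it.
#' @param rater_id rater id stamped on the generated assessments.
#' @return A list with `assessments` (list of `dentale_assessment`),
#'   `severity` (numeric), `expert_label` (logical), and `localized`
#'   (logical, whether the subject was in the single-sextant regime).
#' @export
generate_cohort <- function(p, seed, rater_id = "truth") {
  stopifnot(inherits(p, "cohort_params"))
  with_seed(seed, {
    n <- p$n_subjects
    from_high <- stats::runif(n) < p$mix_weight_high
    s <- ifelse(from_high,
                stats::rbeta(n, p$sev_high_shape[1], p$sev_high_shape[2]),
                stats::rbeta(n, p$sev_low_shape[1], p$sev_low_shape[2]))
    localized <- stats::runif(n) < p$localization_prob
    focal <- sample(1:6, n, replace = TRUE)
    labels <- (s > p$expert_cutoff) != (stats::runif(n) < p$label_noise)
    ages <- round(stats::runif(n, p$age_range[1], p$age_range[2]), 1)
    assessments <- vector("list", n)
    for (i in seq_len(n)) {
      assessments[[i]] <- generate_assessment(
        p, s[i], localized[i], focal[i],
        subject_id = sprintf("SYN%03d", i), rater_id = rater_id,
        age = ages[i])
    }
    list(assessments = assessments, severity = s, expert_label = labels,
         localized = localized)
  })
}

generate_assessment <- function(p, s, localized, focal, subject_id,
                                rater_id, age) {
  chart <- tooth_chart()
  a <- new_assessment(subject_id, rater_id, age)
  s_sext <- effective_severity(s, localized, focal, 1:6,
                               p$localization_boost)
  s_tooth <- s_sext[chart$sextant]
  nt <- nrow(chart)
  missing <- stats::runif(nt) < masked_prob(p, "missing", s_tooth)
  a$teeth$status <- ifelse(missing, "missing", "present")
  for (cls in c("crown", "root", "ratio", "eruption")) {
    col <- switch(cls, crown = "crown_abnormal", root = "root_abnormal",
                  ratio = "crown_root_ratio_abnormal",
                  eruption = "eruption_not_age_appropriate")
    a$teeth[[col]] <- !missing &
      stats::runif(nt) < masked_prob(p, cls, s_tooth)
  }
  any_present <- as.logical(tapply(!missing,
                                   factor(chart$sextant, levels = 1:6),
                                   any))
  a$sextants$alveolar_reduced <-
    stats::runif(6) < masked_prob(p, "alveolar", s_sext)
  a$sextants$tooth_wear <- any_present &
    stats::runif(6) < masked_prob(p, "wear", s_sext)
  s_bony <- if (localized) NA_real_ else s   # bony items are not sextant-local
  p_bony <- c(masked_prob(p, "condyle", s_bony),
              masked_prob(p, "condyle", s_bony),
              masked_prob(p, "ramus", s_bony),
              masked_prob(p, "ramus", s_bony))
  a$bony[] <- stats::runif(4) < p_bony
  a
}

#' Simulate noisy raters reading one radiograph
#'
#' Produces `k` independent noisy copies of a latent-truth assessment:
#' every binary finding (tooth status, aspect flags, sextant flags, bony
#' flags) is flipped with probability `noise$flip_prob`; an optional
#' per-rater bias raises the normal-to-abnormal flip rate on aspect flags.
#' Flips that would violate an invariant are repaired (a tooth flipped to
#' missing drops its aspect flags; wear cannot appear in a sextant left
#' edentulous), so every copy passes [validate_assessment()]. With
#' `flip_prob = 0` and no bias all copies equal the truth.
#'
#' @param truth a valid `dentale_assessment`.
#' @param noise a `rater_noise` object.
#' @param k number of raters, at least 2.
#' @param seed integer seed.
#' @return A list of `k` assessments with rater ids `"R1"`..`"Rk"`.
#' @export
simulate_raters <- function(truth, noise, k, seed = 1L) {
  stopifnot(inherits(truth, "dentale_assessment"),
            inherits(noise, "rater_noise"))
  if (k < 2L) stop("need at least k = 2 raters", call. = FALSE)
  v <- validate_assessment(truth)
  if (length(v)) stop("invalid truth assessment: ", v[1], call. = FALSE)
  if (!is.null(noise$bias) && length(noise$bias) != k) {
    stop("bias must have one entry per rater", call. = FALSE)
  }
  chart <- tooth_chart()
  with_seed(seed, {
    lapply(seq_len(k), function(r) {
      a <- truth
      a$rater_id <- paste0("R", r)
      fp <- noise$flip_prob
      up <- if (is.null(noise$bias)) fp else min(0.5, fp + noise$bias[r])
      nt <- nrow(a$teeth)
      flip_status <- stats::runif(nt) < fp
      miss <- (a$teeth$status == "missing") != flip_status
      a$teeth$status <- ifelse(miss, "missing", "present")
      for (col in aspect_cols()) {
        truthy <- truth$teeth[[col]]
        pr <- ifelse(truthy, fp, up)  # bias only inflates false alarms
        a$teeth[[col]] <- (truthy != (stats::runif(nt) < pr)) & !miss
      }
      flip_alv <- stats::runif(6) < fp
      a$sextants$alveolar_reduced <- truth$sextants$alveolar_reduced != flip_alv
      any_present <- as.logical(tapply(!miss,
                                       factor(chart$sextant, levels = 1:6),
                                       any))
      flip_wear <- stats::runif(6) < fp
      a$sextants$tooth_wear <- (truth$sextants$tooth_wear != flip_wear) &
        any_present
      flip_bony <- stats::runif(4) < fp
      a$bony[] <- truth$bony != flip_bony
      a
    })
  })
}

#' Threshold-recovery experiment
#'
#' End-to-end harness mirroring the pilot design: per replicate a cohort is
#' generated, scored, and swept over candidate referral thresholds; the
#' selected threshold and its operating characteristics are recorded.
#' Replicates with degenerate expert labels (all one class) are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param p a `cohort_params` object.
#' @param weights a `dentale_weights` configuration.
#' @param reps number of replicates.
#' @param seed integer seed; replicate `r` uses `seed + r`.
#' @param thresholds candidate thresholds.
#' @return A data frame with columns `rep`, `selected_threshold`,
#'   `sensitivity`, `specificity` (metrics at the selected threshold;
#'   `NA` when no threshold reached sensitivity 1).
#' @export
recovery_experiment <- function(p, weights = default_weights(), reps = 20,
                                seed = 1L, thresholds = c(14, 16, 18, 20)) {
  stopifnot(inherits(p, "cohort_params"), reps >= 0)
  rows <- list(); skipped <- 0L
  for (r in seq_len(reps)) {
    cohort <- generate_cohort(p, seed = seed + r)
    if (all(cohort$expert_label) || !any(cohort$expert_label)) {
      skipped <- skipped + 1L
      next
    }
    totals <- score_cohort(cohort$assessments, weights)$final_total
    sw <- sweep_thresholds(totals, cohort$expert_label, thresholds)
    sel <- attr(sw, "selected_threshold")
    i <- match(sel, sw$threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      rep = r, selected_threshold = sel,
      sensitivity = if (is.na(sel)) NA_real_ else sw$sensitivity[i],
      specificity = if (is.na(sel)) NA_real_ else sw$specificity[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rep = integer(0), selected_threshold = numeric(0),
               sensitivity = numeric(0), specificity = numeric(0))
  attr(out, "n_skipped") <- skipped
  out
}

# evaluate expr with a local, restored RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
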