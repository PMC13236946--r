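# Independent oracles. These deliberately share no scoring/ICC code with
# the package: the scorer oracle enumerates every item with its own FDI
# arithmetic and hard-coded default weights; the ICC oracle computes the
# two-way ANOVA mean squares from raw sums.

# brute-force scorer, default weights only
oracle_score <- function(a) {
  weight_by_pos <- c(6, 6, 8, 4, 4, 4, 4)
  sext_of <- function(fdi) {
    q <- fdi %/% 10; pos <- fdi %% 10
    if (pos <= 3) { if (q <= 2) 2 else 5 } else c(1, 3, 4, 6)[q]
  }
  total <- 0
  sext <- rep(0, 6)
  for (i in seq_len(nrow(a$teeth))) {
    t <- a$teeth[i, ]
    if (!is.na(t$exclusion_note) && nzchar(t$exclusion_note)) next
    pts <- if (t$status == "missing") {
      weight_by_pos[t$fdi %% 10]
    } else {
      sum(t$crown_abnormal, t$root_abnormal, t$crown_root_ratio_abnormal,
          t$eruption_not_age_appropriate)
    }
    total <- total + pts
    s <- sext_of(t$fdi)
    sext[s] <- sext[s] + pts
  }
  for (j in seq_len(nrow(a$sextants))) {
    s <- a$sextants$sextant[j]
    pts <- sum(a$sextants$alveolar_reduced[j], a$sextants$tooth_wear[j])
    total <- total + pts
    sext[s] <- sext[s] + pts
  }
  total <- total +
    3 * sum(a$bony[c("condyle_left_abnormal", "condyle_right_abnormal")]) +
    1 * sum(a$bony[c("ramus_left_abnormal", "ramus_right_abnormal")])
  adj <- if (any(sext > 10)) 5 else 0
  list(base_total = total, adjustment = adj, final_total = total + adj,
       per_sextant = sext, refer = total + adj >= 16)
}

# direct mean-square ICC(2,1) from raw sums
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm <- rowMeans(m); cm <- colMeans(m)
  msr <- k * sum((rm - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - rm[i] - cm[j] + grand)^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random valid assessment, independent of the synthetic module
random_assessment <- function(id = "X", p_missing = 0.2, p_flag = 0.15,
                              p_note = 0.03) {
  a <- new_assessment(id, "R", age_at_opg_years = runif(1, 6, 20))
  n <- nrow(a$teeth)
  a$teeth$status <- ifelse(runif(n) < p_missing, "missing", "present")
  for (col in c("crown_abnormal", "root_abnormal",
                "crown_root_ratio_abnormal",
                "eruption_not_age_appropriate")) {
    a$teeth[[col]] <- a$teeth$status == "present" & runif(n) < p_flag
  }
  a$teeth$exclusion_note <- ifelse(runif(n) < p_note, "orthodontic extraction",
                                   NA_character_)
  sext <- sextant_of(a$teeth$fdi)
  any_present <- tapply(a$teeth$status == "present",
                        factor(sext, levels = 1:6), any)
  a$sextants$alveolar_reduced <- runif(6) < p_flag
  a$sextants$tooth_wear <- runif(6) < p_flag & as.logical(any_present)
  a$bony[] <- runif(4) < p_flag
  a
}

worst_case_assessment <- function() {
  a <- new_assessment("worst", age_at_opg_years = 18)
  a <- set_tooth(a, fdi_codes(), status = "missing")
  a <- set_sextant(a, 1:6, alveolar_reduced = TRUE)
  set_bony(a, condyle_left_abnormal = TRUE, condyle_right_abnormal = TRUE,
           ramus_left_abnormal = TRUE, ramus_right_abnormal = TRUE)
}

# assessment with a given number of aspect flags spread across sextants so
# that no sextant total exceeds 10: three missing premolars (4+4+4) plus
# n_extra crown flags on anterior teeth
sentinel_assessment <- function(id, n_extra) {
  a <- new_assessment(id, age_at_opg_years = 15)
  a <- set_tooth(a, c(14, 24, 34), status = "missing")
  if (n_extra > 0) {
    a <- set_tooth(a, c(11, 21, 31, 41)[seq_len(n_extra)],
                   crown_abnormal = TRUE)
  }
  a
}
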