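# Cell-level simulator for the statistical stage. Generates analysis tables
# (one response value per participant x vowel x condition cell) directly from
# the mixed-model data-generating process, bypassing audio entirely. Used for
# type-I error calibration and power studies of the split-plot ANOVA, where
# thousands of replicate cohorts are needed.

#' Simulate a cell-level analysis table from the mixed model
#'
#' Generates `y = grand_mean + group + condition-within-group + vowel +
#' participant intercept + residual` for the balanced two-group split-plot
#' design. With all effects zero this is the null model used for type-I
#' error calibration; the `condition_shift` argument takes a named vector of
#' DAF-minus-NAF shifts per group, so opposite-signed values reproduce the
#' crossover (group x condition interaction) scenario.
#'
#' @param n_per_group Participants per group.
#' @param vowels Vowel labels.
#' @param grand_mean Intercept on the response scale.
#' @param group_shift AWS minus ANS main-effect shift.
#' @param condition_shift Named vector `c(AWS = ..., ANS = ...)` of
#'   DAF-minus-NAF shifts within each group.
#' @param vowel_shift Named vector of per-vowel shifts (default 0).
#' @param participant_sd SD of the participant random intercept.
#' @param residual_sd Residual SD.
#' @param response Name of the response column to create.
#' @return Data frame with columns participant, group, condition, vowel and
#'   the response; one row per cell.
#' @export
simulate_analysis_frame <- function(n_per_group = 12,
                                    vowels = c("i", "ih", "eh", "ae"),
                                    grand_mean = 3,
                                    group_shift = 0,
                                    condition_shift = c(AWS = 0, ANS = 0),
                                    vowel_shift = NULL,
                                    participant_sd = 0.2,
                                    residual_sd = 0.2,
                                    response = "log_ttv") {
  groups <- c("AWS", "ANS")
  conditions <- c("NAF", "DAF")
  if (is.null(vowel_shift)) vowel_shift <- stats::setNames(rep(0, length(vowels)), vowels)
  tab <- expand.grid(
    vowel = vowels, condition = conditions,
    subj = seq_len(n_per_group), group = groups,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tab$participant <- sprintf("%s%02d", tab$group, tab$subj)
  intercepts <- stats::rnorm(2 * n_per_group, 0, participant_sd)
  names(intercepts) <- sprintf("%s%02d", rep(groups, each = n_per_group),
                               rep(seq_len(n_per_group), 2))
  y <- grand_mean +
    ifelse(tab$group == "AWS", group_shift / 2, -group_shift / 2) +
    ifelse(tab$condition == "DAF", 1, -1) * condition_shift[tab$group] / 2 +
    vowel_shift[tab$vowel] +
    intercepts[tab$participant] +
    stats::rnorm(nrow(tab), 0, residual_sd)
  tab[[response]] <- as.numeric(y)
  tab$subj <- NULL
  tab[, c("participant", "group", "condition", "vowel", response)]
}
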