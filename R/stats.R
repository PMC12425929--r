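# Split-plot mixed ANOVA for the balanced vowel x condition x group design
# with participant random intercepts, computed from scratch via expected
# mean squares. For this balanced one-observation-per-cell design the
# classical error strata coincide with the REML/Satterthwaite solution a
# general mixed-model fitter would give: the between-subject factor (group)
# is tested against the participants-within-groups stratum, all
# within-subject effects against the residual stratum. Unbalanced input is
# refused rather than approximated.

#' Fit the split-plot mixed ANOVA
#'
#' Model: `response = group * condition * vowel` fixed effects plus a
#' participant random intercept (participants nested in groups) plus
#' residual, one observation per participant x vowel x condition cell.
#' Sums of squares are the classical balanced-design decomposition; variance
#' components come from the expected mean squares (participant variance
#' truncated at zero, REML-consistent). For the default design (24
#' participants, 4 vowels, 2 conditions) the denominator df are 22 for group
#' and 154 for all within-subject effects.
#'
#' @param table Cell-level data frame with columns `participant`, `group`,
#'   `condition`, `vowel` and the response.
#' @param response Name of the response column (e.g. `"log_ttv"`).
#' @return An object of class `vv_anova`: `anova` (per-effect F, df, p),
#'   mean squares and df of the two error strata, variance components, the
#'   design dimensions and the data.
#' @export
fit_mixed_anova <- function(table, response) {
  if (!response %in% names(table)) {
    stop("fit_mixed_anova: no column '", response, "'")
  }
  y <- table[[response]]
  if (any(!is.finite(y))) stop("fit_mixed_anova: non-finite response values")
  G <- factor(table$group)
  V <- factor(table$vowel)
  C <- factor(table$condition)
  P <- factor(table$participant)

  g <- nlevels(G); v <- nlevels(V); c_ <- nlevels(C)
  # balance checks: one row per participant x vowel x condition, participants
  # nested in groups, equal group sizes
  cell_counts <- table(P, V, C)
  p_per_group <- table(unique(data.frame(P, G))$G)
  if (any(cell_counts != 1) || length(unique(p_per_group)) != 1) {
    stop("fit_mixed_anova: design is unbalanced; this fitter requires one ",
         "observation per participant x vowel x condition cell and equal ",
         "group sizes. Subset or aggregate to a balanced table first.")
  }
  if (any(rowSums(table(P, G) > 0) != 1)) {
    stop("fit_mixed_anova: each participant must belong to exactly one group")
  }
  n <- as.integer(p_per_group[1])
  N <- g * n * v * c_

  grand <- mean(y)
  ss <- function(means, mult) mult * sum((means - grand)^2)
  m_p <- tapply(y, P, mean)
  m_g <- tapply(y, G, mean)
  m_v <- tapply(y, V, mean)
  m_c <- tapply(y, C, mean)
  m_gv <- tapply(y, list(G, V), mean)
  m_gc <- tapply(y, list(G, C), mean)
  m_vc <- tapply(y, list(V, C), mean)
  m_gvc <- tapply(y, list(G, V, C), mean)

  ss_total <- sum((y - grand)^2)
  ss_bs <- ss(m_p, v * c_)
  ss_G <- ss(m_g, n * v * c_)
  ss_PG <- ss_bs - ss_G
  ss_V <- ss(m_v, g * n * c_)
  ss_C <- ss(m_c, g * n * v)
  ss_GV <- ss(m_gv, n * c_) - ss_G - ss_V
  ss_GC <- ss(m_gc, n * v) - ss_G - ss_C
  ss_VC <- ss(m_vc, g * n) - ss_V - ss_C
  ss_GVC <- ss(m_gvc, n) - ss_G - ss_V - ss_C - ss_GV - ss_GC - ss_VC
  ss_res <- ss_total - ss_bs -
    (ss_V + ss_C + ss_GV + ss_GC + ss_VC + ss_GVC)

  df_PG <- g * (n - 1)
  df_res <- g * (n - 1) * (v * c_ - 1)
  ms_PG <- ss_PG / df_PG
  ms_res <- ss_res / df_res

  effects <- data.frame(
    effect = c("group", "vowel", "condition", "group:vowel",
               "group:condition", "vowel:condition", "group:vowel:condition"),
    ss = c(ss_G, ss_V, ss_C, ss_GV, ss_GC, ss_VC, ss_GVC),
    df_num = c(g - 1, v - 1, c_ - 1, (g - 1) * (v - 1), (g - 1) * (c_ - 1),
               (v - 1) * (c_ - 1), (g - 1) * (v - 1) * (c_ - 1)),
    stringsAsFactors = FALSE
  )
  effects$df_den <- ifelse(effects$effect == "group", df_PG, df_res)
  denom_ms <- ifelse(effects$effect == "group", ms_PG, ms_res)
  effects$ms <- effects$ss / effects$df_num

  degenerate <- ss_total <= 0 || ms_res <= 0 && ms_PG <= 0
  if (degenerate) {
    warning("fit_mixed_anova: response has no variance; F-tests undefined")
    effects$F <- NA_real_
    effects$p <- NA_real_
  } else {
    effects$F <- effects$ms / denom_ms
    effects$p <- stats::pf(effects$F, effects$df_num, effects$df_den,
                           lower.tail = FALSE)
  }

  sigma_p2 <- (ms_PG - ms_res) / (v * c_)
  if (is.finite(sigma_p2) && sigma_p2 < 0) {
    warning("fit_mixed_anova: participant variance estimate negative; ",
            "truncated at 0")
    sigma_p2 <- 0
  }

  structure(list(
    anova = effects[, c("effect", "df_num", "df_den", "ss", "ms", "F", "p")],
    ms_participant = ms_PG, ms_residual = ms_res,
    df_participant = df_PG, df_residual = df_res,
    sigma_participant2 = sigma_p2, sigma_residual2 = ms_res,
    ss_total = ss_total, degenerate = degenerate,
    design = list(g = g, v = v, c = c_, n = n, N = N,
                  groups = levels(G), vowels = levels(V),
                  conditions = levels(C)),
    data = table, response = response
  ), class = "vv_anova")
}

#' @export
print.vv_anova <- function(x, ...) {
  cat("Split-plot mixed ANOVA:", x$response,
      "~ group * condition * vowel + (1 | participant)\n")
  tab <- x$anova
  tab$F <- round(tab$F, 3)
  tab$p <- signif(tab$p, 4)
  print(tab[, c("effect", "df_num", "df_den", "F", "p")], row.names = FALSE)
  cat(sprintf("participant intercept variance %.4g, residual variance %.4g\n",
              x$sigma_participant2, x$sigma_residual2))
  invisible(x)
}

tukey_p <- function(t_stat, k, df) {
  stats::ptukey(sqrt(2) * abs(t_stat), nmeans = k, df = df,
                lower.tail = FALSE)
}

#' Tukey-adjusted pairwise post-hoc contrasts
#'
#' Estimated marginal means are simple cell-mean averages (exact under
#' balance); all pairwise differences are tested with the studentized-range
#' (Tukey) adjustment. The error stratum follows the split-plot structure:
#' contrasts that span groups use the participant stratum, within-subject
#' contrasts use the residual stratum. For `"group_condition"` the family is
#' the 4 group x condition cell means (6 contrasts).
#'
#' @param fit A [fit_mixed_anova()] object.
#' @param factor One of `"vowel"`, `"group"`, `"group_condition"`.
#' @return Data frame with `contrast`, `estimate`, `se`, `t`, `df`,
#'   `p_unadj`, `p_adj`.
#' @export
posthoc_pairwise <- function(fit, factor = c("vowel", "group",
                                             "group_condition")) {
  factor <- match.arg(factor)
  d <- fit$data
  y <- d[[fit$response]]
  des <- fit$design
  if (factor == "vowel") {
    means <- tapply(y, d$vowel, mean)
    if (length(means) < 2) stop("posthoc_pairwise: factor has one level")
    per_mean <- des$g * des$n * des$c
    se <- sqrt(2 * fit$ms_residual / per_mean)
    df <- rep(fit$df_residual, 1)
    spans_group <- FALSE
  } else if (factor == "group") {
    means <- tapply(y, d$group, mean)
    if (length(means) < 2) stop("posthoc_pairwise: factor has one level")
    per_mean <- des$n * des$v * des$c
    se <- sqrt(2 * fit$ms_participant / per_mean)
    df <- fit$df_participant
    spans_group <- TRUE
  } else {
    key <- interaction(d$group, d$condition, sep = " ")
    means <- tapply(y, key, mean)
    per_mean <- des$n * des$v
  }

  labs <- names(means)
  k <- length(means)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- means[i1] - means[i2]
    if (factor == "group_condition") {
      g1 <- sub(" .*", "", labs[i1]); g2 <- sub(" .*", "", labs[i2])
      if (g1 == g2) {
        se_j <- sqrt(2 * fit$ms_residual / per_mean)
        df_j <- fit$df_residual
      } else {
        se_j <- sqrt((fit$ms_participant + fit$ms_residual) / per_mean)
        df_j <- fit$df_participant
      }
    } else {
      se_j <- se
      df_j <- df
    }
    t_stat <- est / se_j
    data.frame(
      contrast = paste(labs[i1], "-", labs[i2]),
      estimate = unname(est), se = se_j, t = unname(t_stat), df = df_j,
      p_unadj = 2 * stats::pt(-abs(t_stat), df_j),
      p_adj = tukey_p(t_stat, k, df_j),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition simple effects within each group
#'
#' Estimates the DAF-minus-NAF difference separately within each group
#' (marginal over vowels), tested against the residual stratum. This is the
#' decomposition of a group x condition interaction the design was built to
#' detect: delayed feedback shifting variability in opposite directions in
#' the two groups. p-values are Bonferroni-adjusted over the family of two
#' contrasts.
#'
#' @param fit A [fit_mixed_anova()] object.
#' @param higher Condition level treated as the first term of the difference
#'   (default `"DAF"`).
#' @return Data frame with one row per group: `contrast`, `estimate`, `se`,
#'   `t`, `df`, `p_unadj`, `p_adj`.
#' @export
simple_effects_condition_within_group <- function(fit, higher = "DAF") {
  d <- fit$data
  y <- d[[fit$response]]
  des <- fit$design
  conds <- des$conditions
  if (length(conds) != 2) {
    stop("simple_effects_condition_within_group: need exactly 2 conditions")
  }
  lower <- setdiff(conds, higher)
  per_mean <- des$n * des$v
  se <- sqrt(2 * fit$ms_residual / per_mean)
  rows <- lapply(des$groups, function(gr) {
    sel <- d$group == gr
    est <- mean(y[sel & d$condition == higher]) -
      mean(y[sel & d$condition == lower])
    t_stat <- est / se
    p_un <- 2 * stats::pt(-abs(t_stat), fit$df_residual)
    data.frame(
      contrast = paste0(higher, " - ", lower, " | ", gr),
      estimate = est, se = se, t = t_stat, df = fit$df_residual,
      p_unadj = p_un, p_adj = pmin(1, 2 * p_un),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between within-trial and trial-to-trial variability
#'
#' Pearson correlation, with a two-sided t-test, between participant-level
#' mean `log_wtv` and mean `log_ttv` (averaged over vowels) within one
#' group x condition.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param group Group label.
#' @param condition Condition label.
#' @return List with `r`, `p`, `n` (participants).
#' @export
correlate_wtv_ttv <- function(table, group, condition) {
  sel <- table$group == group & table$condition == condition
  if (!any(sel)) stop("correlate_wtv_ttv: no rows for ", group, "/", condition)
  sub <- table[sel, ]
  wtv <- tapply(sub$log_wtv, sub$participant, mean)
  ttv <- tapply(sub$log_ttv, sub$participant, mean)
  if (length(wtv) < 3) stop("correlate_wtv_ttv: need >= 3 participants")
  if (stats::sd(wtv) == 0 || stats::sd(ttv) == 0) {
    stop("correlate_wtv_ttv: zero variance; correlation undefined")
  }
  ct <- stats::cor.test(wtv, ttv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(wtv))
}
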