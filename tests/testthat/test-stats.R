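test_that("denominator df are design-determined and invariant to the response", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      tab <- simulate_analysis_frame()
      fit <- fit_mixed_anova(tab, "log_ttv")
      a <- fit$anova
      expect_equal(a$df_den[a$effect == "group"], 22)
      expect_true(all(a$df_den[a$effect != "group"] == 154))
      expect_equal(a$df_num, c(1, 3, 1, 3, 1, 3, 3))
    }
  })
})

test_that("the from-scratch split-plot ANOVA matches lmerTest on balanced data", {
  library(lmerTest)
  withr::with_seed(9, {
    for (rep in 1:3) {
      tab <- simulate_analysis_frame(
        group_shift = runif(1, -0.5, 0.5),
        condition_shift = c(AWS = runif(1, -0.3, 0.3), ANS = runif(1, -0.3, 0.3)),
        vowel_shift = c(i = -0.3, ih = 0, eh = 0.1, ae = 0.2))
      fit <- fit_mixed_anova(tab, "log_ttv")
      m <- lmer(log_ttv ~ group * condition * vowel + (1 | participant),
                data = tab)
      ref <- anova(m) # Satterthwaite df
      key <- c(group = "group", vowel = "vowel", condition = "condition",
               `group:vowel` = "group:vowel",
               `group:condition` = "group:condition",
               `vowel:condition` = "condition:vowel",
               `group:vowel:condition` = "group:condition:vowel")
      for (eff in fit$anova$effect) {
        row <- fit$anova[fit$anova$effect == eff, ]
        expect_equal(row$F, ref[key[[eff]], "F value"], tolerance = 1e-6)
        expect_equal(row$df_den, ref[key[[eff]], "DenDF"], tolerance = 1e-3)
      }
      vc <- as.data.frame(lme4::VarCorr(m))
      expect_equal(fit$sigma_participant2, vc$vcov[1], tolerance = 1e-6)
      expect_equal(fit$sigma_residual2, vc$vcov[2], tolerance = 1e-6)
    }
  })
})

test_that("sums of squares decompose the total exactly", {
  withr::with_seed(14, {
    tab <- simulate_analysis_frame(group_shift = 0.4)
    fit <- fit_mixed_anova(tab, "log_ttv")
    parts <- sum(fit$anova$ss) +
      fit$ms_participant * fit$df_participant +
      fit$ms_residual * fit$df_residual
    expect_lt(abs(parts - fit$ss_total), 1e-8)
  })
})

test_that("degenerate and unbalanced inputs are refused or flagged", {
  tab <- simulate_analysis_frame()
  tab$log_ttv <- 1
  expect_warning(fit <- fit_mixed_anova(tab, "log_ttv"), "no variance")
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$anova$F)))

  tab2 <- simulate_analysis_frame()[-1, ]
  expect_error(fit_mixed_anova(tab2, "log_ttv"), "unbalanced")
})

test_that("Tukey post-hocs match emmeans and basic expectations", {
  library(lmerTest)
  library(emmeans)
  withr::with_seed(23, {
    tab <- simulate_analysis_frame(
      group_shift = 0.3, condition_shift = c(AWS = -0.2, ANS = 0.2),
      vowel_shift = c(i = -0.25, ih = 0, eh = 0.05, ae = 0.15))
  })
  fit <- fit_mixed_anova(tab, "log_ttv")
  ph <- posthoc_pairwise(fit, "vowel")
  expect_equal(nrow(ph), 6) # 4 levels -> 6 contrasts
  expect_true(all(ph$p_adj >= ph$p_unadj - 1e-12))

  m <- lmer(log_ttv ~ group * condition * vowel + (1 | participant), data = tab)
  em <- summary(pairs(emmeans(m, "vowel")), adjust = "tukey")
  ord <- order(ph$contrast); em <- em[order(as.character(em$contrast)), ]
  expect_equal(gsub("ae|eh|ih|i", "", ph$contrast[ord]),
               gsub("ae|eh|ih|i", "", as.character(em$contrast)))
  expect_equal(ph$estimate[ord], em$estimate, tolerance = 1e-6)
  expect_equal(ph$se[ord], em$SE, tolerance = 1e-6)
  expect_equal(ph$p_adj[ord], em$p.value, tolerance = 1e-3)

  emg <- summary(pairs(emmeans(m, "group")), adjust = "tukey")
  phg <- posthoc_pairwise(fit, "group")
  expect_equal(phg$estimate[1], emg$estimate[1], tolerance = 1e-6)
  expect_equal(phg$se[1], emg$SE[1], tolerance = 1e-6)
  expect_equal(phg$df[1], 22)

  # identical level means -> adjusted p of 1: response ignores vowel entirely
  withr::with_seed(5, {
    base <- simulate_analysis_frame()
    key <- paste(base$participant, base$condition)
    vals <- stats::setNames(rnorm(length(unique(key))), unique(key))
    base$log_ttv <- vals[key]
  })
  fit0 <- fit_mixed_anova(base, "log_ttv")
  ph0 <- posthoc_pairwise(fit0, "vowel")
  expect_true(all(abs(ph0$estimate) < 1e-12))
  expect_true(all(ph0$p_adj > 0.9999))

  expect_equal(nrow(posthoc_pairwise(fit, "group_condition")), 6)
})

test_that("simple effects equal cell-mean differences exactly under balance", {
  withr::with_seed(6, {
    tab <- simulate_analysis_frame(condition_shift = c(AWS = -0.3, ANS = 0.3))
  })
  fit <- fit_mixed_anova(tab, "log_ttv")
  se <- simple_effects_condition_within_group(fit)
  expect_equal(nrow(se), 2)
  for (gr in c("AWS", "ANS")) {
    est <- mean(tab$log_ttv[tab$group == gr & tab$condition == "DAF"]) -
      mean(tab$log_ttv[tab$group == gr & tab$condition == "NAF"])
    expect_equal(se$estimate[grepl(gr, se$contrast)], est, tolerance = 1e-12)
  }
  expect_true(all(se$p_adj >= se$p_unadj))
})

test_that("null simple effects are rarely declared significant", {
  withr::with_seed(77, {
    any_sig <- replicate(400, {
      fit <- fit_mixed_anova(simulate_analysis_frame(), "log_ttv")
      any(simple_effects_condition_within_group(fit)$p_adj < 0.05)
    })
  })
  expect_lt(mean(any_sig), 0.09) # ~5% familywise under the null
})

test_that("group-by-condition power is monotone in the injected interaction", {
  withr::with_seed(55, {
    rates <- vapply(c(0, 0.2, 0.5), function(mag) {
      mean(replicate(150, {
        tab <- simulate_analysis_frame(
          condition_shift = c(AWS = -mag / 2, ANS = mag / 2))
        fit <- fit_mixed_anova(tab, "log_ttv")
        fit$anova$p[fit$anova$effect == "group:condition"] < 0.05
      }))
    }, 0)
  })
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.12)
  expect_gt(rates[3], 0.95)
})

test_that("WTV-TTV correlation matches closed forms and is calibrated", {
  # r = 1 when participant means are identical
  tab <- simulate_analysis_frame()
  tab$log_wtv <- tab$log_ttv
  out <- correlate_wtv_ttv(tab, "AWS", "NAF")
  expect_equal(out$r, 1)
  expect_equal(out$n, 12)

  # closed-form covariance ratio on a 5-point hand example
  x <- c(1, 2, 3, 4, 10); y <- c(2, 1, 4, 3, 8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab5 <- data.frame(
    participant = rep(sprintf("P%d", 1:5), each = 4),
    group = "AWS", condition = "NAF",
    vowel = rep(c("i", "ih", "eh", "ae"), 5),
    log_wtv = rep(x, each = 4), log_ttv = rep(y, each = 4))
  out <- correlate_wtv_ttv(tab5, "AWS", "NAF")
  expect_equal(out$r, r_hand, tolerance = 1e-12)

  const <- tab5; const$log_wtv <- 1
  expect_error(correlate_wtv_ttv(const, "AWS", "NAF"), "zero variance")

  # type-I calibration of the correlation test at n = 12 participants
  withr::with_seed(99, {
    rej <- replicate(4000, {
      w <- rnorm(12); t <- rnorm(12)
      cor.test(w, t)$p.value < 0.05
    })
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})
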