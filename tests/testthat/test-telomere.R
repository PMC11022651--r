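# MMqPCR: standard curves, quantities, ratios, normalizations, and the
# within-subjects ANOVA machinery with its independent oracles.

test_that("standard curve recovers slope and efficiency from perfect doubling", {
  std <- data.frame(target = "albumin", known_mass_ng = c(50, 50 / 3, 50 / 9),
                    cq = c(13.170, 14.755, 16.340))
  curve <- fit_standard_curve(std)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-3)
  expect_equal(curve$efficiency, 1.0, tolerance = 1e-3)
  expect_gt(curve$r2, 0.9999)
})

test_that("degenerate and underdetermined standard curves error", {
  flat <- data.frame(target = "telomere", known_mass_ng = c(50, 50 / 3, 50 / 9),
                     cq = c(20, 20, 20))
  expect_error(fit_standard_curve(flat), class = "orbitomics_curve_error")
  two <- data.frame(target = "telomere", known_mass_ng = c(50, 5),
                    cq = c(13, 16.3))
  expect_error(fit_standard_curve(two), class = "orbitomics_curve_error")
})

test_that("quantify inverts the fitted curve in closed form", {
  curve <- structure(list(target = "albumin", slope = -3.3, intercept = 18,
                          efficiency = 10^(1 / 3.3) - 1, r2 = 1, n_masses = 5),
                     class = "standard_curve")
  expect_equal(quantify(18, curve), 1.0)
  expect_equal(quantify(18 + curve$slope, curve), 10.0)
})

test_that("efficiency is recovered within 0.03 from noisy simulated plates", {
  errs <- vapply(1:100, function(i) {
    eff <- 0.9 + (i %% 11) / 100  # sweep 0.90 .. 1.00
    cfg <- sim_config(seed = 400 + i, qpcr_efficiency_t = eff,
                      qpcr_noise_sd = 0.05)
    plate <- simulate_qpcr_plate(c(S1 = 1), cfg)
    std <- plate[!is.na(plate$known_mass_ng) & plate$target == "telomere", ]
    abs(fit_standard_curve(std)$efficiency - eff)
  }, numeric(1))
  expect_lt(mean(errs), 0.03)
})

test_that("T/A ratios are exact without noise and within 5% at 0.05 Cq noise", {
  truths <- c(A = 0.5, B = 1, C = 1.5, D = 2)
  cfg0 <- sim_config(seed = 31, qpcr_noise_sd = 0)
  res0 <- telomere_quantify(simulate_qpcr_plate(truths, cfg0))
  got0 <- res0$ta_ratio[match(names(truths), res0$sample_id)]
  expect_equal(got0, unname(truths), tolerance = 1e-9)

  rel_errs <- vapply(1:30, function(i) {
    cfg <- sim_config(seed = 500 + i, qpcr_noise_sd = 0.05)
    res <- telomere_quantify(simulate_qpcr_plate(truths, cfg))
    got <- res$ta_ratio[match(names(truths), res$sample_id)]
    mean(abs(got - truths) / truths)
  }, numeric(1))
  expect_lt(mean(rel_errs), 0.05)

  expect_error(ta_ratio(-1, 1), "positive")
  expect_equal(ta_ratio(c(2, 4), c(2, 2)), c(1, 2))
})

test_that("plate normalization removes multiplicative batch effects", {
  cfg <- sim_config(seed = 41, qpcr_noise_sd = 0)
  p1 <- simulate_qpcr_plate(c(S1 = 1.4), cfg, plate_id = "P1", cq_shift = 0)
  p2 <- simulate_qpcr_plate(c(S1 = 1.4), cfg, plate_id = "P2", cq_shift = 0.8)
  res <- plate_normalize(telomere_quantify(rbind(p1, p2)))
  ref <- res[res$sample_id == "REF", ]
  expect_equal(ref$plate_normalized_ratio, rep(1, 2))
  shared <- res$plate_normalized_ratio[res$sample_id == "S1"]
  expect_lt(var(shared), 1e-9)

  no_ref <- res[res$sample_id != "REF", c("sample_id", "plate_id", "ta_ratio")]
  err <- expect_error(plate_normalize(no_ref), class = "orbitomics_plate_error")
  expect_match(conditionMessage(err), "P1")
})

test_that("phase normalization maps the baseline mean to 1", {
  d <- data.frame(subject = "C001",
                  phase = c("pre", "pre", "inflight"),
                  v = c(2, 2, 2.5))
  out <- phase_normalize(d, value = "v")
  expect_equal(out$fold_change, c(1, 1, 1.25))

  const <- data.frame(subject = rep(c("a", "b"), each = 3),
                      phase = rep(c("pre", "inflight", "r1"), 2),
                      v = 3)
  expect_true(all(phase_normalize(const, value = "v")$fold_change == 1))

  nobase <- data.frame(subject = "x", phase = "inflight", v = 1)
  expect_error(phase_normalize(nobase, value = "v"),
               class = "orbitomics_baseline_error")

  # prepost baseline includes recovery phases
  d2 <- data.frame(subject = "s", phase = c("pre", "recovery", "inflight"),
                   v = c(1, 3, 4))
  out2 <- phase_normalize(d2, value = "v", baseline = "prepost")
  expect_equal(out2$fold_change[3], 4 / 2)
})

test_that("an injected +30% in-flight effect shows up as a ~1.3 fold change", {
  fold <- vapply(1:100, function(i) {
    d <- simulate_mission_ratios(600 + i, inflight_effect = 1.3, noise_sd = 0.05)
    out <- phase_normalize(d)
    mean(out$fold_change[out$phase == "inflight"])
  }, numeric(1))
  expect_gt(mean(fold), 1.25)
  expect_lt(mean(fold), 1.35)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  # fixed 4-subject x 3-group table
  set.seed(11)
  d <- expand.grid(subject = paste0("s", 1:4), group = c("g1", "g2", "g3"),
                   stringsAsFactors = FALSE)
  d$value <- round(rnorm(12, 10, 2), 3)
  fit <- repeated_measures_anova(d)
  orc <- rm_anova_oracle(d$value, d$subject, d$group)
  expect_equal(fit$statistic, orc$f, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  expect_equal(fit$ms_error, orc$ms_error, tolerance = 1e-10)

  # cross-check against the standard within-subjects aov fit
  aov_fit <- summary(aov(value ~ group + Error(subject), data = d))
  aov_tab <- aov_fit[["Error: Within"]][[1]]
  expect_equal(fit$statistic, aov_tab["group", "F value"], tolerance = 1e-8)
  expect_equal(fit$p_value, aov_tab["group", "Pr(>F)"], tolerance = 1e-8)
})

test_that("ANOVA degenerate and identity cases behave", {
  d <- expand.grid(subject = paste0("s", 1:3), group = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$value <- 5
  fit <- repeated_measures_anova(d)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p_value, 1)

  # k = 2: F equals the squared paired t statistic
  set.seed(22)
  d$value <- rnorm(6)
  fit2 <- repeated_measures_anova(d)
  wide <- reshape(d, idvar = "subject", timevar = "group", direction = "wide")
  tt <- t.test(wide$value.a, wide$value.b, paired = TRUE)
  expect_equal(fit2$statistic, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(fit2$p_value, tt$p.value, tolerance = 1e-10)

  unb <- d[-1, ]
  expect_error(repeated_measures_anova(unb), class = "orbitomics_design_error")
})

test_that("ANOVA agrees with the oracle over random balanced tables", {
  for (i in 1:20) {
    set.seed(700 + i)
    n <- sample(3:6, 1); k <- sample(2:5, 1)
    d <- expand.grid(subject = paste0("s", 1:n), group = paste0("g", 1:k),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(n * k)
    fit <- repeated_measures_anova(d)
    orc <- rm_anova_oracle(d$value, d$subject, d$group)
    expect_equal(fit$statistic, orc$f, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("Tukey post hoc matches hand-computed q and the range-CDF oracle", {
  set.seed(33)
  d <- expand.grid(subject = paste0("s", 1:4), group = c("g1", "g2", "g3"),
                   stringsAsFactors = FALSE)
  d$value <- round(rnorm(12, 10, 2), 3)
  fit <- repeated_measures_anova(d)
  tk <- tukey_posthoc(fit)

  means <- colMeans(tapply(d$value, list(d$subject, d$group), mean))
  se <- sqrt(fit$ms_error / 4)
  for (r in seq_len(nrow(tk))) {
    q_hand <- abs(means[tk$group1[r]] - means[tk$group2[r]]) / se
    expect_equal(tk$q[r], unname(q_hand), tolerance = 1e-10)
    expect_equal(tk$p_adj[r], ptukey_oracle(tk$q[r], 3, fit$df_error),
                 tolerance = 1e-6)
  }

  # monotonicity: adjusted p >= the unadjusted pairwise p for k > 2
  p_unadj <- 2 * pt(-tk$q / sqrt(2), fit$df_error)
  expect_true(all(tk$p_adj >= p_unadj - 1e-12))
})

test_that("identical group means give Tukey p = 1", {
  d <- expand.grid(subject = paste0("s", 1:3), group = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$value <- rep(c(1, 2, 3), times = 3)  # subject effects only
  fit <- repeated_measures_anova(d)
  tk <- tukey_posthoc(fit)
  expect_true(all(tk$p_adj == 1))
})

test_that("full telomere analysis runs from wells to Tukey table", {
  subjects <- paste0("C00", 1:4)
  tps <- names(mission_phases())
  cfg_list <- lapply(seq_along(tps), function(i) {
    ratios <- setNames(rep(1.2, 4), paste(subjects, tps[i], sep = "_"))
    simulate_qpcr_plate(ratios, sim_config(seed = 800 + i, qpcr_noise_sd = 0.03),
                        plate_id = paste0("P", i))
  })
  wells <- do.call(rbind, cfg_list)
  sheet <- expand.grid(subject = subjects, timepoint = tps,
                       stringsAsFactors = FALSE)
  sheet$sample_id <- paste(sheet$subject, sheet$timepoint, sep = "_")
  ana <- telomere_analysis(wells, sheet)
  expect_s3_class(ana, "telomere_analysis")
  expect_equal(nrow(ana$results), 36)
  expect_equal(nrow(ana$tukey), 6)
  expect_true(all(abs(ana$results$fold_change - 1) < 0.2))
})
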