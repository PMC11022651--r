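# MMqPCR relative telomere length: standard curves, T/A ratios, plate and
# baseline normalization, repeated-measures ANOVA with Tukey post hoc.

#' Fit a qPCR standard curve for one target
#'
#' Ordinary least squares of Cq on log10(mass) over the standard-dilution
#' wells. Amplification efficiency is derived from the slope as
#' `10^(-1/slope) - 1` (slope -3.32 corresponds to perfect doubling,
#' efficiency 1).
#'
#' @param wells data frame of standard wells for a single target, with columns
#'   `cq` and `known_mass_ng` (non-missing).
#' @return Object of class `standard_curve`: `target, slope, intercept,
#'   efficiency, r2, n_masses`.
#' @examples
#' std <- data.frame(target = "albumin", known_mass_ng = c(50, 50/3, 50/9),
#'                   cq = c(13.170, 14.755, 16.340))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(wells) {
  w <- wells[!is.na(wells$known_mass_ng), , drop = FALSE]
  assert_that(nrow(w) > 0, "no standard wells supplied")
  target <- if ("target" %in% names(w)) unique(w$target) else "unknown"
  assert_that(length(target) == 1, "standard wells must be for a single target")
  masses <- unique(w$known_mass_ng)
  if (length(masses) < 3) {
    stop_orbit("standard curve needs >= 3 distinct masses, got ", length(masses),
               class = "orbitomics_curve_error")
  }
  fit <- stats::lm(cq ~ log10(known_mass_ng), data = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope >= 0 || abs(slope) < 0.5) {
    stop_orbit("degenerate standard curve (slope = ", format(slope), ")",
               class = "orbitomics_curve_error")
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noise-free fits are legitimate
  structure(list(target = target, slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1, r2 = r2,
                 n_masses = length(masses)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve [%s]: slope %.4f Cq/log10(ng), intercept %.3f,\n",
              x$target, x$slope, x$intercept))
  cat(sprintf("  efficiency %.3f, R^2 %.5f (%d dilution points)\n",
              x$efficiency, x$r2, x$n_masses))
  invisible(x)
}

#' Convert a Cq value to an ng-equivalent quantity via a standard curve
#'
#' `quantity = 10^((cq - intercept) / slope)`; a well with `cq == intercept`
#' corresponds to 1 ng.
#'
#' @param cq Cq value(s).
#' @param curve a [fit_standard_curve()] result.
#' @return Numeric quantity in ng-equivalents.
#' @export
quantify <- function(cq, curve) {
  assert_that(inherits(curve, "standard_curve"), "curve must be a standard_curve")
  10^((cq - curve$intercept) / curve$slope)
}

#' Telomere-to-albumin ratio
#'
#' Relative telomere length as the ratio of telomere to albumin (single-copy
#' gene) ng-equivalent quantities.
#'
#' @param t_quantity,a_quantity positive quantities.
#' @return `t_quantity / a_quantity` (vectorized).
#' @export
ta_ratio <- function(t_quantity, a_quantity) {
  assert_that(all(t_quantity > 0) && all(a_quantity > 0),
              "quantities must be positive")
  t_quantity / a_quantity
}

#' Aggregate replicate wells to one Cq per (sample, plate, target)
#'
#' Median of the replicate Cq values (robust to a single failed well); flags
#' any (sample, target) whose replicate SD exceeds `qc_sd` Cq. Requires at
#' least 2 surviving replicates.
#'
#' @param wells well data frame (`sample_id, plate_id, target, cq`, optional
#'   `known_mass_ng`).
#' @param qc_sd QC threshold on the replicate Cq standard deviation.
#' @return Data frame `sample_id, plate_id, target, cq, n_wells, cq_sd,
#'   qc_flag`.
#' @export
aggregate_replicates <- function(wells, qc_sd = 0.5) {
  key <- interaction(wells$sample_id, wells$plate_id, wells$target, drop = TRUE)
  parts <- split(wells, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(sample_id = p$sample_id[1], plate_id = p$plate_id[1],
               target = p$target[1], cq = stats::median(p$cq),
               n_wells = nrow(p),
               cq_sd = if (nrow(p) > 1) stats::sd(p$cq) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  assert_that(all(out$n_wells >= 2), "each (sample, target) needs >= 2 wells after QC")
  out$qc_flag <- !is.na(out$cq_sd) & out$cq_sd > qc_sd
  rownames(out) <- NULL
  out
}

#' Quantify T/A ratios for all unknown samples on a set of plates
#'
#' Per plate: fits separate telomere and albumin standard curves from that
#' plate's standard wells, aggregates replicate Cq (median), converts to
#' quantities against each target's own curve, and forms the T/A ratio.
#'
#' @param wells well table covering one or more plates (must include `STD`
#'   standards with `known_mass_ng` on each plate).
#' @param qc_sd replicate-SD QC threshold passed to [aggregate_replicates()].
#' @return Data frame of class `telomere_result`: `sample_id, plate_id,
#'   t_quantity, a_quantity, ta_ratio, qc_flag`.
#' @export
telomere_quantify <- function(wells, qc_sd = 0.5) {
  out <- do.call(rbind, lapply(split(wells, wells$plate_id), function(pw) {
    std <- pw[!is.na(pw$known_mass_ng), , drop = FALSE]
    curves <- lapply(split(std, std$target), fit_standard_curve)
    unk <- pw[is.na(pw$known_mass_ng), , drop = FALSE]
    agg <- aggregate_replicates(unk, qc_sd = qc_sd)
    wide <- merge(
      agg[agg$target == "telomere", c("sample_id", "plate_id", "cq", "qc_flag")],
      agg[agg$target == "albumin", c("sample_id", "plate_id", "cq", "qc_flag")],
      by = c("sample_id", "plate_id"), suffixes = c("_t", "_a")
    )
    data.frame(
      sample_id = wide$sample_id, plate_id = wide$plate_id,
      t_quantity = quantify(wide$cq_t, curves[["telomere"]]),
      a_quantity = quantify(wide$cq_a, curves[["albumin"]]),
      qc_flag = wide$qc_flag_t | wide$qc_flag_a,
      stringsAsFactors = FALSE
    )
  }))
  out$ta_ratio <- ta_ratio(out$t_quantity, out$a_quantity)
  rownames(out) <- NULL
  class(out) <- c("telomere_result", "data.frame")
  out
}

#' Normalize T/A ratios across plates against a shared reference sample
#'
#' Divides every sample's ratio by its plate's reference-sample ratio, so the
#' reference maps to 1.0 on every plate and multiplicative plate batch effects
#' cancel.
#'
#' @param results data frame with `sample_id, plate_id, ta_ratio`.
#' @param ref_sample reference sample id, present on every plate.
#' @return `results` with an added `plate_normalized_ratio` column.
#' @export
plate_normalize <- function(results, ref_sample = "REF") {
  out <- do.call(rbind, lapply(split(results, results$plate_id), function(p) {
    ref <- p$ta_ratio[p$sample_id == ref_sample]
    if (length(ref) == 0) {
      stop_orbit("reference sample '", ref_sample, "' missing on plate '",
                 p$plate_id[1], "'", class = "orbitomics_plate_error")
    }
    p$plate_normalized_ratio <- p$ta_ratio / mean(ref)
    p
  }))
  rownames(out) <- NULL
  out
}

#' Normalize per-subject values to the subject's baseline-phase mean
#'
#' Each measurement becomes a fold change versus the subject's mean over the
#' baseline phase; the baseline mean maps to 1.0. Baseline is the pre-flight
#' phase by default, or pre + recovery phases combined (`"prepost"`).
#'
#' @param results data frame with `subject, phase` and a `value` column.
#' @param value name of the value column.
#' @param baseline `"pre"` (default) or `"prepost"` (pre + r1 + recovery).
#' @param pre_phases,post_phases phase labels counted as pre- and post-flight.
#' @return `results` with an added `fold_change` column.
#' @export
phase_normalize <- function(results, value = "plate_normalized_ratio",
                            baseline = c("pre", "prepost"),
                            pre_phases = "pre", post_phases = c("r1", "recovery")) {
  baseline <- match.arg(baseline)
  base_phases <- if (baseline == "pre") pre_phases else c(pre_phases, post_phases)
  out <- do.call(rbind, lapply(split(results, results$subject), function(s) {
    base <- s[[value]][s$phase %in% base_phases]
    if (length(base) == 0) {
      stop_orbit("subject '", s$subject[1], "' has no baseline measurement",
                 class = "orbitomics_baseline_error")
    }
    s$fold_change <- s[[value]] / mean(base)
    s
  }))
  rownames(out) <- NULL
  out
}

#' Default mission phase grouping of sampling timepoints
#'
#' pre = L-92/L-44/L-3, inflight = FD1-FD3, r1 = R+1, recovery = R+45/R+82.
#'
#' @return Named character vector mapping timepoint label to phase.
#' @export
mission_phases <- function() {
  c("L-92" = "pre", "L-44" = "pre", "L-3" = "pre",
    "FD1" = "inflight", "FD2" = "inflight", "FD3" = "inflight",
    "R+1" = "r1", "R+45" = "recovery", "R+82" = "recovery")
}

#' One-way repeated-measures (within-subjects) ANOVA
#'
#' Classical sums-of-squares partition `SS_total = SS_subjects + SS_time +
#' SS_error` on a complete balanced table; replicate measurements within a
#' subject x group cell are aggregated to the cell mean first.
#' `F = MS_time / MS_error` with `(k-1, (k-1)(n-1))` degrees of freedom.
#' Sphericity is assumed (no Greenhouse-Geisser correction).
#'
#' @param data data frame.
#' @param value,subject,group column names of the measurement, the subject id
#'   and the within-subject grouping factor.
#' @return Object of class `rm_anova` with the ANOVA table, group means,
#'   `ms_error`, `df_error` and the per-group n.
#' @export
repeated_measures_anova <- function(data, value = "value", subject = "subject",
                                    group = "group") {
  cell <- stats::aggregate(data[[value]],
                           list(subject = data[[subject]], group = data[[group]]),
                           mean)
  names(cell)[3] <- "y"
  tab <- table(cell$subject, cell$group)
  if (any(tab != 1)) {
    stop_orbit("unbalanced design: every subject must be measured in every group",
               class = "orbitomics_design_error")
  }
  n <- length(unique(cell$subject))
  k <- length(unique(cell$group))
  assert_that(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 groups")
  grand <- mean(cell$y)
  subj_means <- tapply(cell$y, cell$subject, mean)
  grp_means <- tapply(cell$y, cell$group, mean)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_time <- n * sum((grp_means - grand)^2)
  ss_total <- sum((cell$y - grand)^2)
  ss_error <- ss_total - ss_subj - ss_time
  df_time <- k - 1
  df_error <- (k - 1) * (n - 1)
  ms_time <- ss_time / df_time
  ms_error <- ss_error / df_error
  if (ss_time <= .Machine$double.eps * max(1, ss_total)) {
    f <- 0; p <- 1
  } else if (ms_error <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_time / ms_error
    p <- stats::pf(f, df_time, df_error, lower.tail = FALSE)
  }
  table_df <- data.frame(
    term = c("time", "subjects", "error"),
    df = c(df_time, n - 1, df_error),
    sum_sq = c(ss_time, ss_subj, ss_error),
    mean_sq = c(ms_time, ss_subj / (n - 1), ms_error),
    statistic = c(f, NA, NA),
    p_value = c(p, NA, NA)
  )
  structure(list(table = table_df, group_means = grp_means, n_subjects = n,
                 k = k, ms_error = ms_error, df_error = df_error,
                 statistic = f, p_value = p),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$table$df[1], x$df_error, x$statistic, x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post hoc comparisons after a repeated-measures ANOVA
#'
#' Studentized-range statistic `q = |m_i - m_j| / sqrt(MS_error / n)` for every
#' group pair, with p-values from the studentized range distribution with
#' `(k, df_error)` parameters.
#'
#' @param fit an [repeated_measures_anova()] result.
#' @return Data frame `group1, group2, diff, q, p_adj`.
#' @export
tukey_posthoc <- function(fit) {
  assert_that(inherits(fit, "rm_anova"), "fit must be an rm_anova")
  gm <- fit$group_means
  groups <- names(gm)
  pairs <- utils::combn(length(groups), 2)
  se <- sqrt(fit$ms_error / fit$n_subjects)
  d <- abs(gm[pairs[1, ]] - gm[pairs[2, ]])
  if (se == 0) {
    q <- ifelse(d == 0, 0, Inf)
  } else {
    q <- d / se
  }
  p <- ifelse(is.infinite(q), 0,
              stats::ptukey(q, length(groups), fit$df_error, lower.tail = FALSE))
  data.frame(group1 = groups[pairs[1, ]], group2 = groups[pairs[2, ]],
             diff = unname(gm[pairs[1, ]] - gm[pairs[2, ]]),
             q = unname(q), p_adj = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full telomere analysis from raw wells to phase statistics
#'
#' Runs quantification, plate normalization, phase assignment, baseline
#' normalization, repeated-measures ANOVA over phases and the Tukey post hoc
#' in one call.
#'
#' @param wells multi-plate well table.
#' @param sample_sheet data frame `sample_id, subject, timepoint` mapping
#'   unknown samples to the mission grid.
#' @param phases named timepoint-to-phase map (default [mission_phases()]).
#' @param baseline baseline choice for [phase_normalize()].
#' @param ref_sample cross-plate reference sample id.
#' @param qc_sd replicate QC threshold.
#' @return List of class `telomere_analysis`: `results` (per-sample table),
#'   `anova`, `tukey`.
#' @export
telomere_analysis <- function(wells, sample_sheet, phases = mission_phases(),
                              baseline = "pre", ref_sample = "REF", qc_sd = 0.5) {
  res <- telomere_quantify(wells, qc_sd = qc_sd)
  res <- plate_normalize(res, ref_sample = ref_sample)
  res <- merge(res, sample_sheet, by = "sample_id")
  res$phase <- unname(phases[res$timepoint])
  assert_that(!anyNA(res$phase), "every timepoint must map to a phase")
  res <- phase_normalize(res, baseline = baseline)
  fit <- repeated_measures_anova(res, value = "fold_change",
                                 subject = "subject", group = "phase")
  structure(list(results = res, anova = fit, tukey = tukey_posthoc(fit)),
            class = "telomere_analysis")
}

#' @export
print.telomere_analysis <- function(x, ...) {
  cat("Telomere MMqPCR analysis:", nrow(x$results), "sample measurements\n")
  print(x$anova)
  cat("Tukey post hoc:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
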