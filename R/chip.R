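# Clonal hematopoiesis: UMI consensus counting, panel-of-normals noise model,
# Fisher/Bonferroni discovery, longitudinal pileup rescue, VAF trajectories
# and a VAF-stability test.

#' Collapse read-level base calls to UMI-family consensus counts
#'
#' One consensus call per UMI family by strict majority; families with a tied
#' majority or with fewer than `min_family` reads are discarded. The consensus
#' depth at a locus is the number of surviving families.
#'
#' @param calls data frame of read-level calls: `chrom, pos, umi, base`.
#' @param min_family minimum family size retained (default 2).
#' @return Data frame `chrom, pos, base, families`: surviving consensus calls
#'   per locus and base.
#' @export
umi_consensus <- function(calls, min_family = 2L) {
  assert_that(all(c("chrom", "pos", "umi", "base") %in% names(calls)),
              "calls needs chrom, pos, umi, base")
  fam <- interaction(calls$chrom, calls$pos, calls$umi, drop = TRUE, sep = "\r")
  tab <- table(fam, calls$base)
  size <- rowSums(tab)
  top <- apply(tab, 1, max)
  strict <- top * 2 > size            # strict majority rules out ties
  keep <- strict & size >= min_family
  if (!any(keep)) {
    return(data.frame(chrom = character(), pos = numeric(), base = character(),
                      families = integer(), stringsAsFactors = FALSE))
  }
  cons_base <- colnames(tab)[max.col(tab, ties.method = "first")][keep]
  first_of_level <- match(levels(fam), as.character(fam))
  fam_meta <- calls[first_of_level[keep], c("chrom", "pos"), drop = FALSE]
  agg <- stats::aggregate(list(families = rep(1L, sum(keep))),
                          list(chrom = fam_meta$chrom, pos = fam_meta$pos,
                               base = cons_base), sum)
  agg <- agg[order(agg$chrom, agg$pos, agg$base), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Pool normal-sample pileups into a panel-of-normals noise model
#'
#' Sums alt and depth per locus across all normal samples. Every normal must
#' cover the same locus set.
#'
#' @param normals pileup data frame for the normal samples
#'   (`sample_id, chrom, pos, ref, alt, alt_count, depth`).
#' @return Data frame of class `pon_model`: `chrom, pos, ref, alt, pooled_alt,
#'   pooled_depth, n_normals`.
#' @export
build_pon <- function(normals) {
  key <- paste(normals$chrom, normals$pos, sep = ":")
  per_sample <- split(key, normals$sample_id)
  ref_loci <- sort(unique(key))
  for (s in names(per_sample)) {
    if (!setequal(per_sample[[s]], ref_loci) ||
        length(per_sample[[s]]) != length(ref_loci)) {
      stop_orbit("normal sample '", s, "' does not cover the shared locus set",
                 class = "orbitomics_pon_error")
    }
  }
  agg <- stats::aggregate(
    cbind(pooled_alt = normals$alt_count, pooled_depth = normals$depth),
    by = list(chrom = normals$chrom, pos = normals$pos,
              ref = normals$ref, alt = normals$alt),
    FUN = sum
  )
  agg$n_normals <- length(per_sample)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("pon_model", "data.frame")
  agg
}

#' One-sided Fisher exact test for alt enrichment over the panel of normals
#'
#' Tests whether the sample's alt fraction exceeds the pooled panel-of-normals
#' background at the same locus. The one-sided (greater) Fisher exact p-value
#' on the 2x2 table `[(alt, ref)_sample; (alt, ref)_pon]` is the
#' hypergeometric upper tail, computed in closed form. Vectorized.
#'
#' @param alt,depth sample alt count and consensus depth.
#' @param pon_alt,pon_depth pooled panel alt count and depth.
#' @return One-sided p-value(s); `alt = 0` gives p = 1.
#' @export
fisher_noise_test <- function(alt, depth, pon_alt, pon_depth) {
  assert_that(all(alt >= 0 & alt <= depth), "alt must be in [0, depth]")
  assert_that(all(pon_alt >= 0 & pon_alt <= pon_depth),
              "pon_alt must be in [0, pon_depth]")
  # P(X >= alt), X ~ Hypergeom(total alt, total ref, draws = depth)
  stats::phyper(alt - 1, alt + pon_alt,
                (depth - alt) + (pon_depth - pon_alt),
                depth, lower.tail = FALSE)
}

#' Bonferroni multiple-testing classification
#'
#' `p_adj = min(1, m * p)`; a test passes when its adjusted p-value is below
#' `alpha`. The family size `m` is the number of (locus, sample) pairs tested
#' in the run, supplied explicitly.
#'
#' @param pvalues raw p-values.
#' @param alpha family-wise error target (default 0.05).
#' @param m family size (>= `length(pvalues)`); default `length(pvalues)`.
#' @return Data frame `p, p_adj, pass`.
#' @export
bonferroni_classify <- function(pvalues, alpha = 0.05, m = length(pvalues)) {
  assert_that(m >= length(pvalues), "family size m must be >= number of p-values")
  p_adj <- pmin(1, m * pvalues)
  data.frame(p = pvalues, p_adj = p_adj, pass = p_adj < alpha)
}

#' Longitudinal pileup rescue and VAF trajectories
#'
#' For every variant that passed discovery in at least one sample of a
#' subject, assembles its full timepoint trajectory: VAF (`alt/depth`), Wilson
#' 95% CI, and a per-timepoint rescue flag (nominal one-sided Fisher p <
#' `rescue_alpha` against the panel, no multiplicity correction at the rescue
#' stage). Timepoints without a pileup are emitted as absent rows, not errors.
#'
#' @param passing data frame of passing variants: `subject, chrom, pos`.
#' @param pileups all pileups for the subjects
#'   (`subject, timepoint, chrom, pos, ref, alt, alt_count, depth`).
#' @param pon [build_pon()] model.
#' @param timepoints timepoint labels defining the trajectory grid; default
#'   all timepoints present in `pileups`.
#' @param rescue_alpha nominal rescue threshold (default 0.05).
#' @return Data frame of class `vaf_trajectory`: one row per
#'   (subject, variant, timepoint) with `vaf, ci_low, ci_high, alt, depth,
#'   rescue_flag, present`.
#' @export
rescue_longitudinal <- function(passing, pileups, pon,
                                timepoints = unique(pileups$timepoint),
                                rescue_alpha = 0.05) {
  assert_that(nrow(passing) >= 1, "no passing variants to rescue")
  pon_key <- paste(pon$chrom, pon$pos, sep = ":")
  pile_key <- paste(pileups$subject, pileups$timepoint,
                    pileups$chrom, pileups$pos, sep = "|")
  rows <- list()
  for (i in seq_len(nrow(passing))) {
    v <- passing[i, ]
    pk <- match(paste(v$chrom, v$pos, sep = ":"), pon_key)
    assert_that(!is.na(pk), "passing variant absent from the panel of normals")
    for (tp in timepoints) {
      j <- match(paste(v$subject, tp, v$chrom, v$pos, sep = "|"), pile_key)
      if (is.na(j)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = v$subject, chrom = v$chrom, pos = v$pos, timepoint = tp,
          alt = NA_integer_, depth = NA_integer_, vaf = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_,
          rescue_flag = FALSE, present = FALSE, stringsAsFactors = FALSE)
        next
      }
      alt <- pileups$alt_count[j]; depth <- pileups$depth[j]
      ci <- wilson_ci(alt, depth)
      p <- fisher_noise_test(alt, depth, pon$pooled_alt[pk], pon$pooled_depth[pk])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = v$subject, chrom = v$chrom, pos = v$pos, timepoint = tp,
        alt = alt, depth = depth, vaf = alt / depth,
        ci_low = ci[1, "lower"], ci_high = ci[1, "upper"],
        rescue_flag = p < rescue_alpha, present = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vaf_trajectory", "data.frame")
  out
}

#' Two-stage CHIP variant discovery against a panel of normals
#'
#' Stage 1 (discovery): every (locus, sample) pileup is tested for alt
#' enrichment over the pooled panel with a one-sided Fisher exact test, and
#' Bonferroni-corrected over the whole family `m = loci x samples`. Stage 2
#' (rescue): variants passing in at least one sample are re-examined at every
#' timepoint of their subject at the nominal level. A variant enters the final
#' list if it passes Bonferroni in at least one sample.
#'
#' @param pileups subject pileups
#'   (`sample_id, subject, timepoint, chrom, pos, ref, alt, alt_count, depth`).
#' @param pon [build_pon()] model covering the same loci.
#' @param alpha Bonferroni family-wise level (default 0.05).
#' @param rescue_alpha nominal rescue level (default 0.05).
#' @return List of class `chip_result`: `tests` (all discovery tests),
#'   `final_variants` (unique subject x locus passing), `trajectories`
#'   ([rescue_longitudinal()] output, `NULL` when nothing passes), `m`.
#' @export
chip_call <- function(pileups, pon, alpha = 0.05, rescue_alpha = 0.05) {
  pon_key <- paste(pon$chrom, pon$pos, sep = ":")
  idx <- match(paste(pileups$chrom, pileups$pos, sep = ":"), pon_key)
  assert_that(!anyNA(idx), "every pileup locus must be in the panel of normals")
  p <- fisher_noise_test(pileups$alt_count, pileups$depth,
                         pon$pooled_alt[idx], pon$pooled_depth[idx])
  m <- length(unique(pon_key)) * length(unique(pileups$sample_id))
  cls <- bonferroni_classify(p, alpha = alpha, m = m)
  tests <- cbind(pileups[, c("sample_id", "subject", "timepoint",
                             "chrom", "pos", "ref", "alt")], cls)
  pass <- tests[tests$pass, , drop = FALSE]
  final <- unique(pass[, c("subject", "chrom", "pos", "ref", "alt")])
  traj <- NULL
  if (nrow(final) > 0) {
    traj <- rescue_longitudinal(final, pileups, pon, rescue_alpha = rescue_alpha)
  }
  structure(list(tests = tests, final_variants = final, trajectories = traj,
                 m = m, alpha = alpha),
            class = "chip_result")
}

#' @export
print.chip_result <- function(x, ...) {
  cat(sprintf("CHIP panel-of-normals screen: %d tests (Bonferroni m = %d, alpha = %g)\n",
              nrow(x$tests), x$m, x$alpha))
  cat(sprintf("  final variant list: %d subject x locus entries\n",
              nrow(x$final_variants)))
  invisible(x)
}

#' Test homogeneity of a variant's allele fraction across timepoints
#'
#' k-sample test of equal alt proportions from a 2 x k contingency table of
#' (alt, ref) counts per timepoint. Uses exact conditional enumeration
#' (multivariate hypergeometric, chi-square ordering) when the total alt count
#' is at most `exact_max`; otherwise the chi-square approximation with k-1
#' degrees of freedom.
#'
#' @param alt,depth integer vectors over timepoints (>= 2 with depth > 0).
#' @param exact_max largest total alt count for the exact path (default 10).
#' @return List of class `vaf_stability`: `statistic, p_value, df, method`.
#' @export
vaf_stability_test <- function(alt, depth, exact_max = 10) {
  keep <- depth > 0
  alt <- alt[keep]; depth <- depth[keep]
  k <- length(alt)
  if (k < 2) {
    stop_orbit("VAF stability needs >= 2 timepoints with depth > 0",
               class = "orbitomics_stability_error")
  }
  assert_that(all(alt >= 0 & alt <= depth), "alt must be in [0, depth]")
  total_alt <- sum(alt)
  total <- sum(depth)
  chi_stat <- function(a) {
    e_alt <- depth * total_alt / total
    e_ref <- depth * (total - total_alt) / total
    sum((a - e_alt)^2 / e_alt) + sum(((depth - a) - e_ref)^2 / e_ref)
  }
  if (total_alt == 0) {
    return(structure(list(statistic = 0, p_value = 1, df = k - 1,
                          method = "degenerate (no alt reads)"),
                     class = "vaf_stability"))
  }
  if (total_alt <= exact_max) {
    obs <- chi_stat(alt)
    tabs <- compositions_bounded(total_alt, depth)
    lchoose_total <- lchoose(total, total_alt)
    stats_all <- apply(tabs, 1, chi_stat)
    probs <- exp(rowSums(lchoose(matrix(depth, nrow(tabs), k, byrow = TRUE), tabs)) -
                   lchoose_total)
    p <- sum(probs[stats_all >= obs - 1e-9])
    return(structure(list(statistic = obs, p_value = min(1, p), df = k - 1,
                          method = "exact conditional enumeration"),
                     class = "vaf_stability"))
  }
  obs <- chi_stat(alt)
  structure(list(statistic = obs,
                 p_value = stats::pchisq(obs, k - 1, lower.tail = FALSE),
                 df = k - 1, method = "chi-square approximation"),
            class = "vaf_stability")
}

#' @export
print.vaf_stability <- function(x, ...) {
  cat(sprintf("VAF stability: chi-square = %.4f (df = %d), p = %.4g [%s]\n",
              x$statistic, x$df, x$p_value, x$method))
  invisible(x)
}

# All allocations of `total` alt reads into k cells bounded by per-cell depth.
compositions_bounded <- function(total, depth) {
  k <- length(depth)
  if (k == 1L) {
    if (total > depth[1]) return(matrix(numeric(0), ncol = 1))
    return(matrix(total, ncol = 1))
  }
  out <- list()
  for (x1 in 0:min(total, depth[1])) {
    rest <- compositions_bounded(total - x1, depth[-1])
    if (nrow(rest) > 0) out[[length(out) + 1L]] <- cbind(x1, rest)
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = k))
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  res
}
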