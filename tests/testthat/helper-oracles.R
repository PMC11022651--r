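# Independent oracles and small fixture builders shared across test files.
# Each oracle is coded from first principles, independently of the package
# implementation it checks.

# Full-assignment two-sample test oracle: enumerates every way of labelling
# n1 of the pooled observations as group A and computes the Mann-Whitney U
# (pair-counting with half-credit ties), then a two-sided p by doubling the
# smaller tail. Equivalent in distribution to the midrank rank-sum statistic.
perm_wilcoxon_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  obs <- u_stat(a, b)
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= obs + eps), mean(u_all >= obs - eps)))
}

# Hypergeometric upper-tail oracle for the one-sided Fisher test, by direct
# density summation.
fisher_oracle <- function(alt, depth, pon_alt, pon_depth) {
  total_alt <- alt + pon_alt
  total <- depth + pon_depth
  support <- alt:min(depth, total_alt)
  sum(stats::dhyper(support, total_alt, total - total_alt, depth))
}

# Analytic DFT of a sampled cosine: closed-form magnitude at each frequency
# index via geometric sums, no fft() call.
tone_dft_oracle <- function(period, amplitude, N, b, band = c(160, 210)) {
  x <- seq_len(N) - 1
  samples <- amplitude * cos(2 * pi * ((x + 0.5) * b - N * b / 2) / period)
  samples <- samples - mean(samples)
  k <- seq_len(floor(N / 2))
  in_band <- (N * b / k) >= band[1] & (N * b / k) <= band[2]
  mags <- vapply(k[in_band], function(kk) {
    Mod(sum(samples * exp(-2i * pi * kk * x / N)))
  }, numeric(1))
  2 * sqrt(sum(mags^2)) / N
}

# Brute-force repeated-measures sums of squares from the definition.
rm_anova_oracle <- function(y, subject, group) {
  cells <- tapply(y, list(subject, group), mean)
  n <- nrow(cells); k <- ncol(cells)
  grand <- mean(cells)
  ss_subj <- k * sum((rowMeans(cells) - grand)^2)
  ss_time <- n * sum((colMeans(cells) - grand)^2)
  ss_tot <- sum((cells - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_time
  f <- (ss_time / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(f = f, p = stats::pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE),
       ms_error = ss_err / ((k - 1) * (n - 1)))
}

# Studentized-range upper-tail probability by direct double numerical
# integration of its definition (range of k standard normals divided by an
# independent chi/sqrt(df) scale).
ptukey_oracle <- function(q, k, df) {
  p_range_le <- function(w) {
    f <- function(z) k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
  }
  dscale <- function(s) {
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  integrand <- Vectorize(function(s) p_range_le(q * s) * dscale(s))
  1 - stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
}

# Default tissue trio used across TSS tests.
test_tissues <- c("lymphoid", "myeloid", "hepatocyte")

# One end-to-end deconvolution of a simulated mixture; returns the rank and
# display value of `tissue`.
deconv_run <- function(seed, frac, tissue = "lymphoid", n_genes = 300,
                       n_fragments = 200000) {
  others <- setdiff(test_tissues, tissue)
  mix <- stats::setNames(c(frac, rep((1 - frac) / 2, length(others))),
                         c(tissue, others))
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_fragments = n_fragments,
                    mixture = mix)
  g <- synth_genome(n_genes, seed = seed)
  expr <- simulate_reference_expression(n_genes, test_tissues, seed = seed)
  fr <- simulate_cfdna_fragments(g, expr, mix, cfg)
  d <- deconvolve(fr, g$tss_table, expr)
  cc <- d$correlations
  c(rank = cc$rank[cc$tissue == tissue], display = cc$display[cc$tissue == tissue])
}

# Simulated mission T/A ratio table: 4 subjects, 9 timepoints, optional
# in-flight elongation, multiplicative between-replicate noise.
simulate_mission_ratios <- function(seed, inflight_effect = 1.0, noise_sd = 0.05,
                                    subjects = paste0("C00", 1:4)) {
  phases <- mission_phases()
  set.seed(seed)
  rows <- expand.grid(subject = subjects, timepoint = names(phases),
                      stringsAsFactors = FALSE)
  rows$phase <- unname(phases[rows$timepoint])
  eff <- ifelse(rows$phase == "inflight", inflight_effect, 1)
  rows$plate_normalized_ratio <- eff * exp(stats::rnorm(nrow(rows), 0, noise_sd))
  rows
}
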