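# CHIP statistics: UMI consensus, panel-of-normals pooling, the Fisher noise
# test against its hypergeometric oracle, rescue trajectories and the VAF
# stability test.

test_that("UMI consensus applies strict majority and family-size rules", {
  calls <- data.frame(
    chrom = "chr2", pos = 25235778,
    umi = c("u1", "u1", "u1", "u2", "u2", "u3"),
    base = c("G", "G", "G", "G", "C", "C"),
    stringsAsFactors = FALSE)
  cons <- umi_consensus(calls, min_family = 2)
  # u1 -> G (3/3); u2 tie -> discarded; u3 singleton -> discarded
  expect_equal(nrow(cons), 1)
  expect_equal(cons$base, "G")
  expect_equal(cons$families, 1L)

  cons1 <- umi_consensus(calls, min_family = 1)
  expect_equal(sum(cons1$families), 2)  # u1 (G) and u3 (C) survive
})

test_that("consensus error rate is quadratically suppressed", {
  n_fam <- 1e5
  set.seed(131)
  reads <- matrix(rbinom(3 * n_fam, 1, 1e-2), ncol = 3)  # 1 = errored base
  calls <- data.frame(
    chrom = "chrX", pos = 1,
    umi = rep(sprintf("u%06d", seq_len(n_fam)), each = 3),
    base = ifelse(as.vector(t(reads)) == 1, "T", "A"),
    stringsAsFactors = FALSE)
  cons <- umi_consensus(calls, min_family = 2)
  err <- sum(cons$families[cons$base == "T"]) / sum(cons$families)
  # binomial majority bound: P(Bin(3, 0.01) >= 2) ~ 2.98e-4
  expect_lte(err, 5e-4)
})

test_that("panel of normals pools counts exactly and validates locus coverage", {
  loci <- data.frame(chrom = "chr2", pos = c(100, 200), ref = "C", alt = "G",
                     stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 141, n_normals = 27, error_rate = 0)
  sp <- simulate_pileups(loci, "C001", "L-3", NULL, cfg)
  pon <- build_pon(sp$normals)
  expect_equal(pon$pooled_alt, c(0, 0))
  expect_equal(pon$pooled_depth, rep(27 * 15000, 2))
  expect_equal(unique(pon$n_normals), 27)

  dropped <- sp$normals[-1, ]
  expect_error(build_pon(dropped), class = "orbitomics_pon_error")
})

test_that("pooled panel alt rate matches the generator's error rate", {
  loci <- data.frame(chrom = "chr2", pos = 1:20 * 50, ref = "C", alt = "G",
                     stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 151, error_rate = 1e-3)
  sp <- simulate_pileups(loci, "C001", "L-3", NULL, cfg)
  pon <- build_pon(sp$normals)
  rate <- sum(pon$pooled_alt) / sum(pon$pooled_depth)
  n_trials <- sum(pon$pooled_depth)
  expect_lt(abs(rate - 1e-3), 3 * sqrt(1e-3 * (1 - 1e-3) / n_trials))
})

test_that("Fisher noise test equals the hypergeometric tail oracle", {
  expect_equal(fisher_noise_test(0, 10000, 10, 270000), 1.0)

  p <- fisher_noise_test(5, 10000, 10, 270000)
  expect_equal(p, fisher_oracle(5, 10000, 10, 270000), tolerance = 1e-12)

  # matched rates give a non-significant p
  expect_gt(fisher_noise_test(10, 10000, 270, 270000), 0.05)

  # property: random small tables, equality to the enumeration oracle and to
  # the standard one-sided Fisher exact test
  for (i in 1:60) {
    set.seed(1500 + i)
    depth <- sample(5:800, 1)
    pon_depth <- sample(5:1200, 1)
    alt <- rbinom(1, depth, runif(1, 0, 0.3))
    pon_alt <- rbinom(1, pon_depth, runif(1, 0, 0.3))
    got <- fisher_noise_test(alt, depth, pon_alt, pon_depth)
    expect_equal(got, fisher_oracle(alt, depth, pon_alt, pon_depth),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(alt, depth - alt, pon_alt, pon_depth - pon_alt),
                             nrow = 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(got, ft$p.value, tolerance = 1e-9)
  }
})

test_that("Bonferroni classification is capped, monotone and exact", {
  cls <- bonferroni_classify(c(0.001, 0.5), alpha = 0.05, m = 50)
  expect_equal(cls$p_adj, c(0.05, 1.0))
  expect_equal(cls$pass, c(FALSE, FALSE))  # 0.05 is not < 0.05

  set.seed(161)
  p <- runif(20) / 50  # keep m*p below the cap so ordering is informative
  cls2 <- bonferroni_classify(p, m = 40)
  expect_true(all(diff(cls2$p_adj[order(p)]) >= 0))
  expect_error(bonferroni_classify(p, m = 10), "family size")
})

test_that("rescue emits full trajectories with per-timepoint flags", {
  loci <- data.frame(chrom = "chr2", pos = 100, ref = "C", alt = "G",
                     stringsAsFactors = FALSE)
  tps <- c("L-44", "FD2", "R+45")
  piles <- data.frame(
    sample_id = paste0("C003_", tps), subject = "C003", timepoint = tps,
    chrom = "chr2", pos = 100, ref = "C", alt = "G",
    alt_count = c(60, 0, 0), depth = 15000, stringsAsFactors = FALSE)
  pon <- data.frame(chrom = "chr2", pos = 100, ref = "C", alt = "G",
                    pooled_alt = 400, pooled_depth = 405000, n_normals = 27)
  traj <- rescue_longitudinal(data.frame(subject = "C003", chrom = "chr2", pos = 100),
                              piles, pon, timepoints = tps)
  expect_equal(nrow(traj), 3)
  expect_equal(traj$rescue_flag, c(TRUE, FALSE, FALSE))
  expect_true(all(traj$present))
  expect_true(all(traj$ci_low <= traj$vaf & traj$vaf <= traj$ci_high,
                  na.rm = TRUE))

  # a missing timepoint becomes an absent row, not an error
  traj2 <- rescue_longitudinal(data.frame(subject = "C003", chrom = "chr2", pos = 100),
                               piles[-2, ], pon, timepoints = tps)
  expect_false(traj2$present[traj2$timepoint == "FD2"])
  expect_true(is.na(traj2$vaf[traj2$timepoint == "FD2"]))
})

test_that("a stable low-VAF clone is detected and tracked across timepoints", {
  loci <- data.frame(chrom = "chr2", pos = 1:10 * 100, ref = "C", alt = "G",
                     stringsAsFactors = FALSE)
  tps <- c("L-92", "L-44", "L-3", "R+1", "R+45", "R+82")
  clones <- data.frame(chrom = "chr2", pos = 100, subject = "C004",
                       timepoint = tps, vaf = 0.02, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 171, clones = clones)
  sp <- simulate_pileups(loci, c("C003", "C004"), tps, clones, cfg)
  res <- chip_call(sp$subjects, build_pon(sp$normals))
  expect_equal(nrow(res$final_variants), 1)
  expect_equal(res$final_variants$subject, "C004")
  expect_equal(res$final_variants$pos, 100)
  traj <- res$trajectories
  expect_equal(sum(traj$rescue_flag), 6)
  expect_lt(max(abs(traj$vaf - 0.02)), 0.01)
})

test_that("VAF stability test is exact for tiny counts and calibrated for large", {
  # identical counts at every timepoint: exact p = 1
  st <- vaf_stability_test(c(2, 2, 2), c(100, 100, 100))
  expect_equal(st$p_value, 1)
  expect_match(st$method, "exact")

  expect_error(vaf_stability_test(5, 100), class = "orbitomics_stability_error")

  # exact path agrees with an independent conditional enumeration for k = 2
  alt <- c(4, 1); depth <- c(60, 40)
  st2 <- vaf_stability_test(alt, depth)
  total_alt <- sum(alt); total <- sum(depth)
  chi <- function(a) {
    tab <- rbind(c(a, total_alt - a), c(depth[1] - a, depth[2] - (total_alt - a)))
    e <- outer(rowSums(tab), colSums(tab)) / total
    sum((tab - e)^2 / e)
  }
  support <- max(0, total_alt - depth[2]):min(depth[1], total_alt)
  probs <- dhyper(support, depth[1], depth[2], total_alt)
  p_oracle <- sum(probs[vapply(support, chi, numeric(1)) >= chi(alt[1]) - 1e-9])
  expect_equal(st2$p_value, p_oracle, tolerance = 1e-12)

  # a doubling VAF at deep coverage is rejected decisively
  st3 <- vaf_stability_test(c(750, 1500), c(15000, 15000))
  expect_lt(st3$p_value, 1e-10)
})

test_that("VAF estimates are unbiased across simulated trajectories", {
  set.seed(181)
  true_vaf <- 0.02
  depth <- 15000
  vafs <- rbinom(1000, depth, true_vaf) / depth
  se <- sqrt(true_vaf * (1 - true_vaf) / depth / 1000)
  expect_lt(abs(mean(vafs) - true_vaf), 3 * se)
})
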