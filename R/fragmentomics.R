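# cfDNA fragmentomics: fragment-size distributions, per-chromosome RPKM,
# cf-mtDNA enrichment, and exact nonparametric group comparisons.

#' Fragment-size histogram and summary statistics
#'
#' Counts fragment lengths into fixed-width bins over `[range[1], range[2])`;
#' out-of-range fragments are counted separately, not dropped silently. The
#' mode is the most frequent raw length (smallest on ties); mean and median
#' are computed on raw lengths.
#'
#' @param fragments a `fragment_set` data frame (or anything with a `length`
#'   column), or a bare numeric vector of lengths.
#' @param bin_width histogram bin width in bp (default 5).
#' @param range histogram range in bp, default `[50, 1000)`.
#' @return List of class `fragment_sizes`: `histogram` (data frame
#'   `bin_start, bin_end, count`), `summary` (`mode, mean, median`), and
#'   `n_below`/`n_above` out-of-range counts.
#' @export
fragment_size_distribution <- function(fragments, bin_width = 5, range = c(50, 1000)) {
  lens <- if (is.numeric(fragments)) fragments else fragments$length
  assert_that(length(lens) > 0, "no fragments supplied")
  assert_that(is_count(bin_width), "bin_width must be a positive integer")
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  in_range <- lens >= range[1] & lens < range[2]
  idx <- findInterval(lens[in_range], breaks)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tab <- table(lens)
  mode_len <- as.numeric(names(tab)[which.max(tab)])
  structure(list(
    histogram = data.frame(bin_start = breaks[-length(breaks)],
                           bin_end = breaks[-1], count = counts),
    summary = list(mode = mode_len, mean = mean(lens), median = stats::median(lens)),
    n_below = sum(lens < range[1]), n_above = sum(lens >= range[2]),
    n = length(lens)
  ), class = "fragment_sizes")
}

#' @export
print.fragment_sizes <- function(x, ...) {
  cat(sprintf("Fragment sizes: n = %d (mode %g, mean %.1f, median %g bp); %d below / %d above range\n",
              x$n, x$summary$mode, x$summary$mean, x$summary$median,
              x$n_below, x$n_above))
  invisible(x)
}

#' Per-chromosome RPKM
#'
#' `RPKM_c = count_c / (length_c / 1e3) / (total_reads / 1e6)`, normalizing
#' read counts by chromosome length and library size.
#'
#' @param chrom_counts data frame `chrom, length, count` (as produced by
#'   [simulate_chromosome_counts()] or [read_chrom_counts()]); total reads are
#'   taken from the `total_reads` attribute if present, else the count sum.
#' @return The input with an added `rpkm` column.
#' @export
rpkm <- function(chrom_counts) {
  assert_that(all(c("chrom", "length", "count") %in% names(chrom_counts)),
              "chrom_counts needs chrom, length, count")
  if (any(chrom_counts$length <= 0)) {
    stop_orbit("zero-length chromosome in RPKM input", class = "orbitomics_rpkm_error")
  }
  total <- attr(chrom_counts, "total_reads")
  if (is.null(total)) total <- sum(chrom_counts$count)
  assert_that(total > 0, "total reads must be positive")
  chrom_counts$rpkm <- chrom_counts$count / (chrom_counts$length / 1e3) / (total / 1e6)
  chrom_counts
}

#' Cell-free mitochondrial DNA enrichment
#'
#' Ratio of chrM RPKM to the median autosomal RPKM (sex chromosomes are kept
#' in the table but excluded from the denominator).
#'
#' @param rpkm_table output of [rpkm()] containing a `chrM` row.
#' @return Single numeric enrichment ratio.
#' @export
mt_enrichment <- function(rpkm_table) {
  assert_that("rpkm" %in% names(rpkm_table), "input must contain an rpkm column")
  mt <- rpkm_table$rpkm[rpkm_table$chrom == "chrM"]
  assert_that(length(mt) == 1, "chrM must be present exactly once")
  auto <- rpkm_table$rpkm[!rpkm_table$chrom %in% c("chrM", "chrX", "chrY")]
  if (length(auto) == 0) {
    stop_orbit("no autosomes available for the enrichment denominator",
               class = "orbitomics_rpkm_error")
  }
  mt / stats::median(auto)
}

# Midranks of the pooled sample; ties get the average rank.
midranks <- function(x) rank(x, ties.method = "average")

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Exact two-sided p-value by complete enumeration of group assignments
#' (midranks under ties) when `n1 + n2 <= exact_max`; otherwise the normal
#' approximation with tie-corrected variance. The two-sided exact p is
#' `min(1, 2 * min(P(T <= t), P(T >= t)))` for the rank-sum statistic T of the
#' first group.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param exact_max largest pooled size for which the exact enumeration is
#'   used (default 12).
#' @return List of class `wilcoxon_compare`: `statistic` (rank sum of `a`),
#'   `p_value`, `method`.
#' @export
wilcoxon_compare <- function(a, b, exact_max = 12) {
  n1 <- length(a); n2 <- length(b)
  assert_that(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  pooled <- c(a, b)
  r <- midranks(pooled)
  w <- sum(r[seq_len(n1)])
  n <- n1 + n2
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    t_all <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p_le <- mean(t_all <= w + eps)
    p_ge <- mean(t_all >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration (midranks)"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(pooled)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "wilcoxon_compare")
}

#' @export
print.wilcoxon_compare <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (n1 = %d, n2 = %d): W = %g, p = %.4g [%s]\n",
              x$n1, x$n2, x$statistic, x$p_value, x$method))
  invisible(x)
}
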