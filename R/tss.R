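# Tissue-of-origin deconvolution of cfDNA: TSS coverage profiles,
# neighborhood normalization, Fourier nucleosome-periodicity scoring,
# correlation against tissue expression references, and Ward clustering.

#' Binned cfDNA coverage profiles around transcription start sites
#'
#' For every gene, counts how many fragments overlap each bin of the window
#' `[tss - W, tss + W)`. A fragment contributes to every bin its interval
#' overlaps. Minus-strand profiles are reversed so that index order is always
#' 5' to 3' (downstream of the TSS at high indices). Genes with fewer than
#' `low_cov_floor` overlapping fragments are flagged low-coverage.
#'
#' @param fragments fragment data frame (`chrom, start, end`, 0-based
#'   half-open).
#' @param tss_table data frame `gene, chrom, tss, strand`.
#' @param W window half-width in bp (must be a multiple of `b`).
#' @param b bin width in bp.
#' @param low_cov_floor minimum overlapping fragments per gene.
#' @return Object of class `tss_profiles`: `profiles` (gene x bin matrix),
#'   `n_fragments` (per gene), `low_coverage` (logical per gene), `W`, `b`.
#' @export
tss_coverage <- function(fragments, tss_table, W = 1000L, b = 10L,
                         low_cov_floor = 20L) {
  assert_that(nrow(tss_table) > 0, "tss_table is empty")
  if (W %% b != 0) {
    stop_orbit("window half-width W must be a multiple of bin width b",
               class = "orbitomics_window_error")
  }
  n_bins <- as.integer(2 * W / b)
  n_genes <- nrow(tss_table)
  profiles <- matrix(0, nrow = n_genes, ncol = n_bins,
                     dimnames = list(tss_table$gene, NULL))
  n_frag <- integer(n_genes)
  by_chrom <- split(seq_len(nrow(fragments)), fragments$chrom)
  for (g in seq_len(n_genes)) {
    idx <- by_chrom[[tss_table$chrom[g]]]
    if (is.null(idx)) next
    t0 <- tss_table$tss[g]
    lo <- t0 - W; hi <- t0 + W
    s <- fragments$start[idx]; e <- fragments$end[idx]
    keep <- s < hi & e > lo
    if (!any(keep)) next
    s <- pmax(s[keep], lo); e <- pmin(e[keep], hi)
    i0 <- floor((s - lo) / b)                  # first overlapped bin (0-based)
    i1 <- floor((e - 1 - lo) / b)              # last overlapped bin
    bins <- sequence(i1 - i0 + 1, from = i0 + 1)
    prof <- tabulate(bins, nbins = n_bins)
    if (tss_table$strand[g] == "-") prof <- rev(prof)
    profiles[g, ] <- prof
    n_frag[g] <- sum(keep)
  }
  structure(list(profiles = profiles, n_fragments = n_frag,
                 low_coverage = n_frag < low_cov_floor,
                 W = W, b = b, tss_table = tss_table),
            class = "tss_profiles")
}

#' Neighborhood-normalize a TSS coverage profile
#'
#' Divides each bin by the window's own mean bin coverage, so the normalized
#' vector has mean 1 and is invariant to overall sequencing depth. The
#' normalization is local to the genomic neighborhood of the TSS; no
#' genome-wide background track is needed.
#'
#' @param profile numeric coverage vector.
#' @return Normalized vector with mean exactly 1.
#' @export
normalize_profile <- function(profile) {
  m <- mean(profile)
  if (!is.finite(m) || m <= 0) {
    stop_orbit("zero-mean (low-coverage) profile cannot be normalized",
               class = "orbitomics_lowcov_error")
  }
  profile / m
}

#' Nucleosome-band Fourier periodicity amplitude
#'
#' Discrete Fourier transform of the mean-normalized profile minus 1. The
#' amplitude is the band energy `(2/N) * sqrt(sum_band |X_k|^2)` over
#' frequency indices k whose period `N*b/k` lies inside `band`; for a pure
#' cosine of amplitude A at an integer cycle count inside the band this equals
#' A exactly, and spectral leakage of near-band tones is captured by summing
#' energy over the whole band.
#'
#' @param profile normalized profile (mean 1).
#' @param b bin width in bp.
#' @param band nucleosome period band in bp, default `[160, 210]`.
#' @return Single numeric amplitude (>= 0).
#' @export
periodicity_score <- function(profile, b = 10, band = c(160, 210)) {
  n <- length(profile)
  k <- seq_len(floor(n / 2))
  periods <- n * b / k
  in_band <- periods >= band[1] & periods <= band[2]
  if (!any(in_band)) {
    stop_orbit("no integer frequency falls inside the period band",
               class = "orbitomics_band_error")
  }
  x <- stats::fft(profile - mean(profile))
  mags <- Mod(x[k[in_band] + 1L])
  2 * sqrt(sum(mags^2)) / n
}

#' Score nucleosome periodicity for all genes of a profile set
#'
#' Normalizes each non-low-coverage profile and computes its nucleosome-band
#' amplitude.
#'
#' @param prof a [tss_coverage()] result.
#' @param band period band in bp.
#' @return Data frame `gene, amplitude, coverage_mean, n_fragments,
#'   low_coverage` (amplitude `NA` for low-coverage genes).
#' @export
periodicity_scores <- function(prof, band = c(160, 210)) {
  assert_that(inherits(prof, "tss_profiles"), "prof must be a tss_profiles")
  n_genes <- nrow(prof$profiles)
  amp <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    if (prof$low_coverage[g]) next
    amp[g] <- periodicity_score(normalize_profile(prof$profiles[g, ]),
                                b = prof$b, band = band)
  }
  data.frame(gene = rownames(prof$profiles), amplitude = amp,
             coverage_mean = rowMeans(prof$profiles),
             n_fragments = prof$n_fragments,
             low_coverage = prof$low_coverage,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate per-gene periodicity with tissue expression references
#'
#' Pearson correlation, across genes shared between the score table and the
#' reference matrix (low-coverage genes excluded), between the amplitude
#' vector and each tissue's `log(expression + 1)`. Because expressed genes of
#' a contributing tissue lose periodicity, the contributing tissue's r is
#' negative; the display value is `-r`, and tissues are ranked by display
#' value descending.
#'
#' @param scores data frame from [periodicity_scores()].
#' @param expression tissue x gene reference matrix.
#' @param min_genes minimum shared genes required (default 10).
#' @return Data frame of class `deconvolution_cor`: `tissue, pearson_r,
#'   display, rank`, sorted by rank.
#' @export
correlate_expression <- function(scores, expression, min_genes = 10) {
  ok <- scores[!scores$low_coverage & !is.na(scores$amplitude), , drop = FALSE]
  shared <- intersect(ok$gene, colnames(expression))
  if (length(shared) < min_genes) {
    stop_orbit("fewer than ", min_genes, " genes shared after low-coverage exclusion",
               class = "orbitomics_shared_error")
  }
  amp <- ok$amplitude[match(shared, ok$gene)]
  if (stats::sd(amp) == 0) {
    stop_orbit("zero-variance amplitude vector: correlation undefined",
               class = "orbitomics_variance_error")
  }
  r <- apply(log(expression[, shared, drop = FALSE] + 1), 1,
             function(e) stats::cor(amp, e))
  out <- data.frame(tissue = rownames(expression), pearson_r = unname(r),
                    display = -unname(r), stringsAsFactors = FALSE)
  out <- out[order(-out$display), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("deconvolution_cor", "data.frame")
  out
}

#' Ward clustering of a sample-by-tissue display matrix
#'
#' Agglomerative Ward linkage (`ward.D2`) on Euclidean distances between the
#' chosen margin's vectors. Leaf order is deterministic for a given input
#' (ties broken by input order by the linkage algorithm).
#'
#' @param mat numeric matrix (e.g. samples x tissues of display values).
#' @param margin `"columns"` (default: cluster tissues) or `"rows"`.
#' @return An object of class `hclust`.
#' @export
cluster_result <- function(mat, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  assert_that(!anyNA(mat), "clustering input must not contain NA/NaN")
  m <- if (margin == "columns") t(mat) else mat
  assert_that(nrow(m) >= 2, "need >= 2 items to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Tissue-of-origin deconvolution of a cfDNA fragment set
#'
#' Composition of the footprinting stages: TSS coverage, neighborhood
#' normalization, nucleosome-band Fourier scoring, and correlation ranking
#' against a tissue (or per-sample pseudo-bulk) expression reference.
#'
#' @param fragments fragment data frame.
#' @param tss_table TSS annotation (`gene, chrom, tss, strand`).
#' @param expression tissue x gene reference matrix.
#' @param W,b window half-width and bin width in bp.
#' @param band nucleosome period band in bp.
#' @param low_cov_floor minimum fragments per gene.
#' @return Object of class `deconvolution`: `correlations` (ranked tissue
#'   table), `scores` (per-gene), and the parameters used.
#' @export
deconvolve <- function(fragments, tss_table, expression, W = 1000L, b = 10L,
                       band = c(160, 210), low_cov_floor = 20L) {
  prof <- tss_coverage(fragments, tss_table, W = W, b = b,
                       low_cov_floor = low_cov_floor)
  scores <- periodicity_scores(prof, band = band)
  cors <- correlate_expression(scores, expression)
  structure(list(correlations = cors, scores = scores,
                 params = list(W = W, b = b, band = band,
                               low_cov_floor = low_cov_floor)),
            class = "deconvolution")
}

#' @export
print.deconvolution <- function(x, ...) {
  cat("cfDNA tissue-of-origin deconvolution\n")
  cat(sprintf("  %d genes scored (%d low-coverage excluded)\n",
              nrow(x$scores), sum(x$scores$low_coverage)))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Average deconvolution display values over technical replicates
#'
#' The per-tissue display value of a replicate group is the arithmetic mean of
#' the per-replicate display values.
#'
#' @param results list of `deconvolution` objects (technical replicates).
#' @return Data frame `tissue, display, rank` averaged over replicates.
#' @export
average_replicates <- function(results) {
  assert_that(length(results) >= 1, "no replicates supplied")
  tabs <- lapply(results, function(r) {
    d <- r$correlations
    d[order(d$tissue), c("tissue", "display")]
  })
  out <- tabs[[1]]
  if (length(tabs) > 1) {
    for (t in tabs[-1]) out$display <- out$display + t$display
    out$display <- out$display / length(tabs)
  }
  out <- out[order(-out$display), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
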