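# Synthetic-data generators. Every input the analysis modules consume can be
# produced here with the statistical structure those analyses assume, so the
# whole pipeline is testable without mission sequencing data.

#' Simulation configuration
#'
#' Bundles and validates the parameters shared by the generators. Defaults
#' describe the study conditions the pipeline is built for: cell-free DNA with
#' mono-nucleosome fragments (~167 bp), nucleosome phasing with ~190 bp period,
#' deep targeted pileups at 15,000x consensus depth against a panel of 27
#' normals, and monochrome multiplex qPCR plates run in triplicate.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes in the synthetic genome/reference.
#' @param tissues character vector of tissue names.
#' @param mixture named numeric vector of tissue fractions (must sum to 1).
#' @param n_fragments number of cfDNA fragments to emit.
#' @param frag_len_mean,frag_len_sd fragment length distribution (bp); lengths
#'   are truncated below at 50 bp.
#' @param nucleosome_period nucleosome phasing period in bp.
#' @param phasing_amplitude_max maximum phasing/depletion amplitude in `[0, 1]`;
#'   0 gives statistically flat coverage around every TSS.
#' @param window half-width (bp) of the TSS window fragments are placed in.
#' @param error_rate per-base consensus substitution probability in `[0, 0.1]`.
#' @param depth consensus reads per locus for pileups.
#' @param n_normals number of panel-of-normals samples (default 27).
#' @param clones data frame of injected clones with columns
#'   `chrom, pos, subject, timepoint, vaf` (one row per carried timepoint), or
#'   `NULL` for none.
#' @param qpcr_efficiency_t,qpcr_efficiency_a amplification efficiencies of the
#'   telomere and albumin targets, each in `(0.5, 1.1]`.
#' @param qpcr_intercept_t,qpcr_intercept_a standard-curve intercepts (Cq at
#'   1 ng).
#' @param qpcr_noise_sd per-well Cq noise standard deviation.
#' @param mt_fraction fraction of reads originating from chrM, in `[0, 1)`.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 60, n_fragments = 5000)
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       tissues = c("lymphoid", "myeloid", "hepatocyte"),
                       mixture = NULL,
                       n_fragments = 200000L,
                       frag_len_mean = 167,
                       frag_len_sd = 10,
                       nucleosome_period = 190,
                       phasing_amplitude_max = 0.6,
                       window = 1000L,
                       error_rate = 1e-3,
                       depth = 15000L,
                       n_normals = 27L,
                       clones = NULL,
                       qpcr_efficiency_t = 0.9,
                       qpcr_efficiency_a = 0.9,
                       qpcr_intercept_t = 18.5,
                       qpcr_intercept_a = 16.0,
                       qpcr_noise_sd = 0.05,
                       mt_fraction = 0.005) {
  if (is.null(mixture)) {
    mixture <- stats::setNames(rep(1 / length(tissues), length(tissues)), tissues)
  }
  assert_that(is_count(n_genes) && n_genes >= 10, "n_genes must be a count >= 10")
  assert_that(length(tissues) >= 2, "at least 2 tissues required")
  assert_that(all(mixture >= 0), "mixture fractions must be nonnegative")
  assert_that(abs(sum(mixture) - 1) <= 1e-9, "mixture fractions must sum to 1")
  assert_that(all(names(mixture) %in% tissues), "mixture names must be tissues")
  assert_that(is_count(n_fragments), "n_fragments must be a positive count")
  assert_that(error_rate >= 0 && error_rate <= 0.1, "error_rate must be in [0, 0.1]")
  assert_that(phasing_amplitude_max >= 0 && phasing_amplitude_max <= 1,
              "phasing_amplitude_max must be in [0, 1]")
  assert_that(is_count(depth), "depth must be a positive count")
  assert_that(is_count(n_normals), "n_normals must be a positive count")
  assert_that(mt_fraction >= 0 && mt_fraction < 1, "mt_fraction must be in [0, 1)")
  for (e in c(qpcr_efficiency_t, qpcr_efficiency_a)) {
    assert_that(e > 0.5 && e <= 1.1, "qPCR efficiencies must be in (0.5, 1.1]")
  }
  if (!is.null(clones)) {
    assert_that(is.data.frame(clones) &&
                  all(c("chrom", "pos", "subject", "timepoint", "vaf") %in% names(clones)),
                "clones must have columns chrom, pos, subject, timepoint, vaf")
    assert_that(all(clones$vaf >= 0 & clones$vaf <= 0.5), "clone VAFs must be in [0, 0.5]")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes), tissues = tissues,
    mixture = mixture, n_fragments = as.integer(n_fragments),
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    nucleosome_period = nucleosome_period,
    phasing_amplitude_max = phasing_amplitude_max, window = as.integer(window),
    error_rate = error_rate, depth = as.integer(depth),
    n_normals = as.integer(n_normals), clones = clones,
    qpcr_efficiency_t = qpcr_efficiency_t, qpcr_efficiency_a = qpcr_efficiency_a,
    qpcr_intercept_t = qpcr_intercept_t, qpcr_intercept_a = qpcr_intercept_a,
    qpcr_noise_sd = qpcr_noise_sd, mt_fraction = mt_fraction
  ), class = "sim_config")
}

#' Build a small synthetic genome with a TSS annotation table
#'
#' A handful of autosome-like chromosomes (1-10 Mb) plus chrM at its true
#' 16,569 bp. TSS positions are placed away from chromosome ends so that full
#' fragment windows always fit. Coordinates are 0-based half-open (BED
#' convention) throughout the generator.
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named vector of non-mitochondrial chromosome lengths;
#'   chrM is always appended.
#' @param seed RNG seed.
#' @param margin minimum distance (bp) between a TSS and a chromosome end.
#' @return List of class `synthetic_genome` with elements `chromosomes` (named
#'   lengths, including chrM) and `tss_table` (gene, chrom, tss, strand).
#' @examples
#' g <- synth_genome(n_genes = 30, seed = 1)
#' @export
synth_genome <- function(n_genes = 300L,
                         chrom_lengths = c(chr1 = 5e6, chr2 = 4e6, chr3 = 3e6, chr4 = 2e6),
                         seed = 1L,
                         margin = 10000L) {
  assert_that(is_count(n_genes), "n_genes must be a positive count")
  assert_that(all(chrom_lengths > 2 * margin), "chromosomes must exceed 2*margin")
  chroms <- c(chrom_lengths, chrM = 16569)
  with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                    prob = chrom_lengths / sum(chrom_lengths))
    tss <- vapply(chrom, function(cn) {
      floor(stats::runif(1, margin, chrom_lengths[[cn]] - margin))
    }, numeric(1))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss_table <- data.frame(
      gene = sprintf("G%04d", seq_len(n_genes)),
      chrom = chrom, tss = as.numeric(tss), strand = strand,
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(chromosomes = chroms, tss_table = tss_table),
              class = "synthetic_genome")
  })
}

#' Simulate a tissue-by-gene expression reference matrix
#'
#' Emulates a per-tissue expression reference (as retrieved from a proteome or
#' transcriptome atlas): each tissue gets a designated block of marker genes
#' with high (shifted log-normal) expression, all other genes are low
#' background.
#'
#' @param n_genes number of genes (>= 10, and >= number of tissues).
#' @param tissues character vector of >= 2 tissue names.
#' @param seed RNG seed.
#' @param marker_meanlog,background_meanlog log-normal location parameters for
#'   marker and background expression.
#' @param sdlog log-normal scale parameter.
#' @return A tissue x gene numeric matrix with a `markers` attribute giving the
#'   gene ids of each tissue's marker block.
#' @examples
#' expr <- simulate_reference_expression(60, c("liver", "blood"), seed = 7)
#' @export
simulate_reference_expression <- function(n_genes, tissues, seed = 1L,
                                          marker_meanlog = 3, background_meanlog = 0,
                                          sdlog = 0.5) {
  assert_that(is_count(n_genes) && n_genes >= 10, "n_genes must be a count >= 10")
  assert_that(length(tissues) >= 2, "need at least 2 tissues")
  assert_that(n_genes >= length(tissues), "fewer genes than tissues")
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_t <- length(tissues)
  block <- max(1L, n_genes %/% (2L * n_t))  # half the genes are markers overall
  with_seed(seed, {
    mat <- matrix(stats::rlnorm(n_t * n_genes, background_meanlog, sdlog),
                  nrow = n_t, dimnames = list(tissues, genes))
    markers <- vector("list", n_t)
    names(markers) <- tissues
    for (i in seq_len(n_t)) {
      idx <- ((i - 1L) * block + 1L):(i * block)
      mat[i, idx] <- stats::rlnorm(block, marker_meanlog, sdlog)
      markers[[i]] <- genes[idx]
    }
    attr(mat, "markers") <- markers
    mat
  })
}

# Rank-normalize to [0, 1] (ties averaged); maps any monotone scale to a
# comparable amplitude scale without distributional assumptions.
rank_unit <- function(x) {
  n <- length(x)
  if (n == 1L) return(0.5)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Simulate cell-free DNA fragments with TSS nucleosome footprints
#'
#' Inverse model of TSS coverage-depletion analysis: fragment midpoints around
#' each TSS follow intensity
#' `(1 + a_g cos(2*pi*d/period)) * (1 - c_g exp(-d^2 / (2*75^2)))`
#' where `a_g = amp_max * (1 - e_g)` (phasing, strong at silent genes) and
#' `c_g = amp_max * e_g` (central depletion, strong at expressed genes), with
#' `e_g` the rank-normalized mixture-weighted expression of gene g. Expressed
#' genes of contributing tissues thus show a depleted, weakly phased footprint;
#' silent genes show strong nucleosomal phasing. Fragment lengths are drawn
#' from a normal truncated below at 50 bp; minus-strand genes are mirrored.
#'
#' @param genome a `synthetic_genome`.
#' @param expression tissue x gene reference matrix.
#' @param mixture named tissue fractions summing to 1.
#' @param config a [sim_config()].
#' @return Data frame of class `fragment_set`: `chrom, start, end, length`
#'   (0-based half-open), with the source gene as attribute `gene`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 30, n_fragments = 2000)
#' g <- synth_genome(30, seed = 1)
#' expr <- simulate_reference_expression(30, cfg$tissues, seed = 1)
#' fr <- simulate_cfdna_fragments(g, expr, cfg$mixture, cfg)
#' @export
simulate_cfdna_fragments <- function(genome, expression, mixture, config) {
  assert_that(abs(sum(mixture) - 1) <= 1e-9, "mixture must sum to 1")
  assert_that(all(names(mixture) %in% rownames(expression)),
              "mixture tissues must be a subset of expression tissues")
  tss <- genome$tss_table
  genes <- intersect(tss$gene, colnames(expression))
  assert_that(length(genes) >= 1, "no genes shared between genome and expression")
  tss <- tss[tss$gene %in% genes, , drop = FALSE]
  n_genes <- nrow(tss)

  w_expr <- as.numeric(mixture[rownames(expression)] %*% expression[, tss$gene, drop = FALSE])
  e_g <- rank_unit(w_expr)
  amp <- config$phasing_amplitude_max
  a_g <- amp * (1 - e_g)
  c_g <- amp * e_g

  W <- config$window
  d_grid <- seq(-W, W)
  phase_base <- cos(2 * pi * d_grid / config$nucleosome_period)
  depl_base <- exp(-d_grid^2 / (2 * 75^2))

  with_seed(config$seed, {
    gene_of <- sample.int(n_genes, config$n_fragments, replace = TRUE)
    n_per <- tabulate(gene_of, n_genes)
    d <- integer(config$n_fragments)
    pos_in <- order(gene_of)
    offset <- 0L
    for (g in seq_len(n_genes)) {
      ng <- n_per[g]
      if (ng == 0L) next
      wgt <- (1 + a_g[g] * phase_base) * (1 - c_g[g] * depl_base)
      d[pos_in[(offset + 1L):(offset + ng)]] <-
        sample(d_grid, ng, replace = TRUE, prob = wgt)
      offset <- offset + ng
    }
    # truncated normal lengths, min 50 bp (resample, not clip)
    len <- round(stats::rnorm(config$n_fragments, config$frag_len_mean, config$frag_len_sd))
    bad <- which(len < 50)
    while (length(bad) > 0) {
      len[bad] <- round(stats::rnorm(length(bad), config$frag_len_mean, config$frag_len_sd))
      bad <- bad[len[bad] < 50]
    }
    minus <- tss$strand[gene_of] == "-"
    mid <- ifelse(minus, tss$tss[gene_of] - d, tss$tss[gene_of] + d)
    start <- mid - len %/% 2L
    end <- start + len
    out <- data.frame(
      chrom = tss$chrom[gene_of], start = start, end = end, length = len,
      stringsAsFactors = FALSE
    )
    attr(out, "gene") <- tss$gene[gene_of]
    class(out) <- c("fragment_set", "data.frame")
    out
  })
}

#' Simulate per-chromosome read counts with a controllable chrM fraction
#'
#' chrM receives `Binomial(total_reads, mt_fraction)` reads; the remainder is
#' allocated to the other chromosomes proportional to length (multinomial).
#'
#' @param genome a `synthetic_genome` (or any list with named `chromosomes`
#'   lengths including `chrM`).
#' @param total_reads total reads in the library.
#' @param mt_fraction expected chrM read fraction, in `[0, 1)`.
#' @param seed RNG seed.
#' @return Data frame of class `chrom_counts`: `chrom, length, count`, with
#'   attribute `total_reads`.
#' @examples
#' simulate_chromosome_counts(synth_genome(20, seed = 1), 1e5, 0.01, seed = 2)
#' @export
simulate_chromosome_counts <- function(genome, total_reads, mt_fraction, seed = 1L) {
  assert_that(is_count(total_reads), "total_reads must be positive")
  assert_that(mt_fraction >= 0 && mt_fraction < 1, "mt_fraction must be in [0, 1)")
  chroms <- genome$chromosomes
  assert_that("chrM" %in% names(chroms), "genome must contain chrM")
  nuc <- chroms[names(chroms) != "chrM"]
  with_seed(seed, {
    mt <- stats::rbinom(1L, total_reads, mt_fraction)
    rest <- as.integer(stats::rmultinom(1L, total_reads - mt, prob = nuc / sum(nuc)))
    out <- data.frame(
      chrom = c(names(nuc), "chrM"),
      length = as.numeric(c(nuc, chrM = chroms[["chrM"]])),
      count = c(rest, mt),
      stringsAsFactors = FALSE
    )
    attr(out, "total_reads") <- as.numeric(total_reads)
    class(out) <- c("chrom_counts", "data.frame")
    out
  })
}

#' Simulate UMI-consensus pileup tables for subjects and a panel of normals
#'
#' Background alt counts are `Binomial(depth, error_rate)`. At a clone locus
#' the carrying subject/timepoint draws `Binomial(depth, vaf + error*(1-vaf))`
#' (clone and error additive on the non-clonal fraction). Normals never carry
#' clones.
#'
#' @param loci data frame with columns `chrom, pos, ref, alt` (1-based
#'   positions, VCF convention for this module).
#' @param subjects character vector of subject ids.
#' @param timepoints character vector of timepoint labels.
#' @param clones data frame `chrom, pos, subject, timepoint, vaf` or `NULL`;
#'   every clone locus must appear in `loci`.
#' @param config a [sim_config()] providing `depth`, `error_rate`, `n_normals`
#'   and `seed`.
#' @return List with data frames `subjects` and `normals`, each with columns
#'   `sample_id, subject, timepoint, chrom, pos, ref, alt, alt_count, depth`.
#' @examples
#' loci <- data.frame(chrom = "chr2", pos = 1:5 * 100, ref = "C", alt = "G")
#' sp <- simulate_pileups(loci, "S1", c("T1", "T2"), NULL, sim_config(seed = 3))
#' @export
simulate_pileups <- function(loci, subjects, timepoints, clones, config) {
  assert_that(all(c("chrom", "pos", "ref", "alt") %in% names(loci)),
              "loci needs chrom, pos, ref, alt")
  locus_key <- paste(loci$chrom, loci$pos, sep = ":")
  if (!is.null(clones)) {
    assert_that(all(clones$vaf >= 0 & clones$vaf <= 0.5), "clone VAFs must be in [0, 0.5]")
    ck <- paste(clones$chrom, clones$pos, sep = ":")
    assert_that(all(ck %in% locus_key), "clone locus not present in loci")
  }
  n_loci <- nrow(loci)
  grid <- expand.grid(locus = seq_len(n_loci), subject = subjects,
                      timepoint = timepoints, stringsAsFactors = FALSE)
  p <- rep(config$error_rate, nrow(grid))
  if (!is.null(clones)) {
    gk <- paste(locus_key[grid$locus], grid$subject, grid$timepoint, sep = "|")
    ck <- paste(clones$chrom, clones$pos, sep = ":")
    ck <- paste(ck, clones$subject, clones$timepoint, sep = "|")
    hit <- match(gk, ck)
    has <- !is.na(hit)
    v <- clones$vaf[hit[has]]
    p[has] <- v + config$error_rate * (1 - v)
  }
  with_seed(config$seed, {
    subj <- data.frame(
      sample_id = paste(grid$subject, grid$timepoint, sep = "_"),
      subject = grid$subject, timepoint = grid$timepoint,
      chrom = loci$chrom[grid$locus], pos = loci$pos[grid$locus],
      ref = loci$ref[grid$locus], alt = loci$alt[grid$locus],
      alt_count = stats::rbinom(nrow(grid), config$depth, p),
      depth = config$depth, stringsAsFactors = FALSE
    )
    ngrid <- expand.grid(locus = seq_len(n_loci),
                         normal = sprintf("N%02d", seq_len(config$n_normals)),
                         stringsAsFactors = FALSE)
    normals <- data.frame(
      sample_id = ngrid$normal, subject = ngrid$normal, timepoint = "normal",
      chrom = loci$chrom[ngrid$locus], pos = loci$pos[ngrid$locus],
      ref = loci$ref[ngrid$locus], alt = loci$alt[ngrid$locus],
      alt_count = stats::rbinom(nrow(ngrid), config$depth, config$error_rate),
      depth = config$depth, stringsAsFactors = FALSE
    )
    list(subjects = subj, normals = normals)
  })
}

#' Simulate a monochrome multiplex qPCR plate
#'
#' Standard-dilution wells (3-fold series, 50 ng down to 50/81 = 0.617 ng, both
#' targets, triplicate) plus unknown samples in triplicate for telomere (T) and
#' albumin (A) targets. `Cq = intercept + slope * log10(quantity) + shift +
#' Normal(0, noise_sd)` with `slope = -1/log10(1 + efficiency)`. An unknown's
#' albumin quantity is `sample_mass_ng`; its telomere quantity is
#' `ratio * sample_mass_ng`, so the true T/A ratio is recovered downstream. A
#' reference sample of ratio 1 can be placed on the plate for cross-plate
#' normalization.
#'
#' @param true_ta_ratios named numeric vector of true T/A ratios (> 0).
#' @param config a [sim_config()] providing efficiencies, intercepts, noise and
#'   seed.
#' @param plate_id plate label.
#' @param cq_shift additive plate batch effect in Cq units.
#' @param include_reference add a `REF` sample (ratio `reference_ratio`).
#' @param reference_ratio true ratio of the reference sample.
#' @param sample_mass_ng DNA input mass of unknown wells.
#' @return Data frame of wells: `sample_id, plate_id, target, replicate, cq,
#'   known_mass_ng` (`NA` for unknowns).
#' @examples
#' plate <- simulate_qpcr_plate(c(S1 = 1.5), sim_config(seed = 2))
#' @export
simulate_qpcr_plate <- function(true_ta_ratios, config, plate_id = "P1",
                                cq_shift = 0, include_reference = TRUE,
                                reference_ratio = 1, sample_mass_ng = 10) {
  assert_that(all(true_ta_ratios > 0), "T/A ratios must be positive")
  assert_that(!is.null(names(true_ta_ratios)) && all(nzchar(names(true_ta_ratios))),
              "true_ta_ratios must be named by sample")
  slope_t <- -1 / log10(1 + config$qpcr_efficiency_t)
  slope_a <- -1 / log10(1 + config$qpcr_efficiency_a)
  std_mass <- 50 / 3^(0:4)

  ratios <- true_ta_ratios
  if (include_reference) ratios <- c(ratios, REF = reference_ratio)

  rows <- list()
  add <- function(sample_id, target, q, known_mass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, plate_id = plate_id, target = target,
      replicate = 1:3,
      true_cq = (if (target == "telomere") config$qpcr_intercept_t + slope_t * log10(q)
                 else config$qpcr_intercept_a + slope_a * log10(q)) + cq_shift,
      known_mass_ng = known_mass, stringsAsFactors = FALSE
    )
  }
  for (m in std_mass) {
    add("STD", "telomere", m, m)
    add("STD", "albumin", m, m)
  }
  for (s in names(ratios)) {
    add(s, "telomere", ratios[[s]] * sample_mass_ng, NA_real_)
    add(s, "albumin", sample_mass_ng, NA_real_)
  }
  out <- do.call(rbind, rows)
  with_seed(config$seed, {
    out$cq <- out$true_cq + stats::rnorm(nrow(out), 0, config$qpcr_noise_sd)
  })
  out$true_cq <- NULL
  out[, c("sample_id", "plate_id", "target", "replicate", "cq", "known_mass_ng")]
}
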