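# Orchestration: a validated run configuration drives the simulation and
# analysis stages in dependency order and emits a checksummed manifest.

known_top_keys <- c("seed", "outdir", "stages", "simulate", "telomere",
                    "fragmentomics", "deconvolve", "chip", "log_level")
known_stages <- c("simulate", "telomere", "fragmentomics", "deconvolve",
                  "chip", "report")

validate_config <- function(config) {
  assert_that(is.list(config), "config must be a list")
  unknown <- setdiff(names(config), known_top_keys)
  if (length(unknown) > 0) {
    stop_orbit("unknown config key: ", paste(unknown, collapse = ", "),
               class = "orbitomics_config_error")
  }
  stages <- config$stages %||% character()
  bad <- setdiff(stages, known_stages)
  if (length(bad) > 0) {
    stop_orbit("unknown stage: ", paste(bad, collapse = ", "),
               class = "orbitomics_config_error")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$outdir <- config$outdir %||% stop_orbit(
    "config must set outdir", class = "orbitomics_config_error")
  config$stages <- stages
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the synthetic-mission pipeline
#'
#' Executes the requested stages in dependency order (`simulate` first, then
#' the analyses, then `report`). All stage outputs are plain-text tables under
#' `config$outdir`; re-running with the same config and seed reproduces
#' identical files. An empty stage list is a valid no-op run.
#'
#' @param config named list: `seed`, `outdir`, `stages` (subset of
#'   `simulate, telomere, fragmentomics, deconvolve, chip, report`), and
#'   optional per-stage parameter blocks. Unknown keys are rejected.
#' @return Object of class `report_bundle`: `manifest` (data frame
#'   `path, rows, md5`), `seed`, `version`, `timestamp`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(x, name, writer = write_result_tsv) {
    path <- file.path(outdir, name)
    writer(x, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      path = name, rows = if (is.data.frame(x)) nrow(x) else length(x),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
    path
  }

  stages <- config$stages
  order_now <- intersect(known_stages, stages)

  sim_state <- NULL
  for (stage in order_now) {
    if (stage == "simulate") {
      sp <- config$simulate %||% list()
      cfg <- do.call(sim_config, c(list(seed = config$seed),
                                   sp[intersect(names(sp), names(formals(sim_config)))]))
      genome <- synth_genome(n_genes = cfg$n_genes, seed = config$seed)
      expr <- simulate_reference_expression(cfg$n_genes, cfg$tissues,
                                            seed = config$seed)
      frags <- simulate_cfdna_fragments(genome, expr, cfg$mixture, cfg)
      counts <- simulate_chromosome_counts(genome, total_reads = 1e6,
                                           mt_fraction = cfg$mt_fraction,
                                           seed = config$seed)
      subjects <- sp$subjects %||% c("C001", "C002", "C003", "C004")
      timepoints <- sp$timepoints %||% names(mission_phases())
      loci <- data.frame(chrom = "chr2",
                         pos = seq(25235000, by = 997, length.out = 50),
                         ref = "C", alt = "G", stringsAsFactors = FALSE)
      piles <- simulate_pileups(loci, subjects, timepoints, cfg$clones, cfg)
      ratios <- stats::setNames(rep(1, length(subjects)), subjects)
      wells <- simulate_qpcr_plate(ratios, cfg)
      emit(genome$tss_table, "tss.bed", write_tss_bed6)
      emit(stats::setNames(as.numeric(genome$chromosomes), names(genome$chromosomes)),
           "genome.chrom.sizes", write_chrom_sizes)
      emit(frags, "fragments.bed", write_fragments_bed)
      emit(expr, "expression.tsv", write_expression_tsv)
      emit(counts, "chrom_counts.tsv", write_chrom_counts_tsv)
      emit(piles$subjects, "pileups_subjects.tsv", write_pileups_tsv)
      emit(piles$normals, "pileups_normals.tsv", write_pileups_tsv)
      emit(wells, "qpcr_wells.csv", write_qpcr_csv)
      sim_state <- list(genome = genome, expr = expr, frags = frags,
                        counts = counts, piles = piles, wells = wells)
    } else if (stage == "fragmentomics") {
      counts <- sim_state$counts %||% read_chrom_counts(file.path(outdir, "chrom_counts.tsv"))
      frags <- sim_state$frags %||% read_fragments_bed(file.path(outdir, "fragments.bed"))
      rp <- rpkm(counts)
      sizes <- fragment_size_distribution(frags)
      emit(rp, "rpkm.tsv")
      emit(sizes$histogram, "fragment_size_histogram.tsv")
      emit(data.frame(metric = c("mode", "mean", "median", "mt_enrichment"),
                      value = c(sizes$summary$mode, sizes$summary$mean,
                                sizes$summary$median, mt_enrichment(rp))),
           "fragmentomics_summary.tsv")
    } else if (stage == "deconvolve") {
      frags <- sim_state$frags %||% read_fragments_bed(file.path(outdir, "fragments.bed"))
      tsst <- sim_state$genome$tss_table %||% read_tss_bed6(file.path(outdir, "tss.bed"))
      expr <- sim_state$expr %||% read_expression_tsv(file.path(outdir, "expression.tsv"))
      dp <- config$deconvolve %||% list()
      dec <- deconvolve(frags, tsst, expr,
                        W = dp$window %||% 1000L, b = dp$bin %||% 10L,
                        band = dp$band %||% c(160, 210),
                        low_cov_floor = dp$low_cov_floor %||% 20L)
      emit(dec$scores, "periodicity_scores.tsv")
      emit(dec$correlations, "deconvolution.tsv")
    } else if (stage == "telomere") {
      wells <- sim_state$wells %||% read_qpcr_csv(file.path(outdir, "qpcr_wells.csv"))
      res <- telomere_quantify(wells)
      res <- plate_normalize(res)
      emit(res, "telomere_results.tsv")
    } else if (stage == "chip") {
      piles <- sim_state$piles %||% list(
        subjects = read_pileups_tsv(file.path(outdir, "pileups_subjects.tsv")),
        normals = read_pileups_tsv(file.path(outdir, "pileups_normals.tsv")))
      cp <- config$chip %||% list()
      pon <- build_pon(piles$normals)
      res <- chip_call(piles$subjects, pon,
                       alpha = cp$alpha %||% 0.05,
                       rescue_alpha = cp$rescue_alpha %||% 0.05)
      emit(res$final_variants, "chip_final_variants.tsv")
      if (!is.null(res$trajectories)) {
        emit(res$trajectories, "chip_trajectories.tsv")
      }
    }
    # "report" handled below once the manifest is complete
  }
  bundle <- structure(list(
    manifest = if (length(manifest)) do.call(rbind, manifest)
               else data.frame(path = character(), rows = integer(),
                               md5 = character(), stringsAsFactors = FALSE),
    seed = config$seed,
    version = as.character(utils::packageVersion("orbitomics")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    outdir = outdir
  ), class = "report_bundle")
  if ("report" %in% stages) {
    write_report(bundle, file.path(outdir, "manifest.tsv"))
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, orbitomics %s): %d output files in %s\n",
              x$seed, x$version, nrow(x$manifest), x$outdir))
  if (nrow(x$manifest)) print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Write a machine-readable run manifest and a human-readable summary
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param path manifest TSV path; a `.summary.txt` sibling is written next to
#'   it.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  assert_that(inherits(bundle, "report_bundle"), "bundle must be a report_bundle")
  utils::write.table(bundle$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(sprintf("orbitomics %s", bundle$version),
            sprintf("seed: %d", bundle$seed),
            sprintf("timestamp: %s", bundle$timestamp),
            sprintf("files: %d", nrow(bundle$manifest)))
  writeLines(meta, paste0(path, ".summary.txt"))
  invisible(path)
}

#' Read a manifest back
#' @param path manifest TSV path.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character"))
}

#' Verify that every manifest entry still matches its checksum
#'
#' @param manifest_path manifest TSV path.
#' @param outdir directory holding the listed files (default: the manifest's
#'   directory).
#' @return `TRUE` when all files verify; otherwise a character vector of
#'   failing paths, with class `verify_failure`.
#' @export
verify_report <- function(manifest_path, outdir = dirname(manifest_path)) {
  man <- read_report(manifest_path)
  bad <- character()
  for (i in seq_len(nrow(man))) {
    f <- file.path(outdir, man$path[i])
    if (!file.exists(f) || unname(tools::md5sum(f)) != man$md5[i]) {
      bad <- c(bad, man$path[i])
    }
  }
  if (length(bad) == 0) TRUE else structure(bad, class = "verify_failure")
}
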