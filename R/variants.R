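# Variant-set handling: SNV filtering, severity ranking and two-timepoint
# comparison of (variant, annotation) pairs.

#' Ensembl consequence terms in severity order
#'
#' The canonical consequence-severity ordering used by the Variant Effect
#' Predictor (release ~107), most severe first. Rank 1 is the most severe
#' term.
#'
#' @return Character vector of consequence terms, most severe first.
#' @export
consequence_severity_order <- function() {
  c("transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "transcript_amplification", "feature_elongation", "feature_truncation",
    "inframe_insertion", "inframe_deletion", "missense_variant",
    "protein_altering_variant", "splice_donor_5th_base_variant",
    "splice_region_variant", "splice_donor_region_variant",
    "splice_polypyrimidine_tract_variant", "incomplete_terminal_codon_variant",
    "start_retained_variant", "stop_retained_variant", "synonymous_variant",
    "coding_sequence_variant", "mature_miRNA_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "non_coding_transcript_exon_variant",
    "intron_variant", "NMD_transcript_variant", "non_coding_transcript_variant",
    "coding_transcript_variant", "upstream_gene_variant",
    "downstream_gene_variant", "TFBS_ablation", "TFBS_amplification",
    "TF_binding_site_variant", "regulatory_region_ablation",
    "regulatory_region_amplification", "regulatory_region_variant",
    "intergenic_variant", "sequence_variant")
}

#' Severity rank of consequence annotations
#'
#' Lower rank = more severe. Unknown terms rank below every known term.
#'
#' @param annotation character vector of consequence terms.
#' @return Integer ranks.
#' @export
severity_rank <- function(annotation) {
  ord <- consequence_severity_order()
  r <- match(annotation, ord)
  r[is.na(r)] <- length(ord) + 1L
  r
}

#' Subset variant records to clean biallelic SNVs
#'
#' Keeps records whose ref and alt are both single bases, then removes every
#' record at a position carrying more than one distinct alt allele within the
#' same set (triallelic rule).
#'
#' @param records data frame `chrom, pos, ref, alt` (plus any annotation
#'   columns, carried through).
#' @return Filtered data frame.
#' @export
filter_snv <- function(records) {
  assert_that(all(c("chrom", "pos", "ref", "alt") %in% names(records)),
              "records needs chrom, pos, ref, alt")
  snv <- records[nchar(records$ref) == 1 & nchar(records$alt) == 1 &
                   records$ref != records$alt, , drop = FALSE]
  if (nrow(snv) == 0) return(snv)
  pos_key <- paste(snv$chrom, snv$pos, sep = ":")
  n_alt <- tapply(snv$alt, pos_key, function(a) length(unique(a)))
  keep <- n_alt[pos_key] == 1
  out <- snv[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Compare variant sets between two timepoints
#'
#' Variant identity for sharing is `(chrom, pos, ref, alt)`; annotation is not
#' part of identity. Pair counting deduplicates repeated (variant, annotation)
#' pairs, so one variant carrying two annotations counts as two pairs but one
#' shared variant. Per-gene unique-pair counts and severity-rank distributions
#' are reported for the A-unique, B-unique and shared partitions.
#'
#' @param a,b SNV-filtered variant data frames with columns
#'   `chrom, pos, ref, alt, gene, annotation`.
#' @param label_a,label_b display labels for the two timepoints.
#' @return List of class `variant_comparison`: `counts` (`unique_a, unique_b,
#'   shared` variant counts), `pairs_by_gene` (per gene and partition),
#'   `severity` (per partition severity-rank table), `labels`.
#' @export
compare_variant_sets <- function(a, b, label_a = "A", label_b = "B") {
  for (x in list(a, b)) {
    assert_that(all(c("chrom", "pos", "ref", "alt", "gene", "annotation") %in% names(x)),
                "variant sets need chrom, pos, ref, alt, gene, annotation")
  }
  ka <- unique(variant_key(a))
  kb <- unique(variant_key(b))
  shared_keys <- intersect(ka, kb)
  counts <- c(unique_a = length(setdiff(ka, kb)),
              unique_b = length(setdiff(kb, ka)),
              shared = length(shared_keys))

  pairs <- function(x) unique(x[, c("chrom", "pos", "ref", "alt", "gene", "annotation")])
  pa <- pairs(a); pb <- pairs(b)
  pa$partition <- ifelse(variant_key(pa) %in% shared_keys, "shared", "unique_a")
  pb$partition <- ifelse(variant_key(pb) %in% shared_keys, "shared", "unique_b")
  # shared pairs: union of annotations seen for shared variants at either timepoint
  all_pairs <- unique(rbind(pa, pb))
  all_pairs$severity_rank <- severity_rank(all_pairs$annotation)

  pairs_by_gene <- stats::aggregate(
    list(n_pairs = rep(1L, nrow(all_pairs))),
    by = list(gene = all_pairs$gene, partition = all_pairs$partition), sum)
  severity <- stats::aggregate(
    list(n_pairs = rep(1L, nrow(all_pairs))),
    by = list(partition = all_pairs$partition,
              severity_rank = all_pairs$severity_rank,
              annotation = all_pairs$annotation), sum)
  severity <- severity[order(severity$partition, severity$severity_rank), ]
  rownames(severity) <- NULL
  structure(list(counts = counts, pairs_by_gene = pairs_by_gene,
                 severity = severity, pairs = all_pairs,
                 labels = c(a = label_a, b = label_b)),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("Variant-set comparison [%s vs %s]: %d unique to %s, %d unique to %s, %d shared\n",
              x$labels["a"], x$labels["b"],
              x$counts["unique_a"], x$labels["a"],
              x$counts["unique_b"], x$labels["b"], x$counts["shared"]))
  invisible(x)
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x file and extracts one record per (position, alt allele)
#' with gene and consequence annotation taken from a configurable INFO field
#' formatted as `consequence|gene` (CSQ-style, first sub-field the consequence
#' term, second the gene symbol).
#'
#' @param path VCF file path.
#' @param ann_field INFO key holding the annotation (default `"ANN"`).
#' @return Data frame `chrom, pos, ref, alt, gene, annotation` (1-based
#'   positions).
#' @export
read_variants_vcf <- function(path, ann_field = "ANN") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ann <- vcfR::extract.info(vcf, element = ann_field)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    parts <- strsplit(ifelse(is.na(ann[i]), "|", ann[i]), "|", fixed = TRUE)[[1]]
    consequence <- if (length(parts) >= 1 && nzchar(parts[1])) parts[1] else NA_character_
    gene <- if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_
    for (alt in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        ref = fix$REF[i], alt = alt, gene = gene, annotation = consequence,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
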