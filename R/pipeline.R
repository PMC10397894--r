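#' Generate the synthetic study inputs
#'
#' Stage 1 of the pipeline: writes the seeded reference FASTA, cohort VCF,
#' sample metadata TSV and config echo into \code{outdir}.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param config Optional \code{\link{simulation_config}}; built from
#'   \code{seed} when NULL.
#' @return Named list of file paths, invisibly.
#' @export
run_simulate <- function(outdir, seed = 1, config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  make_fixture_set(config, outdir)
}

#' Derive the splice-site table
#'
#' Stage 2: gene model + reference in, one TSV row per distinct donor or
#' acceptor site with sharing classification, 22-nt window bounds in both
#' forward-genome and transcript-order rendering, extracted sequence,
#' canonical-motif status and acceptor pyrimidine count.
#'
#' @param gene A \code{\link{gene_model}} or path to a gene-model file.
#' @param fasta Path to the reference FASTA (or a \code{\link{ref_contig}}).
#' @param out_tsv Output TSV path (optional).
#' @return The site table data.frame.
#' @export
run_derive_sites <- function(gene, fasta, out_tsv = NULL) {
  if (is.character(gene)) gene <- read_gene_model(gene)
  ref <- if (is.character(fasta)) read_reference_fasta(fasta) else fasta
  tab <- splice_site_table(gene, ref)
  if (!is.null(out_tsv)) write_site_table(tab, out_tsv)
  tab
}

#' Scan splice windows for SNPs
#'
#' Stage 3: loads biallelic PASS SNPs in the gene span from the VCF,
#' intersects them with every splice window, and writes the annotated hit
#' table (positional tier, sex presence, Fisher association, MAF, relevance
#' verdict) plus the per-stratum MAF table.
#'
#' @param gene A \code{\link{gene_model}} or path.
#' @param fasta Reference FASTA path or \code{\link{ref_contig}}.
#' @param vcf VCF path.
#' @param metadata Metadata TSV path or data.frame.
#' @param out_hits,out_maf Optional output TSV paths.
#' @param maf_threshold Relevance-rule MAF threshold.
#' @param quiet Suppress the per-site count summary.
#' @return List with \code{hits}, \code{maf}, \code{sites}, \code{excluded}.
#' @export
run_scan <- function(gene, fasta, vcf, metadata, out_hits = NULL,
                     out_maf = NULL, maf_threshold = 0.05, quiet = FALSE) {
  if (is.character(gene)) gene <- read_gene_model(gene)
  ref <- if (is.character(fasta)) read_reference_fasta(fasta) else fasta
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  sites <- splice_site_table(gene, ref)
  snps <- load_region_snps(vcf, gene$span, chrom = gene$chrom)
  scan <- scan_splice_windows(snps, sites, metadata, gene$strand,
                              maf_threshold = maf_threshold)
  if (!quiet) {
    message(nrow(snps$variants), " biallelic PASS SNPs in span; ",
            "excluded: ", paste(names(snps$excluded), snps$excluded,
                                sep = "=", collapse = ", "))
    for (i in seq_len(nrow(sites))) {
      n <- sum(scan$hits$site_boundary == sites$boundary[i] &
                 scan$hits$site_kind == sites$kind[i])
      message(sites$kind[i], " at ", sites$boundary[i], " (",
              sites$sharing[i], "): ", n, " SNP(s)")
    }
  }
  if (!is.null(out_hits))
    utils::write.table(scan$hits, out_hits, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(out_maf))
    utils::write.table(scan$maf, out_maf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  c(scan, list(sites = sites, excluded = snps$excluded))
}

#' Windowed diversity per stratum
#'
#' Stage 4: per (population, sex) cell with at least \code{min_samples}
#' samples, a windowed nucleotide-diversity track over the gene span, plus
#' a between-strata comparison table.
#'
#' @param gene A \code{\link{gene_model}} or path (provides the span).
#' @param vcf VCF path.
#' @param metadata Metadata TSV path or data.frame.
#' @param window_size Window length in bp (default 500).
#' @param out_tracks,out_comparison Optional output TSV paths.
#' @param min_samples Minimum samples per stratum.
#' @return List with \code{tracks} and \code{comparison}.
#' @export
run_diversity <- function(gene, vcf, metadata, window_size = 500,
                          out_tracks = NULL, out_comparison = NULL,
                          min_samples = 2L) {
  if (is.character(gene)) gene <- read_gene_model(gene)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  snps <- load_region_snps(vcf, gene$span, chrom = gene$chrom)
  tracks <- diversity_by_stratum(snps$gt, snps$variants$pos, metadata,
                                 gene$span, window_size,
                                 min_samples = min_samples)
  comparison <- if (length(tracks) >= 2L) compare_strata(tracks) else NULL
  if (!is.null(out_tracks)) write_diversity_tracks(tracks, out_tracks)
  if (!is.null(out_comparison) && !is.null(comparison))
    utils::write.table(comparison$summary, out_comparison, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(tracks = tracks, comparison = comparison)
}
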