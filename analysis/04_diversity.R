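#!/usr/bin/env Rscript
# Stage 4 — windowed nucleotide diversity per population/sex stratum.
#
# Computes pi in 500-bp windows across the locus for every (country, sex)
# cell with at least two samples, from allele counts (no phasing needed),
# and compares male vs female tracks within each country that has both.

suppressMessages(library(agdsx))

gene <- agdsx_gene_model()
div <- suppressWarnings(
  run_diversity(gene, "results/fixtures/cohort.vcf",
                "results/fixtures/samples.tsv", window_size = 500,
                out_tracks = "results/pi_tracks.tsv",
                out_comparison = "results/pi_summary.tsv"))

cat("Diversity tracks ->", "results/pi_tracks.tsv\n")
s <- div$comparison$summary
for (i in order(s$stratum))
  cat(sprintf("  %-22s n=%3d  mean pi = %.5f\n",
              s$stratum[i], s$n_samples[i], s$mean_pi[i]))
for (cn in c("Burkina Faso", "Cameroon", "France (Mayotte)")) {
  f <- s$mean_pi[s$stratum == paste0(cn, "|F")]
  m <- s$mean_pi[s$stratum == paste0(cn, "|M")]
  if (length(f) && length(m))
    cat(sprintf("  %s: pi(M)/pi(F) = %.3f\n", cn, m / f))
}
plot_diversity(div$tracks, file = "results/pi_tracks.png")
cat("Track plot -> results/pi_tracks.png\n")
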