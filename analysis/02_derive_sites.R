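#!/usr/bin/env Rscript
# Stage 2 — derive the donor/acceptor splice-site table.
#
# From the packaged two-isoform dsx gene model: derive introns, classify every
# junction as shared or isoform-specific (keyed by genomic coordinate, so the
# male exon renumbering does not split junctions), build the 22-nt windows
# (6 exonic + 16 intronic bases), extract strand-corrected sequences from the
# reference, check the GT/NYag motifs, and score acceptor polypyrimidine
# tracts. Run analysis/01_simulate.R first.

suppressMessages(library(agdsx))

gene <- agdsx_gene_model()
tab <- run_derive_sites(gene, "results/fixtures/reference.fa",
                        out_tsv = "results/splice_sites.tsv")
write_junction_table(gene, "results/junctions.tsv")

cat("Derived", nrow(tab), "distinct splice sites ->", "results/splice_sites.tsv\n")
cat(sprintf("  %d shared donors + %d female-specific, %d shared acceptors + %d female-specific\n",
            sum(tab$kind == "donor" & tab$sharing == "shared"),
            sum(tab$kind == "donor" & tab$sharing == "specific"),
            sum(tab$kind == "acceptor" & tab$sharing == "shared"),
            sum(tab$kind == "acceptor" & tab$sharing == "specific")))
cas <- detect_cassette_exons(gene)
cat(sprintf("Cassette exon: %s exon %d [%d-%d] inside %s intron %d\n",
            cas$exon_transcript, cas$exon_ordinal, cas$exon_low,
            cas$exon_high, cas$host_transcript, cas$host_intron_ordinal))
acc <- tab[tab$kind == "acceptor" & !is.na(tab$pyrimidine_count), ]
cat("Acceptor pyrimidine counts (of 12):",
    paste(sprintf("%s:%d", acc$boundary, acc$pyrimidine_count),
          collapse = " "), "\n")
noncan <- tab[!tab$canonical, ]
if (nrow(noncan))
  cat("Non-canonical motif at", noncan$kind, "boundary", noncan$boundary,
      "(NYag Y position is a purine)\n")
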