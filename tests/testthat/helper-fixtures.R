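# Shared fixtures, all built in code.

# Plus-strand two-isoform toy gene: B skips the middle exon of A.
toy_plus_gene <- function() {
  a <- transcript_model("trA", rbind(c(20, 39), c(50, 60), c(81, 100)))
  b <- transcript_model("trB", rbind(c(20, 39), c(81, 100)))
  gene_model("toy", "chr1", "+", list(a, b), span = c(1, 120))
}

toy_ref <- function(seq, chrom = "chr1", offset = 0) {
  ref_contig(seq, chrom, offset)
}

# Minimal VCF writer for hand-built records. Each record is a list with
# pos, ref, alt, filter, id and a vector of GT strings (one per sample).
write_test_vcf <- function(path, records, samples, chrom = "2R",
                           format = "GT") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(chrom, r$pos, if (is.null(r$id)) "." else r$id, r$ref, r$alt,
            ".", if (is.null(r$filter)) "PASS" else r$filter, ".", format,
            r$gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# Tiny two-country cohort for fast end-to-end runs.
small_cohort <- function() {
  data.frame(country = c("Burkina Faso", "Cameroon"),
             site = c("Bana", "Mayos"), year = c(2012, 2009),
             latitude = 0, longitude = 0,
             n_total = c(15, 15), n_female = c(10, 10), n_male = c(5, 5))
}

small_config <- function(seed = 11, density = 0.002, ...) {
  simulation_config(seed = seed, cohort = small_cohort(), density = density,
                    ...)
}

# Single-country balanced cohort on a small two-exon contig, used for
# panmictic diversity checks where only site-frequency structure matters.
panmictic_config <- function(seed, n_f = 50, n_m = 50, density = 0.05) {
  gene <- gene_model("simgene", "chrS", "+",
                     list(transcript_model("t1", rbind(c(1, 2000),
                                                      c(3000, 5000)))),
                     span = c(1, 5000))
  cohort <- data.frame(country = "Simland", site = "Sim", year = 2020,
                       latitude = 0, longitude = 0, n_total = n_f + n_m,
                       n_female = n_f, n_male = n_m)
  empty_sites <- agdsx_site_sequences()[0, ]
  simulation_config(seed = seed, gene = gene, site_sequences = empty_sites,
                    cohort = cohort, density = density,
                    planted = data.frame(pos = numeric(), country = character(),
                                         sex = character(), freq = numeric()))
}

# The nine splice-window variant positions the screen reports.
reported_positions <- function() {
  c(48715291, 48715294, 48715302, 48715306, 48715307, 48715308, 48715309,
    48712947, 48712962)
}
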