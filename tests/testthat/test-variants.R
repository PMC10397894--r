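gene <- agdsx_gene_model()
sites <- splice_site_table(gene)  # coordinates only, no sequences needed

test_that("region loading keeps only in-span biallelic PASS SNPs", {
  vcf <- tempfile(fileext = ".vcf")
  recs <- c(
    lapply(48714000 + seq_len(10) * 10, function(p)
      list(pos = p, ref = "A", alt = "G", gt = c("0/0", "0/1"))),
    list(list(pos = 48700000, ref = "A", alt = "G", gt = c("0/0", "0/0")),  # below span
         list(pos = 48790000, ref = "A", alt = "G", gt = c("0/0", "0/0")),  # above span
         list(pos = 48714500, ref = "AT", alt = "A", gt = c("0/0", "0/0")), # indel
         list(pos = 48714600, ref = "A", alt = "G", filter = "LowQual",
              gt = c("0/0", "0/0")),                                        # non-PASS
         list(pos = 48714700, ref = "A", alt = "G,T", gt = c("0/0", "0/0"))))# multiallelic
  write_test_vcf(vcf, recs, samples = c("s1", "s2"))
  snps <- load_region_snps(vcf, gene$span, chrom = gene$chrom)
  expect_equal(nrow(snps$variants), 10)
  expect_equal(unname(snps$excluded["off_target"]), 2L)
  expect_equal(unname(snps$excluded["non_pass"]), 1L)
  expect_equal(unname(snps$excluded["multiallelic"]), 1L)
  expect_equal(unname(snps$excluded["non_snp"]), 1L)
  expect_true(all(diff(snps$variants$pos) > 0))
  # missing IDs synthesised as rs + position
  expect_equal(snps$variants$id, paste0("rs", snps$variants$pos))
  expect_equal(dim(snps$gt), c(10L, 2L))
  expect_equal(unname(snps$gt[1, ]), c(0L, 1L))
})

test_that("a VCF without genotypes is rejected and an empty region is empty", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               "2R\t48714000\t.\tA\tG\t.\tPASS\t."), vcf)
  expect_error(load_region_snps(vcf, gene$span), "GT")
  vcf2 <- tempfile(fileext = ".vcf")
  write_test_vcf(vcf2, list(list(pos = 100, ref = "A", alt = "G",
                                 gt = "0/0")), samples = "s1")
  snps <- load_region_snps(vcf2, gene$span, chrom = gene$chrom)
  expect_equal(nrow(snps$variants), 0)
})

test_that("the nine reported positions hit the windows 7/2/0", {
  v <- data.frame(pos = reported_positions())
  v$id <- paste0("rs", v$pos)
  hits <- intersect_windows(v, sites, gene$strand)
  n_in <- function(lo, hi) sum(hits$win_low == lo & hits$win_high == hi)
  expect_equal(n_in(48715290, 48715311), 7)  # intron 3 acceptor
  expect_equal(n_in(48712941, 48712962), 2)  # female exon 5 donor
  expect_equal(n_in(48714643, 48714664), 0)  # female intron 4 acceptor
  expect_equal(nrow(hits), 9)
  expect_setequal(hits$id[hits$win_low == 48712941],
                  c("rs48712947", "rs48712962"))
})

test_that("window intersection agrees with a brute-force double loop", {
  set.seed(42)
  v <- data.frame(pos = sort(sample(48703664:48788460, 400)))
  v$id <- paste0("rs", v$pos)
  hits <- intersect_windows(v, sites, gene$strand)
  brute <- 0L
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(nrow(sites))) {
      if (v$pos[i] >= sites$win_low[j] && v$pos[i] <= sites$win_high[j]) {
        brute <- brute + 1L
        h <- hits[hits$pos == v$pos[i] & hits$win_low == sites$win_low[j], ]
        expect_equal(nrow(h), 1)
        expect_equal(h$offset, sites$win_high[j] - v$pos[i])
      }
    }
  }
  expect_equal(nrow(hits), brute)
  expect_true(all(hits$offset >= 0 & hits$offset <= 21))
})

test_that("positional tiers follow the window anatomy", {
  # donor: first two intronic bases are the invariant gt
  expect_equal(classify_tier("donor", 6L), "dinucleotide")
  expect_equal(classify_tier("donor", 7L), "dinucleotide")
  expect_equal(classify_tier("donor", c(0L, 5L, 8L, 21L)),
               rep("window", 4))
  # acceptor: ag at offsets 14-15, Y at 13, N at 12 stays plain window
  expect_equal(classify_tier("acceptor", c(14L, 15L)),
               rep("dinucleotide", 2))
  expect_equal(classify_tier("acceptor", 13L), "NYag_Y")
  expect_equal(classify_tier("acceptor", 12L), "window")
  # first intronic base of the female exon 5 donor is on the gt
  v <- data.frame(pos = c(48712956, 48712962), id = c("a", "b"))
  h <- intersect_windows(v, sites[sites$win_low == 48712941, ], "-")
  expect_equal(h$tier[h$pos == 48712956], "dinucleotide")
  expect_equal(h$tier[h$pos == 48712962], "window")  # exon-side window edge
})

test_that("sex presence flags and the exact test behave on hand-built cohorts", {
  md <- data.frame(sample_id = paste0("s", 1:8),
                   country = rep(c("Burkina Faso", "Cameroon"), each = 4),
                   sex = rep(c("F", "F", "M", "M"), 2))
  d <- stats::setNames(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L), md$sample_id)
  expect_equal(sex_specificity(d, md)$sex_presence, "female_only")
  # alt in Burkina Faso both sexes and Cameroon females: both
  d2 <- stats::setNames(c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L), md$sample_id)
  r2 <- sex_specificity(d2, md)
  expect_equal(r2$sex_presence, "both")
  expect_false(r2$test_skipped)
  expect_true(r2$p_value >= 0 && r2$p_value <= 1)
  # no males at all: presence still computed, test skipped
  md_f <- md[md$sex == "F", ]
  r3 <- sex_specificity(d[md$sex == "F"], md_f)
  expect_true(r3$test_skipped)
  expect_equal(r3$sex_presence, "female_only")
  d0 <- stats::setNames(rep(0L, 8), md$sample_id)
  expect_equal(sex_specificity(d0, md)$sex_presence, "absent")
})

test_that("the exact test holds its size on sex-independent rare alleles", {
  set.seed(202)
  md <- data.frame(sample_id = paste0("s", 1:500),
                   country = "Simland", sex = rep(c("F", "M"), each = 250))
  reject <- 0L
  for (r in 1:200) {
    d <- stats::setNames(stats::rbinom(500, 2, 0.01), md$sample_id)
    res <- sex_specificity(d, md)
    if (!is.na(res$p_value) && res$p_value < 0.05) reject <- reject + 1L
  }
  expect_lte(reject / 200, 0.05)
})

test_that("stratified MAF counts alleles per cell and conserves totals", {
  md <- data.frame(sample_id = paste0("s", 1:50), country = "Burkina Faso",
                   sex = "F")
  d <- stats::setNames(c(1L, rep(0L, 49)), md$sample_id)
  sm <- stratified_maf(d, md)
  expect_equal(sm$maf, 0.01)
  expect_equal(sm$alt_alleles, 1L)
  # all-missing cell is undefined, not zero
  d[] <- NA_integer_
  expect_true(is.na(stratified_maf(d, md)$maf))
  # conservation over a multi-cell cohort with missingness
  set.seed(7)
  md2 <- data.frame(sample_id = paste0("t", 1:120),
                    country = sample(c("A", "B", "C"), 120, replace = TRUE),
                    sex = sample(c("F", "M"), 120, replace = TRUE))
  d2 <- stats::setNames(stats::rbinom(120, 2, 0.3), md2$sample_id)
  d2[sample(120, 10)] <- NA
  sm2 <- stratified_maf(d2, md2)
  expect_equal(sum(sm2$alt_alleles, na.rm = TRUE), sum(d2, na.rm = TRUE))
  expect_equal(sum(sm2$n_called), sum(!is.na(d2)))
  expect_true(all(sm2$maf >= 0 & sm2$maf <= 0.5, na.rm = TRUE))
})

test_that("the relevance rule reproduces the reported verdict and its exceptions", {
  base <- data.frame(id = "x", tier = "window", sex_presence = "both",
                     max_maf = 0.2)
  expect_false(splice_relevance(base)$splice_relevant)
  base$sex_presence <- "female_only"
  expect_true(splice_relevance(base)$splice_relevant)
  base$max_maf <- 0.01  # sex-exclusive but too rare
  expect_false(splice_relevance(base)$splice_relevant)
  base$tier <- "dinucleotide"  # invariant machinery is always relevant
  expect_true(splice_relevance(base)$splice_relevant)
  base$tier <- "NYag_Y"
  expect_true(splice_relevance(base)$splice_relevant)
  # threshold is exposed
  base2 <- data.frame(id = "y", tier = "window", sex_presence = "male_only",
                      max_maf = 0.03)
  expect_false(splice_relevance(base2, maf_threshold = 0.05)$splice_relevant)
  expect_true(splice_relevance(base2, maf_threshold = 0.02)$splice_relevant)
})
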