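gene <- agdsx_gene_model()
fem <- gene$transcripts$AgdsxF
mal <- gene$transcripts$AgdsxM

test_that("packaged model reproduces the printed transcript and element sizes", {
  expect_equal(transcript_length(fem), 8667)
  expect_equal(transcript_length(mal), 6975)
  expect_equal(fem$exons$high - fem$exons$low + 1,
               c(1415, 1445, 45, 135, 1692, 1267, 2668))
  expect_equal(derive_introns(fem, "-")$length,
               c(1416, 36447, 32397, 512, 162, 5196))
  expect_equal(derive_introns(mal, "-")$length,
               c(1416, 36447, 32397, 2366, 5196))
  # the printed female intron 4 and male intron 4 coordinate pairs
  fi <- derive_introns(fem, "-")
  expect_equal(unlist(fi[fi$ordinal == 4, c("low", "high")], use.names = FALSE),
               c(48714649, 48715160))
  mi <- derive_introns(mal, "-")
  expect_equal(unlist(mi[mi$ordinal == 4, c("low", "high")], use.names = FALSE),
               c(48712795, 48715160))
})

test_that("exons and introns tile each transcript's genomic footprint", {
  for (tr in gene$transcripts) {
    iv <- rbind(tr$exons[c("low", "high")],
                derive_introns(tr, gene$strand)[c("low", "high")])
    iv <- iv[order(iv$low), ]
    expect_true(all(iv$low[-1] == iv$high[-nrow(iv)] + 1))
    expect_equal(c(min(iv$low), max(iv$high)),
                 c(min(tr$exons$low), max(tr$exons$high)))
  }
})

test_that("intron derivation handles degenerate inputs", {
  single <- transcript_model("s", rbind(c(5, 5)))
  expect_equal(transcript_length(single), 1)
  expect_equal(nrow(derive_introns(single, "+")), 0)
  adjacent <- transcript_model("adj", rbind(c(1, 10), c(11, 20)))
  expect_error(derive_introns(adjacent, "+"), "zero-length gap")
  expect_error(
    gene_model("bad", "chr1", "+",
               list(transcript_model("o", rbind(c(1, 10), c(5, 20))))),
    "overlap")
})

test_that("junction classification recovers the shared/specific partition", {
  j <- classify_junctions(gene)
  don <- j[j$kind == "donor", ]
  acc <- j[j$kind == "acceptor", ]
  expect_equal(sum(don$sharing == "shared"), 5)
  expect_equal(sum(acc$sharing == "shared"), 5)
  expect_equal(don$boundary[don$sharing == "specific"], 48712957)
  expect_equal(don$transcripts[don$sharing == "specific"], "AgdsxF")
  expect_equal(acc$boundary[acc$sharing == "specific"], 48714648)
  # the female-intron-5 / male-intron-4 acceptor is one shared junction
  shared_acc <- acc[acc$boundary == 48712794, ]
  expect_equal(shared_acc$sharing, "shared")
  expect_match(shared_acc$intron_ordinals, "AgdsxF:5")
  expect_match(shared_acc$intron_ordinals, "AgdsxM:4")
})

test_that("junction classification matches brute-force edge enumeration on a 3-isoform toy", {
  a <- transcript_model("a", rbind(c(1, 10), c(20, 30), c(40, 50), c(60, 70)))
  b <- transcript_model("b", rbind(c(1, 10), c(20, 30), c(60, 70)))
  cc <- transcript_model("c", rbind(c(1, 10), c(40, 50), c(60, 70)))
  g <- gene_model("toy3", "chr1", "+", list(a, b, cc))
  j <- classify_junctions(g)

  # oracle: enumerate every exon edge of every transcript directly
  oracle <- list()
  for (tr in list(a, b, cc)) {
    k <- nrow(tr$exons)
    for (i in seq_len(k)) {
      if (i < k) {
        key <- paste("donor", tr$exons$high[i])
        oracle[[key]] <- union(oracle[[key]], tr$id)
      }
      if (i > 1) {
        key <- paste("acceptor", tr$exons$low[i])
        oracle[[key]] <- union(oracle[[key]], tr$id)
      }
    }
  }
  expect_setequal(paste(j$kind, j$boundary), names(oracle))
  for (i in seq_len(nrow(j))) {
    key <- paste(j$kind[i], j$boundary[i])
    expect_setequal(strsplit(j$transcripts[i], ",")[[1]], oracle[[key]])
    expect_equal(j$sharing[i],
                 if (length(oracle[[key]]) == 3) "shared" else "specific")
  }
})

test_that("duplicate transcripts share everything; a lone transcript shares nothing", {
  a <- transcript_model("a", rbind(c(1, 10), c(20, 30)))
  a2 <- transcript_model("a2", rbind(c(1, 10), c(20, 30)))
  dup <- gene_model("dup", "chr1", "+", list(a, a2))
  expect_true(all(classify_junctions(dup)$sharing == "shared"))
  solo <- gene_model("solo", "chr1", "+", list(a))
  expect_true(all(classify_junctions(solo)$sharing == "specific"))
})

test_that("the female cassette exon is detected inside the male intron", {
  cas <- detect_cassette_exons(gene)
  expect_equal(nrow(cas), 1)
  expect_equal(cas$exon_transcript, "AgdsxF")
  expect_equal(cas$exon_ordinal, 5)
  expect_equal(c(cas$exon_low, cas$exon_high), c(48712957, 48714648))
  expect_equal(cas$host_transcript, "AgdsxM")
  expect_equal(cas$host_intron_ordinal, 4)
  expect_equal(c(cas$host_low, cas$host_high), c(48712795, 48715160))
})

test_that("cassette detection requires full containment of exon and flanks", {
  g <- toy_plus_gene()  # trA exon [50,60] inside trB intron [40,80]
  cas <- detect_cassette_exons(g)
  expect_equal(nrow(cas), 1)
  expect_equal(c(cas$exon_low, cas$exon_high), c(50, 60))
  expect_equal(c(cas$host_low, cas$host_high), c(40, 80))
  # exon only partially inside the host intron [40, 80]: no cassette
  a2 <- transcript_model("trA", rbind(c(20, 39), c(70, 90), c(101, 120)))
  b <- transcript_model("trB", rbind(c(20, 39), c(81, 100)))
  g2 <- gene_model("toy", "chr1", "+", list(a2, b), span = c(1, 140))
  expect_equal(nrow(detect_cassette_exons(g2)), 0)
  # identical transcripts: nothing to skip
  expect_equal(nrow(detect_cassette_exons(
    gene_model("dup", "chr1", "+",
               list(transcript_model("x", rbind(c(1, 10), c(20, 30), c(40, 50))),
                    transcript_model("y", rbind(c(1, 10), c(20, 30), c(40, 50))))))),
    0)
})

test_that("junction classification is strand-symmetric under coordinate mirroring", {
  m <- gene$span[1] + gene$span[2]
  mirrored <- lapply(gene$transcripts, function(tr) {
    ex <- data.frame(low = m - tr$exons$high, high = m - tr$exons$low)
    transcript_model(tr$id, ex[order(ex$low), ])
  })
  gmir <- gene_model(gene$gene_id, gene$chrom, "+", unname(mirrored),
                     span = c(m - gene$span[2], m - gene$span[1]))
  j <- classify_junctions(gene)
  jm <- classify_junctions(gmir)
  expect_equal(table(jm$kind, jm$sharing), table(j$kind, j$sharing))
  # a donor at boundary b maps to a donor at m - b
  for (kind in c("donor", "acceptor"))
    expect_setequal(m - j$boundary[j$kind == kind],
                    jm$boundary[jm$kind == kind])
})

test_that("JSON and GFF3 readers reconstruct the same model", {
  jf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    gene_id = "toy", chrom = "chr1", strand = "+", span = c(1, 120),
    transcripts = list(
      list(id = "trA", sex_label = "none",
           exons = list(c(20, 39), c(50, 60), c(81, 100))),
      list(id = "trB", sex_label = "none",
           exons = list(c(20, 39), c(81, 100))))),
    jf, auto_unbox = TRUE)
  gj <- read_gene_model(jf)
  expect_equal(gj$transcripts$trA$exons, toy_plus_gene()$transcripts$trA$exons)

  skip_if_not_installed("rtracklayer")
  gf <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t20\t100\t.\t+\t.\tID=toy",
    "chr1\ttest\tmRNA\t20\t100\t.\t+\t.\tID=trA;Parent=toy",
    "chr1\ttest\texon\t20\t39\t.\t+\t.\tParent=trA",
    "chr1\ttest\texon\t50\t60\t.\t+\t.\tParent=trA",
    "chr1\ttest\texon\t81\t100\t.\t+\t.\tParent=trA",
    "chr1\ttest\tmRNA\t20\t100\t.\t+\t.\tID=trB;Parent=toy",
    "chr1\ttest\texon\t20\t39\t.\t+\t.\tParent=trB",
    "chr1\ttest\texon\t81\t100\t.\t+\t.\tParent=trB"), gf)
  gg <- read_gene_model_gff3(gf, gene_id = "toy")
  expect_equal(gg$transcripts$trA$exons$low, c(20, 50, 81))
  expect_equal(gg$transcripts$trB$exons$high, c(39, 100))
  expect_equal(gg$strand, "+")
})
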