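#' Packaged splice-site sequence table
#'
#' The donor/acceptor site sequences and transcript-order position pairs of
#' the Agdsx gene, as used both to embed sites into the synthetic reference
#' and as the expected output of the site-derivation stage.
#'
#' @return data.frame with columns \code{kind}, \code{gender},
#'   \code{ordinal}, \code{element_size}, \code{element_start},
#'   \code{element_end}, \code{site_start}, \code{site_end}, \code{sequence}.
#' @export
agdsx_site_sequences <- function() {
  utils::read.delim(system.file("extdata", "agdsx_splice_sites.tsv",
                                package = "agdsx", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Packaged cohort sampling table
#'
#' Sampling sites with female/male counts per population, mirroring the
#' Ag1000G phase 2 An. gambiae s.s. cohort structure.
#'
#' @return data.frame with columns \code{country}, \code{site}, \code{year},
#'   \code{latitude}, \code{longitude}, \code{n_total}, \code{n_female},
#'   \code{n_male}.
#' @export
agdsx_cohort_sites <- function() {
  utils::read.delim(system.file("extdata", "ag1000g_cohort.tsv",
                                package = "agdsx", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

country_codes <- c("Burkina Faso" = "BF", "Cameroon" = "CM",
                   "Equatorial Guinea" = "GQ", "France (Mayotte)" = "FR",
                   "Gabon" = "GA", "Ghana" = "GH", "Guinea" = "GN",
                   "Uganda" = "UG")

#' Default planted splice-window variants
#'
#' The nine variant positions reported inside Agdsx splice windows: seven in
#' the intron 3 acceptor window and two in the female exon 5 donor window.
#' Frequencies follow the reported pattern: the exon-5-donor pair is rare
#' (female alt frequencies under 1\%, 2\% in Burkina Faso males for
#' rs48712947, rs48712962 in Cameroon females only); the intron-3 set occurs
#' in all strata at varied low frequencies. \code{country}/\code{sex} value
#' \code{"*"} means every stratum.
#'
#' @return data.frame with columns \code{pos}, \code{country}, \code{sex},
#'   \code{freq}.
#' @export
default_planted_variants <- function() {
  rbind(
    data.frame(pos = 48712947, country = c("Burkina Faso", "Burkina Faso",
                                           "Cameroon"),
               sex = c("F", "M", "F"), freq = c(0.008, 0.02, 0.005)),
    data.frame(pos = 48712962, country = "Cameroon", sex = "F", freq = 0.005),
    data.frame(pos = c(48715291, 48715294, 48715302, 48715306, 48715307,
                       48715308, 48715309),
               country = "*", sex = "*",
               freq = c(0.02, 0.10, 0.03, 0.05, 0.08, 0.04, 0.06)))
}

#' Simulation configuration
#'
#' Bundles everything the generators need: the gene model whose splice sites
#' are embedded, the cohort structure, background SNP density, planted
#' stratum-specific variants, and the seed. The default background density,
#' 17196 / 84797 sites per bp, makes the expected polymorphic-site count of
#' the default contig match the density observed at this locus in the
#' Ag1000G phase 2 cohort.
#'
#' @param seed Integer seed driving all randomness.
#' @param gene Gene model to embed (default \code{\link{agdsx_gene_model}}).
#' @param site_sequences Site-sequence table (default
#'   \code{\link{agdsx_site_sequences}}).
#' @param cohort Sampling table (default \code{\link{agdsx_cohort_sites}}).
#' @param density Background SNP density in sites per bp.
#' @param planted data.frame of planted variants (pos, country, sex, freq).
#' @param missing_rate Per-genotype missingness probability.
#' @param shift Uniform coordinate shift applied to the whole system (gene
#'   model, sites, contig), for producing small or relocated contigs.
#' @param avoid_windows When TRUE (default) background variants are kept out
#'   of the 22-nt splice windows, so window content is exactly the planted
#'   set; planted variants may sit anywhere.
#' @param contig Contig name.
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 1, gene = agdsx_gene_model(),
                              site_sequences = agdsx_site_sequences(),
                              cohort = agdsx_cohort_sites(),
                              density = 17196 / 84797,
                              planted = default_planted_variants(),
                              missing_rate = 0, shift = 0,
                              avoid_windows = TRUE,
                              contig = gene$chrom) {
  stopifnot(all(planted$freq >= 0 & planted$freq <= 1), missing_rate >= 0,
            missing_rate <= 1, density >= 0)
  if (shift != 0) {
    gene <- shift_gene_model(gene, shift)
    for (col in c("element_start", "element_end", "site_start", "site_end"))
      site_sequences[[col]] <- site_sequences[[col]] + shift
    planted$pos <- planted$pos + shift
  }
  span <- gene$span
  if (any(planted$pos < span[1] | planted$pos > span[2]))
    stop("planted position outside the contig span")
  structure(list(seed = as.integer(seed), gene = gene,
                 site_sequences = site_sequences, cohort = cohort,
                 density = density, planted = planted,
                 missing_rate = missing_rate, shift = shift,
                 avoid_windows = avoid_windows, contig = contig,
                 span = span),
            class = "sim_config")
}

#' Shift a gene model's coordinates uniformly
#'
#' @param gene A \code{\link{gene_model}}.
#' @param shift Signed integer shift added to every coordinate.
#' @return The shifted \code{\link{gene_model}}.
#' @export
shift_gene_model <- function(gene, shift) {
  trs <- lapply(gene$transcripts, function(t) {
    t$exons$low <- t$exons$low + shift
    t$exons$high <- t$exons$high + shift
    t
  })
  cds <- if (!is.null(gene$cds)) lapply(gene$cds, function(iv) iv + shift)
  gene_model(gene$gene_id, gene$chrom, gene$strand, unname(trs),
             span = gene$span + shift, cds = cds)
}

#' Generate the synthetic reference contig
#'
#' Fills the gene span with seeded random bases, then overwrites every
#' splice-site window with its known sequence (reverse-complemented for
#' forward-strand storage when the gene is on the minus strand). Each
#' embedded window is first validated against the window derived from the
#' gene model; overlapping embeddings that disagree on a base are an error.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{ref_contig}} whose offset places local base 1 at the
#'   span's low coordinate.
#' @export
make_reference <- function(config) {
  gene <- config$gene
  span <- config$span
  len <- span[2] - span[1] + 1
  set.seed(config$seed)
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  derived <- splice_site_table(gene)
  owner <- rep(NA_integer_, len)
  st <- config$site_sequences
  for (i in seq_len(nrow(st))) {
    lo <- min(st$site_start[i], st$site_end[i])
    hi <- max(st$site_start[i], st$site_end[i])
    hit <- derived$kind == st$kind[i] & derived$win_low == lo &
      derived$win_high == hi
    if (!any(hit))
      stop("site-sequence row ", i, " (", st$kind[i], " [", lo, ", ", hi,
           "]) does not match any window derived from the gene model")
    s <- toupper(gsub("/", "", st$sequence[i]))
    if (nchar(s) != hi - lo + 1) stop("sequence length mismatch at row ", i)
    if (gene$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    idx <- (lo:hi) - span[1] + 1
    chars <- strsplit(s, "")[[1]]
    clash <- !is.na(owner[idx]) & bases[idx] != chars
    if (any(clash))
      stop("embedded windows overlap with conflicting bases near position ",
           lo + which(clash)[1] - 1)
    bases[idx] <- chars
    owner[idx] <- i
  }
  ref_contig(paste(bases, collapse = ""), config$contig, offset = span[1] - 1)
}

#' Expand the sampling table into per-sample metadata
#'
#' @param config A \code{\link{simulation_config}} (or a cohort data.frame).
#' @return data.frame with columns \code{sample_id}, \code{country},
#'   \code{site}, \code{year}, \code{sex}; ids are deterministic
#'   (country code + sex + counter).
#' @export
make_cohort_metadata <- function(config) {
  cohort <- if (inherits(config, "sim_config")) config$cohort else config
  rows <- list()
  counter <- new.env()
  for (i in seq_len(nrow(cohort))) {
    for (sx in c("F", "M")) {
      n <- if (sx == "F") cohort$n_female[i] else cohort$n_male[i]
      if (n == 0) next
      code <- country_codes[cohort$country[i]]
      if (is.na(code))
        code <- toupper(substr(gsub("[^A-Za-z]", "", cohort$country[i]), 1, 2))
      key <- paste0(code, sx)
      base <- if (is.null(counter[[key]])) 0L else counter[[key]]
      counter[[key]] <- base + n
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s%s%03d", code, sx, base + seq_len(n)),
        country = cohort$country[i], site = cohort$site[i],
        year = cohort$year[i], sex = sx, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-sample alt-allele frequency vector for one planted variant
planted_freqs <- function(planted_rows, metadata) {
  p <- rep(0, nrow(metadata))
  for (i in seq_len(nrow(planted_rows))) {
    sel <- rep(TRUE, nrow(metadata))
    if (planted_rows$country[i] != "*")
      sel <- sel & metadata$country == planted_rows$country[i]
    if (planted_rows$sex[i] != "*")
      sel <- sel & metadata$sex == planted_rows$sex[i]
    p[sel] <- planted_rows$freq[i]
  }
  p
}

#' Simulate the cohort variant panel
#'
#' Draws background SNP positions at the configured density (Poisson count,
#' uniform placement avoiding planted positions), assigns each background
#' variant one cohort-wide alt frequency from a neutral 1/x site-frequency
#' spectrum on [0.001, 0.5] (the cohort is panmictic by construction), and
#' plants the configured stratum-specific variants. Diploid genotypes are
#' drawn per sample as Binomial(2, p) (Hardy-Weinberg); missing calls are
#' injected at the configured rate. REF alleles come from the reference;
#' ALT is a random different base. IDs are \code{"rs" + position}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param ref Reference contig from \code{\link{make_reference}}.
#' @param metadata Optional precomputed \code{\link{make_cohort_metadata}}.
#' @return List with \code{variants} (chrom, pos, id, ref, alt),
#'   \code{gt} (dosage matrix, variants x samples), \code{metadata}.
#' @export
simulate_cohort <- function(config, ref, metadata = NULL) {
  force(ref)  # evaluate before seeding: make_reference() seeds the RNG itself
  if (is.null(metadata)) metadata <- make_cohort_metadata(config)
  span <- config$span
  set.seed(config$seed + 1L)
  n_bg <- stats::rpois(1, config$density * (span[2] - span[1] + 1))
  allowed <- setdiff(seq(span[1], span[2]), config$planted$pos)
  if (isTRUE(config$avoid_windows)) {
    win <- splice_site_table(config$gene)
    in_win <- unlist(mapply(seq, win$win_low, win$win_high,
                            SIMPLIFY = FALSE))
    allowed <- setdiff(allowed, in_win)
  }
  bg_pos <- sort(sample(allowed, min(n_bg, length(allowed))))
  pmin_sfs <- 0.001
  bg_p <- pmin_sfs * (0.5 / pmin_sfs)^stats::runif(length(bg_pos))

  pl_pos <- sort(unique(config$planted$pos))
  pos <- c(bg_pos, pl_pos)
  o <- order(pos)
  pos <- pos[o]
  is_planted <- c(rep(FALSE, length(bg_pos)), rep(TRUE, length(pl_pos)))[o]
  bg_lookup <- stats::setNames(bg_p, bg_pos)

  refb <- strsplit(ref_subseq(ref, span[1], span[2]), "")[[1]]
  ref_allele <- refb[pos - span[1] + 1]
  if (any(!ref_allele %in% c("A", "C", "G", "T")))
    stop("planted or background position falls on a non-ACGT reference base")
  alt_allele <- vapply(ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")

  n_samp <- nrow(metadata)
  gt <- matrix(NA_integer_, length(pos), n_samp,
               dimnames = list(paste0("rs", pos), metadata$sample_id))
  for (i in seq_along(pos)) {
    p <- if (is_planted[i])
      planted_freqs(config$planted[config$planted$pos == pos[i], , drop = FALSE],
                    metadata)
    else rep(bg_lookup[[as.character(pos[i])]], n_samp)
    gt[i, ] <- stats::rbinom(n_samp, 2L, p)
  }
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(gt)) < config$missing_rate
    gt[drop] <- NA_integer_
  }
  list(variants = data.frame(chrom = config$contig, pos = pos,
                             id = paste0("rs", pos), ref = ref_allele,
                             alt = alt_allele, stringsAsFactors = FALSE),
       gt = gt, metadata = metadata)
}

#' Write a cohort panel as a VCF (plus metadata TSV)
#'
#' Emits a minimal VCFv4.2 with FILTER=PASS, GT-only FORMAT and diploid
#' unphased genotypes; missing calls are \code{./.}.
#'
#' @param panel Result of \code{\link{simulate_cohort}}.
#' @param vcf_path Output VCF path (plain text).
#' @param meta_path Optional output metadata TSV path.
#' @return \code{vcf_path}, invisibly.
#' @export
write_cohort_vcf <- function(panel, vcf_path, meta_path = NULL) {
  v <- panel$variants
  gt_str <- matrix(c("0/0", "0/1", "1/1")[panel$gt + 1L], nrow = nrow(v))
  gt_str[is.na(gt_str)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=agdsx synthetic cohort simulator",
           sprintf("##contig=<ID=%s>", v$chrom[1]),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(panel$gt)), collapse = "\t"))
  body <- do.call(paste, c(list(v$chrom, v$pos, v$id, v$ref, v$alt, ".",
                                "PASS", ".", "GT"),
                           as.data.frame(gt_str, stringsAsFactors = FALSE),
                           sep = "\t"))
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(meta_path))
    utils::write.table(panel$metadata, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(vcf_path)
}

#' Generate the full synthetic fixture set
#'
#' Reference FASTA, cohort VCF, metadata TSV and a JSON echo of the
#' configuration, all derived from one seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
make_fixture_set <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- make_reference(config)
  panel <- simulate_cohort(config, ref)
  paths <- list(reference = file.path(outdir, "reference.fa"),
                vcf = file.path(outdir, "cohort.vcf"),
                metadata = file.path(outdir, "samples.tsv"),
                config = file.path(outdir, "config.json"))
  write_reference_fasta(ref, paths$reference)
  write_cohort_vcf(panel, paths$vcf, paths$metadata)
  echo <- list(seed = config$seed, contig = config$contig,
               span = config$span, density = config$density,
               missing_rate = config$missing_rate, shift = config$shift,
               planted = config$planted,
               n_samples = nrow(panel$metadata),
               n_variants = nrow(panel$variants))
  jsonlite::write_json(echo, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
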