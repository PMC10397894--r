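#' Read sample metadata
#'
#' @param path TSV with at least columns \code{sample_id}, \code{country},
#'   \code{sex} (\code{"F"}/\code{"M"}); \code{site} and \code{year} optional.
#' @return data.frame of metadata.
#' @export
read_sample_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c(sex = "character"))
  need <- c("sample_id", "country", "sex")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample ids in metadata")
  if (any(!nzchar(m$sex)) || any(!nzchar(m$country)))
    stop("empty sex or country in metadata")
  if (!all(m$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  m
}

# diploid GT string -> alt-allele dosage (0/1/2, NA for missing)
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- rep(NA_integer_, length(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  hit <- gt %in% names(known)
  out[hit] <- known[gt[hit]]
  out
}

#' Load biallelic PASS SNPs from a VCF region
#'
#' Retains only records that are FILTER=PASS, have single-nucleotide REF and
#' ALT (one ALT allele), and fall inside the requested span, in coordinate
#' order. Multiallelic and non-SNP records are counted and dropped. Missing
#' IDs are synthesised as \code{"rs" + position}.
#'
#' @param vcf_path Path to a VCF (plain or gzipped) with GT genotypes.
#' @param span A \code{\link{genomic_interval}} or numeric \code{c(low, high)}.
#' @param chrom Chromosome to keep; taken from \code{span} when it is a
#'   \code{genomic_interval}.
#' @return List with \code{variants} (data.frame: chrom, pos, id, ref, alt),
#'   \code{gt} (integer dosage matrix, variants x samples), \code{samples},
#'   and \code{excluded} (named counts of dropped records).
#' @export
load_region_snps <- function(vcf_path, span, chrom = NULL) {
  if (inherits(span, "genomic_interval")) {
    chrom <- span$chrom; span <- c(span$low, span$high)
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(list(variants = data.frame(chrom = character(), pos = numeric(),
                                      id = character(), ref = character(),
                                      alt = character()),
                gt = matrix(integer(), 0, 0), samples = character(),
                excluded = c(off_target = 0L, non_pass = 0L,
                             multiallelic = 0L, non_snp = 0L)))
  if (ncol(v@gt) < 2L || v@gt[1, "FORMAT"] == "" ||
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF has no GT genotype field")
  pos <- as.numeric(fix$POS)
  in_span <- pos >= span[1] & pos <= span[2]
  if (!is.null(chrom)) in_span <- in_span & fix$CHROM == chrom
  is_pass <- fix$FILTER == "PASS"
  is_bi <- !grepl(",", fix$ALT)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & is_bi &
    fix$REF != fix$ALT
  keep <- in_span & is_pass & is_bi & is_snp
  excluded <- c(off_target = sum(!in_span),
                non_pass = sum(in_span & !is_pass),
                multiallelic = sum(in_span & is_pass & !is_bi),
                non_snp = sum(in_span & is_pass & is_bi & !is_snp))
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  o <- order(pos)
  fix <- fix[o, , drop = FALSE]; pos <- pos[o]
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0("rs", pos[is.na(id) | id == "."])
  samples <- colnames(v@gt)[-1]
  gtm <- v@gt[keep, -1, drop = FALSE][o, , drop = FALSE]
  dos <- matrix(gt_to_dosage(gtm), nrow = nrow(fix), ncol = length(samples),
                dimnames = list(id, samples))
  list(variants = data.frame(chrom = fix$CHROM, pos = pos, id = id,
                             ref = fix$REF, alt = fix$ALT,
                             stringsAsFactors = FALSE),
       gt = dos, samples = samples, excluded = excluded)
}

#' Positional tier of a SNP inside a splice window
#'
#' Offsets run 0-21 in transcript orientation. Donor windows: offsets 0-5
#' exonic, 6-7 the invariant gt dinucleotide, 8-21 intron. Acceptor windows:
#' offsets 0-11 polypyrimidine tract, 12 N, 13 Y, 14-15 the invariant ag,
#' 16-21 exonic.
#'
#' @param kind \code{"donor"} or \code{"acceptor"} (vectorised).
#' @param offset Integer window offset 0-21 (vectorised).
#' @return Character vector: \code{"dinucleotide"}, \code{"NYag_Y"} or
#'   \code{"window"}.
#' @export
classify_tier <- function(kind, offset) {
  stopifnot(all(offset >= 0 & offset <= 21))
  tier <- rep("window", length(offset))
  tier[kind == "donor" & offset %in% 6:7] <- "dinucleotide"
  tier[kind == "acceptor" & offset %in% 14:15] <- "dinucleotide"
  tier[kind == "acceptor" & offset == 13] <- "NYag_Y"
  tier
}

#' Intersect variants with splice-site windows
#'
#' @param variants data.frame with \code{pos} (and optionally \code{id}).
#' @param sites Splice-site table from \code{\link{splice_site_table}} (needs
#'   \code{kind}, \code{win_low}, \code{win_high}, \code{sharing}).
#' @param strand Gene strand, for transcript-orientation offsets.
#' @return data.frame of hits: one row per (variant, site) pair with the
#'   variant inside the window; columns include \code{offset} (0-21 in
#'   transcript orientation) and \code{tier}.
#' @export
intersect_windows <- function(variants, sites, strand) {
  res <- list()
  for (i in seq_len(nrow(sites))) {
    sel <- variants$pos >= sites$win_low[i] & variants$pos <= sites$win_high[i]
    if (!any(sel)) next
    hv <- variants[sel, , drop = FALSE]
    offset <- if (strand == "-") sites$win_high[i] - hv$pos else
      hv$pos - sites$win_low[i]
    res[[length(res) + 1L]] <- data.frame(
      id = if ("id" %in% names(hv)) hv$id else paste0("rs", hv$pos),
      pos = hv$pos,
      site_kind = sites$kind[i],
      site_boundary = sites$boundary[i],
      site_sharing = sites$sharing[i],
      site_transcripts = sites$transcripts[i],
      win_low = sites$win_low[i], win_high = sites$win_high[i],
      offset = as.integer(offset),
      tier = classify_tier(sites$kind[i], offset),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(id = character(), pos = numeric(),
                      site_kind = character(), site_boundary = numeric(),
                      site_sharing = character(), site_transcripts = character(),
                      win_low = numeric(), win_high = numeric(),
                      offset = integer(), tier = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Sex presence and association of a variant
#'
#' Presence flags are descriptive: which sexes contain at least one
#' non-missing alt-carrying sample. The two-sided Fisher exact test on the
#' 2x2 sex-by-allele count table is an added inferential summary and never
#' overrides the descriptive flags.
#'
#' @param dosages Integer alt dosages (0/1/2, NA missing), one per sample.
#' @param metadata Metadata data.frame aligned with \code{dosages} by
#'   \code{sample_id} = names, or positionally if unnamed.
#' @return List: \code{sex_presence} (\code{"female_only"}, \code{"male_only"},
#'   \code{"both"}, \code{"absent"}), \code{odds_ratio}, \code{p_value},
#'   \code{test_skipped} (TRUE when a sex has no called samples).
#' @export
sex_specificity <- function(dosages, metadata) {
  sex <- metadata$sex[match_samples(dosages, metadata)]
  called <- !is.na(dosages)
  carrier_f <- any(dosages[called & sex == "F"] > 0)
  carrier_m <- any(dosages[called & sex == "M"] > 0)
  presence <- if (carrier_f && carrier_m) "both"
    else if (carrier_f) "female_only"
    else if (carrier_m) "male_only" else "absent"
  n_f <- sum(called & sex == "F"); n_m <- sum(called & sex == "M")
  if (n_f == 0L || n_m == 0L)
    return(list(sex_presence = presence, odds_ratio = NA_real_,
                p_value = NA_real_, test_skipped = TRUE))
  alt_f <- sum(dosages[called & sex == "F"])
  alt_m <- sum(dosages[called & sex == "M"])
  tab <- matrix(c(2 * n_f - alt_f, alt_f, 2 * n_m - alt_m, alt_m),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("F", "M"), c("ref", "alt")))
  ft <- stats::fisher.test(tab)
  list(sex_presence = presence, odds_ratio = unname(ft$estimate),
       p_value = ft$p.value, test_skipped = FALSE)
}

# align a dosage vector with metadata rows; by names when available
match_samples <- function(dosages, metadata) {
  if (!is.null(names(dosages))) {
    idx <- match(names(dosages), metadata$sample_id)
    if (anyNA(idx))
      stop("samples absent from metadata: ",
           paste(utils::head(names(dosages)[is.na(idx)]), collapse = ", "))
    idx
  } else {
    if (length(dosages) != nrow(metadata))
      stop("unnamed dosages must match metadata length")
    seq_len(nrow(metadata))
  }
}

#' Stratified minor allele frequency
#'
#' @param dosages Integer alt dosages (0/1/2, NA missing), one per sample,
#'   named by sample id (or positionally aligned with \code{metadata}).
#' @param metadata Metadata data.frame with the stratifying columns.
#' @param strata Character vector of metadata columns defining the cells
#'   (default population and sex).
#' @return data.frame with one row per stratum cell: stratifier columns,
#'   \code{n_samples}, \code{n_called} (samples with a genotype),
#'   \code{alt_alleles}, \code{alt_freq}, \code{maf}. Cells with no called
#'   samples have NA frequencies (undefined, not zero).
#' @export
stratified_maf <- function(dosages, metadata, strata = c("country", "sex")) {
  idx <- match_samples(dosages, metadata)
  md <- metadata[idx, , drop = FALSE]
  key <- interaction(md[strata], drop = TRUE, sep = "|")
  cells <- lapply(levels(key), function(lv) {
    sel <- key == lv
    d <- dosages[sel]
    n_called <- sum(!is.na(d))
    alt <- if (n_called > 0) sum(d, na.rm = TRUE) else NA_integer_
    p <- if (n_called > 0) alt / (2 * n_called) else NA_real_
    cbind(md[which(sel)[1], strata, drop = FALSE],
          data.frame(n_samples = sum(sel), n_called = n_called,
                     alt_alleles = alt, alt_freq = p,
                     maf = ifelse(is.na(p), NA_real_, pmin(p, 1 - p))))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Apply the splice-relevance rule to hits
#'
#' A hit is called splice-relevant when it falls on invariant machinery
#' (the gt/ag dinucleotides or the acceptor Y position), or when it is a
#' plain window hit that is both sex-exclusive and common (maximum stratum
#' MAF at or above \code{maf_threshold}). This operationalises a judgement
#' the source data leaves informal; both the rule and the threshold are
#' exposed.
#'
#' @param hits Hit data.frame from \code{\link{intersect_windows}} augmented
#'   with \code{sex_presence} and \code{max_maf} columns.
#' @param maf_threshold MAF threshold for sex-exclusive window hits.
#' @return \code{hits} with a logical \code{splice_relevant} column and a
#'   \code{verdict} string.
#' @export
splice_relevance <- function(hits, maf_threshold = 0.05) {
  critical <- hits$tier %in% c("dinucleotide", "NYag_Y")
  sexed <- hits$sex_presence %in% c("female_only", "male_only")
  common <- !is.na(hits$max_maf) & hits$max_maf >= maf_threshold
  hits$splice_relevant <- critical | (hits$tier == "window" & sexed & common)
  hits$verdict <- ifelse(hits$splice_relevant, "splice-relevant",
                         "not splice-relevant")
  hits
}

#' Full splice-window SNP scan
#'
#' Intersects variants with splice windows, then annotates every hit with
#' sex presence, the Fisher sex-association test, per-stratum MAFs, and the
#' splice-relevance verdict.
#'
#' @param snps Result of \code{\link{load_region_snps}} (or a list with
#'   \code{variants} and \code{gt}).
#' @param sites Splice-site table from \code{\link{splice_site_table}}.
#' @param metadata Sample metadata (see \code{\link{read_sample_metadata}}).
#' @param strand Gene strand.
#' @param maf_threshold Threshold for \code{\link{splice_relevance}}.
#' @return List with \code{hits} (annotated hit table) and \code{maf}
#'   (long-format per-stratum MAF table for every hit variant).
#' @export
scan_splice_windows <- function(snps, sites, metadata, strand,
                                maf_threshold = 0.05) {
  miss <- setdiff(snps$samples, metadata$sample_id)
  if (length(miss))
    stop("VCF samples missing from metadata: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  hits <- intersect_windows(snps$variants, sites, strand)
  if (nrow(hits) == 0L)
    return(list(hits = cbind(hits, data.frame(sex_presence = character(),
                                              odds_ratio = numeric(),
                                              p_value = numeric(),
                                              max_maf = numeric(),
                                              splice_relevant = logical(),
                                              verdict = character())),
                maf = data.frame()))
  ann <- lapply(seq_len(nrow(hits)), function(i) {
    d <- snps$gt[match(hits$id[i], rownames(snps$gt)), ]
    ss <- sex_specificity(d, metadata)
    sm <- stratified_maf(d, metadata)
    data.frame(sex_presence = ss$sex_presence,
               odds_ratio = ss$odds_ratio, p_value = ss$p_value,
               max_maf = if (all(is.na(sm$maf))) NA_real_ else
                 max(sm$maf, na.rm = TRUE))
  })
  hits <- cbind(hits, do.call(rbind, ann))
  hits <- splice_relevance(hits, maf_threshold)
  maf_long <- do.call(rbind, lapply(unique(hits$id), function(vid) {
    d <- snps$gt[match(vid, rownames(snps$gt)), ]
    cbind(data.frame(id = vid,
                     pos = snps$variants$pos[match(vid, snps$variants$id)]),
          stratified_maf(d, metadata))
  }))
  list(hits = hits, maf = maf_long)
}
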