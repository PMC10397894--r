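#' Donor splice-site window
#'
#' A donor window spans the last 6 exonic bases and the first 16 intronic
#' bases of the exon/intron junction, 22 nt in all. \code{boundary} is the
#' genomic coordinate of the last exonic base in transcript orientation.
#'
#' @param boundary Genomic coordinate of the last exonic base.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Numeric \code{c(low, high)} genomic bounds of the 22-nt window.
#' @export
build_donor_window <- function(boundary, strand) {
  if (strand == "-") c(boundary - 16, boundary + 5) else c(boundary - 5, boundary + 16)
}

#' Acceptor splice-site window
#'
#' An acceptor window spans the last 16 intronic bases (a 12-nt
#' polypyrimidine tract followed by the NYag pattern that closes the intron)
#' and the first 6 exonic bases, 22 nt in all. \code{boundary} is the genomic
#' coordinate of the first exonic base in transcript orientation.
#'
#' @param boundary Genomic coordinate of the first exonic base.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Numeric \code{c(low, high)} genomic bounds of the 22-nt window.
#' @export
build_acceptor_window <- function(boundary, strand) {
  if (strand == "-") c(boundary - 5, boundary + 16) else c(boundary - 16, boundary + 5)
}

#' Donor window of a specific exon, with terminal-exon guard
#'
#' @param gene A \code{\link{gene_model}}.
#' @param transcript_id Transcript id within the gene.
#' @param exon_ordinal 1-based exon ordinal in transcript order.
#' @return Numeric \code{c(low, high)}.
#' @export
transcript_donor_window <- function(gene, transcript_id, exon_ordinal) {
  tr <- gene$transcripts[[transcript_id]]
  if (is.null(tr)) stop("unknown transcript ", transcript_id)
  k <- nrow(tr$exons)
  if (exon_ordinal >= k) stop("no donor at terminal exon ", exon_ordinal,
                              " of ", transcript_id)
  b <- if (gene$strand == "-") tr$exons$low[exon_ordinal] else
    tr$exons$high[exon_ordinal]
  build_donor_window(b, gene$strand)
}

#' Acceptor window of a specific exon, with first-exon guard
#'
#' @inheritParams transcript_donor_window
#' @return Numeric \code{c(low, high)}.
#' @export
transcript_acceptor_window <- function(gene, transcript_id, exon_ordinal) {
  tr <- gene$transcripts[[transcript_id]]
  if (is.null(tr)) stop("unknown transcript ", transcript_id)
  if (exon_ordinal <= 1L) stop("no acceptor at first exon of ", transcript_id)
  b <- if (gene$strand == "-") tr$exons$high[exon_ordinal] else
    tr$exons$low[exon_ordinal]
  build_acceptor_window(b, gene$strand)
}

#' Extract the strand-corrected sequence of a splice-site window
#'
#' Returns the window sequence in transcript (5' to 3') orientation:
#' reverse-complemented when the gene is on the minus strand. Case encodes
#' annotation: intronic bases are lower case; exonic bases are upper case when
#' coding (inside a \code{cds} interval) and lower case otherwise; with no
#' \code{cds} all exonic bases are upper case. Non-ACGT bases are carried
#' through upper-cased with a warning. Windows that run off the contig are
#' truncated and flagged rather than padded.
#'
#' @param ref A \code{\link{ref_contig}}.
#' @param window Numeric \code{c(low, high)} genomic bounds (22 nt).
#' @param kind \code{"donor"} or \code{"acceptor"}.
#' @param strand \code{"+"} or \code{"-"}.
#' @param cds Optional list of \code{c(low, high)} coding intervals.
#' @return A list of class \code{"splice_site_seq"}: \code{kind},
#'   \code{window}, \code{exonic_part}, \code{intronic_part}, \code{tract12}
#'   and \code{nyag} (acceptors only), \code{rendered} (exon/intron parts
#'   joined with \code{"/"} in transcript order), \code{truncated}.
#' @export
extract_site_sequence <- function(ref, window, kind, strand, cds = NULL) {
  stopifnot(kind %in% c("donor", "acceptor"))
  b <- ref_bounds(ref)
  lo <- window[1]; hi <- window[2]
  if (hi < b[1] || lo > b[2])
    stop("window [", lo, ", ", hi, "] entirely outside contig bounds")
  truncated <- lo < b[1] || hi > b[2]
  clo <- max(lo, b[1]); chi <- min(hi, b[2])
  fwd <- ref_subseq(ref, clo, chi)

  # per-base genomic positions and sequence in transcript orientation
  pos <- clo:chi
  seqc <- strsplit(fwd, "")[[1]]
  if (strand == "-") {
    seqc <- strsplit(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(fwd))), "")[[1]]
    pos <- rev(pos)
  }

  # full-window offsets 0..21 in transcript orientation; map surviving bases
  full_lo <- lo; full_hi <- hi
  off <- if (strand == "-") full_hi - pos else pos - full_lo
  n_ex <- 6L; n_in <- 16L
  exonic_off <- if (kind == "donor") 0:(n_ex - 1L) else (n_in):(n_ex + n_in - 1L)
  is_ex <- off %in% exonic_off

  if (is.null(cds)) {
    coding <- rep(TRUE, length(pos))  # no CDS: all exonic bases render upper
  } else {
    coding <- rep(FALSE, length(pos))
    for (iv in cds) coding <- coding | (pos >= iv[1] & pos <= iv[2])
  }

  bad <- !toupper(seqc) %in% c("A", "C", "G", "T")
  if (any(bad))
    warning("non-ACGT base(s) in window [", lo, ", ", hi, "]: ",
            paste(unique(seqc[bad]), collapse = ","))
  out <- tolower(seqc)
  up <- is_ex & coding & !bad
  out[up] <- toupper(out[up])
  out[bad] <- toupper(seqc[bad])

  exonic_part <- paste(out[is_ex], collapse = "")
  intronic_part <- paste(out[!is_ex], collapse = "")
  rendered <- if (kind == "donor") paste0(exonic_part, "/", intronic_part)
              else paste0(intronic_part, "/", exonic_part)
  res <- list(kind = kind, window = c(lo, hi), strand = strand,
              exonic_part = exonic_part, intronic_part = intronic_part,
              rendered = rendered, truncated = truncated)
  if (kind == "acceptor" && nchar(intronic_part) == 16L) {
    res$tract12 <- substr(intronic_part, 1L, 12L)
    res$nyag <- substr(intronic_part, 13L, 16L)
  }
  class(res) <- "splice_site_seq"
  res
}

#' Check canonical splice motifs
#'
#' A donor is canonical when its intron starts with \code{gt}; an acceptor is
#' canonical when its closing NYag pattern has a pyrimidine (c/t) at the Y
#' position and ends with \code{ag}.
#'
#' @param site A \code{\link{extract_site_sequence}} result.
#' @return List with \code{canonical} (logical) and \code{violations}
#'   (character vector naming the offending window offsets).
#' @export
validate_canonical_motifs <- function(site) {
  viol <- character()
  if (site$kind == "donor") {
    din <- tolower(substr(site$intronic_part, 1L, 2L))
    if (substr(din, 1L, 1L) != "g")
      viol <- c(viol, "offset 6: donor intron base 1 is not g")
    if (substr(din, 2L, 2L) != "t")
      viol <- c(viol, "offset 7: donor intron base 2 is not t")
  } else {
    ny <- tolower(site$nyag)
    if (is.null(ny) || nchar(ny) != 4L) {
      viol <- c(viol, "acceptor intronic part incomplete")
    } else {
      if (!substr(ny, 2L, 2L) %in% c("c", "t"))
        viol <- c(viol, "offset 13: NYag Y position is a purine")
      if (substr(ny, 3L, 3L) != "a")
        viol <- c(viol, "offset 14: acceptor dinucleotide base is not a")
      if (substr(ny, 4L, 4L) != "g")
        viol <- c(viol, "offset 15: acceptor dinucleotide base is not g")
    }
  }
  list(canonical = length(viol) == 0L, violations = viol)
}

#' Polypyrimidine-tract score of an acceptor
#'
#' Counts pyrimidines (c/t) in the 12 intronic bases preceding the NYag
#' pattern and reports the signed difference from a literature consensus mean
#' for Anopheles gambiae acceptor sites (default 8.69).
#'
#' @param tract12 12-character tract (or a \code{splice_site_seq} acceptor).
#' @param consensus Consensus mean pyrimidine count, in \code{[0, 12]}.
#' @return List with \code{count} and \code{diff_from_consensus}.
#' @export
polypyrimidine_score <- function(tract12, consensus = 8.69) {
  if (inherits(tract12, "splice_site_seq")) tract12 <- tract12$tract12
  if (is.null(tract12) || nchar(tract12) != 12L)
    stop("polypyrimidine tract must be exactly 12 nt")
  if (consensus < 0 || consensus > 12) stop("consensus must be in [0, 12]")
  n <- sum(strsplit(tolower(tract12), "")[[1]] %in% c("c", "t"))
  list(count = n, diff_from_consensus = n - consensus)
}

#' Derive the full splice-site table of a gene
#'
#' One row per distinct junction (shared junctions appear once), with window
#' bounds, sharing classification, extracted sequences, canonical-motif
#' status, and pyrimidine counts for acceptors. This is the machine-readable
#' analogue of a printed donor/acceptor site table.
#'
#' @param gene A \code{\link{gene_model}}.
#' @param ref Optional \code{\link{ref_contig}}; without it only coordinates
#'   and classifications are produced.
#' @return data.frame, one row per junction, ordered donors first then
#'   acceptors, each in transcript order.
#' @export
splice_site_table <- function(gene, ref = NULL) {
  j <- classify_junctions(gene)
  win <- t(vapply(seq_len(nrow(j)), function(i) {
    if (j$kind[i] == "donor") build_donor_window(j$boundary[i], gene$strand)
    else build_acceptor_window(j$boundary[i], gene$strand)
  }, numeric(2)))
  j$win_low <- win[, 1]; j$win_high <- win[, 2]
  # transcript-order rendering of the window (start > end on minus strand)
  j$site_start <- if (gene$strand == "-") j$win_high else j$win_low
  j$site_end <- if (gene$strand == "-") j$win_low else j$win_high
  j$sequence <- NA_character_
  j$canonical <- NA
  j$pyrimidine_count <- NA_integer_
  if (!is.null(ref)) {
    for (i in seq_len(nrow(j))) {
      s <- extract_site_sequence(ref, c(j$win_low[i], j$win_high[i]),
                                 j$kind[i], gene$strand, cds = gene$cds)
      j$sequence[i] <- s$rendered
      j$canonical[i] <- validate_canonical_motifs(s)$canonical
      if (j$kind[i] == "acceptor" && !is.null(s$tract12))
        j$pyrimidine_count[i] <- polypyrimidine_score(s$tract12)$count
    }
  }
  j
}

#' Write the splice-site table as TSV
#'
#' Columns carry 1-based inclusive forward-genome coordinates
#' (\code{win_low}, \code{win_high}) plus the transcript-order rendering
#' (\code{site_start}, \code{site_end}).
#'
#' @param site_table Output of \code{\link{splice_site_table}}.
#' @param path Output path.
#' @return \code{site_table}, invisibly.
#' @export
write_site_table <- function(site_table, path) {
  utils::write.table(site_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(site_table)
}
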