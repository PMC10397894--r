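#' Reference contig with a coordinate offset
#'
#' A contig that represents a genomic slice: local position 1 of the stored
#' sequence corresponds to genomic position \code{offset + 1}. This lets the
#' pipeline work in true genome coordinates (matching the VCF and the gene
#' model) while carrying only the region of interest on disk.
#'
#' @param seq A \code{Biostrings::DNAString} (or coercible character).
#' @param chrom Chromosome name.
#' @param offset Genomic coordinate of the base just before local position 1
#'   (0 for a full chromosome).
#' @return A list of class \code{"ref_contig"}.
#' @export
ref_contig <- function(seq, chrom, offset = 0) {
  if (!methods::is(seq, "DNAString")) seq <- Biostrings::DNAString(seq)
  structure(list(seq = seq, chrom = chrom, offset = as.numeric(offset)),
            class = "ref_contig")
}

#' Genomic bounds covered by a reference contig
#' @param ref A \code{\link{ref_contig}}.
#' @return Numeric \code{c(low, high)} in genome coordinates.
#' @export
ref_bounds <- function(ref) ref$offset + c(1, length(ref$seq))

#' Extract forward-strand sequence at genomic coordinates
#'
#' @param ref A \code{\link{ref_contig}}.
#' @param low,high 1-based inclusive genomic coordinates.
#' @return Character string (forward strand, as stored).
#' @export
ref_subseq <- function(ref, low, high) {
  b <- ref_bounds(ref)
  if (low < b[1] || high > b[2])
    stop("requested region [", low, ", ", high, "] outside contig bounds [",
         b[1], ", ", b[2], "]")
  as.character(Biostrings::subseq(ref$seq, low - ref$offset, high - ref$offset))
}

#' Write a reference contig to FASTA
#'
#' The offset is recorded in the header as \code{offset=<n>} so that
#' \code{\link{read_reference_fasta}} restores genome coordinates.
#'
#' @param ref A \code{\link{ref_contig}}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  dss <- Biostrings::DNAStringSet(list(ref$seq))
  names(dss) <- sprintf("%s offset=%d length=%d", ref$chrom,
                        as.integer(ref$offset), length(ref$seq))
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Read a reference contig from FASTA
#'
#' @param path FASTA path; the first record is used. An \code{offset=<n>}
#'   token in the header is honoured, otherwise the offset is 0.
#' @return A \code{\link{ref_contig}}.
#' @export
read_reference_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) < 1L) stop("empty FASTA: ", path)
  header <- names(dss)[1]
  chrom <- strsplit(header, "\\s+")[[1]][1]
  offset <- 0
  m <- regmatches(header, regexpr("offset=[0-9]+", header))
  if (length(m) == 1L) offset <- as.numeric(sub("offset=", "", m))
  ref_contig(dss[[1]], chrom, offset)
}
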