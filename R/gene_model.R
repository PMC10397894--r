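#' Construct a genomic interval
#'
#' Intervals are stored 1-based inclusive as \code{[low, high]} regardless of
#' strand; transcript-order rendering (start > end on the minus strand) is a
#' display concern handled by the report writers.
#'
#' @param chrom Chromosome name.
#' @param low,high 1-based inclusive bounds, \code{low <= high}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return A list of class \code{"genomic_interval"}.
#' @export
genomic_interval <- function(chrom, low, high, strand) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.na(low) || is.na(high) || low > high)
    stop("invalid interval: need low <= high, got [", low, ", ", high, "]")
  structure(list(chrom = chrom, low = low, high = high, strand = strand),
            class = "genomic_interval")
}

#' @export
length.genomic_interval <- function(x) x$high - x$low + 1

#' Construct a transcript model
#'
#' @param id Transcript label (e.g. \code{"AgdsxF"}).
#' @param exons Two-column matrix or data.frame of \code{[low, high]} exon
#'   bounds, one row per exon, in transcript (5' to 3') order.
#' @param sex_label Optional \code{"female"}, \code{"male"} or \code{"none"}.
#' @return A list of class \code{"transcript_model"}.
#' @export
transcript_model <- function(id, exons, sex_label = "none") {
  exons <- as.data.frame(exons)
  names(exons) <- c("low", "high")
  exons$low <- as.numeric(exons$low); exons$high <- as.numeric(exons$high)
  if (nrow(exons) < 1L) stop("transcript needs at least one exon")
  if (any(exons$low > exons$high)) stop("exon with low > high in ", id)
  structure(list(id = id, sex_label = sex_label, exons = exons),
            class = "transcript_model")
}

#' Assemble a gene model from transcripts
#'
#' Validates that exons are non-overlapping, ordered consistently with the
#' strand (genomic coordinates strictly decreasing along a minus-strand
#' transcript), and contained in the gene span.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name shared by all transcripts.
#' @param strand \code{"+"} or \code{"-"}.
#' @param transcripts List of \code{\link{transcript_model}} objects.
#' @param span Optional numeric \code{c(low, high)} gene span; defaults to the
#'   exon envelope.
#' @param cds Optional list of \code{c(low, high)} coding intervals, used only
#'   for the upper/lower-case rendering of extracted site sequences.
#' @return A list of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts, span = NULL,
                       cds = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(transcripts) < 1L) stop("need at least one transcript")
  for (tr in transcripts) {
    ex <- tr$exons
    if (nrow(ex) > 1L) {
      if (strand == "-") {
        if (any(diff(ex$high) >= 0) || any(ex$low[-nrow(ex)] <= ex$high[-1]))
          stop("exons of ", tr$id, " overlap or are out of transcript order ",
               "for strand '-'")
      } else {
        if (any(diff(ex$low) <= 0) || any(ex$high[-nrow(ex)] >= ex$low[-1]))
          stop("exons of ", tr$id, " overlap or are out of transcript order ",
               "for strand '+'")
      }
    }
  }
  lo <- min(vapply(transcripts, function(t) min(t$exons$low), 0))
  hi <- max(vapply(transcripts, function(t) max(t$exons$high), 0))
  if (is.null(span)) span <- c(lo, hi)
  if (lo < span[1] || hi > span[2]) stop("exons fall outside the gene span")
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 span = as.numeric(span), cds = cds,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Derive introns of a transcript
#'
#' Intron \code{i} is the genomic gap between exon \code{i} and exon
#' \code{i + 1} in transcript order. Together exons and introns tile the
#' transcript's genomic footprint with no gaps or overlaps.
#'
#' @param transcript A \code{\link{transcript_model}}.
#' @param strand Strand of the parent gene.
#' @return data.frame with columns \code{ordinal}, \code{low}, \code{high},
#'   \code{length}; zero rows for a single-exon transcript.
#' @export
derive_introns <- function(transcript, strand) {
  ex <- transcript$exons
  k <- nrow(ex)
  if (k < 2L)
    return(data.frame(ordinal = integer(), low = numeric(),
                      high = numeric(), length = numeric()))
  if (strand == "-") {
    low <- ex$high[-1] + 1
    high <- ex$low[-k] - 1
  } else {
    low <- ex$high[-k] + 1
    high <- ex$low[-1] - 1
  }
  if (any(low > high))
    stop("adjacent exons of ", transcript$id,
         " leave no room for an intron (zero-length gap)")
  data.frame(ordinal = seq_len(k - 1L), low = low, high = high,
             length = high - low + 1)
}

#' Spliced transcript length in bp
#'
#' @param transcript A \code{\link{transcript_model}}.
#' @return Sum of exon lengths.
#' @export
transcript_length <- function(transcript) {
  sum(transcript$exons$high - transcript$exons$low + 1)
}

# Junctions of one transcript: donors at the 3' edge of every non-terminal
# exon, acceptors at the 5' edge of every non-first exon. The boundary is the
# genomic coordinate of the exonic edge base (not the intronic GT/AG base).
transcript_junctions <- function(transcript, strand) {
  ex <- transcript$exons
  k <- nrow(ex)
  don <- acc <- NULL
  if (k >= 2L) {
    don_idx <- seq_len(k - 1L)
    acc_idx <- seq.int(2L, k)
    don <- data.frame(
      kind = "donor",
      boundary = if (strand == "-") ex$low[don_idx] else ex$high[don_idx],
      exon_ordinal = don_idx, intron_ordinal = don_idx)
    acc <- data.frame(
      kind = "acceptor",
      boundary = if (strand == "-") ex$high[acc_idx] else ex$low[acc_idx],
      exon_ordinal = acc_idx, intron_ordinal = acc_idx - 1L)
  }
  out <- rbind(don, acc)
  if (is.null(out))
    out <- data.frame(kind = character(), boundary = numeric(),
                      exon_ordinal = integer(), intron_ordinal = integer())
  out$transcript <- rep(transcript$id, nrow(out))
  out
}

#' Classify splice junctions as shared or isoform-specific
#'
#' Junction identity is keyed by (kind, genomic boundary coordinate), so the
#' exon/intron renumbering caused by a skipped cassette exon does not split
#' one physical junction into two. A junction is shared iff it occurs in every
#' transcript of the gene.
#'
#' @param gene A \code{\link{gene_model}}.
#' @return data.frame with one row per distinct junction: \code{kind},
#'   \code{boundary}, \code{sharing} (\code{"shared"}/\code{"specific"}),
#'   \code{transcripts} (comma-joined ids), \code{exon_ordinals} and
#'   \code{intron_ordinals} (comma-joined, per transcript, as
#'   \code{id:ordinal}).
#' @export
classify_junctions <- function(gene) {
  per_tr <- do.call(rbind, lapply(gene$transcripts, transcript_junctions,
                                  strand = gene$strand))
  if (nrow(per_tr) == 0L) stop("gene has no junctions (single-exon model?)")
  n_tr <- length(gene$transcripts)
  key <- paste(per_tr$kind, per_tr$boundary)
  grp <- split(per_tr, key)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(
      kind = g$kind[1], boundary = g$boundary[1],
      sharing = if (n_tr > 1L && length(unique(g$transcript)) == n_tr)
        "shared" else "specific",
      transcripts = paste(g$transcript, collapse = ","),
      exon_ordinals = paste0(g$transcript, ":", g$exon_ordinal, collapse = ","),
      intron_ordinals = paste0(g$transcript, ":", g$intron_ordinal, collapse = ","))
  }))
  rownames(out) <- NULL
  # report in transcript order: donors and acceptors interleaved by position
  out[order(out$kind, if (gene$strand == "-") -out$boundary else out$boundary), ,
      drop = FALSE]
}

#' Detect cassette exons
#'
#' An exon of transcript A is a cassette exon relative to transcript B when
#' the exon and both of its flanking introns in A lie entirely inside a single
#' intron of B (i.e. B splices the whole region out in one piece).
#'
#' @param gene A \code{\link{gene_model}} with at least two transcripts.
#' @return data.frame with one row per detected cassette:
#'   \code{exon_transcript}, \code{exon_ordinal}, \code{exon_low},
#'   \code{exon_high}, \code{host_transcript}, \code{host_intron_ordinal},
#'   \code{host_low}, \code{host_high}. Zero rows when none found.
#' @export
detect_cassette_exons <- function(gene) {
  trs <- gene$transcripts
  res <- list()
  for (a in trs) {
    intr_a <- derive_introns(a, gene$strand)
    k <- nrow(a$exons)
    for (b in trs) {
      if (identical(a$id, b$id)) next
      intr_b <- derive_introns(b, gene$strand)
      if (nrow(intr_b) == 0L || k < 3L) next
      for (i in seq.int(2L, k - 1L)) {
        ex <- a$exons[i, ]
        up <- intr_a[intr_a$ordinal == i - 1L, ]
        dn <- intr_a[intr_a$ordinal == i, ]
        reg_lo <- min(ex$low, up$low, dn$low)
        reg_hi <- max(ex$high, up$high, dn$high)
        host <- intr_b[intr_b$low <= reg_lo & intr_b$high >= reg_hi, ]
        if (nrow(host) == 1L) {
          res[[length(res) + 1L]] <- data.frame(
            exon_transcript = a$id, exon_ordinal = i,
            exon_low = ex$low, exon_high = ex$high,
            host_transcript = b$id, host_intron_ordinal = host$ordinal,
            host_low = host$low, host_high = host$high)
        }
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(exon_transcript = character(), exon_ordinal = integer(),
                      exon_low = numeric(), exon_high = numeric(),
                      host_transcript = character(),
                      host_intron_ordinal = integer(),
                      host_low = numeric(), host_high = numeric()))
  do.call(rbind, res)
}

#' Read a gene model from JSON or GFF3
#'
#' The JSON dialect is \code{{gene_id, chrom, strand, span, cds,
#' transcripts: [{id, sex_label, exons: [[low, high], ...]}]}} with exons in
#' transcript order. GFF3 input uses feature type \code{"exon"} grouped by the
#' \code{Parent} attribute (requires the \pkg{rtracklayer} package); other
#' feature types are ignored.
#'
#' @param path Path to a \code{.json}, \code{.gff3} or \code{.gff} file.
#' @param gene_id For GFF3, optional gene identifier to select/label.
#' @return A \code{\link{gene_model}}.
#' @export
read_gene_model <- function(path, gene_id = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    read_gene_model_json(path)
  else
    read_gene_model_gff3(path, gene_id = gene_id)
}

#' @rdname read_gene_model
#' @export
read_gene_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  trs <- lapply(seq_len(nrow(j$transcripts)), function(i) {
    t <- j$transcripts[i, ]
    ex <- t$exons[[1]]
    transcript_model(t$id, ex, sex_label = if (!is.null(t$sex_label))
      t$sex_label else "none")
  })
  cds <- NULL
  if (!is.null(j$cds)) cds <- lapply(seq_len(nrow(j$cds)),
                                     function(i) as.numeric(j$cds[i, ]))
  gene_model(j$gene_id, j$chrom, j$strand, trs, span = as.numeric(j$span),
             cds = cds)
}

#' @rdname read_gene_model
#' @export
read_gene_model_gff3 <- function(path, gene_id = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type == "exon", , drop = FALSE]
  if (nrow(gr) == 0L) stop("no exon features in ", path)
  parent <- vapply(gr$Parent, function(p) p[[1]], "")
  strand <- as.character(gr$strand)[1]
  chrom <- as.character(gr$seqnames)[1]
  trs <- lapply(split(seq_len(nrow(gr)), parent), function(idx) {
    lo <- gr$start[idx]
    hi <- gr$end[idx]
    o <- order(if (strand == "-") -hi else lo)
    transcript_model(parent[idx][1], cbind(lo[o], hi[o]))
  })
  gene_model(if (is.null(gene_id)) "gene" else gene_id, chrom, strand,
             unname(trs))
}

#' The packaged Agdsx gene model
#'
#' Two-isoform model of the Anopheles gambiae doublesex gene AGAP004050
#' (2R:48703664-48788460, reverse strand): the female transcript AgdsxF keeps
#' cassette exon 5, the male transcript AgdsxM skips it.
#'
#' @return A \code{\link{gene_model}}.
#' @export
agdsx_gene_model <- function() {
  read_gene_model_json(system.file("extdata", "agdsx_gene_model.json",
                                   package = "agdsx", mustWork = TRUE))
}

#' Write the junction classification as TSV
#'
#' @param gene A \code{\link{gene_model}}.
#' @param path Output path.
#' @return The junction data.frame, invisibly.
#' @export
write_junction_table <- function(gene, path) {
  j <- classify_junctions(gene)
  utils::write.table(j, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(j)
}
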