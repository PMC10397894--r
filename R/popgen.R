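#' Windowed nucleotide diversity
#'
#' Per window, the unbiased per-site estimator from allele counts:
#' \deqn{\pi = \frac{1}{L} \sum_v \frac{2 d_v (n_v - d_v)}{n_v (n_v - 1)}}
#' where, at variant \eqn{v}, \eqn{n_v} is the number of called alleles
#' (twice the called diploid samples), \eqn{d_v} the alt-allele count, and
#' \eqn{L} the window length in bp. This equals the mean pairwise Hamming
#' distance per site over all allele pairs. Monomorphic or variant-free
#' windows score 0. Variants with fewer than two called alleles are skipped
#' and counted.
#'
#' The denominator \eqn{L} is the full window length; no accessibility mask
#' is applied, so values from masked pipelines are approximated, not
#' matched.
#'
#' @param gt Integer dosage matrix (variants x samples; 0/1/2, NA missing).
#' @param positions Genomic positions, one per row of \code{gt}.
#' @param span Numeric \code{c(low, high)} region to tile.
#' @param window_size Window length in bp (default 500); the last window is
#'   truncated at the span edge so that windows tile the span exactly.
#' @param stratum Label stored on the track.
#' @return A data.frame track of class \code{"diversity_track"}: columns
#'   \code{window_low}, \code{window_high}, \code{n_variants}, \code{pi};
#'   attributes \code{stratum}, \code{n_samples}, \code{n_skipped}.
#' @export
nucleotide_diversity <- function(gt, positions, span, window_size = 500,
                                 stratum = "all") {
  stopifnot(window_size >= 1, length(positions) == nrow(gt))
  n_called <- 2 * rowSums(!is.na(gt))
  d <- rowSums(gt, na.rm = TRUE)
  usable <- n_called >= 2
  n_skipped <- sum(!usable)
  contrib <- rep(0, length(positions))
  contrib[usable] <- 2 * d[usable] * (n_called[usable] - d[usable]) /
    (n_called[usable] * (n_called[usable] - 1))
  starts <- seq(span[1], span[2], by = window_size)
  ends <- pmin(starts + window_size - 1, span[2])
  bin <- findInterval(positions, starts)
  pi_sum <- rep(0, length(starts))
  ok <- usable & positions >= span[1] & positions <= span[2]
  if (any(ok)) {
    agg <- tapply(contrib[ok], bin[ok], sum)
    pi_sum[as.integer(names(agg))] <- agg
  }
  nv <- rep(0L, length(starts))
  if (any(ok)) {
    cnt <- table(bin[ok])
    nv[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out <- data.frame(window_low = starts, window_high = ends,
                    n_variants = nv, pi = pi_sum / (ends - starts + 1))
  attr(out, "stratum") <- stratum
  attr(out, "n_samples") <- ncol(gt)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' Diversity tracks per stratum
#'
#' @param gt Dosage matrix with sample-id column names.
#' @param positions Genomic positions per row.
#' @param metadata Sample metadata.
#' @param span Numeric \code{c(low, high)}.
#' @param window_size Window length in bp.
#' @param strata Metadata columns defining cells.
#' @param min_samples Cells with fewer samples are skipped with a warning.
#' @return Named list of \code{diversity_track}s.
#' @export
diversity_by_stratum <- function(gt, positions, metadata, span,
                                 window_size = 500,
                                 strata = c("country", "sex"),
                                 min_samples = 2L) {
  idx <- match(colnames(gt), metadata$sample_id)
  if (anyNA(idx)) stop("gt columns missing from metadata")
  md <- metadata[idx, , drop = FALSE]
  key <- interaction(md[strata], drop = TRUE, sep = "|")
  tracks <- list()
  for (lv in levels(key)) {
    sel <- key == lv
    if (sum(sel) < min_samples) {
      warning("stratum ", lv, " has ", sum(sel),
              " sample(s); diversity track skipped")
      next
    }
    tracks[[lv]] <- nucleotide_diversity(gt[, sel, drop = FALSE], positions,
                                         span, window_size, stratum = lv)
  }
  tracks
}

#' Compare diversity tracks between strata
#'
#' @param tracks List of \code{diversity_track}s on identical windows.
#' @return List with \code{windows} (per window, per stratum pair:
#'   \code{delta_pi} = pi_a - pi_b and \code{ratio} = pi_a / pi_b, NaN when
#'   both are 0) and \code{summary} (per stratum: length-weighted mean pi
#'   over the span; per pair: mean delta and overall ratio).
#' @export
compare_strata <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  w0 <- tracks[[1]][c("window_low", "window_high")]
  for (t in tracks[-1])
    if (!identical(t$window_low, w0$window_low) ||
        !identical(t$window_high, w0$window_high))
      stop("tracks computed on mismatched windows")
  labs <- names(tracks)
  wlen <- w0$window_high - w0$window_low + 1
  mean_pi <- vapply(tracks, function(t) sum(t$pi * wlen) / sum(wlen), 0)
  summary <- data.frame(stratum = labs, mean_pi = unname(mean_pi),
                        n_samples = vapply(tracks, attr, 0L, "n_samples"))
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  win <- do.call(rbind, lapply(pairs, function(p) {
    a <- tracks[[p[1]]]$pi; b <- tracks[[p[2]]]$pi
    data.frame(window_low = w0$window_low, window_high = w0$window_high,
               stratum_a = p[1], stratum_b = p[2],
               pi_a = a, pi_b = b, delta_pi = a - b, ratio = a / b)
  }))
  pair_summary <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(stratum_a = p[1], stratum_b = p[2],
               mean_delta_pi = mean_pi[p[1]] - mean_pi[p[2]],
               mean_ratio = unname(mean_pi[p[1]] / mean_pi[p[2]]))
  }))
  list(windows = win, summary = summary, pair_summary = pair_summary)
}

#' Write diversity tracks as a long TSV
#'
#' @param tracks List of \code{diversity_track}s.
#' @param path Output path.
#' @return The combined data.frame, invisibly.
#' @export
write_diversity_tracks <- function(tracks, path) {
  out <- do.call(rbind, lapply(names(tracks), function(lv) {
    t <- tracks[[lv]]
    data.frame(stratum = lv, n_samples = attr(t, "n_samples"),
               window_low = t$window_low, window_high = t$window_high,
               n_variants = t$n_variants, pi = t$pi)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Plot diversity tracks
#'
#' Simple static line plot of per-window pi for each stratum.
#'
#' @param tracks List of \code{diversity_track}s.
#' @param file Optional PNG path; plots to the active device when NULL.
#' @return NULL, invisibly.
#' @export
plot_diversity <- function(tracks, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  xs <- (tracks[[1]]$window_low + tracks[[1]]$window_high) / 2
  ymax <- max(vapply(tracks, function(t) max(t$pi), 0), 1e-6)
  graphics::plot(range(xs), c(0, ymax), type = "n",
                 xlab = "genomic position (bp)",
                 ylab = expression(pi ~ "(diffs per site)"))
  cols <- grDevices::hcl.colors(length(tracks), "Dark 3")
  for (i in seq_along(tracks))
    graphics::lines(xs, tracks[[i]]$pi, col = cols[i])
  graphics::legend("topright", legend = names(tracks), col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(NULL)
}
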