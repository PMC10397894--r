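# Independent brute-force oracle for nucleotide diversity: mean pairwise
# allele difference per site over all C(n,2) called-allele pairs, per variant.
brute_pi <- function(gt, positions, span) {
  total <- 0
  for (v in seq_len(nrow(gt))) {
    g <- gt[v, !is.na(gt[v, ])]
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      diffs <- diffs + (alleles[i] != alleles[j])
    total <- total + diffs / choose(n, 2)
  }
  total / (span[2] - span[1] + 1)
}
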