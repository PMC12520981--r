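# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Gini by the literal double sum over all ordered pairs
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# exact binomial upper tail P(X >= k) by direct enumeration of the pmf
binom_upper_tail_enum <- function(k, n, p) {
  if (k <= 0) return(1)
  kk <- k:n
  sum(exp(lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)))
}

# plain softmax cross-entropy, mean over samples, with optional weights
cross_entropy_oracle <- function(probs, labels, weights = NULL) {
  n <- ncol(probs)
  if (is.null(weights)) weights <- rep(1, n)
  mean(-log(probs[cbind(labels + 1L, seq_len(n))]) * weights)
}

# toy genome shared by many tests: 4 x 20 Mb, 80 bins at 1 Mb
toy_genome <- function(resolution = 1e6) {
  sc_genome(paste0("chr", 1:4), rep(2e7, 4), resolution)
}

# tiny hand-built pairs table
toy_pairs <- function(genome = toy_genome()) {
  p <- tibble::tibble(
    barcode = c("c1", "c1", "c2"),
    chrom1 = c("chr1", "chr1", "chr2"),
    pos1 = c(100, 5e6, 2e6),
    chrom2 = c("chr1", "chr3", "chr2"),
    pos2 = c(900, 1e6, 2.5e6)
  )
  p <- normalize_pairs(p, genome)
  attr(p, "genome") <- genome
  p
}

# Jaccard of two integer bin intervals given as c(start, end) inclusive
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  uni <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / uni
}
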