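# Independent oracles used to freeze expected values. These deliberately
# avoid the implementation paths they check.

library(data.table)

# per-base membership count of shared exonic bases between two exon lists
brute_overlap_bp <- function(exons_a, exons_b) {
  expand_bases <- function(ex) unlist(lapply(ex, function(p)
    seq.int(p[1], p[2] - 1L)))
  length(intersect(expand_bases(exons_a), expand_bases(exons_b)))
}

# term-by-term Shannon entropy (bits), summing only positive terms
entropy_oracle <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log2(x)
  s
}

jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  entropy_oracle(m) - (entropy_oracle(p) + entropy_oracle(q)) / 2
}

# O(n^2) max over all nonempty contiguous segments
brute_max_subarray <- function(x) {
  best <- -Inf
  for (i in seq_along(x)) {
    s <- 0
    for (j in i:length(x)) {
      s <- s + x[j]
      if (s > best) best <- s
    }
  }
  best
}

# exhaustive hypergeometric upper tail: fraction of all n-subsets of a
# 1..N universe (first K elements carry the term) with >= k term members
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d <= K) >= k))
}

# textbook BH step-up: q_i = min_{j >= i} (m * p_(j) / j), in p order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# random small transcript fixture for property tests
random_tx <- function(id, seed_chrom = "chr1", strand = "+",
                      max_exons = 4L, span = 1000L) {
  n_ex <- sample(seq_len(max_exons), 1L)
  bounds <- sort(sample(0:span, 2L * n_ex))
  exons <- matrix(bounds, ncol = 2L, byrow = TRUE)
  exons[, 2] <- exons[, 2] + 1L  # guarantee end > start
  # enforce non-overlap after the +1 widening
  for (i in seq_len(n_ex - 1L)[n_ex > 1L]) {
    if (exons[i + 1L, 1] < exons[i, 2]) exons[i + 1L, 1] <- exons[i, 2]
    if (exons[i + 1L, 2] <= exons[i + 1L, 1]) {
      exons[i + 1L, 2] <- exons[i + 1L, 1] + 1L
    }
  }
  tx_new(id, seed_chrom, strand, exons)
}

exon_list <- function(tx) {
  d <- as.data.table(tx)[order(start)]
  lapply(seq_len(nrow(d)), function(i) c(d$start[i], d$end[i]))
}
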