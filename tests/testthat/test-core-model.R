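# Core transcript model: interval arithmetic, intron-chain matching,
# merging, distances.

test_that("exonic overlap follows the half-open convention", {
  a <- tx_new("a", "chr1", "+", list(c(0, 100)))
  expect_identical(exonic_overlap_bp(a, tx_new("b", "chr1", "+", list(c(50, 150)))), 50L)
  expect_identical(exonic_overlap_bp(a, tx_new("b", "chr1", "+", list(c(100, 200)))), 0L)
  expect_identical(
    exonic_overlap_bp(tx_new("a", "chr1", "+", list(c(0, 10), c(20, 30))),
                      tx_new("b", "chr1", "+", list(c(5, 25)))),
    10L)
  # strand / chrom gating
  expect_identical(exonic_overlap_bp(a, tx_new("b", "chr1", "-", list(c(0, 100)))), 0L)
  expect_identical(
    exonic_overlap_bp(a, tx_new("b", "chr1", "-", list(c(0, 100))),
                      same_strand_required = FALSE), 100L)
  expect_identical(exonic_overlap_bp(a, tx_new("b", "chr2", "+", list(c(0, 100)))), 0L)
})

test_that("exonic overlap is symmetric and matches a per-base oracle", {
  set.seed(101)
  for (i in 1:25) {
    a <- random_tx("a")
    b <- random_tx("b")
    got <- exonic_overlap_bp(a, b)
    expect_identical(got, exonic_overlap_bp(b, a))
    expect_identical(got, brute_overlap_bp(exon_list(a), exon_list(b)))
  }
})

test_that("match level distinguishes full, partial and none", {
  q <- tx_new("q", "chr1", "+", list(c(100, 200), c(300, 400)))
  expect_identical(match_level(q, q), "full")
  # terminus-shifted copy with the same intron chain is still full
  shifted <- tx_new("s", "chr1", "+", list(c(50, 200), c(300, 400)))
  expect_identical(match_level(shifted, q), "full")
  # one exon overlap, no shared intron -> partial
  p <- tx_new("p", "chr1", "+", list(c(150, 250), c(500, 600)))
  expect_identical(match_level(p, q), "partial")
  # shared intron, no exon overlap is still partial
  i <- tx_new("i", "chr1", "+", list(c(190, 200), c(300, 310)))
  expect_identical(match_level(i, tx_new("r", "chr1", "+",
                                         list(c(100, 200), c(300, 400), c(600, 700)))),
                   "partial")
  expect_identical(match_level(q, tx_new("n", "chr1", "+", list(c(1000, 1100)))), "none")
  expect_identical(match_level(q, tx_new("o", "chr1", "-", list(c(100, 200), c(300, 400)))), "none")
  # single-exon pairs need overlap to be full
  s1 <- tx_new("s1", "chr1", "+", list(c(0, 500)))
  expect_identical(match_level(s1, tx_new("s2", "chr1", "+", list(c(100, 300)))), "full")
  expect_identical(match_level(s1, tx_new("s3", "chr1", "+", list(c(900, 1000)))), "none")
})

test_that("match_level(x, x) is full for random transcripts", {
  set.seed(77)
  for (i in 1:20) {
    x <- random_tx("x")
    expect_identical(match_level(x, x), "full")
  }
})

test_that("merging unifies intron-chain groups and extends termini", {
  m <- merge_transcripts(list(
    tx_new("x", "chr1", "+", list(c(0, 100), c(200, 500))),
    tx_new("y", "chr1", "+", list(c(50, 100), c(200, 600)))))
  expect_identical(n_tx(m), 1L)
  sp <- tx_spans(m)
  expect_identical(sp$start, 0L)
  expect_identical(sp$end, 600L)
  expect_identical(sp$n_exons, 2L)
  # internal boundaries (the intron chain) are preserved
  expect_identical(as.data.table(m)$end[1], 100L)
  expect_identical(as.data.table(m)$start[2], 200L)
})

test_that("disjoint loci and distinct chains are kept apart", {
  m <- merge_transcripts(list(
    tx_new("x", "chr1", "+", list(c(0, 100), c(200, 300))),
    tx_new("y", "chr2", "+", list(c(0, 100), c(200, 300)))))
  expect_identical(n_tx(m), 2L)
  # 3 transcripts, two sharing a chain -> 2 representatives
  m2 <- merge_transcripts(list(
    tx_new("a", "chr1", "+", list(c(0, 100), c(200, 300))),
    tx_new("b", "chr1", "+", list(c(10, 100), c(200, 280))),
    tx_new("c", "chr1", "+", list(c(0, 100), c(250, 300)))))
  expect_identical(n_tx(m2), 2L)
})

test_that("merging is idempotent and assigns loci by exonic linkage", {
  set.seed(5)
  sets <- lapply(1:3, function(s) {
    parts <- lapply(1:8, function(i) {
      off <- sample(0:5000, 1)
      tx_new(sprintf("t%d_%d", s, i), "chr1", sample(c("+", "-"), 1),
             list(c(off, off + 100), c(off + 200, off + 400)))
    })
    do.call(tx_bind, parts)
  })
  m1 <- merge_transcripts(sets)
  m2 <- merge_transcripts(m1)
  expect_equal(as.data.table(m2), as.data.table(m1), ignore_attr = TRUE)
  # same-strand overlapping representatives share a gene id
  sp <- tx_spans(m1)
  for (i in seq_len(nrow(sp))) {
    for (j in seq_len(nrow(sp))) {
      if (i == j || sp$strand[i] != sp$strand[j]) next
      ov <- exonic_overlap_bp(tx_subset(m1, sp$transcript_id[i]),
                              tx_subset(m1, sp$transcript_id[j]))
      if (ov >= 1L) expect_identical(sp$gene_id[i], sp$gene_id[j])
    }
  }
})

test_that("single-exon transcripts chain by overlap, not abutment", {
  m <- merge_transcripts(list(tx_new("a", "chr1", "+", list(c(0, 100))),
                              tx_new("b", "chr1", "+", list(c(100, 200))),
                              tx_new("c", "chr1", "+", list(c(150, 250)))))
  expect_identical(n_tx(m), 2L)
  sp <- tx_spans(m)[order(start)]
  expect_identical(sp$end[2], 250L)
  expect_identical(sp$start[2], 100L)
})

test_that("distance to nearest coding gene is span-level and strand-blind", {
  gene <- tx_new("g", "chr1", "-", list(c(0, 4000)))
  t1 <- tx_new("t", "chr1", "+", list(c(5000, 6000)))
  expect_identical(unname(distance_to_nearest(t1, gene)), 1000)
  t2 <- tx_new("t", "chr1", "+", list(c(3000, 5000)))
  expect_identical(unname(distance_to_nearest(t2, gene)), 0)
  t3 <- tx_new("t", "chr9", "+", list(c(0, 100)))
  expect_identical(unname(distance_to_nearest(t3, gene)), Inf)
})

test_that("transcript sets validate their invariants", {
  expect_error(tx_new("t", "chr1", "+", list(c(10, 10))), "end > start")
  expect_error(tx_new("t", "chr1", "*", list(c(0, 10))), "strand")
  expect_error(tx_set(data.frame(transcript_id = "t", chrom = "chr1",
                                 strand = "+", start = c(0, 5), end = c(10, 15))),
               "overlapping exons")
  x <- tx_new("t", "chr1", "+", list(c(0, 10), c(20, 30), c(40, 50)))
  expect_identical(nrow(introns(x)), 2L)
  expect_identical(introns(x)$start, c(10L, 30L))
  expect_identical(tx_spans(x)$length, 30L)
})
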