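# Adjoining-triplet log-odds classifier.

zero_model <- function() {
  m <- matrix(0, 64, 64, dimnames = list(TRIPLETS, TRIPLETS))
  structure(list(logodds = m, pseudocount = 1, threshold = 0,
                 skipped = c(coding = 0, noncoding = 0)),
            class = "triplet_model")
}

test_that("identical training sets give an all-zero log-odds table", {
  m <- train_triplet_model("ATGGCC", "ATGGCC")
  expect_true(all(m$logodds == 0))
  expect_identical(dim(m$logodds), c(64L, 64L))
  expect_identical(rownames(m$logodds)[1], "AAA")
  expect_identical(rownames(m$logodds)[64], "TTT")
})

test_that("pseudocount smoothing gives the exact hand-computed log-odds", {
  # coding contributes the single transition ATG->GCC; the noncoding
  # sequence CCCCCC contributes CCC->CCC only. With pseudocount 1:
  # P_c(GCC|ATG) = (1+1)/(1+64) = 2/65; P_n(GCC|ATG) = 1/64
  m <- train_triplet_model("ATGGCC", "CCCCCC", pseudocount = 1,
                           threshold = 0)
  expect_equal(m$logodds["ATG", "GCC"], log2((2 / 65) * 64))
  # untouched rows (neither class saw them) are exactly zero
  expect_equal(m$logodds["AAA", "TTT"], 0)
  # the rest of the ATG row: P_c = 1/65 vs P_n = 1/64
  expect_equal(m$logodds["ATG", "AAA"], log2(64 / 65))
})

test_that("swapping the training sets negates every entry exactly", {
  set.seed(42)
  mk <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1))
  a <- mk(10); b <- mk(10)
  m1 <- train_triplet_model(a, b, threshold = 0)
  m2 <- train_triplet_model(b, a, threshold = 0)
  expect_equal(m2$logodds, -m1$logodds)
})

test_that("training rejects unusable input and reports skipped sequences", {
  expect_error(train_triplet_model(character(0), "ACGTAC"), "usable")
  expect_error(train_triplet_model("ACG", "ACGTAC"), "usable")
  m <- train_triplet_model(c("ATGGCCTAA", "NNNNNN"), "ACGTACGTA")
  expect_equal(unname(m$skipped["coding"]), 1)
})

test_that("scoring finds the best frame and segment", {
  m <- zero_model()
  r <- score_sequence("ACGTACGTACGT", m)
  expect_identical(r$score, 0)
  expect_identical(r$segment, c(0L, 0L))

  m2 <- zero_model()
  m2$logodds["ATG", "GCC"] <- 2
  r2 <- score_sequence("ATGGCCAAA", m2)
  expect_identical(r2$score, 2)
  expect_identical(r2$frame, 0L)
  expect_identical(r2$segment, c(0L, 6L))
  # frame 1: place the scoring pair one base in
  r3 <- score_sequence("TATGGCCAAA", m2)
  expect_identical(r3$frame, 1L)
  expect_identical(r3$score, 2)
  expect_error(score_sequence("ACGTACG", m), "9 nt")
})

test_that("scores ignore trailing bases beyond the last full triplet", {
  set.seed(11)
  tab <- triplet_bias_tables(1, 2)
  seqs <- simulate_sequences(ids = letters[1:10], lengths = rep(90L, 10),
                             classes = rep("coding", 10), tables = tab,
                             seed = 3)
  m <- train_triplet_model(seqs[1:5], vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = ""),
    character(1)), threshold = 0)
  for (s in seqs[6:10]) {
    base <- score_sequence(s, m)
    for (trail in c("A", "GC")) {
      expect_identical(score_sequence(paste0(s, trail), m)$score, base$score)
    }
  }
})

test_that("Kadane equals brute-force max over all segments", {
  set.seed(99)
  for (i in 1:200) {
    x <- round(rnorm(sample(1:20, 1)), 2)
    expect_equal(linctools:::kadane(x)$score, brute_max_subarray(x))
  }
})

test_that("classification accuracy is high under bias and chance-level without", {
  tab <- triplet_bias_tables(1, 11)
  lens <- function(n, s) {
    set.seed(s)
    as.integer(pmax(200, round(rlnorm(n, log(1200), 0.4))))
  }
  tr_c <- simulate_sequences(ids = paste0("c", 1:250), lengths = lens(250, 1),
                             classes = rep("coding", 250), tables = tab, seed = 21)
  tr_n <- simulate_sequences(ids = paste0("n", 1:250), lengths = lens(250, 2),
                             classes = rep("noncoding", 250), tables = tab, seed = 22)
  model <- train_triplet_model(tr_c, tr_n)
  te_c <- simulate_sequences(ids = paste0("tc", 1:500), lengths = lens(500, 3),
                             classes = rep("coding", 500), tables = tab, seed = 23)
  te_n <- simulate_sequences(ids = paste0("tn", 1:500), lengths = lens(500, 4),
                             classes = rep("noncoding", 500), tables = tab, seed = 24)
  expect_gte(mean(score_sequences(te_c, model)$label == "coding"), 0.9)
  expect_gte(mean(score_sequences(te_n, model)$label == "noncoding"), 0.9)

  tab0 <- triplet_bias_tables(0, 11)
  z_c <- simulate_sequences(ids = paste0("a", 1:500), lengths = lens(500, 5),
                            classes = rep("coding", 500), tables = tab0, seed = 31)
  z_n <- simulate_sequences(ids = paste0("b", 1:500), lengths = lens(500, 6),
                            classes = rep("noncoding", 500), tables = tab0, seed = 32)
  m0 <- train_triplet_model(z_c[1:250], z_n[1:250])
  acc <- (sum(score_sequences(z_c[251:500], m0)$label == "coding") +
            sum(score_sequences(z_n[251:500], m0)$label == "noncoding")) / 500
  expect_gt(acc, 0.45)
  expect_lt(acc, 0.55)
})

test_that("the model serializes to TSV and back", {
  tab <- triplet_bias_tables(0.5, 4)
  s <- simulate_sequences(ids = paste0("x", 1:20), lengths = rep(300L, 20),
                          classes = rep(c("coding", "noncoding"), 10),
                          tables = tab, seed = 5)
  m <- train_triplet_model(s[seq(1, 20, 2)], s[seq(2, 20, 2)])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_triplet_model(m, f)
  back <- read_triplet_model(f)
  expect_equal(back$logodds, m$logodds)
  expect_equal(back$threshold, m$threshold)
})
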