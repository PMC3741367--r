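# Co-expression graph, MCL, GO enrichment, lincRNA annotation.

clique_matrix <- function(sizes, bridge = NULL) {
  n <- sum(sizes)
  ids <- sprintf("g%02d", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    A[idx, idx] <- 1
    at <- at + s
  }
  diag(A) <- 0
  if (!is.null(bridge)) A[bridge[1], bridge[2]] <- A[bridge[2], bridge[1]] <- 1
  A
}

test_that("coexpression edges require |r| at threshold on log-FPKM", {
  e <- rbind(a = c(1, 2, 4, 8, 16, 32),
             b = 2 * c(1, 2, 4, 8, 16, 32),
             c = rev(c(1, 2, 4, 8, 16, 32)),
             d = c(5, 5, 5, 5, 5, 5))
  colors <- setNames(rep("coding", 4), rownames(e))
  g <- build_coexpression_graph(e, colors, edge_threshold = 0.9)
  ek <- paste(g$edges$from, g$edges$to)
  expect_true("a b" %in% ek)                 # proportional profiles
  ab <- g$edges[from == "a" & to == "b"]
  expect_gt(ab$r, 0.99)
  ac <- g$edges[from == "a" & to == "c"]     # anti-proportional, sign kept
  expect_identical(nrow(ac), 1L)
  expect_lt(ac$r, 0)
  expect_equal(ac$weight, abs(ac$r))
  expect_false("d" %in% c(g$edges$from, g$edges$to))  # constant profile
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(21)
  e <- matrix(rlnorm(30 * 6, 2, 1), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  colors <- setNames(rep("coding", 30), rownames(e))
  counts <- vapply(c(0.5, 0.7, 0.9, 0.95),
                   function(th) nrow(build_coexpression_graph(e, colors, th)$edges),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MCL separates disjoint and bridged cliques", {
  cl <- mcl(clique_matrix(c(4, 4)))
  expect_identical(lengths(cl), c(4L, 4L))
  expect_setequal(cl[[1]], sprintf("g%02d", 1:4))

  # two 5-cliques joined by one unit edge: the cliques are recovered
  cl2 <- mcl(clique_matrix(c(5, 5), bridge = c(5, 6)))
  expect_identical(length(cl2), 2L)
  expect_setequal(cl2[[1]], sprintf("g%02d", 1:5))
  expect_setequal(cl2[[2]], sprintf("g%02d", 6:10))
})

test_that("MCL keeps columns stochastic at every iteration", {
  set.seed(4)
  A <- clique_matrix(c(5, 5), bridge = c(5, 6))
  cl <- mcl(A)
  expect_true(all(attr(cl, "colsum_dev") < 1e-9))
  B <- matrix(runif(225), 15, 15, dimnames = list(letters[1:15], letters[1:15]))
  B <- (B + t(B)) / 2; diag(B) <- 0
  cl2 <- mcl(B)
  expect_true(all(attr(cl2, "colsum_dev") < 1e-9))
})

test_that("MCL is equivariant under node relabeling", {
  set.seed(33)
  for (i in 1:20) {
    n <- 15L
    A <- matrix(rbinom(n * n, 1, 0.25), n, n) * 1
    A <- pmax(A, t(A)); diag(A) <- 0
    dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    perm <- sample(n)
    Ap <- A[perm, perm]
    canon <- function(cl) {
      cl <- lapply(cl, sort)
      cl[order(vapply(cl, `[`, character(1), 1L))]
    }
    expect_identical(canon(mcl(A)), canon(mcl(Ap)))
  }
})

test_that("higher inflation never coarsens a path graph clustering", {
  n <- 12L
  A <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in seq_len(n - 1L)) A[i, i + 1L] <- A[i + 1L, i] <- 1
  expect_gte(length(mcl(A, inflation = 10)), length(mcl(A, inflation = 1.8)))
})

test_that("hypergeometric enrichment equals exhaustive enumeration (N <= 12)", {
  go <- data.table(gene_id = sprintf("g%02d", 1:5), term_id = "T1")
  background <- sprintf("g%02d", 1:20)
  enr <- go_enrichment(sprintf("g%02d", 1:5), go, background, alpha = 0.05)
  expect_equal(enr$p, 1 / choose(20, 5))   # all 5 term genes drawn

  for (cfg in list(c(N = 10, K = 4, n = 3), c(N = 12, K = 5, n = 4),
                   c(N = 8, K = 2, n = 5))) {
    N <- cfg["N"]; K <- cfg["K"]; n <- cfg["n"]
    bg <- sprintf("x%02d", seq_len(N))
    go2 <- data.table(gene_id = bg[seq_len(K)], term_id = "T")
    for (k in 1:min(K, n)) {
      filler <- if (n > k) bg[(K + 1):(K + n - k)] else character(0)
      cluster <- c(bg[seq_len(k)], filler)
      p <- go_enrichment(cluster, go2, bg)$p
      expect_equal(p, hyper_enum_oracle(N, K, n, k), tolerance = 1e-12)
    }
  }
})

test_that("clusters without term genes yield no enrichment rows", {
  bg <- sprintf("x%02d", 1:10)
  go <- data.table(gene_id = bg[1:3], term_id = "T")
  enr <- go_enrichment(bg[4:6], go, bg)
  expect_identical(nrow(enr), 0L)
  expect_error(go_enrichment(bg[1:3], go, character(0)), "background")
})

test_that("BH correction reproduces the hand-worked step-up on a 10-value fixture", {
  # one cluster, 10 terms with graded overlaps -> 10 distinct p-values
  bg <- sprintf("b%03d", 1:60)
  rows <- lapply(1:10, function(t) {
    data.table(gene_id = bg[seq_len(6 + t)], term_id = sprintf("T%02d", t))
  })
  go <- rbindlist(rows)
  cluster <- bg[1:8]
  enr <- go_enrichment(cluster, go, bg, alpha = 0.05)
  expect_identical(nrow(enr), 10L)
  expect_equal(enr$q, bh_oracle(enr$p), tolerance = 1e-12)
  # q-values are monotone in p
  expect_true(all(diff(enr$q) >= -1e-12))
  expect_identical(enr$enriched, enr$q <= 0.05)
})

test_that("planted modules are recovered with their signature terms on top", {
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    cx <- simulate_coexpression(seed)
    g <- build_coexpression_graph(cx$expr, cx$colors)
    cls <- mcl(g)
    ms <- module_set(cls, cx$colors, cx$go)
    for (m in unique(cx$planted_modules)) {
      total <- total + 1L
      members <- names(cx$planted_modules)[cx$planted_modules == m]
      ov <- vapply(ms$kept, function(i)
        length(intersect(ms$clusters[[i]], members)), integer(1))
      if (!length(ov) || max(ov) < length(members) / 2) next
      best <- which.max(ov)
      top <- ms$enrichment[[best]]$term_id[1]
      if (identical(top, unname(cx$signature_terms[[m]]))) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("lincRNAs inherit all enriched terms of their module", {
  clusters <- list(c("c1", "c2", "c3", "c4", "c5", "l1", "l2", "l3"),
                   c("c6", "c7", "c8", "c9", "c10", "l4"))
  colors <- setNames(c(rep("coding", 10), rep("lincRNA", 4)),
                     c(sprintf("c%d", 1:10), sprintf("l%d", 1:4)))
  go <- data.table(gene_id = c(sprintf("c%d", 1:5), sprintf("c%d", 1:5)),
                   term_id = rep(c("TA", "TB"), each = 5))
  ms <- module_set(clusters, colors, go, min_module_size = 6)
  ann <- annotate_lincrnas(ms)
  expect_identical(sort(names(ann)), c("l1", "l2", "l3"))
  for (l in c("l1", "l2", "l3")) expect_setequal(ann[[l]], c("TA", "TB"))
  # module without enrichment annotates nothing (l4's module has no terms)
  expect_null(ann[["l4"]])

  # end-to-end planted function recovery
  cx <- simulate_coexpression(9)
  g <- build_coexpression_graph(cx$expr, cx$colors)
  ms2 <- module_set(mcl(g), cx$colors, cx$go)
  ann2 <- annotate_lincrnas(ms2)
  planted_lincs <- names(cx$planted_modules)[cx$colors[names(cx$planted_modules)] == "lincRNA"]
  ok <- vapply(planted_lincs, function(l) {
    sig <- cx$signature_terms[[cx$planted_modules[[l]]]]
    !is.null(ann2[[l]]) && sig %in% ann2[[l]]
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
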