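# Synthetic-data generators: determinism, counts, planted invariants.

test_that("annotation simulation is seeded, counted, and honors planted invariants", {
  t1 <- simulate_annotation(7)
  t2 <- simulate_annotation(7)
  expect_equal(as.data.table(t1$annotation), as.data.table(t2$annotation),
               ignore_attr = TRUE)
  sp <- tx_spans(t1$annotation)
  expect_identical(nrow(sp[biotype == "coding"]), 50L)
  expect_identical(length(t1$planted_lincrna_ids), 20L)
  # planted lincRNAs pass the structural and positional filters
  pl <- tx_subset(t1$annotation, t1$planted_lincrna_ids)
  psp <- tx_spans(pl)
  expect_true(all(psp$n_exons >= 2L))
  expect_true(all(psp$length > 200L))
  expect_true(all(distance_to_nearest(pl, t1$catalogs$coding) >= 1000))
  for (cls in names(t1$catalogs)) {
    m <- match_against(pl, t1$catalogs[[cls]])
    expect_true(all(m$level == "none"))
  }
  expect_error(simulate_annotation(1, n_coding = 500, genome_size = 1e5),
               "genome_size")
})

test_that("expression simulation plants dominant-tissue patterns with lower lincRNA totals", {
  tr <- simulate_annotation(7)
  e1 <- simulate_expression(tr, frac_specific = 0.5, seed = 3)
  e2 <- simulate_expression(tr, frac_specific = 0.5, seed = 3)
  expect_identical(e1$fpkm, e2$fpkm)
  expect_identical(ncol(e1$fpkm), 6L)
  expect_true(all(e1$fpkm >= 0))
  spec <- names(e1$specific_tissue)[!is.na(e1$specific_tissue)]
  expect_identical(length(spec), 10L)
  for (id in spec) {
    v <- e1$fpkm[id, ]
    expect_identical(names(which.max(v)), unname(e1$specific_tissue[id]))
    expect_gte(max(v) / sum(v), 0.9)
  }
  linc_tot <- rowSums(e1$fpkm[tr$planted_lincrna_ids, ])
  coding_ids <- tx_spans(tr$annotation)[biotype == "coding"]$transcript_id
  expect_lt(median(linc_tot), median(rowSums(e1$fpkm[coding_ids, ])))
})

test_that("assembly simulation honors dropout limits and is reproducible", {
  tr <- simulate_annotation(11, n_coding = 5, n_known_nc = 0, n_pseudo = 0,
                            n_novel_linc = 10)
  ex <- simulate_expression(tr, frac_specific = 0, seed = 2)
  a0 <- simulate_assemblies(tr, ex, dropout = 0, noise_intronic = 0,
                            noise_fragment = 0, seed = 4)
  expect_identical(nrow(attr(a0, "samples")), 36L)
  # dropout 0: every expressed transcript is present in every sample
  ids <- tx_spans(tr$annotation)$transcript_id
  for (s in names(a0)) {
    expect_true(all(tr$planted_lincrna_ids %in% a0[[s]]$transcript_id))
  }
  a1 <- simulate_assemblies(tr, ex, dropout = 0.3, seed = 9)
  a2 <- simulate_assemblies(tr, ex, dropout = 0.3, seed = 9)
  expect_identical(lapply(a1, as.data.table), lapply(a2, as.data.table))
  # near-total dropout: recurrence counts concentrate at <= 1
  a3 <- simulate_assemblies(tr, ex, dropout = 0.98, noise_intronic = 0,
                            noise_fragment = 0, seed = 5)
  rec <- recurrence(tx_subset(tr$annotation, tr$planted_lincrna_ids), a3)
  expect_gte(mean(rec$results$recurrence <= 1), 0.9)
})

test_that("assembled noise fragments are intronic or exon-truncations of coding genes", {
  tr <- simulate_annotation(21, n_coding = 10, n_known_nc = 0, n_pseudo = 0,
                            n_novel_linc = 5)
  ex <- simulate_expression(tr, seed = 2)
  asm <- simulate_assemblies(tr, ex, noise_intronic = 5, noise_fragment = 5,
                             seed = 6)
  all_tx <- rbindlist(lapply(asm, as.data.table))
  noise_i <- all_tx[origin == "noise_intronic"]
  expect_gt(nrow(noise_i), 0L)
  # intronic fragments never overlap coding exons
  if (nrow(noise_i)) {
    ni <- tx_set(noise_i[, .(transcript_id, gene_id, chrom, strand, start, end)])
    m <- match_against(ni, tr$catalogs$coding)
    expect_true(all(m$level == "none"))
    expect_true(all(tx_spans(ni)$n_exons == 1L))
  }
  noise_f <- unique(all_tx[origin == "noise_fragment"]$transcript_id)
  expect_gt(length(noise_f), 0L)
})

test_that("sequence simulation is seeded with sane composition", {
  tab <- triplet_bias_tables(1, 5)
  expect_equal(unname(rowSums(tab$coding)), rep(1, 64))
  s1 <- simulate_sequences(ids = paste0("s", 1:50),
                           lengths = rep(300L, 50),
                           classes = rep(c("coding", "noncoding"), 25),
                           tables = tab, seed = 8)
  s2 <- simulate_sequences(ids = paste0("s", 1:50),
                           lengths = rep(300L, 50),
                           classes = rep(c("coding", "noncoding"), 25),
                           tables = tab, seed = 8)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1) == 300L))
  gc <- mean(vapply(s1, function(s)
    mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1)))
  expect_gt(gc, 0.3)
  expect_lt(gc, 0.7)
})

test_that("histone tracks plant TSS enrichment and a flat null", {
  tr <- simulate_annotation(31, n_coding = 0, n_known_nc = 0, n_pseudo = 0,
                            n_novel_linc = 40, genome_size = 1e7,
                            min_locus_gap = 12000)
  ex <- simulate_expression(tr, frac_specific = 0, seed = 1)
  t1 <- simulate_histone_tracks(tr, ex, enrichment = 1, marks = "H3K4me3",
                                seed = 3)
  prof <- metagene(t1$H3K4me3$heart, tss(tr$annotation), window = 3000,
                   bin = 100)
  ctr <- mean(prof$mean[abs(prof$center) < 500])
  edge <- mean(prof$mean[abs(prof$center) > 2500])
  expect_lt(abs(ctr - edge), 0.15)
  t2 <- simulate_histone_tracks(tr, ex, enrichment = 1, marks = "H3K4me3",
                                seed = 3)
  expect_identical(as.data.table(t1$H3K4me3$liver),
                   as.data.table(t2$H3K4me3$liver))
})

test_that("coexpression simulation plants shared signature terms", {
  cx <- simulate_coexpression(17)
  cx2 <- simulate_coexpression(17)
  expect_identical(cx$expr, cx2$expr)
  # every pair of coding genes in one module shares the signature term
  for (m in unique(cx$planted_modules)) {
    members <- names(cx$planted_modules)[cx$planted_modules == m]
    coding <- members[cx$colors[members] == "coding"]
    sig <- cx$signature_terms[[m]]
    for (g in coding) {
      expect_true(sig %in% cx$go[gene_id == g]$term_id)
    }
  }
  # planted cis partners are genuine nearest coding neighbors
  lincs <- tx_subset(cx$annotation, cx$annotation[biotype == "lincRNA"]$transcript_id)
  cod <- tx_subset(cx$annotation, cx$annotation[biotype == "coding"]$transcript_id)
  pairs <- nearest_pairs(lincs, cod, cx$expr)
  mrg <- merge(pairs, cx$cis_pairs, by = "lincrna_id")
  expect_true(all(mrg$coding_id.x == mrg$coding_id.y))
})
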