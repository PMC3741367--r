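# Seeded synthetic-data generator: genome annotation with planted novel
# lincRNAs, per-sample assemblies with dropout and noise, FPKM matrices
# with planted tissue-specificity, triplet-biased sequences, histone
# tracks with TSS enrichment, and GO labels with module structure.
# Every generator is a pure function of (arguments, seed).

SIM_TISSUES <- c("heart", "hippocampus", "liver", "lung", "spleen", "thymus")

sim_exon_structure <- function(class) {
  if (class == "coding") {
    n_ex <- sample(2:12, 1L)
    ex_len <- pmax(60L, as.integer(round(rgamma(n_ex, shape = 2, scale = 150))))
    int_len <- as.integer(round(runif(n_ex - 1L, 200, 2000)))
  } else if (class == "lincRNA") {
    # 2-4 exons with expectation 2.5, mean exon ~620 nt
    n_ex <- sample(2:4, 1L, prob = c(0.6, 0.3, 0.1))
    ex_len <- pmax(80L, as.integer(round(rgamma(n_ex, shape = 4, scale = 155))))
    int_len <- as.integer(round(runif(n_ex - 1L, 500, 3000)))
  } else {
    n_ex <- sample(1:5, 1L)
    ex_len <- pmax(60L, as.integer(round(rgamma(n_ex, shape = 2, scale = 200))))
    int_len <- if (n_ex > 1L) as.integer(round(runif(n_ex - 1L, 200, 2000))) else integer(0)
  }
  list(ex_len = ex_len, int_len = int_len)
}

#' Simulate a genome annotation with planted novel lincRNAs
#'
#' Places coding, known-noncoding, pseudogene and novel lincRNA loci on
#' one chromosome without overlap, with inter-locus gaps large enough
#' that every planted lincRNA is multi-exon, longer than 200 nt, at
#' least 1 kb from every coding gene and free of exonic overlap with
#' all catalogs (so all planted lincRNAs pass the structural and
#' positional filters by construction). Coding genes get 2-12 exons;
#' novel lincRNAs 2-4 exons (expectation 2.5) of ~620 nt mean.
#'
#' @param seed integer seed.
#' @param n_coding,n_known_nc,n_pseudo,n_novel_linc locus counts.
#' @param genome_size chromosome length in bp (error if the loci do not
#'   fit).
#' @param chrom chromosome name.
#' @param min_locus_gap minimal gap between neighboring loci (bp; keep
#'   > 1 kb plus assembly terminus jitter).
#' @return A `sim_truth` list: `annotation` (all loci, `tx_set`),
#'   `catalogs` (coding / known_noncoding / pseudogene subsets),
#'   `planted_lincrna_ids`, `genome_size`, `chrom`, `seed`.
#' @export
simulate_annotation <- function(seed, n_coding = 50L, n_known_nc = 15L,
                                n_pseudo = 10L, n_novel_linc = 20L,
                                genome_size = 5e6, chrom = "chr1",
                                min_locus_gap = 1200L) {
  stopifnot(n_coding >= 0, n_known_nc >= 0, n_pseudo >= 0, n_novel_linc >= 0)
  with_seed(seed, {
    classes <- c(rep("coding", n_coding), rep("known_noncoding", n_known_nc),
                 rep("pseudogene", n_pseudo), rep("lincRNA", n_novel_linc))
    if (!length(classes)) {
      return(structure(list(
        annotation = tx_new("..empty", "chr0", "+", list(c(0L, 1L)))[0],
        catalogs = list(), planted_lincrna_ids = character(0),
        genome_size = genome_size, chrom = chrom, seed = seed),
        class = "sim_truth"))
    }
    classes <- sample(classes)
    prefix <- c(coding = "CODG", known_noncoding = "NONC",
                pseudogene = "PSEU", lincRNA = "LINC")
    counter <- c(coding = 0L, known_noncoding = 0L,
                 pseudogene = 0L, lincRNA = 0L)
    pos <- 0L
    rows <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cls <- classes[i]
      st <- sim_exon_structure(cls)
      if (cls == "lincRNA") {
        while (sum(st$ex_len) <= 200L) st <- sim_exon_structure(cls)
      }
      gap <- as.integer(round(runif(1, min_locus_gap, min_locus_gap + 3000)))
      start <- pos + gap
      n_ex <- length(st$ex_len)
      ex_start <- start + c(0L, cumsum(st$ex_len[-n_ex] + st$int_len))
      ex_end <- ex_start + st$ex_len
      pos <- ex_end[n_ex]
      counter[cls] <- counter[cls] + 1L
      id <- sprintf("%s%04d", prefix[cls], counter[cls])
      rows[[i]] <- data.table(
        transcript_id = paste0(id, ".1"), gene_id = id,
        chrom = chrom, strand = sample(c("+", "-"), 1L),
        start = ex_start, end = ex_end, biotype = cls,
        source = "simulated")
    }
    if (pos > genome_size) {
      stop(sprintf("loci need %d bp; increase genome_size (= %g)",
                   pos, genome_size))
    }
    annotation <- tx_set(rbindlist(rows))
    planted <- unique(annotation[biotype == "lincRNA"]$transcript_id)
    truth <- structure(list(
      annotation = annotation,
      catalogs = list(
        coding = tx_subset(annotation, annotation[biotype == "coding"]$transcript_id),
        known_noncoding = tx_subset(annotation, annotation[biotype == "known_noncoding"]$transcript_id),
        pseudogene = tx_subset(annotation, annotation[biotype == "pseudogene"]$transcript_id)),
      planted_lincrna_ids = planted,
      genome_size = genome_size, chrom = chrom, seed = seed),
      class = "sim_truth")
    # planted invariants (guaranteed by construction; asserted anyway)
    if (length(planted)) {
      pl <- tx_subset(annotation, planted)
      sp <- tx_spans(pl)
      stopifnot(all(sp$n_exons >= 2L), all(sp$length > 200L),
                all(distance_to_nearest(pl, truth$catalogs$coding) >= 1000))
    }
    truth
  })
}

#' Simulate an FPKM matrix with planted tissue-specificity
#'
#' A chosen fraction of lincRNAs is tissue-specific (one dominant
#' tissue carrying >= 90% of expression mass); the rest are
#' near-uniform. LincRNA totals are drawn with a lower median than
#' coding totals. All values are non-negative.
#'
#' @param truth a `sim_truth` from [simulate_annotation()], or NULL to
#'   simulate `n_lincrna` standalone lincRNAs.
#' @param frac_specific fraction of lincRNAs planted tissue-specific
#'   (the count is `round(frac_specific * n)`).
#' @param fpkm_scale multiplicative scale on all totals.
#' @param seed integer seed.
#' @param tissues tissue names (default: the six-tissue panel).
#' @param n_lincrna number of lincRNAs when `truth` is NULL.
#' @return list(`fpkm` (matrix rows = transcripts, columns = tissues),
#'   `specific_tissue` (named vector, NA for non-specific lincRNAs),
#'   `tissues`).
#' @export
simulate_expression <- function(truth = NULL, frac_specific = 0.5,
                                fpkm_scale = 1, seed = 1L,
                                tissues = SIM_TISSUES, n_lincrna = 2000L) {
  stopifnot(frac_specific >= 0, frac_specific <= 1)
  if (!is.null(truth)) {
    sp <- tx_spans(truth$annotation)
    linc_ids <- sp[biotype == "lincRNA"]$transcript_id
    other <- sp[biotype != "lincRNA"]
  } else {
    linc_ids <- sprintf("LINC%05d", seq_len(n_lincrna))
    other <- NULL
  }
  nt <- length(tissues)
  rdirichlet1 <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  with_seed(seed, {
    n <- length(linc_ids)
    n_spec <- round(frac_specific * n)
    spec_idx <- if (n_spec > 0) sample(n, n_spec) else integer(0)
    spec_tissue <- setNames(rep(NA_character_, n), linc_ids)
    spec_tissue[spec_idx] <- sample(tissues, n_spec, replace = TRUE)
    fpkm <- matrix(0, n, nt, dimnames = list(linc_ids, tissues))
    totals <- rlnorm(n, meanlog = log(20 * fpkm_scale), sdlog = 0.5)
    for (i in seq_len(n)) {
      if (!is.na(spec_tissue[i])) {
        dom <- runif(1, 0.90, 0.98)
        shares <- rep(0, nt)
        shares[match(spec_tissue[i], tissues)] <- dom
        rest <- rdirichlet1(rep(1, nt - 1L)) * (1 - dom)
        shares[shares == 0] <- rest
      } else {
        shares <- rdirichlet1(rep(50, nt))
      }
      fpkm[i, ] <- totals[i] * shares
    }
    if (!is.null(other) && nrow(other)) {
      om <- matrix(0, nrow(other), nt,
                   dimnames = list(other$transcript_id, tissues))
      ot <- rlnorm(nrow(other), meanlog = log(60 * fpkm_scale), sdlog = 0.6)
      for (i in seq_len(nrow(other))) {
        om[i, ] <- ot[i] * rdirichlet1(rep(20, nt))
      }
      fpkm <- rbind(fpkm, om)
    }
    list(fpkm = fpkm, specific_tissue = spec_tissue, tissues = tissues)
  })
}

#' Simulate per-sample transcript assemblies
#'
#' Each annotated transcript expressed in a tissue (FPKM >=
#' `min_expressed_fpkm`) appears in each of that tissue's replicates
#' with probability `1 - dropout`, with small outward terminus jitter
#' (the intron chain is preserved, so recovered models match the truth
#' at level "full"). Noise transcripts are single-exon intronic
#' fragments and truncated exon runs of coding genes; their counts per
#' sample are Poisson.
#'
#' @param truth a `sim_truth`.
#' @param expr output of [simulate_expression()] over the truth.
#' @param replicates biological replicates per tissue (default 6).
#' @param dropout per-transcript per-replicate miss probability in
#'   `[0, 1)`.
#' @param noise_intronic,noise_fragment Poisson means of per-sample
#'   noise transcript counts.
#' @param terminus_jitter max outward extension of assembled termini
#'   (bp).
#' @param min_expressed_fpkm FPKM at which a transcript counts as
#'   expressed in a tissue.
#' @param seed integer seed.
#' @return Named list of per-sample `tx_set` (names `tissue_rep`),
#'   with attribute `samples` = data.table(sample, tissue, replicate).
#' @export
simulate_assemblies <- function(truth, expr, replicates = 6L, dropout = 0.1,
                                noise_intronic = 3, noise_fragment = 3,
                                terminus_jitter = 60L,
                                min_expressed_fpkm = 0.5, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1)
  tissues <- expr$tissues
  ann <- truth$annotation
  sp <- tx_spans(ann)
  coding_sp <- sp[biotype == "coding"]
  fpkm <- expr$fpkm
  samples <- CJ(tissue = tissues, replicate = seq_len(replicates),
                sorted = FALSE)
  samples[, sample := sprintf("%s_%d", tissue, replicate)]
  with_seed(seed, {
    out <- vector("list", nrow(samples))
    names(out) <- samples$sample
    for (si in seq_len(nrow(samples))) {
      tis <- samples$tissue[si]
      present_ids <- rownames(fpkm)[fpkm[, tis] >= min_expressed_fpkm]
      present_ids <- intersect(present_ids, sp$transcript_id)
      keep <- present_ids[runif(length(present_ids)) >= dropout]
      asm <- copy(as.data.table(tx_subset(ann, keep)))
      if (nrow(asm)) {
        # outward jitter of the two termini; chains untouched
        firsts <- asm[, .I[which.min(start)], by = transcript_id]$V1
        lasts <- asm[, .I[which.max(end)], by = transcript_id]$V1
        asm[firsts, start := pmax(0L, start - as.integer(floor(runif(.N, 0, terminus_jitter + 1))))]
        asm[lasts, end := end + as.integer(floor(runif(.N, 0, terminus_jitter + 1)))]
        asm[, origin := fifelse(biotype == "lincRNA", "planted", "annotated")]
      }
      noise <- list()
      n_i <- rpois(1L, noise_intronic)
      multi_coding <- coding_sp[n_exons >= 2L]
      if (n_i > 0L && nrow(multi_coding)) {
        for (k in seq_len(n_i)) {
          host <- multi_coding[sample(.N, 1L)]
          ints <- introns(tx_subset(ann, host$transcript_id))
          iv <- ints[sample(.N, 1L)]
          max_len <- min(500L, iv$end - iv$start)
          if (max_len < 80L) next
          len <- as.integer(round(runif(1, 80, max_len)))
          s0 <- iv$start + as.integer(floor(runif(1, 0, iv$end - iv$start - len + 1)))
          noise[[length(noise) + 1L]] <- data.table(
            transcript_id = sprintf("NOISEI_%s_%03d", samples$sample[si], k),
            gene_id = sprintf("NOISEI_%s_%03d", samples$sample[si], k),
            chrom = iv$chrom, strand = host$strand,
            start = s0, end = s0 + len,
            biotype = "unannotated", source = samples$sample[si],
            origin = "noise_intronic")
        }
      }
      n_f <- rpois(1L, noise_fragment)
      if (n_f > 0L && nrow(coding_sp)) {
        for (k in seq_len(n_f)) {
          host <- coding_sp[sample(.N, 1L)]
          hex <- as.data.table(tx_subset(ann, host$transcript_id))[order(start)]
          take <- min(nrow(hex), sample(1:2, 1L))
          at <- sample(nrow(hex) - take + 1L, 1L)
          frag <- hex[at:(at + take - 1L)]
          noise[[length(noise) + 1L]] <- data.table(
            transcript_id = sprintf("NOISEF_%s_%03d", samples$sample[si], k),
            gene_id = sprintf("NOISEF_%s_%03d", samples$sample[si], k),
            chrom = frag$chrom, strand = frag$strand,
            start = frag$start, end = frag$end,
            biotype = "unannotated", source = samples$sample[si],
            origin = "noise_fragment")
        }
      }
      parts <- c(list(asm), noise)
      parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0,
                            logical(1))]
      tab <- if (length(parts)) rbindlist(parts, fill = TRUE) else asm
      if (nrow(tab)) tab[, source := samples$sample[si]]
      out[[si]] <- tx_set(tab)
    }
    setattr(out, "samples", samples[, .(sample, tissue, replicate)])
    out
  })
}

#' Triplet transition tables for sequence simulation
#'
#' Coding sequences are emitted from an in-frame triplet Markov chain
#' with seeded, skewed codon-pair usage (log-weights
#' `Normal(0, bias_strength)`); noncoding sequences from the uniform
#' triplet chain. `bias_strength = 0` makes the two classes
#' statistically indistinguishable.
#'
#' @param bias_strength standard deviation of the codon-pair
#'   log-weights (>= 0).
#' @param seed integer seed.
#' @return list(`coding`, `noncoding`) of 64x64 row-stochastic
#'   transition matrices.
#' @export
triplet_bias_tables <- function(bias_strength = 1, seed = 1L) {
  stopifnot(bias_strength >= 0)
  with_seed(seed, {
    W <- matrix(rnorm(64 * 64, 0, bias_strength), 64, 64,
                dimnames = list(TRIPLETS, TRIPLETS))
    Tc <- exp(W)
    Tc <- Tc / rowSums(Tc)
    Tn <- matrix(1 / 64, 64, 64, dimnames = list(TRIPLETS, TRIPLETS))
    list(coding = Tc, noncoding = Tn)
  })
}

emit_chain_seq <- function(len, trans_cum) {
  m <- ceiling(len / 3)
  idx <- integer(m)
  idx[1L] <- sample.int(64L, 1L)
  if (m > 1L) {
    u <- runif(m - 1L)
    for (k in 2:m) {
      idx[k] <- findInterval(u[k - 1L], trans_cum[idx[k - 1L], ]) + 1L
    }
  }
  substr(paste(TRIPLETS[idx], collapse = ""), 1L, len)
}

#' Simulate sequences for a set of transcripts
#'
#' Coding transcripts get sequences from the biased coding triplet
#' chain; all others from the near-uniform noncoding chain; lengths
#' equal transcript (summed exon) lengths.
#'
#' @param truth a `sim_truth` (or pass `ids`/`lengths`/`classes`
#'   directly).
#' @param coding_bias_strength bias of the coding chain (see
#'   [triplet_bias_tables()]).
#' @param seed integer seed.
#' @param tables optional precomputed [triplet_bias_tables()] (so that
#'   training and evaluation sets share one chain).
#' @param ids,lengths,classes explicit specification overriding
#'   `truth`: ids, sequence lengths, and `"coding"`/`"noncoding"`
#'   class per sequence.
#' @return Named character vector of sequences.
#' @export
simulate_sequences <- function(truth = NULL, coding_bias_strength = 1,
                               seed = 1L, tables = NULL, ids = NULL,
                               lengths = NULL, classes = NULL) {
  if (is.null(tables)) {
    tables <- triplet_bias_tables(coding_bias_strength, seed)
  }
  if (is.null(ids)) {
    sp <- tx_spans(truth$annotation)
    ids <- sp$transcript_id
    lengths <- sp$length
    classes <- ifelse(sp$biotype == "coding", "coding", "noncoding")
  }
  stopifnot(length(ids) == length(lengths), length(ids) == length(classes),
            all(classes %in% c("coding", "noncoding")))
  cum <- lapply(tables, function(Tm) t(apply(Tm, 1L, cumsum)))
  with_seed(seed + 1L, {
    out <- vapply(seq_along(ids), function(i)
      emit_chain_seq(lengths[i], cum[[classes[i]]]), character(1))
    setNames(out, ids)
  })
}

#' Simulate histone signal tracks with TSS enrichment
#'
#' Per mark and tissue: a noisy piecewise-constant background (gamma
#' noise, mean 1) over the whole chromosome, multiplied by
#' `enrichment` within +/- 1 kb of the TSS of every gene expressed in
#' that tissue. `enrichment = 1` gives a flat expected profile.
#'
#' @param truth a `sim_truth`.
#' @param expr output of [simulate_expression()].
#' @param enrichment TSS signal multiplier (>= 1).
#' @param marks track names.
#' @param bin background bin width (bp).
#' @param min_expressed_fpkm expression call threshold.
#' @param seed integer seed.
#' @return Nested list `tracks[[mark]][[tissue]]` of [signal_track]s.
#' @export
simulate_histone_tracks <- function(truth, expr, enrichment = 3,
                                    marks = c("H3K4me3", "H3K4me1"),
                                    bin = 100L, min_expressed_fpkm = 0.5,
                                    seed = 1L) {
  stopifnot(enrichment >= 1)
  size <- as.integer(truth$genome_size)
  nb <- ceiling(size / bin)
  starts <- as.integer((seq_len(nb) - 1L) * bin)
  ends <- pmin(starts + as.integer(bin), size)
  anchors <- tss(truth$annotation)
  anchors <- merge(anchors,
                   tx_spans(truth$annotation)[, .(transcript_id)],
                   by = "transcript_id")
  with_seed(seed, {
    out <- list()
    for (mk in marks) {
      out[[mk]] <- list()
      for (tis in expr$tissues) {
        vals <- rgamma(nb, shape = 20, rate = 20)
        ex_ids <- rownames(expr$fpkm)[expr$fpkm[, tis] >= min_expressed_fpkm]
        a <- anchors[transcript_id %in% ex_ids]
        if (nrow(a)) {
          for (j in seq_len(nrow(a))) {
            lo <- max(0L, a$pos[j] - 1000L)
            hi <- min(size, a$pos[j] + 1000L)
            bidx <- which(starts < hi & ends > lo)
            vals[bidx] <- vals[bidx] * enrichment
          }
        }
        out[[mk]][[tis]] <- signal_track(data.table(
          chrom = truth$chrom, start = starts, end = ends, value = vals))
      }
    }
    out
  })
}

#' Simulate a co-expression study with planted modules
#'
#' Generates gene-level expression over six tissues with planted
#' co-expression modules (each containing coding genes and lincRNAs
#' following a shared tissue profile, with multiplicative noise),
#' unclustered background genes, a GO map in which each module's coding
#' genes share a signature term, and a genome placement in which each
#' module lincRNA sits next to a coding gene of its own module (its
#' nearest coding neighbor), supporting the cis-correlation analyses.
#' Module base profiles are drawn with pairwise `|r| <= 0.5` so that
#' planted modules are mutually distinguishable at the default edge
#' threshold.
#'
#' @param seed integer seed.
#' @param n_modules number of planted modules.
#' @param coding_per_module,linc_per_module module composition.
#' @param n_background_coding,n_background_linc unclustered genes.
#' @param n_terms,terms_per_gene background GO map size.
#' @param noise_sd multiplicative log2-scale expression noise.
#' @param tissues tissue names.
#' @return list(`expr` (gene x tissue FPKM), `colors`,
#'   `planted_modules` (named module id per planted gene),
#'   `signature_terms` (named per module), `go`
#'   (data.table(gene_id, term_id), coding genes only), `annotation`
#'   (`tx_set` gene placement), `cis_pairs`
#'   (data.table(lincrna_id, coding_id) planted adjacencies), `seed`.
#' @export
simulate_coexpression <- function(seed, n_modules = 8L,
                                  coding_per_module = 8L,
                                  linc_per_module = 2L,
                                  n_background_coding = 30L,
                                  n_background_linc = 10L,
                                  n_terms = 40L, terms_per_gene = 2L,
                                  noise_sd = 0.15,
                                  tissues = SIM_TISSUES) {
  nt <- length(tissues)
  with_seed(seed, {
    # mutually dissimilar module base profiles (log2 scale)
    profiles <- matrix(NA_real_, n_modules, nt)
    for (m in seq_len(n_modules)) {
      repeat {
        cand <- rnorm(nt, mean = 4, sd = 1.5)
        if (m == 1L) { profiles[m, ] <- cand; break }
        rr <- apply(profiles[seq_len(m - 1L), , drop = FALSE], 1L,
                    function(p) abs(cor(p, cand)))
        if (all(rr <= 0.5)) { profiles[m, ] <- cand; break }
      }
    }
    genes <- list(); colors <- character(0)
    modules <- character(0)
    expr_rows <- list()
    mk_profile <- function(base_log2) {
      scale <- rlnorm(1, 0, 0.5)
      pmax(0, scale * 2^(base_log2 + rnorm(nt, 0, noise_sd)) - 1)
    }
    for (m in seq_len(n_modules)) {
      for (k in seq_len(coding_per_module)) {
        id <- sprintf("MODC%02d_%02d", m, k)
        expr_rows[[id]] <- mk_profile(profiles[m, ])
        colors[id] <- "coding"
        modules[id] <- sprintf("PM%02d", m)
      }
      for (k in seq_len(linc_per_module)) {
        id <- sprintf("MODL%02d_%02d", m, k)
        expr_rows[[id]] <- mk_profile(profiles[m, ])
        colors[id] <- "lincRNA"
        modules[id] <- sprintf("PM%02d", m)
      }
    }
    for (k in seq_len(n_background_coding)) {
      id <- sprintf("BGC%03d", k)
      expr_rows[[id]] <- mk_profile(rnorm(nt, 4, 1.5))
      colors[id] <- "coding"
    }
    for (k in seq_len(n_background_linc)) {
      id <- sprintf("BGL%03d", k)
      expr_rows[[id]] <- mk_profile(rnorm(nt, 4, 1.5))
      colors[id] <- "lincRNA"
    }
    expr <- do.call(rbind, expr_rows)
    colnames(expr) <- tissues

    # GO map over coding genes: background terms plus module signatures
    coding_ids <- names(colors)[colors == "coding"]
    go_rows <- lapply(coding_ids, function(g)
      data.table(gene_id = g,
                 term_id = sample(sprintf("GO:%07d", seq_len(n_terms)),
                                  terms_per_gene)))
    signature_terms <- setNames(sprintf("GO:SIG%04d", seq_len(n_modules)),
                                sprintf("PM%02d", seq_len(n_modules)))
    for (m in seq_len(n_modules)) {
      members <- names(modules)[modules == sprintf("PM%02d", m)]
      members <- intersect(members, coding_ids)
      go_rows[[length(go_rows) + 1L]] <- data.table(
        gene_id = members, term_id = signature_terms[[sprintf("PM%02d", m)]])
    }
    go <- rbindlist(go_rows)

    # genome placement: isolated neighborhoods; each module lincRNA is
    # adjacent to one coding gene of its module
    rows <- list(); pos <- 0L
    cis <- list()
    place_gene <- function(id, pos, strand = "+") {
      w1 <- 400L; gap <- 300L; w2 <- 400L
      data.table(transcript_id = paste0(id, ".1"), gene_id = id,
                 chrom = "chr1", strand = strand,
                 start = c(pos, pos + w1 + gap),
                 end = c(pos + w1, pos + w1 + gap + w2),
                 biotype = NA_character_, source = "simulated")
    }
    linc_ids <- names(colors)[colors == "lincRNA"]
    linc_module <- modules[intersect(names(modules), linc_ids)]
    partner_of <- character(0)
    for (l in names(linc_module)) {
      cands <- setdiff(names(modules)[modules == linc_module[[l]]], linc_ids)
      partner_of[l] <- sample(cands, 1L)
    }
    placed <- character(0)
    for (l in names(partner_of)) {
      p <- partner_of[[l]]
      rows[[length(rows) + 1L]] <- place_gene(p, pos)
      rows[[length(rows) + 1L]] <- place_gene(l, pos + 1100L + 3000L)
      cis[[length(cis) + 1L]] <- data.table(lincrna_id = l, coding_id = p)
      placed <- c(placed, l, p)
      pos <- pos + 60000L
    }
    for (g in sample(setdiff(names(colors), placed))) {
      rows[[length(rows) + 1L]] <- place_gene(g, pos)
      pos <- pos + 60000L
    }
    annotation <- tx_set(rbindlist(rows))
    annotation[, biotype := fifelse(colors[gene_id] == "coding",
                                    "coding", "lincRNA")]
    list(expr = expr, colors = colors,
         planted_modules = modules,
         signature_terms = signature_terms, go = go,
         annotation = annotation, cis_pairs = rbindlist(cis),
         seed = seed)
  })
}

#' Simulate a GO annotation with planted module structure
#'
#' Thin wrapper exposing the GO component of [simulate_coexpression()]:
#' coding genes get `terms_per_gene` background terms, and genes of one
#' planted module always share that module's signature term.
#'
#' @param truth output of [simulate_coexpression()].
#' @return data.table(gene_id, term_id).
#' @export
simulate_go <- function(truth) {
  as.data.table(truth$go)
}

#' Simulate a complete identification study
#'
#' Orchestrates all generators into the inputs of [run_pipeline()]
#' under one seed: annotation with planted lincRNAs, expression,
#' per-sample assemblies (6 tissues x `replicates`), the merged
#' assembly, coverage, sequences for every merged transcript, and a
#' triplet model trained on independently simulated sequences from the
#' same chains.
#'
#' @param seed integer seed.
#' @param n_coding,n_known_nc,n_pseudo,n_novel_linc locus counts
#'   (defaults: the 50-coding / 20-lincRNA study design).
#' @param replicates replicates per tissue.
#' @param dropout per-replicate assembly miss probability.
#' @param frac_specific planted tissue-specific fraction.
#' @param noise_intronic,noise_fragment per-sample noise Poisson
#'   means; set both to 0 for a noise-free run.
#' @param coding_bias_strength sequence chain bias.
#' @param n_train training sequences per class for the triplet model.
#' @param genome_size chromosome length.
#' @return list(`truth`, `expr`, `assemblies`, `merged`, `coverage`,
#'   `sequences`, `model`, `catalogs`, `config`).
#' @export
simulate_study <- function(seed, n_coding = 50L, n_known_nc = 15L,
                           n_pseudo = 10L, n_novel_linc = 20L,
                           replicates = 6L, dropout = 0.1,
                           frac_specific = 0.5, noise_intronic = 3,
                           noise_fragment = 3, coding_bias_strength = 1,
                           n_train = 250L, genome_size = 5e6) {
  truth <- simulate_annotation(seed, n_coding = n_coding,
                               n_known_nc = n_known_nc, n_pseudo = n_pseudo,
                               n_novel_linc = n_novel_linc,
                               genome_size = genome_size)
  expr <- simulate_expression(truth, frac_specific = frac_specific,
                              seed = seed + 1L)
  assemblies <- simulate_assemblies(truth, expr, replicates = replicates,
                                    dropout = dropout,
                                    noise_intronic = noise_intronic,
                                    noise_fragment = noise_fragment,
                                    seed = seed + 2L)
  merged <- merge_transcripts(assemblies)

  tables <- triplet_bias_tables(coding_bias_strength, seed + 3L)
  train_len <- function(n) {
    as.integer(pmax(200, round(rlnorm(n, log(1200), 0.4))))
  }
  train <- with_seed(seed + 4L, {
    list(coding = train_len(n_train), noncoding = train_len(n_train))
  })
  train_c <- simulate_sequences(ids = sprintf("TRC%04d", seq_len(n_train)),
                                lengths = train$coding,
                                classes = rep("coding", n_train),
                                tables = tables, seed = seed + 5L)
  train_n <- simulate_sequences(ids = sprintf("TRN%04d", seq_len(n_train)),
                                lengths = train$noncoding,
                                classes = rep("noncoding", n_train),
                                tables = tables, seed = seed + 6L)
  model <- train_triplet_model(train_c, train_n)

  msp <- tx_spans(merged)
  classes <- ifelse(!is.na(msp$biotype) & msp$biotype == "coding",
                    "coding", "noncoding")
  sequences <- simulate_sequences(ids = msp$transcript_id,
                                  lengths = pmax(9L, msp$length),
                                  classes = classes,
                                  tables = tables, seed = seed + 7L)

  # expression and coverage over the merged transcript ids
  noise_ids <- setdiff(msp$transcript_id, rownames(expr$fpkm))
  extra <- with_seed(seed + 8L, {
    cov <- setNames(rlnorm(nrow(msp), log(20), 0.4), msp$transcript_id)
    nmat <- NULL
    if (length(noise_ids)) {
      nmat <- matrix(0, length(noise_ids), ncol(expr$fpkm),
                     dimnames = list(noise_ids, colnames(expr$fpkm)))
      nmat[cbind(seq_along(noise_ids),
                 sample(ncol(expr$fpkm), length(noise_ids), replace = TRUE))] <-
        rlnorm(length(noise_ids), log(3), 0.5)
      cov[noise_ids] <- rlnorm(length(noise_ids), log(3), 0.8)
    }
    list(coverage = cov, noise_fpkm = nmat)
  })
  fpkm <- if (is.null(extra$noise_fpkm)) expr$fpkm else
    rbind(expr$fpkm, extra$noise_fpkm)
  coverage <- extra$coverage

  list(truth = truth, expr = expr, assemblies = assemblies, merged = merged,
       coverage = coverage, sequences = sequences, model = model,
       catalogs = truth$catalogs,
       config = run_config(seed = seed),
       fpkm = fpkm)
}
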