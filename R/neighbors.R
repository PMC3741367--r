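# Nearest-coding-neighbor correlation analysis and the randomized
# GO-sharing null behind the cis-regulation hypothesis.

log_cor <- function(a, b) {
  x <- log2(a + 1); y <- log2(b + 1)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Nearest coding neighbor of each lincRNA
#'
#' One pair per lincRNA gene: the coding gene with the minimal
#' span-to-span gap on the same chromosome (strand-blind; ties broken
#' by leftmost gene start). Pearson correlation is computed on
#' `log2(FPKM + 1)` across tissues; pairs whose members lack an
#' expression row are dropped with a warning, and constant profiles
#' yield `r = NA` with `r_defined = FALSE`.
#'
#' @param lincrnas `tx_set` of lincRNA transcripts (paired at gene
#'   level).
#' @param coding_catalog `tx_set` of coding genes.
#' @param expr gene-level FPKM matrix (rows must cover both gene sets).
#' @return data.table(lincrna_id, coding_id, gap_bp, r, r_defined).
#' @export
nearest_pairs <- function(lincrnas, coding_catalog, expr) {
  lg <- gene_spans(lincrnas)
  cg <- gene_spans(coding_catalog)
  rows <- vector("list", nrow(lg))
  for (i in seq_len(nrow(lg))) {
    cand <- cg[chrom == lg$chrom[i] & gene_id != lg$gene_id[i]]
    if (!nrow(cand)) next
    gap <- pmax(0L, pmax(cand$start - lg$end[i], lg$start[i] - cand$end))
    best <- which(gap == min(gap))
    if (length(best) > 1L) best <- best[which.min(cand$start[best])]
    rows[[i]] <- data.table(lincrna_id = lg$gene_id[i],
                            coding_id = cand$gene_id[best],
                            gap_bp = as.integer(gap[best]))
  }
  pairs <- rbindlist(rows)
  if (!nrow(pairs)) return(pairs)
  have <- pairs$lincrna_id %in% rownames(expr) &
    pairs$coding_id %in% rownames(expr)
  if (any(!have)) {
    warning(sum(!have), " neighbor pair(s) dropped for missing expression")
    pairs <- pairs[have]
  }
  pairs[, r := vapply(seq_len(.N), function(j)
    log_cor(expr[lincrna_id[j], ], expr[coding_id[j], ]), numeric(1))]
  pairs[, r_defined := !is.na(r)]
  pairs[]
}

#' Nearest-neighbor pairs among coding genes
#'
#' The coding:coding analog of [nearest_pairs()] (each coding gene
#' paired with its nearest other coding gene), used as the comparison
#' distribution.
#'
#' @inheritParams nearest_pairs
#' @return data.table(gene_id, neighbor_id, gap_bp, r, r_defined).
#' @export
coding_coding_pairs <- function(coding_catalog, expr) {
  p <- nearest_pairs(coding_catalog, coding_catalog, expr)
  if (nrow(p)) setnames(p, c("lincrna_id", "coding_id"),
                        c("gene_id", "neighbor_id"))
  p
}

#' Correlations of random gene pairs
#'
#' Seeded uniform draws (with replacement) of pairs `(from, to)`;
#' correlation on `log2(FPKM + 1)`.
#'
#' @param expr gene-level FPKM matrix.
#' @param n number of pairs.
#' @param seed integer seed.
#' @param from_ids,to_ids id pools (defaults: all rows).
#' @return data.table(from, to, r).
#' @export
random_pair_correlations <- function(expr, n, seed,
                                     from_ids = rownames(expr),
                                     to_ids = rownames(expr)) {
  with_seed(seed, {
    a <- sample(from_ids, n, replace = TRUE)
    b <- sample(to_ids, n, replace = TRUE)
    data.table(from = a, to = b,
               r = vapply(seq_len(n), function(j)
                 log_cor(expr[a[j], ], expr[b[j], ]), numeric(1)))
  })
}

#' Compare neighbor-pair correlation distributions
#'
#' @param r_linc_coding,r_coding_coding,r_random numeric vectors of
#'   correlations for the three groups (NAs dropped).
#' @return list(`groups` = named list of sorted r vectors, `medians`,
#'   `sizes`).
#' @export
pair_distributions <- function(r_linc_coding, r_coding_coding, r_random) {
  gr <- list(linc_coding = sort(r_linc_coding[!is.na(r_linc_coding)]),
             coding_coding = sort(r_coding_coding[!is.na(r_coding_coding)]),
             random = sort(r_random[!is.na(r_random)]))
  if (any(lengths(gr) == 0L)) stop("pair_distributions: empty group")
  list(groups = gr,
       medians = vapply(gr, median, numeric(1)),
       sizes = lengths(gr))
}

#' Shared-GO test for highly correlated neighbor pairs
#'
#' Among neighbor pairs with `r >= r_cutoff`, a pair shares GO when
#' both members are annotated and their term sets intersect (lincRNA
#' terms from module inheritance, coding terms from the direct map).
#' The null is `n_random` seeded uniform draws of (annotated lincRNA,
#' annotated coding) pairs; the empirical p-value is the binomial
#' upper-tail probability of observing at least the observed number of
#' sharing pairs at the null rate.
#'
#' @param pairs output of [nearest_pairs()].
#' @param linc_terms named list lincRNA id -> inherited term ids (from
#'   [annotate_lincrnas()]).
#' @param go data.table(gene_id, term_id) for coding genes.
#' @param r_cutoff correlation cutoff (default 0.8, `>=`).
#' @param n_random null size (default 10000).
#' @param seed integer seed.
#' @return list(`frac_high_r`, `n_high`, `n_shared`,
#'   `frac_shared_among_high`, `null_frac`, `empirical_p`, `pairs`
#'   with a `shares_go` column).
#' @export
shared_go_test <- function(pairs, linc_terms, go, r_cutoff = 0.8,
                           n_random = 10000L, seed = 1L) {
  pairs <- copy(as.data.table(pairs))
  go <- as.data.table(go)
  coding_terms <- split(go$term_id, go$gene_id)
  shares <- function(linc, coding) {
    lt <- linc_terms[[linc]]
    ct <- coding_terms[[coding]]
    !is.null(lt) && !is.null(ct) && length(intersect(lt, ct)) > 0L
  }
  pairs[, shares_go := vapply(seq_len(.N), function(j)
    shares(lincrna_id[j], coding_id[j]), logical(1))]
  high <- pairs[!is.na(r) & r >= r_cutoff]
  frac_high <- if (nrow(pairs)) nrow(high) / nrow(pairs) else NA_real_
  n_shared <- sum(high$shares_go)
  frac_shared <- if (nrow(high)) n_shared / nrow(high) else NA_real_

  linc_pool <- names(linc_terms)[lengths(linc_terms) > 0L]
  coding_pool <- names(coding_terms)[lengths(coding_terms) > 0L]
  if (!length(linc_pool) || !length(coding_pool)) {
    null_frac <- 0
  } else {
    null_frac <- with_seed(seed, {
      a <- sample(linc_pool, n_random, replace = TRUE)
      b <- sample(coding_pool, n_random, replace = TRUE)
      mean(vapply(seq_len(n_random), function(j)
        shares(a[j], b[j]), logical(1)))
    })
  }
  empirical_p <- if (nrow(high)) {
    pbinom(n_shared - 1L, nrow(high), max(null_frac, .Machine$double.eps),
           lower.tail = FALSE)
  } else {
    NA_real_
  }
  list(frac_high_r = frac_high, n_high = nrow(high), n_shared = n_shared,
       frac_shared_among_high = frac_shared, null_frac = null_frac,
       empirical_p = empirical_p, pairs = pairs[])
}
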