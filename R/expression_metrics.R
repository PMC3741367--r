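# Tissue-specificity scoring based on Jensen-Shannon divergence, cutoff
# classification, and the replicate-recurrence statistic.

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence (bits)
#'
#' `JSD(p, q) = H((p + q)/2) - (H(p) + H(q))/2` with Shannon entropy in
#' bits, so the result lies in `[0, 1]`; `0 * log(0)` is taken as 0.
#'
#' @param p,q probability vectors of equal length (non-negative, each
#'   summing to 1 within 1e-9).
#' @return JSD in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("p and q must each sum to 1 (within 1e-9)")
  }
  m <- (p + q) / 2
  d <- shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  min(max(d, 0), 1)
}

#' Tissue-specificity (JS) score of one expression pattern
#'
#' The expression vector is normalized to a pattern `p`; for each tissue
#' `t` the similarity to the perfectly specific pattern `delta_t` is
#' `1 - sqrt(JSD(p, delta_t))`, and the JS score is the maximum over
#' tissues (ties broken by tissue order). A score of 1 means all
#' expression mass in a single tissue.
#'
#' @param expr non-negative expression vector over >= 2 tissues,
#'   optionally named.
#' @return list(`js_score`, `argmax_tissue`, `defined`); an all-zero
#'   vector is flagged undefined (`js_score = NA`).
#' @export
specificity_score <- function(expr) {
  stopifnot(length(expr) >= 2L)
  if (any(expr < 0)) stop("expression must be non-negative")
  tissues <- names(expr) %||% as.character(seq_along(expr))
  if (sum(expr) <= 0) {
    return(list(js_score = NA_real_, argmax_tissue = NA_character_,
                defined = FALSE))
  }
  p <- expr / sum(expr)
  scores <- vapply(seq_along(p), function(t) {
    d <- numeric(length(p)); d[t] <- 1
    1 - sqrt(js_divergence(p, d))
  }, numeric(1))
  i <- which.max(scores)
  list(js_score = scores[i], argmax_tissue = tissues[i], defined = TRUE)
}

#' JS scores for an expression matrix
#'
#' @param expr non-negative matrix, rows = transcripts/genes, columns =
#'   tissues.
#' @param cutoff specificity call threshold (`is_specific` iff
#'   `js_score >= cutoff`).
#' @return data.table(transcript_id, js_score, argmax_tissue,
#'   is_specific, defined). All-zero rows are flagged undefined and get
#'   `NA` scores.
#' @export
specificity_scores <- function(expr, cutoff = 0.5) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  ids <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    r <- specificity_score(setNames(expr[i, ], colnames(expr)))
    data.table(transcript_id = ids[i], js_score = r$js_score,
               argmax_tissue = r$argmax_tissue, defined = r$defined)
  })
  out <- rbindlist(rows)
  out[, is_specific := !is.na(js_score) & js_score >= cutoff]
  out[]
}

#' Classify tissue specificity at a cutoff
#'
#' @param results output of [specificity_scores()].
#' @param cutoff JS score cutoff (default 0.5; `>=`).
#' @param biotype optional character vector parallel to `results`
#'   grouping transcripts (e.g. lincRNA vs coding).
#' @return list(`results` with refreshed `is_specific`, `fractions` =
#'   data.table(biotype, n, n_specific, fraction) over defined scores).
#' @export
classify_specific <- function(results, cutoff = 0.5, biotype = NULL) {
  res <- copy(as.data.table(results))
  res[, is_specific := !is.na(js_score) & js_score >= cutoff]
  bt <- if (is.null(biotype)) rep("all", nrow(res)) else biotype
  res[, biotype_tmp := bt]
  frac <- res[defined == TRUE,
              .(n = .N, n_specific = sum(is_specific),
                fraction = mean(is_specific)), by = .(biotype = biotype_tmp)]
  res[, biotype_tmp := NULL]
  list(results = res[], fractions = frac[])
}

#' Replicate recurrence of transcripts across assemblies
#'
#' A transcript scores a hit in sample (tissue, replicate) when some
#' assembled transcript in that sample matches it at level full or
#' partial ([match_level()] semantics). The recurrence of a transcript
#' is the maximum over tissues of its within-tissue replicate hit
#' count.
#'
#' @param novel a `tx_set` of transcripts to audit.
#' @param assemblies named list of `tx_set`, one per sample.
#' @param samples data.table(sample, tissue, replicate) describing
#'   `names(assemblies)`; defaults to `attr(assemblies, "samples")`.
#' @return list(`results` = data.table(transcript_id, recurrence),
#'   `per_tissue` = hit-count matrix transcripts x tissues,
#'   `histogram` = data.table(recurrence, n, fraction) over
#'   `0..max(replicates)`).
#' @export
recurrence <- function(novel, assemblies, samples = attr(assemblies, "samples")) {
  if (is.null(samples)) stop("recurrence: sample sheet required")
  samples <- as.data.table(samples)
  stopifnot(all(c("sample", "tissue", "replicate") %in% names(samples)),
            all(samples$sample %in% names(assemblies)))
  ids <- unique(novel$transcript_id)
  tissues <- unique(samples$tissue)
  hits <- matrix(0L, length(ids), length(tissues),
                 dimnames = list(ids, tissues))
  for (i in seq_len(nrow(samples))) {
    m <- match_against(novel, assemblies[[samples$sample[i]]])
    hit_ids <- m[level %in% c("full", "partial")]$transcript_id
    hits[hit_ids, samples$tissue[i]] <- hits[hit_ids, samples$tissue[i]] + 1L
  }
  rec <- apply(hits, 1L, max)
  n_rep <- max(samples[, .N, by = tissue]$N)
  histo <- data.table(recurrence = 0:n_rep)
  cnt <- table(factor(rec, levels = 0:n_rep))
  histo[, n := as.integer(cnt)]
  histo[, fraction := n / length(ids)]
  list(results = data.table(transcript_id = ids, recurrence = as.integer(rec)),
       per_tissue = hits, histogram = histo[])
}
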