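# Core genomic data model: transcript sets, interval arithmetic,
# intron-chain matching, merging, and distances.
#
# A transcript set (`tx_set`) is a data.table with one row per exon and
# columns transcript_id, gene_id, chrom, strand, start, end, biotype,
# source. Coordinates are 0-based half-open (BED convention) throughout
# the package; GTF input/output converts from/to 1-based inclusive.

#' Construct a transcript set
#'
#' The universal unit flowing through all pipeline stages: a validated
#' exon table. Exons of each transcript must lie on one chromosome and
#' strand, be non-overlapping, and have `end > start`.
#'
#' @param exons data.frame/data.table with columns `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` and optionally `gene_id`
#'   (default: the transcript id), `biotype` (default `"unannotated"`)
#'   and `source`. Coordinates 0-based half-open.
#' @return A `tx_set` (a keyed data.table, one row per exon, exons sorted
#'   by start within transcript).
#' @examples
#' tx_set(data.frame(transcript_id = "t1", chrom = "chr1", strand = "+",
#'                   start = c(0, 200), end = c(100, 300)))
#' @export
tx_set <- function(exons) {
  ex <- as.data.table(exons)
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(ex))
  if (length(miss)) {
    stop("tx_set: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"gene_id" %in% names(ex)) ex[, gene_id := transcript_id]
  if (!"biotype" %in% names(ex)) ex[, biotype := "unannotated"]
  if (!"source" %in% names(ex)) ex[, source := NA_character_]
  ex[, transcript_id := as.character(transcript_id)]
  ex[, gene_id := as.character(gene_id)]
  ex[, chrom := as.character(chrom)]
  ex[, strand := as.character(strand)]
  ex[, start := as.integer(start)]
  ex[, end := as.integer(end)]
  front <- c("transcript_id", "gene_id", "chrom", "strand",
             "start", "end", "biotype", "source")
  setcolorder(ex, c(front, setdiff(names(ex), front)))
  if (nrow(ex)) {
    if (anyNA(ex$start) || anyNA(ex$end)) stop("tx_set: NA coordinates")
    if (!all(ex$strand %in% c("+", "-"))) {
      stop("tx_set: strand must be '+' or '-'")
    }
    if (any(ex$end <= ex$start)) {
      stop("tx_set: every exon must satisfy end > start")
    }
    setorder(ex, transcript_id, start)
    chk <- ex[, .(
      one_place = uniqueN(chrom) == 1L && uniqueN(strand) == 1L,
      disjoint = .N == 1L || all(start[-1L] >= end[-.N])
    ), by = transcript_id]
    if (!all(chk$one_place)) {
      stop("tx_set: transcript on multiple chromosomes/strands: ",
           paste(head(chk[one_place == FALSE]$transcript_id, 3), collapse = ", "))
    }
    if (!all(chk$disjoint)) {
      stop("tx_set: overlapping exons within transcript: ",
           paste(head(chk[disjoint == FALSE]$transcript_id, 3), collapse = ", "))
    }
  }
  setattr(ex, "class", unique(c("tx_set", class(ex))))
  ex[]
}

#' @export
print.tx_set <- function(x, ...) {
  cat(sprintf("<tx_set> %d transcripts, %d exons\n",
              uniqueN(x$transcript_id), nrow(x)))
  NextMethod()
}

# single-transcript convenience constructor used widely in tests
#' Build a one-transcript set from exon coordinates
#'
#' @param transcript_id,chrom,strand scalars.
#' @param exons two-column matrix or list of `(start, end)` pairs,
#'   0-based half-open.
#' @param gene_id,biotype,source optional scalars.
#' @return A `tx_set` with a single transcript.
#' @export
tx_new <- function(transcript_id, chrom, strand, exons,
                   gene_id = transcript_id, biotype = "unannotated",
                   source = NA_character_) {
  if (is.list(exons) && !is.data.frame(exons)) {
    exons <- do.call(rbind, lapply(exons, function(p) c(p[[1]], p[[2]])))
  }
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2)
  tx_set(data.table(transcript_id = transcript_id, gene_id = gene_id,
                    chrom = chrom, strand = strand,
                    start = exons[, 1], end = exons[, 2],
                    biotype = biotype, source = source))
}

#' Combine transcript sets by row
#' @param ... `tx_set` objects (transcript ids must not collide).
#' @return A single `tx_set`.
#' @export
tx_bind <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- rbindlist(lapply(parts, as.data.table), fill = TRUE)
  tx_set(out)
}

#' Number of transcripts in a set
#' @param x A `tx_set`.
#' @export
n_tx <- function(x) uniqueN(x$transcript_id)

#' Per-transcript summary table
#'
#' @param x A `tx_set`.
#' @return data.table with one row per transcript: genomic span
#'   (`start`,`end`), summed exonic `length`, `n_exons`, and carried
#'   metadata.
#' @export
tx_spans <- function(x) {
  out <- x[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end),
               length = sum(end - start), n_exons = .N,
               biotype = biotype[1L], source = source[1L]),
           by = transcript_id]
  setattr(out, "class", c("data.table", "data.frame"))
  out[]
}

#' Subset a transcript set by transcript id
#' @param x A `tx_set`; `ids` character vector.
#' @export
tx_subset <- function(x, ids) {
  out <- x[transcript_id %in% ids]
  setattr(out, "class", class(x))
  out[]
}

#' Intron table of a transcript set
#'
#' Introns are the gaps between consecutive exons; a transcript with k
#' exons has k - 1 introns. Single-exon transcripts contribute no rows.
#'
#' @param x A `tx_set`.
#' @return data.table(transcript_id, chrom, strand, start, end), 0-based
#'   half-open intron coordinates.
#' @export
introns <- function(x) {
  out <- x[, if (.N > 1L) .(chrom = chrom[1L], strand = strand[1L],
                            start = end[-.N], end = start[-1L]),
           by = transcript_id]
  setattr(out, "class", c("data.table", "data.frame"))
  out[]
}

# Canonical intron-chain key per transcript: "" for single-exon
# transcripts, else "chrom|strand|s-e;s-e;...".
chain_key <- function(x) {
  k <- x[, .(key = if (.N == 1L) "" else
    paste(chrom[1L], strand[1L],
          paste(sprintf("%d-%d", end[-.N], start[-1L]), collapse = ";"),
          sep = "|")), by = transcript_id]
  setNames(k$key, k$transcript_id)
}

# Exon-level GRanges view (1-based inclusive) with transcript metadata.
as_exon_granges <- function(x) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x$strand)
  S4Vectors::mcols(gr)$transcript_id <- x$transcript_id
  S4Vectors::mcols(gr)$gene_id <- x$gene_id
  gr
}

#' Exonic overlap between two transcripts
#'
#' Total number of bases shared between any exon of `a` and any exon of
#' `b`. Zero when the transcripts are on different chromosomes, or when
#' `same_strand_required` is set and strands differ. Half-open
#' convention: abutting exons share 0 bases.
#'
#' @param a,b single-transcript `tx_set` objects.
#' @param same_strand_required require matching strands (default TRUE).
#' @return Integer number of shared bases.
#' @export
exonic_overlap_bp <- function(a, b, same_strand_required = TRUE) {
  stopifnot(n_tx(a) == 1L, n_tx(b) == 1L)
  if (a$chrom[1L] != b$chrom[1L]) return(0L)
  if (same_strand_required && a$strand[1L] != b$strand[1L]) return(0L)
  ra <- IRanges::IRanges(a$start + 1L, a$end)
  rb <- IRanges::IRanges(b$start + 1L, b$end)
  sum(IRanges::width(IRanges::intersect(ra, rb)))
}

#' Reconstruction match level between two transcripts
#'
#' `"full"`: same chromosome and strand and identical intron chains
#' (terminus-tolerant; for a pair of single-exon transcripts, whose
#' intron chains are both empty, at least 1 bp of exonic overlap is
#' additionally required). `"partial"`: not full, but same chromosome
#' and strand with at least one shared intron or >= 1 bp of exonic
#' overlap. Otherwise `"none"`. Full implies the partial criteria.
#'
#' @param query,reference single-transcript `tx_set` objects.
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
match_level <- function(query, reference) {
  stopifnot(n_tx(query) == 1L, n_tx(reference) == 1L)
  if (query$chrom[1L] != reference$chrom[1L] ||
      query$strand[1L] != reference$strand[1L]) {
    return("none")
  }
  kq <- unname(chain_key(query))
  kr <- unname(chain_key(reference))
  ov <- exonic_overlap_bp(query, reference, same_strand_required = TRUE)
  if (kq == kr && (nzchar(kq) || ov >= 1L)) return("full")
  iq <- introns(query); ir <- introns(reference)
  shared_intron <- nrow(iq) > 0L && nrow(ir) > 0L &&
    nrow(merge(iq, ir, by = c("chrom", "strand", "start", "end"))) > 0L
  if (shared_intron || ov >= 1L) return("partial")
  "none"
}

#' Best reconstruction match level per query transcript
#'
#' Vectorized [match_level()]: for every transcript of `query`, the
#' best level (`"full"` > `"partial"` > `"none"`) achieved against any
#' transcript of `subject`. Used by recurrence counting and
#' planted-truth recovery audits.
#'
#' @param query,subject `tx_set` objects.
#' @return data.table(transcript_id, level), one row per query
#'   transcript.
#' @export
match_against <- function(query, subject) {
  qs <- tx_spans(query)
  out <- data.table(transcript_id = qs$transcript_id, level = "none")
  if (n_tx(subject) == 0L || n_tx(query) == 0L) return(out)

  # partial via >=1bp exon overlap (same strand)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_exon_granges(query),
                                as_exon_granges(subject),
                                ignore.strand = FALSE))
  ov_q <- unique(query$transcript_id[S4Vectors::queryHits(hits)])

  # partial via a shared intron
  iq <- introns(query); is_ <- introns(subject)
  int_q <- character(0)
  if (nrow(iq) && nrow(is_)) {
    m <- merge(iq, unique(is_[, .(chrom, strand, start, end)]),
               by = c("chrom", "strand", "start", "end"))
    int_q <- unique(m$transcript_id)
  }
  out[transcript_id %in% c(ov_q, int_q), level := "partial"]

  # full: identical intron chains (multi-exon)
  kq <- chain_key(query); ks <- chain_key(subject)
  multi_full <- names(kq)[nzchar(kq) & kq %in% ks[nzchar(ks)]]
  out[transcript_id %in% multi_full, level := "full"]

  # full: single-exon vs single-exon with overlap
  sq <- names(kq)[!nzchar(kq)]
  ss <- names(ks)[!nzchar(ks)]
  if (length(sq) && length(ss)) {
    h2 <- suppressWarnings(GenomicRanges::findOverlaps(
      as_exon_granges(tx_subset(query, sq)),
      as_exon_granges(tx_subset(subject, ss)),
      ignore.strand = FALSE))
    se_full <- unique(tx_subset(query, sq)$transcript_id[S4Vectors::queryHits(h2)])
    out[transcript_id %in% se_full, level := "full"]
  }
  out
}

#' Merge transcript collections into non-redundant representatives
#'
#' Multi-exon transcripts are grouped by (chromosome, strand, intron
#' chain); each group is represented by one transcript whose terminal
#' exons extend to the extreme termini observed in the group.
#' Single-exon transcripts are grouped by overlap-chaining on the same
#' strand (>= 1 bp; abutting intervals are not chained) and represented
#' by the chained span. Gene ids are reassigned by single-linkage
#' clustering of representatives sharing >= 1 bp of same-strand exonic
#' overlap. Idempotent: merging a merged set changes nothing.
#'
#' @param sets a `tx_set` or list of `tx_set` collections (e.g. one per
#'   assembler/sample).
#' @return A merged `tx_set`; representative transcripts keep the id and
#'   metadata of their first member (by span start, then id), with
#'   `source` collapsed over unique member sources.
#' @export
merge_transcripts <- function(sets) {
  if (inherits(sets, "tx_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  tabs <- lapply(seq_along(sets), function(i) {
    d <- copy(as.data.table(sets[[i]]))
    d[, set_i_ := i]
    d
  })
  ex <- rbindlist(tabs, fill = TRUE)
  if (!nrow(ex)) return(tx_set(ex[, set_i_ := NULL]))
  ex[, mid_ := paste(set_i_, transcript_id, sep = "\r")]

  mem <- ex[, .(chrom = chrom[1L], strand = strand[1L],
                start = min(start), end = max(end), n_exons = .N,
                transcript_id = transcript_id[1L], gene_id = gene_id[1L],
                biotype = biotype[1L], source = source[1L],
                set_i_ = set_i_[1L]),
            by = mid_]
  keys <- ex[, .(key = if (.N == 1L) "" else
    paste(chrom[1L], strand[1L],
          paste(sprintf("%d-%d", end[-.N], start[-1L]), collapse = ";"),
          sep = "|")), by = mid_]
  mem <- merge(mem, keys, by = "mid_")

  # group id: multi-exon by chain key; single-exon by overlap chains
  mem[, grp := NA_character_]
  mem[nzchar(key), grp := key]
  se <- mem[!nzchar(key)]
  if (nrow(se)) {
    gr <- GenomicRanges::GRanges(se$chrom,
                                 IRanges::IRanges(se$start + 1L, se$end),
                                 strand = se$strand)
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    h <- GenomicRanges::findOverlaps(gr, red)
    se_grp <- paste0("SE\r", S4Vectors::subjectHits(h))
    mem[!nzchar(key), grp := se_grp]
  }

  setorder(mem, grp, start, transcript_id, set_i_)
  reps <- mem[, {
    first <- 1L
    if (nzchar(key[first])) {
      # reconstruct exons from the shared chain plus extreme termini
      parts <- strsplit(strsplit(key[first], "|", fixed = TRUE)[[1L]][3L],
                        ";", fixed = TRUE)[[1L]]
      ise <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
      istart <- as.integer(ise[, 1L]); iend <- as.integer(ise[, 2L])
      es <- c(min(start), iend)
      ee <- c(istart, max(end))
    } else {
      es <- min(start); ee <- max(end)
    }
    .(exon_start = es, exon_end = ee,
      chrom = chrom[first], strand = strand[first],
      transcript_id = transcript_id[first], biotype = biotype[first],
      source = paste(sort(unique(unlist(strsplit(source[!is.na(source)], ",", fixed = TRUE)))),
                     collapse = ","))
  }, by = grp]
  reps[source == "", source := NA_character_]

  out <- reps[, .(transcript_id, chrom, strand,
                  start = exon_start, end = exon_end, biotype, source)]

  # gene assignment: single-linkage over same-strand exonic overlap
  spans <- out[, .(chrom = chrom[1L], strand = strand[1L],
                   start = min(start), end = max(end)),
               by = transcript_id]
  egr <- GenomicRanges::GRanges(out$chrom,
                                IRanges::IRanges(out$start + 1L, out$end),
                                strand = out$strand)
  h <- GenomicRanges::findOverlaps(egr, egr)
  qi <- out$transcript_id[S4Vectors::queryHits(h)]
  si <- out$transcript_id[S4Vectors::subjectHits(h)]
  g <- igraph::graph_from_data_frame(
    unique(data.table(from = qi, to = si)),
    directed = FALSE, vertices = spans$transcript_id)
  comp <- igraph::components(g)$membership
  spans[, comp := comp[transcript_id]]
  setorder(spans, chrom, start, transcript_id)
  comp_rank <- spans[, .(first = .I[1L]), by = comp][order(first)]
  comp_rank[, gene_id := sprintf("MLOC_%06d", .I)]
  spans <- merge(spans, comp_rank[, .(comp, gene_id)], by = "comp")

  out <- merge(out, spans[, .(transcript_id, gene_id)], by = "transcript_id")
  res <- tx_set(out)
  setorder(res, chrom, start, transcript_id)
  res[]
}

# Gene-level spans (one row per gene_id).
gene_spans <- function(x) {
  out <- x[, .(chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end), biotype = biotype[1L]),
           by = gene_id]
  setattr(out, "class", c("data.table", "data.frame"))
  out[]
}

#' Distance to the nearest gene of a catalog
#'
#' Minimal span-to-span gap in bases between each transcript and any
#' gene of `catalog` on the same chromosome, strand-blind; 0 when the
#' spans overlap; `Inf` when the catalog has no gene on the transcript's
#' chromosome.
#'
#' @param x A `tx_set` (one or many transcripts).
#' @param catalog A `tx_set` of reference genes (typically
#'   protein-coding).
#' @return Named numeric vector of gaps (bp), one per transcript in `x`.
#' @export
distance_to_nearest <- function(x, catalog) {
  sp <- tx_spans(x)
  res <- setNames(rep(Inf, nrow(sp)), sp$transcript_id)
  if (is.null(catalog) || n_tx(catalog) == 0L) return(res)
  gs <- gene_spans(catalog)
  qgr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start + 1L, sp$end))
  sgr <- GenomicRanges::GRanges(gs$chrom, IRanges::IRanges(gs$start + 1L, gs$end))
  dtn <- suppressWarnings(
    GenomicRanges::distanceToNearest(qgr, sgr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(dtn)
  res[sp$transcript_id[qh]] <- S4Vectors::mcols(dtn)$distance
  res
}
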