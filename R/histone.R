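# TSS-centered metagene profiles from piecewise-constant signal tracks
# (bedGraph semantics: disjoint intervals with float values, implicit 0
# elsewhere). Bin means are exact integrals, no interpolation.

#' Construct a signal track
#'
#' @param x data.frame/data.table with columns chrom, start, end, value
#'   (0-based half-open). Intervals must be disjoint within each
#'   chromosome; they are sorted on construction.
#' @return A `signal_track` (sorted data.table).
#' @export
signal_track <- function(x) {
  d <- as.data.table(x)[, .(chrom = as.character(chrom),
                            start = as.integer(start),
                            end = as.integer(end),
                            value = as.numeric(value))]
  if (nrow(d)) {
    if (any(d$end <= d$start)) stop("signal_track: intervals need end > start")
    if (anyNA(d$value)) stop("signal_track: NA values")
    setorder(d, chrom, start)
    bad <- d[, .(ok = .N == 1L || all(start[-1L] >= end[-.N])), by = chrom]
    if (!all(bad$ok)) {
      stop("signal_track: overlapping intervals on ",
           bad[ok == FALSE]$chrom[1L])
    }
  }
  setattr(d, "class", unique(c("signal_track", class(d))))
  d[]
}

# Exact integral of the track over [from, to) per query; vectorized.
# Queries may extend beyond covered intervals (gaps integrate to 0).
track_integral <- function(track, chrom, from, to) {
  stopifnot(length(chrom) == length(from), length(from) == length(to))
  out <- numeric(length(from))
  for (ch in unique(chrom)) {
    tr <- track[chrom == ch]
    sel <- which(chrom == ch)
    if (!nrow(tr)) next
    s <- tr$start; e <- tr$end; v <- tr$value
    cum <- c(0, cumsum(v * (e - s)))
    F <- function(x) {
      idx <- findInterval(x, s)
      full <- cum[idx + 1L]
      # subtract the part of interval idx beyond x (if x inside it)
      inside <- idx >= 1L & x < e[pmax(idx, 1L)]
      adj <- numeric(length(x))
      adj[inside] <- v[idx[inside]] * (e[idx[inside]] - x[inside])
      full - adj
    }
    out[sel] <- F(pmin(to[sel], max(e))) - F(pmax(from[sel], min(s)))
  }
  out
}

#' Transcription start sites of a transcript set
#'
#' The 5'-most transcribed base: first exon start on the plus strand,
#' last exon end minus one on the minus strand (0-based).
#'
#' @param x A [tx_set].
#' @return data.table(transcript_id, chrom, pos, strand).
#' @export
tss <- function(x) {
  sp <- tx_spans(x)
  sp[, .(transcript_id, chrom,
         pos = ifelse(strand == "+", start, end - 1L), strand)]
}

#' Metagene signal profile around anchor positions
#'
#' For each anchor the window `[-window, +window)` is divided into
#' strand-oriented bins; the bin value is the exact mean track signal
#' over the bin (integral / bin width, gaps count as 0). The profile is
#' the unweighted mean over anchors; bins extending below position 0
#' are dropped for that anchor and the per-bin anchor count is
#' reported.
#'
#' @param track A [signal_track].
#' @param tss_list data.table(chrom, pos, strand) (e.g. from [tss()]),
#'   or a `tx_set`.
#' @param window half-window size in bp.
#' @param bin bin width in bp; must divide `window`.
#' @return A `metagene_profile`: list(`center` = bin centers relative
#'   to the anchor, `mean`, `n` per-bin anchor counts, `n_regions`,
#'   `window`, `bin`).
#' @export
metagene <- function(track, tss_list, window = 5000L, bin = 100L) {
  if (inherits(tss_list, "tx_set")) tss_list <- tss(tss_list)
  tl <- as.data.table(tss_list)
  if (!nrow(tl)) stop("metagene: empty TSS list")
  if (window %% bin != 0L) stop("metagene: window must be a multiple of bin")
  offs <- seq.int(-window, window - bin, by = bin)
  nb <- length(offs)
  n <- nrow(tl)
  gs <- matrix(NA_integer_, n, nb)
  plus <- tl$strand == "+"
  for (j in seq_len(nb)) {
    d <- offs[j]
    gs[plus, j] <- tl$pos[plus] + d
    gs[!plus, j] <- tl$pos[!plus] - d - bin + 1L
  }
  vals <- matrix(NA_real_, n, nb)
  ok <- gs >= 0L
  if (any(ok)) {
    idx <- which(ok, arr.ind = TRUE)
    starts <- gs[ok]
    vals[ok] <- track_integral(track, tl$chrom[idx[, 1L]],
                               starts, starts + bin) / bin
  }
  structure(list(center = offs + bin / 2,
                 mean = colMeans(vals, na.rm = TRUE),
                 n = as.integer(colSums(!is.na(vals))),
                 n_regions = n, window = window, bin = bin),
            class = "metagene_profile")
}

#' Write a metagene profile as TSV
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @export
write_metagene_tsv <- function(profile, path) {
  fwrite(data.table(bin_center = profile$center, mean = profile$mean,
                    n = profile$n), path, sep = "\t")
  invisible(path)
}

#' Random intergenic control positions
#'
#' Samples `n` positions uniformly from intergenic space (at least
#' `min_gap` bp from any gene of `coding_catalog`), with per-chromosome
#' counts matched to the chromosome frequencies of `tss_like`
#' (largest-remainder apportionment, exact when `n` is a multiple of
#' the group size). Seeded and reproducible.
#'
#' @param coding_catalog `tx_set` of protein-coding genes.
#' @param tss_like data.table(chrom, ...) whose chromosome frequencies
#'   are matched (e.g. the lincRNA TSS table).
#' @param n number of control positions (>= 1).
#' @param seed integer seed.
#' @param chrom_sizes named vector of chromosome sizes (bp).
#' @param min_gap minimum distance from any coding gene span.
#' @return data.table(chrom, pos, strand = "+").
#' @export
random_control <- function(coding_catalog, tss_like, n, seed, chrom_sizes,
                           min_gap = 1000L) {
  stopifnot(n >= 1L)
  tl <- as.data.table(tss_like)
  tab <- tl[, .N, by = chrom]
  counts <- apportion(n, tab$N)
  gs <- gene_spans(coding_catalog)
  with_seed(seed, {
    out <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      if (counts[i] == 0L) next
      ch <- tab$chrom[i]
      size <- chrom_sizes[[ch]]
      if (is.null(size) || is.na(size)) {
        stop("random_control: no size for chromosome ", ch)
      }
      g <- gs[chrom == ch]
      excl <- IRanges::reduce(IRanges::IRanges(
        pmax(g$start - min_gap, 0L) + 1L, pmin(g$end + min_gap, size)))
      allowed <- IRanges::setdiff(IRanges::IRanges(1L, size), excl)
      w <- IRanges::width(allowed)
      if (!length(w) || sum(w) == 0L) {
        stop("random_control: no intergenic space left on ", ch)
      }
      iv <- sample.int(length(w), counts[i], replace = TRUE, prob = w)
      off <- floor(runif(counts[i]) * w[iv])
      out[[i]] <- data.table(chrom = ch,
                             pos = IRanges::start(allowed)[iv] - 1L + as.integer(off),
                             strand = "+")
    }
    rbindlist(out)[]
  })
}
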