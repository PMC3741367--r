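# Readers and writers for the standard formats consumed and produced by
# the pipeline. GTF and BED12 go through rtracklayer; FASTA through
# Biostrings; tabular files through data.table. All genomic coordinates
# are converted to the package's internal 0-based half-open convention.

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; other feature rows are ignored. Each
#' exon row must carry `gene_id` and `transcript_id` attributes and an
#' explicit strand. 1-based inclusive GTF coordinates are converted to
#' 0-based half-open. The GTF `source` column is kept in the `source`
#' field (`"."` becomes `NA`), and a `gene_biotype` attribute, when
#' present, populates `biotype`.
#'
#' @param path GTF file path.
#' @return A [tx_set].
#' @export
read_gtf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[nf < 9L]
    if (length(bad)) {
      stop(sprintf("malformed GTF record at line %d of %s (expected 9 tab-separated fields)",
                   bad[1L], path))
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == "exon"]
  if (!length(gr)) {
    return(tx_set(data.table(transcript_id = character(), chrom = character(),
                             strand = character(), start = integer(),
                             end = integer())))
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id)) {
    stop("GTF exon record without a transcript_id attribute in ", path)
  }
  if (is.null(mc$gene_id) || anyNA(mc$gene_id)) {
    stop("GTF exon record without a gene_id attribute in ", path)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("GTF exon record without strand in ", path)
  }
  src <- as.character(mc$source %||% rep(NA_character_, length(gr)))
  src[src == "."] <- NA_character_
  biot <- as.character(mc$gene_biotype %||% rep("unannotated", length(gr)))
  biot[is.na(biot)] <- "unannotated"
  tx_set(data.table(
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = biot,
    source = src))
}

#' Write a transcript set as GTF
#'
#' Writes one `exon` row per exon (1-based inclusive), with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes so that
#' `read_gtf(write_gtf(x))` is the identity on the transcript model.
#'
#' @param x A [tx_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  src <- ifelse(is.na(x$source), ".", x$source)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    x$chrom, src, x$start + 1L, x$end, x$strand,
    x$gene_id, x$transcript_id, x$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a BED12 file
#'
#' Block (exon) structure is expanded; the BED name column becomes both
#' `transcript_id` and `gene_id`.
#'
#' @param path BED12 file path.
#' @return A [tx_set].
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) {
    return(tx_set(data.table(transcript_id = character(), chrom = character(),
                             strand = character(), start = integer(),
                             end = integer())))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("BED12 record without strand in ", path)
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) {
    blocks <- IRanges::IRangesList(lapply(GenomicRanges::width(gr), function(w)
      IRanges::IRanges(1L, w)))
  }
  nb <- lengths(blocks)
  bu <- unlist(blocks)
  tx_start0 <- rep(GenomicRanges::start(gr) - 1L, nb)
  tx_set(data.table(
    transcript_id = rep(as.character(S4Vectors::mcols(gr)$name), nb),
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), nb),
    strand = rep(strand, nb),
    start = tx_start0 + IRanges::start(bu) - 1L,
    end = tx_start0 + IRanges::end(bu)))
}

#' Write a transcript set as BED12
#'
#' @param x A [tx_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(x, path) {
  sp <- tx_spans(x)
  setorder(sp, chrom, start, transcript_id)
  rows <- vapply(seq_len(nrow(sp)), function(i) {
    e <- x[transcript_id == sp$transcript_id[i]][order(start)]
    paste(sp$chrom[i], sp$start[i], sp$end[i], sp$transcript_id[i], 0,
          sp$strand[i], sp$start[i], sp$end[i], "0,0,0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - sp$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column: transcript/gene ids; remaining columns: one per tissue
#' (or tissue x replicate) of non-negative FPKM. Missing cells are set
#' to 0 with a warning reporting the count.
#'
#' @param path TSV file path with a header row.
#' @return Numeric matrix with row and column names.
#' @export
read_expression_tsv <- function(path) {
  d <- fread(path, sep = "\t", header = TRUE)
  if (ncol(d) < 2L) stop("expression TSV needs an id column plus >=1 tissue column")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stop("duplicated ids in expression TSV: ",
                               ids[duplicated(ids)][1L])
  m <- as.matrix(d[, -1L, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  nmiss <- sum(is.na(m))
  if (nmiss > 0L) {
    warning(sprintf("%d missing expression cells set to 0", nmiss))
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("negative FPKM values in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the id column header.
#' @export
write_expression_tsv <- function(m, path, id_col = "transcript_id") {
  d <- data.table(id = rownames(m))
  setnames(d, "id", id_col)
  fwrite(cbind(d, as.data.table(m)), path, sep = "\t")
  invisible(path)
}

#' Read a bedGraph signal file
#'
#' Intervals are sorted per chromosome; overlapping intervals are an
#' error. Gaps are implicit zeros.
#'
#' @param path bedGraph file path.
#' @return A [signal_track].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  d <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  value = as.numeric(S4Vectors::mcols(gr)$score))
  signal_track(d)
}

#' Write a signal track as bedGraph
#' @param track A [signal_track].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  fwrite(as.data.table(track)[, .(chrom, start, end, value)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Sequences are uppercased; ids are truncated at the first whitespace.
#' Non-ACGT letters are retained; the number of sequences containing any
#' is attached as attribute `n_ambiguous`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  s <- toupper(as.character(ss))
  names(s) <- sub("\\s.*$", "", names(ss))
  attr(s, "n_ambiguous") <- sum(grepl("[^ACGT]", s))
  s
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(as.character(seqs), names(seqs))), path)
  invisible(path)
}

#' Read a two-column GO annotation TSV
#'
#' @param path TSV with header and two columns: gene id, term id.
#' @return data.table(gene_id, term_id).
#' @export
read_go_tsv <- function(path) {
  d <- fread(path, sep = "\t", header = TRUE)
  if (ncol(d) < 2L) stop("GO TSV needs two columns (gene_id, term_id)")
  d <- d[, 1:2]
  setnames(d, c("gene_id", "term_id"))
  d[, gene_id := as.character(gene_id)]
  d[, term_id := as.character(term_id)]
  if (anyNA(d)) stop("missing values in GO TSV ", path)
  d[]
}

#' Write a GO annotation table as TSV
#' @param go data.table(gene_id, term_id).
#' @param path output path.
#' @export
write_go_tsv <- function(go, path) {
  fwrite(as.data.table(go)[, .(gene_id, term_id)], path, sep = "\t")
  invisible(path)
}

#' FPKM from fragment counts
#'
#' Plumbing surrogate when only counts are available:
#' `FPKM = 1e9 * C / (N * L)` with `C` fragments on the transcript, `N`
#' total mapped fragments and `L` transcript length in bp.
#'
#' @param counts fragment counts per transcript.
#' @param total_fragments total mapped fragments `N`.
#' @param lengths transcript lengths (bp).
#' @return Numeric FPKM vector.
#' @export
fpkm_from_counts <- function(counts, total_fragments, lengths) {
  stopifnot(all(counts >= 0), total_fragments > 0, all(lengths > 0))
  1e9 * counts / (total_fragments * lengths)
}
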