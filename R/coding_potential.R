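# Alignment-free coding/noncoding classification by log-odds profiling
# of adjoining nucleotide triplets. A 64x64 table of log2 likelihood
# ratios over transitions between consecutive non-overlapping triplets
# is trained from coding and noncoding sequence sets; a sequence is
# scored per reading frame by its maximal-scoring contiguous segment of
# transition scores (Kadane), and the best frame wins.

# lexicographic AAA..TTT order
TRIPLETS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"))[, 3:1], 1L, paste,
                  collapse = "")

# Non-overlapping triplet index sequence of `seq` in `frame` (0/1/2).
# Returns integer codes in 1..64; NA for triplets with non-ACGT letters.
seq_triplet_codes <- function(seq, frame = 0L) {
  n <- nchar(seq)
  starts <- seq.int(frame + 1L, by = 3L, length.out = (n - frame) %/% 3L)
  if (!length(starts)) return(integer(0))
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- unname(base_code[ch])
  idx <- 16L * b[starts] + 4L * b[starts + 1L] + b[starts + 2L] + 1L
  idx
}

count_triplet_transitions <- function(seqs) {
  counts <- matrix(0, 64L, 64L, dimnames = list(TRIPLETS, TRIPLETS))
  usable <- 0L
  for (s in seqs) {
    if (nchar(s) < 6L || grepl("[^ACGT]", s)) next
    usable <- usable + 1L
    codes <- seq_triplet_codes(s, 0L)
    if (length(codes) < 2L) next
    from <- codes[-length(codes)]
    to <- codes[-1L]
    tab <- table(factor(from, levels = 1:64), factor(to, levels = 1:64))
    counts <- counts + unclass(tab)
  }
  attr(counts, "n_usable") <- usable
  counts
}

score_from_steps <- function(model, codes) {
  if (length(codes) < 2L || anyNA(codes)) {
    # skip transitions touching an ambiguous triplet
    keep <- !is.na(codes)
    codes <- codes[keep]
    if (length(codes) < 2L) return(numeric(0))
  }
  model$logodds[cbind(codes[-length(codes)], codes[-1L])]
}

# Maximal-scoring contiguous subarray (nonempty), leftmost on ties.
# Returns list(score, from, to) in step indices; from=to=0 for empty x.
kadane <- function(x) {
  if (!length(x)) return(list(score = -Inf, from = 0L, to = 0L))
  best <- -Inf; bf <- 0L; bt <- 0L
  cur <- 0; cf <- 1L
  for (k in seq_along(x)) {
    if (cur <= 0) {
      cur <- x[k]; cf <- k
    } else {
      cur <- cur + x[k]
    }
    if (cur > best) {
      best <- cur; bf <- cf; bt <- k
    }
  }
  list(score = best, from = bf, to = bt)
}

#' Train an adjoining-triplet log-odds model
#'
#' Counts transitions between consecutive non-overlapping (codon-style)
#' triplets in frame 0 of each training sequence, smooths both class
#' count tables with a pseudocount, and stores
#' `log2(P_coding(t_j | t_i) / P_noncoding(t_j | t_i))` as a 64x64
#' table indexed in lexicographic `AAA..TTT` order. Sequences shorter
#' than 6 nt or containing non-ACGT letters are skipped; their counts
#' are reported in the `skipped` field.
#'
#' By default the decision threshold separating coding from noncoding
#' scores is calibrated on the training sequences themselves (the split
#' point of the two score distributions that minimizes training error);
#' pass a numeric `threshold` (e.g. 0) to fix it instead. See the
#' methods vignette for why the likelihood-ratio neutral point 0 is a
#' poor decision threshold for maximal-segment scores.
#'
#' @param coding_seqs,noncoding_seqs character vectors of training
#'   sequences (>= 1 usable sequence per class).
#' @param pseudocount additive smoothing count (> 0).
#' @param threshold `"calibrate"` (default) or a numeric threshold.
#' @return A `triplet_model` list: `logodds` (64x64), `pseudocount`,
#'   `threshold`, `skipped`.
#' @export
train_triplet_model <- function(coding_seqs, noncoding_seqs,
                                pseudocount = 1, threshold = "calibrate") {
  stopifnot(pseudocount > 0)
  cc <- count_triplet_transitions(toupper(coding_seqs))
  cn <- count_triplet_transitions(toupper(noncoding_seqs))
  if (attr(cc, "n_usable") == 0L || attr(cn, "n_usable") == 0L) {
    stop("no usable training sequences (need >=6 nt of ACGT in each class)")
  }
  n_usable <- c(attr(cc, "n_usable"), attr(cn, "n_usable"))
  attr(cc, "n_usable") <- NULL
  attr(cn, "n_usable") <- NULL
  pc <- (cc + pseudocount) / (rowSums(cc) + 64 * pseudocount)
  pn <- (cn + pseudocount) / (rowSums(cn) + 64 * pseudocount)
  model <- structure(list(
    logodds = log2(pc / pn),
    pseudocount = pseudocount,
    threshold = 0,
    skipped = c(coding = length(coding_seqs) - n_usable[1L],
                noncoding = length(noncoding_seqs) - n_usable[2L])),
    class = "triplet_model")
  if (identical(threshold, "calibrate")) {
    model$threshold <- calibrate_threshold(model, toupper(coding_seqs),
                                           toupper(noncoding_seqs))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    model$threshold <- as.numeric(threshold)
  }
  model
}

# Error-minimizing split point between the two training score samples.
# Candidates are midpoints between consecutive pooled scores; the first
# (smallest) maximizer is returned; 0 when nothing is scorable.
calibrate_threshold <- function(model, coding_seqs, noncoding_seqs) {
  sc <- score_many(coding_seqs, model)
  sn <- score_many(noncoding_seqs, model)
  sc <- sc[is.finite(sc)]; sn <- sn[is.finite(sn)]
  if (!length(sc) || !length(sn)) return(0)
  pool <- sort(unique(c(sc, sn)))
  if (length(pool) == 1L) return(pool[1L] - 1e-9)
  cand <- c(pool[1L] - 1, (pool[-length(pool)] + pool[-1L]) / 2)
  acc <- vapply(cand, function(t) sum(sc > t) + sum(sn <= t), numeric(1))
  cand[which.max(acc)]
}

score_many <- function(seqs, model) {
  vapply(seqs, function(s) {
    if (nchar(s) < 9L || grepl("[^ACGT]", s)) return(NA_real_)
    score_sequence(s, model)$score
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score a sequence under a triplet model
#'
#' For each reading frame 0..2, the per-step scores are the log-odds of
#' consecutive non-overlapping triplet transitions; the frame's score is
#' that of its maximal-scoring contiguous segment (Kadane). The overall
#' score is the maximum over frames, ties broken by the lower frame
#' index and then the leftmost segment. The score is invariant to
#' trailing nucleotides beyond the last full triplet of each frame.
#'
#' @param seq a sequence of >= 9 nt.
#' @param model a `triplet_model`.
#' @return list(`score`, `frame` in 0..2, `segment` = 0-based half-open
#'   nucleotide interval of the best segment; `c(0, 0)` when every step
#'   score is zero).
#' @export
score_sequence <- function(seq, model) {
  seq <- toupper(seq)
  if (nchar(seq) < 9L) stop("sequence shorter than 9 nt cannot be scored")
  best <- NULL
  all_zero <- TRUE
  for (f in 0:2) {
    steps <- score_from_steps(model, seq_triplet_codes(seq, f))
    if (!length(steps)) next
    if (any(steps != 0)) all_zero <- FALSE
    k <- kadane(steps)
    if (is.null(best) || k$score > best$score) {
      best <- list(score = k$score, frame = f,
                   segment = c(f + (k$from - 1L) * 3L, f + (k$to + 1L) * 3L))
    }
  }
  if (is.null(best)) stop("no scorable frame (ambiguous letters?)")
  if (all_zero) return(list(score = 0, frame = 0L, segment = c(0L, 0L)))
  best
}

#' Score many sequences under a triplet model
#'
#' @param seqs named character vector.
#' @param model a `triplet_model`.
#' @return data.table(id, score, frame, seg_start, seg_end, label).
#' @export
score_sequences <- function(seqs, model) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    r <- score_sequence(seqs[[i]], model)
    data.table(id = ids[i], score = r$score, frame = r$frame,
               seg_start = r$segment[1L], seg_end = r$segment[2L])
  })
  out <- rbindlist(rows)
  out[, label := ifelse(score > model$threshold, "coding", "noncoding")]
  out[]
}

#' Classify a sequence as coding or noncoding
#'
#' `"coding"` iff the [score_sequence()] score exceeds the model
#' threshold.
#'
#' @param seq sequence of >= 9 nt.
#' @param model a `triplet_model`.
#' @return `"coding"` or `"noncoding"`.
#' @export
classify_coding <- function(seq, model) {
  if (score_sequence(seq, model)$score > model$threshold) "coding" else "noncoding"
}

#' Serialize / read a triplet model as TSV
#'
#' 65 rows: a header naming the 64 destination triplets, then one row
#' per source triplet. The threshold and pseudocount are kept in
#' `#`-prefixed comment lines.
#'
#' @param model a `triplet_model`.
#' @param path file path.
#' @return `path` / a `triplet_model`.
#' @export
write_triplet_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseudocount\t%.17g", model$pseudocount), con)
  writeLines(sprintf("# threshold\t%.17g", model$threshold), con)
  writeLines(paste(c("triplet", TRIPLETS), collapse = "\t"), con)
  for (i in 1:64) {
    writeLines(paste(c(TRIPLETS[i], sprintf("%.17g", model$logodds[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_triplet_model
#' @export
read_triplet_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- fread(text = lines[!startsWith(lines, "#")], sep = "\t", header = TRUE)
  m <- as.matrix(body[, -1L, with = FALSE])
  rownames(m) <- body[[1L]]
  getmeta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*\t", "", hit[1L])) else default
  }
  structure(list(logodds = m, pseudocount = getmeta("pseudocount", 1),
                 threshold = getmeta("threshold", 0),
                 skipped = c(coding = NA, noncoding = NA)),
            class = "triplet_model")
}
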