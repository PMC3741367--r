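# Two-color co-expression network construction, Markov clustering
# (implemented here), per-module hypergeometric GO enrichment with BH
# correction, and enrichment-based lincRNA function assignment.

#' Build a two-color co-expression graph
#'
#' Nodes are genes colored `coding` or `lincRNA`; an edge joins two
#' genes when the absolute Pearson correlation of their
#' `log2(FPKM + 1)` profiles across tissues reaches `edge_threshold`.
#' Genes with constant profiles get no edges.
#'
#' @param expr non-negative FPKM matrix, rows = genes, columns =
#'   tissues (>= 3).
#' @param colors named character vector over the rows of `expr`, values
#'   `"coding"` or `"lincRNA"`.
#' @param edge_threshold minimum `|r|` for an edge (default 0.9).
#' @return A `coexpr_graph`: list(`nodes` = data.table(gene_id, color),
#'   `edges` = data.table(from, to, r, weight = `|r|`)).
#' @export
build_coexpression_graph <- function(expr, colors, edge_threshold = 0.9) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L,
            !is.null(rownames(expr)), all(rownames(expr) %in% names(colors)))
  x <- log2(expr + 1)
  keep <- apply(x, 1L, sd) > 0
  xs <- x[keep, , drop = FALSE]
  nodes <- data.table(gene_id = rownames(expr),
                      color = unname(colors[rownames(expr)]))
  edges <- data.table(from = character(), to = character(),
                      r = numeric(), weight = numeric())
  if (nrow(xs) >= 2L) {
    C <- suppressWarnings(cor(t(xs)))
    C[is.na(C)] <- 0
    hit <- which(abs(C) >= edge_threshold & upper.tri(C), arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- data.table(from = rownames(C)[hit[, 1L]],
                          to = rownames(C)[hit[, 2L]],
                          r = C[hit])
      edges[, weight := abs(r)]
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "coexpr_graph")
}

as_adjacency <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == ncol(x), !is.null(rownames(x)))
    return(x)
  }
  if (inherits(x, "coexpr_graph")) {
    ids <- x$nodes$gene_id
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(x$edges)) {
      A[cbind(x$edges$from, x$edges$to)] <- x$edges$weight
      A[cbind(x$edges$to, x$edges$from)] <- x$edges$weight
    }
    return(A)
  }
  stop("mcl: expected a coexpr_graph or a symmetric weighted adjacency matrix")
}

#' Markov clustering (MCL)
#'
#' Self-loops of weight 1 are added, columns are normalized to
#' stochastic, and the process iterates expansion (matrix power),
#' inflation (entrywise power with column renormalization) and pruning
#' of entries below `prune` until the maximum absolute change drops
#' below `tol` or `max_iter` is reached (non-convergence gives a
#' warning and uses the last iterate). Clusters are the connected
#' components of the nonzero support of the limit matrix.
#'
#' @param x a `coexpr_graph` or symmetric weighted adjacency matrix
#'   with row names.
#' @param inflation inflation exponent (default 1.8).
#' @param expansion expansion power (default 2).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the iterate change.
#' @param max_iter iteration cap.
#' @return List of clusters (character vectors of node ids), ordered by
#'   decreasing size then first member; attribute `colsum_dev` records
#'   the maximum absolute column-sum deviation from 1 after each
#'   iteration, and `iterations` the number performed.
#' @export
mcl <- function(x, inflation = 1.8, expansion = 2L, prune = 1e-5,
                tol = 1e-6, max_iter = 100L) {
  A <- as_adjacency(x)
  if (!nrow(A)) stop("mcl: empty graph")
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  dev <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Me <- M
    for (k in seq_len(expansion - 1L)) Me <- Me %*% M
    Mi <- Me^inflation
    Mi[Mi < prune] <- 0
    cs <- colSums(Mi)
    dead <- cs == 0
    if (any(dead)) {
      Mi[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    Mn <- sweep(Mi, 2L, cs, "/")
    dev <- c(dev, max(abs(colSums(Mn) - 1)))
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("mcl: no convergence after ", max_iter,
            " iterations; using last iterate")
  }
  support <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  memb <- igraph::components(g)$membership
  clusters <- split(names(memb), memb)
  first <- vapply(clusters, function(cl) sort(cl)[1L], character(1))
  ord <- order(-lengths(clusters), first)
  clusters <- unname(clusters[ord])
  clusters <- lapply(clusters, function(cl) sort(cl))
  attr(clusters, "colsum_dev") <- dev
  attr(clusters, "iterations") <- length(dev)
  clusters
}

#' Hypergeometric GO enrichment of one gene cluster
#'
#' For each term annotated to at least one cluster gene, the upper-tail
#' hypergeometric probability of drawing `k` or more term genes in `n`
#' draws from a background of `N` genes of which `K` carry the term,
#' followed by Benjamini-Hochberg correction across the cluster's
#' terms. Only background genes count (lincRNAs, being unannotated,
#' are excluded by passing a coding background).
#'
#' @param cluster character vector of gene ids.
#' @param go data.table(gene_id, term_id) annotation map.
#' @param background character vector of background gene ids (must be
#'   non-empty; cluster genes outside it are ignored).
#' @param alpha BH significance level (`enriched` iff `q <= alpha`).
#' @return data.table(term_id, k, K, n, N, p, q, enriched) sorted by p.
#' @export
go_enrichment <- function(cluster, go, background, alpha = 0.05) {
  background <- unique(as.character(background))
  if (!length(background)) stop("go_enrichment: empty background")
  go <- as.data.table(go)[gene_id %in% background]
  cl <- intersect(unique(as.character(cluster)), background)
  N <- length(background)
  n <- length(cl)
  terms <- unique(go[gene_id %in% cl]$term_id)
  if (!length(terms) || n == 0L) {
    return(data.table(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  }
  tab <- go[term_id %in% terms,
            .(K = uniqueN(gene_id), k = uniqueN(intersect(gene_id, cl))),
            by = term_id]
  tab[, `:=`(n = n, N = N)]
  tab[, p := phyper(k - 1L, K, N - K, n, lower.tail = FALSE)]
  tab[, q := p.adjust(p, method = "BH")]
  tab[, enriched := q <= alpha]
  setorder(tab, p, term_id)
  tab[, .(term_id, k, K, n, N, p, q, enriched)]
}

#' Build a module set with per-module enrichment
#'
#' Runs [go_enrichment()] on every cluster of at least
#' `min_module_size` genes, using the cluster's coding genes against
#' the coding background.
#'
#' @param clusters list of gene-id vectors (e.g. from [mcl()]).
#' @param colors named color vector (`"coding"`/`"lincRNA"`).
#' @param go data.table(gene_id, term_id).
#' @param background coding background gene ids; defaults to all
#'   `"coding"`-colored genes.
#' @param min_module_size smallest reported module (default 6).
#' @param alpha BH level.
#' @return A `module_set`: list(`clusters`, `colors`, `enrichment`
#'   (per reported module), `modules` summary data.table, parameters).
#' @export
module_set <- function(clusters, colors, go,
                       background = names(colors)[colors == "coding"],
                       min_module_size = 6L, alpha = 0.05) {
  keep <- which(lengths(clusters) >= min_module_size)
  enr <- lapply(keep, function(i) {
    coding_genes <- intersect(clusters[[i]], background)
    go_enrichment(coding_genes, go, background, alpha)
  })
  names(enr) <- sprintf("M%03d", keep)
  summary <- data.table(
    module_id = names(enr),
    size = lengths(clusters[keep]),
    n_coding = vapply(clusters[keep], function(cl)
      sum(colors[cl] == "coding", na.rm = TRUE), integer(1)),
    n_lincrna = vapply(clusters[keep], function(cl)
      sum(colors[cl] == "lincRNA", na.rm = TRUE), integer(1)),
    n_enriched_terms = vapply(enr, function(e) sum(e$enriched), integer(1)))
  summary[, two_color := n_coding > 0L & n_lincrna > 0L]
  structure(list(clusters = clusters, kept = keep, colors = colors,
                 enrichment = enr, modules = summary[],
                 min_module_size = min_module_size, alpha = alpha),
            class = "module_set")
}

#' Assign module-enriched terms to lincRNAs
#'
#' Every lincRNA in a reported module (size >= `min_module_size`) with
#' at least one enriched term inherits all of that module's enriched
#' terms; lincRNAs elsewhere get none.
#'
#' @param ms a [module_set()].
#' @return Named list mapping lincRNA id to its inherited term ids.
#' @export
annotate_lincrnas <- function(ms) {
  out <- list()
  for (m in seq_along(ms$kept)) {
    terms <- ms$enrichment[[m]][enriched == TRUE]$term_id
    if (!length(terms)) next
    cl <- ms$clusters[[ms$kept[m]]]
    lincs <- cl[!is.na(ms$colors[cl]) & ms$colors[cl] == "lincRNA"]
    for (l in lincs) out[[l]] <- sort(unique(c(out[[l]], terms)))
  }
  out
}
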