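#' Co-target genes of a miRNA pair
#'
#' @param tm `target_map`.
#' @param mirna_a,mirna_b miRNA ids present in `tm`.
#' @return character vector: the intersection of the two target sets.
#' @export
co_targets <- function(tm, mirna_a, mirna_b) {
  stopifnot(inherits(tm, "target_map"))
  for (id in c(mirna_a, mirna_b))
    if (!id %in% names(tm)) stop("miRNA not in target map: ", id)
  sort(intersect(tm[[mirna_a]], tm[[mirna_b]]))
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `k` pathway members among `n`
#' co-targets drawn from a universe of `N` target genes of which `M`
#' belong to the pathway:
#' `p = sum_{x=k}^{min(n,M)} C(M,x) C(N-M,n-x) / C(N,n)`
#' (tail includes the observed overlap; evaluated through the
#' log-space hypergeometric CDF for numerical stability).
#'
#' @param N universe size (number of all target genes).
#' @param M pathway size within the universe.
#' @param n co-target set size.
#' @param k observed overlap between co-targets and the pathway.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(N, M, n, k) {
  if (any(c(N, M, n, k) < 0) || M > N || n > N || k > min(n, M))
    stop("invalid hypergeometric problem: need k <= min(n, M), n <= N, M <= N")
  if (k == 0) return(1)
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Test one miRNA pair for co-target pathway synergy
#'
#' Computes the co-target set of the pair, one [hypergeom_tail()] per
#' pathway (pathway sizes and overlaps are taken within the target
#' universe `N`, the union of all targets in `tm`), BH-adjusts the
#' p-values across pathways within this pair, and declares a synergy
#' edge iff at least one adjusted p-value falls below `alpha`.  With
#' `global_adjust = TRUE` raw p-values are returned unadjusted so the
#' caller can correct across all pairs instead.
#'
#' @param tm `target_map`.
#' @param mirna_a,mirna_b the pair.
#' @param pathways named list of pathway gene sets.
#' @param alpha significance level on the adjusted p-values.
#' @param global_adjust skip the within-pair BH (edge decision is then
#'   deferred to the caller).
#' @return `NULL` when the co-target set is empty or no pathway is
#'   significant; otherwise a list of class `synergy_edge` with
#'   `mirna_a`, `mirna_b`, `co_target_count` and `pathways` (data.frame
#'   `pathway`, `overlap`, `p_raw`, `p_adj` restricted to significant
#'   terms, best first).
#' @export
synergy_test_pair <- function(tm, mirna_a, mirna_b, pathways,
                              alpha = 0.05, global_adjust = FALSE) {
  co <- co_targets(tm, mirna_a, mirna_b)
  if (!length(co)) return(NULL)
  universe <- attr(tm, "universe")
  N <- length(universe)
  n <- length(co)
  p_raw <- vapply(pathways, function(genes) {
    pw <- intersect(genes, universe)
    hypergeom_tail(N, length(pw), n, length(intersect(co, pw)))
  }, 0)
  overlap <- vapply(pathways, function(genes)
    length(intersect(co, intersect(genes, universe))), 0L)
  p_adj <- if (global_adjust) p_raw else bh_adjust(p_raw)
  sig <- which(p_adj < alpha)
  if (!length(sig)) return(NULL)
  ord <- sig[order(p_adj[sig], p_raw[sig])]
  structure(list(mirna_a = min(mirna_a, mirna_b),
                 mirna_b = max(mirna_a, mirna_b),
                 co_target_count = n,
                 pathways = data.frame(pathway = names(pathways)[ord],
                                       overlap = overlap[ord],
                                       p_raw = unname(p_raw[ord]),
                                       p_adj = unname(p_adj[ord]),
                                       stringsAsFactors = FALSE)),
            class = "synergy_edge")
}

#' Build the miRNA-miRNA correlation/synergy network
#'
#' For every candidate pair (normally all unordered pairs of the
#' differential miRNAs, carrying their Pearson CE from
#' [pairwise_ce()]), runs [synergy_test_pair()]; pairs with at least
#' one significantly enriched co-target pathway become undirected
#' edges, annotated with CE, sign class, co-target count and the best
#' pathway.  Nodes are the miRNAs incident to at least one edge.
#'
#' @param candidate_pairs data.frame with columns `mirna_a`, `mirna_b`,
#'   `ce` (and optionally `sign_class`), e.g. from [pairwise_ce()].
#' @param tm `target_map` (pairs whose miRNAs lack target annotation
#'   are skipped).
#' @param pathways named list of pathway gene sets.
#' @param alpha significance level for the within-pair BH-adjusted
#'   enrichment.
#' @return list of class `synergy_network`: `graph` (igraph with edge
#'   attributes `ce`, `sign_class`, `co_target_count`, `best_pathway`,
#'   `best_p_adj`, `n_sig_pathways`), `edges` (the same as a
#'   data.frame), `n_positive`, `n_negative`.  Empty networks (no
#'   surviving edge) are returned with a warning.
#' @export
build_network <- function(candidate_pairs, tm, pathways, alpha = 0.05) {
  stopifnot(is.data.frame(candidate_pairs),
            all(c("mirna_a", "mirna_b", "ce") %in% names(candidate_pairs)))
  rows <- list()
  for (i in seq_len(nrow(candidate_pairs))) {
    a <- candidate_pairs$mirna_a[i]; b <- candidate_pairs$mirna_b[i]
    if (!a %in% names(tm) || !b %in% names(tm)) next
    edge <- synergy_test_pair(tm, a, b, pathways, alpha = alpha)
    if (is.null(edge)) next
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_a = edge$mirna_a, mirna_b = edge$mirna_b,
      ce = candidate_pairs$ce[i],
      sign_class = ifelse(candidate_pairs$ce[i] > 0, "positive", "negative"),
      co_target_count = edge$co_target_count,
      best_pathway = edge$pathways$pathway[1],
      best_p_adj = edge$pathways$p_adj[1],
      n_sig_pathways = nrow(edge$pathways),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no synergy edge survived; returning an empty network")
    edges <- data.frame(mirna_a = character(), mirna_b = character(),
                        ce = numeric(), sign_class = character(),
                        co_target_count = integer(),
                        best_pathway = character(), best_p_adj = numeric(),
                        n_sig_pathways = integer(), stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- do.call(rbind, rows)
    edges <- edges[order(edges$mirna_a, edges$mirna_b), , drop = FALSE]
    rownames(edges) <- NULL
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  structure(list(graph = g, edges = edges,
                 n_positive = sum(edges$ce > 0),
                 n_negative = sum(edges$ce < 0)),
            class = "synergy_network")
}

#' @export
print.synergy_network <- function(x, ...) {
  cat("synergy_network:", igraph::vcount(x$graph), "miRNAs,",
      nrow(x$edges), "edges (", x$n_positive, "positive,",
      x$n_negative, "negative )\n")
  invisible(x)
}

#' Write the synergy edge table as TSV
#' @param network `synergy_network`.
#' @param path output path.
#' @export
write_edge_table <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
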