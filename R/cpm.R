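#' Enumerate all complete subgraphs of exactly k nodes
#'
#' Finds maximal cliques of size >= k (pivoting Bron-Kerbosch via
#' igraph) and expands each into its k-subsets, deduplicated.  A guard
#' caps the number of maximal cliques processed; graphs beyond the cap
#' abort rather than silently truncating.
#'
#' @param graph simple undirected igraph graph.
#' @param k clique size (>= 2).
#' @param max_maximal_cliques guard against pathological inputs.
#' @return list of character vectors (sorted node names); empty when k
#'   exceeds the node count or no k-clique exists.
#' @export
find_k_cliques <- function(graph, k, max_maximal_cliques = 1e5) {
  stopifnot(igraph::is_igraph(graph), k >= 2)
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (k > igraph::vcount(graph)) return(list())
  mc <- igraph::max_cliques(graph, min = k)
  if (length(mc) > max_maximal_cliques)
    stop("more than ", max_maximal_cliques, " maximal cliques; ",
         "raise max_maximal_cliques to proceed")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (cl in mc) {
    nm <- sort(igraph::V(graph)$name[as.integer(cl)])
    if (length(nm) == k) {
      subs <- list(nm)
    } else {
      cmb <- combn(nm, k)
      subs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }
    for (s in subs) {
      key <- paste(s, collapse = "\r")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- s
      }
    }
  }
  out
}

#' Clique Percolation Method (CPM) community detection
#'
#' Two k-cliques are adjacent iff they share k-1 nodes; modules are the
#' node unions of the connected components of this clique-adjacency
#' graph.  Nodes belonging to no k-clique belong to no module; modules
#' may overlap in nodes but never share a k-clique.  With k = 2 the
#' modules are exactly the connected components with at least one edge.
#'
#' @param graph simple undirected igraph graph.
#' @param k clique size (default 3, the smallest non-trivial choice).
#' @param max_maximal_cliques passed to [find_k_cliques()].
#' @return list of `clique_module` objects (fields `members`, `k`,
#'   `index`), ordered by decreasing size then lexicographically.
#' @export
clique_percolation <- function(graph, k = 3, max_maximal_cliques = 1e5) {
  cliques <- find_k_cliques(graph, k, max_maximal_cliques)
  if (!length(cliques)) return(list())
  n <- length(cliques)
  # union-find over cliques; cliques sharing any (k-1)-subset are merged
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  subset_owner <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    cl <- cliques[[i]]
    for (drop in seq_len(k)) {
      key <- paste(cl[-drop], collapse = "\r")
      prev <- subset_owner[[key]]
      if (is.null(prev)) subset_owner[[key]] <- i else unite(prev, i)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(seq_len(n), roots)
  modules <- lapply(comp, function(ix)
    sort(unique(unlist(cliques[ix], use.names = FALSE))))
  ord <- order(-lengths(modules),
               vapply(modules, `[`, "", 1L))
  modules <- modules[ord]
  lapply(seq_along(modules), function(i)
    structure(list(members = modules[[i]], k = k, index = i),
              class = "clique_module"))
}

#' @export
print.clique_module <- function(x, ...) {
  cat(sprintf("clique_module %d (k=%d, %d miRNAs): %s\n", x$index, x$k,
              length(x$members), paste(x$members, collapse = " ")))
  invisible(x)
}

#' Write CPM modules as a TSV table
#' @param modules list of `clique_module` (from [clique_percolation()]).
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(
    module_index = vapply(modules, `[[`, 0L, "index"),
    k = vapply(modules, `[[`, 0L, "k"),
    miRNAs = vapply(modules, function(m)
      paste(m$members, collapse = ","), ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
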