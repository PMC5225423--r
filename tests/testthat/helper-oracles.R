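# Independent brute-force oracles.  Everything here is deliberately naive
# and shares no code path with the package implementation.

# Mann-Whitney AUC by explicit enumeration of all case-control pairs.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# BH step-up from the definition: q_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Welch two-sample t-test from the formula.
oracle_welch_p <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  2 * pt(-abs(tt), df)
}

# Hypergeometric upper tail by enumerating every n-subset of the universe.
oracle_hypergeom_enum <- function(N, M, n, k) {
  if (k == 0) return(1)
  in_pathway <- c(rep(TRUE, M), rep(FALSE, N - M))
  draws <- combn(N, n)
  hits <- colSums(matrix(in_pathway[draws], nrow = n))
  mean(hits >= k)
}

# Pearson correlation from the product-moment formula.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force CPM on an adjacency matrix: enumerate all k-subsets, keep
# complete ones, connect those sharing k-1 nodes, take component unions.
oracle_cpm <- function(adj, k) {
  nodes <- rownames(adj)
  n <- length(nodes)
  if (k > n) return(list())
  subs <- combn(n, k)
  complete <- logical(ncol(subs))
  for (j in seq_len(ncol(subs))) {
    s <- subs[, j]
    ok <- TRUE
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[s[a], s[b]] == 0) { ok <- FALSE }
    complete[j] <- ok
  }
  cl <- lapply(which(complete), function(j) subs[, j])
  if (!length(cl)) return(list())
  nc <- length(cl)
  cadj <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc))
    if (i != j && length(intersect(cl[[i]], cl[[j]])) == k - 1)
      cadj[i, j] <- TRUE
  seen <- rep(FALSE, nc)
  modules <- list()
  for (i in seq_len(nc)) {
    if (seen[i]) next
    queue <- i; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(cadj[v, ] & !seen))
    }
    modules[[length(modules) + 1L]] <-
      sort(nodes[unique(unlist(cl[comp]))])
  }
  modules
}

canonical_modules <- function(mods) {
  keys <- vapply(mods, function(m) paste(sort(m), collapse = "|"), "")
  sort(keys)
}

# Floyd-Warshall distances + shortest-path counts, then the five global
# topology statistics with the package's documented conventions.
oracle_topology <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  d[adj > 0] <- 1
  sig[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) {
      d[i, j] <- alt
      sig[i, j] <- sig[i, k] * sig[k, j]
    } else if (is.finite(alt) && alt == d[i, j]) {
      sig[i, j] <- sig[i, j] + sig[i, k] * sig[k, j]
    }
  }
  finite_off <- is.finite(d) & row(d) != col(d)
  asp <- mean(d[finite_off])
  # component labels
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    comp[is.finite(d[v, ])] <- cid
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t] && sig[s, t] > 0)
        acc <- acc + sig[s, v] * sig[v, t] / sig[s, t]
    }
    nc <- sum(comp == comp[v])
    btw[v] <- if (nc >= 3) acc / ((nc - 1) * (nc - 2) / 2) else 0
  }
  cls <- numeric(n)
  for (v in seq_len(n)) {
    nc <- sum(comp == comp[v])
    cls[v] <- if (nc >= 2) (nc - 1) / sum(d[v, comp == comp[v]]) else 0
  }
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && adj[nb[a], nb[b]] > 0) links <- links + 1
    cc[v] <- links / choose(length(nb), 2)
  }
  c(avg_shortest_path = asp, avg_betweenness = mean(btw),
    avg_closeness = mean(cls), avg_clustering_coefficient = mean(cc),
    avg_degree = sum(adj) / n)
}

# ---- fixture builders ------------------------------------------------------

toy_expr <- function(values, groups = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("mir-", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(groups)) {
    half <- ceiling(ncol(values) / 2)
    groups <- setNames(rep(c("case", "control"),
                           c(half, ncol(values) - half)), colnames(values))
  }
  mirna_expr(values, groups)
}

random_er_adjacency <- function(n, p, seed) {
  set.seed(seed)
  nm <- sprintf("n%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

graph_from_adjacency <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# two dense blocks joined by a single bridging edge
two_block_adjacency <- function(n_block = 8, p = 0.9, seed = 1) {
  set.seed(seed)
  n <- 2 * n_block
  nm <- sprintf("v%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (blk in list(seq_len(n_block), n_block + seq_len(n_block)))
    for (i in blk) for (j in blk)
      if (i < j && runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj[1, n_block + 1] <- adj[n_block + 1, 1] <- 1L
  adj
}
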