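# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths (and igraph where
# the checked operation is itself graph traversal).

# edge list -> adjacency list (named list of character vectors)
adj_list <- function(edges) {
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# hand-rolled breadth-first search truncated at a given depth
bfs_within <- function(edges, seed, depth) {
  adj <- adj_list(edges)
  seen <- seed
  frontier <- seed
  d <- 0L
  while (d < depth && length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# set-based deduplication oracle for interactome cleaning
clean_oracle <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  key <- unique(paste(pmin(a, b), pmax(a, b), sep = "|"))
  parts <- strsplit(key, "|", fixed = TRUE)
  list(edges = sort(key),
       nodes = sort(unique(unlist(parts))))
}

# dense linear-system oracle for the modified PageRank fixed point:
# (I - D M) w = (1 - d) / (2N), with M the column-normalized adjacency.
pagerank_oracle <- function(edges) {
  adj <- adj_list(edges)
  nodes <- names(adj)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (v in nodes) A[v, adj[[v]]] <- 1
  deg <- rowSums(A)
  d <- vapply(nodes, function(v) {
    if (deg[v] == 0) 0 else deg[v] / sum(deg[adj[[v]]])
  }, 1)
  M <- sweep(A, 2L, pmax(deg, 1), "/")
  w <- solve(diag(n) - diag(d, n) %*% M, (1 - d) / (2 * n))
  stats::setNames(as.vector(w), nodes)
}

# log-space exact upper-tail hypergeometric summation
hyper_tail_oracle <- function(N, K, n, k) {
  kk <- seq.int(max(k, max(0L, K + n - N)), min(K, n))
  if (!length(kk)) return(0)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

# random connected undirected simple graph as a 2-column character matrix:
# a random spanning tree plus extra random edges
random_connected_edges <- function(n, extra = n) {
  nodes <- sprintf("N%02d", seq_len(n))
  edges <- cbind(nodes[1L], nodes[1L])[0, , drop = FALSE]
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    edges <- rbind(edges, c(nodes[j], nodes[i]))
  }
  for (e in seq_len(extra)) {
    ij <- sample.int(n, 2L)
    edges <- rbind(edges, nodes[ij])
  }
  # drop loops and duplicates
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges[!duplicated(key), , drop = FALSE]
}

# the worked 8-node toy graph used for the two-step construction example
toy8_edges <- function() {
  cbind(c("P1", "P1", "P1", "P2", "P3", "P4", "P4", "P4"),
        c("P2", "P3", "P4", "P4", "P5", "P6", "P7", "P8"))
}

make_subnetwork <- function(seed, nodes) {
  structure(list(seed = seed, network_id = paste0("net:", seed),
                 nodes = sort(nodes), graph = NULL),
            class = "subnetwork")
}

# brute-force O(n^2) subset-removal oracle: drop any network whose node
# set is contained in a different network's node set, preferring the
# lexicographically smallest seed among identical sets
subset_removal_oracle <- function(sets, seeds) {
  n <- length(sets)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      sub <- all(sets[[i]] %in% sets[[j]])
      if (!sub) next
      eq <- length(sets[[i]]) == length(sets[[j]])
      if (!eq || seeds[j] < seeds[i]) { keep[i] <- FALSE; break }
    }
  }
  sort(seeds[keep])
}
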