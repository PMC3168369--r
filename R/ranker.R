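#' Dynamic damping factor of a node
#'
#' The damping factor of protein A is the ratio of A's degree to the sum
#' of the degrees of A's interactors, all within the sub-network:
#' \deqn{d_A = \mathrm{deg}(A) / \sum_{g \in N(A)} \mathrm{deg}(g).}
#' It is computed per node from local connectivity rather than fixed
#' globally, which adapts the weight propagation to the topology of each
#' biological network. An isolated node has damping 0 by convention.
#'
#' @param subnetwork A `subnetwork` carrying its induced graph (see
#'   [subnetwork_graph()]), or an igraph graph.
#' @param node Gene symbol of the node.
#' @return Damping factor in `[0, 1]`.
#' @examples
#' it <- as_interactome(cbind(c("A", "B", "C"), c("B", "C", "A")))
#' sn <- build_two_step_network(it, "A")
#' damping_factor(sn, "A")  # 1/2 on a triangle
#' @export
damping_factor <- function(subnetwork, node) {
  g <- if (igraph::is_igraph(subnetwork)) subnetwork else subnetwork_graph(subnetwork)
  node <- as.character(node)
  if (!node %in% igraph::V(g)$name) {
    stop(sprintf("node '%s' is not in the sub-network", node), call. = FALSE)
  }
  deg <- igraph::degree(g)
  if (deg[[node]] == 0L) return(0)
  nb <- igraph::neighbors(g, node)$name
  unname(deg[[node]] / sum(deg[nb]))
}

#' Modified PageRank weights with dynamic damping
#'
#' Computes per-node weights of a sub-network as the fixed point of
#' \deqn{w(A) = \frac{1 - d_A}{2N} + d_A \sum_{H \in N(A)} \frac{w(H)}{\mathrm{deg}(H)},}
#' where \eqn{d_A} is the node's dynamic damping factor
#' ([damping_factor()]) and \eqn{N} the number of proteins in the
#' sub-network. The denominator \eqn{2N} (rather than \eqn{N}) scales the
#' total weight of a network into (0, 1), so each individual weight lies
#' strictly between 0 and 1. The fixed point is reached by synchronous
#' power iteration from the uniform start \eqn{w^{(0)} = 1/(2N)},
#' stopping when the maximum absolute change drops below `tol`.
#'
#' Undirected graphs have no dangling nodes, so every node participates in
#' the iteration; on any k-regular graph the weights are exactly
#' \eqn{1/(2N)}.
#'
#' @param subnetwork A `subnetwork` carrying its induced graph, or an
#'   igraph graph.
#' @param tol Convergence tolerance on the max-norm change per iteration.
#' @param max_iter Iteration cap; if reached, the result is returned with
#'   `converged = FALSE` and a warning.
#' @return A `weight_vector` object: list with `network_id`, `weights`
#'   (named, each in (0, 1)), `damping` (named, each in `[0, 1]`),
#'   `iterations_used`, `converged`.
#' @examples
#' star <- as_interactome(cbind("C", c("L1", "L2", "L3")))
#' wv <- pagerank_weights(build_two_step_network(star, "C"))
#' wv$weights  # center 3/8, leaves 1/8
#' @export
pagerank_weights <- function(subnetwork, tol = 1e-10, max_iter = 1000L) {
  if (igraph::is_igraph(subnetwork)) {
    g <- subnetwork
    id <- NA_character_
  } else {
    g <- subnetwork_graph(subnetwork)
    id <- subnetwork$network_id
  }
  n <- igraph::vcount(g)
  if (n < 1L) stop("sub-network has no nodes", call. = FALSE)
  nms <- igraph::V(g)$name
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)
  # d_A = deg(A) / sum of neighbor degrees; isolated nodes get d = 0 and
  # keep the bare teleport weight 1/(2N)
  nbr_deg_sum <- as.vector(adj %*% deg)
  d <- ifelse(deg > 0, deg / pmax(nbr_deg_sum, 1), 0)
  tele <- (1 - d) / (2 * n)
  w <- rep(1 / (2 * n), n)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  iter <- 0L
  converged <- TRUE
  if (n > 1L) {
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      w_new <- tele + d * as.vector(adj %*% (w * inv_deg))
      delta <- max(abs(w_new - w))
      w <- w_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      warning(sprintf("modified PageRank did not converge within %d iterations (network %s)",
                      max_iter, id), call. = FALSE)
    }
  }
  names(w) <- nms
  names(d) <- nms
  structure(list(network_id = id, weights = w, damping = d,
                 iterations_used = iter, converged = converged),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Modified PageRank weights (%s): %d nodes, %d iterations%s\n",
              x$network_id, length(x$weights), x$iterations_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Rank every sub-network's proteins
#'
#' Computes [pagerank_weights()] for each sub-network, extracting the
#' induced subgraph from the interactome when necessary.
#'
#' @param interactome The parent `interactome`.
#' @param networks List of `subnetwork` objects.
#' @inheritParams pagerank_weights
#' @return Named list of `weight_vector` objects (names are network ids).
#' @export
rank_networks <- function(interactome, networks, tol = 1e-10, max_iter = 1000L) {
  out <- lapply(networks, function(sn) {
    g <- subnetwork_graph(sn, interactome)
    wv <- pagerank_weights(g, tol = tol, max_iter = max_iter)
    wv$network_id <- sn$network_id
    wv
  })
  names(out) <- vapply(networks, `[[`, "", "network_id")
  out
}

#' Write a per-gene weight dump
#'
#' One row per (network, gene): `network_id`, `gene`, `damping`, `weight`.
#'
#' @param weights Named list of `weight_vector` objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path) {
  parts <- lapply(weights, function(wv) {
    data.frame(network_id = wv$network_id,
               gene = names(wv$weights),
               damping = unname(wv$damping[names(wv$weights)]),
               weight = unname(wv$weights),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, parts), path)
}

#' Read a weight dump written by [write_weights()]
#'
#' @param path Path to the TSV dump.
#' @return Named list of `weight_vector` objects (convergence metadata is
#'   not stored in the dump and is set to `NA`).
#' @export
read_weights <- function(path) {
  df <- read_tsv(path)
  out <- lapply(split(df, df$network_id), function(d) {
    w <- d$weight; names(w) <- d$gene
    dmp <- d$damping; names(dmp) <- d$gene
    structure(list(network_id = d$network_id[1L], weights = w, damping = dmp,
                   iterations_used = NA_integer_, converged = NA),
              class = "weight_vector")
  })
  out[order(names(out))]
}
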