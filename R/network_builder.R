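#' Build the two-step sub-network around a seed protein
#'
#' The two-step sub-network of a seed is the induced subgraph on all nodes
#' within graph distance 2 of the seed: the seed, its interactors, and the
#' interactors of those interactors. Edges are exactly the interactome
#' edges with both endpoints inside that node set.
#'
#' @param interactome An `interactome`.
#' @param seed Gene symbol of the seed protein (must be a node).
#' @return A `subnetwork` object: list with elements `seed`, `network_id`
#'   (`"net:<seed>"`), `nodes` (sorted character vector) and `graph`
#'   (induced igraph subgraph).
#' @examples
#' it <- as_interactome(cbind(c("A", "B"), c("B", "C")))
#' build_two_step_network(it, "A")
#' @export
build_two_step_network <- function(interactome, seed) {
  stopifnot(inherits(interactome, "interactome"))
  seed <- as.character(seed)
  if (!seed %in% interactome_nodes(interactome)) {
    stop(sprintf("unknown seed protein: '%s'", seed), call. = FALSE)
  }
  nodes <- igraph::ego(interactome$graph, order = 2L, nodes = seed)[[1L]]$name
  new_subnetwork(seed, sort(nodes),
                 graph = igraph::induced_subgraph(interactome$graph, nodes))
}

new_subnetwork <- function(seed, nodes, graph = NULL) {
  structure(list(seed = seed,
                 network_id = paste0("net:", seed),
                 nodes = nodes,
                 graph = graph),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Two-step sub-network %s: seed %s, %d proteins\n",
              x$network_id, x$seed, length(x$nodes)))
  invisible(x)
}

#' Induced subgraph of a sub-network
#'
#' Returns the igraph subgraph induced by the sub-network's node set,
#' extracting it from `interactome` when the sub-network does not already
#' carry one (sub-networks from [build_all_networks()] carry node sets
#' only, for economy).
#'
#' @param subnetwork A `subnetwork`.
#' @param interactome The parent `interactome` (needed when the
#'   sub-network has no attached graph).
#' @return An igraph graph.
#' @export
subnetwork_graph <- function(subnetwork, interactome = NULL) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  if (!is.null(subnetwork$graph)) return(subnetwork$graph)
  if (is.null(interactome)) {
    stop("sub-network has no attached graph; supply the parent interactome",
         call. = FALSE)
  }
  igraph::induced_subgraph(interactome$graph, subnetwork$nodes)
}

#' Build the two-step sub-network of every protein
#'
#' Creates exactly one sub-network per interactome node, seeded at that
#' node. Node sets are computed in one pass; induced subgraphs are not
#' attached (see [subnetwork_graph()]).
#'
#' @param interactome An `interactome`.
#' @return List of `subnetwork` objects, one per node, in node order.
#' @export
build_all_networks <- function(interactome) {
  stopifnot(inherits(interactome, "interactome"))
  nodes <- interactome_nodes(interactome)
  if (!length(nodes)) stop("empty interactome", call. = FALSE)
  hoods <- igraph::ego(interactome$graph, order = 2L)
  mapply(function(seed, hood) new_subnetwork(seed, sort(hood$name)),
         nodes, hoods, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Remove sub-networks that are subsets of other sub-networks
#'
#' A sub-network is excluded when its node set is contained in (or equal
#' to) the node set of another retained sub-network. When two sub-networks
#' have identical node sets the one whose seed is lexicographically
#' smallest is retained.
#'
#' @param networks List of `subnetwork` objects.
#' @return The retained sub-networks, in decreasing size order (ties by
#'   seed).
#' @export
remove_subset_networks <- function(networks) {
  if (!length(networks)) return(networks)
  sizes <- vapply(networks, function(x) length(x$nodes), 1L)
  seeds <- vapply(networks, `[[`, "", "seed")
  ord <- order(-sizes, seeds)
  networks <- networks[ord]
  nodesets <- lapply(networks, `[[`, "nodes")
  # any superset of network i must contain i's first node, so index
  # retained networks by member node and only test those containing it
  membership <- new.env(parent = emptyenv(), hash = TRUE)
  retained <- logical(length(networks))
  for (i in seq_along(networks)) {
    v <- nodesets[[i]]
    cand <- mget(v[1L], envir = membership,
                 ifnotfound = list(integer()))[[1L]]
    is_sub <- FALSE
    for (j in cand) {
      if (all(v %in% nodesets[[j]])) { is_sub <- TRUE; break }
    }
    if (!is_sub) {
      retained[i] <- TRUE
      for (nd in v) {
        membership[[nd]] <- c(mget(nd, envir = membership,
                                   ifnotfound = list(integer()))[[1L]], i)
      }
    }
  }
  networks[retained]
}

#' Filter sub-networks by size
#'
#' Retains sub-networks whose protein count lies in `[min_n, max_n]`
#' (inclusive). The defaults restrict to 20-200 proteins, the working
#' range that keeps sub-networks informative while limiting the
#' multiple-testing burden of very large networks.
#'
#' @param networks List of `subnetwork` objects.
#' @param min_n,max_n Inclusive size bounds.
#' @return The surviving sub-networks.
#' @export
filter_by_size <- function(networks, min_n = 20L, max_n = 200L) {
  if (min_n > max_n) {
    stop(sprintf("invalid size bounds: min_n (%s) > max_n (%s)", min_n, max_n),
         call. = FALSE)
  }
  sizes <- vapply(networks, function(x) length(x$nodes), 1L)
  networks[sizes >= min_n & sizes <= max_n]
}

#' Write a sub-network membership dump
#'
#' One row per sub-network: `network_id`, `seed`, `n_nodes`, and the
#' comma-joined member list.
#'
#' @param networks List of `subnetwork` objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_subnetworks <- function(networks, path) {
  df <- data.frame(
    network_id = vapply(networks, `[[`, "", "network_id"),
    seed = vapply(networks, `[[`, "", "seed"),
    n_nodes = vapply(networks, function(x) length(x$nodes), 1L),
    members = vapply(networks, function(x) paste(x$nodes, collapse = ","), ""),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sub-network membership dump written by [write_subnetworks()]
#'
#' @param path Path to the TSV dump.
#' @return List of `subnetwork` objects (node sets only).
#' @export
read_subnetworks <- function(path) {
  df <- read_tsv(path)
  lapply(seq_len(nrow(df)), function(i) {
    new_subnetwork(df$seed[i], sort(strsplit(df$members[i], ",", fixed = TRUE)[[1L]]))
  })
}
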