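#' Permute interactome node labels
#'
#' Applies a uniformly random bijection of node labels to the edge list.
#' The graph structure (node count, edge count, degree multiset) is
#' unchanged, but which gene carries which connectivity is randomized, so
#' hubs do not remain hubs. Used to diagnose sub-networks that rank highly
#' for purely topological ("small-world") reasons.
#'
#' @param interactome An `interactome`.
#' @param seed Integer seed; the permutation is reproducible from it.
#' @return A new `interactome` on the same label set.
#' @export
permute_node_labels <- function(interactome, seed) {
  stopifnot(inherits(interactome, "interactome"))
  labels <- interactome_nodes(interactome)
  perm <- with_seed(seed, sample(labels))
  g <- interactome$graph
  igraph::V(g)$name <- perm[match(igraph::V(g)$name, labels)]
  new_interactome(g)
}

#' Permute the gene-to-p-value assignment of a GWAS table
#'
#' Shuffles which gene carries which association p-value. The p-value
#' multiset — hence `mean_p` and `sd_p` — is preserved exactly.
#'
#' @param table A [gene_score_table()].
#' @param seed Integer seed.
#' @return A `gene_score_table` with permuted assignment.
#' @export
permute_gene_pvalues <- function(table, seed) {
  stopifnot(inherits(table, "gene_score_table"))
  out <- table
  out$p <- with_seed(seed, sample(table$p))
  out
}

#' Null recurrence frequency of each sub-network
#'
#' Re-runs the scoring pipeline on permuted inputs and records, for every
#' baseline sub-network, how often it lands in the top fraction of the
#' ranking. Two null procedures are available: `"gwas"` permutes the
#' gene-to-p-value assignment (networks and weights are fixed, so only
#' re-scoring is needed), and `"networks"` permutes interactome node
#' labels and rebuilds sub-networks and weights from scratch each run.
#' Sub-networks that recur in a large share of null runs reflect generic
#' topology rather than the trait and should be down-weighted when
#' interpreting results.
#'
#' @param interactome An `interactome`.
#' @param gene_table A [gene_score_table()].
#' @param runs Number of permutation runs (the reference analysis used
#'   10000 GWAS permutations and 100 network randomizations; tests and
#'   examples use far fewer).
#' @param mode `"gwas"` or `"networks"`.
#' @param top_fraction Fraction of the ranking counted as a top hit
#'   (default 0.02: a network scores a hit when its percentile is
#'   `<= 100 * top_fraction`).
#' @param size_min,size_max Sub-network size bounds (see
#'   [filter_by_size()]).
#' @param alpha_gene Passed through to scoring (unused by the ranking but
#'   kept for config parity).
#' @param tol,max_iter Passed to [pagerank_weights()].
#' @param seed Master seed; per-run child seeds are spawned from it.
#' @return A data.frame of class `null_frequency_table` with columns
#'   `network_id`, `n_runs`, `n_top_hits`, `frequency` and `flag`
#'   (`recurrent` when frequency > 0.5, `trait_specific` when < 0.05,
#'   otherwise `intermediate`), plus attribute `"scores"` holding the
#'   pooled per-run `p_network` values.
#' @export
null_frequency <- function(interactome, gene_table, runs,
                           mode = c("gwas", "networks"),
                           top_fraction = 0.02,
                           size_min = 20L, size_max = 200L,
                           alpha_gene = 0.05,
                           tol = 1e-10, max_iter = 1000L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (runs < 1L) stop("runs must be >= 1", call. = FALSE)
  nets <- filter_by_size(remove_subset_networks(build_all_networks(interactome)),
                         size_min, size_max)
  if (!length(nets)) stop("no sub-network survives the size filter", call. = FALSE)
  base_ids <- sort(vapply(nets, `[[`, "", "network_id"))
  hits <- integer(length(base_ids))
  names(hits) <- base_ids
  seeds <- child_seeds(seed, runs)
  pooled_p <- vector("list", runs)
  cutoff <- 100 * top_fraction

  if (mode == "gwas") {
    wts <- rank_networks(interactome, nets, tol = tol, max_iter = max_iter)
    ctx <- make_scoring_context(nets, wts, gene_table)
    for (r in seq_len(runs)) {
      p_perm <- with_seed(seeds[r], sample(gene_table$p))
      sc <- score_with_context(ctx, p_perm)
      top <- sc$network_id[sc$percentile <= cutoff]
      hits[top[top %in% base_ids]] <- hits[top[top %in% base_ids]] + 1L
      pooled_p[[r]] <- sc$p_network
    }
  } else {
    for (r in seq_len(runs)) {
      perm_it <- permute_node_labels(interactome, seeds[r])
      pnets <- filter_by_size(remove_subset_networks(build_all_networks(perm_it)),
                              size_min, size_max)
      if (!length(pnets)) next
      pwts <- rank_networks(perm_it, pnets, tol = tol, max_iter = max_iter)
      ctx <- make_scoring_context(pnets, pwts, gene_table)
      sc <- score_with_context(ctx, match_p(gene_table))
      top <- sc$network_id[sc$percentile <= cutoff]
      top <- top[top %in% base_ids]
      hits[top] <- hits[top] + 1L
      pooled_p[[r]] <- sc$p_network
    }
  }
  freq <- hits / runs
  flag <- ifelse(freq > 0.5, "recurrent",
                 ifelse(freq < 0.05, "trait_specific", "intermediate"))
  out <- data.frame(network_id = base_ids, n_runs = runs, n_top_hits = unname(hits),
                    frequency = unname(freq), flag = unname(flag),
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- unlist(pooled_p)
  class(out) <- c("null_frequency_table", "data.frame")
  out
}

# observed p-values in gene_table order (the context is built on the same
# table, so its indices line up)
match_p <- function(gene_table) gene_table$p

#' Write a null-frequency report
#'
#' @param table A `null_frequency_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_null_frequency <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}
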