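#' Fit a network-based prioritization of GWAS gene results
#'
#' Runs the full prioritization pipeline: builds the two-step sub-network
#' of every protein in the interactome, removes sub-networks whose node
#' sets are contained in other sub-networks, filters by size, weights each
#' sub-network's genes by modified PageRank with dynamic damping, and
#' combines weights with standardized gene association z-scores through
#' the Liptak-Stouffer method into a ranked table of trait-prioritized
#' sub-networks.
#'
#' @param interactome An `interactome` (see [clean_interactome()],
#'   [as_interactome()]).
#' @param gene_scores A [gene_score_table()] of gene-level association
#'   p-values.
#' @param size_min,size_max Inclusive sub-network size bounds (defaults
#'   20 and 200).
#' @param alpha_gene Gene-wise significance cutoff used to partition each
#'   network's member genes in the summary (default 0.05).
#' @param tol,max_iter Convergence controls for [pagerank_weights()].
#' @return An object of class `netprior`: list with elements
#'   `interactome`, `networks` (retained sub-networks), `weights`,
#'   `scores` (the ranked `network_scores` table), `gene_scores`,
#'   `counts` (pipeline accounting: sub-networks built, retained after
#'   subset removal, retained after size filtering, scored), `params`,
#'   and `call`.
#' @examples
#' spec <- synthetic_spec(n_genes = 300, seed = 7)
#' it <- generate_interactome(spec)
#' gt <- generate_gene_pvalues(spec, it)
#' fit <- netprior(it, gt, size_min = 5, size_max = 100)
#' summary(fit)
#' @export
netprior <- function(interactome, gene_scores,
                     size_min = 20L, size_max = 200L,
                     alpha_gene = 0.05, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(interactome, "interactome"),
            inherits(gene_scores, "gene_score_table"))
  built <- build_all_networks(interactome)
  nosub <- remove_subset_networks(built)
  nets <- filter_by_size(nosub, size_min, size_max)
  if (!length(nets)) {
    stop(sprintf("no sub-network has between %d and %d proteins", size_min, size_max),
         call. = FALSE)
  }
  wts <- rank_networks(interactome, nets, tol = tol, max_iter = max_iter)
  scores <- score_all_networks(nets, wts, gene_scores, alpha_gene = alpha_gene)
  structure(list(interactome = interactome,
                 networks = nets,
                 weights = wts,
                 scores = scores,
                 gene_scores = gene_scores,
                 counts = list(built = length(built),
                               after_subset_removal = length(nosub),
                               after_size_filter = length(nets),
                               scored = nrow(scores)),
                 params = list(size_min = size_min, size_max = size_max,
                               alpha_gene = alpha_gene, tol = tol,
                               max_iter = max_iter),
                 call = match.call()),
            class = "netprior")
}

#' @export
print.netprior <- function(x, ...) {
  cat("Network-based GWAS prioritization\n")
  cat(sprintf("  interactome: %d proteins, %d interactions\n",
              igraph::vcount(x$interactome$graph),
              igraph::ecount(x$interactome$graph)))
  cat(sprintf("  sub-networks: %d built -> %d after subset removal -> %d in size band [%d, %d] -> %d scored\n",
              x$counts$built, x$counts$after_subset_removal,
              x$counts$after_size_filter, x$params$size_min,
              x$params$size_max, x$counts$scored))
  cat(sprintf("  top network: %s (z_comb = %.3f, corrected p = %.3g)\n",
              x$scores$network_id[1L], x$scores$z_comb[1L],
              x$scores$p_corrected[1L]))
  invisible(x)
}

#' @export
summary.netprior <- function(object, n_top = 10L, ...) {
  structure(list(counts = object$counts, params = object$params,
                 n_genes = nrow(object$gene_scores),
                 top = utils::head(as.data.frame(object$scores)[
                   , c("network_id", "n_genes", "n_significant", "z_comb",
                       "p_network", "p_corrected", "rank", "percentile")],
                   n_top)),
            class = "summary.netprior")
}

#' @export
print.summary.netprior <- function(x, ...) {
  cat("Network-based GWAS prioritization\n")
  cat(sprintf("  pipeline: %d sub-networks built, %d after subset removal, %d after size filter, %d scored\n",
              x$counts$built, x$counts$after_subset_removal,
              x$counts$after_size_filter, x$counts$scored))
  cat(sprintf("  gene table: %d genes\n", x$n_genes))
  cat("\nTop-ranked sub-networks:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Combined z-scores of the fitted networks
#'
#' @param object A `netprior` fit.
#' @param ... Unused.
#' @return Named numeric vector of each scored network's combined z-score,
#'   in rank order.
#' @export
coef.netprior <- function(object, ...) {
  stats::setNames(object$scores$z_comb, object$scores$network_id)
}

#' Gene-level predictions from a fitted prioritization
#'
#' Returns the per-gene report (gene-wise vs network percentile ranks),
#' optionally restricted to selected genes.
#'
#' @param object A `netprior` fit.
#' @param genes Optional character vector of gene symbols.
#' @param ... Unused.
#' @return The [gene_report()] data.frame (subset to `genes` if given).
#' @export
predict.netprior <- function(object, genes = NULL, ...) {
  rep_ <- gene_report(object$scores, object$gene_scores)
  if (!is.null(genes)) rep_ <- rep_[rep_$gene %in% toupper(genes), , drop = FALSE]
  rep_
}

#' Simulate permuted-null network scores from a fit
#'
#' Draws GWAS-permutation replicates: the gene-to-p-value assignment is
#' shuffled and every retained sub-network re-scored, keeping networks and
#' weights fixed. Useful for judging how extreme the observed combined
#' z-scores are against the permutation null.
#'
#' @param object A `netprior` fit.
#' @param nsim Number of permutation replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return Data.frame of permuted-null combined z-scores, one row per
#'   scored network (`network_id` column) and one `sim_*` column per
#'   replicate.
#' @export
simulate.netprior <- function(object, nsim = 1L, seed = 1L, ...) {
  ctx <- make_scoring_context(object$networks, object$weights,
                              object$gene_scores)
  seeds <- child_seeds(seed, nsim)
  out <- data.frame(network_id = ctx$ids, stringsAsFactors = FALSE)
  for (s in seq_len(nsim)) {
    p_perm <- with_seed(seeds[s], sample(object$gene_scores$p))
    out[[paste0("sim_", s)]] <- score_with_context(ctx, p_perm)$z_comb
  }
  out
}

#' Plot gene-wise against network percentile ranks
#'
#' Scatterplot of each gene's own association percentile against the
#' percentile of its best containing sub-network. Points below the
#' diagonal are genes the network ranking promotes relative to their
#' single-gene signal.
#'
#' @param x A `netprior` fit.
#' @param highlight Optional character vector of gene symbols drawn in
#'   red.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.netprior <- function(x, highlight = NULL, ...) {
  rep_ <- gene_report(x$scores, x$gene_scores)
  graphics::plot(rep_$gene_percentile, rep_$network_percentile,
                 xlab = "gene-wise percentile rank",
                 ylab = "network percentile rank",
                 pch = 16, cex = 0.5, col = "grey40", ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(highlight)) {
    sel <- rep_$gene %in% toupper(highlight)
    graphics::points(rep_$gene_percentile[sel], rep_$network_percentile[sel],
                     pch = 16, col = "red")
  }
  invisible(rep_)
}
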