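#' Specification of a synthetic prioritization study
#'
#' Bundles the parameters of a synthetic interactome plus GWAS gene
#' p-value dataset with a planted trait module. The defaults emulate the
#' scale regime the method targets: a 2000-gene scale-free interactome
#' whose two-step sub-networks mostly fall inside the 20-200 size band,
#' with a 30-gene planted module. Background genes draw p ~ Uniform(0,1);
#' planted genes draw p ~ Beta(a, 1), which equals the null at `a = 1` and
#' concentrates near 0 as `a` decreases.
#'
#' @param n_genes Number of genes (nodes).
#' @param graph_model One of `"preferential_attachment"` (default;
#'   scale-free, connected by construction), `"erdos_renyi"`, or
#'   `"configuration"`.
#' @param model_params List of model parameters: `m` (edges per added
#'   node, preferential attachment, default 2), `p` (edge probability,
#'   Erdos-Renyi), `degrees` (degree sequence, configuration model).
#' @param planted_size Number of genes in the planted trait module.
#' @param effect_beta_a Beta shape parameter `a` in (0, 1] of the planted
#'   p-value distribution.
#' @param seed Master integer seed; every draw is reproducible from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           graph_model = c("preferential_attachment",
                                           "erdos_renyi", "configuration"),
                           model_params = list(),
                           planted_size = min(30L, n_genes),
                           effect_beta_a = 1,
                           seed = 1L) {
  graph_model <- match.arg(graph_model)
  if (effect_beta_a <= 0 || effect_beta_a > 1) {
    stop("effect_beta_a must lie in (0, 1]", call. = FALSE)
  }
  if (planted_size < 0L || planted_size > n_genes) {
    stop("planted_size must lie in [0, n_genes]", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), graph_model = graph_model,
                 model_params = model_params,
                 planted_size = as.integer(planted_size),
                 effect_beta_a = effect_beta_a, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic interactome
#'
#' Draws a random graph according to the spec's model and wraps it as an
#' `interactome` with gene symbols `G00001`, `G00002`, ... Preferential
#' attachment yields a connected scale-free-like graph; the configuration
#' model fails with an error on an infeasible degree sequence.
#'
#' @param spec A [synthetic_spec()].
#' @return An `interactome`.
#' @export
generate_interactome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gseed <- child_seeds(spec$seed, 1L)[1L]
  g <- with_seed(gseed, switch(
    spec$graph_model,
    preferential_attachment = igraph::sample_pa(
      spec$n_genes, power = spec$model_params$power %||% 1,
      m = spec$model_params$m %||% 2L, directed = FALSE),
    erdos_renyi = igraph::sample_gnp(
      spec$n_genes, spec$model_params$p %||% 0.01),
    configuration = {
      degs <- spec$model_params$degrees
      if (is.null(degs) || length(degs) != spec$n_genes) {
        stop("configuration model requires model_params$degrees of length n_genes",
             call. = FALSE)
      }
      if (sum(degs) %% 2L != 0L) {
        stop("infeasible degree sequence: odd degree sum", call. = FALSE)
      }
      tryCatch(igraph::sample_degseq(degs, method = "fast.heur.simple"),
               error = function(e) stop("infeasible degree sequence: ",
                                        conditionMessage(e), call. = FALSE))
    }))
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  igraph::V(g)$name <- sprintf("G%05d", seq_len(igraph::vcount(g)))
  new_interactome(g)
}

#' Select a planted trait module
#'
#' Picks a mid-degree center gene (degree between the 40th and 80th
#' degree percentiles when possible) and grows the module outward from
#' it: the center, then its radius-1 neighborhood, then radius-2 nodes,
#' highest-degree first within each shell, until `size` genes are
#' collected. Centering the module on a buildable neighborhood aligns it
#' with an actual two-step sub-network, so recovery is well defined.
#'
#' @param interactome An `interactome`.
#' @param size Module size in genes.
#' @param seed Integer seed for the center choice.
#' @return Character vector of module genes; the center is the first
#'   element and is stored in the `"center"` attribute.
#' @export
select_planted_module <- function(interactome, size, seed = 1L) {
  stopifnot(inherits(interactome, "interactome"))
  g <- interactome$graph
  deg <- igraph::degree(g)
  qs <- stats::quantile(deg, c(0.4, 0.8), names = FALSE)
  mid <- names(deg)[deg >= qs[1] & deg <= qs[2] & deg >= 1]
  if (!length(mid)) mid <- names(deg)[deg >= 1]
  if (!length(mid)) stop("interactome has no connected node", call. = FALSE)
  # prefer centers whose two-step neighborhood can hold the whole module,
  # so the module aligns with a buildable sub-network
  hood2 <- vapply(igraph::ego(g, order = 2L, nodes = mid), length, 1L)
  fits <- mid[hood2 >= size]
  if (length(fits)) mid <- fits
  center <- with_seed(seed, sample(mid, 1L))
  module <- center
  shell_nodes <- center
  radius <- 0L
  while (length(module) < size && radius < 10L) {
    radius <- radius + 1L
    shell <- setdiff(
      igraph::ego(g, order = radius, nodes = center)[[1L]]$name, module)
    if (!length(shell)) break
    shell <- shell[order(-deg[shell], shell)]
    need <- size - length(module)
    module <- c(module, shell[seq_len(min(need, length(shell)))])
  }
  structure(module, center = center)
}

#' Generate synthetic gene-level GWAS p-values
#'
#' Background genes draw p ~ Uniform(0, 1); genes in `module` draw
#' p ~ Beta(a, 1) with `a = spec$effect_beta_a` (the null when a = 1).
#'
#' @param spec A [synthetic_spec()].
#' @param interactome The interactome whose genes are scored.
#' @param module Character vector of planted genes (e.g. from
#'   [select_planted_module()]); `NULL` for a pure null dataset.
#' @param replicate Replicate index; each replicate redraws all p-values
#'   under a distinct child seed (same module, new "cohort").
#' @return A [gene_score_table()] covering every interactome gene.
#' @export
generate_gene_pvalues <- function(spec, interactome, module = NULL,
                                  replicate = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(interactome, "interactome"))
  genes <- interactome_nodes(interactome)
  if (!is.null(module) && !all(module %in% genes)) {
    stop("planted module contains genes absent from the interactome", call. = FALSE)
  }
  pseed <- child_seeds(spec$seed, 2L + replicate)[2L + replicate]
  p <- with_seed(pseed, {
    p <- stats::runif(length(genes))
    if (!is.null(module) && length(module)) {
      p[genes %in% module] <- stats::rbeta(sum(genes %in% module),
                                           spec$effect_beta_a, 1)
    }
    p
  })
  gene_score_table(genes, pmax(p, .Machine$double.xmin))
}

#' Planted-module recovery experiment
#'
#' Runs the full prioritization pipeline end to end on a synthetic system
#' and measures how reliably the planted trait module is recovered across
#' replicate "cohorts" (independent redraws of all gene p-values over the
#' same interactome and module). For each replicate it records the best
#' percentile among scored sub-networks seeded inside the planted module,
#' and for each planted gene its gene-wise percentile (by its own p-value)
#' versus its network percentile (of the best sub-network containing it).
#' The contrast between the across-replicate spread of the two percentile
#' types measures how much the network ranking stabilizes noisy
#' single-gene signals.
#'
#' @param spec A [synthetic_spec()] (typically with `effect_beta_a < 1`).
#' @param n_replicates Number of replicate cohorts.
#' @param size_min,size_max Sub-network size bounds.
#' @param tol,max_iter Passed to [pagerank_weights()].
#' @return A `recovery_report`: list with `replicates` (data.frame of
#'   per-replicate planted-network percentile), `gene_percentiles` and
#'   `network_percentiles` (replicate x planted-gene matrices), `module`,
#'   and `spec`.
#' @export
recovery_experiment <- function(spec, n_replicates = 20L,
                                size_min = 20L, size_max = 200L,
                                tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  interactome <- generate_interactome(spec)
  mseed <- child_seeds(spec$seed, 2L)[2L]
  module <- select_planted_module(interactome, spec$planted_size, mseed)
  nets <- filter_by_size(remove_subset_networks(build_all_networks(interactome)),
                         size_min, size_max)
  if (!length(nets)) stop("no sub-network survives the size filter", call. = FALSE)
  wts <- rank_networks(interactome, nets, tol = tol, max_iter = max_iter)
  seeds_in_module <- vapply(nets, function(sn) sn$seed %in% module, TRUE)
  if (!any(seeds_in_module)) {
    warning("no retained sub-network is seeded inside the planted module",
            call. = FALSE)
  }
  # replicate scoring only redraws p-values; membership/weights are fixed
  tab0 <- generate_gene_pvalues(spec, interactome, module, replicate = 1L)
  ctx <- make_scoring_context(nets, wts, tab0)
  members <- lapply(ctx$nets, function(nt) tab0$gene[nt$idx])
  n_genes_total <- nrow(tab0)

  planted_pct <- numeric(n_replicates)
  gene_pct <- matrix(NA_real_, n_replicates, length(module),
                     dimnames = list(NULL, module))
  net_pct <- matrix(NA_real_, n_replicates, length(module),
                    dimnames = list(NULL, module))
  in_module_net <- vapply(ctx$nets, function(nt) {
    sub("^net:", "", nt$network_id) %in% module
  }, TRUE)
  for (r in seq_len(n_replicates)) {
    tab <- generate_gene_pvalues(spec, interactome, module, replicate = r)
    sc <- score_with_context(ctx, tab$p)
    planted_pct[r] <- if (any(in_module_net)) min(sc$percentile[in_module_net]) else NA_real_
    grank <- rank(tab$p, ties.method = "first")
    names(grank) <- tab$gene
    gene_pct[r, ] <- 100 * grank[module] / n_genes_total
    best <- rep(NA_real_, length(module))
    for (j in seq_along(ctx$nets)) {
      inn <- module %in% members[[j]]
      if (any(inn)) best[inn] <- pmin(best[inn], sc$percentile[j], na.rm = TRUE)
    }
    net_pct[r, ] <- best
  }
  structure(list(replicates = data.frame(replicate = seq_len(n_replicates),
                                         planted_network_percentile = planted_pct),
                 gene_percentiles = gene_pct,
                 network_percentiles = net_pct,
                 module = module, spec = spec),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  pct <- x$replicates$planted_network_percentile
  cat(sprintf("Planted-module recovery over %d replicates (module size %d, Beta a = %g):\n",
              nrow(x$replicates), length(x$module), x$spec$effect_beta_a))
  cat(sprintf("  planted-network percentile: median %.2f, <= 2 in %d/%d replicates\n",
              stats::median(pct), sum(pct <= 2, na.rm = TRUE), length(pct)))
  vg <- mean(apply(x$gene_percentiles, 2L, stats::var), na.rm = TRUE)
  vn <- mean(apply(x$network_percentiles, 2L, stats::var), na.rm = TRUE)
  cat(sprintf("  across-replicate variance, planted genes: gene-wise %.1f vs network %.1f\n",
              vg, vn))
  invisible(x)
}

#' Write synthetic fixtures in the external TSV dialects
#'
#' Emits a simple two-column PPI edge list and a gene p-value TSV in the
#' same dialects the readers consume, so synthetic data can exercise the
#' parsers and the command-line pipeline.
#'
#' @param interactome An `interactome`.
#' @param gene_table A [gene_score_table()].
#' @param dir Output directory (created if missing).
#' @return Named character vector with the `ppi` and `gene_p` paths.
#' @export
write_synthetic_inputs <- function(interactome, gene_table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ppi <- file.path(dir, "interactome.tsv")
  e <- interactome_edges(interactome)
  writeLines(c("# synthetic interactome edge list",
               paste(e[, 1L], e[, 2L], sep = "\t")), ppi)
  gp <- file.path(dir, "gene_pvalues.tsv")
  write_tsv(data.frame(Gene = gene_table$gene, Pvalue = gene_table$p), gp)
  c(ppi = ppi, gene_p = gp)
}
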