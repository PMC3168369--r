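#' Standardize a gene p-value against the dataset
#'
#' Converts an association p-value to a z-score by centering on the mean
#' and scaling by the standard deviation of all p-values in the dataset:
#' \deqn{z = (\bar p - p) / s_p.} The orientation makes smaller (more
#' significant) p-values map to larger z, so an upper-tail conversion
#' applies downstream.
#'
#' @param p P-value(s) in (0, 1]; vectorized.
#' @param mean_p Mean of all p-values in the dataset.
#' @param sd_p Standard deviation (sample, n-1) of the p-values; must be
#'   positive.
#' @return Numeric z-score(s).
#' @examples
#' p_to_z(0.1, mean_p = 0.5, sd_p = 0.4)  # 1
#' @export
p_to_z <- function(p, mean_p, sd_p) {
  if (!is.finite(sd_p) || sd_p <= 0) {
    stop("sd_p must be positive (degenerate p-value dataset)", call. = FALSE)
  }
  (mean_p - p) / sd_p
}

#' Liptak-Stouffer combined z-score of a network
#'
#' Combines the member genes' z-scores into one network statistic,
#' weighting each gene by its modified-PageRank weight:
#' \deqn{Z_{comb} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}.}
#' In the classical Liptak-Stouffer method the weights are square-root
#' sample sizes; here they carry each gene's importance in the network.
#' Only genes present in both maps are combined. The statistic is
#' invariant to rescaling all weights by a positive constant, and with
#' equal weights reduces to the unweighted Stouffer statistic
#' \eqn{\sum z_i / \sqrt{n}}.
#'
#' @param weights Named numeric vector of gene weights.
#' @param zscores Named numeric vector of gene z-scores.
#' @return The combined z-score (scalar).
#' @examples
#' combine_liptak(c(A = 0.5, B = 0.5), c(A = 1.2, B = -0.4))
#' @export
combine_liptak <- function(weights, zscores) {
  shared <- intersect(names(weights), names(zscores))
  if (!length(shared)) {
    stop("no shared genes between weight and z-score maps; network cannot be scored",
         call. = FALSE)
  }
  w <- weights[shared]
  z <- zscores[shared]
  sum(w * z) / sqrt(sum(w^2))
}

#' Convert a combined z-score to a network p-value
#'
#' Upper-tail standard normal probability \eqn{P(Z > z)}.
#'
#' @param z_comb Combined z-score(s).
#' @return P-value(s).
#' @export
z_to_p <- function(z_comb) {
  stats::pnorm(z_comb, lower.tail = FALSE)
}

#' Bonferroni-correct a network p-value
#'
#' Corrects for the number of genes in the network and the total number of
#' networks tested: `min(1, p * n_genes * n_networks)`.
#'
#' @param p Uncorrected network p-value(s).
#' @param n_genes Number of genes in the network.
#' @param n_networks Total number of networks tested.
#' @return Corrected p-value(s), capped at 1.
#' @export
correct_network_p <- function(p, n_genes, n_networks) {
  if (any(n_genes < 1L) || any(n_networks < 1L)) {
    stop("n_genes and n_networks must be >= 1", call. = FALSE)
  }
  pmin(1, p * n_genes * n_networks)
}

#' Score and rank all sub-networks against a GWAS gene table
#'
#' For each sub-network, member genes found in the gene table are
#' standardized ([p_to_z()]) and combined with their modified-PageRank
#' weights ([combine_liptak()]); the combined z is converted to a network
#' p-value and Bonferroni-corrected for the network's scored gene count
#' and the total number of scored networks. Networks are ranked by
#' ascending corrected p-value (ties: descending z_comb, then network id)
#' and assigned percentiles `100 * rank / n_networks`. Member genes are
#' partitioned into significant and non-significant at `alpha_gene`.
#'
#' Genes present in a network but absent from the gene table are dropped
#' from that network's score (a message reports the total dropped count);
#' networks sharing no gene with the table are left unscored and recorded
#' in the `"unscored"` attribute of the result.
#'
#' @param networks List of `subnetwork` objects.
#' @param weights Named list of `weight_vector`s, one per network.
#' @param gene_table A [gene_score_table()].
#' @param alpha_gene Gene-wise significance cutoff for the summary
#'   partition (default 0.05).
#' @return A data.frame of class `network_scores`, ordered by rank, with
#'   columns `network_id`, `seed`, `n_genes`, `n_significant`,
#'   `n_nonsignificant`, `significant_genes`, `nonsignificant_genes`,
#'   `z_comb`, `p_network`, `p_corrected`, `rank`, `percentile`.
#' @export
score_all_networks <- function(networks, weights, gene_table, alpha_gene = 0.05) {
  stopifnot(inherits(gene_table, "gene_score_table"))
  mean_p <- attr(gene_table, "mean_p")
  sd_p <- attr(gene_table, "sd_p")
  z <- p_to_z(gene_table$p, mean_p, sd_p)
  names(z) <- gene_table$gene
  p_by_gene <- gene_table$p
  names(p_by_gene) <- gene_table$gene

  ids <- vapply(networks, `[[`, "", "network_id")
  rows <- vector("list", length(networks))
  unscored <- character()
  n_dropped <- 0L
  for (i in seq_along(networks)) {
    sn <- networks[[i]]
    wv <- weights[[sn$network_id]]
    if (is.null(wv)) stop(sprintf("no weights for network %s", sn$network_id), call. = FALSE)
    member <- names(wv$weights)
    scored <- member[member %in% names(z)]
    n_dropped <- n_dropped + (length(member) - length(scored))
    if (!length(scored)) {
      unscored <- c(unscored, sn$network_id)
      next
    }
    w <- wv$weights[scored]
    zc <- sum(w * z[scored]) / sqrt(sum(w^2))
    sig <- scored[p_by_gene[scored] < alpha_gene]
    nonsig <- setdiff(scored, sig)
    rows[[i]] <- data.frame(
      network_id = sn$network_id, seed = sn$seed,
      n_genes = length(scored),
      n_significant = length(sig), n_nonsignificant = length(nonsig),
      significant_genes = paste(sort(sig), collapse = ","),
      nonsignificant_genes = paste(sort(nonsig), collapse = ","),
      z_comb = zc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || !nrow(out)) {
    stop("no network shares any gene with the supplied gene table", call. = FALSE)
  }
  if (n_dropped > 0L) {
    message(sprintf("score_all_networks: dropped %d network-gene memberships absent from the gene table",
                    n_dropped))
  }
  n_networks <- nrow(out)
  out$p_network <- z_to_p(out$z_comb)
  out$p_corrected <- correct_network_p(out$p_network, out$n_genes, n_networks)
  ord <- order(out$p_corrected, -out$z_comb, out$network_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n_networks)
  out$percentile <- 100 * out$rank / n_networks
  rownames(out) <- NULL
  attr(out, "unscored") <- unscored
  attr(out, "n_networks") <- n_networks
  class(out) <- c("network_scores", "data.frame")
  out
}

#' Best network percentile of a gene
#'
#' The percentile of the best-ranked (lowest corrected p-value) scored
#' network containing the gene.
#'
#' @param gene Gene symbol.
#' @param table A `network_scores` table from [score_all_networks()].
#' @return Percentile in (0, 100], or `NA` (with a message) when the gene
#'   appears in no scored network.
#' @export
gene_network_percentile <- function(gene, table) {
  stopifnot(inherits(table, "network_scores"))
  gene <- toupper(as.character(gene))
  members <- network_members(table)
  hit <- vapply(members, function(m) gene %in% m, TRUE)
  if (!any(hit)) {
    message(sprintf("gene '%s' appears in no scored network; unranked", gene))
    return(NA_real_)
  }
  min(table$percentile[hit])
}

# split the comma-joined member columns back into per-network gene vectors
network_members <- function(table) {
  mapply(function(s, ns) {
    c(if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1L]] else character(),
      if (nzchar(ns)) strsplit(ns, ",", fixed = TRUE)[[1L]] else character())
  }, table$significant_genes, table$nonsignificant_genes,
  SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Per-gene report: gene-wise versus network percentile ranks
#'
#' For every gene in the gene table, reports its association p-value, its
#' gene-wise rank and percentile (ascending p, ties by gene symbol), and
#' the id and percentile of the best-ranked scored network containing it.
#' Genes in no scored network get `NA` network columns.
#'
#' @param table A `network_scores` table.
#' @param gene_table A [gene_score_table()].
#' @return Data.frame with columns `gene`, `gene_p`, `gene_rank`,
#'   `gene_percentile`, `best_network_id`, `network_percentile`.
#' @export
gene_report <- function(table, gene_table) {
  stopifnot(inherits(table, "network_scores"),
            inherits(gene_table, "gene_score_table"))
  n <- nrow(gene_table)
  ord <- order(gene_table$p, gene_table$gene)
  grank <- integer(n)
  grank[ord] <- seq_len(n)
  members <- network_members(table)
  best_id <- rep(NA_character_, n)
  best_pct <- rep(NA_real_, n)
  # table rows are rank-ordered, so the first containing network is best
  gene_first <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in rev(seq_along(members))) {
    for (g in members[[i]]) gene_first[[g]] <- i
  }
  for (k in seq_len(n)) {
    g <- gene_table$gene[k]
    i <- gene_first[[g]]
    if (!is.null(i)) {
      best_id[k] <- table$network_id[i]
      best_pct[k] <- table$percentile[i]
    }
  }
  data.frame(gene = gene_table$gene,
             gene_p = gene_table$p,
             gene_rank = grank,
             gene_percentile = 100 * grank / n,
             best_network_id = best_id,
             network_percentile = best_pct,
             stringsAsFactors = FALSE)
}

#' Positional SNP-to-gene assignment with a min-p gene score
#'
#' Assigns every SNP to each gene whose flanked interval
#' `[start - flank, end + flank]` (same chromosome) contains its position;
#' a SNP inside several flanked genes is assigned to all of them. The
#' gene-level p-value is the Sidak-corrected minimum over its m assigned
#' SNPs, \eqn{1 - (1 - p_{min})^m}. This is a simple positional fallback
#' for when no LD-aware gene-based association tool has been run; it
#' ignores linkage disequilibrium, so supplying gene-based results from
#' such a tool directly is preferred.
#'
#' @param snps An `snp_table` (see [read_snp_pvalues()]).
#' @param genes Gene coordinate data.frame with columns `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive; see [read_gene_coords()]).
#' @param flank Flanking distance in bases added to both gene ends
#'   (default 50000, capturing nearby regulatory regions).
#' @return A [gene_score_table()] over the genes with at least one
#'   assigned SNP; genes with none are omitted.
#' @export
snp_to_gene_p <- function(snps, genes, flank = 50000L) {
  stopifnot(is.data.frame(snps), is.data.frame(genes))
  out_gene <- character()
  out_p <- numeric()
  for (i in seq_len(nrow(genes))) {
    sel <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$start[i] - flank &
      snps$pos <= genes$end[i] + flank
    m <- sum(sel)
    if (m == 0L) next
    pmin_ <- min(snps$p[sel])
    out_gene <- c(out_gene, genes$gene[i])
    out_p <- c(out_p, 1 - (1 - pmin_)^m)
  }
  if (!length(out_gene)) stop("no SNP could be assigned to any gene", call. = FALSE)
  gene_score_table(out_gene, pmax(out_p, .Machine$double.xmin))
}

#' Write the network summary table
#'
#' One row per scored network with the summary-statistics fields:
#' significant/non-significant member genes and counts, total gene count,
#' network id, combined z-score, network p-value, corrected p-value, rank
#' and percentile.
#'
#' @param table A `network_scores` table.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_network_summary <- function(table, path) {
  cols <- c("network_id", "n_genes", "n_significant", "n_nonsignificant",
            "significant_genes", "nonsignificant_genes", "z_comb",
            "p_network", "p_corrected", "rank", "percentile")
  write_tsv(as.data.frame(table)[, cols], path)
}

# Lean re-scoring path used by the permutation procedures: membership and
# weights are frozen once, only the z vector changes per run.
make_scoring_context <- function(networks, weights, gene_table) {
  genes <- gene_table$gene
  ctx <- lapply(networks, function(sn) {
    wv <- weights[[sn$network_id]]
    idx <- match(names(wv$weights), genes)
    keep <- !is.na(idx)
    if (!any(keep)) return(NULL)
    w <- unname(wv$weights[keep])
    list(network_id = sn$network_id, idx = idx[keep], w = w,
         denom = sqrt(sum(w^2)), n_genes = sum(keep))
  })
  ctx <- ctx[!vapply(ctx, is.null, TRUE)]
  structure(list(nets = ctx,
                 ids = vapply(ctx, `[[`, "", "network_id"),
                 n_genes = vapply(ctx, `[[`, 1L, "n_genes"),
                 mean_p = attr(gene_table, "mean_p"),
                 sd_p = attr(gene_table, "sd_p")),
            class = "scoring_context")
}

# p: vector aligned with the gene_table used to build the context.
# Returns data.frame(network_id, z_comb, p_network, p_corrected, rank,
# percentile) using the same ranking rules as score_all_networks().
score_with_context <- function(ctx, p) {
  z <- (ctx$mean_p - p) / ctx$sd_p
  zc <- vapply(ctx$nets, function(nt) sum(nt$w * z[nt$idx]) / nt$denom, 1)
  n <- length(zc)
  p_net <- stats::pnorm(zc, lower.tail = FALSE)
  p_cor <- pmin(1, p_net * ctx$n_genes * n)
  ord <- order(p_cor, -zc, ctx$ids)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  data.frame(network_id = ctx$ids, z_comb = zc, p_network = p_net,
             p_corrected = p_cor, rank = rank,
             percentile = 100 * rank / n,
             stringsAsFactors = FALSE)
}
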