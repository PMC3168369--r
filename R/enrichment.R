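#' Hypergeometric candidate-gene overlap test
#'
#' Tests whether a drawn gene set (e.g. the genes inside the top-ranked
#' sub-networks) contains more known candidate genes than expected by
#' chance, given a finite gene universe. With a universe of `N` genes of
#' which `K` are candidates, and `n` genes drawn, the upper-tail p-value
#' for observing `k` candidates is \eqn{P(X \ge k)} under
#' X ~ Hypergeometric(N, K, n), computed exactly.
#'
#' `inclusive = FALSE` instead returns the strict tail \eqn{P(X > k)}.
#' Some enrichment tools report this convention (passing the observed
#' count straight to an exclusive upper-tail routine); it is offered for
#' comparability with results computed that way.
#'
#' @param universe_n Universe size N (e.g. all genes appearing in any
#'   scored sub-network).
#' @param candidates_k Number of candidate genes K in the universe.
#' @param drawn_n Number of genes drawn n.
#' @param observed_k Observed candidate count k in the draw.
#' @param inclusive If `TRUE` (default), p = P(X >= k); if `FALSE`,
#'   p = P(X > k).
#' @return An `overlap_result`: list with `universe_n`, `candidates_k`,
#'   `drawn_n`, `observed_k`, `p_upper`, `inclusive`.
#' @examples
#' hypergeom_overlap(6035, 34, 1232, 16)
#' @export
hypergeom_overlap <- function(universe_n, candidates_k, drawn_n, observed_k,
                              inclusive = TRUE) {
  N <- as.integer(universe_n); K <- as.integer(candidates_k)
  n <- as.integer(drawn_n); k <- as.integer(observed_k)
  if (anyNA(c(N, K, n, k)) || N < 1L || K < 0L || n < 0L || k < 0L) {
    stop("counts must be non-negative integers with universe_n >= 1", call. = FALSE)
  }
  if (K > N || n > N) {
    stop(sprintf("inconsistent counts: candidates_k (%d) and drawn_n (%d) must not exceed universe_n (%d)",
                 K, n, N), call. = FALSE)
  }
  if (k > min(K, n)) {
    stop(sprintf("inconsistent counts: observed_k (%d) exceeds min(candidates_k, drawn_n) = %d",
                 k, min(K, n)), call. = FALSE)
  }
  q <- if (inclusive) k - 1L else k
  p <- stats::phyper(q, K, N - K, n, lower.tail = FALSE)
  structure(list(universe_n = N, candidates_k = K, drawn_n = n,
                 observed_k = k, p_upper = p, inclusive = inclusive),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: %d of %d drawn genes are candidates (%d candidates in a %d-gene universe)\n",
              x$observed_k, x$drawn_n, x$candidates_k, x$universe_n))
  cat(sprintf("  P(X %s %d) = %.3g\n", if (x$inclusive) ">=" else ">",
              x$observed_k, x$p_upper))
  invisible(x)
}

#' Compare top sub-networks across datasets
#'
#' Given two or more network score tables computed on the same interactome
#' (so network ids are comparable), extracts each dataset's top fraction
#' of the ranking and reports the full inclusion-exclusion partition of
#' those top sets: which networks are shared by every dataset, by each
#' subset of datasets, and which are dataset-specific. Networks that stay
#' near the top of the ranking across independent cohorts are the most
#' trustworthy trait candidates.
#'
#' @param tables Named list (length >= 2) of `network_scores` tables.
#' @param top_fraction Fraction of each ranking taken as the top set
#'   (default 0.02).
#' @return A `ranking_overlap` object: list with `top_sets` (named list of
#'   id vectors) and `partition`, a data.frame with columns `label`
#'   (`"+"`-joined dataset names), `count`, `ids` (comma-joined).
#' @export
compare_rankings <- function(tables, top_fraction = 0.02) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("dataset", seq_along(tables))
  }
  lapply(tables, function(t) stopifnot(inherits(t, "network_scores")))
  idsets <- lapply(tables, function(t) t$network_id)
  if (!length(Reduce(intersect, idsets))) {
    stop("network id namespaces are disjoint; tables must come from the same interactome",
         call. = FALSE)
  }
  cutoff <- 100 * top_fraction
  top_sets <- lapply(tables, function(t) t$network_id[t$percentile <= cutoff])
  nm <- names(tables)
  all_top <- sort(unique(unlist(top_sets)))
  membership <- vapply(top_sets, function(s) all_top %in% s,
                       logical(length(all_top)))
  if (length(all_top) == 1L) membership <- matrix(membership, nrow = 1L)
  sig <- apply(membership, 1L, function(row) paste(nm[row], collapse = "+"))
  parts <- split(all_top, sig)
  partition <- data.frame(label = names(parts),
                          count = vapply(parts, length, 1L),
                          ids = vapply(parts, paste, "", collapse = ","),
                          stringsAsFactors = FALSE)
  rownames(partition) <- NULL
  structure(list(top_sets = top_sets, partition = partition),
            class = "ranking_overlap")
}

#' @export
print.ranking_overlap <- function(x, ...) {
  cat("Top-set overlap across datasets:\n")
  for (i in seq_len(nrow(x$partition))) {
    cat(sprintf("  %-30s %d\n", x$partition$label[i], x$partition$count[i]))
  }
  invisible(x)
}

#' Write the overlap partition report
#'
#' One line per region of the Venn partition: label, count, comma-joined
#' network ids.
#'
#' @param overlap A `ranking_overlap` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_ranking_overlap <- function(overlap, path) {
  write_tsv(overlap$partition, path)
}
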