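#' Read protein-protein interaction records
#'
#' Parses raw interaction records from either a minimal two-column
#' tab-separated symbol file or a BioGRID-style tab-delimited export with
#' named header columns. Records are returned untouched (no deduplication,
#' no self-loop removal); use [clean_interactome()] to reduce them to a
#' clean interactome.
#'
#' @param path Path to the interaction file.
#' @param dialect `"simple_tsv"` for two tab-separated gene-symbol columns
#'   (lines starting with `#` are comments), or `"biogrid_tab"` for a
#'   tab-delimited file whose header names official-symbol and organism
#'   columns for both interactors (BioGRID TAB dialect).
#' @return A data.frame with columns `protein_a`, `protein_b`,
#'   `organism_a`, `organism_b`, `method` (the latter three `NA` when the
#'   dialect does not carry them), one row per data row of the file.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC"), tf)
#' read_ppi_records(tf, "simple_tsv")
#' @export
read_ppi_records <- function(path, dialect = c("simple_tsv", "biogrid_tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (dialect == "simple_tsv") read_simple_tsv(path) else read_biogrid_tab(path)
}

read_simple_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(empty_records())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed interaction row at line %d of '%s': expected >= 2 tab-separated columns",
                 idx[bad[1L]], path), call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop(sprintf("empty gene symbol at line %d of '%s'",
                 idx[which(!nzchar(a) | !nzchar(b))[1L]], path), call. = FALSE)
  }
  data.frame(protein_a = a, protein_b = b,
             organism_a = NA_character_, organism_b = NA_character_,
             method = NA_character_, stringsAsFactors = FALSE)
}

read_biogrid_tab <- function(path) {
  nfields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (!length(nfields)) return(empty_records())
  if (length(unique(nfields)) > 1L) {
    bad <- which(nfields != nfields[1L])[1L]
    stop(sprintf("malformed row at line %d of '%s': %d columns where header has %d",
                 bad, path, nfields[bad], nfields[1L]), call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  nms <- names(tab)
  ia <- match_column(nms, c("official.?symbol.*a", "symbol.*a"), "official symbol A", path)
  ib <- match_column(nms, c("official.?symbol.*b", "symbol.*b"), "official symbol B", path)
  oa <- grep("organism.*a", nms, ignore.case = TRUE)
  ob <- grep("organism.*b", nms, ignore.case = TRUE)
  im <- grep("experimental.?system$|^method$", nms, ignore.case = TRUE)
  if (nrow(tab) == 0L) return(empty_records())
  a <- tab[[ia]]; b <- tab[[ib]]
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop(sprintf("empty gene symbol at line %d of '%s'",
                 which(!nzchar(a) | !nzchar(b))[1L] + 1L, path), call. = FALSE)
  }
  data.frame(protein_a = a, protein_b = b,
             organism_a = if (length(oa)) tab[[oa[1L]]] else NA_character_,
             organism_b = if (length(ob)) tab[[ob[1L]]] else NA_character_,
             method = if (length(im)) tab[[im[1L]]] else NA_character_,
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(protein_a = character(), protein_b = character(),
             organism_a = character(), organism_b = character(),
             method = character(), stringsAsFactors = FALSE)
}

#' Reduce interaction records to a clean interactome
#'
#' Applies the interactome-cleaning rules: optional within-taxon filtering
#' (records where either interactor's organism differs from `taxon` are
#' dropped), case normalization of gene symbols to upper case, removal of
#' self-interactions, and merging of duplicate pairs (the same unordered
#' pair reported by several experimental methods becomes one edge).
#'
#' @param records Data.frame of interaction records as returned by
#'   [read_ppi_records()].
#' @param taxon Optional taxon label (e.g. `"9606"` for human). When given
#'   and organism columns are present, only records with both interactors
#'   in that taxon are kept.
#' @return An `interactome` object: an undirected simple graph whose nodes
#'   are the union of edge endpoints.
#' @examples
#' recs <- data.frame(protein_a = c("a", "B", "A"), protein_b = c("B", "A", "A"))
#' clean_interactome(recs)
#' @export
clean_interactome <- function(records, taxon = NULL) {
  stopifnot(is.data.frame(records))
  a <- toupper(as.character(records$protein_a))
  b <- toupper(as.character(records$protein_b))
  keep <- rep(TRUE, length(a))
  if (!is.null(taxon) && length(a)) {
    oa <- as.character(records$organism_a %||% rep(NA_character_, length(a)))
    ob <- as.character(records$organism_b %||% rep(NA_character_, length(a)))
    keep <- !is.na(oa) & !is.na(ob) & oa == taxon & ob == taxon
  }
  a <- a[keep]; b <- b[keep]
  loop <- a == b
  a <- a[!loop]; b <- b[!loop]
  # store unordered: lexicographically smaller endpoint first, then dedupe
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  g <- igraph::graph_from_data_frame(data.frame(from = lo, to = hi),
                                     directed = FALSE)
  new_interactome(g)
}

new_interactome <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph), class = "interactome")
}

#' Coerce to an interactome
#'
#' @param x An igraph graph (undirected; will be simplified), a two-column
#'   data.frame/matrix edge list, or an `interactome`.
#' @return An `interactome` object.
#' @export
as_interactome <- function(x) {
  if (inherits(x, "interactome")) return(x)
  if (igraph::is_igraph(x)) {
    g <- igraph::as_undirected(x, mode = "collapse")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    return(new_interactome(g))
  }
  if (is.matrix(x) || is.data.frame(x)) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    recs <- data.frame(protein_a = as.character(df[[1L]]),
                       protein_b = as.character(df[[2L]]),
                       stringsAsFactors = FALSE)
    return(clean_interactome(recs))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to an interactome", call. = FALSE)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("Interactome: %d proteins, %d unique interactions\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Interactome accessors
#'
#' @param x An `interactome`.
#' @return `interactome_nodes()` returns the character vector of gene
#'   symbols; `interactome_edges()` a two-column character matrix of
#'   unordered edges (smaller symbol first).
#' @export
interactome_nodes <- function(x) {
  stopifnot(inherits(x, "interactome"))
  igraph::V(x$graph)$name
}

#' @rdname interactome_nodes
#' @export
interactome_edges <- function(x) {
  stopifnot(inherits(x, "interactome"))
  e <- igraph::as_edgelist(x$graph)
  if (nrow(e)) {
    m <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  } else {
    m <- matrix(character(), ncol = 2L)
  }
  colnames(m) <- c("a", "b")
  m
}

#' Construct a gene score table
#'
#' A gene score table holds one association p-value per gene together with
#' the dataset-level mean and standard deviation of all p-values, which are
#' the standardization constants for the p-to-z conversion. The standard
#' deviation is the sample (n-1) standard deviation.
#'
#' @param gene Character vector of gene symbols (upper-cased on ingest).
#' @param p Numeric vector of association p-values in (0, 1].
#' @return A data.frame of class `gene_score_table` with columns `gene`,
#'   `p` and attributes `mean_p`, `sd_p`.
#' @examples
#' gene_score_table(c("G1", "G2", "G3"), c(0.1, 0.5, 0.9))
#' @export
gene_score_table <- function(gene, p) {
  gene <- toupper(as.character(gene))
  p <- as.numeric(p)
  if (length(gene) != length(p)) stop("gene and p must have equal length", call. = FALSE)
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    bad <- which(is.na(p) | p <= 0 | p > 1)[1L]
    stop(sprintf("p-value out of (0, 1] for gene '%s': %s", gene[bad],
                 format(p[bad])), call. = FALSE)
  }
  if (anyDuplicated(gene)) {
    stop(sprintf("duplicate gene in p-value table: '%s'",
                 gene[anyDuplicated(gene)]), call. = FALSE)
  }
  out <- data.frame(gene = gene, p = p, stringsAsFactors = FALSE)
  attr(out, "mean_p") <- mean(p)
  attr(out, "sd_p") <- stats::sd(p)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat(sprintf("Gene score table: %d genes, mean p = %.4g, sd p = %.4g\n",
              nrow(x), attr(x, "mean_p"), attr(x, "sd_p")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read a gene-level p-value table
#'
#' Reads a tab-separated table of gene-level association results (as
#' produced by gene-based association tools) with a header naming a gene
#' column and a p-value column.
#'
#' @param path Path to the TSV file.
#' @return A [gene_score_table()].
#' @export
read_gene_pvalues <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- read_tsv(path)
  ig <- match_column(names(tab), c("^gene$", "gene"), "gene", path)
  ip <- match_column(names(tab), c("^p.?value$", "^p$", "^pval", "^p"), "p-value", path)
  gene_score_table(tab[[ig]], tab[[ip]])
}

#' Read a SNP-level association table
#'
#' Whitespace-delimited association output with header columns `SNP`,
#' `CHR`, `BP`, `P` (the common single-marker association dialect).
#'
#' @param path Path to the file.
#' @return A data.frame of class `snp_table` with columns `snp`, `chrom`,
#'   `pos`, `p`.
#' @export
read_snp_pvalues <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  is <- match_column(names(tab), c("^snp$", "snp"), "SNP", path)
  ic <- match_column(names(tab), c("^chr", "chrom"), "chromosome", path)
  ib <- match_column(names(tab), c("^bp$", "^pos", "position"), "position", path)
  ip <- match_column(names(tab), c("^p$", "^p.?value$", "^p"), "p-value", path)
  out <- data.frame(snp = as.character(tab[[is]]),
                    chrom = as.character(tab[[ic]]),
                    pos = as.integer(tab[[ib]]),
                    p = as.numeric(tab[[ip]]),
                    stringsAsFactors = FALSE)
  if (any(out$pos < 1L, na.rm = TRUE)) stop("SNP positions must be >= 1", call. = FALSE)
  if (any(is.na(out$p) | out$p <= 0 | out$p > 1)) {
    stop("SNP p-values must lie in (0, 1]", call. = FALSE)
  }
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Read a gene coordinate table
#'
#' Tab-separated table with header columns `gene`, `chrom`, `start`, `end`;
#' coordinates are 1-based and inclusive.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_coords <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  tab <- read_tsv(path)
  ig <- match_column(names(tab), c("^gene"), "gene", path)
  ic <- match_column(names(tab), c("^chr", "chrom"), "chromosome", path)
  is <- match_column(names(tab), c("^start$"), "start", path)
  ie <- match_column(names(tab), c("^end$", "^stop$"), "end", path)
  out <- data.frame(gene = toupper(as.character(tab[[ig]])),
                    chrom = as.character(tab[[ic]]),
                    start = as.integer(tab[[is]]),
                    end = as.integer(tab[[ie]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 1L | out$end < out$start)) {
    stop("gene coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  out
}
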