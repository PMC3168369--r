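test_that("simple TSV interaction files parse row-per-record", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tA"), tf)
  recs <- read_ppi_records(tf, "simple_tsv")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$protein_a, c("A", "B", "C"))
  expect_equal(recs$protein_b, c("B", "C", "A"))

  # comments and blank lines are skipped
  writeLines(c("# interactome", "", "A\tB"), tf)
  expect_equal(nrow(read_ppi_records(tf, "simple_tsv")), 1L)

  # empty file is a vacuous, valid input
  writeLines(character(), tf)
  expect_equal(nrow(read_ppi_records(tf, "simple_tsv")), 0L)

  # malformed rows are reported with their line number
  writeLines(c("A\tB", "LONELY"), tf)
  expect_error(read_ppi_records(tf, "simple_tsv"), "line 2")
})

test_that("BioGRID-style tab files retain organism and method columns", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    paste("Official Symbol Interactor A", "Official Symbol Interactor B",
          "Organism Interactor A", "Organism Interactor B",
          "Experimental System", sep = "\t"),
    "TP53\tMDM2\t9606\t9606\tTwo-hybrid",
    "TP53\tTrp53\t9606\t10090\tAffinity Capture-MS"), tf)
  recs <- read_ppi_records(tf, "biogrid_tab")
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$organism_a, c("9606", "9606"))
  expect_equal(recs$organism_b, c("9606", "10090"))
  expect_equal(recs$method[1L], "Two-hybrid")

  writeLines(c("Official Symbol Interactor A\tOfficial Symbol Interactor B",
               "TP53\tMDM2\tEXTRA"), tf)
  expect_error(read_ppi_records(tf, "biogrid_tab"), "line 2")
})

test_that("interactome cleaning deduplicates, drops self-loops and filters taxa", {
  recs <- data.frame(protein_a = c("A", "B", "A", "A", "A"),
                     protein_b = c("B", "A", "A", "C", "B"),
                     stringsAsFactors = FALSE)
  it <- clean_interactome(recs)
  expect_equal(sort(interactome_nodes(it)), c("A", "B", "C"))
  e <- interactome_edges(it)
  expect_equal(sort(paste(e[, 1L], e[, 2L])), c("A B", "A C"))

  # taxon filter drops any record with a non-matching organism
  recs2 <- data.frame(protein_a = c("A", "A"), protein_b = c("B", "C"),
                      organism_a = c("9606", "9606"),
                      organism_b = c("10090", "9606"),
                      stringsAsFactors = FALSE)
  it2 <- clean_interactome(recs2, taxon = "9606")
  expect_equal(sort(interactome_nodes(it2)), c("A", "C"))

  # mixed-case symbols collapse to one node
  it3 <- clean_interactome(data.frame(protein_a = c("abc", "ABC"),
                                      protein_b = c("XYZ", "xyz")))
  expect_equal(igraph::vcount(it3$graph), 2L)
  expect_equal(igraph::ecount(it3$graph), 1L)
})

test_that("cleaning matches a set-based oracle on noisy random records", {
  set.seed(42)
  for (rep in 1:5) {
    syms <- sprintf("G%02d", 1:25)
    a <- sample(syms, 80, replace = TRUE)
    b <- sample(syms, 80, replace = TRUE)
    dup <- sample(80, 20)                 # 20 duplicated records
    a <- c(a, a[dup]); b <- c(b, b[dup])
    loops <- sample(syms, 5)              # 5 self-loops
    a <- c(a, loops); b <- c(b, loops)
    it <- clean_interactome(data.frame(protein_a = a, protein_b = b))
    orc <- clean_oracle(a, b)
    expect_equal(sort(interactome_nodes(it)), orc$nodes)
    e <- interactome_edges(it)
    expect_equal(sort(paste(e[, 1L], e[, 2L], sep = "|")), orc$edges)
  }
})

test_that("cleaning is idempotent and edges are unordered", {
  set.seed(7)
  edges <- random_connected_edges(15)
  it <- as_interactome(edges)
  again <- clean_interactome(data.frame(protein_a = interactome_edges(it)[, 1L],
                                        protein_b = interactome_edges(it)[, 2L]))
  expect_equal(sort(interactome_nodes(again)), sort(interactome_nodes(it)))
  expect_equal(interactome_edges(again), interactome_edges(it))
  # symmetry of membership
  e1 <- interactome_edges(it)[1L, ]
  expect_true(igraph::are_adjacent(it$graph, e1[1L], e1[2L]))
  expect_true(igraph::are_adjacent(it$graph, e1[2L], e1[1L]))
  # node set equals union of edge endpoints
  expect_setequal(interactome_nodes(it), unique(as.vector(interactome_edges(it))))
})

test_that("gene p-value tables validate and carry dataset mean/sd", {
  gt <- gene_score_table(c("G1", "G2", "G3"), c(0.1, 0.5, 0.9))
  expect_equal(attr(gt, "mean_p"), 0.5)
  expect_equal(attr(gt, "sd_p"), 0.4)

  expect_error(gene_score_table("G1", 1.5), "out of \\(0, 1\\]")
  expect_error(gene_score_table("G1", 0), "out of \\(0, 1\\]")
  expect_error(gene_score_table(c("G1", "G1"), c(0.1, 0.2)), "duplicate gene")

  # mean/sd equal an independent recomputation on random data
  set.seed(11)
  p <- runif(1000)
  gt2 <- gene_score_table(sprintf("G%04d", 1:1000), p)
  expect_equal(attr(gt2, "mean_p"), sum(p) / 1000)
  expect_equal(attr(gt2, "sd_p"), sqrt(sum((p - mean(p))^2) / 999))
})

test_that("gene p-value and SNP readers parse their dialects", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tPvalue", "brca2\t0.01", "TP53\t0.5"), tf)
  gt <- read_gene_pvalues(tf)
  expect_equal(gt$gene, c("BRCA2", "TP53"))   # upper-cased on ingest
  expect_equal(gt$p, c(0.01, 0.5))

  writeLines(c("Gene\tPvalue", "A\t0.1", "A\t0.2"), tf)
  expect_error(read_gene_pvalues(tf), "duplicate gene")

  sf <- withr::local_tempfile(fileext = ".assoc")
  writeLines(c(" SNP  CHR  BP  P",
               " rs1  1  1000  0.001",
               " rs2  2  5000  0.5"), sf)
  st <- read_snp_pvalues(sf)
  expect_equal(st$snp, c("rs1", "rs2"))
  expect_equal(st$pos, c(1000L, 5000L))

  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstart\tend", "GENE1\t1\t500\t1500"), cf)
  gc <- read_gene_coords(cf)
  expect_equal(gc$start, 500L)
  writeLines(c("gene\tchrom\tstart\tend", "GENE1\t1\t1500\t500"), cf)
  expect_error(read_gene_coords(cf), "start <= end")
})
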