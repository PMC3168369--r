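test_that("p-to-z standardization is centered, scaled and antisymmetric", {
  expect_equal(p_to_z(0.5, 0.5, 0.4), 0)
  # dataset {0.1, 0.5, 0.9}: mean 0.5, sample sd 0.4
  gt <- gene_score_table(c("G1", "G2", "G3"), c(0.1, 0.5, 0.9))
  expect_equal(p_to_z(0.1, attr(gt, "mean_p"), attr(gt, "sd_p")), 1)
  # antisymmetry about the mean
  for (p in c(0.01, 0.2, 0.44)) {
    expect_equal(p_to_z(p, 0.5, 0.3) + p_to_z(2 * 0.5 - p, 0.5, 0.3), 0)
  }
  expect_error(p_to_z(0.1, 0.5, 0), "sd_p")
})

test_that("the Liptak-Stouffer combination matches hand arithmetic", {
  w <- c(A = 0.2, B = 0.2, C = 0.2)
  expect_equal(combine_liptak(w, c(A = 1, B = 1, C = 1)), sqrt(3))
  expect_equal(combine_liptak(w, c(A = 0, B = 0, C = 0)), 0)
  expect_equal(combine_liptak(c(A = 0.5, B = 0.5), c(A = 1.2, B = -0.4)),
               (0.6 - 0.2) / sqrt(0.5))
  expect_error(combine_liptak(c(A = 1), c(B = 1)), "no shared genes")
})

test_that("z_comb is weight-scale invariant and reduces to unweighted Stouffer", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    nm <- sprintf("G%02d", seq_len(n))
    w <- setNames(runif(n, 0.01, 1), nm)
    z <- setNames(rnorm(n), nm)
    zc <- combine_liptak(w, z)
    expect_equal(combine_liptak(w * runif(1, 0.1, 50), z), zc, tolerance = 1e-12)
    expect_equal(combine_liptak(setNames(rep(0.37, n), nm), z),
                 sum(z) / sqrt(n), tolerance = 1e-12)
  }
})

test_that("z-to-p conversion is the upper normal tail", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(z_to_p(qnorm(0.95)), 0.05)
  expect_equal(z_to_p(1.6449), 0.05, tolerance = 1e-4)
  for (z in c(-2.3, -0.5, 0.7, 3.1)) expect_equal(z_to_p(z) + z_to_p(-z), 1)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(correct_network_p(1e-6, 50, 100), 5e-3)
  expect_equal(correct_network_p(0.01, 50, 2849), 1)
  expect_equal(correct_network_p(0, 50, 2849), 0)
  expect_error(correct_network_p(0.1, 0, 10), ">= 1")
})

# small fixture: two disjoint 3-gene networks scored against a 7-gene table
scorer_fixture <- function() {
  it <- as_interactome(cbind(c("A", "B", "C", "X", "Y", "Z"),
                             c("B", "C", "A", "Y", "Z", "X")))
  nets <- list(make_subnetwork("A", c("A", "B", "C")),
               make_subnetwork("X", c("X", "Y", "Z")))
  wts <- rank_networks(it, nets)
  list(it = it, nets = nets, wts = wts)
}

test_that("a single all-null network scores p = 0.5 at rank 1", {
  fx <- scorer_fixture()
  # member p-values equal the dataset mean (0.4), so every member z is 0
  gt <- gene_score_table(c("A", "B", "C", "D", "E"),
                         c(0.4, 0.4, 0.4, 0.2, 0.6))
  sc <- suppressMessages(score_all_networks(fx$nets[1], fx$wts[1], gt))
  expect_equal(sc$z_comb, 0)
  expect_equal(sc$p_network, 0.5)
  expect_equal(sc$rank, 1L)
  expect_equal(sc$percentile, 100)
})

test_that("hub-concentrated signal outranks leaf-concentrated signal", {
  # two identical star networks; one carries its smallest p on the hub
  it <- as_interactome(rbind(cbind("H1", c("A1", "A2", "A3")),
                             cbind("H2", c("B1", "B2", "B3"))))
  nets <- list(make_subnetwork("H1", c("H1", "A1", "A2", "A3")),
               make_subnetwork("H2", c("H2", "B1", "B2", "B3")))
  wts <- rank_networks(it, nets)
  p <- c(H1 = 0.001, A1 = 0.5, A2 = 0.5, A3 = 0.5,   # signal on the hub
         H2 = 0.5, B1 = 0.001, B2 = 0.5, B3 = 0.5)   # same signal on a leaf
  gt <- gene_score_table(names(p), unname(p))
  sc <- score_all_networks(nets, wts, gt)
  expect_equal(sc$network_id[1L], "net:H1")
  expect_gt(sc$z_comb[sc$network_id == "net:H1"],
            sc$z_comb[sc$network_id == "net:H2"])
})

test_that("scoring partitions genes, ranks totally and reports percentiles", {
  set.seed(55)
  it <- as_interactome(random_connected_edges(40, extra = 40))
  nets <- filter_by_size(remove_subset_networks(build_all_networks(it)), 3L, 30L)
  wts <- rank_networks(it, nets)
  genes <- interactome_nodes(it)
  gt <- gene_score_table(genes, runif(length(genes)))
  sc <- score_all_networks(nets, wts, gt, alpha_gene = 0.05)
  n <- nrow(sc)
  expect_setequal(sc$rank, seq_len(n))
  expect_equal(sc$percentile, 100 * sc$rank / n)
  expect_true(all(diff(sc$percentile) > 0))
  expect_true(!is.unsorted(sc$p_corrected))
  expect_true(all(sc$p_corrected >= sc$p_network - 1e-15))
  expect_true(all(sc$p_corrected <= 1))
  expect_equal(sc$n_genes, sc$n_significant + sc$n_nonsignificant)
  # partition respects the alpha cutoff
  p_by_gene <- setNames(gt$p, gt$gene)
  for (i in seq_len(min(5, n))) {
    sig <- strsplit(sc$significant_genes[i], ",")[[1]]
    if (length(sig) && nzchar(sig[1])) expect_true(all(p_by_gene[sig] < 0.05))
    nonsig <- strsplit(sc$nonsignificant_genes[i], ",")[[1]]
    if (length(nonsig) && nzchar(nonsig[1])) expect_true(all(p_by_gene[nonsig] >= 0.05))
  }
})

test_that("genes missing from the table are dropped with a message", {
  fx <- scorer_fixture()
  gt <- gene_score_table(c("A", "B", "C", "X"), c(0.1, 0.2, 0.3, 0.4))
  expect_message(sc <- score_all_networks(fx$nets, fx$wts, gt),
                 "dropped 2")
  expect_equal(sc$n_genes[sc$network_id == "net:X"], 1L)
})

test_that("gene network percentile takes the best containing network", {
  set.seed(66)
  it <- as_interactome(random_connected_edges(30, extra = 25))
  nets <- filter_by_size(remove_subset_networks(build_all_networks(it)), 3L, 25L)
  wts <- rank_networks(it, nets)
  genes <- interactome_nodes(it)
  gt <- gene_score_table(genes, runif(length(genes)))
  sc <- score_all_networks(nets, wts, gt)
  members <- netprior:::network_members(sc)
  for (g in sample(genes, 15)) {
    hit <- vapply(members, function(m) g %in% m, TRUE)
    want <- if (any(hit)) min(sc$percentile[hit]) else NA_real_
    got <- suppressMessages(gene_network_percentile(g, sc))
    expect_equal(got, want)
  }
  # gene report agrees with the scan and with gene-wise ranking arithmetic
  rep_ <- gene_report(sc, gt)
  expect_equal(rep_$gene_percentile, 100 * rep_$gene_rank / nrow(gt))
  for (k in sample(nrow(rep_), 10)) {
    expect_equal(rep_$network_percentile[k],
                 suppressMessages(gene_network_percentile(rep_$gene[k], sc)))
  }
})

test_that("positional SNP assignment applies the flank and Sidak min-p", {
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("1", "2"),
                      start = c(100000L, 500000L), end = c(110000L, 510000L))
  # boundary: exactly at start - flank is assigned
  snps <- data.frame(snp = "rs1", chrom = "1", pos = 100000L - 50000L, p = 0.01)
  class(snps) <- c("snp_table", "data.frame")
  gt <- snp_to_gene_p(snps, genes)
  expect_equal(gt$gene, "G1")
  expect_equal(gt$p, 0.01)  # m = 1 keeps the SNP p

  # three SNPs in one gene: 1 - 0.99^3
  snps3 <- data.frame(snp = paste0("rs", 1:3), chrom = "1",
                      pos = c(105000L, 106000L, 107000L),
                      p = c(0.01, 0.5, 0.9))
  class(snps3) <- c("snp_table", "data.frame")
  gt3 <- snp_to_gene_p(snps3, genes)
  expect_equal(gt3$p, 1 - 0.99^3)
  expect_equal(gt3$p, 0.029701)

  # one past the flank is not assigned; G2 has no SNPs and is omitted
  snps_out <- data.frame(snp = "rs9", chrom = "1", pos = 49999L, p = 0.01)
  class(snps_out) <- c("snp_table", "data.frame")
  expect_error(snp_to_gene_p(snps_out, genes), "no SNP")

  # a SNP in two overlapping flanked genes is assigned to both
  genes2 <- data.frame(gene = c("GA", "GB"), chrom = "1",
                       start = c(1000L, 40000L), end = c(2000L, 41000L))
  snp_both <- data.frame(snp = "rs5", chrom = "1", pos = 10000L, p = 0.2)
  class(snp_both) <- c("snp_table", "data.frame")
  gtb <- snp_to_gene_p(snp_both, genes2)
  expect_setequal(gtb$gene, c("GA", "GB"))
})

test_that("the lean re-scoring path equals the full scorer", {
  set.seed(99)
  it <- as_interactome(random_connected_edges(35, extra = 30))
  nets <- filter_by_size(remove_subset_networks(build_all_networks(it)), 3L, 30L)
  wts <- rank_networks(it, nets)
  genes <- interactome_nodes(it)
  gt <- gene_score_table(genes, runif(length(genes)))
  full <- score_all_networks(nets, wts, gt)
  ctx <- netprior:::make_scoring_context(nets, wts, gt)
  fast <- netprior:::score_with_context(ctx, gt$p)
  m <- match(full$network_id, fast$network_id)
  expect_equal(fast$z_comb[m], full$z_comb, tolerance = 1e-12)
  expect_equal(fast$p_corrected[m], full$p_corrected, tolerance = 1e-12)
  expect_equal(fast$rank[m], full$rank)
  expect_equal(fast$percentile[m], full$percentile)
})
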