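# Cis/trans target prediction and network export.

test_that("cis window arithmetic and boundaries", {
  lnc <- data.frame(id = "L1", chrom = "c1", start = 60000, end = 61000)
  gene_up <- data.frame(id = "G1", chrom = "c1", start = 5000, end = 10000)
  res <- cis_targets(lnc, gene_up)
  expect_equal(res$distance, -50000)   # gene upstream, gap 50 kb
  # boundary: gap exactly max_dist emitted, one past not
  g100k <- data.frame(id = "G2", chrom = "c1", start = 161000, end = 162000)
  expect_equal(nrow(cis_targets(lnc, g100k)), 1)
  g100k1 <- data.frame(id = "G3", chrom = "c1", start = 161001, end = 162000)
  expect_equal(nrow(cis_targets(lnc, g100k1)), 0)
  # gap below min_dist excluded; min_dist = 0 reproduces "within max_dist"
  gnear <- data.frame(id = "G4", chrom = "c1", start = 61500, end = 62000)
  expect_equal(nrow(cis_targets(lnc, gnear)), 0)
  expect_equal(nrow(cis_targets(lnc, gnear, min_dist = 0)), 1)
  # different chromosome never pairs
  gchr <- data.frame(id = "G5", chrom = "c2", start = 80000, end = 81000)
  expect_equal(nrow(cis_targets(lnc, gchr)), 0)
})

test_that("cis_targets equals the all-pairs brute-force scan", {
  set.seed(17)
  for (rep in 1:40) {
    nl <- sample(1:6, 1); ng <- sample(1:15, 1)
    lnc <- data.frame(id = paste0("L", 1:nl),
                      chrom = sample(c("c1", "c2"), nl, TRUE),
                      start = sample(0:9e5, nl))
    lnc$end <- lnc$start + sample(500:5000, nl, TRUE)
    genes <- data.frame(id = paste0("G", 1:ng),
                        chrom = sample(c("c1", "c2"), ng, TRUE),
                        start = sample(0:9e5, ng))
    genes$end <- genes$start + sample(500:5000, ng, TRUE)
    got <- cis_targets(lnc, genes)
    want <- oracle_cis(lnc, genes, 10000, 100000)
    key <- function(d) sort(paste(d$lnc_id, d$gene_id, d$distance))
    expect_equal(key(got), key(want))
  }
})

test_that("cis membership is preserved under coordinate mirroring", {
  set.seed(18)
  L <- 1e6
  lnc <- data.frame(id = paste0("L", 1:4), chrom = "c1",
                    start = sample(0:9e5, 4))
  lnc$end <- lnc$start + 1000
  genes <- data.frame(id = paste0("G", 1:20), chrom = "c1",
                      start = sample(0:9e5, 20))
  genes$end <- genes$start + 2000
  fwd <- cis_targets(lnc, genes)
  mirror <- function(d) transform(d, start = L - end, end = L - start)
  rev <- cis_targets(mirror(lnc), mirror(genes))
  key <- function(d) sort(paste(d$lnc_id, d$gene_id))
  expect_equal(key(fwd), key(rev))
  m <- merge(fwd, rev, by = c("lnc_id", "gene_id"))
  expect_equal(m$distance.x, -m$distance.y)
})

test_that("pearson_cor matches the textbook formula", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  set.seed(19)
  for (rep in 1:30) {
    a <- rnorm(9); b <- 0.8 * a + rnorm(9)
    got <- pearson_cor(a, b)
    # independent recomputation from raw sums
    n <- 9
    r <- (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    t <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(got$p, 2 * pt(-abs(t), n - 2), tolerance = 1e-12)
    # cross-check p against the standard test
    expect_equal(got$p, cor.test(a, b)$p.value, tolerance = 1e-12)
  }
  expect_warning(res <- pearson_cor(rep(1, 5), rnorm(5)), "variance")
  expect_true(is.na(res$r))
})

test_that("trans_targets recovers planted pairs and rejects nulls", {
  lncs <- sprintf("lnc%03d", 1:30)
  genes <- sprintf("g%04d", 1:800)
  cfg <- synthetic_config(seed = 23, n_trans_pairs = 20, target_r = 0.99,
                          de_fraction = 0)
  g <- gen_counts(cfg, c(lncs, genes), lnc_ids = lncs)
  ex <- fpkm(g$counts, g$lengths)
  tt <- trans_targets(ex, lncs, genes)
  tp <- g$truth$trans_pairs
  key <- function(d) paste(d$lnc_id, d$gene_id)
  expect_gte(mean(key(tp) %in% key(tt)), 0.9)
  # sample-permutation invariance
  perm <- sample(ncol(ex))
  tt_perm <- trans_targets(ex[, perm], lncs, genes)
  expect_equal(key(tt), key(tt_perm))
  # a duplicated gene row yields identical edges
  ex2 <- rbind(ex, dup_gene = ex[tp$gene_id[1], ])
  tt2 <- trans_targets(ex2, tp$lnc_id[1], c(tp$gene_id[1], "dup_gene"))
  expect_equal(sum(tt2$gene_id == "dup_gene"),
               sum(tt2$gene_id == tp$gene_id[1]))
  # r_min = 1 on noisy data is empty
  expect_equal(nrow(trans_targets(ex, lncs, genes, r_min = 1)), 0)
  expect_error(trans_targets(ex[, 1:2], lncs, genes), "3 samples")
})

test_that("network construction, degrees and exports are consistent", {
  pairs <- data.frame(lnc_id = c("L1", "L1", "L2"),
                      gene_id = c("G1", "G2", "G1"),
                      mode = "trans", r = c(0.99, 0.97, 0.96),
                      p = c(1e-5, 1e-4, 1e-4), stringsAsFactors = FALSE)
  net <- build_network(pairs)
  deg <- igraph::degree(net)
  expect_equal(unname(deg["L1"]), 2)
  expect_equal(unname(deg["G1"]), 2)
  expect_equal(igraph::ecount(net), sum(deg) / 2)
  expect_equal(igraph::vcount(net), 4)
  # single pair -> 2 nodes 1 edge
  net1 <- build_network(pairs[1, ])
  expect_equal(c(igraph::vcount(net1), igraph::ecount(net1)), c(2, 1))
  # SIF round trip reproduces the edge set
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  back <- read_sif(sif)
  expect_setequal(paste(back$lnc_id, back$gene_id),
                  paste(pairs$lnc_id, pairs$gene_id))
  # GraphML export parses as XML with typed nodes
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
  expect_error(export_network(net, sif, "dot"), "supported")
  # bipartiteness guarded
  bad <- data.frame(lnc_id = "A", gene_id = "A", mode = "trans",
                    r = 1, p = 0)
  expect_error(build_network(bad), "both")
  hubs <- hub_report(net, 2)
  expect_equal(hubs$degree, c(2, 2))
})
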