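# Generators: determinism, planted geometry, count-model contracts.

test_that("generation is deterministic given (config, seed)", {
  cfg <- tiny_config(seed = 6)
  a1 <- gen_annotation(cfg)
  a2 <- gen_annotation(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gtf(a1$reference, p1); write_gtf(a2$reference, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a1$genome, a2$genome)
  expect_identical(gen_assembly(cfg, a1)$sequences,
                   gen_assembly(cfg, a2)$sequences)
  r1 <- gen_reads(cfg); r2 <- gen_reads(cfg)
  expect_identical(r1, r2)
  g1 <- gen_counts(cfg, paste0("g", 1:50))
  g2 <- gen_counts(cfg, paste0("g", 1:50))
  expect_identical(g1$counts, g2$counts)
  # a different seed changes the output
  expect_false(identical(a1$genome,
                         gen_annotation(tiny_config(seed = 7))$genome))
})

test_that("empty feature classes are honoured", {
  cfg <- tiny_config(seed = 2, n_coding_genes = 0, n_decoys_biotype = 0)
  ann <- gen_annotation(cfg)
  expect_equal(sum(ann$reference$tx$biotype == "protein_coding"),
               length(cfg$cis_offsets))  # only the planted cis neighbors
  cfg2 <- tiny_config(seed = 2, n_coding_genes = 0, n_decoys_biotype = 0,
                      cis_offsets = numeric(0))
  ann2 <- gen_annotation(cfg2)
  expect_equal(sum(ann2$reference$tx$biotype == "protein_coding"), 0)
})

test_that("a too-short chromosome raises a sizing error naming the feature", {
  cfg <- tiny_config(seed = 2, chrom_len = 5000)
  expect_error(gen_annotation(cfg), "too short.*t_")
})

test_that("planted cis neighbors sit at the configured offsets", {
  cfg <- tiny_config(seed = 8, cis_offsets = c(15000, 50000))
  ann <- gen_annotation(cfg)
  feats <- ann$truth$layout$features
  for (i in seq_len(nrow(ann$truth$cis_pairs))) {
    pr <- ann$truth$cis_pairs[i, ]
    lnc <- feats[feats$id == pr$lnc_id, ]
    gene <- feats[feats$id == pr$gene_id, ]
    # independent arithmetic on the emitted coordinates
    expect_equal(gene$start - lnc$end, pr$offset)
  }
  # and the window finder recovers them from the written GTF
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$reference, gtf)
  ref_back <- read_gtf(gtf)
  asm <- gen_assembly(cfg, ann)
  lnc_loci <- data.frame(id = asm$tx$transcript_id, chrom = asm$tx$chrom,
                         start = asm$tx$span_start, end = asm$tx$span_end)
  gene_tx <- ref_back$tx[ref_back$tx$biotype == "protein_coding", ]
  gene_loci <- data.frame(id = gene_tx$transcript_id, chrom = gene_tx$chrom,
                          start = gene_tx$span_start, end = gene_tx$span_end)
  found <- cis_targets(lnc_loci, gene_loci)
  key <- paste(found$lnc_id, found$gene_id)
  expect_true(all(paste(ann$truth$cis_pairs$lnc_id,
                        ann$truth$cis_pairs$gene_id) %in% key))
})

test_that("planted novel transcripts are intergenic by independent scan", {
  cfg <- tiny_config(seed = 3)
  ann <- gen_annotation(cfg)
  asm <- gen_assembly(cfg, ann)
  rex <- ann$reference$exons
  for (id in ann$truth$novel_ids) {
    qex <- asm$exons[asm$exons$transcript_id == id, ]
    hit <- FALSE
    for (i in seq_len(nrow(qex))) for (j in seq_len(nrow(rex)))
      if (qex$chrom[i] == rex$chrom[j] &&
          qex$start[i] < rex$end[j] && rex$start[j] < qex$end[i])
        hit <- TRUE
    expect_false(hit, label = sprintf("novel %s overlaps a reference exon", id))
  }
})

test_that("decoy classes satisfy their defining property by brute force", {
  cfg <- tiny_config(seed = 5)
  ann <- gen_annotation(cfg)
  asm <- gen_assembly(cfg, ann)
  by_reason <- ann$truth$rejected_ids_by_reason
  # short decoys < 200 nt
  lens <- setNames(asm$tx$spliced_len, asm$tx$transcript_id)
  expect_true(all(lens[by_reason$too_short] < 200))
  # coding decoys: longest ORF > 300 by the independent 6-frame scan
  for (id in by_reason$long_orf)
    expect_gt(oracle_orf(asm$sequences[[id]])$length_nt, 300)
  # novel lncRNAs: >= 200 nt and ORF <= 300 by the same scan
  expect_true(all(lens[ann$truth$novel_ids] >= 200))
  for (id in ann$truth$novel_ids[1:5]) {
    o <- oracle_orf(asm$sequences[[id]])
    expect_true(is.null(o) || o$length_nt <= 300)
  }
  # score decoys: ORF exactly 300 nt
  for (id in by_reason$coding_score)
    expect_equal(oracle_orf(asm$sequences[[id]])$length_nt, 300)
  # truth ids are a subset of emitted ids and classes are disjoint
  all_truth <- c(ann$truth$novel_ids, ann$truth$known_ids,
                 unlist(by_reason))
  expect_true(all(all_truth %in% asm$tx$transcript_id))
  expect_equal(anyDuplicated(all_truth), 0)
})

test_that("count generator honours null and planted-effect contracts", {
  ids <- paste0("g", 1:120)
  # de_fraction = 0: configured group means equal for every gene
  cfg0 <- tiny_config(seed = 10, de_fraction = 0, n_trans_pairs = 0)
  g0 <- gen_counts(cfg0, ids)
  expect_true(all(g0$mu[, 1] == g0$mu))
  expect_equal(nrow(g0$truth$de_ids_by_comparison[[1]]), 0)
  # planted DE: configured means differ by exactly 2^de_log2fc
  cfg1 <- tiny_config(seed = 10, de_fraction = 0.2, de_log2fc = 1.5,
                      n_trans_pairs = 0)
  g1 <- gen_counts(cfg1, ids)
  ele <- g1$truth$elevated_group
  de <- names(ele)[!is.na(ele)]
  expect_gt(length(de), 0)
  for (id in de) {
    hi <- g1$mu[id, g1$groups == ele[id]][1]
    lo <- g1$mu[id, g1$groups != ele[id]][1]
    expect_equal(unname(hi / lo), 2^1.5, tolerance = 1e-12)
  }
  # planted trans pairs reach the target correlation at n = 9
  cfg2 <- tiny_config(seed = 10, n_trans_pairs = 10, target_r = 0.99,
                      de_fraction = 0)
  lncs <- paste0("lnc", 1:10)
  g2 <- gen_counts(cfg2, c(lncs, ids), lnc_ids = lncs)
  le <- log2(fpkm(g2$counts, g2$lengths) + 1)
  rr <- mapply(function(a, b) cor(le[a, ], le[b, ]),
               g2$truth$trans_pairs$lnc_id, g2$truth$trans_pairs$gene_id)
  expect_gte(median(rr), 0.95)
  expect_true(all(rr < 1))   # latent noise keeps realized r below 1
  expect_error(gen_counts(cfg2, ids, base_mean = -1), "base_mean")
})

test_that("read generator respects the labelled QC boundaries", {
  cfg <- tiny_config(seed = 13)
  gr <- gen_reads(cfg)
  len <- cfg$read_len
  n_count <- nchar(gsub("[^N]", "", gr$reads$seq))
  lowq <- vapply(gr$reads$qual, function(q) sum(utf8ToInt(q) - 33 <= 5),
                 numeric(1), USE.NAMES = FALSE)
  has_ad <- grepl(cfg$adaptor, gr$reads$seq, fixed = TRUE)
  expect_true(all(has_ad[gr$labels == "adaptor"]))
  expect_true(all(n_count[gr$labels == "N-fraction"] / len > 0.10))
  expect_true(all(lowq[gr$labels == "low-quality"] / len > 0.50))
  pass <- gr$labels == "pass"
  expect_true(all(!has_ad[pass]))
  expect_true(all(n_count[pass] / len <= 0.10))
  expect_true(all(lowq[pass] / len <= 0.50))
  # some pass reads sit exactly at the N boundary
  expect_gt(sum(pass & n_count == floor(0.10 * len)), 0)
})
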