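# Transcript models, GTF round-trips, classification, assembly stats.

test_that("GTF coordinates convert to 0-based half-open and back", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\ttranscript_id "t2"; gene_id "g2";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\ttranscript_id "t2"; gene_id "g2";'),
    path)
  ts <- read_gtf(path)
  e1 <- ts$exons[ts$exons$transcript_id == "t1", ]
  expect_equal(c(e1$start, e1$end), c(100, 200))
  # spliced length of the two-exon transcript, summed by hand: 100 + 100
  expect_equal(ts$tx$spliced_len[ts$tx$transcript_id == "t2"], 200)

  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ts, out)
  back <- read_gtf(out)
  expect_equal(back$exons, ts$exons)
  expect_equal(back$tx, ts$tx)
})

test_that("GTF parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t50\t60\t.\t+\t.\tgene_id "g2";'), path)
  expect_error(read_gtf(path), "line 2.*transcript_id")
  writeLines('chr1\tsrc\texon\t200\t100\t.\t+\t.\ttranscript_id "t1";', path)
  expect_error(read_gtf(path), "line 1")
})

test_that("non-exon feature rows are ignored with a logged count", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1\t500\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";'),
    path)
  expect_message(ts <- read_gtf(path), "ignored 1")
  expect_equal(n_transcripts(ts), 1)
})

test_that("transcript_set validates exon structure", {
  expect_error(transcript_set(exdf("chr1", 100, 100, "+", "t1")),
               "start < end")
  expect_error(transcript_set(exdf("chr1", c(0, 50), c(100, 150), "+",
                                   c("t1", "t1"))), "overlapping")
  expect_error(transcript_set(exdf(c("chr1", "chr2"), c(0, 200), c(100, 300),
                                   "+", c("t1", "t1"))), "mixes")
  ts <- transcript_set(exdf("chr1", c(200, 0), c(300, 100), "+", c("t1", "t1")))
  expect_equal(ts$exons$start, c(0, 200))  # sorted
})

test_that("splice_sequences respects strand", {
  genome <- c(chr1 = "AAAACCCCGGGGTTTT")
  ts <- transcript_set(exdf("chr1", c(0, 8), c(4, 12), "+", c("tp", "tp")))
  expect_equal(unname(splice_sequences(ts, genome)$sequences["tp"]),
               "AAAAGGGG")
  tm <- transcript_set(exdf("chr1", c(0, 8), c(4, 12), "-", c("tm", "tm")))
  # minus strand: reverse complement of AAAA|GGGG read 3'->5' = CCCCTTTT
  expect_equal(unname(splice_sequences(tm, genome)$sequences["tm"]),
               "CCCCTTTT")
})

test_that("hand-built classification cases get the expected codes", {
  ref <- transcript_set(rbind(
    exdf("chr1", c(1000, 2000, 3000), c(1500, 2500, 3500), "+",
         rep("r1", 3)),
    exdf("chr1", 9000, 9400, "-", "r2")))
  q <- transcript_set(rbind(
    exdf("chr1", c(1000, 2000, 3000), c(1500, 2500, 3500), "+", rep("q_eq", 3)),
    exdf("chr1", 1600, 1900, "+", "q_i"),       # inside intron 1, same strand
    exdf("chr1", 1600, 1900, "-", "q_u_intron"),# opposite-strand intron
    exdf("chr1", 1400, 1700, "+", "q_o"),       # partial same-strand overlap
    exdf("chr1", 9100, 9300, "+", "q_x"),       # overlap on '-' ref only
    exdf("chr1", 20000, 20500, "+", "q_u"),     # far from everything
    exdf("chr2", 100, 400, "+", "q_u_chr")))    # unknown chromosome
  res <- suppressWarnings(classify_transcripts(q, ref))
  codes <- setNames(res$class_code, res$transcript_id)
  expect_equal(unname(codes[c("q_eq", "q_i", "q_u_intron", "q_o", "q_x",
                              "q_u", "q_u_chr")]),
               c("=", "i", "u", "o", "x", "u", "u"))
  expect_true(is.na(res$ref_id[res$transcript_id == "q_u"]))
  expect_equal(res$ref_id[res$transcript_id == "q_eq"], "r1")
  expect_warning(classify_transcripts(q, ref), "chr2")
})

test_that("classification matches the brute-force oracle on random instances", {
  set.seed(42)
  n_match <- 0
  for (rep in 1:300) {
    # small random reference: 1-4 transcripts on a 10 kb chromosome
    ref_ex <- list()
    for (t in seq_len(sample(1:4, 1))) {
      k <- sample(1:3, 1)
      starts <- sort(sample(seq(0, 9000, by = 50), k))
      lens <- sample(seq(50, 400, by = 50), k, replace = TRUE)
      ends <- pmin(starts + lens, c(starts[-1], 10000))
      keep <- ends > starts
      if (!any(keep)) next
      ref_ex[[length(ref_ex) + 1]] <- exdf("chr1", starts[keep], ends[keep],
                                           sample(c("+", "-"), 1),
                                           sprintf("r%d", t))
    }
    ref_ex <- do.call(rbind, ref_ex)
    ref <- tryCatch(transcript_set(ref_ex), error = function(e) NULL)
    if (is.null(ref)) next
    # random query
    k <- sample(1:2, 1)
    starts <- sort(sample(seq(0, 9500, by = 25), k))
    lens <- sample(seq(25, 600, by = 25), k, replace = TRUE)
    ends <- pmin(starts + lens, c(starts[-1], 10000))
    keep <- ends > starts
    if (!any(keep)) next
    qex <- exdf("chr1", starts[keep], ends[keep], sample(c("+", "-"), 1), "q1")
    q <- tryCatch(transcript_set(qex), error = function(e) NULL)
    if (is.null(q)) next
    got <- classify_transcripts(q, ref)$class_code
    want <- oracle_classify(q$exons, ref$exons, ref$tx)
    expect_equal(got, want,
                 info = sprintf("rep %d: query %s vs ref %s", rep,
                                paste(qex$start, qex$end, collapse = ";"),
                                paste(ref_ex$start, ref_ex$end, collapse = ";")))
    n_match <- n_match + 1
  }
  expect_gt(n_match, 250)
})

test_that("N50 follows the descending-accumulation definition", {
  # lengths 5,4,3,2,1: total 15, cumulative 5, 9 >= 7.5 at the second
  s <- transcript_stats(vapply(c(5, 4, 3, 2, 1), rseq, character(1)))
  expect_equal(s$N50, 4)
  one <- transcript_stats(rseq(200))
  expect_equal(one$N50, 200)
  expect_equal(one$min_len, 200)
  expect_equal(one$max_len, 200)
  expect_equal(transcript_stats("GGCC")$gc_percent, 100)
  # GC over unambiguous bases only
  expect_equal(transcript_stats("GGCCNNNN")$gc_percent, 100)
  expect_error(transcript_stats(character(0)), "empty")
})

test_that("N50 is invariant under permutation and whole-set duplication", {
  set.seed(7)
  lens <- sample(100:2000, 40)
  seqs <- vapply(lens, rseq, character(1))
  base <- transcript_stats(seqs)$N50
  expect_equal(transcript_stats(sample(seqs))$N50, base)
  expect_equal(transcript_stats(c(seqs, seqs))$N50, base)
})
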