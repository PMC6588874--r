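# ORF scanning, coding-potential scoring, hit filters and the cascade.

test_that("longest_orf handles canonical and degenerate sequences", {
  o <- longest_orf("ATGAAATAG")
  expect_equal(o$length_nt, 9)
  expect_equal(o$strand, "+")
  expect_equal(o$frame, 0)
  expect_equal(o$start, 0)
  expect_null(longest_orf("CCCCCCCCC"))
  # stop codon counted: ATG + 1 codon + TAA = 9 nt
  expect_equal(longest_orf_length("ATGGGGTAA"), 9)
  # N codons never match ATG or stop, but may sit inside an ORF
  expect_equal(longest_orf_length("ATGNNNTAG"), 9)
  expect_equal(longest_orf_length("ATGAAATNA"), 0)  # TNA is not a stop
  # minus-strand ORF: revcomp of ATGAAATAG
  m <- longest_orf("CTATTTCAT")
  expect_equal(m$strand, "-")
  expect_equal(m$length_nt, 9)
  # no stop -> no ORF (partial ORFs not counted)
  expect_null(longest_orf("ATGAAAAAAAAA"))
})

test_that("longest_orf matches the exhaustive brute-force scan", {
  set.seed(11)
  for (rep in 1:400) {
    n <- sample(c(30:120, sample(200:600, 5)), 1)
    seq <- rseq(n, alphabet = c("A", "C", "G", "T",
                                if (rep %% 5 == 0) "N"))
    got <- longest_orf(seq)
    want <- oracle_orf(seq)
    if (is.null(want)) {
      expect_null(got, info = seq)
    } else {
      expect_equal(got[c("start", "end", "strand", "frame", "length_nt")],
                   want[c("start", "end", "strand", "frame", "length_nt")],
                   info = seq)
    }
  }
})

test_that("coding potential separates designed coding from noncoding sequence", {
  set.seed(5)
  # a long ORF built from the coding model scores higher than a shuffled
  # version of itself (same length, same base composition)
  orf <- lncweave:::rand_coding(600)
  shuffled <- paste(sample(strsplit(orf, "")[[1]]), collapse = "")
  s_orf <- coding_potential(orf)$S
  s_shuf <- coding_potential(shuffled)$S
  expect_gt(s_orf, s_shuf)
  expect_gt(s_orf, 0)
  # ORF-free noncoding sequence scores below zero
  nc <- lncweave:::rand_noncoding(400)
  cp <- coding_potential(nc)
  expect_equal(cp$orf_len, 0)
  expect_equal(cp$hexamer_llr, 0)
  expect_lt(cp$S, 0)
  # degenerate weights give S = 0 for any sequence
  w0 <- cp_weights(w = c(0, 0, 0, 0))
  expect_equal(coding_potential(orf, weights = w0)$S, 0)
  expect_equal(coding_potential(nc, weights = w0)$S, 0)
})

test_that("hexamer_llr is 0 without an ORF and positive on model-coding ORFs", {
  expect_equal(hexamer_llr("CCCCCCCCCCCC"), 0)
  expect_message(expect_equal(hexamer_llr("ACG"), 0), "shorter")
  set.seed(6)
  vals <- replicate(20, hexamer_llr(lncweave:::rand_coding(300)))
  expect_true(all(vals > 0))
})

test_that("hit filter partitions at an inclusive cutoff", {
  hits <- data.frame(query_id = c("a", "a", "b", "c"),
                     subject_id = "s", percent_identity = 90,
                     alignment_len = 100,
                     e_value = c(1e-3, 1e-5, 1e-20, 2e-5),
                     bit_score = 50, stringsAsFactors = FALSE)
  res <- apply_hit_filter(c("a", "b", "c", "d"), hits, 1e-5)
  expect_setequal(res$hit, c("a", "b"))     # 1e-5 exactly counts as a hit
  expect_setequal(res$no_hit, c("c", "d"))
  empty <- apply_hit_filter(c("a", "b"), hits[0, ], 1e-5)
  expect_equal(empty$no_hit, c("a", "b"))
  # brute-force check on random tables
  set.seed(8)
  for (rep in 1:50) {
    ids <- paste0("q", 1:20)
    tab <- data.frame(query_id = sample(ids, 40, TRUE), subject_id = "s",
                      percent_identity = 90, alignment_len = 100,
                      e_value = 10^runif(40, -12, 0), bit_score = 1,
                      stringsAsFactors = FALSE)
    e_max <- 10^runif(1, -8, -2)
    got <- apply_hit_filter(ids, tab, e_max)
    want <- vapply(ids, function(id) {
      ev <- tab$e_value[tab$query_id == id]
      length(ev) > 0 && min(ev) <= e_max
    }, logical(1))
    expect_setequal(got$hit, ids[want])
  }
})

test_that("hit tables round-trip through the 12-column format", {
  hits <- data.frame(query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
                     percent_identity = c(95.5, 88.25),
                     alignment_len = c(120, 300),
                     e_value = c(1e-8, 1e-5), bit_score = c(80, 50),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$e_value, hits$e_value)
  writeLines("q1\ts1\tbad", path)
  expect_error(read_hits(path), "line 1")
})

test_that("cascade recovers planted truth and conserves counts", {
  cfg <- tiny_config(seed = 2)
  ann <- gen_annotation(cfg)
  asm <- gen_assembly(cfg, ann)
  hits <- gen_hits(cfg, ann$truth)
  cat <- discover_lncrnas(asm, ann$reference, hits$known_lnc_hits,
                          hits$protein_hits)
  expect_setequal(cat$transcript_id[cat$status == "novel_lncRNA"],
                  ann$truth$novel_ids)
  expect_setequal(cat$transcript_id[cat$status == "known_lncRNA"],
                  ann$truth$known_ids)
  for (r in names(ann$truth$rejected_ids_by_reason))
    expect_setequal(cat$transcript_id[cat$status == "rejected" &
                                      cat$reason == r],
                    ann$truth$rejected_ids_by_reason[[r]])
  # conservation
  expect_equal(sum(catalog_counts(cat)), n_transcripts(asm))
  # reasons present iff rejected
  expect_true(all(is.na(cat$reason[cat$status != "rejected"])))
  expect_true(all(!is.na(cat$reason[cat$status == "rejected"])))
})

test_that("first failing step is the recorded reason", {
  # one intergenic transcript, 150 nt, that also contains a 100-nt-scale
  # ORF violation is impossible at that length; build a short transcript
  # with a long-ORF *and* short-length conflict at 150 nt using max_orf=60
  ref <- transcript_set(exdf("chr1", 50000, 51000, "+", "r1"))
  seq <- lncweave:::rand_coding(150)   # whole sequence one ORF of 150
  asm <- transcript_set(exdf("chr1", 1000, 1150, "+", "tq"),
                        sequences = c(tq = seq))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_len = numeric(),
                      e_value = numeric(), bit_score = numeric())
  cat <- discover_lncrnas(asm, ref, empty, empty,
                          params = cascade_params(min_len = 200, max_orf = 60))
  expect_equal(cat$reason, "too_short")   # length precedes the ORF rule
})

test_that("relaxing min_len or max_orf never shrinks the novel set", {
  cfg <- tiny_config(seed = 9)
  ann <- gen_annotation(cfg)
  asm <- gen_assembly(cfg, ann)
  hits <- gen_hits(cfg, ann$truth)
  cl <- classify_transcripts(asm, ann$reference)
  novel_at <- function(min_len, max_orf) {
    cat <- discover_lncrnas(asm, ann$reference, hits$known_lnc_hits,
                            hits$protein_hits,
                            params = cascade_params(min_len = min_len,
                                                    max_orf = max_orf),
                            classification = cl)
    cat$transcript_id[cat$status == "novel_lncRNA"]
  }
  base <- novel_at(200, 300)
  expect_true(all(base %in% novel_at(100, 300)))   # smaller min_len
  expect_true(all(base %in% novel_at(200, 600)))   # larger max_orf
  expect_true(all(base %in% novel_at(100, 600)))
})

test_that("empty assembly yields an empty catalog", {
  ref <- transcript_set(exdf("chr1", 0, 100, "+", "r1"))
  asm <- transcript_set(exdf("chr1", 0, 100, "+", "t")[0, ])
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_len = numeric(),
                      e_value = numeric(), bit_score = numeric())
  cat <- discover_lncrnas(asm, ref, empty, empty)
  expect_equal(nrow(cat), 0)
  expect_equal(sum(catalog_counts(cat)), 0)
})
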