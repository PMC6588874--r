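# Independent brute-force oracles used to check the package's optimized
# implementations, plus small fixture builders. Each oracle is written as
# plain nested-loop arithmetic, sharing no code with the implementation.

# exon-level overlap between two interval sets (0-based half-open)
ov <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

# Brute-force transcript classifier over explicit exon tables.
oracle_classify <- function(qex, ref_exons, ref_tx, single_exon_tol = 0) {
  qstrand <- qex$strand[1]; qchrom <- qex$chrom[1]
  same_overlap <- FALSE; oppo_overlap <- FALSE
  for (j in seq_len(nrow(ref_exons))) {
    if (ref_exons$chrom[j] != qchrom) next
    for (i in seq_len(nrow(qex))) {
      if (ov(qex$start[i], qex$end[i], ref_exons$start[j], ref_exons$end[j])) {
        if (qstrand != "." && ref_exons$strand[j] == qstrand)
          same_overlap <- TRUE else oppo_overlap <- TRUE
      }
    }
  }
  if (same_overlap) {
    # identical intron chain?
    for (rid in unique(ref_exons$transcript_id)) {
      rex <- ref_exons[ref_exons$transcript_id == rid, , drop = FALSE]
      rex <- rex[order(rex$start), ]
      if (rex$chrom[1] != qchrom || rex$strand[1] != qstrand) next
      if (nrow(rex) != nrow(qex)) next
      if (nrow(qex) == 1) {
        if (abs(rex$start - qex$start) <= single_exon_tol &&
            abs(rex$end - qex$end) <= single_exon_tol) return("=")
      } else {
        ends_q <- qex$end[-nrow(qex)]; starts_q <- qex$start[-1]
        ends_r <- rex$end[-nrow(rex)]; starts_r <- rex$start[-1]
        if (all(ends_q == ends_r) && all(starts_q == starts_r)) return("=")
      }
    }
    return("o")
  }
  if (oppo_overlap) return("x")
  qs <- min(qex$start); qe <- max(qex$end)
  if (qstrand != ".") {
    for (rid in unique(ref_exons$transcript_id)) {
      rex <- ref_exons[ref_exons$transcript_id == rid, , drop = FALSE]
      rex <- rex[order(rex$start), ]
      if (rex$chrom[1] != qchrom || rex$strand[1] != qstrand) next
      if (nrow(rex) < 2) next
      for (k in seq_len(nrow(rex) - 1))
        if (rex$end[k] <= qs && qe <= rex$start[k + 1]) return("i")
    }
  }
  "u"
}

# Exhaustive ORF scan over all (strand, frame, start) triples.
oracle_orf <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  rc <- function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    n <- nchar(s)
    for (start in seq_len(n)) {
      if (substring(s, start, start + 2) != "ATG") next
      pos <- start + 3
      while (pos + 2 <= n) {
        cod <- substring(s, pos, pos + 2)
        if (cod %in% stops) {
          len <- pos + 3 - start
          cand <- list(start = start - 1, end = start - 1 + len,
                       strand = strand, frame = (start - 1) %% 3,
                       length_nt = len)
          if (is.null(best) || len > best$length_nt ||
              (len == best$length_nt && strand == "+" && best$strand == "-") ||
              (len == best$length_nt && strand == best$strand &&
               cand$start < best$start))
            best <- cand
          break
        }
        pos <- pos + 3
      }
    }
  }
  best
}

# All-pairs cis window scan.
oracle_cis <- function(lnc, genes, min_dist, max_dist) {
  out <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(genes))) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    if (ov(lnc$start[i], lnc$end[i], genes$start[j], genes$end[j])) {
      d <- 0; signed <- 0
    } else if (genes$end[j] <= lnc$start[i]) {
      d <- lnc$start[i] - genes$end[j]; signed <- -d
    } else {
      d <- genes$start[j] - lnc$end[i]; signed <- d
    }
    if (d >= min_dist && d <= max_dist)
      out[[length(out) + 1]] <- data.frame(
        lnc_id = lnc$id[i], gene_id = genes$id[j], distance = signed,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(lnc_id = character(),
                                      gene_id = character(),
                                      distance = numeric()))
  do.call(rbind, out)
}

# Hypergeometric upper tail by explicit enumeration of the mass.
oracle_hyper_tail <- function(N, K, n, k) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / total
}

# Conditional binomial (Poisson, phi = 0) exact test by enumeration.
oracle_exact_poisson <- function(sA, sB, nA, nB) {
  total <- sA + sB
  pr <- dbinom(0:total, total, nA / (nA + nB))
  sum(pr[pr <= pr[sA + 1] * (1 + 1e-10)])
}

# random DNA string
rseq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small fast synthetic config for unit tests
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_chroms = 2, chrom_len = 4e5, n_coding_genes = 10, n_known_lncs = 6,
    n_novel_lncs = 20, n_decoys_short = 5, n_decoys_coding = 5,
    n_decoys_overlap = 4, n_decoys_protein = 4, n_decoys_score = 2,
    n_decoys_biotype = 4, cis_offsets = c(15000, 50000),
    n_reads = 200, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# exon data.frame shortcut
exdf <- function(chrom, start, end, strand, tid, gid = sub("^t", "g", tid)) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
}
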