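# Transcript models, GTF/FASTA I/O and assembly summary statistics.
#
# Coordinates are 0-based half-open internally; conversion to/from the
# 1-based inclusive GTF convention happens only at the file boundary.

#' Construct a transcript set
#'
#' A `transcript_set` is the package's container for exon-structured,
#' stranded transcript models: an exon table, a per-transcript table and an
#' optional named vector of spliced sequences.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`, `-` or `.`), `transcript_id`, `gene_id`.
#' @param biotype optional named character vector (by transcript_id) of
#'   biotype labels (`protein_coding`, `lncRNA`, `rRNA`, `tRNA`, `miRNA`,
#'   `pseudogene`, `unknown`).
#' @param sequences optional named character vector of spliced sequences.
#' @return an object of class `transcript_set` with elements `exons`
#'   (sorted per transcript) and `tx` (one row per transcript:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`, `n_exons`,
#'   `spliced_len`, `span_start`, `span_end`), plus `sequences`.
#' @export
transcript_set <- function(exons, biotype = NULL, sequences = NULL) {
  req <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  assert_that(all(req %in% names(exons)),
              "exon table must have columns: %s", paste(req, collapse = ", "))
  if (nrow(exons)) {
    assert_that(all(exons$start >= 0 & exons$start < exons$end),
                "invalid exon interval: need 0 <= start < end")
    assert_that(all(nzchar(exons$chrom)), "empty chrom name")
  }
  exons <- exons[order(exons$transcript_id, exons$start), req, drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(idx) > 1) {
        assert_that(length(unique(exons$chrom[idx])) == 1 &&
                    length(unique(exons$strand[idx])) == 1,
                    "transcript %s mixes chromosomes or strands",
                    exons$transcript_id[idx[1]])
        assert_that(all(exons$start[idx][-1] >= exons$end[idx][-length(idx)]),
                    "transcript %s has overlapping exons",
                    exons$transcript_id[idx[1]])
      }
    }
    first <- vapply(by_tx, `[`, integer(1), 1L)
    tx <- data.frame(
      transcript_id = names(by_tx),
      gene_id = exons$gene_id[first],
      chrom = exons$chrom[first],
      strand = exons$strand[first],
      n_exons = lengths(by_tx),
      spliced_len = vapply(by_tx, function(i) sum(exons$end[i] - exons$start[i]),
                           numeric(1)),
      span_start = vapply(by_tx, function(i) min(exons$start[i]), numeric(1)),
      span_end = vapply(by_tx, function(i) max(exons$end[i]), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     n_exons = integer(), spliced_len = numeric(),
                     span_start = numeric(), span_end = numeric(),
                     stringsAsFactors = FALSE)
  }
  tx$biotype <- if (is.null(biotype)) rep("unknown", nrow(tx)) else
    unname(ifelse(is.na(biotype[tx$transcript_id]), "unknown",
                  biotype[tx$transcript_id]))
  rownames(tx) <- NULL
  if (!is.null(sequences)) {
    missing <- setdiff(tx$transcript_id, names(sequences))
    assert_that(length(missing) == 0, "sequences missing for: %s",
                paste(head(missing, 3), collapse = ", "))
    bad <- tx$transcript_id[nchar(sequences[tx$transcript_id]) != tx$spliced_len]
    assert_that(length(bad) == 0,
                "sequence length != spliced length for: %s",
                paste(head(bad, 3), collapse = ", "))
    sequences <- sequences[tx$transcript_id]
  }
  structure(list(exons = exons, tx = tx, sequences = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons on %d chromosome(s)%s\n",
              nrow(x$tx), nrow(x$exons), length(unique(x$tx$chrom)),
              if (is.null(x$sequences)) "" else " (+sequences)"))
  invisible(x)
}

#' Number of transcripts in a transcript set
#' @param x a `transcript_set`
#' @return integer count
#' @export
n_transcripts <- function(x) nrow(x$tx)

# ---- GTF I/O ---------------------------------------------------------------

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_,
         character(1))
}

#' Read a GTF file into a transcript set
#'
#' Parses the exon rows of a GTF file (attribute keys `gene_id`,
#' `transcript_id`, optional `biotype`/`gene_biotype`/`transcript_biotype`).
#' 1-based inclusive GTF coordinates are converted to the internal 0-based
#' half-open convention. Feature rows other than `exon` are ignored and
#' their count reported via [message()].
#'
#' @param path GTF file path
#' @return a [transcript_set()]
#' @export
read_gtf <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno))
    return(transcript_set(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), strand = character(),
                                     transcript_id = character(),
                                     gene_id = character())))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9))
    stopf("GTF parse error at line %d: expected 9 tab-separated fields",
          lineno[which(nf < 9)[1]])
  feat <- vapply(f, `[`, character(1), 3L)
  is_exon <- feat == "exon"
  n_skip <- sum(!is_exon)
  if (n_skip) msgf("read_gtf: ignored %d non-exon feature row(s)", n_skip)
  f <- f[is_exon]; lineno <- lineno[is_exon]
  if (!length(f))
    return(transcript_set(data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), strand = character(),
                                     transcript_id = character(),
                                     gene_id = character())))
  start1 <- as.numeric(vapply(f, `[`, character(1), 4L))
  end1 <- as.numeric(vapply(f, `[`, character(1), 5L))
  bad <- which(is.na(start1) | is.na(end1) | end1 < start1)
  if (length(bad))
    stopf("GTF parse error at line %d: end < start or non-numeric coordinate",
          lineno[bad[1]])
  attrs <- vapply(f, `[`, character(1), 9L)
  tid <- gtf_attr(attrs, "transcript_id")
  if (anyNA(tid))
    stopf("GTF parse error at line %d: missing transcript_id attribute",
          lineno[which(is.na(tid))[1]])
  gid <- gtf_attr(attrs, "gene_id")
  gid[is.na(gid)] <- tid[is.na(gid)]
  bt <- gtf_attr(attrs, "biotype")
  bt2 <- gtf_attr(attrs, "transcript_biotype")
  bt3 <- gtf_attr(attrs, "gene_biotype")
  bt <- ifelse(is.na(bt), ifelse(is.na(bt2), bt3, bt2), bt)
  exons <- data.frame(
    chrom = vapply(f, `[`, character(1), 1L),
    start = start1 - 1, end = end1,
    strand = vapply(f, `[`, character(1), 7L),
    transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
  biotype <- NULL
  if (!all(is.na(bt))) {
    biotype <- tapply(bt, tid, function(v) {
      v <- v[!is.na(v)]; if (length(v)) v[1] else NA_character_
    })
    biotype <- setNames(as.character(biotype), names(biotype))
  }
  transcript_set(exons, biotype = biotype)
}

#' Write a transcript set as GTF
#'
#' Emits one `exon` row per exon, converting back to 1-based inclusive
#' coordinates, with `gene_id`, `transcript_id` and `biotype` attributes.
#' Output ordering is deterministic (transcript id, then start).
#'
#' @param ts a [transcript_set()]
#' @param path output file
#' @param source_label value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(ts, path, source_label = "lncweave") {
  ex <- ts$exons
  bt <- setNames(ts$tx$biotype, ts$tx$transcript_id)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
    ex$chrom, source_label, as.integer(ex$start + 1), as.integer(ex$end),
    ex$strand, ex$gene_id, ex$transcript_id, unname(bt[ex$transcript_id]))
  writeLines(lines, path)
  invisible(path)
}

# ---- FASTA I/O (Biostrings behind a thin surface) --------------------------

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA (wrapped at 60 columns)
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Splice transcript sequences out of a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts.
#'
#' @param ts a [transcript_set()]
#' @param genome named character vector of chromosome sequences
#' @return the transcript set with `sequences` filled in
#' @export
splice_sequences <- function(ts, genome) {
  missing <- setdiff(unique(ts$tx$chrom), names(genome))
  assert_that(length(missing) == 0, "chromosome(s) absent from genome: %s",
              paste(missing, collapse = ", "))
  seqs <- vapply(seq_len(nrow(ts$tx)), function(i) {
    id <- ts$tx$transcript_id[i]
    ex <- ts$exons[ts$exons$transcript_id == id, , drop = FALSE]
    s <- paste(substring(genome[[ex$chrom[1]]], ex$start + 1, ex$end),
               collapse = "")
    if (ts$tx$strand[i] == "-") revcomp(s) else s
  }, character(1))
  ts$sequences <- setNames(seqs, ts$tx$transcript_id)
  ts
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ---- transcript-vs-reference classification --------------------------------

#' Classify transcripts against a reference annotation
#'
#' Assigns each query transcript one of five class codes in the style of
#' transcript-vs-annotation comparison tools:
#' \describe{
#'   \item{`=`}{same-strand reference transcript with an identical intron
#'     chain (single-exon queries: identical exon within
#'     `single_exon_tol` bp at each end).}
#'   \item{`o`}{any other same-strand exonic overlap with a reference exon.}
#'   \item{`x`}{exonic overlap with reference exons on the opposite strand
#'     only.}
#'   \item{`i`}{contained entirely within an intron of a same-strand
#'     reference transcript, with no exonic overlap.}
#'   \item{`u`}{intergenic: no exonic overlap with any reference exon on
#'     either strand, and not intronic.}
#' }
#' Codes are assigned in the precedence order `=`, `o`, `x`, `i`, `u`, so
#' classification is a total function. Queries on chromosomes absent from
#' the reference are `u` with a logged warning. Strand `.` matches no
#' strand for the same-strand tests.
#'
#' @param query a [transcript_set()] of assembled transcripts
#' @param reference a [transcript_set()] of annotated transcripts
#' @param single_exon_tol end tolerance (bp) for single-exon `=` matches
#'   (default 0 = exact)
#' @return data.frame with columns `transcript_id`, `class_code`, `ref_id`
#'   (`NA` for code `u`)
#' @export
classify_transcripts <- function(query, reference, single_exon_tol = 0) {
  rex <- reference$exons
  rtx <- reference$tx
  qtx <- query$tx
  out <- data.frame(transcript_id = qtx$transcript_id,
                    class_code = rep("u", nrow(qtx)),
                    ref_id = rep(NA_character_, nrow(qtx)),
                    stringsAsFactors = FALSE)
  if (!nrow(qtx) || !nrow(rtx)) return(out)
  unknown <- setdiff(unique(qtx$chrom), unique(rtx$chrom))
  if (length(unknown))
    warnf("classify_transcripts: query chromosome(s) %s absent from reference; classified 'u'",
          paste(unknown, collapse = ", "))
  # exon-level overlap index per chromosome
  ref_by_chrom <- split(seq_len(nrow(rex)), rex$chrom)
  ref_introns <- lapply(split(seq_len(nrow(rex)), rex$transcript_id), function(i) {
    if (length(i) < 2) return(NULL)
    cbind(start = rex$end[i][-length(i)], end = rex$start[i][-1])
  })
  for (qi in seq_len(nrow(qtx))) {
    qid <- qtx$transcript_id[qi]
    qex <- query$exons[query$exons$transcript_id == qid, , drop = FALSE]
    chrom <- qtx$chrom[qi]; strand <- qtx$strand[qi]
    ridx <- ref_by_chrom[[chrom]]
    if (is.null(ridx)) next
    qr <- IRanges::IRanges(start = qex$start + 1, end = qex$end)
    rr <- IRanges::IRanges(start = rex$start[ridx] + 1, end = rex$end[ridx])
    hits <- IRanges::findOverlaps(qr, rr)
    hit_ref <- ridx[S4Vectors::subjectHits(hits)]
    same <- hit_ref[strand != "." & rex$strand[hit_ref] == strand]
    oppo <- hit_ref[rex$strand[hit_ref] != strand]
    if (length(same)) {
      # candidate '=': identical intron chain on a same-strand transcript
      eq_ref <- NA_character_
      for (rid in unique(rex$transcript_id[same])) {
        ri <- which(rex$transcript_id == rid)
        if (length(ri) != nrow(qex)) next
        if (nrow(qex) == 1) {
          ok <- abs(rex$start[ri] - qex$start) <= single_exon_tol &&
                abs(rex$end[ri] - qex$end) <= single_exon_tol
        } else {
          # identical intron chain: internal boundaries must match exactly
          ok <- all(rex$end[ri][-length(ri)] == qex$end[-nrow(qex)]) &&
                all(rex$start[ri][-1] == qex$start[-1])
        }
        if (ok) { eq_ref <- rid; break }
      }
      if (!is.na(eq_ref)) {
        out$class_code[qi] <- "="; out$ref_id[qi] <- eq_ref
      } else {
        out$class_code[qi] <- "o"
        out$ref_id[qi] <- rex$transcript_id[same[1]]
      }
      next
    }
    if (length(oppo)) {
      out$class_code[qi] <- "x"
      out$ref_id[qi] <- rex$transcript_id[oppo[1]]
      next
    }
    # intronic: whole query span inside one intron of a same-strand transcript
    span <- c(qtx$span_start[qi], qtx$span_end[qi])
    cand <- rtx$transcript_id[rtx$chrom == chrom & rtx$strand == strand &
                              strand != "." &
                              rtx$span_start <= span[1] & rtx$span_end >= span[2]]
    intr_hit <- NA_character_
    for (rid in cand) {
      intr <- ref_introns[[rid]]
      if (is.null(intr)) next
      if (any(intr[, "start"] <= span[1] & intr[, "end"] >= span[2])) {
        intr_hit <- rid; break
      }
    }
    if (!is.na(intr_hit)) {
      out$class_code[qi] <- "i"; out$ref_id[qi] <- intr_hit
    }
  }
  out
}

# ---- assembly summary ------------------------------------------------------

#' Summary statistics of an assembly
#'
#' Computes the usual assembly summary: sequence/gene counts, length
#' distribution, N50 and GC percentage. N50 is the length L such that
#' sequences of length >= L accumulate to at least half the total bases
#' (descending-length accumulation). GC is computed over unambiguous
#' A/C/G/T only.
#'
#' @param x a [transcript_set()] (with or without sequences) or a character
#'   vector of sequences
#' @return list of class `assembly_summary`: `n_sequences`, `n_genes`,
#'   `total_bases`, `max_len`, `min_len`, `mean_len`, `median_len`, `N50`,
#'   `gc_percent` (`NA` without sequences)
#' @export
transcript_stats <- function(x) {
  if (inherits(x, "transcript_set")) {
    assert_that(nrow(x$tx) > 0, "transcript_stats: empty input")
    lens <- x$tx$spliced_len
    n_genes <- length(unique(x$tx$gene_id))
    seqs <- x$sequences
  } else {
    assert_that(length(x) > 0, "transcript_stats: empty input")
    lens <- nchar(x)
    n_genes <- length(x)
    seqs <- x
  }
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
  gc <- NA_real_
  if (!is.null(seqs)) {
    f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                     c("A", "C", "G", "T"))
    tot <- colSums(f)
    gc <- 100 * sum(tot[c("C", "G")]) / sum(tot)
  }
  structure(list(
    n_sequences = length(lens), n_genes = n_genes,
    total_bases = sum(lens), max_len = max(lens), min_len = min(lens),
    mean_len = mean(lens), median_len = median(lens),
    N50 = n50, gc_percent = gc), class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "assembly summary\n  sequences: %d  genes: %d  total: %s bp\n",
    "  length min/median/mean/max: %s / %s / %.2f / %s\n  N50: %s  GC%%: %s\n"),
    x$n_sequences, x$n_genes, format(x$total_bases, big.mark = ","),
    x$min_len, x$median_len, x$mean_len, x$max_len, x$N50,
    ifelse(is.na(x$gc_percent), "NA", sprintf("%.2f", x$gc_percent))))
  invisible(x)
}
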