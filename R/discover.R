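# The novel-lncRNA filter cascade and its hit-table helpers.

#' Read a 12-column tabular alignment hit table
#'
#' The standard tab-separated dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), as produced by common
#' sequence-similarity searches.
#'
#' @param path file path; an empty file yields an empty table
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_len`, `e_value`, `bit_score`
#' @export
read_hits <- function(path) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), alignment_len = numeric(),
                      e_value = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE)
  assert_that(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 12)
  if (length(bad))
    stopf("hit-table parse error at line %d: expected 12 tab-separated columns",
          bad[1])
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), k)))
    if (anyNA(v))
      stopf("hit-table parse error at line %d: non-numeric column %d",
            which(is.na(v))[1], k)
    v
  }
  data.frame(query_id = vapply(f, `[`, character(1), 1L),
             subject_id = vapply(f, `[`, character(1), 2L),
             percent_identity = num(3L), alignment_len = num(4L),
             e_value = num(11L), bit_score = num(12L),
             stringsAsFactors = FALSE)
}

#' Write hit records in the 12-column tabular dialect
#' @param hits data.frame as returned by [read_hits()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_hits <- function(hits, path) {
  if (!nrow(hits)) { writeLines(character(), path); return(invisible(path)) }
  writeLines(sprintf("%s\t%s\t%.2f\t%d\t0\t0\t1\t%d\t1\t%d\t%.3g\t%.1f",
                     hits$query_id, hits$subject_id, hits$percent_identity,
                     as.integer(hits$alignment_len),
                     as.integer(hits$alignment_len),
                     as.integer(hits$alignment_len),
                     hits$e_value, hits$bit_score), path)
  invisible(path)
}

#' Partition ids by presence of a hit at an E-value cutoff
#'
#' An id is a "hit" iff any record for it has `e_value <= e_max`
#' (inclusive). The returned partition is exact and disjoint.
#'
#' @param ids character vector of query ids
#' @param hits hit table from [read_hits()] (possibly empty)
#' @param e_max E-value cutoff (> 0, inclusive)
#' @return list with `hit` and `no_hit` character vectors
#' @export
apply_hit_filter <- function(ids, hits, e_max) {
  assert_that(e_max > 0, "e_max must be > 0")
  hit_ids <- unique(hits$query_id[hits$e_value <= e_max])
  is_hit <- ids %in% hit_ids
  list(hit = ids[is_hit], no_hit = ids[!is_hit])
}

#' Cascade parameters for novel-lncRNA discovery
#'
#' @param min_len minimum spliced length in nt (default 200; transcripts
#'   shorter than this are rejected)
#' @param max_orf maximum tolerated longest-ORF length in nt (default 300,
#'   strict: an ORF of exactly 300 nt passes, 303 nt -- 100 aa plus stop --
#'   does not)
#' @param protein_evalue_max E-value cutoff for the known-protein
#'   similarity filter (default 1e-5, inclusive)
#' @param known_lnc_evalue_max E-value cutoff for assignment to the known
#'   lncRNA set (default 1e-10, inclusive)
#' @param cpc_threshold coding-potential decision threshold (default 0:
#'   `S < 0` = noncoding)
#' @param excluded_biotypes reference biotypes whose matching transcripts
#'   are removed up front
#' @return list of class `cascade_params`
#' @export
cascade_params <- function(min_len = 200, max_orf = 300,
                           protein_evalue_max = 1e-5,
                           known_lnc_evalue_max = 1e-10,
                           cpc_threshold = 0,
                           excluded_biotypes = c("protein_coding", "pseudogene",
                                                 "rRNA", "tRNA", "miRNA")) {
  assert_that(min_len > 0, "min_len must be > 0")
  assert_that(protein_evalue_max > 0 && known_lnc_evalue_max > 0,
              "e-value cutoffs must be > 0")
  structure(list(min_len = min_len, max_orf = max_orf,
                 protein_evalue_max = protein_evalue_max,
                 known_lnc_evalue_max = known_lnc_evalue_max,
                 cpc_threshold = cpc_threshold,
                 excluded_biotypes = excluded_biotypes),
            class = "cascade_params")
}

#' Novel-lncRNA discovery cascade
#'
#' Classifies every assembled transcript as `known_lncRNA`, `novel_lncRNA`
#' or `rejected` with a reason, applying the filter steps in fixed order:
#' \enumerate{
#'   \item \strong{biotype}: transcripts whose reference match (class code
#'     other than `u`) carries an excluded biotype (protein-coding,
#'     pseudogene, rRNA, tRNA, miRNA) are removed.
#'   \item \strong{known-lncRNA assignment}: transcripts with a hit in the
#'     known-lncRNA table at `e <= known_lnc_evalue_max` become
#'     `known_lncRNA`.
#'   \item \strong{not_u}: remaining transcripts whose class code is not
#'     `u` (intergenic) are rejected.
#'   \item \strong{too_short}: spliced length `< min_len` nt.
#'   \item \strong{known_lnc_overlap}: exonic overlap with reference
#'     transcripts of biotype lncRNA. Under the strand-agnostic `u`
#'     definition this step cannot remove anything (intergenic transcripts
#'     overlap no annotated exon); it is retained and its count reported.
#'   \item \strong{long_orf}: longest ORF `> max_orf` nt.
#'   \item \strong{protein_hit}: hit in the protein table at
#'     `e <= protein_evalue_max`.
#'   \item \strong{coding_score}: combined coding-potential score
#'     `S >= cpc_threshold`.
#' }
#' Survivors are `novel_lncRNA`. The first failing step is the recorded
#' reason; because all filters are conjunctive, membership in the novel set
#' does not depend on step order, only the recorded reasons do.
#'
#' @param assembly a [transcript_set()] with sequences
#' @param reference a [transcript_set()] of the annotation
#' @param known_lnc_hits,protein_hits hit tables from [read_hits()]
#'   (possibly empty)
#' @param params a [cascade_params()]
#' @param hexamer_table,weights passed to [coding_potential()]
#' @param classification optional precomputed [classify_transcripts()]
#'   result
#' @return data.frame of class `lnc_catalog`: one row per transcript with
#'   `transcript_id`, `status`, `reason` (`NA` unless rejected),
#'   `class_code`, `orf_len`, `orf_coverage`, `fickett`, `hexamer_llr`,
#'   `S` (coding-potential fields `NA` where the cascade stopped earlier)
#' @export
discover_lncrnas <- function(assembly, reference, known_lnc_hits,
                             protein_hits, params = cascade_params(),
                             hexamer_table = default_hexamer_table(),
                             weights = cp_weights(),
                             classification = NULL) {
  if (is.null(classification))
    classification <- classify_transcripts(assembly, reference)
  tx <- assembly$tx
  n <- nrow(tx)
  cat <- data.frame(transcript_id = tx$transcript_id,
                    status = rep(NA_character_, n),
                    reason = rep(NA_character_, n),
                    class_code = classification$class_code[
                      match(tx$transcript_id, classification$transcript_id)],
                    orf_len = rep(NA_real_, n), orf_coverage = rep(NA_real_, n),
                    fickett = rep(NA_real_, n), hexamer_llr = rep(NA_real_, n),
                    S = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (!n) return(structure(cat, class = c("lnc_catalog", "data.frame")))

  ref_bt <- setNames(reference$tx$biotype, reference$tx$transcript_id)
  ref_id <- classification$ref_id[match(tx$transcript_id,
                                        classification$transcript_id)]
  open <- rep(TRUE, n)

  # (0) excluded biotypes, via the matched reference transcript
  matched_bt <- ifelse(is.na(ref_id), NA_character_, unname(ref_bt[ref_id]))
  hit0 <- open & !is.na(matched_bt) & matched_bt %in% params$excluded_biotypes
  cat$status[hit0] <- "rejected"; cat$reason[hit0] <- "biotype"
  open <- open & !hit0

  # (a) known-lncRNA assignment by similarity
  known <- apply_hit_filter(tx$transcript_id, known_lnc_hits,
                            params$known_lnc_evalue_max)$hit
  hita <- open & tx$transcript_id %in% known
  cat$status[hita] <- "known_lncRNA"
  open <- open & !hita

  # (1) class code must be 'u'
  hit1 <- open & cat$class_code != "u"
  cat$status[hit1] <- "rejected"; cat$reason[hit1] <- "not_u"
  open <- open & !hit1

  # (2) length filter
  hit2 <- open & tx$spliced_len < params$min_len
  cat$status[hit2] <- "rejected"; cat$reason[hit2] <- "too_short"
  open <- open & !hit2

  # (3) overlap with annotated lncRNA exons
  lnc_ref <- reference$tx$transcript_id[reference$tx$biotype == "lncRNA"]
  if (length(lnc_ref) && any(open)) {
    lex <- reference$exons[reference$exons$transcript_id %in% lnc_ref, ,
                           drop = FALSE]
    ov <- vapply(which(open), function(i) {
      qex <- assembly$exons[assembly$exons$transcript_id == tx$transcript_id[i], ,
                            drop = FALSE]
      sub <- lex[lex$chrom == tx$chrom[i], , drop = FALSE]
      if (!nrow(sub)) return(FALSE)
      any(IRanges::countOverlaps(
        IRanges::IRanges(qex$start + 1, qex$end),
        IRanges::IRanges(sub$start + 1, sub$end)) > 0)
    }, logical(1))
    hit3 <- which(open)[ov]
    cat$status[hit3] <- "rejected"; cat$reason[hit3] <- "known_lnc_overlap"
    open[hit3] <- FALSE
  }

  # sequence-based steps
  need_seq <- which(open)
  if (length(need_seq)) {
    assert_that(!is.null(assembly$sequences),
                "transcript %s lacks a sequence required by the ORF filter",
                tx$transcript_id[need_seq[1]])
    for (i in need_seq) {
      id <- tx$transcript_id[i]
      seq <- assembly$sequences[[id]]
      assert_that(!is.null(seq) && !is.na(seq),
                  "transcript %s lacks a sequence required by the ORF filter", id)
      cp <- coding_potential(seq, hexamer_table, weights)
      cat$orf_len[i] <- cp$orf_len; cat$orf_coverage[i] <- cp$orf_coverage
      cat$fickett[i] <- cp$fickett; cat$hexamer_llr[i] <- cp$hexamer_llr
      cat$S[i] <- cp$S
    }
    # (4) long ORF
    hit4 <- open & !is.na(cat$orf_len) & cat$orf_len > params$max_orf
    cat$status[hit4] <- "rejected"; cat$reason[hit4] <- "long_orf"
    open <- open & !hit4
    # (5) protein similarity
    prot <- apply_hit_filter(tx$transcript_id, protein_hits,
                             params$protein_evalue_max)$hit
    hit5 <- open & tx$transcript_id %in% prot
    cat$status[hit5] <- "rejected"; cat$reason[hit5] <- "protein_hit"
    open <- open & !hit5
    # (6) coding score
    hit6 <- open & cat$S >= params$cpc_threshold
    cat$status[hit6] <- "rejected"; cat$reason[hit6] <- "coding_score"
    open <- open & !hit6
  }
  cat$status[open] <- "novel_lncRNA"
  structure(cat, class = c("lnc_catalog", "data.frame"))
}

#' Tally a discovery catalog by status and rejection reason
#' @param catalog an `lnc_catalog` from [discover_lncrnas()]
#' @return named integer vector (known_lncRNA, novel_lncRNA, and one entry
#'   per rejection reason); entries sum to the catalog size
#' @export
catalog_counts <- function(catalog) {
  reasons <- c("biotype", "not_u", "too_short", "known_lnc_overlap",
               "long_orf", "protein_hit", "coding_score")
  c(known_lncRNA = sum(catalog$status == "known_lncRNA"),
    novel_lncRNA = sum(catalog$status == "novel_lncRNA"),
    setNames(vapply(reasons, function(r)
      sum(catalog$status == "rejected" & catalog$reason == r, na.rm = TRUE),
      numeric(1)), reasons))
}

#' Write a discovery catalog as TSV
#' @param catalog an `lnc_catalog`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
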