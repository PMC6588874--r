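# FASTQ read-discard rules and retention reporting.

#' QC thresholds for read filtering
#'
#' The three discard rules applied to raw reads, in fixed order:
#' (1) the read contains the adaptor string as an exact substring;
#' (2) the fraction of unknown bases (N) is strictly greater than
#' `max_n_frac`; (3) the fraction of bases with Phred quality <= `low_q`
#' is strictly greater than `max_lowq_frac`. Both fraction rules are
#' strict inequalities, so a 100-nt read with exactly 10 Ns passes the
#' default N rule.
#'
#' @param adaptor adaptor sequence to match exactly, or `NULL` to skip the
#'   adaptor rule
#' @param max_n_frac maximum tolerated N fraction (default 0.10)
#' @param low_q Phred value at or below which a base counts as low quality
#'   (default 5)
#' @param max_lowq_frac maximum tolerated low-quality-base fraction
#'   (default 0.50)
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(adaptor = NULL, max_n_frac = 0.10, low_q = 5,
                          max_lowq_frac = 0.50) {
  assert_that(max_n_frac >= 0 && max_n_frac <= 1 &&
              max_lowq_frac >= 0 && max_lowq_frac <= 1,
              "fractions must be in [0, 1]")
  assert_that(low_q >= 0, "low_q must be >= 0")
  structure(list(adaptor = adaptor, max_n_frac = max_n_frac, low_q = low_q,
                 max_lowq_frac = max_lowq_frac), class = "qc_thresholds")
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ file
#' @return data.frame with columns `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) %% 4 == 0, "truncated FASTQ: %d lines", length(lines))
  n <- length(lines) / 4
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[seq(1, by = 4, length.out = n)])),
             seq = lines[seq(2, by = 4, length.out = n)],
             qual = lines[seq(4, by = 4, length.out = n)],
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#' @param reads data.frame with `id`, `seq`, `qual`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)),
             path)
  invisible(path)
}

#' Filter reads by the discard rules
#'
#' Applies the [qc_thresholds()] rules to each read. The first matching
#' rule in the order adaptor, N fraction, low quality is recorded as the
#' failure reason; clean reads keep their input order. Every input read is
#' accounted for exactly once (clean or one failure tally).
#'
#' @param reads FASTQ path or data.frame from [read_fastq()]
#' @param thresholds a [qc_thresholds()]
#' @return list with `clean` (data.frame of retained reads), `reasons`
#'   (per-read character: `pass`, `adaptor`, `N-fraction`, `low-quality`)
#'   and `report` (class `qc_report`: `n_raw`, `n_clean`, `clean_percent`
#'   -- `NA` when `n_raw` is 0 -- and `failures` counts per reason)
#' @export
filter_reads <- function(reads, thresholds = qc_thresholds()) {
  if (is.character(reads)) reads <- read_fastq(reads)
  n <- nrow(reads)
  bad_len <- which(nchar(reads$seq) != nchar(reads$qual))
  assert_that(length(bad_len) == 0,
              "FASTQ format error: sequence/quality length mismatch at record %d",
              if (length(bad_len)) bad_len[1] else 0L)
  reasons <- rep("pass", n)
  if (n) {
    len <- nchar(reads$seq)
    n_count <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
    lowq_count <- vapply(reads$qual, function(q)
      sum(utf8ToInt(q) - 33L <= thresholds$low_q), numeric(1), USE.NAMES = FALSE)
    fail_n <- n_count / len > thresholds$max_n_frac
    fail_q <- lowq_count / len > thresholds$max_lowq_frac
    fail_a <- if (!is.null(thresholds$adaptor))
      grepl(thresholds$adaptor, reads$seq, fixed = TRUE) else rep(FALSE, n)
    reasons[fail_q] <- "low-quality"
    reasons[fail_n] <- "N-fraction"
    reasons[fail_a] <- "adaptor"          # highest priority last
  }
  clean <- reads[reasons == "pass", , drop = FALSE]
  rownames(clean) <- NULL
  failures <- c(`adaptor` = sum(reasons == "adaptor"),
                `N-fraction` = sum(reasons == "N-fraction"),
                `low-quality` = sum(reasons == "low-quality"))
  report <- structure(list(
    n_raw = n, n_clean = nrow(clean),
    clean_percent = if (n > 0) 100 * nrow(clean) / n else NA_real_,
    failures = failures), class = "qc_report")
  list(clean = clean, reasons = reasons, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("read QC: %d raw, %d clean (%s%%); failed: adaptor %d, N %d, low-quality %d\n",
              x$n_raw, x$n_clean,
              ifelse(is.na(x$clean_percent), "NA", sprintf("%.2f", x$clean_percent)),
              x$failures[["adaptor"]], x$failures[["N-fraction"]],
              x$failures[["low-quality"]]))
  invisible(x)
}
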