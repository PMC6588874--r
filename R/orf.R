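# Open reading frame scanning.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Longest complete ORF (ATG..stop, no internal stop) in one strand-sequence.
# Returns NULL or list(start, end, frame, length_nt) with 0-based offsets
# into the scanned sequence; ORF length includes the stop codon.
scan_orfs_one_strand <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 2) next
    starts <- frame + 1 + 3 * (0:(n_codons - 1))
    codons <- substring(seq, starts, starts + 2)
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    prev <- 0L
    for (si in stop_idx) {
      cand <- which(is_start[(prev + 1):si])
      if (length(cand)) {
        a <- prev + cand[1]
        len <- (si - a + 1) * 3
        if (is.null(best) || len > best$length_nt ||
            (len == best$length_nt && (a - 1) * 3 + frame < best$start)) {
          best <- list(start = (a - 1) * 3 + frame,
                       end = (a - 1) * 3 + frame + len,
                       frame = frame, length_nt = len)
        }
      }
      prev <- si
    }
  }
  best
}

#' Longest open reading frame in a transcript sequence
#'
#' Scans all three frames on both strands for complete ORFs
#' (`ATG` ... `TAA`/`TAG`/`TGA` in frame with no internal stop). The stop
#' codon is counted in the ORF length, so the conventional "100 amino
#' acids" boundary corresponds to 303 nt here. Partial (stop-less) ORFs at
#' sequence ends are not counted. Codons containing `N` never match `ATG`
#' or a stop. Ties are broken in favour of the plus strand, then the
#' smallest start offset.
#'
#' @param seq a nucleotide string over A/C/G/T/N
#' @return `NULL` if no ORF, else a list with `start`, `end` (0-based
#'   half-open offsets into the scanned strand's sequence, i.e. the input
#'   for `+`, its reverse complement for `-`), `strand`, `frame`,
#'   `length_nt`
#' @export
longest_orf <- function(seq) {
  assert_that(is.character(seq) && length(seq) == 1 && nchar(seq) >= 1,
              "longest_orf expects a single non-empty sequence")
  seq <- toupper(seq)
  fwd <- scan_orfs_one_strand(seq)
  rev <- scan_orfs_one_strand(revcomp(seq))
  pick <- function(f, r) {
    if (is.null(r)) return(f)
    if (is.null(f)) return(r)
    if (f$length_nt >= r$length_nt) f else r   # '+' wins ties
  }
  best <- pick(fwd, rev)
  if (is.null(best)) return(NULL)
  best$strand <- if (identical(best, fwd)) "+" else "-"
  # identical() can confuse equal-valued records; recompute strand robustly
  best$strand <- if (!is.null(fwd) && best$length_nt == fwd$length_nt &&
                     best$start == fwd$start && best$frame == fwd$frame)
    "+" else "-"
  best[c("start", "end", "strand", "frame", "length_nt")]
}

#' Length of the longest ORF (0 when none)
#' @param seq nucleotide string
#' @return integer length in nt, stop codon included
#' @export
longest_orf_length <- function(seq) {
  o <- longest_orf(seq)
  if (is.null(o)) 0L else as.integer(o$length_nt)
}
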