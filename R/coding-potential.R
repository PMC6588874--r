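# Coding-potential scoring: Fickett TESTCODE, in-frame hexamer
# log-likelihood ratio, and the combined linear score S whose sign decides
# coding (S >= 0) versus noncoding (S < 0).

# Fickett (1982) TESTCODE lookup tables (as popularised by CPAT):
# position/content parameter values are binned and mapped to the
# probability that the sequence is coding, then combined with fixed
# weights.
.fickett <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
  position_para = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
  content_para = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0))

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' The classic position/composition statistic separating coding from
#' noncoding nucleotide sequences: for each base, a position parameter
#' (max over the three codon positions of the base's count, divided by the
#' min plus one) and a content parameter (overall base fraction) are looked
#' up in the published probability tables and combined with the published
#' weights. Higher scores indicate coding-like sequence; the conventional
#' coding threshold is about 0.95. Bases other than A/C/G/T are ignored.
#'
#' @param seq nucleotide string
#' @return numeric score
#' @export
fickett_score <- function(seq) {
  seq <- toupper(seq)
  bases <- strsplit(seq, "")[[1]]
  keep <- bases %in% c("A", "C", "G", "T")
  pos <- ((seq_along(bases) - 1) %% 3)[keep]
  bases <- bases[keep]
  if (!length(bases)) return(0)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(bases == b & pos == p), numeric(1))
    posval <- max(counts) / (min(counts) + 1)
    content <- sum(counts) / length(bases)
    pi <- which(posval >= .fickett$position_para)[1]
    ci <- which(content >= .fickett$content_para)[1]
    score <- score +
      .fickett$position_prob[[b]][pi] * .fickett$position_weight[[b]] +
      .fickett$content_prob[[b]][ci] * .fickett$content_weight[[b]]
  }
  score
}

# Codon-position base preferences of the synthetic coding model; also the
# analytic source of the default hexamer table. Stop codons are excluded
# and the codon distribution renormalised.
.codon_pos_probs <- matrix(c(
  # A     C     G     T
  0.20, 0.17, 0.50, 0.13,   # codon position 1 (G-rich, as in real CDS)
  0.45, 0.25, 0.10, 0.20,   # codon position 2
  0.10, 0.40, 0.35, 0.15),  # codon position 3 (GC-ended codons favoured)
  nrow = 3, byrow = TRUE, dimnames = list(NULL, c("A", "C", "G", "T")))

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Codon usage of the built-in coding model
#'
#' Probability of each of the 61 sense codons under the package's fixed
#' position-specific base preference model (stop codons excluded,
#' renormalised). Used both to generate synthetic coding sequence and to
#' derive the default hexamer table, so generator and scorer share one
#' coding model.
#'
#' @return named numeric vector over 61 codons summing to 1
#' @export
codon_usage <- function() {
  codons <- all_codons()
  p <- vapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    .codon_pos_probs[1, ch[1]] * .codon_pos_probs[2, ch[2]] *
      .codon_pos_probs[3, ch[3]]
  }, numeric(1))
  p[STOP_CODONS] <- 0
  p / sum(p)
}

.hexamer_cache <- new.env(parent = emptyenv())

#' Default hexamer log-ratio table
#'
#' Log ratio of in-frame hexamer (dicodon) frequency under the coding
#' model ([codon_usage()] products) versus a uniform mononucleotide
#' background, for all 4096 hexamers. Hexamers containing stop codons get
#' the floor value (strongly noncoding). Deterministic; computed once per
#' session.
#'
#' @param floor_log log value assigned where the coding probability is 0
#'   (default -10)
#' @return named numeric vector of length 4096
#' @export
default_hexamer_table <- function(floor_log = -10) {
  key <- sprintf("tab_%g", floor_log)
  if (!is.null(.hexamer_cache[[key]])) return(.hexamer_cache[[key]])
  cu <- codon_usage()
  codons <- all_codons()
  cu_all <- setNames(rep(0, 64), codons)
  cu_all[names(cu)] <- cu
  hex <- as.vector(outer(codons, codons, paste0))
  p_cod <- as.vector(outer(cu_all, cu_all))
  p_bg <- (1 / 4) ^ 6
  llr <- ifelse(p_cod > 0, log(p_cod / p_bg), floor_log)
  tab <- setNames(pmax(llr, floor_log), hex)
  .hexamer_cache[[key]] <- tab
  tab
}

#' Mean in-frame hexamer log-ratio over the longest ORF
#'
#' Steps through the longest ORF codon by codon and averages the hexamer
#' table's log-ratio over consecutive codon pairs. Returns 0 when the
#' sequence has no ORF, when the ORF is too short to contain a hexamer, or
#' when the sequence is shorter than 6 nt (logged).
#'
#' @param seq nucleotide string
#' @param table hexamer log-ratio table (default [default_hexamer_table()])
#' @param orf optional precomputed [longest_orf()] result
#' @return numeric score (positive = coding-biased)
#' @export
hexamer_llr <- function(seq, table = default_hexamer_table(), orf) {
  seq <- toupper(seq)
  if (nchar(seq) < 6) {
    msgf("hexamer_llr: sequence shorter than 6 nt; score 0")
    return(0)
  }
  if (missing(orf)) orf <- longest_orf(seq)
  if (is.null(orf)) return(0)
  s <- if (orf$strand == "-") revcomp(seq) else seq
  orf_seq <- substring(s, orf$start + 1, orf$end)
  n_hex <- (nchar(orf_seq) - 6) %/% 3 + 1
  if (nchar(orf_seq) < 6 || n_hex < 1) return(0)
  starts <- 1 + 3 * (0:(n_hex - 1))
  hex <- substring(orf_seq, starts, starts + 5)
  vals <- table[hex]
  vals[is.na(vals)] <- 0   # hexamers with N
  mean(vals)
}

#' Coding-potential weights and standardization constants
#'
#' The combined score is
#' `S = w1*z(orf_len) + w2*z(orf_coverage) + w3*z(fickett) + w4*hexamer_llr`
#' with `z(x) = (x - center)/scale`. Defaults centre the ORF-length term at
#' the 300 nt decision boundary, coverage at 0.5, and the Fickett score at
#' its conventional coding threshold 0.95, so that short-ORF, low-coverage,
#' composition-neutral transcripts land below 0 and ORF-covered,
#' codon-biased transcripts land above it.
#'
#' @param w numeric length-4 weights for (orf_len, orf_coverage, fickett,
#'   hexamer_llr)
#' @param centers,scales standardization constants for the first three
#'   features
#' @return list of class `cp_weights`
#' @export
cp_weights <- function(w = c(1, 1, 0.5, 0.5),
                       centers = c(orf_len = 300, orf_coverage = 0.5,
                                   fickett = 0.95),
                       scales = c(orf_len = 300, orf_coverage = 0.5,
                                  fickett = 0.15)) {
  assert_that(length(w) == 4, "need 4 weights")
  assert_that(all(scales > 0), "scales must be positive")
  structure(list(w = w, centers = centers, scales = scales),
            class = "cp_weights")
}

#' Coding potential of a transcript sequence
#'
#' Computes the four features (longest-ORF length in nt, ORF coverage of
#' the transcript, Fickett TESTCODE score, mean in-frame hexamer log-ratio
#' over the longest ORF) and the combined linear score `S` (see
#' [cp_weights()]). The classification rule is `S < threshold` (default 0)
#' = noncoding, preserving the sign semantics of conventional
#' coding-potential calculators.
#'
#' @param seq nucleotide string
#' @param table hexamer table
#' @param weights a [cp_weights()]
#' @return list with `orf_len`, `orf_coverage`, `fickett`, `hexamer_llr`,
#'   `S`
#' @export
coding_potential <- function(seq, table = default_hexamer_table(),
                             weights = cp_weights()) {
  orf <- longest_orf(seq)
  orf_len <- if (is.null(orf)) 0 else orf$length_nt
  cov <- orf_len / nchar(seq)
  fick <- fickett_score(seq)
  hll <- if (nchar(seq) < 6) 0 else hexamer_llr(seq, table, orf = orf)
  z <- function(x, name) (x - weights$centers[[name]]) / weights$scales[[name]]
  S <- weights$w[1] * z(orf_len, "orf_len") +
       weights$w[2] * z(cov, "orf_coverage") +
       weights$w[3] * z(fick, "fickett") +
       weights$w[4] * hll
  list(orf_len = orf_len, orf_coverage = cov, fickett = fick,
       hexamer_llr = hll, S = S)
}
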