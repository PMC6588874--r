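# FPKM quantification, TMM normalization, moment/shrinkage dispersion
# estimation, the conditional negative-binomial exact test, BH adjustment
# and significance calls.

#' FPKM from an expected-count matrix
#'
#' `FPKM(g, s) = count(g, s) * 1e9 / (length(g) * total(s))` with
#' `total(s)` the column sum.
#'
#' @param counts numeric matrix, genes x samples (rownames = gene ids)
#' @param lengths numeric vector of gene lengths in bp, named by gene or in
#'   row order
#' @return FPKM matrix of the same shape
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  assert_that(length(lengths) == nrow(counts), "one length per gene required")
  assert_that(all(lengths > 0), "gene lengths must be > 0")
  totals <- colSums(counts)
  zero <- which(totals <= 0)
  assert_that(length(zero) == 0, "sample '%s' has zero total counts",
              if (length(zero)) colnames(counts)[zero[1]] %||% zero[1] else "")
  sweep(counts * 1e9 / lengths, 2, totals, "/")
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference sample,
#' gene-wise log ratios (M) and average log abundances (A) are computed on
#' library-size-scaled counts, genes in the most extreme 30% of M and 5%
#' of A are trimmed, and the factor is 2 to the weighted mean of the
#' remaining M values, weighted by inverse asymptotic (delta-method)
#' variance. Factors are rescaled so their geometric mean is 1; they
#' multiply library sizes to give effective library sizes.
#'
#' @param counts genes x samples count matrix (>= 2 samples)
#' @param ref reference sample (index or name); default: the sample whose
#'   upper quartile of scaled counts is closest to the mean upper quartile
#' @param logratio_trim two-sided trim fraction on M (default 0.30)
#' @param abundance_trim two-sided trim fraction on A (default 0.05)
#' @return named numeric vector of factors, geometric mean 1
#' @export
tmm_factors <- function(counts, ref = NULL, logratio_trim = 0.30,
                        abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2, "TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (is.null(ref)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  yr <- counts[, ref]; Nr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    yk <- counts[, k]; Nk <- lib[k]
    keep <- yk > 0 & yr > 0
    if (!any(keep)) {
      warnf("tmm_factors: sample %d shares no expressed genes with the reference; factor 1", k)
      return(1)
    }
    M <- log2((yk[keep] / Nk) / (yr[keep] / Nr))
    A <- 0.5 * log2((yk[keep] / Nk) * (yr[keep] / Nr))
    w <- (Nk - yk[keep]) / (Nk * yk[keep]) + (Nr - yr[keep]) / (Nr * yr[keep])
    if (max(abs(M)) < 1e-10) return(1)    # identical composition
    loM <- quantile(M, logratio_trim, names = FALSE)
    hiM <- quantile(M, 1 - logratio_trim, names = FALSE)
    loA <- quantile(A, abundance_trim, names = FALSE)
    hiA <- quantile(A, 1 - abundance_trim, names = FALSE)
    use <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(use)) return(1)
    2 ^ (sum(M[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Effective library sizes
#' @param counts count matrix
#' @param factors TMM factors (default computed)
#' @return named numeric vector `colSums(counts) * factors`
#' @export
effective_libsizes <- function(counts, factors = tmm_factors(counts)) {
  colSums(as.matrix(counts)) * factors
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimation on normalized counts (counts scaled to the
#' geometric-mean effective library size): within each group with >= 2
#' replicates, `phi = (var - mean) / mean^2`; estimates are pooled across
#' groups by degrees of freedom, floored at 0, and shrunk toward the
#' all-gene median raw dispersion with weight `n / (n + n0)` where `n` is
#' the number of samples.
#'
#' @param counts genes x samples count matrix
#' @param groups character/factor of group labels per sample
#' @param eff_lib effective library sizes (default TMM)
#' @param n0 shrinkage prior weight in sample units (default 10)
#' @return named numeric vector of dispersions, one per gene
#' @export
estimate_dispersion <- function(counts, groups,
                                eff_lib = effective_libsizes(counts),
                                n0 = 10) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  assert_that(length(groups) == ncol(counts), "one group label per sample")
  scale_to <- exp(mean(log(eff_lib)))
  norm <- sweep(counts, 2, eff_lib / scale_to, "/")
  tab <- table(groups)
  rep_groups <- names(tab)[tab >= 2]
  if (!length(rep_groups)) {
    warnf("estimate_dispersion: no group has replicates; using dispersion 0.1 for all genes")
    return(setNames(rep(0.1, nrow(counts)), rownames(counts)))
  }
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in rep_groups) {
    cols <- which(groups == g)
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1, var)
    ok <- m > 0
    contrib <- ifelse(ok, (v - m) / pmax(m, 1e-8)^2, 0)
    df <- length(cols) - 1
    num <- num + ifelse(ok, df * contrib, 0)
    den <- den + ifelse(ok, df, 0)
  }
  raw <- ifelse(den > 0, pmax(num / pmax(den, 1), 0), NA_real_)
  # Common dispersion from the median raw estimate, corrected for the
  # chi-square skew of small-df sample variances: with d pooled df,
  # median(S^2) ~ (qchisq(.5, d)/d) * (m + phi m^2), so the median raw
  # estimate understates phi by that factor (plus a -(1-f)/m offset).
  common <- median(raw, na.rm = TRUE)
  if (is.na(common)) {
    common <- 0.1
  } else {
    d_med <- median(den[den > 0])
    f <- stats::qchisq(0.5, d_med) / d_med
    m_all <- rowMeans(norm)
    inv_m <- median(1 / m_all[den > 0 & m_all > 0])
    common <- max(0, (common + (1 - f) * inv_m) / f)
  }
  n <- ncol(counts)
  w <- n / (n + n0)
  phi <- ifelse(is.na(raw), common, w * raw + (1 - w) * common)
  setNames(pmax(phi, 0), rownames(counts))
}

#' Conditional negative-binomial exact test for one gene
#'
#' Counts are scaled to equalized effective library sizes (the geometric
#' mean), group sums are modeled as negative binomial (sum of `n`
#' independent NB(mu, phi) is NB(n*mu, phi/n)), and conditional on the
#' observed total the two-sided p-value is the summed probability of all
#' splits at most as probable as the observed one. With `phi = 0` the test
#' reduces to the conditional binomial (Poisson) exact test.
#'
#' @param yA,yB count vectors for the two groups
#' @param libA,libB effective library sizes of the samples in each group
#' @param phi negative-binomial dispersion (>= 0)
#' @return two-sided p-value
#' @export
nb_exact_test <- function(yA, yB, libA, libB, phi = 0) {
  assert_that(phi >= 0, "dispersion must be >= 0")
  assert_that(length(yA) >= 1 && length(yB) >= 1, "both groups must be non-empty")
  assert_that(length(libA) == length(yA) && length(libB) == length(yB),
              "one library size per sample")
  ref <- exp(mean(log(c(libA, libB))))
  sA <- round(sum(yA * ref / libA)); sB <- round(sum(yB * ref / libB))
  total <- sA + sB
  if (total == 0) return(1)
  nA <- length(yA); nB <- length(yB)
  mu <- total / (nA + nB)
  a <- 0:total
  if (phi == 0) {
    pa <- dpois(a, nA * mu); pb <- dpois(total - a, nB * mu)
  } else {
    pa <- dnbinom(a, size = nA / phi, mu = nA * mu)
    pb <- dnbinom(total - a, size = nB / phi, mu = nB * mu)
  }
  joint <- pa * pb
  denom <- sum(joint)
  if (denom <= 0) return(1)
  obs <- joint[sA + 1]
  min(1, sum(joint[joint <= obs * (1 + 1e-10)]) / denom)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure
#' (`q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1), returning values
#' in the input order. Delegates the arithmetic to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted values in input order
#' @export
bh_adjust <- function(p) {
  assert_that(all(!is.na(p) & p >= 0 & p <= 1),
              "p-values must be in [0, 1] and non-missing")
  p.adjust(p, method = "BH")
}

#' Pairwise differential-expression calls
#'
#' For each requested two-group comparison: TMM effective library sizes
#' are computed on the full matrix, per-gene dispersions estimated with
#' [estimate_dispersion()], the conditional NB exact test applied per
#' gene, p-values BH-adjusted within the comparison, and genes called
#' `up` (`fdr <= fdr_max` and `log2FC >= lfc_min`), `down` (`fdr <=
#' fdr_max` and `log2FC <= -lfc_min`) or `ns`. The reported fold change is
#' `log2((meanA + c)/(meanB + c))` on normalized counts with pseudo-count
#' `c` (reporting only; the test itself uses no pseudo-count).
#'
#' @param counts genes x samples count matrix
#' @param groups group label per sample
#' @param comparisons list of 2-vectors `c(A, B)`; each yields a
#'   comparison labelled `A_vs_B` with positive log2FC meaning higher in A
#' @param fdr_max,lfc_min significance thresholds (defaults 0.05 and 1)
#' @param pseudo_frac pseudo-count as a fraction of the mean normalized
#'   library scale (default 0.125)
#' @param dispersion optional fixed dispersion (scalar or per-gene vector);
#'   default: estimated from the data
#' @return data.frame of class `de_table`: `gene_id`, `comparison`,
#'   `log2FC`, `p`, `fdr`, `call`
#' @export
call_de <- function(counts, groups, comparisons, fdr_max = 0.05,
                    lfc_min = 1, pseudo_frac = 0.125, dispersion = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  assert_that(length(groups) == ncol(counts), "one group label per sample")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  for (cmp in comparisons)
    assert_that(all(cmp %in% groups), "unknown group label in comparison %s",
                paste(cmp, collapse = ":"))
  factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, groups, eff_lib = eff)
  if (length(dispersion) == 1)
    dispersion <- setNames(rep(dispersion, nrow(counts)), rownames(counts))
  scale_to <- exp(mean(log(eff)))
  norm <- sweep(counts, 2, eff / scale_to, "/")
  pseudo <- pseudo_frac
  out <- lapply(comparisons, function(cmp) {
    A <- which(groups == cmp[1]); B <- which(groups == cmp[2])
    p <- vapply(seq_len(nrow(counts)), function(i)
      nb_exact_test(counts[i, A], counts[i, B], eff[A], eff[B],
                    phi = dispersion[i]), numeric(1))
    mA <- rowMeans(norm[, A, drop = FALSE])
    mB <- rowMeans(norm[, B, drop = FALSE])
    lfc <- log2((mA + pseudo) / (mB + pseudo))
    fdr <- bh_adjust(p)
    call <- ifelse(fdr <= fdr_max & lfc >= lfc_min, "up",
                   ifelse(fdr <= fdr_max & lfc <= -lfc_min, "down", "ns"))
    data.frame(gene_id = rownames(counts),
               comparison = paste0(cmp[1], "_vs_", cmp[2]),
               log2FC = lfc, p = p, fdr = fdr, call = call,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(do.call(rbind, out), class = c("de_table", "data.frame"))
}

#' Read a counts TSV (genes x samples, first column gene ids)
#' @param path TSV file
#' @return numeric matrix with gene rownames
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a counts/expression matrix as TSV
#' @param m matrix with gene rownames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_counts <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
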