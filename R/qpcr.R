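# qPCR relative quantification (2^-ddCt with dual reference genes) and
# one-way ANOVA.

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, the reference Ct is the arithmetic mean over reference
#' genes of the replicate-mean Ct (equivalent to the geometric mean of the
#' reference expression levels). Then `dCt = mean target Ct - reference
#' Ct`, `ddCt = dCt - mean dCt(calibrator group)`, and relative expression
#' is `2^-ddCt`, so the calibrator group's mean `ddCt` is 0 and its
#' geometric-mean expression is 1. Adding a constant to every Ct leaves
#' the result unchanged. Samples missing reference measurements are
#' skipped with a warning.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`,
#'   `role` (`target` or `reference`), `ct` (one row per replicate well)
#' @param target target gene name (default: the single target present)
#' @param calibrator calibrator group label
#' @return data.frame with `sample`, `group`, `gene`, `dct`, `ddct`,
#'   `fold_change`
#' @export
ddct <- function(ct, target = NULL, calibrator) {
  req <- c("sample", "group", "gene", "role", "ct")
  assert_that(all(req %in% names(ct)), "Ct table must have columns: %s",
              paste(req, collapse = ", "))
  assert_that(all(ct$ct > 0), "Ct values must be > 0")
  targets <- unique(ct$gene[ct$role == "target"])
  if (is.null(target)) {
    assert_that(length(targets) == 1,
                "multiple target genes present; specify `target`")
    target <- targets
  }
  assert_that(calibrator %in% ct$group, "calibrator group '%s' not present",
              calibrator)
  tgt <- ct[ct$role == "target" & ct$gene == target, , drop = FALSE]
  refs <- ct[ct$role == "reference", , drop = FALSE]
  assert_that(nrow(refs) > 0, "no reference gene measurements")
  samples <- unique(tgt$sample)
  rows <- lapply(samples, function(s) {
    t_ct <- mean(tgt$ct[tgt$sample == s])
    r <- refs[refs$sample == s, , drop = FALSE]
    if (!nrow(r)) {
      warnf("ddct: sample '%s' has no reference measurements; skipped", s)
      return(NULL)
    }
    per_ref <- tapply(r$ct, r$gene, mean)
    data.frame(sample = s, group = tgt$group[tgt$sample == s][1],
               gene = target, dct = t_ct - mean(per_ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  assert_that(!is.null(out) && any(out$group == calibrator),
              "no usable samples in calibrator group '%s'", calibrator)
  cal_mean <- mean(out$dct[out$group == calibrator])
  out$ddct <- out$dct - cal_mean
  out$fold_change <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA (classical decomposition)
#'
#' Between/within sum-of-squares decomposition with an F test. Degenerate
#' inputs follow explicit contracts: all values identical gives `F = 0,
#' p = 1`; zero within-group variance with unequal means gives `F = Inf,
#' p = 0` with a flag.
#'
#' @param values numeric vector, or a list of per-group numeric vectors
#' @param groups group labels (ignored when `values` is a list)
#' @return list with `F`, `p`, `df_between`, `df_within`, `degenerate`
#'   (TRUE when the within-group variance is zero)
#' @export
anova_oneway <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.character(groups)
  assert_that(length(values) == length(groups), "one group label per value")
  ng <- length(unique(groups))
  assert_that(ng >= 2, "need >= 2 groups")
  assert_that(any(table(groups) >= 2), "need >= 2 values in some group")
  gm <- tapply(values, groups, mean)
  nn <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(nn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- ng - 1; df_w <- length(values) - ng
  if (ss_within == 0) {
    if (ss_between == 0)
      return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                  degenerate = TRUE))
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
                degenerate = TRUE))
  }
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  list(F = Fstat, p = pf(Fstat, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w, degenerate = FALSE)
}

#' Read a Ct table TSV
#' @param path TSV with columns sample, group, gene, role, ct
#' @return data.frame
#' @export
read_ct_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "group", "gene", "role", "ct")
  assert_that(all(req %in% names(df)), "Ct table must have columns: %s",
              paste(req, collapse = ", "))
  df
}
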