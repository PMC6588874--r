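# Over-representation statistics for gene sets against term-to-gene maps.

#' Hypergeometric over-representation test
#'
#' For each term with at least one background gene: `k` = study genes in
#' the term, `K` = background genes in the term, `n` = study size, `N` =
#' background size; the p-value is the upper hypergeometric tail
#' `P(X >= k)`. The optional EASE variant tests `P(X >= k)` with one study
#' hit removed (`k - 1`), a conservative adjustment used by some tools.
#' q-values are BH-adjusted across all tested terms.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`)
#' @param background character vector of background gene ids
#' @param term_map data.frame with columns `gene_id`, `term_id`,
#'   `term_name`, `namespace`
#' @param p_max significance threshold used by [namespace_summary()]
#'   consumers (stored on the result; default 0.05)
#' @param ease use the EASE-style `k - 1` tail (default FALSE)
#' @return data.frame of class `enrichment_table`, sorted by p:
#'   `term_id`, `term_name`, `namespace`, `k`, `K`, `n`, `N`, `p`, `q`
#' @export
enrich <- function(study, background, term_map, p_max = 0.05, ease = FALSE) {
  study <- unique(study); background <- unique(background)
  offenders <- setdiff(study, background)
  assert_that(length(offenders) == 0,
              "study gene(s) absent from background: %s",
              paste(head(offenders, 5), collapse = ", "))
  assert_that(nrow(term_map) > 0, "term map is empty")
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(study)
  terms <- unique(tm[, c("term_id", "term_name", "namespace")])
  genes_by_term <- split(tm$gene_id, tm$term_id)
  K <- vapply(genes_by_term[terms$term_id],
              function(g) length(unique(g)), numeric(1))
  k <- vapply(genes_by_term[terms$term_id],
              function(g) length(intersect(unique(g), study)), numeric(1))
  kk <- if (ease) pmax(k - 1, 0) else k
  p <- phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    namespace = terms$namespace, k = k, K = K, n = n, N = N,
                    p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_max") <- p_max
  structure(res, class = c("enrichment_table", "data.frame"))
}

#' Per-namespace tallies of enriched terms
#'
#' Counts terms per namespace and reports percentages of the reported
#' total, rounded to two decimals.
#'
#' @param records an `enrichment_table` (or any data.frame with
#'   `namespace` and `p`)
#' @param significant_only restrict to `p <= p_max` (default TRUE)
#' @param p_max threshold (default: the table's stored `p_max`, else 0.05)
#' @return data.frame with `namespace`, `count`, `percent`, plus
#'   attribute `total`
#' @export
namespace_summary <- function(records, significant_only = TRUE,
                              p_max = attr(records, "p_max") %||% 0.05) {
  if (significant_only) records <- records[records$p <= p_max, , drop = FALSE]
  if (!nrow(records)) {
    out <- data.frame(namespace = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- table(records$namespace)
  out <- data.frame(namespace = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$namespace), , drop = FALSE]
  total <- sum(out$count)
  out$percent <- round(100 * out$count / total, 2)
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}

#' Read a term-to-gene map TSV
#' @param path TSV with columns gene_id, term_id, term_name, namespace
#' @return data.frame
#' @export
read_term_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "term_id", "term_name", "namespace")
  assert_that(all(req %in% names(df)),
              "term map must have columns: %s", paste(req, collapse = ", "))
  df
}
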