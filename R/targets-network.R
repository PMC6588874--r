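# Cis (genomic window) and trans (Pearson co-expression) target
# prediction, and bipartite network construction/export.

#' Cis targets of lncRNA loci
#'
#' Pairs every lncRNA locus with every coding-gene locus on the same
#' chromosome whose gap distance lies in `[min_dist, max_dist]`
#' (inclusive at both ends). Gap distance is 0 when the spans overlap and
#' otherwise the number of bases between the nearest feature ends. The
#' signed distance reports the gene's position relative to the lncRNA in
#' reference-forward coordinates: negative when the gene lies upstream
#' (left) of the lncRNA. Output ordering is deterministic (lnc id, then
#' distance).
#'
#' @param lnc_loci,gene_loci data.frames with columns `id`, `chrom`,
#'   `start`, `end` (0-based half-open spans)
#' @param min_dist,max_dist window bounds in bp (defaults 10 kb and
#'   100 kb); setting `min_dist = 0` reproduces the common "within
#'   `max_dist`" alternative
#' @return data.frame with `lnc_id`, `gene_id`, `mode` (= "cis"),
#'   `distance` (signed bp)
#' @export
cis_targets <- function(lnc_loci, gene_loci, min_dist = 10000,
                        max_dist = 100000) {
  assert_that(min_dist < max_dist, "min_dist must be < max_dist")
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(lnc_loci) || !nrow(gene_loci)) return(empty)
  out <- list()
  for (i in seq_len(nrow(lnc_loci))) {
    g <- gene_loci[gene_loci$chrom == lnc_loci$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    ls <- lnc_loci$start[i]; le <- lnc_loci$end[i]
    gap_left <- ls - g$end      # > 0 when gene entirely upstream
    gap_right <- g$start - le   # > 0 when gene entirely downstream
    d <- pmax(gap_left, gap_right, 0)
    signed <- ifelse(gap_left > 0, -d, d)
    keep <- d >= min_dist & d <= max_dist
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        lnc_id = lnc_loci$id[i], gene_id = g$id[keep], mode = "cis",
        distance = signed[keep], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$lnc_id, res$distance, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pearson correlation with t-distribution p-value
#'
#' Standard product-moment coefficient; the two-sided p-value comes from
#' `t = r * sqrt((n - 2)/(1 - r^2))` against a t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`
#' @return list with `r` and `p` (`NA` with a warning when either vector
#'   has zero variance)
#' @export
pearson_cor <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warnf("pearson_cor: zero variance; result undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

#' Trans targets by expression correlation
#'
#' Tests all lncRNA x gene pairs on (by default) log2(FPKM + 1) expression
#' and emits pairs with `r >= r_min` (or `|r| >= r_min` when
#' `use_absolute`) and `p < p_max` (strict). Zero-variance rows are
#' skipped with a logged count; no multiple-testing correction is applied
#' to the correlation p-values.
#'
#' @param expr expression matrix, genes x samples (>= 3 samples)
#' @param lnc_ids,gene_ids row names to pair
#' @param r_min correlation threshold (default 0.95)
#' @param p_max p-value threshold, strict (default 0.05)
#' @param use_absolute test `|r|` instead of signed `r` (default FALSE)
#' @param transform `"log2"` (default, log2(x + 1)) or `"none"`
#' @return data.frame with `lnc_id`, `gene_id`, `mode` (= "trans"), `r`,
#'   `p`, ordered by lnc id then decreasing r
#' @export
trans_targets <- function(expr, lnc_ids, gene_ids, r_min = 0.95,
                          p_max = 0.05, use_absolute = FALSE,
                          transform = c("log2", "none")) {
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  assert_that(ncol(expr) >= 3, "trans_targets needs >= 3 samples")
  missing <- setdiff(c(lnc_ids, gene_ids), rownames(expr))
  assert_that(length(missing) == 0, "ids absent from matrix: %s",
              paste(head(missing, 3), collapse = ", "))
  if (transform == "log2") expr <- log2(expr + 1)
  lx <- t(expr[lnc_ids, , drop = FALSE])
  gx <- t(expr[gene_ids, , drop = FALSE])
  sd_l <- apply(lx, 2, sd); sd_g <- apply(gx, 2, sd)
  n_skip <- sum(sd_l == 0) + sum(sd_g == 0)
  if (n_skip) msgf("trans_targets: skipped %d zero-variance row(s)", n_skip)
  lx <- lx[, sd_l > 0, drop = FALSE]; gx <- gx[, sd_g > 0, drop = FALSE]
  empty <- data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), r = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  if (!ncol(lx) || !ncol(gx)) return(empty)
  n <- nrow(lx)
  R <- cor(lx, gx)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, 1e-300))
  P <- 2 * pt(-abs(tstat), df = n - 2)
  P[abs(R) >= 1] <- 0
  pass <- (if (use_absolute) abs(R) else R) >= r_min & P < p_max
  idx <- which(pass, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  res <- data.frame(lnc_id = colnames(lx)[idx[, 1]],
                    gene_id = colnames(gx)[idx[, 2]],
                    mode = "trans", r = R[idx], p = P[idx],
                    stringsAsFactors = FALSE)
  res <- res[res$lnc_id != res$gene_id, , drop = FALSE]  # no self-loops
  res <- res[order(res$lnc_id, -res$r, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a bipartite lncRNA-gene interaction network
#'
#' Nodes are typed (`lncRNA` / `gene`); edges carry the pair attributes
#' (`mode`, `r`, `p`, `distance`). Self-loops are disallowed by
#' construction of the pair tables. An id appearing in both columns (a
#' lncRNA targeted as a gene) is rejected, preserving bipartiteness.
#'
#' @param pairs data.frame from [cis_targets()] and/or [trans_targets()]
#'   (rbind-compatible; missing attribute columns are filled with `NA`)
#' @return an [igraph::graph] with vertex attribute `node_type`
#' @export
build_network <- function(pairs) {
  for (col in c("r", "p", "distance"))
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  both <- intersect(unique(pairs$lnc_id), unique(pairs$gene_id))
  assert_that(length(both) == 0,
              "id(s) appear as both lncRNA and gene: %s",
              paste(head(both, 3), collapse = ", "))
  verts <- data.frame(
    name = c(unique(pairs$lnc_id), unique(pairs$gene_id)),
    node_type = c(rep("lncRNA", length(unique(pairs$lnc_id))),
                  rep("gene", length(unique(pairs$gene_id)))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    pairs[, c("lnc_id", "gene_id", "mode", "r", "p", "distance")],
    directed = FALSE, vertices = verts)
}

#' Export a network as SIF or GraphML
#' @param net igraph network from [build_network()]
#' @param path output file
#' @param format `"sif"` (tab-separated `lnc interacts gene`) or
#'   `"graphml"`
#' @return `path`, invisibly
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stopf("unknown network format '%s'; supported: sif, graphml",
          format[1]))
  if (format == "sif") {
    el <- igraph::as_edgelist(net)
    writeLines(sprintf("%s\tinteracts\t%s", el[, 1], el[, 2]), path)
  } else {
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a SIF edge list
#' @param path SIF file
#' @return data.frame with `lnc_id`, `gene_id`
#' @export
read_sif <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  data.frame(lnc_id = vapply(f, `[`, character(1), 1L),
             gene_id = vapply(f, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Top network hubs by degree
#' @param net igraph network
#' @param k number of nodes to report (default 10)
#' @return data.frame with `id`, `node_type`, `degree`, decreasing degree
#' @export
hub_report <- function(net, k = 10) {
  deg <- igraph::degree(net)
  ord <- order(-deg, names(deg))
  data.frame(id = names(deg)[ord],
             node_type = igraph::vertex_attr(net, "node_type")[ord],
             degree = unname(deg[ord]),
             stringsAsFactors = FALSE)[seq_len(min(k, length(deg))), ]
}
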