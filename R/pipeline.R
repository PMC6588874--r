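# Pipeline orchestration: simulate -> qc -> discover -> fpkm/de ->
# targets -> enrich, plus the summary report.

#' Default pipeline configuration
#'
#' A single flat configuration covering every stage. Stage sections may be
#' overridden individually; `simulate` holds a [synthetic_config()] (the
#' pipeline's input generator), `de` the significance thresholds, `cis`
#' and `trans` the target-prediction windows/thresholds.
#'
#' @param out_dir output directory for all stage files
#' @param seed master seed (propagated into the synthetic config)
#' @param ... overrides for elements of the returned list
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("lncweave_run_"), seed = 1,
                            ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    simulate = synthetic_config(seed = seed),
    qc = list(max_n_frac = 0.10, low_q = 5, max_lowq_frac = 0.50),
    cascade = cascade_params(),
    de = list(fdr_max = 0.05, lfc_min = 1),
    cis = list(min_dist = 10000, max_dist = 100000),
    trans = list(r_min = 0.95, p_max = 0.05, use_absolute = FALSE),
    enrich = list(p_max = 0.05))
  dots <- list(...)
  cfg[names(dots)] <- dots
  assert_that(cfg$de$fdr_max > 0 && cfg$de$fdr_max <= 1 &&
              cfg$de$lfc_min >= 0, "invalid DE thresholds")
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(synthetic_config, y$simulate %||% list(seed = y$seed %||% 1))
  casc <- do.call(cascade_params, y$cascade %||% list())
  y$simulate <- NULL; y$cascade <- NULL
  do.call(pipeline_config, c(y, list(simulate = sim, cascade = casc)))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$simulate <- unclass(y$simulate)
  y$cascade <- unclass(y$cascade)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the stages in order -- simulate, read QC, discovery cascade,
#' FPKM + differential expression, cis/trans target prediction, network,
#' enrichment -- writing each stage's outputs under `config$out_dir` and
#' returning the summary report plus stage results. All randomness derives
#' from `config$seed`, so a rerun with the same config reproduces every
#' output byte for byte.
#'
#' @param config a [pipeline_config()]
#' @param term_map optional term-to-gene map for the enrichment stage; by
#'   default a synthetic map is built over the simulated genes
#' @return list of class `pipeline_result` with elements `report` (see
#'   [summary_report()]), `annotation`, `assembly`, `catalog`, `qc`,
#'   `counts`, `fpkm`, `de`, `de_summary`, `cis`, `trans`, `network`,
#'   `enrichment`
#' @export
run_pipeline <- function(config = pipeline_config(), term_map = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$simulate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ann <- stage("simulate", gen_annotation(scfg))
  assembly <- stage("simulate", gen_assembly(scfg, ann))
  hits <- stage("simulate", gen_hits(scfg, ann$truth))
  write_gtf(ann$reference, file.path(config$out_dir, "reference.gtf"))
  write_fasta(ann$genome, file.path(config$out_dir, "genome.fa"))
  write_gtf(assembly, file.path(config$out_dir, "assembly.gtf"))
  write_fasta(assembly$sequences, file.path(config$out_dir, "assembly.fa"))
  write_hits(hits$known_lnc_hits, file.path(config$out_dir, "known_lnc_hits.tsv"))
  write_hits(hits$protein_hits, file.path(config$out_dir, "protein_hits.tsv"))

  reads <- stage("simulate", gen_reads(scfg))
  qc <- stage("qc", filter_reads(reads$reads, do.call(qc_thresholds,
              c(list(adaptor = scfg$adaptor), config$qc))))

  catalog <- stage("discover", discover_lncrnas(
    assembly, ann$reference, hits$known_lnc_hits, hits$protein_hits,
    params = config$cascade))
  write_catalog(catalog, file.path(config$out_dir, "catalog.tsv"))

  # expression: reference coding genes + known + novel lncRNAs
  lnc_ids <- c(catalog$transcript_id[catalog$status == "known_lncRNA"],
               catalog$transcript_id[catalog$status == "novel_lncRNA"])
  coding_ids <- ann$reference$tx$transcript_id[
    ann$reference$tx$biotype == "protein_coding"]
  sim_counts <- stage("simulate",
                      gen_counts(scfg, c(coding_ids, lnc_ids), lnc_ids))
  write_counts(sim_counts$counts, file.path(config$out_dir, "counts.tsv"))
  expr <- stage("fpkm", fpkm(sim_counts$counts, sim_counts$lengths))
  write_counts(round(expr, 4), file.path(config$out_dir, "fpkm.tsv"))

  cmps <- utils::combn(scfg$groups, 2, simplify = FALSE)
  de <- stage("de", call_de(sim_counts$counts, sim_counts$groups, cmps,
                            fdr_max = config$de$fdr_max,
                            lfc_min = config$de$lfc_min))
  write.table(de, file.path(config$out_dir, "de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  de_sum <- summarize_de(de, catalog)

  # targets of DE lncRNAs
  de_lncs <- intersect(unique(de$gene_id[de$call != "ns"]), lnc_ids)
  all_feats <- rbind(ann$reference$tx, assembly$tx[, names(ann$reference$tx)])
  loci <- function(ids) data.frame(id = ids,
    chrom = all_feats$chrom[match(ids, all_feats$transcript_id)],
    start = all_feats$span_start[match(ids, all_feats$transcript_id)],
    end = all_feats$span_end[match(ids, all_feats$transcript_id)],
    stringsAsFactors = FALSE)
  cis <- stage("targets", cis_targets(loci(de_lncs), loci(coding_ids),
                                      config$cis$min_dist, config$cis$max_dist))
  trans <- stage("targets", trans_targets(
    expr, lnc_ids, coding_ids, r_min = config$trans$r_min,
    p_max = config$trans$p_max, use_absolute = config$trans$use_absolute))
  pairs <- rbind(
    if (nrow(cis)) cbind(cis, r = NA_real_, p = NA_real_) else NULL,
    if (nrow(trans)) cbind(trans, distance = NA_real_)[, c(
      "lnc_id", "gene_id", "mode", "distance", "r", "p")] else NULL)
  if (is.null(pairs))
    pairs <- data.frame(lnc_id = character(), gene_id = character(),
                        mode = character(), distance = numeric(),
                        r = numeric(), p = numeric())
  if (!("distance" %in% names(pairs)) && nrow(pairs))
    pairs$distance <- NA_real_
  write.table(pairs, file.path(config$out_dir, "target_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  network <- if (nrow(pairs)) stage("network", build_network(pairs)) else NULL
  if (!is.null(network)) {
    export_network(network, file.path(config$out_dir, "network.sif"), "sif")
    export_network(network, file.path(config$out_dir, "network.graphml"),
                   "graphml")
  }

  # enrichment of DE mRNAs against all simulated coding genes
  if (is.null(term_map))
    term_map <- synthetic_term_map(coding_ids, seed = sub_seed(scfg$seed, 6))
  de_mrnas <- intersect(unique(de$gene_id[de$call != "ns"]), coding_ids)
  enr <- NULL
  if (length(de_mrnas) >= 1)
    enr <- stage("enrich", enrich(de_mrnas, coding_ids, term_map,
                                  p_max = config$enrich$p_max))

  report <- summary_report(qc$report, catalog, de, de_sum, cis, trans,
                           network, enr)
  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  res <- list(report = report, annotation = ann, assembly = assembly,
              catalog = catalog, qc = qc, counts = sim_counts, fpkm = expr,
              de = de, de_summary = de_sum, cis = cis, trans = trans,
              network = network, enrichment = enr)
  class(res) <- "pipeline_result"
  res
}

#' Synthetic term-to-gene map
#'
#' Random GO/pathway-style term assignments over a gene universe, used as
#' the default enrichment input in synthetic runs.
#'
#' @param gene_ids gene universe
#' @param n_terms number of terms
#' @param seed RNG seed
#' @return data.frame in the [read_term_map()] schema
#' @export
synthetic_term_map <- function(gene_ids, n_terms = 30, seed = 1) {
  with_seed(seed, {
    ns <- c("biological_process", "cellular_component", "molecular_function",
            "pathway")
    rows <- lapply(seq_len(n_terms), function(i) {
      size <- sample(3:max(4, length(gene_ids) %/% 3), 1)
      data.frame(gene_id = sample(gene_ids, min(size, length(gene_ids))),
                 term_id = sprintf("T%04d", i),
                 term_name = sprintf("term %d", i),
                 namespace = ns[(i - 1) %% length(ns) + 1],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Distinct DE tallies and known/novel split across comparisons
#'
#' @param de a `de_table` from [call_de()]
#' @param catalog optional `lnc_catalog` used to split DE genes into
#'   known/novel lncRNAs and other (mRNA) genes
#' @return list with `per_comparison` (data.frame comparison/up/down),
#'   `distinct_total`, `distinct_up`, `distinct_down`, `intersections`
#'   (named counts of genes significant in 1, 2, 3... comparisons and the
#'   all-comparison intersection), and when a catalog is given
#'   `n_de_known_lnc`, `n_de_novel_lnc`, `n_de_lnc`, `n_de_other`
#' @export
summarize_de <- function(de, catalog = NULL) {
  sig <- de[de$call != "ns", , drop = FALSE]
  cmps <- unique(de$comparison)
  per_cmp <- data.frame(
    comparison = cmps,
    up = vapply(cmps, function(cm) sum(sig$comparison == cm & sig$call == "up"),
                numeric(1)),
    down = vapply(cmps, function(cm) sum(sig$comparison == cm &
                                         sig$call == "down"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  genes <- unique(sig$gene_id)
  n_in <- vapply(genes, function(g) length(unique(sig$comparison[sig$gene_id == g])),
                 numeric(1))
  inter <- table(factor(n_in, levels = seq_along(cmps)))
  out <- list(per_comparison = per_cmp,
              distinct_total = length(genes),
              distinct_up = length(unique(sig$gene_id[sig$call == "up"])),
              distinct_down = length(unique(sig$gene_id[sig$call == "down"])),
              intersections = setNames(as.integer(inter),
                                       paste0("in_", seq_along(cmps))),
              all_comparisons = sum(n_in == length(cmps)))
  if (!is.null(catalog)) {
    status <- setNames(catalog$status, catalog$transcript_id)
    st <- status[genes]
    out$n_de_known_lnc <- sum(!is.na(st) & st == "known_lncRNA")
    out$n_de_novel_lnc <- sum(!is.na(st) & st == "novel_lncRNA")
    out$n_de_lnc <- out$n_de_known_lnc + out$n_de_novel_lnc
    out$n_de_other <- length(genes) - out$n_de_lnc
  }
  out
}

#' Assemble the pipeline summary report
#'
#' All percentages are recomputed from the counts with [pct()] at print
#' time; none is stored independently.
#'
#' @param qc_report,catalog,de,de_summary,cis,trans,network,enrichment
#'   stage outputs (any may be `NULL` where a stage did not run)
#' @return list of class `summary_report`
#' @export
summary_report <- function(qc_report = NULL, catalog = NULL, de = NULL,
                           de_summary = NULL, cis = NULL, trans = NULL,
                           network = NULL, enrichment = NULL) {
  rep <- list()
  if (!is.null(qc_report))
    rep$reads <- list(n_raw = qc_report$n_raw, n_clean = qc_report$n_clean,
                      failures = qc_report$failures)
  if (!is.null(catalog)) {
    cc <- catalog_counts(catalog)
    rep$lncRNA <- list(n_transcripts = nrow(catalog),
                       n_known = unname(cc["known_lncRNA"]),
                       n_novel = unname(cc["novel_lncRNA"]),
                       rejected = cc[!(names(cc) %in%
                                       c("known_lncRNA", "novel_lncRNA"))])
  }
  if (!is.null(de_summary)) rep$de <- de_summary
  if (!is.null(cis))
    rep$cis <- list(n_pairs = nrow(cis),
                    n_lncs = length(unique(cis$lnc_id)),
                    n_genes = length(unique(cis$gene_id)))
  if (!is.null(trans))
    rep$trans <- list(n_pairs = nrow(trans),
                      n_lncs = length(unique(trans$lnc_id)),
                      n_genes = length(unique(trans$gene_id)))
  if (!is.null(network))
    rep$network <- list(n_nodes = igraph::vcount(network),
                        n_edges = igraph::ecount(network),
                        top_hubs = hub_report(network, 5))
  if (!is.null(enrichment))
    rep$enrichment <- list(n_terms_tested = nrow(enrichment),
                           namespaces = namespace_summary(enrichment))
  class(rep) <- "summary_report"
  rep
}

#' Known/novel percentage split
#'
#' Recomputes the known/novel percentages of a lncRNA set from its two
#' counts (e.g. 4252 known and 72907 novel give 5.5% and 94.5% of a
#' 77159 total).
#'
#' @param n_known,n_novel counts
#' @param digits rounding (default 1)
#' @return list with `total`, `known_pct`, `novel_pct`
#' @export
known_novel_split <- function(n_known, n_novel, digits = 1) {
  total <- n_known + n_novel
  list(total = total, known_pct = pct(n_known, total, digits),
       novel_pct = pct(n_novel, total, digits))
}

#' Render a summary report as text lines
#' @param report a `summary_report`
#' @return character vector of lines
#' @export
format_report <- function(report) {
  out <- c("lncweave pipeline summary", "=========================")
  if (!is.null(report$reads)) {
    r <- report$reads
    out <- c(out, sprintf("reads: %d raw, %d clean (%.2f%%)", r$n_raw,
                          r$n_clean, pct(r$n_clean, r$n_raw, 2)),
             sprintf("  failed: %s", paste(names(r$failures), r$failures,
                                           sep = "=", collapse = ", ")))
  }
  if (!is.null(report$lncRNA)) {
    l <- report$lncRNA
    split <- known_novel_split(l$n_known, l$n_novel)
    out <- c(out, sprintf(
      "lncRNAs: %d known (%.1f%%), %d novel (%.1f%%) of %d; rejected: %s",
      l$n_known, split$known_pct, l$n_novel, split$novel_pct, split$total,
      paste(names(l$rejected), l$rejected, sep = "=", collapse = ", ")))
  }
  if (!is.null(report$de)) {
    d <- report$de
    out <- c(out, sprintf("DE: %d distinct significant genes (%d up, %d down)",
                          d$distinct_total, d$distinct_up, d$distinct_down),
             sprintf("  %s: %d up / %d down", d$per_comparison$comparison,
                     d$per_comparison$up, d$per_comparison$down))
    if (!is.null(d$n_de_lnc))
      out <- c(out, sprintf("  lncRNAs: %d (%d known + %d novel), other: %d",
                            d$n_de_lnc, d$n_de_known_lnc, d$n_de_novel_lnc,
                            d$n_de_other))
  }
  if (!is.null(report$cis))
    out <- c(out, sprintf("cis: %d pairs (%d lncRNAs, %d genes)",
                          report$cis$n_pairs, report$cis$n_lncs,
                          report$cis$n_genes))
  if (!is.null(report$trans))
    out <- c(out, sprintf("trans: %d pairs (%d lncRNAs, %d genes)",
                          report$trans$n_pairs, report$trans$n_lncs,
                          report$trans$n_genes))
  if (!is.null(report$network))
    out <- c(out, sprintf("network: %d nodes, %d edges",
                          report$network$n_nodes, report$network$n_edges))
  if (!is.null(report$enrichment)) {
    ns <- report$enrichment$namespaces
    out <- c(out, sprintf("enrichment: %d terms tested; significant by namespace: %s",
                          report$enrichment$n_terms_tested,
                          if (nrow(ns)) paste(sprintf("%s %d (%.2f%%)",
                                                      ns$namespace, ns$count,
                                                      ns$percent),
                                              collapse = ", ") else "none"))
  }
  out
}

#' @export
print.summary_report <- function(x, ...) {
  writeLines(format_report(x)); invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report); invisible(x)
}
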