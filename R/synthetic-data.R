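# Synthetic-data generators: every input the pipeline consumes, with
# planted ground truth, emulating a three-group (black/white/red skin),
# three-replicate RNA-seq study design on a toy genome.

#' Synthetic study configuration
#'
#' Defaults mirror the emulated study design: three groups (BS, WS, RS)
#' with three replicates each, an assembly of roughly 500 transcripts in
#' which each cascade filter has a dedicated planted decoy class, planted
#' differential expression at `|log2FC| = de_log2fc`, and planted
#' trans-correlated lncRNA-gene pairs built from a shared latent profile.
#'
#' @param n_chroms,chrom_len chromosome count and length (bp)
#' @param gc_content genome GC fraction target
#' @param n_coding_genes,n_known_lncs reference annotation composition
#' @param n_novel_lncs planted intergenic novel lncRNAs (>= 200 nt, no
#'   ORF, noncoding composition)
#' @param n_decoys_short intergenic decoys with spliced length < 200 nt
#' @param n_decoys_coding intergenic decoys whose whole sequence is an
#'   ORF > 300 nt
#' @param n_decoys_overlap decoys overlapping annotated lncRNA exons
#'   (class code not `u`)
#' @param n_decoys_protein noncoding decoys listed in the protein hit
#'   table at E <= 1e-5
#' @param n_decoys_score decoys with a 300 nt ORF, high ORF coverage and
#'   coding-biased composition (rejected by the coding score alone)
#' @param n_decoys_biotype assembly copies of protein-coding reference
#'   transcripts (rejected by biotype)
#' @param groups,reps_per_group sample design (default 3 x 3)
#' @param de_fraction,de_log2fc,nb_dispersion count-model parameters
#' @param libsize_spread lognormal sd of per-sample library-size factors
#'   (the emulated study does not state its spread; exposed rather than
#'   guessed)
#' @param n_trans_pairs,target_r,trans_sd_log2 planted trans-pair count,
#'   latent-profile correlation and log2-scale latent sd
#' @param cis_offsets bp gap offsets at which a coding gene is planted
#'   next to one designated lncRNA locus per offset
#' @param n_reads,read_len,adaptor,frac_adaptor,frac_n,frac_lowq read
#'   simulation parameters for the QC stage
#' @param seed master RNG seed; identical configs give byte-identical
#'   outputs
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(
    n_chroms = 3, chrom_len = 2e6, gc_content = 0.45,
    n_coding_genes = 60, n_known_lncs = 40, n_novel_lncs = 300,
    n_decoys_short = 40, n_decoys_coding = 40, n_decoys_overlap = 30,
    n_decoys_protein = 30, n_decoys_score = 10, n_decoys_biotype = 20,
    groups = c("BS", "WS", "RS"), reps_per_group = 3,
    de_fraction = 0.1, de_log2fc = 2, nb_dispersion = 0.1,
    libsize_spread = 0.1,
    n_trans_pairs = 30, target_r = 0.99, trans_sd_log2 = 1.2,
    cis_offsets = c(15000, 50000, 100000),
    n_reads = 600, read_len = 100, adaptor = "AGATCGGAAGAGC",
    frac_adaptor = 0.013, frac_n = 0.013, frac_lowq = 0.014,
    seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_chroms = n_chroms, chrom_len = chrom_len,
              n_coding_genes = n_coding_genes, n_known_lncs = n_known_lncs,
              n_novel_lncs = n_novel_lncs, n_decoys_short = n_decoys_short,
              n_decoys_coding = n_decoys_coding,
              n_decoys_overlap = n_decoys_overlap,
              n_decoys_protein = n_decoys_protein,
              n_decoys_score = n_decoys_score,
              n_decoys_biotype = n_decoys_biotype,
              reps_per_group = reps_per_group, n_trans_pairs = n_trans_pairs,
              n_reads = n_reads)
  assert_that(all(counts >= 0), "all counts must be >= 0")
  assert_that(de_log2fc >= 0, "de_log2fc must be >= 0")
  assert_that(target_r > 0 && target_r <= 1, "target_r must be in (0, 1]")
  assert_that(nb_dispersion >= 0, "nb_dispersion must be >= 0")
  assert_that(n_chroms >= 1 && length(groups) >= 2, "need chromosomes and >= 2 groups")
  structure(cfg, class = "synthetic_config")
}

# -- sequence design ---------------------------------------------------------

rand_dna <- function(n, probs = c(A = 0.275, C = 0.225, G = 0.225, T = 0.275)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Noncoding sequence: no ATG on either strand (CAT forward = ATG reverse),
# hence no ORF at all; slightly AT-rich.
rand_noncoding <- function(n) {
  s <- rand_dna(n, c(A = 0.30, C = 0.20, G = 0.20, T = 0.30))
  while (grepl("ATG", s, fixed = TRUE) || grepl("CAT", s, fixed = TRUE)) {
    s <- gsub("ATG", "ACG", s, fixed = TRUE)
    s <- gsub("CAT", "CGT", s, fixed = TRUE)
  }
  s
}

# Coding sequence of length n (multiple of 3): ATG + sense codons + TGA;
# the whole sequence is one ORF of length n.
rand_coding <- function(n) {
  stopifnot(n %% 3 == 0, n >= 9)
  cu <- codon_usage()
  codons <- sample(names(cu), n / 3 - 2, replace = TRUE, prob = cu)
  paste0("ATG", paste(codons, collapse = ""), "TGA")
}

# Score decoy: noncoding flanks around a 300 nt ORF; rejection-sampled so
# the longest ORF on either strand is exactly 300 nt.
rand_score_decoy <- function(total_len = 312, orf_len = 300) {
  flank <- total_len - orf_len
  left <- flank %/% 2; right <- flank - left
  repeat {
    s <- paste0(rand_noncoding(left), rand_coding(orf_len), rand_noncoding(right))
    if (longest_orf_length(s) == orf_len) return(s)
  }
}

# -- layout ------------------------------------------------------------------

# Allocate loci for every reference and assembly feature along the
# chromosomes: cursor-based sequential placement with inter-feature gaps,
# exact-gap placement for cis-designated neighbors, and deliberate exon
# overlap for the overlap decoys.
build_layout <- function(config) {
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  cursor <- setNames(rep(1000, config$n_chroms), chroms)
  gap_min <- 800; gap_max <- 1500
  feats <- list(); exons <- list()
  chrom_i <- 0L

  place <- function(kind, id, exon_lens, intron_lens, strand, chrom = NULL,
                    at = NULL) {
    if (is.null(chrom)) {
      chrom_i <<- chrom_i %% config$n_chroms + 1L
      chrom <- chroms[chrom_i]
    }
    start <- if (is.null(at))
      cursor[[chrom]] + round(runif(1, gap_min, gap_max)) else at
    span <- sum(exon_lens) + sum(intron_lens)
    if (start + span > config$chrom_len)
      stopf("chromosome %s too short to place feature '%s' (%s): need %d bp beyond position %d",
            chrom, id, kind, span, start)
    es <- start + cumsum(c(0, head(exon_lens, -1) + intron_lens))
    exons[[length(exons) + 1]] <<- data.frame(
      chrom = chrom, start = es, end = es + exon_lens, strand = strand,
      transcript_id = id, gene_id = sub("^t_", "g_", id),
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1]] <<- data.frame(
      kind = kind, id = id, chrom = chrom, start = start,
      end = start + span, strand = strand, stringsAsFactors = FALSE)
    if (is.null(at) || start + span > cursor[[chrom]])
      cursor[[chrom]] <<- start + span
    invisible(NULL)
  }
  strand_of <- function() sample(c("+", "-"), 1)

  mult3 <- function(n) n - n %% 3
  for (i in seq_len(config$n_coding_genes)) {
    lens <- c(150, mult3(round(runif(1, 350, 550))), 150)  # total %% 3 == 0
    place("coding", sprintf("t_pc%03d", i), lens, c(200, 200), strand_of())
  }
  for (i in seq_len(config$n_known_lncs)) {
    lens <- c(200, round(runif(1, 150, 350)))
    place("known_lnc", sprintf("t_klnc%03d", i), lens, 300, strand_of())
  }
  n_cis <- length(config$cis_offsets)
  for (i in seq_len(config$n_novel_lncs)) {
    k <- sample(1:3, 1)
    lens <- round(runif(k, 120, 250)) + 80
    place("novel_lnc", sprintf("t_nov%03d", i), lens,
          if (k > 1) rep(250, k - 1) else numeric(0), strand_of())
    if (i <= n_cis) {
      # plant a coding neighbor at an exact gap from this lncRNA's end
      f <- feats[[length(feats)]]
      lens2 <- c(150, mult3(round(runif(1, 350, 550))), 150)
      place("cis_gene", sprintf("t_cis%02d", i), lens2, c(200, 200),
            strand_of(), chrom = f$chrom, at = f$end + config$cis_offsets[i])
    }
  }
  for (i in seq_len(config$n_decoys_short))
    place("decoy_short", sprintf("t_dsh%03d", i),
          round(runif(1, 120, 199)), numeric(0), strand_of())
  for (i in seq_len(config$n_decoys_coding))
    place("decoy_coding", sprintf("t_dco%03d", i),
          mult3(round(runif(1, 400, 600))), numeric(0), strand_of())
  for (i in seq_len(config$n_decoys_protein))
    place("decoy_protein", sprintf("t_dpr%03d", i),
          round(runif(1, 220, 500)), numeric(0), strand_of())
  for (i in seq_len(config$n_decoys_score))
    place("decoy_score", sprintf("t_dsc%03d", i), 312, numeric(0), strand_of())

  feats_df <- do.call(rbind, feats)
  exons_df <- do.call(rbind, exons)

  # overlap decoys: single exon straddling a known lncRNA's first exon
  if (config$n_decoys_overlap > 0) {
    kl <- feats_df[feats_df$kind == "known_lnc", , drop = FALSE]
    assert_that(nrow(kl) > 0,
                "n_decoys_overlap > 0 requires n_known_lncs > 0")
    for (i in seq_len(config$n_decoys_overlap)) {
      host <- kl[(i - 1) %% nrow(kl) + 1, ]
      hex <- exons_df[exons_df$transcript_id == host$id, ][1, ]
      id <- sprintf("t_dov%03d", i)
      exons_df <- rbind(exons_df, data.frame(
        chrom = hex$chrom, start = hex$start + 40, end = hex$end + 120,
        strand = hex$strand, transcript_id = id, gene_id = sub("^t_", "g_", id),
        stringsAsFactors = FALSE))
      feats_df <- rbind(feats_df, data.frame(
        kind = "decoy_overlap", id = id, chrom = hex$chrom,
        start = hex$start + 40, end = hex$end + 120, strand = hex$strand,
        stringsAsFactors = FALSE))
    }
  }
  # biotype decoys: exact assembly copies of coding reference transcripts
  if (config$n_decoys_biotype > 0) {
    pc <- feats_df[feats_df$kind == "coding", , drop = FALSE]
    assert_that(nrow(pc) > 0,
                "n_decoys_biotype > 0 requires n_coding_genes > 0")
    for (i in seq_len(config$n_decoys_biotype)) {
      host <- pc[(i - 1) %% nrow(pc) + 1, ]
      id <- sprintf("t_dbt%03d", i)
      hx <- exons_df[exons_df$transcript_id == host$id, , drop = FALSE]
      hx$transcript_id <- id; hx$gene_id <- sub("^t_", "g_", id)
      exons_df <- rbind(exons_df, hx)
      feats_df <- rbind(feats_df, data.frame(
        kind = "decoy_biotype", id = id, chrom = host$chrom,
        start = host$start, end = host$end, strand = host$strand,
        stringsAsFactors = FALSE))
    }
  }
  # assembly copies of known lncRNAs (assigned known via the hit table)
  if (config$n_known_lncs > 0) {
    kl <- feats_df[feats_df$kind == "known_lnc", , drop = FALSE]
    for (i in seq_len(nrow(kl))) {
      id <- sprintf("t_aklnc%03d", i)
      hx <- exons_df[exons_df$transcript_id == kl$id[i], , drop = FALSE]
      hx$transcript_id <- id; hx$gene_id <- sub("^t_", "g_", id)
      exons_df <- rbind(exons_df, hx)
      feats_df <- rbind(feats_df, data.frame(
        kind = "asm_known_lnc", id = id, chrom = kl$chrom[i],
        start = kl$start[i], end = kl$end[i], strand = kl$strand[i],
        stringsAsFactors = FALSE))
    }
  }
  rownames(feats_df) <- rownames(exons_df) <- NULL
  list(features = feats_df, exons = exons_df)
}

REFERENCE_KINDS <- c("coding", "cis_gene", "known_lnc")
ASSEMBLY_KINDS <- c("novel_lnc", "decoy_short", "decoy_coding",
                    "decoy_overlap", "decoy_protein", "decoy_score",
                    "decoy_biotype", "asm_known_lnc")

#' Generate the reference annotation, genome and ground truth
#'
#' Lays out every reference and assembly feature on the toy genome, writes
#' designed sequences into exon positions (strand-aware: minus-strand
#' features are embedded as the reverse complement), and returns the
#' reference annotation, genome and a ground-truth object from which
#' [gen_assembly()], [gen_hits()] and [gen_counts()] draw.
#'
#' @param config a [synthetic_config()]
#' @return list with `reference` (a [transcript_set()] of protein-coding
#'   genes, planted cis neighbors and known lncRNAs), `genome` (named
#'   character vector), and `truth` (list: `layout`, `novel_ids`,
#'   `rejected_ids_by_reason`, `known_ids`, `cis_pairs`,
#'   `designed_sequences`, `config`)
#' @export
gen_annotation <- function(config = synthetic_config()) {
  with_seed(sub_seed(config$seed, 1), {
    layout <- build_layout(config)
    feats <- layout$features
    exons <- layout$exons
    spl_len <- tapply(exons$end - exons$start, exons$transcript_id, sum)

    # designed spliced sequences (5'->3' on the feature strand)
    designed <- list()
    for (i in seq_len(nrow(feats))) {
      id <- feats$id[i]; kind <- feats$kind[i]
      n <- spl_len[[id]]
      designed[[id]] <- switch(
        kind,
        coding = , cis_gene = rand_coding(n),
        known_lnc = , novel_lnc = , decoy_protein = rand_noncoding(n),
        decoy_short = rand_noncoding(n),
        decoy_coding = rand_coding(n),
        decoy_score = rand_score_decoy(n, 300),
        NA_character_)  # overlap/copy features take the host's sequence
    }

    # genome: random background, then embed designed sequences; chromosomes
    # are held as per-base character vectors during embedding (string
    # replacement would copy the whole chromosome per exon) and pasted once
    gc <- config$gc_content
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
    genome_v <- lapply(chrom_names, function(ch)
      sample(names(base_probs), config$chrom_len, replace = TRUE,
             prob = base_probs))
    names(genome_v) <- chrom_names
    for (i in seq_len(nrow(feats))) {
      id <- feats$id[i]
      s <- designed[[id]]
      if (is.na(s)) next
      ex <- exons[exons$transcript_id == id, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      ch <- ex$chrom[1]
      if (feats$strand[i] == "-")
        ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]  # transcript order
      off <- 0
      for (j in seq_len(nrow(ex))) {
        len <- ex$end[j] - ex$start[j]
        piece <- substring(s, off + 1, off + len)
        if (feats$strand[i] == "-") piece <- revcomp(piece)
        genome_v[[ch]][(ex$start[j] + 1):ex$end[j]] <- strsplit(piece, "")[[1]]
        off <- off + len
      }
    }
    genome <- vapply(genome_v, paste, character(1), collapse = "")

    ref_ids <- feats$id[feats$kind %in% REFERENCE_KINDS]
    bt <- setNames(ifelse(
      feats$kind[feats$kind %in% REFERENCE_KINDS] == "known_lnc",
      "lncRNA", "protein_coding"), ref_ids)
    reference <- transcript_set(
      exons[exons$transcript_id %in% ref_ids, , drop = FALSE], biotype = bt)

    cis_pairs <- NULL
    n_cis <- min(length(config$cis_offsets), config$n_novel_lncs)
    if (n_cis > 0)
      cis_pairs <- data.frame(
        lnc_id = sprintf("t_nov%03d", seq_len(n_cis)),
        gene_id = sprintf("t_cis%02d", seq_len(n_cis)),
        offset = config$cis_offsets[seq_len(n_cis)],
        stringsAsFactors = FALSE)

    truth <- list(
      layout = layout,
      novel_ids = feats$id[feats$kind == "novel_lnc"],
      known_ids = feats$id[feats$kind == "asm_known_lnc"],
      rejected_ids_by_reason = list(
        biotype = feats$id[feats$kind == "decoy_biotype"],
        not_u = feats$id[feats$kind == "decoy_overlap"],
        too_short = feats$id[feats$kind == "decoy_short"],
        long_orf = feats$id[feats$kind == "decoy_coding"],
        protein_hit = feats$id[feats$kind == "decoy_protein"],
        coding_score = feats$id[feats$kind == "decoy_score"]),
      cis_pairs = cis_pairs,
      designed_sequences = designed,
      config = config)
    list(reference = reference, genome = genome, truth = truth)
  })
}

#' Generate the assembled transcript set
#'
#' Emits the assembly-side features of the layout (planted novel lncRNAs,
#' all decoy classes, and re-assembled copies of the known lncRNAs),
#' splicing their sequences out of the genome with strand-aware
#' reverse-complementation.
#'
#' @param config the [synthetic_config()] used for [gen_annotation()]
#' @param annotation the list returned by [gen_annotation()]
#' @return a [transcript_set()] with sequences
#' @export
gen_assembly <- function(config, annotation) {
  truth <- annotation$truth
  assert_that(identical(truth$config[names(config)], config[names(config)]),
              "config does not match the truth object (reference/truth mismatch)")
  feats <- truth$layout$features
  ids <- feats$id[feats$kind %in% ASSEMBLY_KINDS]
  assert_that(all(ids %in% truth$layout$exons$transcript_id),
              "truth layout is internally inconsistent")
  ts <- transcript_set(
    truth$layout$exons[truth$layout$exons$transcript_id %in% ids, ,
                       drop = FALSE])
  splice_sequences(ts, annotation$genome)
}

#' Generate the similarity hit tables
#'
#' The known-lncRNA table gives each re-assembled known lncRNA a strong
#' hit (E far below the 1e-10 assignment cutoff) plus weak, above-cutoff
#' hits for a few novel transcripts so the threshold is exercised. The
#' protein table gives every protein decoy a hit at E <= 1e-5 (one exactly
#' at the boundary) plus above-cutoff noise hits.
#'
#' @param config a [synthetic_config()]
#' @param truth the truth object from [gen_annotation()]
#' @return list with `known_lnc_hits` and `protein_hits` data.frames
#'   ([read_hits()] schema)
#' @export
gen_hits <- function(config, truth) {
  with_seed(sub_seed(config$seed, 2), {
    mk <- function(q, s, e) data.frame(
      query_id = q, subject_id = s,
      percent_identity = round(runif(length(q), 85, 100), 2),
      alignment_len = round(runif(length(q), 100, 400)),
      e_value = e, bit_score = round(-10 * log10(e + 1e-300)),
      stringsAsFactors = FALSE)
    known <- mk(truth$known_ids,
                sprintf("DR_NONC%05d", seq_along(truth$known_ids)),
                10^runif(length(truth$known_ids), -60, -20))
    # above-cutoff noise on a few novels: must NOT be assigned known
    n_noise <- min(5, length(truth$novel_ids))
    if (n_noise > 0)
      known <- rbind(known, mk(truth$novel_ids[seq_len(n_noise)],
                               sprintf("DR_NONCW%04d", seq_len(n_noise)),
                               10^runif(n_noise, -8, -3)))
    prot_ids <- truth$rejected_ids_by_reason$protein_hit
    prot_e <- 10^runif(length(prot_ids), -30, -6)
    if (length(prot_e)) prot_e[1] <- 1e-5   # inclusive-boundary control
    protein <- mk(prot_ids, sprintf("NR_%06d", seq_along(prot_ids)), prot_e)
    n_noise2 <- min(5, length(truth$novel_ids))
    if (n_noise2 > 0)
      protein <- rbind(protein,
                       mk(truth$novel_ids[seq_len(n_noise2)],
                          sprintf("NRW_%05d", seq_len(n_noise2)),
                          10^runif(n_noise2, -4, -2)))
    list(known_lnc_hits = known, protein_hits = protein)
  })
}

#' Generate an expected-count matrix with planted truth
#'
#' Negative-binomial counts for `gene_ids` across the configured group
#' design. A `de_fraction` of genes get one elevated group whose
#' configured mean is exactly `2^de_log2fc` times the baseline. Planted
#' trans pairs share a per-sample latent log2 profile with correlation
#' `target_r` between the two members (independent noise makes realized r
#' < 1, so the detection threshold is genuinely exercised); pair members
#' are excluded from the DE truth.
#'
#' @param config a [synthetic_config()]
#' @param gene_ids character vector of gene ids to simulate
#' @param lnc_ids subset of `gene_ids` eligible as trans-pair lncRNA
#'   members (default none, disabling trans planting)
#' @param base_mean median baseline expected count (default 100)
#' @return list with `counts` (matrix), `lengths` (bp, named), `groups`
#'   (per sample), `mu` (configured mean matrix), and `truth` (list:
#'   `de_ids_by_comparison` with per-gene direction, `elevated_group`,
#'   `trans_pairs`)
#' @export
gen_counts <- function(config, gene_ids, lnc_ids = character(0),
                       base_mean = 100) {
  assert_that(base_mean > 0, "base_mean must be > 0")
  with_seed(sub_seed(config$seed, 3), {
    groups <- rep(config$groups, each = config$reps_per_group)
    samples <- paste0(groups, "_", sequence(rep(config$reps_per_group,
                                                length(config$groups))))
    n_g <- length(gene_ids); n_s <- length(samples)
    lib <- rlnorm(n_s, 0, config$libsize_spread)

    base <- rlnorm(n_g, log(base_mean), 1)
    lengths <- setNames(round(runif(n_g, 300, 3000)), gene_ids)

    # trans pairs from a shared latent profile
    n_tp <- min(config$n_trans_pairs,
                length(lnc_ids) , max(0, (n_g - length(lnc_ids))))
    trans_pairs <- NULL
    mu_log2 <- matrix(log2(base), n_g, n_s, dimnames = list(gene_ids, samples))
    is_trans <- rep(FALSE, n_g)
    if (n_tp > 0) {
      lmem <- lnc_ids[seq_len(n_tp)]
      gpool <- setdiff(gene_ids, lnc_ids)
      gmem <- gpool[seq_len(n_tp)]
      trans_pairs <- data.frame(lnc_id = lmem, gene_id = gmem,
                                stringsAsFactors = FALSE)
      sig <- config$trans_sd_log2
      r <- config$target_r
      for (j in seq_len(n_tp)) {
        z <- rnorm(n_s)
        for (id in c(lmem[j], gmem[j])) {
          e <- rnorm(n_s)
          i <- match(id, gene_ids)
          # high baseline so count-level noise stays small next to the
          # latent profile; the realized r is then dominated by target_r
          mu_log2[i, ] <- log2(max(base[i], 3000)) +
            sig * (sqrt(r) * z + sqrt(1 - r) * e)
          is_trans[i] <- TRUE
        }
      }
    }

    # planted DE: one elevated group per DE gene, exact 2^lfc mean ratio
    eligible <- which(!is_trans)
    n_de <- round(config$de_fraction * n_g)
    de_idx <- eligible[seq_len(min(n_de, length(eligible)))]
    elevated <- setNames(rep(NA_character_, n_g), gene_ids)
    if (length(de_idx)) {
      elevated[de_idx] <- sample(config$groups, length(de_idx), replace = TRUE)
      for (i in de_idx) {
        cols <- groups == elevated[i]
        mu_log2[i, cols] <- mu_log2[i, cols] + config$de_log2fc
      }
    }

    mu <- 2^mu_log2
    phi <- ifelse(is_trans, min(config$nb_dispersion, 5e-4),
                  config$nb_dispersion)
    counts <- matrix(0L, n_g, n_s, dimnames = list(gene_ids, samples))
    for (s in seq_len(n_s)) {
      m <- mu[, s] * lib[s]
      counts[, s] <- if (config$nb_dispersion == 0) rpois(n_g, m) else
        rnbinom(n_g, size = 1 / phi, mu = m)
    }

    cmps <- utils::combn(config$groups, 2, simplify = FALSE)
    de_by_cmp <- lapply(cmps, function(cmp) {
      up <- gene_ids[!is.na(elevated) & elevated == cmp[1]]
      down <- gene_ids[!is.na(elevated) & elevated == cmp[2]]
      data.frame(gene_id = c(up, down),
                 direction = rep(c("up", "down"), c(length(up), length(down))),
                 stringsAsFactors = FALSE)
    })
    names(de_by_cmp) <- vapply(cmps, function(cmp)
      paste0(cmp[1], "_vs_", cmp[2]), character(1))

    list(counts = counts, lengths = lengths, groups = groups, mu = mu,
         truth = list(de_ids_by_comparison = de_by_cmp,
                      elevated_group = elevated,
                      trans_pairs = trans_pairs))
  })
}

#' @importFrom stats rpois
NULL

#' Generate FASTQ reads with planted QC labels
#'
#' Each read is labeled `pass` or with the single discard rule it
#' violates: `adaptor` (contains the adaptor substring), `N-fraction`
#' (strictly more than 10% N) or `low-quality` (strictly more than 50% of
#' bases at Phred <= 5). Passing reads are constructed at or below every
#' boundary (some carry exactly the threshold N fraction).
#'
#' @param config a [synthetic_config()]
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and
#'   `labels` (character vector)
#' @export
gen_reads <- function(config) {
  with_seed(sub_seed(config$seed, 4), {
    n <- config$n_reads; len <- config$read_len
    u <- runif(n)
    labels <- ifelse(u < config$frac_adaptor, "adaptor",
              ifelse(u < config$frac_adaptor + config$frac_n, "N-fraction",
              ifelse(u < config$frac_adaptor + config$frac_n + config$frac_lowq,
                     "low-quality", "pass")))
    qual_hi <- function(k) paste(rawToChar(as.raw(33 + sample(30:40, k,
                                 replace = TRUE))), collapse = "")
    qual_lo <- function(k) paste(rawToChar(as.raw(33 + sample(0:5, k,
                                 replace = TRUE))), collapse = "")
    max_n_ok <- floor(config$frac_n * 0 + 0.10 * len)  # boundary N count
    seqs <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      s <- rand_dna(len)
      while (grepl(config$adaptor, s, fixed = TRUE)) s <- rand_dna(len)
      q <- qual_hi(len)
      if (labels[i] == "adaptor") {
        pos <- sample(seq_len(len - nchar(config$adaptor) + 1), 1)
        substr(s, pos, pos + nchar(config$adaptor) - 1) <- config$adaptor
      } else if (labels[i] == "N-fraction") {
        k <- sample((max_n_ok + 1):min(len, max_n_ok + 20), 1)
        pos <- sample(len, k)
        for (p in pos) substr(s, p, p) <- "N"
      } else if (labels[i] == "low-quality") {
        k <- sample((floor(0.50 * len) + 1):len, 1)
        pos <- sort(sample(len, k))
        qv <- strsplit(q, "")[[1]]
        qv[pos] <- strsplit(qual_lo(k), "")[[1]]
        q <- paste(qv, collapse = "")
      } else if (runif(1) < 0.1) {
        # boundary control: exactly the tolerated N fraction must pass
        pos <- sample(len, max_n_ok)
        for (p in pos) substr(s, p, p) <- "N"
      }
      seqs[i] <- s; quals[i] <- q
    }
    list(reads = data.frame(id = sprintf("read%05d", seq_len(n)), seq = seqs,
                            qual = quals, stringsAsFactors = FALSE),
         labels = labels)
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Triplicate target Cts and duplicate-gene reference Cts (GAPDH and
#' beta-actin) for a set of groups (developmental stages by default), with
#' the target's true ddCt relative to the first (calibrator) group set by
#' `log2fc_by_group`.
#'
#' @param config a [synthetic_config()] (only the seed is used)
#' @param groups group labels; first is the intended calibrator
#' @param log2fc_by_group planted log2 fold change per group (0 for the
#'   calibrator)
#' @param n_samples_per_group biological replicates per group
#' @param ct_sd technical replicate noise (Ct units)
#' @return data.frame in the [ddct()] schema
#' @export
gen_ct_table <- function(config,
                         groups = c("Zy", "Cl", "BL", "Ga", "Ne", "Or", "Ha",
                                    "20pdh"),
                         log2fc_by_group = setNames(c(0, seq_along(groups)[-1] %% 3 - 1),
                                                    groups),
                         n_samples_per_group = 3, ct_sd = 0.05) {
  with_seed(sub_seed(config$seed, 5), {
    rows <- list()
    for (g in groups) for (r in seq_len(n_samples_per_group)) {
      s <- paste0(g, "_", r)
      ref_base <- c(GAPDH = 15, actb = 17)
      tgt_ct <- 24 - log2fc_by_group[[g]]    # lower Ct = higher expression
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, group = g, gene = "target1", role = "target",
        ct = rnorm(3, tgt_ct, ct_sd), stringsAsFactors = FALSE)
      for (rg in names(ref_base))
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, group = g, gene = rg, role = "reference",
          ct = rnorm(2, ref_base[[rg]], ct_sd), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
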