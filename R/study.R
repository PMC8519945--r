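# Orchestrated synthetic study: wires every generator into one coherent
# data set with a single planted-truth record, mirroring the structure of the
# real inputs (association signals + reference panel + annotation resources +
# cohorts) at roughly one tenth of their scale.

#' Simulate a complete synthetic study with planted ground truth
#'
#' Generates every input the pipeline consumes: an LD-structured genotype
#' panel whose risk blocks carry association signals; gene models with
#' planted proximal and distal risk genes (plus decoys and background
#' genes); enhancer and eQTL links; per-variant annotation scores with
#' planted tiered risk variants; a functional network, term annotations and
#' stringent/lenient training sets; expression cohorts with planted
#' co-expression modules and prognostic genes; cell-type profiles with
#' planted markers; and a reference sequence plus motif library with planted
#' motif-disrupting alleles.
#'
#' All randomness derives from `seed`; identical seeds and parameters give
#' identical studies.
#'
#' @param seed Master integer seed.
#' @param n_samples Panel samples.
#' @param n_risk_blocks LD blocks that receive association signals (the
#'   first `n_proximal_risk` host proximal risk genes, the next
#'   `n_distal_risk` are enhancer-linked to distal risk genes).
#' @param n_background_blocks Signal-free LD blocks.
#' @param n_signals Association signals.
#' @param n_proximal_risk,n_distal_risk,n_distal_decoy,n_background Gene
#'   counts (see [simulate_genome_annotation()]).
#' @param n_training `c(n_stringent, n_lenient)`.
#' @param score_params Passed to [simulate_variant_annotations()].
#' @param elevation Passed to [simulate_gene_evidence()].
#' @param n_case,n_control Cohort samples per group per region.
#' @param regions Brain-region labels for the cohort.
#' @param prognostic_beta Log-hazard per SD for planted prognostic genes
#'   (vector recycled; signs kept).
#' @param n_motifs Motif-library size.
#' @param include_sequence Generate the reference sequence and motif
#'   plantings (the slowest part; disable for region/gene-only studies).
#' @param n_celltypes Cell types in the expression profile.
#' @return List of class `postgwas_study` with components `panel`,
#'   `signals`, `genes`, `enhancers`, `links` (mapping links: enhancer +
#'   eQTL), `eqtls` (support tables `reference`, `cohort`), `annotations`,
#'   `network`, `terms`, `training`, `cohort`, `celltype`, `sequence`,
#'   `motif_library`, and `truth`.
#' @export
simulate_study <- function(seed = 1,
                           n_samples = 100,
                           n_risk_blocks = 60,
                           n_background_blocks = 15,
                           n_signals = 100,
                           n_proximal_risk = 20,
                           n_distal_risk = 10,
                           n_distal_decoy = 7,
                           n_background = 120,
                           n_training = c(20, 40),
                           score_params = list(risk_shift = 1, noise_sd = 0.05),
                           elevation = 6,
                           n_case = 90, n_control = 64,
                           regions = c("BM10", "BM22", "BM36", "BM44"),
                           prognostic_beta = c(0.9, 0.9, -0.9, 0.9),
                           n_motifs = 8,
                           include_sequence = TRUE,
                           n_celltypes = 8) {
  blocks <- block_layout(n_risk_blocks + n_background_blocks)
  risk_blocks <- blocks$block_id[seq_len(n_risk_blocks)]

  anno <- simulate_genome_annotation(
    blocks, risk_blocks, seed = derive_seed(seed, "annotation"),
    n_proximal_risk = n_proximal_risk, n_distal_risk = n_distal_risk,
    n_distal_decoy = n_distal_decoy, n_background = n_background
  )

  # pin one panel-variant position per planted risk-variant site
  blocks$positions <- vector("list", nrow(blocks))
  sites <- anno$planted_sites
  pin <- with_seed(derive_seed(seed, "positions"), {
    lapply(seq_len(nrow(blocks)), function(k) {
      b <- blocks[k, ]
      pinned <- sites$pos[sites$block_id == b$block_id]
      free <- setdiff(b$start + seq_len(b$span_bp) - 1L, pinned)
      sort(c(pinned, sample(free, b$n_variants - length(pinned))))
    })
  })
  blocks$positions <- I(pin)

  panel <- simulate_genotype_panel(n_samples, blocks,
                                   seed = derive_seed(seed, "panel"))
  signals <- simulate_gwas_signals(panel, n_signals,
                                   seed = derive_seed(seed, "signals"),
                                   favored_blocks = risk_blocks)

  # planted risk variants: the panel variant sitting at each planted site
  vt <- panel$variants
  site_key <- paste(sites$block_id, sites$pos)
  var_key <- paste(vt$block_id, vt$pos)
  planted_variants <- data.frame(
    variant_id = vt$id[match(site_key, var_key)],
    tier = sites$tier, gene_id = sites$gene_id,
    stringsAsFactors = FALSE
  )
  stopifnot(!anyNA(planted_variants$variant_id))

  annotations <- simulate_variant_annotations(
    vt, planted_variants[, c("variant_id", "tier")],
    score_params = score_params, seed = derive_seed(seed, "scores")
  )

  # mapping links: enhancers plus eQTL links for the distal decoy genes
  enh_links <- data.frame(
    link_id = anno$enhancers$link_id, kind = "enhancer",
    chrom = anno$enhancers$chrom, start = anno$enhancers$start,
    end = anno$enhancers$end, variant_id = NA_character_,
    target_gene = anno$enhancers$target_gene,
    tissue = anno$enhancers$tissue, fdr = NA_real_,
    stringsAsFactors = FALSE
  )
  eqtl_support <- with_seed(derive_seed(seed, "eqtl"), {
    dl <- anno$eqtl_decoy_links
    eqtl_links <- NULL
    if (nrow(dl) > 0) {
      vids <- vapply(dl$block_id, function(b) {
        pool <- vt$id[vt$block_id == b]
        pool[sample.int(length(pool), 1)]
      }, character(1))
      eqtl_links <- data.frame(
        link_id = paste0("eqtl_", dl$gene_id), kind = "eqtl",
        chrom = NA_character_, start = NA_integer_, end = NA_integer_,
        variant_id = vids, target_gene = dl$gene_id, tissue = "brain",
        fdr = runif(nrow(dl), 0, 0.049), stringsAsFactors = FALSE
      )
    }
    # support tables: ~60% of planted variants are eQTLs for their gene,
    # split between the reference-style and cohort-style tables, plus
    # non-significant noise rows
    n_pl <- nrow(planted_variants)
    supported <- sample(seq_len(n_pl), round(0.6 * n_pl))
    half <- sample(c(TRUE, FALSE), length(supported), replace = TRUE)
    mk <- function(idx) {
      if (length(idx) == 0) {
        return(data.frame(variant_id = character(), gene_id = character(),
                          tissue = character(), fdr = numeric()))
      }
      data.frame(variant_id = planted_variants$variant_id[idx],
                 gene_id = planted_variants$gene_id[idx],
                 tissue = sample(c("TCX", "DLPFC", "CBE"), length(idx), TRUE),
                 fdr = runif(length(idx), 0, 0.049),
                 stringsAsFactors = FALSE)
    }
    noise <- data.frame(
      variant_id = sample(vt$id, 50), gene_id = sample(anno$genes$gene_id, 50),
      tissue = "TCX", fdr = runif(50, 0.05, 1), stringsAsFactors = FALSE
    )
    list(
      links = eqtl_links,
      reference = rbind(mk(supported[half]), noise),
      cohort = mk(supported[!half])
    )
  })
  links <- rbind(enh_links, eqtl_support$links)

  evidence <- simulate_gene_evidence(
    anno$genes$gene_id, anno$planted_genes$gene_id,
    n_training = n_training, seed = derive_seed(seed, "evidence"),
    training_pool = grep("^bg_", anno$genes$gene_id, value = TRUE),
    elevation = elevation
  )

  risk_gene_ids <- anno$planted_genes$gene_id
  modules <- with_seed(derive_seed(seed, "modules"), {
    case_mod <- sample(risk_gene_ids, 10)
    list(case = case_mod,
         control = sample(setdiff(risk_gene_ids, case_mod), 10))
  })
  prognostic <- with_seed(derive_seed(seed, "prognostic"), {
    pg <- sample(risk_gene_ids, length(prognostic_beta))
    data.frame(gene_id = pg, beta = prognostic_beta, stringsAsFactors = FALSE)
  })
  cohort <- simulate_expression_cohort(
    anno$genes$gene_id, n_case, n_control,
    seed = derive_seed(seed, "cohort"), regions = regions,
    module_case = modules$case, module_control = modules$control,
    prognostic = prognostic
  )

  cell_types <- paste0("type_", seq_len(n_celltypes))
  markers <- with_seed(derive_seed(seed, "markers"), {
    pool <- sample(anno$genes$gene_id)
    split(pool[seq_len(n_celltypes * 15)],
          rep(cell_types, each = 15))
  })
  celltype <- simulate_celltype_profile(anno$genes$gene_id, cell_types,
                                        markers = markers,
                                        seed = derive_seed(seed, "celltype"))

  sequence <- NULL
  motif_library <- list()
  planted_motifs <- NULL
  if (include_sequence) {
    genome_length <- max(anno$genes$end, vt$pos) + 10000L
    # plant motif-disrupting alleles at the enhancer-tier variants (losses)
    # and at half of the promoter-tier variants (gains)
    enh_idx <- which(planted_variants$tier == "enhancer")
    prom_idx <- which(planted_variants$tier == "promoter")
    prom_idx <- prom_idx[seq_len(ceiling(length(prom_idx) / 2))]
    plant <- data.frame(
      id = planted_variants$variant_id[c(enh_idx, prom_idx)],
      pos = vt$pos[match(planted_variants$variant_id[c(enh_idx, prom_idx)],
                         vt$id)],
      direction = c(rep("loss", length(enh_idx)),
                    rep("gain", length(prom_idx))),
      stringsAsFactors = FALSE
    )
    sm <- simulate_sequence_motifs(genome_length, n_motifs,
                                   seed = derive_seed(seed, "motifs"),
                                   plant = plant)
    sequence <- sm$sequence
    motif_library <- sm$library
    planted_motifs <- sm$planted
    # make every panel variant consistent with the generated sequence
    seq_base <- vapply(vt$pos, function(p) substr(sequence[[1]], p + 1, p + 1),
                       character(1))
    vt$ref <- seq_base
    vt$alt <- with_seed(derive_seed(seed, "alts"), {
      vapply(seq_base, function(r) sample(setdiff(DNA_BASES, r), 1),
             character(1))
    })
    if (!is.null(planted_motifs)) {
      i <- match(planted_motifs$id, vt$id)
      vt$ref[i] <- planted_motifs$ref
      vt$alt[i] <- planted_motifs$alt
    }
    panel$variants <- vt
  }

  truth <- structure(list(
    planted_risk_genes = anno$planted_genes,
    planted_risk_variants = planted_variants,
    planted_prognostic_genes = prognostic,
    planted_marker_genes = markers,
    planted_motif_variants = planted_motifs,
    modules = modules,
    risk_blocks = risk_blocks,
    seed = seed
  ), class = "synthetic_truth")

  structure(list(
    panel = panel, signals = signals, genes = anno$genes,
    enhancers = anno$enhancers, links = links,
    eqtls = list(reference = eqtl_support$reference,
                 cohort = eqtl_support$cohort),
    annotations = annotations,
    network = evidence$network, terms = evidence$terms,
    training = evidence$training, unannotated = evidence$unannotated,
    cohort = cohort, celltype = celltype,
    sequence = sequence, motif_library = motif_library,
    truth = truth
  ), class = "postgwas_study")
}

#' @export
print.postgwas_study <- function(x, ...) {
  cat("Synthetic post-GWAS study (seed ", x$truth$seed, ")\n", sep = "")
  cat("  panel:     ", nrow(x$panel$dosages), " samples x ",
      nrow(x$panel$variants), " variants\n", sep = "")
  cat("  signals:   ", nrow(x$signals), "\n", sep = "")
  cat("  genes:     ", nrow(x$genes), " (",
      nrow(x$truth$planted_risk_genes), " planted risk genes)\n", sep = "")
  cat("  variants:  ", nrow(x$truth$planted_risk_variants),
      " planted risk variants\n", sep = "")
  invisible(x)
}
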