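# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with planted ground truth: risk blocks carrying association
# signals, proximal/distal risk genes, tiered risk variants, prognostic
# genes, cell-type markers, and motif-disrupting alleles. All generators are
# deterministic under their seed.

#' Lay out LD blocks along a chromosome
#'
#' @param n_blocks Number of blocks.
#' @param chrom Chromosome name.
#' @param span_bp Width of each block.
#' @param gap_bp Gap between consecutive blocks (keep above the region-merge
#'   threshold if blocks should stay distinct downstream).
#' @param n_variants Variants per block.
#' @param r2_target Expected pairwise dosage r2 within a block.
#' @return Block data frame consumed by [simulate_genotype_panel()].
#' @export
block_layout <- function(n_blocks, chrom = "chr1", span_bp = 30000,
                         gap_bp = 290000, n_variants = 12, r2_target = 0.8) {
  start <- (seq_len(n_blocks) - 1L) * (span_bp + gap_bp)
  data.frame(
    block_id = paste0("block_", seq_len(n_blocks)),
    chrom = chrom, start = start, span_bp = span_bp,
    n_variants = n_variants, r2_target = r2_target,
    stringsAsFactors = FALSE
  )
}

#' Generate a genotype panel with block-structured LD
#'
#' Within each block, variants are generated by haplotype copying: every
#' sample carries two founder haplotype alleles for the block, and each
#' variant copies the founder allele with a per-site flip probability `e`
#' chosen so that the expected pairwise dosage r2 equals the block's target
#' (`r2 = (1 - 2e)^4` at copy fidelity `1 - e`). Blocks are mutually
#' independent. Dosages are 0/1/2; positions are strictly increasing.
#'
#' @param n_samples Number of samples (>= 4).
#' @param blocks Block table from [block_layout()]; an optional list-column
#'   `positions` pins exact variant positions (0-based) within each block.
#' @param seed Integer seed.
#' @param maf_range Range the per-block founder allele frequency is drawn
#'   from.
#' @return List of class `genotype_panel`: `variants` (id, chrom, pos, ref,
#'   alt, block_id), `dosages` (samples x variants), `blocks`.
#' @export
simulate_genotype_panel <- function(n_samples, blocks, seed = 1,
                                    maf_range = c(0.3, 0.5)) {
  if (n_samples < 4) stop_invalid("n_samples must be >= 4")
  if (any(blocks$n_variants < 1)) stop_invalid("each block needs >= 1 variant")
  with_seed(seed, {
    var_rows <- list()
    dosage_cols <- list()
    for (k in seq_len(nrow(blocks))) {
      b <- blocks[k, ]
      m <- b$n_variants
      if (!is.null(blocks$positions) && !is.null(blocks$positions[[k]])) {
        pos <- sort(unique(blocks$positions[[k]]))
        if (length(pos) != m) stop_invalid("pinned positions must match n_variants")
      } else {
        pos <- b$start + sort(sample.int(b$span_bp, m)) - 1L
      }
      e <- (1 - b$r2_target^(1 / 4)) / 2
      p <- runif(1, maf_range[1], maf_range[2])
      h1 <- rbinom(n_samples, 1, p)
      h2 <- rbinom(n_samples, 1, p)
      block_d <- sapply(seq_len(m), function(j) {
        f1 <- rbinom(n_samples, 1, e)
        f2 <- rbinom(n_samples, 1, e)
        abs(h1 - f1) + abs(h2 - f2) # copy with per-site flips
      })
      ids <- paste0(b$block_id, "_v", seq_len(m))
      ref <- sample(DNA_BASES, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                    character(1))
      var_rows[[k]] <- data.frame(
        id = ids, chrom = b$chrom, pos = pos, ref = ref, alt = alt,
        block_id = b$block_id, stringsAsFactors = FALSE
      )
      colnames(block_d) <- ids
      dosage_cols[[k]] <- block_d
    }
    variants <- do.call(rbind, var_rows)
    rownames(variants) <- NULL
    dosages <- do.call(cbind, dosage_cols)
    rownames(dosages) <- paste0("sample_", seq_len(n_samples))
    structure(list(variants = variants, dosages = dosages, blocks = blocks),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$dosages), "samples x",
      nrow(x$variants), "variants in", nrow(x$blocks), "LD blocks\n")
  invisible(x)
}

#' Generate association signals over a genotype panel
#'
#' Draws `n_signals` distinct panel variants with p-values log-uniform in
#' `p_range`. When `favored_blocks` is given, at least one signal lands in
#' each favored block and the remainder are drawn from favored blocks with
#' probability `favor_prob`.
#'
#' @param panel A [simulate_genotype_panel()] result.
#' @param n_signals Number of signals (<= number of panel variants).
#' @param p_range `c(low, high)` with `0 < low <= high < 1`.
#' @param seed Integer seed.
#' @param favored_blocks Block ids that preferentially receive signals.
#' @param favor_prob Probability a free signal is placed in a favored block.
#' @return Data frame `id`, `chrom`, `pos`, `pvalue`, sorted by position.
#' @export
simulate_gwas_signals <- function(panel, n_signals, p_range = c(1e-12, 1e-5),
                                  seed = 1, favored_blocks = NULL,
                                  favor_prob = 0.9) {
  vt <- panel$variants
  if (n_signals > nrow(vt)) {
    stop_invalid("n_signals exceeds the number of panel variants")
  }
  if (!(p_range[1] > 0 && p_range[1] <= p_range[2] && p_range[2] < 1)) {
    stop_invalid("p_range must satisfy 0 < low <= high < 1")
  }
  if (n_signals == 0) {
    return(data.frame(id = character(), chrom = character(), pos = integer(),
                      pvalue = numeric()))
  }
  with_seed(seed, {
    chosen <- character(0)
    if (!is.null(favored_blocks)) {
      for (b in favored_blocks) {
        pool <- setdiff(vt$id[vt$block_id == b], chosen)
        if (length(pool) > 0 && length(chosen) < n_signals) {
          chosen <- c(chosen, pool[sample.int(length(pool), 1)])
        }
      }
    }
    while (length(chosen) < n_signals) {
      pool <- if (!is.null(favored_blocks) && runif(1) < favor_prob) {
        setdiff(vt$id[vt$block_id %in% favored_blocks], chosen)
      } else {
        setdiff(vt$id, chosen)
      }
      if (length(pool) == 0) pool <- setdiff(vt$id, chosen)
      chosen <- c(chosen, pool[sample.int(length(pool), 1)])
    }
    lp <- runif(n_signals, log10(p_range[1]), log10(p_range[2]))
    i <- match(chosen, vt$id)
    out <- data.frame(id = chosen, chrom = vt$chrom[i], pos = vt$pos[i],
                      pvalue = 10^lp, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Build one gene model row.
gene_row <- function(gene_id, chrom, start, width = 10000, strand = "+") {
  end <- start + width
  tss <- if (strand == "+") start else end - 1L
  coding <- cbind(start + c(1000L, 4000L, 8000L),
                  start + c(1500L, 4700L, 8600L))
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, tss = tss, coding = I(list(coding)),
             stringsAsFactors = FALSE)
}

#' Generate gene models, enhancers and planted candidate structure
#'
#' Places non-overlapping gene bodies relative to the LD blocks: planted
#' proximal risk genes inside risk blocks, planted distal risk genes more
#' than 20 kb away from any block but targeted by an enhancer lying inside a
#' risk block, proximal/distal decoy genes, and background genes far from all
#' blocks. Also records the position of one planted risk-variant site per
#' planted risk gene (coding, promoter or enhancer tier).
#'
#' @param blocks Block table from [block_layout()].
#' @param risk_blocks Block ids that carry association signals.
#' @param seed Integer seed.
#' @param n_proximal_risk,n_distal_risk Planted risk gene counts (proximal
#'   genes split evenly between coding- and promoter-tier planted variants).
#' @param n_distal_decoy Number of eQTL-linked distal decoy genes.
#' @param n_background Background genes placed away from every block.
#' @param n_both Planted proximal risk genes additionally enhancer-linked to
#'   a different risk block (exercising the "both" relation).
#' @return List with `genes`, `enhancers` (`link_id`, `chrom`, `start`,
#'   `end`, `target_gene`, `tissue`), `planted_genes` (data frame `gene_id`,
#'   `relation`, `tier`), `planted_sites` (`gene_id`, `tier`, `pos`,
#'   `block_id`), and `eqtl_decoy_links` (`gene_id`, `block_id` for distal
#'   decoys to be wired to a panel variant later).
#' @export
simulate_genome_annotation <- function(blocks, risk_blocks, seed = 1,
                                       n_proximal_risk = 20,
                                       n_distal_risk = 10,
                                       n_distal_decoy = 7,
                                       n_background = 120,
                                       n_both = 2) {
  if (length(risk_blocks) < n_proximal_risk + n_distal_risk) {
    stop_invalid("not enough risk blocks for the requested planted genes")
  }
  with_seed(seed, {
    genes <- list()
    enhancers <- list()
    planted_genes <- list()
    planted_sites <- list()
    eqtl_decoys <- list()
    bi <- match(risk_blocks, blocks$block_id)
    prox_blocks <- risk_blocks[seq_len(n_proximal_risk)]
    dist_blocks <- risk_blocks[n_proximal_risk + seq_len(n_distal_risk)]

    for (i in seq_along(prox_blocks)) {
      b <- blocks[blocks$block_id == prox_blocks[i], ]
      gid <- sprintf("riskP_%03d", i)
      strand <- if (i %% 2 == 0) "-" else "+"
      g <- gene_row(gid, b$chrom, b$start + 5000L, strand = strand)
      genes[[length(genes) + 1L]] <- g
      tier <- if (i <= ceiling(length(prox_blocks) / 2)) "coding" else "promoter"
      pos <- if (tier == "coding") {
        g$coding[[1]][2, 1] + 100L # inside the middle exon
      } else if (strand == "+") {
        g$tss - 1000L # upstream window on the forward strand
      } else {
        g$tss + 1000L
      }
      planted_genes[[length(planted_genes) + 1L]] <-
        data.frame(gene_id = gid, relation = "proximal", tier = tier)
      planted_sites[[length(planted_sites) + 1L]] <-
        data.frame(gene_id = gid, tier = tier, pos = pos,
                   block_id = b$block_id)
    }

    for (i in seq_along(dist_blocks)) {
      b <- blocks[blocks$block_id == dist_blocks[i], ]
      gid <- sprintf("riskD_%03d", i)
      g <- gene_row(gid, b$chrom, b$start + b$span_bp + 35000L)
      genes[[length(genes) + 1L]] <- g
      es <- b$start + 12000L
      enh_id <- paste0("enh_", gid)
      enhancers[[length(enhancers) + 1L]] <- data.frame(
        link_id = enh_id, chrom = b$chrom, start = es, end = es + 600L,
        target_gene = gid, tissue = "brain", stringsAsFactors = FALSE
      )
      planted_genes[[length(planted_genes) + 1L]] <-
        data.frame(gene_id = gid, relation = "distal", tier = "enhancer")
      planted_sites[[length(planted_sites) + 1L]] <-
        data.frame(gene_id = gid, tier = "enhancer", pos = es + 300L,
                   block_id = b$block_id)
    }

    # proximal decoy genes fill the remaining gene slots: two slots per risk
    # block (one taken by the planted gene where present), one per
    # background block
    for (bid in blocks$block_id) {
      b <- blocks[blocks$block_id == bid, ]
      slots <- b$start + c(5000L, 16000L)
      if (bid %in% prox_blocks) slots <- slots[2]
      if (!bid %in% risk_blocks) slots <- slots[1]
      for (j in seq_along(slots)) {
        gid <- paste0("decoyP_", bid, letters[j])
        genes[[length(genes) + 1L]] <- gene_row(gid, b$chrom, slots[j])
      }
    }

    # eQTL-linked distal decoys hang off the first proximal-risk blocks
    for (i in seq_len(n_distal_decoy)) {
      b <- blocks[blocks$block_id == prox_blocks[i], ]
      gid <- sprintf("decoyD_%03d", i)
      genes[[length(genes) + 1L]] <-
        gene_row(gid, b$chrom, b$start + b$span_bp + 50000L)
      eqtl_decoys[[length(eqtl_decoys) + 1L]] <-
        data.frame(gene_id = gid, block_id = b$block_id)
    }

    # "both" genes: proximal risk genes enhancer-linked to a different block
    for (i in seq_len(n_both)) {
      other <- blocks[blocks$block_id == dist_blocks[i], ]
      gid <- sprintf("riskP_%03d", i)
      es <- other$start + 20000L
      enhancers[[length(enhancers) + 1L]] <- data.frame(
        link_id = paste0("enh_both_", gid), chrom = other$chrom, start = es,
        end = es + 400L, target_gene = gid, tissue = "brain",
        stringsAsFactors = FALSE
      )
    }

    # background genes beyond the last block
    tail_start <- max(blocks$start + blocks$span_bp) + 100000L
    for (i in seq_len(n_background)) {
      gid <- sprintf("bg_%03d", i)
      genes[[length(genes) + 1L]] <-
        gene_row(gid, blocks$chrom[1], tail_start + (i - 1L) * 15000L)
    }

    list(
      genes = do.call(rbind, genes),
      enhancers = do.call(rbind, enhancers),
      planted_genes = do.call(rbind, planted_genes),
      planted_sites = do.call(rbind, planted_sites),
      eqtl_decoy_links = if (length(eqtl_decoys)) do.call(rbind, eqtl_decoys)
        else data.frame(gene_id = character(), block_id = character())
    )
  })
}

#' Generate per-variant annotation scores with planted risk variants
#'
#' Background scores: coding pathogenicity ~ Beta(2, 8), promoter effect
#' (signed log fold change) ~ Normal(0, 0.05), enhancer selection score ~
#' Beta(2, 8). Planted risk variants receive, in the score of their tier,
#' `clip(background + risk_shift * (base_shift + noise_sd * Z))` where the
#' tier base shifts (0.65 coding, 0.40 promoter with random sign, 0.85
#' enhancer) put them above their tier threshold with probability >= 0.9 at
#' the defaults. `risk_shift = 0` makes planted and background scores
#' identically distributed.
#'
#' @param variants Variant table (`id`, ...). Every planted variant must
#'   appear in it.
#' @param planted Data frame `variant_id`, `tier`
#'   (`coding`/`promoter`/`enhancer`).
#' @param score_params List with `risk_shift` (multiplier, default 1) and
#'   `noise_sd` (default 0.05).
#' @param seed Integer seed.
#' @return Annotation data frame: `variant_id`, `coding_score`,
#'   `promoter_effect`, `enhancer_score`.
#' @export
simulate_variant_annotations <- function(variants, planted = NULL,
                                         score_params = list(risk_shift = 1,
                                                             noise_sd = 0.05),
                                         seed = 1) {
  n <- nrow(variants)
  shift <- score_params$risk_shift %||% 1
  noise <- score_params$noise_sd %||% 0.05
  if (!is.null(planted) && nrow(planted) > 0 &&
      !all(planted$variant_id %in% variants$id)) {
    stop_invalid("planted variants missing from the variant universe")
  }
  with_seed(seed, {
    ann <- data.frame(
      variant_id = variants$id,
      coding_score = rbeta(n, 2, 8),
      promoter_effect = rnorm(n, 0, 0.05),
      enhancer_score = rbeta(n, 2, 8),
      stringsAsFactors = FALSE
    )
    if (!is.null(planted) && nrow(planted) > 0) {
      base <- c(coding = 0.65, promoter = 0.40, enhancer = 0.85)
      for (k in seq_len(nrow(planted))) {
        i <- match(planted$variant_id[k], ann$variant_id)
        tier <- planted$tier[k]
        bump <- shift * (base[[tier]] + noise * rnorm(1))
        if (tier == "coding") {
          ann$coding_score[i] <- min(1, max(0, ann$coding_score[i] + bump))
        } else if (tier == "enhancer") {
          ann$enhancer_score[i] <- min(1, max(0, ann$enhancer_score[i] + bump))
        } else {
          sgn <- sample(c(-1, 1), 1)
          ann$promoter_effect[i] <- ann$promoter_effect[i] + sgn * bump
        }
      }
    }
    ann
  })
}

#' Generate functional network, term annotation and training gene sets
#'
#' Training genes are drawn from the non-planted genes; the stringent set is
#' a subset of the lenient set. Every annotated gene draws `k_edges` network
#' partners and `n_terms` annotation terms; for planted risk genes and
#' training genes, training-gene partners and disease-pool terms are
#' oversampled by the `elevation` factor (and undersampled by `1/elevation`
#' for all other genes, so disease genes cluster together as the
#' guilt-by-association premise assumes) and planted-to-training edge weights
#' are raised by `0.15 * (elevation - 1)`. `elevation = 1` is an exact null:
#' planted genes are generated identically to background genes. A fraction
#' `unannotated_frac` of the background genes lack both network membership
#' and terms, exercising the unscorable path downstream.
#'
#' @param gene_ids All gene ids.
#' @param planted_risk_genes Planted risk gene ids.
#' @param n_training `c(n_stringent, n_lenient)` with stringent <= lenient.
#' @param training_pool Genes the training sets are drawn from (default: all
#'   non-planted genes).
#' @param seed Integer seed.
#' @param elevation Oversampling factor (default 6).
#' @param unannotated_frac Fraction of background genes left unannotated.
#' @param k_edges Partners drawn per gene.
#' @param n_terms Terms drawn per annotated gene.
#' @param n_disease_terms,n_background_terms Term-pool sizes.
#' @return List with `network` (edge data frame `from`, `to`, `weight`),
#'   `terms` (named list), `training` (list `stringent`, `lenient`),
#'   `unannotated` (gene ids).
#' @export
simulate_gene_evidence <- function(gene_ids, planted_risk_genes,
                                   n_training = c(20, 40), seed = 1,
                                   training_pool = NULL,
                                   elevation = 6, unannotated_frac = 0.05,
                                   k_edges = 8, n_terms = 5,
                                   n_disease_terms = 15,
                                   n_background_terms = 60) {
  if (n_training[1] > n_training[2]) {
    stop_invalid("stringent set cannot be larger than the lenient set")
  }
  pool <- setdiff(training_pool %||% gene_ids, planted_risk_genes)
  if (length(pool) < n_training[2]) stop_invalid("not enough non-planted genes")
  with_seed(seed, {
    lenient <- sample(pool, n_training[2])
    stringent <- sample(lenient, n_training[1])
    favored <- union(planted_risk_genes, lenient)

    bg_pool <- setdiff(gene_ids, favored)
    n_un <- round(unannotated_frac * length(bg_pool))
    unannotated <- if (n_un > 0) sample(bg_pool, n_un) else character(0)
    annotated <- setdiff(gene_ids, unannotated)

    # network edges: favored genes oversample training-gene partners by the
    # elevation factor, non-favored genes undersample them symmetrically
    from <- character(0); to <- character(0); weight <- numeric(0)
    for (g in annotated) {
      others <- setdiff(annotated, g)
      fac <- if (g %in% favored) elevation else 1 / elevation
      w <- ifelse(others %in% lenient, fac, 1)
      partners <- sample(others, min(k_edges, length(others)), prob = w)
      ew <- rbeta(length(partners), 2, 5)
      boost <- g %in% favored & partners %in% lenient
      ew[boost] <- pmin(1, ew[boost] + 0.15 * (elevation - 1))
      from <- c(from, rep(g, length(partners)))
      to <- c(to, partners)
      weight <- c(weight, ew)
    }
    # deduplicate undirected pairs, keeping the first weight
    key <- ifelse(from < to, paste(from, to), paste(to, from))
    keep <- !duplicated(key)
    network <- data.frame(from = from[keep], to = to[keep],
                          weight = weight[keep], stringsAsFactors = FALSE)

    disease_terms <- paste0("term_disease_", seq_len(n_disease_terms))
    background_terms <- paste0("term_bg_", seq_len(n_background_terms))
    all_terms <- c(disease_terms, background_terms)
    terms <- lapply(setNames(annotated, annotated), function(g) {
      fac <- if (g %in% favored) elevation else 1 / elevation
      w <- ifelse(all_terms %in% disease_terms, fac, 1)
      sample(all_terms, n_terms, prob = w)
    })

    list(network = network, terms = terms,
         training = list(stringent = stringent, lenient = lenient),
         unannotated = unannotated)
  })
}

#' Generate an expression cohort with planted modules and survival structure
#'
#' Per brain region, a genes x samples matrix where the genes of
#' `module_case` share a latent factor among cases only (pairwise expected
#' r ~ 0.9) and `module_control` among controls only; all other entries are
#' independent standard normals. Ages are uniform per group. Survival times
#' are exponential with log-hazard proportional to the (standardised)
#' expression of the planted prognostic genes; a `censor_frac` fraction of
#' samples is censored uniformly before their event time.
#'
#' @param gene_ids Genes (rows).
#' @param n_case,n_control Samples per group per region (>= 4).
#' @param seed Integer seed.
#' @param regions Region labels.
#' @param module_case,module_control Gene ids of the two planted modules.
#' @param prognostic Data frame `gene_id`, `beta` (log-hazard per SD).
#' @param base_rate Baseline hazard (events per time unit).
#' @param censor_frac Fraction censored, in `[0, 1)`.
#' @param age_range_case,age_range_control Uniform age ranges (years).
#' @param module_r Expected within-module pairwise correlation.
#' @param missing_frac If positive, also return a character matrix `raw` in
#'   which this fraction of entries is replaced by the missing-value tokens
#'   `"0"` or `"#N/A"` (proteomic-style input for the cleaning path).
#' @return List of class `expression_cohort`: `matrix`, `meta` (`sample`,
#'   `group`, `region`, `age`, `time`, `event`), and optionally `raw`.
#' @export
simulate_expression_cohort <- function(gene_ids, n_case, n_control, seed = 1,
                                       regions = c("BM10", "BM22"),
                                       module_case = character(0),
                                       module_control = character(0),
                                       prognostic = NULL,
                                       base_rate = 0.1, censor_frac = 0.2,
                                       age_range_case = c(65, 90),
                                       age_range_control = c(60, 90),
                                       module_r = 0.9,
                                       missing_frac = 0) {
  if (n_case < 4 || n_control < 4) stop_invalid("need >= 4 samples per group")
  if (censor_frac < 0 || censor_frac >= 1) {
    stop_invalid("censor_frac must be in [0, 1)")
  }
  lam <- sqrt(module_r) # factor loading giving pairwise r = lam^2
  noise_sd <- sqrt(1 - lam^2)
  with_seed(seed, {
    mats <- list(); metas <- list()
    for (rg in regions) {
      n <- n_case + n_control
      group <- c(rep("case", n_case), rep("control", n_control))
      ids <- paste0(rg, "_s", seq_len(n))
      m <- matrix(rnorm(length(gene_ids) * n), length(gene_ids), n,
                  dimnames = list(gene_ids, ids))
      plant <- function(mod, which_group) {
        mod <- intersect(mod, gene_ids)
        if (length(mod) == 0) return()
        cols <- which(group == which_group)
        f <- rnorm(length(cols))
        for (g in mod) {
          m[g, cols] <<- lam * f + noise_sd * rnorm(length(cols))
        }
      }
      plant(module_case, "case")
      plant(module_control, "control")
      age <- c(runif(n_case, age_range_case[1], age_range_case[2]),
               runif(n_control, age_range_control[1], age_range_control[2]))
      lp <- rep(0, n)
      if (!is.null(prognostic) && nrow(prognostic) > 0) {
        for (k in seq_len(nrow(prognostic))) {
          g <- prognostic$gene_id[k]
          if (g %in% gene_ids) {
            z <- as.numeric(scale(m[g, ]))
            lp <- lp + prognostic$beta[k] * z
          }
        }
      }
      t_event <- rexp(n, rate = base_rate * exp(lp))
      censored <- runif(n) < censor_frac
      time <- ifelse(censored, runif(n) * t_event, t_event)
      event <- as.integer(!censored)
      mats[[rg]] <- m
      metas[[rg]] <- data.frame(sample = ids, group = group, region = rg,
                                age = age, time = time, event = event,
                                stringsAsFactors = FALSE)
    }
    out <- list(matrix = do.call(cbind, mats), meta = do.call(rbind, metas))
    rownames(out$meta) <- NULL
    if (missing_frac > 0) {
      raw <- matrix(as.character(round(out$matrix, 4)),
                    nrow(out$matrix), ncol(out$matrix),
                    dimnames = dimnames(out$matrix))
      n_entries <- length(raw)
      miss <- sample.int(n_entries, round(missing_frac * n_entries))
      raw[miss] <- sample(c("0", "#N/A"), length(miss), replace = TRUE)
      out$raw <- raw
    }
    structure(out, class = "expression_cohort")
  })
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("Expression cohort:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples in", length(unique(x$meta$region)), "region(s)\n")
  invisible(x)
}

#' Generate cell-type mean-expression profiles with planted markers
#'
#' Baseline mean expression is log-normal; each cell type's marker genes are
#' multiplied by `marker_fold` in that type only.
#'
#' @param gene_ids Genes.
#' @param cell_types Cell-type labels.
#' @param markers Named list mapping cell type to its marker gene ids.
#' @param seed Integer seed.
#' @param marker_fold Fold elevation of markers in their own type.
#' @return List with `mean_expr` (genes x types) and `markers`.
#' @export
simulate_celltype_profile <- function(gene_ids, cell_types, markers = list(),
                                      seed = 1, marker_fold = 8) {
  with_seed(seed, {
    m <- matrix(exp(rnorm(length(gene_ids) * length(cell_types), 0, 0.3)),
                length(gene_ids), length(cell_types),
                dimnames = list(gene_ids, cell_types))
    for (ct in names(markers)) {
      mg <- intersect(markers[[ct]], gene_ids)
      m[mg, ct] <- m[mg, ct] * marker_fold
    }
    list(mean_expr = m, markers = markers)
  })
}

# Sharp PWM whose full consensus scores above `threshold` but any single
# mismatch drops below it (width 7, consensus probability 0.99).
sharp_pwm <- function(motif_id, consensus) {
  w <- nchar(consensus)
  mat <- matrix((1 - 0.99) / 3, 4, w, dimnames = list(DNA_BASES, NULL))
  idx <- match(strsplit(consensus, "")[[1]], DNA_BASES)
  mat[cbind(idx, seq_len(w))] <- 0.99
  pwm(motif_id, mat)
}

#' Generate a reference sequence, a PWM library, and planted motif variants
#'
#' Builds a random DNA sequence, a library of sharp motifs (width 7: a full
#' consensus match scores ~13.9, one mismatch ~6.0, so a single substitution
#' crosses the 7.5 calling threshold), and plants, at each requested variant,
#' either a consensus destroyed by the alternative allele (`loss`) or a
#' single-mismatch site repaired by it (`gain`). Windows around planted
#' variants are locally resampled until they contain no accidental full
#' match of any library motif, so the planted call is guaranteed by
#' construction.
#'
#' @param genome_length Sequence length in bp.
#' @param n_motifs Library size.
#' @param seed Integer seed.
#' @param plant Data frame `id`, `pos` (0-based), `direction`
#'   (`gain`/`loss`); optional — planted variants are returned with ref/alt
#'   alleles filled in.
#' @param motif_width Motif width (must fit in the +/- 25 bp window).
#' @param chrom Chromosome name of the generated sequence.
#' @return List with `sequence` (named character: chromosome -> sequence),
#'   `library` (list of [pwm()]), `planted` (variant table `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `motif_id`, `direction`).
#' @export
simulate_sequence_motifs <- function(genome_length, n_motifs, seed = 1,
                                     plant = NULL, motif_width = 7,
                                     chrom = "chr1") {
  if (motif_width > 51) stop_invalid("motif wider than the scan window")
  with_seed(seed, {
    codes <- utf8ToInt("ACGT")
    seq <- intToUtf8(codes[sample.int(4, genome_length, replace = TRUE)])
    library <- list()
    if (n_motifs > 0) {
      # consensus sequences (and their reverse complements) must be unique:
      # a duplicated motif could never be destroyed for one library member
      # without staying present for the other
      seen <- character(0)
      for (i in seq_len(n_motifs)) {
        repeat {
          cons <- paste(sample(DNA_BASES, motif_width, replace = TRUE),
                        collapse = "")
          rc <- reverse_complement(cons)
          if (!(cons %in% seen) && !(rc %in% seen)) break
        }
        seen <- c(seen, cons, rc)
        library[[i]] <- sharp_pwm(sprintf("motif_%02d", i), cons)
      }
    }
    planted <- NULL
    if (!is.null(plant) && nrow(plant) > 0 && n_motifs > 0) {
      rows <- list()
      for (k in seq_len(nrow(plant))) {
        mi <- ((k - 1L) %% n_motifs) + 1L
        motif <- library[[mi]]
        cons <- pwm_consensus(motif)
        pos <- plant$pos[k]
        direction <- plant$direction[k]
        # try variant offsets inside the motif until a clean local window is
        # found; a fixed offset can be unplantable when the allele-modified
        # motif string itself matches another library motif
        placed <- FALSE
        for (offset in sample.int(motif_width) - 1L) {
          mstart <- pos - offset # 0-based motif start
          if (mstart < 0 || mstart + motif_width > genome_length) next
          cons_base <- substr(cons, offset + 1, offset + 1)
          other <- sample(setdiff(DNA_BASES, cons_base), 1)
          embedded <- cons
          if (direction == "gain") {
            substr(embedded, offset + 1, offset + 1) <- other
          }
          ref <- substr(embedded, offset + 1, offset + 1)
          alt <- if (direction == "gain") cons_base else other
          win_s <- max(pos - 60, 0)
          win_e <- min(pos + 61, genome_length)
          for (attempt in 1:50) {
            local <- intToUtf8(codes[sample.int(4, win_e - win_s, TRUE)])
            substr(local, mstart - win_s + 1,
                   mstart - win_s + motif_width) <- embedded
            alt_local <- local
            substr(alt_local, pos - win_s + 1, pos - win_s + 1) <- alt
            clean <- TRUE
            for (m in library) {
              thr <- 7.5
              rb <- pwm_best_score(m, local)
              ab <- pwm_best_score(m, alt_local)
              want_ref <- direction == "loss" && m$motif_id == motif$motif_id
              want_alt <- direction == "gain" && m$motif_id == motif$motif_id
              if ((rb > thr) != want_ref || (ab > thr) != want_alt) {
                clean <- FALSE
                break
              }
            }
            if (clean) break
          }
          if (clean) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          warning("could not plant a motif variant at position ", pos,
                  "; skipped")
          next
        }
        substr(seq, win_s + 1, win_e) <- local
        rows[[length(rows) + 1L]] <- data.frame(
          id = plant$id[k], chrom = chrom, pos = pos, ref = ref, alt = alt,
          motif_id = motif$motif_id, direction = direction,
          stringsAsFactors = FALSE
        )
      }
      planted <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    list(sequence = setNames(seq, chrom), library = library,
         planted = planted)
  })
}
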