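test_that("genotype panels are deterministic and respect block structure", {
  blocks <- block_layout(3, n_variants = 6, r2_target = 0.8)
  p1 <- simulate_genotype_panel(30, blocks, seed = 5)
  p2 <- simulate_genotype_panel(30, blocks, seed = 5)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variants, p2$variants)
  expect_true(all(p1$dosages %in% 0:2))
  expect_true(all(diff(p1$variants$pos) > 0)) # strictly increasing
  expect_error(simulate_genotype_panel(2, blocks), ">= 4")
  bad <- blocks; bad$n_variants <- 0
  expect_error(simulate_genotype_panel(30, bad), ">= 1 variant")
})

test_that("perfect copy fidelity gives r2 = 1 within a block", {
  blocks <- block_layout(1, n_variants = 5, r2_target = 1.0)
  p <- simulate_genotype_panel(50, blocks, seed = 2)
  ids <- p$variants$id
  for (i in 1:4) {
    expect_equal(ld_r2(p, ids[i], ids[i + 1]), 1)
  }
})

test_that("cross-block r2 is pure sampling noise, ~1/n at fidelity 1", {
  vals <- c()
  for (s in 1:30) {
    blocks <- block_layout(2, n_variants = 6, r2_target = 1.0)
    p <- simulate_genotype_panel(100, blocks, seed = 1000 + s)
    a <- p$variants$id[p$variants$block_id == "block_1"]
    b <- p$variants$id[p$variants$block_id == "block_2"]
    # one representative pair per replicate: within-block copies are
    # identical at fidelity 1, so extra pairs add no information
    vals <- c(vals, ld_r2(p, a[1], b[1]))
  }
  expect_gt(mean(vals), 0.002)
  expect_lt(mean(vals), 0.03) # E[r2] ~ 1/(n-1) = 0.0101 under independence
})

test_that("association signals follow the requested p-value range and counts", {
  blocks <- block_layout(3, n_variants = 5)
  p <- simulate_genotype_panel(20, blocks, seed = 1)
  expect_equal(nrow(simulate_gwas_signals(p, 0)), 0)
  sg <- simulate_gwas_signals(p, 10, p_range = c(1e-9, 1e-9), seed = 2)
  expect_true(all(sg$pvalue == 1e-9))
  expect_equal(length(unique(sg$id)), 10)
  expect_error(simulate_gwas_signals(p, 100), "exceeds")
  expect_error(simulate_gwas_signals(p, 5, p_range = c(0, 0.5)), "p_range")
  # favored blocks each receive at least one signal
  sg2 <- simulate_gwas_signals(p, 6, seed = 3,
                               favored_blocks = c("block_1", "block_3"))
  hit_blocks <- p$variants$block_id[match(sg2$id, p$variants$id)]
  expect_true(all(c("block_1", "block_3") %in% hit_blocks))
})

test_that("planted distal genes sit > 20 kb away yet link into a block", {
  blocks <- block_layout(40)
  anno <- simulate_genome_annotation(blocks, blocks$block_id[1:30], seed = 3,
                                     n_proximal_risk = 15, n_distal_risk = 10,
                                     n_distal_decoy = 5, n_background = 20)
  distal <- anno$planted_genes$gene_id[anno$planted_genes$relation == "distal"]
  for (g in distal) {
    gr <- anno$genes[anno$genes$gene_id == g, ]
    gaps <- pmax(blocks$start - gr$end, gr$start - (blocks$start + blocks$span_bp))
    expect_gt(min(gaps), 20000) # beyond the proximal flank of every block
    enh <- anno$enhancers[anno$enhancers$target_gene == g, ]
    expect_gte(nrow(enh), 1)
    b <- blocks[blocks$block_id ==
                  anno$planted_sites$block_id[anno$planted_sites$gene_id == g], ]
    expect_true(enh$start[1] >= b$start && enh$end[1] <= b$start + b$span_bp)
  }
  # gene bodies never overlap
  g <- anno$genes[order(anno$genes$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
})

test_that("variant annotations are clipped, shifted, and null at zero shift", {
  variants <- data.frame(id = paste0("v", 1:400), chrom = "chr1",
                         pos = seq_len(400) * 10)
  planted <- data.frame(variant_id = paste0("v", 1:200),
                        tier = rep(c("coding", "promoter", "enhancer"),
                                   length.out = 200))
  frac_pass <- c()
  for (s in 1:5) {
    ann <- simulate_variant_annotations(variants, planted, seed = s)
    expect_true(all(ann$coding_score >= 0 & ann$coding_score <= 1))
    expect_true(all(ann$enhancer_score >= 0 & ann$enhancer_score <= 1))
    thr <- tier_thresholds()
    pass <- vapply(seq_len(nrow(planted)), function(k) {
      a <- ann[match(planted$variant_id[k], ann$variant_id), ]
      isTRUE(call_risk_variant(planted$tier[k], a, thr))
    }, logical(1))
    frac_pass <- c(frac_pass, mean(pass))
  }
  expect_gte(mean(frac_pass), 0.9) # planted variants exceed their tier cutoff

  # zero shift: planted scores are draws from the background distribution
  ann0 <- simulate_variant_annotations(variants, planted,
                                       score_params = list(risk_shift = 0,
                                                           noise_sd = 0.05),
                                       seed = 1)
  pl <- ann0$coding_score[ann0$variant_id %in%
                            planted$variant_id[planted$tier == "coding"]]
  bg <- ann0$coding_score[!ann0$variant_id %in% planted$variant_id]
  expect_gt(suppressWarnings(ks.test(pl, bg)$p.value), 0.01)

  expect_error(
    simulate_variant_annotations(variants[1:10, ], planted),
    "missing from the variant universe"
  )
})

test_that("gene evidence has nested training sets and an unscorable fraction", {
  genes <- paste0("g", sprintf("%04d", 1:1000))
  planted <- genes[1:30]
  ev <- simulate_gene_evidence(genes, planted, n_training = c(20, 40),
                               seed = 9, unannotated_frac = 0.02)
  expect_true(all(ev$training$stringent %in% ev$training$lenient))
  expect_equal(length(ev$training$stringent), 20)
  expect_equal(length(ev$training$lenient), 40)
  # unannotated genes are absent from both network and terms
  expect_false(any(ev$unannotated %in% names(ev$terms)))
  expect_false(any(ev$unannotated %in% c(ev$network$from, ev$network$to)))
  # ~2% of the eligible background pool
  n_bg <- length(genes) - length(union(planted, ev$training$lenient))
  expect_equal(length(ev$unannotated), round(0.02 * n_bg))
  expect_true(all(ev$network$weight > 0 & ev$network$weight <= 1))
  expect_false(any(ev$network$from == ev$network$to))
  expect_error(simulate_gene_evidence(genes, planted, n_training = c(50, 40)),
               "stringent")
})

test_that("elevation factor one is an exact null for the planted genes", {
  genes <- paste0("g", 1:300)
  planted <- genes[1:30]
  ev <- simulate_gene_evidence(genes, planted, n_training = c(10, 30),
                               seed = 4, elevation = 1, unannotated_frac = 0)
  w_to_training <- function(set) {
    sel <- (ev$network$from %in% set & ev$network$to %in% ev$training$lenient) |
      (ev$network$to %in% set & ev$network$from %in% ev$training$lenient)
    edges <- ev$network[sel, ]
    sum(edges$weight) / length(set)
  }
  bg <- setdiff(genes, union(planted, ev$training$lenient))
  # mean per-gene training-edge weight of planted ~ background (ratio near 1)
  expect_lt(abs(w_to_training(planted) / w_to_training(bg) - 1), 0.5)
})

test_that("expression cohorts plant modules, hazards and censoring correctly", {
  genes <- paste0("g", 1:40)
  mod <- genes[1:8]
  co <- simulate_expression_cohort(genes, n_case = 100, n_control = 50,
                                   seed = 3, regions = "R1",
                                   module_case = mod, censor_frac = 0)
  expect_true(all(co$meta$event == 1)) # no censoring
  cases <- co$meta$sample[co$meta$group == "case"]
  cors <- cor(t(co$matrix[mod, cases]))
  off <- cors[upper.tri(cors)]
  expect_gte(mean(off > 0.7), 0.9) # planted module is tightly correlated
  ctrl <- co$meta$sample[co$meta$group == "control"]
  cors_c <- cor(t(co$matrix[mod, ctrl]))
  expect_lt(mean(abs(cors_c[upper.tri(cors_c)])), 0.3) # decorrelated
  expect_error(
    simulate_expression_cohort(genes, 10, 10, censor_frac = 1),
    "censor_frac"
  )
  # requested censoring fraction is roughly realised
  co2 <- simulate_expression_cohort(genes, 100, 100, seed = 5,
                                    regions = "R1", censor_frac = 0.3)
  expect_lt(abs(mean(co2$meta$event == 0) - 0.3), 0.12)
  # proteomic-style raw matrix carries the two missing tokens
  co3 <- simulate_expression_cohort(genes, 10, 10, seed = 6, regions = "R1",
                                    missing_frac = 0.1)
  expect_true(any(co3$raw == "#N/A"))
  expect_true(any(co3$raw == "0"))
})

test_that("sequence generator plants recoverable motif gains and losses", {
  plant <- data.frame(id = paste0("pv", 1:6), pos = c(2000, 4000, 6000, 8000,
                                                      10000, 12000),
                      direction = rep(c("loss", "gain"), 3))
  sm <- simulate_sequence_motifs(20000, n_motifs = 4, seed = 8, plant = plant)
  expect_equal(nrow(sm$planted), 6)
  for (k in seq_len(nrow(sm$planted))) {
    pv <- sm$planted[k, ]
    w <- extract_allele_windows(sm$sequence, pv)
    d <- call_gain_loss(sm$library, w$ref, w$alt, variant_id = pv$id)
    expect_true(pv$motif_id %in% d$motif_id)
    expect_equal(d$direction[d$motif_id == pv$motif_id], pv$direction)
  }
  # empty library -> nothing to call
  sm0 <- simulate_sequence_motifs(5000, n_motifs = 0, seed = 1)
  expect_equal(length(sm0$library), 0)
  expect_error(simulate_sequence_motifs(1000, 2, motif_width = 60), "wider")
})

test_that("an embedded consensus is located at its planted offset", {
  sm <- simulate_sequence_motifs(3000, n_motifs = 1, seed = 3,
                                 plant = data.frame(id = "v", pos = 1500,
                                                    direction = "loss"))
  m <- sm$library[[1]]
  cons <- pwm_consensus(m)
  seqc <- sm$sequence[[1]]
  # brute-force scan of the neighbourhood finds the full consensus exactly
  # once, overlapping the planted position
  hits <- c()
  for (off in 1400:1560) {
    sub <- substr(seqc, off, off + nchar(cons) - 1)
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(sub, "")[[1]])),
                collapse = "")
    if (sub == cons || rc == cons) hits <- c(hits, off)
  }
  expect_equal(length(hits), 1)
  expect_true(hits - 1 <= 1500 && 1500 < hits - 1 + nchar(cons))
})

test_that("the orchestrated study is reproducible end to end", {
  s1 <- simulate_study(seed = 42, include_sequence = FALSE)
  s2 <- simulate_study(seed = 42, include_sequence = FALSE)
  expect_identical(s1$panel$dosages, s2$panel$dosages)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$network, s2$network)
  expect_identical(s1$cohort$matrix, s2$cohort$matrix)
  expect_identical(s1$truth$planted_risk_variants,
                   s2$truth$planted_risk_variants)
  # planted sets are subsets of the generated universes
  expect_true(all(s1$truth$planted_risk_genes$gene_id %in% s1$genes$gene_id))
  expect_true(all(s1$truth$planted_risk_variants$variant_id %in%
                    s1$panel$variants$id))
})
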