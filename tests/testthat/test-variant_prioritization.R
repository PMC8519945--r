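risk_gene_models <- rbind(
  make_gene("rg1", 100000L, strand = "+",
            coding = cbind(c(101000L, 104000L), c(101500L, 104700L))),
  make_gene("rg2", 200000L, strand = "-"),
  make_gene("other", 300000L)
)
enh <- data.frame(chrom = "chr1", start = 150000L, end = 150600L,
                  target_gene = c("rg1", "rg2"), stringsAsFactors = FALSE)

test_that("variant contexts cover coding, promoter and enhancer relations", {
  v_cod <- data.frame(id = "v1", chrom = "chr1", pos = 101200L)
  ctx <- assign_context(v_cod, c("rg1", "rg2"), risk_gene_models, enh)
  expect_equal(ctx$tier, "coding")
  expect_equal(ctx$gene_id, "rg1")

  # promoter window on the forward strand: [tss - 2000, tss + 500)
  v_prom <- data.frame(id = "v2", chrom = "chr1", pos = 99000L)
  ctx <- assign_context(v_prom, c("rg1"), risk_gene_models, enh)
  expect_equal(ctx$tier, "promoter")

  # reverse strand promoter sits downstream of the gene end
  v_prom_m <- data.frame(id = "v3", chrom = "chr1", pos = 210500L)
  ctx <- assign_context(v_prom_m, c("rg2"), risk_gene_models, enh)
  expect_equal(ctx$tier, "promoter")
  expect_equal(ctx$gene_id, "rg2")

  # enhancer linked to two risk genes -> two contexts
  v_enh <- data.frame(id = "v4", chrom = "chr1", pos = 150300L)
  ctx <- assign_context(v_enh, c("rg1", "rg2"), risk_gene_models, enh)
  expect_equal(sort(ctx$gene_id[ctx$tier == "enhancer"]), c("rg1", "rg2"))

  # context in a non-risk gene only -> empty
  v_non <- data.frame(id = "v5", chrom = "chr1", pos = 301200L)
  expect_equal(nrow(assign_context(v_non, c("rg1"), risk_gene_models, enh)), 0)
})

test_that("tier calls are strict at 0.7, ln(1.2) and 0.9", {
  ann <- function(c = NA, p = NA, e = NA) {
    data.frame(coding_score = c, promoter_effect = p, enhancer_score = e)
  }
  expect_true(call_risk_variant("coding", ann(c = 0.80)))
  expect_false(call_risk_variant("coding", ann(c = 0.70))) # not strict greater
  expect_true(call_risk_variant("promoter", ann(p = 0.194))) # > ln(1.2)
  expect_false(call_risk_variant("promoter", ann(p = log(1.2))))
  expect_true(call_risk_variant("promoter", ann(p = -0.194))) # sign-agnostic
  expect_true(call_risk_variant("enhancer", ann(e = 0.91)))
  expect_false(call_risk_variant("enhancer", ann(e = 0.90)))
  expect_true(is.na(call_risk_variant("coding", ann()))) # missing score
})

test_that("risk-variant prediction restricts to regions and counts uniques once", {
  regions <- data.frame(region_id = "r1", chrom = "chr1",
                        start = 95000L, end = 160000L,
                        stringsAsFactors = FALSE)
  variants <- data.frame(
    id = c("in_cod", "in_enh", "outside", "dual"),
    chrom = "chr1",
    pos = c(101200L, 150300L, 301200L, 101200L),
    stringsAsFactors = FALSE
  )
  annotations <- data.frame(
    variant_id = c("in_cod", "in_enh", "outside", "dual"),
    coding_score = c(0.95, NA, 0.99, 0.9),
    promoter_effect = NA_real_,
    enhancer_score = c(NA, 0.95, NA, NA)
  )
  rv <- predict_risk_variants(variants, annotations, c("rg1", "rg2"),
                              risk_gene_models, enh, regions)
  expect_false("outside" %in% rv$variant_id) # outside every region
  expect_setequal(rv$variant_id, c("in_cod", "in_enh", "dual"))
  expect_equal(attr(rv, "n_unique"), 3L)
  # empty risk-gene set -> empty result
  rv0 <- predict_risk_variants(variants, annotations, character(0),
                               risk_gene_models, enh, regions)
  expect_equal(nrow(rv0), 0)
})

test_that("a variant passing in two tiers counts once in the unique tally", {
  regions <- data.frame(region_id = "r1", chrom = "chr1",
                        start = 95000L, end = 160000L)
  # position both inside rg1 coding and inside the enhancer? use two contexts
  # via a variant inside the promoter of rg1 and an enhancer moved onto it
  enh2 <- data.frame(chrom = "chr1", start = 98900L, end = 99200L,
                     target_gene = "rg2", stringsAsFactors = FALSE)
  variants <- data.frame(id = "multi", chrom = "chr1", pos = 99000L)
  annotations <- data.frame(variant_id = "multi", coding_score = NA,
                            promoter_effect = 0.5, enhancer_score = 0.95)
  rv <- predict_risk_variants(variants, annotations, c("rg1", "rg2"),
                              risk_gene_models, enh2, regions)
  expect_equal(nrow(rv), 2) # one record per tier
  expect_setequal(rv$tier, c("promoter", "enhancer"))
  expect_equal(attr(rv, "n_unique"), 1L)
})

test_that("eQTL cross-referencing is strict in FDR and gene-matched", {
  rv <- data.frame(variant_id = c("v1", "v2", "v3"),
                   chrom = "chr1", pos = 1:3, tier = "coding", score = 0.9,
                   region_id = "r1",
                   linked_genes = I(list("g1", "g2", "g3")))
  eq <- data.frame(variant_id = c("v1", "v2", "v3"),
                   gene_id = c("g1", "g2", "gX"),
                   tissue = "TCX", fdr = c(0.01, 0.05, 0.001))
  flags <- cross_reference_eqtls(rv, eq)
  got <- setNames(flags$eqtl_reference, flags$variant_id)
  expect_true(got[["v1"]])
  expect_false(got[["v2"]]) # fdr exactly 0.05 excluded
  expect_false(got[["v3"]]) # eQTL for a non-linked gene
})

test_that("support fractions follow set algebra on unique variants", {
  rv <- data.frame(variant_id = c("a", "a", "b", "c"),
                   chrom = "chr1", pos = c(1, 1, 2, 3),
                   tier = c("coding", "enhancer", "coding", "coding"),
                   score = 0.9, region_id = "r1",
                   linked_genes = I(list("g", "g", "g", "g")))
  flags <- data.frame(variant_id = c("a", "b", "c"),
                      eqtl_reference = c(FALSE, TRUE, FALSE),
                      eqtl_cohort = FALSE)
  sup <- summarize_support(rv, motif_variant_ids = c("a", "zz"),
                           eqtl_flags = flags)
  expect_equal(sup$n, 3L)
  expect_equal(sup$frac_motif, 1 / 3)
  expect_equal(sup$frac_eqtl, 1 / 3)
  # disjoint support sets: fractions add
  expect_equal(sup$frac_either, sup$frac_motif + sup$frac_eqtl)
  # empty risk-variant set: not-applicable fractions
  sup0 <- summarize_support(rv[0, ], motif_variant_ids = "a")
  expect_true(is.na(sup0$frac_either))
})

test_that("union support fraction matches a set oracle on a synthetic run", {
  set.seed(8)
  ids <- paste0("v", 1:40)
  rv <- data.frame(variant_id = ids, chrom = "chr1", pos = seq_along(ids),
                   tier = "coding", score = 0.9, region_id = "r1",
                   linked_genes = I(as.list(rep("g", 40))))
  motif_ids <- sample(ids, 15)
  eq_ids <- sample(ids, 12)
  flags <- data.frame(variant_id = ids, eqtl_reference = ids %in% eq_ids,
                      eqtl_cohort = FALSE)
  sup <- summarize_support(rv, motif_ids, flags)
  expect_equal(sup$n_either, length(union(motif_ids, eq_ids)))
  expect_equal(sup$frac_either, length(union(motif_ids, eq_ids)) / 40)
})
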