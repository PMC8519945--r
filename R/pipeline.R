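# End-to-end orchestration: configuration, stage ordering, run summary and
# optional on-disk outputs with a manifest.

#' Pipeline configuration
#'
#' Collects every operating point of the pipeline with its default. Unknown
#' arguments are rejected; thresholds are validated against their declared
#' ranges.
#'
#' @param r2_min LD threshold for block membership (strict `>`).
#' @param max_dist Maximum seed distance in bp (strict `<`).
#' @param gap_max Region-merge gap in bp (strict `<`).
#' @param flank Proximal-gene extension in bp.
#' @param alpha Network/annotation mixing weight, open interval (0, 1).
#' @param precision_target Precision for threshold calibration.
#' @param tier_thresholds Named vector `coding`, `promoter`, `enhancer`.
#' @param motif_threshold PWM match-score threshold.
#' @param r_min Co-expression edge threshold.
#' @param hub_k Number of network hubs.
#' @param fdr_max eQTL FDR cutoff.
#' @param n_perm Permutations for gene scoring.
#' @param n_boot Bootstrap draws for cell-type enrichment.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @param partial_scores Combine single-component scores (see
#'   [combine_scores()]).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(r2_min = 0.5, max_dist = 400000,
                            gap_max = 250000, flank = 20000, alpha = 0.5,
                            precision_target = 0.8,
                            tier_thresholds = c(coding = 0.7,
                                                promoter = log(1.2),
                                                enhancer = 0.9),
                            motif_threshold = 7.5, r_min = 0.7, hub_k = 20,
                            fdr_max = 0.05, n_perm = 2000, n_boot = 2000,
                            promoter_window = c(2000, 500),
                            partial_scores = FALSE, seed = 1) {
  stopifnot(r2_min >= 0, r2_min <= 1, max_dist > 0, gap_max >= 0, flank >= 0)
  if (alpha <= 0 || alpha >= 1) {
    stop_invalid("alpha must lie strictly inside (0, 1)")
  }
  stopifnot(precision_target > 0, precision_target <= 1,
            all(c("coding", "promoter", "enhancer") %in%
                  names(tier_thresholds)),
            r_min >= -1, r_min <= 1, hub_k >= 1,
            fdr_max >= 0, fdr_max <= 1, n_perm >= 100, n_boot >= 100)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full post-GWAS pipeline on a study
#'
#' Executes the stages in dependency order: risk regions from association
#' seeds, proximal/distal gene mapping, permutation-based gene scoring with
#' precision-calibrated thresholds, tiered risk-variant prediction, motif
#' and eQTL support, co-expression connectivity contrasts and hubs per
#' region, the prognostic survival screen, tissue clustering, and cell-type
#' enrichment. Deterministic under `config$seed` for a fixed study.
#'
#' @param study A [simulate_study()] result (or a list with the same
#'   components read from files).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: stage outputs are written as TSV/BED
#'   plus a `manifest.tsv` of row counts and parameters.
#' @return List of class `postgwas_run` with components `regions`,
#'   `candidates`, `scores`, `thresholds`, `risk_genes`, `risk_variants`,
#'   `motif_deltas`, `eqtl_flags`, `support`, `coexpression`, `survival`,
#'   `tissue_clusters`, `celltype_enrichment`, `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  regions <- build_risk_regions(study$panel, study$signals$id,
                                r2_min = config$r2_min,
                                max_dist = config$max_dist,
                                gap_max = config$gap_max)

  prox <- map_proximal(study$genes, regions, flank = config$flank)
  dist <- map_distal(study$genes, regions, study$links,
                     variants = study$panel$variants, proximal = prox,
                     fdr_max = config$fdr_max)
  candidates <- classify_candidates(rbind(prox, dist))

  # score candidates together with the training genes (needed to calibrate
  # the decision threshold); scores use the lenient (full) training set,
  # thresholds are calibrated per training set
  universe <- union(candidates$gene_id, study$training$lenient)
  scores <- score_genes(universe, study$network, study$terms,
                        study$training$lenient, alpha = config$alpha,
                        n_perm = config$n_perm,
                        partial = config$partial_scores, seed = seed)
  sv <- setNames(scores$s_gene, scores$gene_id)
  tau_s <- estimate_threshold(sv, study$training$stringent,
                              precision_target = config$precision_target,
                              exclude = study$training$lenient,
                              seed = derive_seed(seed, "tau_stringent"))
  tau_l <- estimate_threshold(sv, study$training$lenient,
                              precision_target = config$precision_target,
                              seed = derive_seed(seed, "tau_lenient"))
  scores <- call_risk_genes(scores, tau_s, tau_l)
  called <- scores$gene_id[(scores$call_stringent | scores$call_lenient)]
  risk_genes <- intersect(candidates$gene_id, called)

  risk_variants <- predict_risk_variants(
    study$panel$variants, study$annotations, risk_genes, study$genes,
    study$enhancers, regions, thresholds = config$tier_thresholds,
    promoter_window = config$promoter_window
  )

  motif_deltas <- NULL
  if (!is.null(study$sequence) && length(study$motif_library) > 0 &&
      nrow(risk_variants) > 0) {
    uniq <- study$panel$variants[
      study$panel$variants$id %in% unique(risk_variants$variant_id), ,
      drop = FALSE]
    motif_deltas <- scan_variants_motifs(study$sequence, uniq,
                                         study$motif_library,
                                         threshold = config$motif_threshold)
  }
  eqtl_flags <- cross_reference_eqtls(risk_variants, study$eqtls,
                                      fdr_max = config$fdr_max)
  support <- summarize_support(
    risk_variants,
    motif_variant_ids = unique(motif_deltas$variant_id),
    eqtl_flags = eqtl_flags
  )

  # co-expression contrast per region on the risk-gene universe
  coexpression <- list()
  meta <- study$cohort$meta
  for (rg in unique(meta$region)) {
    sel <- function(grp) meta$sample[meta$region == rg & meta$group == grp]
    sub <- study$cohort$matrix[intersect(risk_genes,
                                         rownames(study$cohort$matrix)), ,
                               drop = FALSE]
    if (nrow(sub) < 2) next
    net_case <- build_network(sub[, sel("case"), drop = FALSE],
                              r_min = config$r_min)
    net_control <- build_network(sub[, sel("control"), drop = FALSE],
                                 r_min = config$r_min)
    coexpression[[rg]] <- list(
      contrast = compare_connectivity(net_case, net_control, rownames(sub)),
      hubs_case = find_hubs(net_case, rownames(sub),
                            k = min(config$hub_k, nrow(sub))),
      hubs_control = find_hubs(net_control, rownames(sub),
                               k = min(config$hub_k, nrow(sub)))
    )
  }

  survival_screen <- screen_prognostic_genes(study$cohort, risk_genes)

  tissue_clusters <- NULL
  ct_enrich <- NULL
  if (!is.null(study$celltype)) {
    prof_genes <- intersect(risk_genes, rownames(study$celltype$mean_expr))
    if (length(prof_genes) >= 3) {
      tissue_clusters <- cluster_tissues(
        study$celltype$mean_expr[prof_genes, , drop = FALSE])
      spec <- celltype_specificity(study$celltype$mean_expr)
      ct_enrich <- celltype_enrichment(prof_genes, spec,
                                       n_boot = config$n_boot,
                                       seed = derive_seed(seed, "ewce"))
    }
  }

  run <- structure(list(
    regions = regions, candidates = candidates, scores = scores,
    thresholds = c(stringent = tau_s, lenient = tau_l),
    risk_genes = risk_genes, risk_variants = risk_variants,
    motif_deltas = motif_deltas, eqtl_flags = eqtl_flags, support = support,
    coexpression = coexpression, survival = survival_screen,
    tissue_clusters = tissue_clusters, celltype_enrichment = ct_enrich,
    config = config
  ), class = "postgwas_run")

  if (!is.null(out_dir)) write_run(run, study, out_dir)
  run
}

#' @export
print.postgwas_run <- function(x, ...) {
  s <- summarize_regions(x$regions)
  rel <- table(factor(x$candidates$relation,
                      levels = c("proximal", "distal", "both")))
  cat("Post-GWAS pipeline run\n")
  cat(sprintf("  risk regions:    %d (%.2f Mb)\n", s$count, s$span_bp / 1e6))
  cat(sprintf("  candidates:      %d (%d proximal, %d distal, %d both)\n",
              nrow(x$candidates), rel[["proximal"]], rel[["distal"]],
              rel[["both"]]))
  cat(sprintf("  risk genes:      %d (thresholds: stringent %.3g, lenient %.3g)\n",
              length(x$risk_genes), x$thresholds[["stringent"]],
              x$thresholds[["lenient"]]))
  cat(sprintf("  risk variants:   %d unique (%d tier records)\n",
              attr(x$risk_variants, "n_unique") %||%
                length(unique(x$risk_variants$variant_id)),
              nrow(x$risk_variants)))
  if (!is.na(x$support$frac_either)) {
    cat(sprintf("  supported:       %d/%d (%.0f%%) by motif delta or eQTL\n",
                x$support$n_either, x$support$n, 100 * x$support$frac_either))
  }
  cat(sprintf("  prognostic hits: %d gene(s)\n",
              length(unique(x$survival$gene_id[x$survival$flagged]))))
  invisible(x)
}

#' @export
summary.postgwas_run <- function(object, ...) {
  rel <- table(factor(object$candidates$relation,
                      levels = c("proximal", "distal", "both")))
  s <- summarize_regions(object$regions)
  list(
    n_regions = s$count, span_bp = s$span_bp,
    n_candidates = nrow(object$candidates),
    n_proximal = unname(rel[["proximal"]] + rel[["both"]]),
    n_distal = unname(rel[["distal"]] + rel[["both"]]),
    n_both = unname(rel[["both"]]),
    n_risk_genes = length(object$risk_genes),
    n_risk_variants = attr(object$risk_variants, "n_unique") %||%
      length(unique(object$risk_variants$variant_id)),
    support = object$support
  )
}
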