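# Risk-variant prediction: variants inside risk regions are grouped by the
# functional context they hit in called risk genes (coding sequence, promoter
# window, linked enhancer) and called against tier-specific score thresholds.

#' Default tier thresholds
#'
#' Coding pathogenicity > 0.7, promoter |log fold change| > ln(1.2), enhancer
#' selection score > 0.9; all strict.
#' @export
tier_thresholds <- function() {
  c(coding = 0.7, promoter = log(1.2), enhancer = 0.9)
}

# Strand-aware promoter window [tss - up, tss + down) on +, mirrored on -.
promoter_interval <- function(tss, strand, window = c(2000, 500)) {
  up <- window[1]
  down <- window[2]
  if (strand == "-") {
    c(max(tss - down + 1, 0), tss + up + 1)
  } else {
    c(max(tss - up, 0), tss + down)
  }
}

#' Functional contexts of a variant with respect to risk genes
#'
#' Returns every (tier, gene) context the variant position hits: `coding` if
#' inside a risk gene's coding interval, `promoter` if inside the strand-aware
#' promoter window around a risk gene's TSS, `enhancer` if inside an enhancer
#' interval linked to a risk gene. A variant may carry multiple contexts and
#' multiple genes.
#'
#' @param variant One-row variant data frame (`id`, `chrom`, `pos`).
#' @param risk_genes Character vector of called risk gene ids.
#' @param genes Gene models with list-column `coding` (two-column
#'   start/end matrices, 0-based half-open) plus `tss` and `strand`.
#' @param enhancers Enhancer link rows (`chrom`, `start`, `end`,
#'   `target_gene`).
#' @param promoter_window `c(upstream_bp, downstream_bp)` around the TSS.
#' @return Data frame with columns `tier`, `gene_id` (possibly empty).
#' @export
assign_context <- function(variant, risk_genes, genes, enhancers,
                           promoter_window = c(2000, 500)) {
  pos <- variant$pos
  chrom <- variant$chrom
  out <- list()
  g <- genes[genes$gene_id %in% risk_genes & genes$chrom == chrom, ,
             drop = FALSE]
  for (k in seq_len(nrow(g))) {
    cd <- g$coding[[k]]
    if (!is.null(cd) && nrow(cd) > 0 &&
        any(pos >= cd[, 1] & pos < cd[, 2])) {
      out[[length(out) + 1L]] <- data.frame(tier = "coding",
                                            gene_id = g$gene_id[k])
    }
    pw <- promoter_interval(g$tss[k], g$strand[k], promoter_window)
    if (pos >= pw[1] && pos < pw[2]) {
      out[[length(out) + 1L]] <- data.frame(tier = "promoter",
                                            gene_id = g$gene_id[k])
    }
  }
  if (!is.null(enhancers) && nrow(enhancers) > 0) {
    hit <- enhancers$chrom == chrom & pos >= enhancers$start &
      pos < enhancers$end & enhancers$target_gene %in% risk_genes
    for (tg in unique(enhancers$target_gene[hit])) {
      out[[length(out) + 1L]] <- data.frame(tier = "enhancer", gene_id = tg)
    }
  }
  if (length(out) == 0) {
    return(data.frame(tier = character(), gene_id = character()))
  }
  unique(do.call(rbind, out))
}

#' Call one variant in one tier against its score threshold
#'
#' Strict comparisons throughout: a score exactly at the threshold is not
#' called. The promoter tier compares the absolute log fold change
#' (direction-agnostic). A missing score for the tier returns `NA`
#' (not callable), never an error.
#'
#' @param tier `"coding"`, `"promoter"` or `"enhancer"`.
#' @param annotation One-row annotation data frame with columns
#'   `coding_score`, `promoter_effect`, `enhancer_score` (NA = absent).
#' @param thresholds Named numeric vector as from [tier_thresholds()].
#' @return `TRUE`, `FALSE`, or `NA` when the tier's score is absent.
#' @export
call_risk_variant <- function(tier, annotation,
                              thresholds = tier_thresholds()) {
  score <- switch(tier,
    coding = annotation$coding_score,
    promoter = annotation$promoter_effect,
    enhancer = annotation$enhancer_score,
    stop_invalid("unknown tier: ", tier)
  )
  if (is.null(score) || length(score) == 0 || is.na(score)) return(NA)
  if (tier == "promoter") score <- abs(score)
  score > thresholds[[tier]]
}

#' Predict risk variants for a set of risk genes
#'
#' Considers every panel variant inside a risk region, assigns functional
#' contexts with respect to the called risk genes, and calls each context's
#' tier against its threshold. A variant passing in several tiers emits one
#' record per tier but counts once in the unique tally.
#'
#' @param variants Variant table (`id`, `chrom`, `pos`).
#' @param annotations Annotation table keyed by `variant_id` with score
#'   columns `coding_score`, `promoter_effect`, `enhancer_score`.
#' @param risk_genes Called risk gene ids.
#' @param genes Gene models (see [assign_context()]).
#' @param enhancers Enhancer link rows.
#' @param regions Merged risk regions.
#' @param thresholds Tier thresholds.
#' @param promoter_window Promoter window around the TSS.
#' @return Data frame, one row per (variant, tier): `variant_id`, `chrom`,
#'   `pos`, `tier`, `score`, `region_id`, and list-column `linked_genes`;
#'   ordered by (chrom, pos, tier). Attribute `n_unique` holds the unique
#'   variant tally.
#' @export
predict_risk_variants <- function(variants, annotations, risk_genes, genes,
                                  enhancers, regions,
                                  thresholds = tier_thresholds(),
                                  promoter_window = c(2000, 500)) {
  empty <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), tier = character(), score = numeric(),
                      region_id = character(),
                      linked_genes = I(list()))
  attr(empty, "n_unique") <- 0L
  if (length(risk_genes) == 0 || nrow(regions) == 0) return(empty)

  # restrict to variants inside a risk region
  region_of <- rep(NA_character_, nrow(variants))
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    inside <- variants$chrom == r$chrom & variants$pos >= r$start &
      variants$pos < r$end
    region_of[inside] <- r$region_id
  }
  keep <- !is.na(region_of)
  vv <- variants[keep, , drop = FALSE]
  region_of <- region_of[keep]

  ann_idx <- match(vv$id, annotations$variant_id)
  rows <- list()
  for (k in seq_len(nrow(vv))) {
    if (is.na(ann_idx[k])) next
    ann <- annotations[ann_idx[k], , drop = FALSE]
    ctx <- assign_context(vv[k, ], risk_genes, genes, enhancers,
                          promoter_window)
    if (nrow(ctx) == 0) next
    for (tier in unique(ctx$tier)) {
      called <- call_risk_variant(tier, ann, thresholds)
      if (isTRUE(called)) {
        score <- switch(tier, coding = ann$coding_score,
                        promoter = ann$promoter_effect,
                        enhancer = ann$enhancer_score)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vv$id[k], chrom = vv$chrom[k], pos = vv$pos[k],
          tier = tier, score = score, region_id = region_of[k],
          linked_genes = I(list(sort(ctx$gene_id[ctx$tier == tier]))),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$tier), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unique") <- length(unique(out$variant_id))
  out
}

#' Cross-reference risk variants against eQTL tables
#'
#' A support flag is set when the (variant, linked gene) pair appears in the
#' eQTL table with `fdr < fdr_max` (strict). Population-reference-style and
#' disease-cohort-style tables are flagged separately.
#'
#' @param risk_variants Output of [predict_risk_variants()].
#' @param eqtls Data frame (`variant_id`, `gene_id`, `tissue`, `fdr`), or a
#'   named list of two such tables `list(reference = ..., cohort = ...)`.
#' @param fdr_max FDR cutoff (strict `<`).
#' @return Data frame keyed by unique `variant_id` with logical columns
#'   `eqtl_reference`, `eqtl_cohort`.
#' @export
cross_reference_eqtls <- function(risk_variants, eqtls, fdr_max = 0.05) {
  if (is.data.frame(eqtls)) eqtls <- list(reference = eqtls)
  ids <- unique(risk_variants$variant_id)
  linked <- lapply(ids, function(v) {
    unique(unlist(risk_variants$linked_genes[risk_variants$variant_id == v]))
  })
  names(linked) <- ids
  flag_for <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(rep(FALSE, length(ids)))
    tab <- tab[!is.na(tab$fdr) & tab$fdr < fdr_max, , drop = FALSE]
    key <- paste(tab$variant_id, tab$gene_id)
    vapply(ids, function(v) {
      any(paste(v, linked[[v]]) %in% key)
    }, logical(1))
  }
  out <- data.frame(variant_id = ids,
                    eqtl_reference = flag_for(eqtls$reference),
                    eqtl_cohort = flag_for(eqtls$cohort),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fraction of risk variants with functional support
#'
#' @param risk_variants Output of [predict_risk_variants()].
#' @param motif_variant_ids Variant ids with at least one motif gain/loss.
#' @param eqtl_flags Output of [cross_reference_eqtls()] (optional).
#' @return List with counts and fractions of unique risk variants supported
#'   by (a) a motif delta, (b) an eQTL, (c) either. `NA` fractions when there
#'   are no risk variants.
#' @export
summarize_support <- function(risk_variants, motif_variant_ids = character(),
                              eqtl_flags = NULL) {
  ids <- unique(risk_variants$variant_id)
  n <- length(ids)
  if (n == 0) {
    return(list(n = 0L, n_motif = 0L, n_eqtl = 0L, n_either = 0L,
                frac_motif = NA_real_, frac_eqtl = NA_real_,
                frac_either = NA_real_))
  }
  motif_set <- intersect(ids, motif_variant_ids)
  eqtl_set <- character(0)
  if (!is.null(eqtl_flags) && nrow(eqtl_flags) > 0) {
    any_flag <- eqtl_flags$eqtl_reference | eqtl_flags$eqtl_cohort
    eqtl_set <- intersect(ids, eqtl_flags$variant_id[any_flag])
  }
  either <- union(motif_set, eqtl_set)
  list(n = n, n_motif = length(motif_set), n_eqtl = length(eqtl_set),
       n_either = length(either),
       frac_motif = length(motif_set) / n,
       frac_eqtl = length(eqtl_set) / n,
       frac_either = length(either) / n)
}
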