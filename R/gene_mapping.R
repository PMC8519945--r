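# Linking candidate genes to risk regions: proximal (gene body overlaps the
# region after a 20 kb extension) or distal (regulatory element inside the
# region targets the gene).

#' Map proximal genes to risk regions
#'
#' A gene is proximal to a region when its body, extended by `flank` bp on
#' each end (floored at 0), intersects the region under the half-open
#' convention. A gap of exactly `flank` bp therefore does not qualify.
#'
#' @param genes Gene-model data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `tss`.
#' @param regions Merged region data frame (see [build_risk_regions()]).
#' @param flank Extension in bp applied to both gene ends.
#' @return Evidence data frame: `gene_id`, `region_id`, `mechanism`
#'   (`"overlap"`), `link_id` (`NA`).
#' @export
map_proximal <- function(genes, regions, flank = 20000) {
  rows <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    hit <- genes$chrom == r$chrom &
      intervals_overlap(pmax(genes$start - flank, 0), genes$end + flank,
                        r$start, r$end)
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[hit], region_id = r$region_id,
        mechanism = "overlap", link_id = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), region_id = character(),
                      mechanism = character(), link_id = character()))
  }
  do.call(rbind, rows)
}

#' Map distal genes to risk regions through regulatory links
#'
#' A regulatory link contributes distal evidence (gene, region) when its
#' element lies inside the region — the enhancer interval intersects it, or
#' the eQTL variant's position falls in it — and the target gene is not
#' proximal to that same region. eQTL links additionally require
#' `fdr < fdr_max` (strict). Links naming unknown genes are skipped with a
#' warning.
#'
#' @inheritParams map_proximal
#' @param links Link data frame with columns `link_id`, `kind`
#'   (`"enhancer"`/`"eqtl"`), `chrom`, `start`, `end` (enhancer interval; `NA`
#'   for eQTLs), `variant_id` (eQTLs; `NA` for enhancers), `target_gene`,
#'   `tissue`, `fdr` (eQTLs).
#' @param variants Variant table locating eQTL variant ids (`id`, `chrom`,
#'   `pos`); may be `NULL` when `links` holds no eQTLs.
#' @param proximal Evidence from [map_proximal()] for the same regions, used
#'   for the per-region exclusivity rule.
#' @param fdr_max eQTL FDR cutoff (strict `<`).
#' @return Evidence data frame: `gene_id`, `region_id`, `mechanism`
#'   (`"enhancer"`/`"eqtl"`), `link_id`.
#' @export
map_distal <- function(genes, regions, links, variants = NULL,
                       proximal = NULL, fdr_max = 0.05) {
  if (is.null(proximal)) proximal <- map_proximal(genes, regions)
  empty <- data.frame(gene_id = character(), region_id = character(),
                      mechanism = character(), link_id = character())
  if (nrow(links) == 0 || nrow(regions) == 0) return(empty)

  unknown <- !(links$target_gene %in% genes$gene_id)
  if (any(unknown)) {
    warning(sum(unknown), " link(s) reference unknown genes; skipped")
    links <- links[!unknown, , drop = FALSE]
  }
  is_eqtl <- links$kind == "eqtl"
  if (any(is_eqtl)) {
    links <- links[!is_eqtl | (!is.na(links$fdr) & links$fdr < fdr_max), ,
                   drop = FALSE]
    is_eqtl <- links$kind == "eqtl"
    if (any(is_eqtl)) {
      if (is.null(variants)) stop_invalid("eQTL links need a variant table")
      j <- match(links$variant_id[is_eqtl], variants$id)
      if (anyNA(j)) stop_invalid("eQTL links reference unknown variants")
      links$chrom[is_eqtl] <- variants$chrom[j]
      links$start[is_eqtl] <- variants$pos[j]
      links$end[is_eqtl] <- variants$pos[j] + 1L
    }
  }
  prox_key <- paste(proximal$gene_id, proximal$region_id)

  rows <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    inside <- links$chrom == r$chrom &
      links$start >= r$start & links$end <= r$end
    if (!any(inside)) next
    l <- links[inside, , drop = FALSE]
    keep <- !(paste(l$target_gene, r$region_id) %in% prox_key)
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = l$target_gene[keep], region_id = r$region_id,
        mechanism = l$kind[keep], link_id = l$link_id[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  unique(do.call(rbind, rows))
}

#' Classify candidate genes from mapping evidence
#'
#' Genes with at least one evidence row become candidates; the relation is
#' `"proximal"` (only overlap evidence), `"distal"` (only regulatory-link
#' evidence) or `"both"`.
#'
#' @param evidence Row-bound output of [map_proximal()] and [map_distal()].
#' @return Data frame: `gene_id`, `relation`, `n_regions`, plus list-columns
#'   `region_ids` and `evidence` (the gene's evidence rows).
#' @export
classify_candidates <- function(evidence) {
  if (nrow(evidence) == 0) {
    return(data.frame(gene_id = character(), relation = character(),
                      n_regions = integer(),
                      region_ids = I(list()), evidence = I(list())))
  }
  split_ev <- split(evidence, evidence$gene_id)
  res <- lapply(names(split_ev), function(g) {
    ev <- split_ev[[g]]
    has_prox <- any(ev$mechanism == "overlap")
    has_dist <- any(ev$mechanism %in% c("enhancer", "eqtl"))
    relation <- if (has_prox && has_dist) "both"
      else if (has_prox) "proximal" else "distal"
    regs <- sort(unique(ev$region_id))
    data.frame(gene_id = g, relation = relation, n_regions = length(regs),
               region_ids = I(list(regs)), evidence = I(list(ev)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$gene_id), , drop = FALSE]
}

#' Tally candidate relations and check inclusion-exclusion bookkeeping
#'
#' Given per-relation counts (genes with proximal evidence, genes with distal
#' evidence, genes with both), returns the implied unique-candidate count and
#' derived fractions used in run reports.
#'
#' @param n_proximal,n_distal,n_both Relation tallies; `n_proximal` and
#'   `n_distal` each include the `both` genes.
#' @return List with `n_unique` (= proximal + distal - both) and the three
#'   inputs.
#' @export
candidate_tally <- function(n_proximal, n_distal, n_both) {
  stopifnot(n_both <= n_proximal, n_both <= n_distal)
  list(n_unique = n_proximal + n_distal - n_both,
       n_proximal = n_proximal, n_distal = n_distal, n_both = n_both)
}
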