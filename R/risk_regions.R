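# Construction of genomic risk regions: LD blocks seeded by association SNPs,
# merged when overlapping or close.

#' Squared Pearson correlation (r2) between two variants' dosages
#'
#' Linkage disequilibrium is measured as the squared Pearson correlation of
#' genotype dosage vectors (composite LD; no phasing required). When either
#' dosage vector is constant (monomorphic in the panel) the correlation is
#' undefined and `NA` is returned.
#'
#' @param panel A genotype panel as returned by [simulate_genotype_panel()] or
#'   [read_vcf_panel()]: a list with `variants` (data frame) and `dosages`
#'   (samples x variants matrix with entries 0/1/2, columns named by variant
#'   id).
#' @param v1,v2 Variant ids present in the panel.
#' @return A single numeric in \[0, 1\], or `NA` when undefined.
#' @examples
#' p <- list(
#'   variants = data.frame(id = c("a", "b"), chrom = "1", pos = c(0L, 10L)),
#'   dosages = cbind(a = c(0, 0, 2, 2), b = c(2, 2, 0, 0))
#' )
#' ld_r2(p, "a", "b") # perfectly anti-correlated -> 1
#' @export
ld_r2 <- function(panel, v1, v2) {
  d <- panel$dosages
  for (v in c(v1, v2)) {
    if (!v %in% colnames(d)) stop_invalid("variant not found in panel: ", v)
  }
  x <- d[, v1]
  y <- d[, v2]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  min(r * r, 1)
}

# All pairwise r2 of a seed variant against panel columns, NA where undefined.
ld_r2_vector <- function(panel, seed) {
  d <- panel$dosages
  if (!seed %in% colnames(d)) stop_invalid("variant not found in panel: ", seed)
  x <- d[, seed]
  if (stats::var(x) == 0) {
    return(setNames(rep(NA_real_, ncol(d)), colnames(d)))
  }
  sds <- apply(d, 2, stats::sd)
  r <- suppressWarnings(as.vector(stats::cor(x, d)))
  r[sds == 0] <- NA_real_
  setNames(pmin(r * r, 1), colnames(d))
}

#' Build the LD block seeded by one association SNP
#'
#' Recruits every panel variant on the seed's chromosome that is in
#' substantial LD with the seed (`r2 > r2_min`, strict) and lies strictly
#' closer than `max_dist` base pairs. Membership is seed-anchored (star
#' topology); chaining across blocks is handled later by [merge_regions()].
#' A monomorphic seed yields a single-SNP region with a warning: LD with a
#' monomorphic variant is undefined and treated as below threshold.
#'
#' @inheritParams ld_r2
#' @param seed Variant id of the association SNP seeding the block.
#' @param r2_min LD threshold; membership requires r2 strictly greater.
#' @param max_dist Maximum seed distance in bp; membership requires strictly
#'   less.
#' @return A one-row data frame with columns `region_id`, `chrom`, `start`,
#'   `end` (0-based half-open) and list-columns `seed_snps`, `member_snps`.
#' @export
build_seed_region <- function(panel, seed, r2_min = 0.5, max_dist = 400000) {
  vt <- panel$variants
  i <- match(seed, vt$id)
  if (is.na(i)) stop_invalid("seed variant not found in panel: ", seed)
  r2 <- ld_r2_vector(panel, seed)
  if (all(is.na(r2))) {
    warning("seed variant ", seed, " is monomorphic; region contains only the seed")
  }
  same_chrom <- vt$chrom == vt$chrom[i]
  near <- abs(vt$pos - vt$pos[i]) < max_dist
  pass <- !is.na(r2) & r2 > r2_min & same_chrom & near
  members <- union(seed, vt$id[pass])
  pos <- vt$pos[match(members, vt$id)]
  data.frame(
    region_id = paste0("region_", seed),
    chrom = vt$chrom[i],
    start = min(pos),
    end = max(pos) + 1L,
    seed_snps = I(list(seed)),
    member_snps = I(list(members[order(pos, members)])),
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping or nearby LD blocks into risk regions
#'
#' Blocks on the same chromosome whose gap is strictly less than `gap_max`
#' (overlapping blocks have negative gap) are merged transitively until a
#' fixpoint: the result is a set of per-chromosome, sorted regions pairwise
#' separated by at least `gap_max`. Seed and member SNP sets of merged blocks
#' are unioned.
#'
#' @param regions A data frame of regions as produced by
#'   [build_seed_region()] (rows may come from many seeds).
#' @param gap_max Merge blocks whose gap is strictly below this many bp.
#' @return A region data frame of the same shape, with fresh `region_id`s of
#'   the form `chrom:start-end`.
#' @export
merge_regions <- function(regions, gap_max = 250000) {
  if (nrow(regions) == 0) return(regions)
  ord <- order(regions$chrom, regions$start, regions$region_id)
  regions <- regions[ord, , drop = FALSE]
  out <- list()
  cur <- NULL
  for (k in seq_len(nrow(regions))) {
    row <- regions[k, , drop = FALSE]
    if (!is.null(cur) && row$chrom == cur$chrom && row$start - cur$end < gap_max) {
      cur$end <- max(cur$end, row$end)
      cur$seed_snps[[1]] <- union(cur$seed_snps[[1]], row$seed_snps[[1]])
      cur$member_snps[[1]] <- union(cur$member_snps[[1]], row$member_snps[[1]])
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  res$region_id <- paste0(res$chrom, ":", res$start, "-", res$end)
  rownames(res) <- NULL
  res
}

#' Build merged risk regions from association SNPs
#'
#' Convenience wrapper: one LD block per association seed (deterministic
#' processing order: chromosome, position, id), then [merge_regions()].
#'
#' @inheritParams build_seed_region
#' @inheritParams merge_regions
#' @param seeds Character vector of association SNP ids (must be panel
#'   variants).
#' @export
build_risk_regions <- function(panel, seeds, r2_min = 0.5, max_dist = 400000,
                               gap_max = 250000) {
  if (length(seeds) == 0) {
    return(data.frame(
      region_id = character(), chrom = character(),
      start = integer(), end = integer(),
      seed_snps = I(list()), member_snps = I(list())
    ))
  }
  vt <- panel$variants
  i <- match(seeds, vt$id)
  if (anyNA(i)) stop_invalid("seed variants absent from panel: ",
                             paste(seeds[is.na(i)], collapse = ", "))
  seeds <- seeds[order(vt$chrom[i], vt$pos[i], seeds)]
  blocks <- do.call(rbind, lapply(seeds, function(s) {
    build_seed_region(panel, s, r2_min = r2_min, max_dist = max_dist)
  }))
  merge_regions(blocks, gap_max = gap_max)
}

#' Count and total span of merged risk regions
#'
#' @param regions Merged (non-overlapping) region data frame.
#' @return A list with `count` and `span_bp` (sum of end - start).
#' @export
summarize_regions <- function(regions) {
  if (nrow(regions) > 1) {
    ord <- order(regions$chrom, regions$start)
    r <- regions[ord, ]
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    if (any(same & r$start[-1] < r$end[-nrow(r)])) {
      stop_invalid("regions overlap; merge them first")
    }
  }
  list(count = nrow(regions), span_bp = sum(regions$end - regions$start))
}
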