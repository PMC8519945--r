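# Shared fixtures and independent oracles, built in code at test time.

# Build a genotype panel from an explicit dosage matrix (samples x variants).
make_panel <- function(dosages, pos = NULL, chrom = "chr1") {
  m <- ncol(dosages)
  ids <- colnames(dosages) %||% paste0("v", seq_len(m))
  colnames(dosages) <- ids
  if (is.null(pos)) pos <- seq_len(m) * 100L
  structure(list(
    variants = data.frame(id = ids, chrom = chrom, pos = pos,
                          ref = "A", alt = "C", stringsAsFactors = FALSE),
    dosages = dosages,
    blocks = NULL
  ), class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent all-pairs implementation of region construction: per-seed star
# recruitment by direct cor()^2, then transitive merging by union-find.
brute_force_regions <- function(panel, seeds, r2_min = 0.5,
                                max_dist = 400000, gap_max = 250000) {
  vt <- panel$variants
  d <- panel$dosages
  members <- lapply(seeds, function(s) {
    i <- match(s, vt$id)
    keep <- s
    for (j in seq_len(nrow(vt))) {
      if (vt$id[j] == s) next
      if (vt$chrom[j] != vt$chrom[i]) next
      if (abs(vt$pos[j] - vt$pos[i]) >= max_dist) next
      x <- d[, i]; y <- d[, j]
      if (sd(x) == 0 || sd(y) == 0) next
      if (cor(x, y)^2 > r2_min) keep <- c(keep, vt$id[j])
    }
    keep
  })
  span <- lapply(members, function(mm) {
    p <- vt$pos[match(mm, vt$id)]
    c(min(p), max(p) + 1L, match(vt$chrom[match(mm[1], vt$id)],
                                 unique(vt$chrom)))
  })
  # union-find over blocks closer than gap_max on the same chromosome
  n <- length(seeds)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (span[[i]][3] != span[[j]][3]) next
      gap <- max(span[[i]][1], span[[j]][1]) - min(span[[i]][2], span[[j]][2])
      if (gap < gap_max) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  lapply(groups, function(g) {
    mm <- sort(unique(unlist(members[g])))
    p <- vt$pos[match(mm, vt$id)]
    list(members = mm, start = min(p), end = max(p) + 1L)
  })
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive PWM scan written independently of the package implementation.
brute_pwm_best <- function(mat, pseudocount, seq) {
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  lo <- log2(p / 0.25)
  score_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- ncol(mat)
    if (length(ch) < w) return(NA_real_)
    best <- -Inf
    for (off in 0:(length(ch) - w)) {
      sc <- 0
      for (i in 1:w) {
        b <- match(ch[off + i], c("A", "C", "G", "T"))
        if (!is.na(b)) sc <- sc + lo[b, i]
      }
      best <- max(best, sc)
    }
    best
  }
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(seq, "")[[1]])),
              collapse = "")
  max(score_of(seq), score_of(rc))
}

# A tiny gene-model table builder.
make_gene <- function(gene_id, start, width = 10000, chrom = "chr1",
                      strand = "+", coding = NULL) {
  end <- start + width
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand,
             tss = if (strand == "+") start else end - 1L,
             coding = I(list(coding %||% cbind(start + 1000L, start + 2000L))),
             stringsAsFactors = FALSE)
}
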