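# Co-expression networks, connectivity contrasts, tissue clustering, and
# expression-weighted cell-type enrichment.

#' Clean a proteomic-style matrix with missing-value tokens
#'
#' Values of `0` or the token `"#N/A"` are treated as missing. Rows
#' (proteins) observed in fewer than `min_obs` samples in either group are
#' dropped; remaining missing entries are imputed with the mean of the
#' observed values of the same row within the entry's own group.
#'
#' @param mat Numeric or character matrix (genes x samples); character
#'   matrices may mix numbers with `"#N/A"` tokens.
#' @param groups Factor/character vector of sample groups (two levels, e.g.
#'   case/control), aligned with columns.
#' @param min_obs Minimum observed samples per group (default 3).
#' @return Numeric matrix with rows filtered and missing entries imputed.
#' @export
preprocess_proteomics <- function(mat, groups, min_obs = 3) {
  stopifnot(length(groups) == ncol(mat))
  x <- matrix(suppressWarnings(as.numeric(mat)), nrow(mat), ncol(mat),
              dimnames = dimnames(mat))
  x[!is.na(x) & x == 0] <- NA # the 0 token encodes a missing measurement
  lev <- unique(as.character(groups))
  obs_by_group <- vapply(lev, function(g) {
    rowSums(!is.na(x[, groups == g, drop = FALSE]))
  }, numeric(nrow(x)))
  obs_by_group <- matrix(obs_by_group, nrow = nrow(x))
  keep <- rowSums(obs_by_group >= min_obs) == length(lev)
  x <- x[keep, , drop = FALSE]
  for (g in lev) {
    cols <- which(groups == g)
    mu <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    stopifnot(all(is.finite(mu))) # guaranteed by the min_obs filter
    for (j in cols) {
      miss <- is.na(x[, j])
      x[miss, j] <- mu[miss]
    }
  }
  x
}

#' Build a co-expression network by Pearson correlation
#'
#' Genes are connected when their Pearson correlation across samples is
#' strictly greater than `r_min` (signed r, not absolute, by default).
#' Constant genes have undefined correlations and receive no edges.
#'
#' @param mat Numeric matrix, genes x samples (>= 3 samples).
#' @param r_min Correlation threshold (default 0.7, strict `>`).
#' @param absolute Use `|r|` instead of signed r.
#' @return List of class `coexpression_network` with `genes`, `adjacency`
#'   (logical symmetric matrix, no self-edges) and `r_min`.
#' @export
build_network <- function(mat, r_min = 0.7, absolute = FALSE) {
  if (ncol(mat) < 3) stop_invalid("need at least 3 samples")
  r <- suppressWarnings(stats::cor(t(mat)))
  if (absolute) r <- abs(r)
  adj <- !is.na(r) & r > r_min
  diag(adj) <- FALSE
  structure(list(genes = rownames(mat), adjacency = adj, r_min = r_min),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", length(x$genes), "genes,",
      sum(x$adjacency) / 2, "edges (r >", x$r_min, ")\n")
  invisible(x)
}

#' Degrees of a gene set within its induced subgraph
#'
#' @param network A [build_network()] result.
#' @param gene_set Character vector of genes of interest.
#' @param induced Count edges only within `gene_set` (default) or against the
#'   whole network.
#' @return Data frame `gene_id`, `degree`, `in_network`; genes absent from
#'   the network get degree 0 and `in_network = FALSE`.
#' @export
connectivity <- function(network, gene_set, induced = TRUE) {
  present <- gene_set %in% network$genes
  deg <- setNames(rep(0L, length(gene_set)), gene_set)
  inside <- gene_set[present]
  if (length(inside) > 0) {
    cols <- if (induced) inside else network$genes
    sub <- network$adjacency[inside, cols, drop = FALSE]
    deg[inside] <- rowSums(sub)
  }
  data.frame(gene_id = gene_set, degree = as.integer(deg),
             in_network = present, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Contrast risk-gene connectivity between two networks
#'
#' Welch two-sided t-test on the per-gene degrees of the same gene set in two
#' networks (e.g. case vs control co-expression networks over the same gene
#' universe).
#'
#' @param net_a,net_b Two [build_network()] results.
#' @param gene_set Genes whose induced-subgraph degrees are compared.
#' @param induced Passed to [connectivity()].
#' @return List with `t` (sign positive when degrees in `net_a` exceed
#'   `net_b`), `p`, and the two mean degrees.
#' @export
compare_connectivity <- function(net_a, net_b, gene_set, induced = TRUE) {
  da <- connectivity(net_a, gene_set, induced)$degree
  db <- connectivity(net_b, gene_set, induced)$degree
  if (length(da) < 2) stop_invalid("need at least 2 genes")
  if (stats::var(da) == 0 && stats::var(db) == 0) {
    return(list(t = 0, p = 1, mean_a = mean(da), mean_b = mean(db)))
  }
  tt <- stats::t.test(da, db, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(da), mean_b = mean(db))
}

#' Network hubs: the k most connected genes
#'
#' Ranks genes of a set by their induced-subgraph degree (descending), with
#' lexicographic gene-id tie-break, and returns the top `k`. When the set has
#' fewer than `k` genes all are returned with a warning.
#'
#' @inheritParams connectivity
#' @param k Number of hubs (default 20).
#' @return Data frame of the hub genes with their degrees, in rank order.
#' @export
find_hubs <- function(network, gene_set, k = 20, induced = TRUE) {
  deg <- connectivity(network, gene_set, induced)
  if (nrow(deg) < k) {
    warning("fewer genes (", nrow(deg), ") than requested hubs (", k, ")")
    k <- nrow(deg)
  }
  ord <- order(-deg$degree, deg$gene_id)
  out <- deg[ord[seq_len(k)], c("gene_id", "degree"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster genes by tissue expression profile
#'
#' Agglomerative hierarchical clustering of gene expression profiles across
#' tissues using Euclidean distance and Ward's method (`ward.D2`), with the
#' tree cut at `n_clusters`.
#'
#' @param mat Numeric matrix, genes x tissues (finite values).
#' @param n_clusters Number of clusters (default 3).
#' @return Named integer vector of cluster labels (1..n_clusters).
#' @export
cluster_tissues <- function(mat, n_clusters = 3) {
  if (!all(is.finite(mat))) stop_invalid("expression matrix must be finite")
  if (nrow(mat) < n_clusters) stop_invalid("fewer genes than clusters")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  stats::cutree(hc, k = n_clusters)
}

#' Per-gene cell-type expression specificity
#'
#' The specificity of gene g in cell type c is its mean expression in c
#' divided by the sum of its mean expressions over all types; rows of
#' expressed genes sum to 1.
#'
#' @param mean_expr Numeric matrix, genes x cell types, of average expression
#'   per type.
#' @return Matrix of the same shape with rows normalised (all-zero rows stay
#'   zero).
#' @export
celltype_specificity <- function(mean_expr) {
  tot <- rowSums(mean_expr)
  spec <- mean_expr / ifelse(tot == 0, 1, tot)
  spec[tot == 0, ] <- 0
  spec
}

#' Expression-weighted cell-type enrichment (bootstrap specificity test)
#'
#' For each cell type, the statistic is the summed specificity of the target
#' genes in that type; its p-value is estimated against `n_boot` random gene
#' sets of equal size drawn uniformly from the profiled genes, with the
#' add-one estimator `p = (1 + #{bootstrap >= observed}) / (n_boot + 1)`.
#' P-values are Benjamini-Hochberg adjusted across cell types.
#'
#' @param target_genes Character vector (must be a subset of profiled genes).
#' @param specificity Matrix from [celltype_specificity()].
#' @param n_boot Number of bootstrap draws (>= 100).
#' @param seed Integer seed.
#' @return Data frame `cell_type`, `statistic`, `p`, `fdr`, sorted by `p`.
#' @export
celltype_enrichment <- function(target_genes, specificity, n_boot = 10000,
                                seed = 1) {
  if (length(target_genes) == 0) stop_invalid("empty target gene set")
  if (n_boot < 100) stop_invalid("n_boot must be at least 100")
  genes <- rownames(specificity)
  missing <- setdiff(target_genes, genes)
  if (length(missing) > 0) {
    stop_invalid("target genes absent from profile: ",
                 paste(head(missing, 5), collapse = ", "))
  }
  m <- length(target_genes)
  obs <- colSums(specificity[target_genes, , drop = FALSE])
  exceed <- with_seed(seed, {
    acc <- rep(0L, ncol(specificity))
    for (b in seq_len(n_boot)) {
      draw <- sample(genes, m)
      acc <- acc + (colSums(specificity[draw, , drop = FALSE]) >= obs)
    }
    acc
  })
  p <- (1 + exceed) / (n_boot + 1)
  out <- data.frame(cell_type = colnames(specificity), statistic = obs,
                    p = p, fdr = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$cell_type), , drop = FALSE]
}
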