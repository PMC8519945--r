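# Candidate-gene risk scoring: permutation-based network and annotation
# statistics combined as S_g = alpha * S^(n) + (1 - alpha) * S^(a), with a
# precision-calibrated decision threshold against training gene sets.

# Dense symmetric weight matrix over network nodes from an edge list.
network_weight_matrix <- function(network) {
  stopifnot(all(c("from", "to", "weight") %in% names(network)))
  if (any(network$from == network$to)) stop_invalid("self-loops not allowed")
  if (any(network$weight <= 0)) stop_invalid("edge weights must be positive")
  nodes <- sort(unique(c(network$from, network$to)))
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  i <- match(network$from, nodes)
  j <- match(network$to, nodes)
  W[cbind(i, j)] <- network$weight
  W[cbind(j, i)] <- network$weight
  W
}

#' Network-based gene score
#'
#' The gene's training-connectivity statistic is the summed edge weight from
#' the gene to training genes, `T(g) = sum over t in N(g) ∩ training of
#' w(g, t)`. Its empirical p-value is estimated against a null of `n_perm`
#' random gene sets of the same size as the (network-restricted) training
#' set, drawn uniformly from the network nodes; the gene's own edges are kept
#' fixed, so the gene's degree is preserved under the null. The score is
#' `-log10(p)` with the add-one estimator, hence bounded by
#' `log10(n_perm + 1)`.
#'
#' @param gene Gene id. Genes absent from the network are unscorable and get
#'   `NA` (not an error).
#' @param network Weighted undirected edge list: columns `from`, `to`,
#'   `weight` in (0, 1\].
#' @param training Character vector of training gene ids.
#' @param n_perm Number of null draws.
#' @param seed Integer seed for the null draws.
#' @return Numeric score (`-log10` empirical p), or `NA` if unscorable.
#' @export
network_score <- function(gene, network, training, n_perm = 10000, seed = 1) {
  scores <- network_score_all(gene, network, training, n_perm = n_perm,
                              seed = seed)
  unname(scores[1])
}

#' @rdname network_score
#' @param genes Character vector of gene ids to score together (shared null
#'   draws; much faster than calling [network_score()] per gene).
#' @export
network_score_all <- function(genes, network, training, n_perm = 10000,
                              seed = 1) {
  W <- network_weight_matrix(network)
  nodes <- rownames(W)
  tr <- intersect(training, nodes)
  out <- setNames(rep(NA_real_, length(genes)), genes)
  in_net <- genes %in% nodes
  if (!any(in_net) || length(tr) == 0) return(out)
  Wg <- W[genes[in_net], , drop = FALSE]
  T_obs <- rowSums(Wg[, tr, drop = FALSE])
  m <- length(tr)
  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(length(nodes), m),
           integer(m))
  })
  # T_null: genes x n_perm, summed weights to each random draw
  P <- matrix(0, length(nodes), n_perm)
  P[cbind(as.vector(perm_idx), rep(seq_len(n_perm), each = m))] <- 1
  T_null <- Wg %*% P
  exceed <- rowSums(T_null >= T_obs)
  p <- (1 + exceed) / (n_perm + 1)
  out[in_net] <- -log10(p)
  out
}

# Jaccard similarity matrix between two gene sets' term annotations.
jaccard_matrix <- function(terms, genes_a, genes_b) {
  all_terms <- sort(unique(unlist(terms[c(genes_a, genes_b)], use.names = FALSE)))
  inc <- function(gs) {
    M <- matrix(0L, length(gs), length(all_terms),
                dimnames = list(gs, all_terms))
    for (g in gs) M[g, match(terms[[g]], all_terms)] <- 1L
    M
  }
  A <- inc(genes_a)
  B <- inc(genes_b)
  inter <- A %*% t(B)
  sizes_a <- rowSums(A)
  sizes_b <- rowSums(B)
  un <- outer(sizes_a, sizes_b, "+") - inter
  J <- inter / un
  J[un == 0] <- 0
  J
}

#' Annotation-based gene score
#'
#' The gene's annotation statistic `A(g)` is the mean of the top `top_k`
#' Jaccard similarities between its term set and the term sets of training
#' genes. The empirical p-value is estimated against `n_perm` random draws of
#' equally many annotated genes, and the score is `-log10(p)` (add-one
#' estimator). A gene's similarity to itself never counts towards the
#' statistic (observed or null), so training genes are scored by their match
#' to the *other* training genes. Genes without any term annotation are
#' unscorable (`NA`).
#'
#' @param gene Gene id.
#' @param terms Named list mapping gene id to a character vector of term ids.
#' @param training Character vector of training gene ids.
#' @param n_perm Number of null draws.
#' @param top_k Number of best training matches averaged (default 5).
#' @param seed Integer seed.
#' @export
annotation_score <- function(gene, terms, training, n_perm = 10000,
                             top_k = 5, seed = 1) {
  unname(annotation_score_all(gene, terms, training, n_perm = n_perm,
                              top_k = top_k, seed = seed)[1])
}

#' @rdname annotation_score
#' @param genes Character vector of gene ids to score together.
#' @export
annotation_score_all <- function(genes, terms, training, n_perm = 10000,
                                 top_k = 5, seed = 1) {
  annotated <- names(terms)[lengths(terms) > 0]
  tr <- intersect(training, annotated)
  out <- setNames(rep(NA_real_, length(genes)), genes)
  has_terms <- genes %in% annotated
  if (!any(has_terms) || length(tr) == 0) return(out)
  g_in <- genes[has_terms]
  J <- jaccard_matrix(terms, g_in, annotated)
  # self-similarity never counts towards the statistic (observed or null):
  # a training gene's trivial match with itself would otherwise dominate
  self <- intersect(g_in, annotated)
  J[cbind(match(self, g_in), match(self, annotated))] <- 0
  top_mean <- function(x, k) mean(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])
  A_obs <- apply(J[, tr, drop = FALSE], 1, top_mean, k = top_k)
  m <- length(tr)
  perm_sets <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(length(annotated), m),
           integer(m))
  })
  exceed <- rep(0L, length(g_in))
  for (b in seq_len(n_perm)) {
    A_null <- apply(J[, perm_sets[, b], drop = FALSE], 1, top_mean, k = top_k)
    exceed <- exceed + (A_null >= A_obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  out[has_terms] <- -log10(p)
  out
}

#' Combine network and annotation scores
#'
#' `S_g = alpha * s_network + (1 - alpha) * s_annotation`, with `alpha`
#' strictly inside (0, 1). Genes unscorable on exactly one component receive
#' the other component at full weight only when `partial = TRUE`; otherwise
#' they are flagged unscored (`NA`).
#'
#' @param s_network,s_annotation Numeric vectors (NA = unscorable component).
#' @param alpha Relative weight of the network score, in the open interval
#'   (0, 1).
#' @param partial Fall back to the single available component?
#' @export
combine_scores <- function(s_network, s_annotation, alpha = 0.5,
                           partial = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop_invalid("alpha must lie strictly inside (0, 1)")
  }
  s <- alpha * s_network + (1 - alpha) * s_annotation
  if (partial) {
    only_n <- !is.na(s_network) & is.na(s_annotation)
    only_a <- is.na(s_network) & !is.na(s_annotation)
    s[only_n] <- s_network[only_n]
    s[only_a] <- s_annotation[only_a]
  }
  s
}

#' Score candidate genes
#'
#' Driver combining [network_score_all()], [annotation_score_all()] and
#' [combine_scores()] into a per-gene score table. Genes lacking both network
#' membership and term annotation are reported unscored.
#'
#' @param gene_ids Candidate gene ids.
#' @inheritParams network_score
#' @inheritParams annotation_score
#' @inheritParams combine_scores
#' @return Data frame with `gene_id`, `s_network`, `s_annotation`, `s_gene`,
#'   `scored`.
#' @export
score_genes <- function(gene_ids, network, terms, training, alpha = 0.5,
                        n_perm = 10000, top_k = 5, partial = FALSE, seed = 1) {
  s_n <- network_score_all(gene_ids, network, training, n_perm = n_perm,
                           seed = derive_seed(seed, "network_score"))
  s_a <- annotation_score_all(gene_ids, terms, training, n_perm = n_perm,
                              top_k = top_k,
                              seed = derive_seed(seed, "annotation_score"))
  s_g <- combine_scores(s_n, s_a, alpha = alpha, partial = partial)
  data.frame(
    gene_id = gene_ids,
    s_network = unname(s_n),
    s_annotation = unname(s_a),
    s_gene = unname(s_g),
    scored = !is.na(s_g),
    stringsAsFactors = FALSE
  )
}

#' Precision-calibrated score threshold
#'
#' Finds the smallest threshold whose cross-validated precision reaches
#' `precision_target`. Training genes present among the scored candidates are
#' split into `k_folds` folds; each fold's held-out training genes are the
#' positives and an equal-size uniform draw of non-training scored genes the
#' negatives. The whole cross-validation is repeated `repeats` times with
#' fresh fold assignments and negative draws (repeated cross-validation; a
#' single equal-size negative draw makes the precision estimate noisy).
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores; precision at a threshold pools true/false positives over folds
#' and repeats. A threshold qualifies only while it still calls at least
#' `min_recall` of the held-out positives — otherwise a spuriously clean
#' precision on a near-empty call set (e.g. a lone top-scoring training gene
#' under shuffled labels) would be accepted. Returns `NA` when no threshold
#' attains the target (e.g. shuffled labels) or when scores are degenerate.
#'
#' @param scores Named numeric vector of combined gene scores (names = gene
#'   ids; `NA` entries are unscored genes and are ignored).
#' @param training Training gene ids.
#' @param precision_target Required precision (default 0.8).
#' @param k_folds Number of folds.
#' @param repeats Number of independent cross-validation repetitions.
#' @param exclude Genes barred from the negative pool in addition to
#'   `training` (e.g. the lenient superset when calibrating on the stringent
#'   subset: a known disease gene is never a valid negative).
#' @param min_recall Minimum fraction of held-out positives a qualifying
#'   threshold must still call.
#' @param seed Integer seed controlling fold assignment and negative draws.
#' @return Threshold value, or `NA_real_` if unattainable.
#' @export
estimate_threshold <- function(scores, training, precision_target = 0.8,
                               k_folds = 5, repeats = 20,
                               exclude = character(0), min_recall = 0.5,
                               seed = 1) {
  scores <- scores[!is.na(scores)]
  genes <- names(scores)
  pos_genes <- intersect(genes, training)
  neg_pool <- setdiff(genes, union(training, exclude))
  if (length(pos_genes) < 5) {
    stop_invalid("need at least 5 scored training genes to calibrate")
  }
  uniq <- sort(unique(scores))
  if (length(uniq) < 2) return(NA_real_)
  taus <- (uniq[-1] + uniq[-length(uniq)]) / 2

  with_seed(seed, {
    pos_scores <- numeric(0)
    neg_scores <- numeric(0)
    for (r in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k_folds), length.out = length(pos_genes)))
      for (f in seq_len(k_folds)) {
        held <- pos_genes[fold == f]
        if (length(held) == 0) next
        negs <- sample(neg_pool, min(length(held), length(neg_pool)))
        pos_scores <- c(pos_scores, scores[held])
        neg_scores <- c(neg_scores, scores[negs])
      }
    }
    for (tau in taus) {
      tp <- sum(pos_scores > tau)
      fp <- sum(neg_scores > tau)
      if (tp >= min_recall * length(pos_scores) &&
          tp + fp > 0 && tp / (tp + fp) >= precision_target) {
        return(tau)
      }
    }
    NA_real_
  })
}

#' Call risk genes at stringent and lenient thresholds
#'
#' A gene is called when its combined score strictly exceeds the threshold.
#' An `NA` threshold (calibration unattainable) yields no calls for that set.
#'
#' @param scores Score table from [score_genes()].
#' @param tau_stringent,tau_lenient Thresholds from [estimate_threshold()]
#'   calibrated on the stringent and lenient training sets.
#' @return The score table with logical columns `call_stringent`,
#'   `call_lenient` added.
#' @export
call_risk_genes <- function(scores, tau_stringent, tau_lenient) {
  call_at <- function(s, tau) {
    if (is.na(tau)) rep(FALSE, length(s)) else !is.na(s) & s > tau
  }
  scores$call_stringent <- call_at(scores$s_gene, tau_stringent)
  scores$call_lenient <- call_at(scores$s_gene, tau_lenient)
  scores
}
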