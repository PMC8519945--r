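toy_network <- function() {
  # hub connected to all training genes; decoys connected among themselves
  data.frame(
    from = c("hub", "hub", "hub", "d1", "d2", "d3", "lone_t",
             "t1", "t2"),
    to = c("t1", "t2", "t3", "d2", "d3", "d4", "d1",
           "t2", "t3"),
    weight = c(0.9, 0.8, 0.7, 0.3, 0.3, 0.3, 0.2, 0.6, 0.6),
    stringsAsFactors = FALSE
  )
}

test_that("network score is maximal for a fully training-connected gene", {
  # hub connected to every training gene; a large background ring keeps the
  # chance of drawing the exact training set as a null draw negligible
  ring <- data.frame(from = paste0("b", 1:28), to = paste0("b", c(2:28, 1)),
                     weight = 0.1)
  net <- rbind(data.frame(from = "hub", to = c("t1", "t2", "t3"),
                          weight = c(0.9, 0.8, 0.7)), ring)
  training <- c("t1", "t2", "t3")
  n_perm <- 300
  s <- network_score("hub", net, training, n_perm = n_perm, seed = 3)
  expect_equal(s, log10(n_perm + 1))
  # absent gene: unscorable, not an error
  expect_true(is.na(network_score("ghost", net, training, n_perm = 100)))
})

test_that("a gene with no training edges scores near zero", {
  net <- rbind(toy_network(),
               data.frame(from = "iso", to = "d4", weight = 0.01))
  # d4's edges avoid training genes entirely; with T > 0 its p reflects how
  # often random sets catch its few partners -- but "iso" with tiny weight
  # and no training contact must sit at the bottom
  s_all <- network_score_all(c("hub", "iso"), net, c("t1", "t2", "t3"),
                             n_perm = 500, seed = 3)
  expect_true(s_all["hub"] > s_all["iso"])
})

test_that("network score matches a brute-force permutation oracle", {
  set.seed(21)
  nodes <- paste0("n", 1:30)
  edges <- t(combn(nodes, 2))
  keep <- sample(nrow(edges), 60)
  net <- data.frame(from = edges[keep, 1], to = edges[keep, 2],
                    weight = round(runif(60, 0.1, 1), 3),
                    stringsAsFactors = FALSE)
  training <- sample(nodes, 6)
  gene <- setdiff(nodes, training)[1]
  n_perm <- 1000

  # independent oracle: explicit loops over draws with the same seed stream
  W <- matrix(0, 30, 30, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(net))) {
    W[net$from[k], net$to[k]] <- net$weight[k]
    W[net$to[k], net$from[k]] <- net$weight[k]
  }
  t_obs <- sum(W[gene, training])
  set.seed(77)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    draw <- nodes[sample.int(30, length(training))]
    if (sum(W[gene, draw]) >= t_obs) exceed <- exceed + 1
  }
  oracle <- -log10((1 + exceed) / (n_perm + 1))

  got <- network_score(gene, net, training, n_perm = n_perm, seed = 77)
  # same null law, different draw stream order is possible; require
  # Monte-Carlo agreement
  expect_lt(abs(10^-got - 10^-oracle), 0.05)
})

test_that("adding a training edge never decreases the connectivity statistic", {
  net <- toy_network()
  training <- c("t1", "t2", "t3")
  base <- network_score("d1", net, training, n_perm = 300, seed = 5)
  net2 <- rbind(net, data.frame(from = "d1", to = "t1", weight = 0.9))
  more <- network_score("d1", net2, training, n_perm = 300, seed = 5)
  expect_gte(more, base)
})

test_that("annotation score rewards term overlap with training genes", {
  terms <- list(
    twin = c("a", "b", "c"), t1 = c("a", "b", "c"), t2 = c("x", "y"),
    stranger = c("q", "r"), bg1 = c("m"), bg2 = c("n"), bg3 = c("o"),
    bg4 = c("p"), bg5 = c("s")
  )
  training <- c("t1", "t2")
  s_twin <- annotation_score("twin", terms, training, n_perm = 500, seed = 2)
  s_str <- annotation_score("stranger", terms, training, n_perm = 500, seed = 2)
  expect_gt(s_twin, s_str)
  # disjoint terms give statistic 0 -> every null draw ties -> p = 1
  expect_equal(s_str, 0)
  # no terms: unscorable
  expect_true(is.na(annotation_score("absent", terms, training, n_perm = 100)))
})

test_that("annotation score matches a brute-force oracle on a 20-gene toy", {
  set.seed(31)
  pool <- letters
  terms <- lapply(setNames(1:20, paste0("g", 1:20)), function(i) {
    sample(pool, 4)
  })
  training <- paste0("g", 1:5)
  gene <- "g10"
  n_perm <- 800
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  a_of <- function(g, set) {
    js <- sort(vapply(setdiff(set, g), function(t) jac(terms[[g]], terms[[t]]),
                      numeric(1)), decreasing = TRUE)
    mean(js[seq_len(min(5, length(js)))])
  }
  a_obs <- a_of(gene, training)
  set.seed(55)
  exceed <- 0
  for (b in seq_len(n_perm)) {
    draw <- sample(names(terms), length(training))
    # mirror the package rule: self-similarity never counts
    if (a_of(gene, draw) >= a_obs) exceed <- exceed + 1
  }
  oracle_p <- (1 + exceed) / (n_perm + 1)
  got <- annotation_score(gene, terms, training, n_perm = n_perm, seed = 55)
  expect_lt(abs(10^-got - oracle_p), 0.05)
})

test_that("score combination is a validated convex mixture", {
  expect_equal(combine_scores(10, 20, alpha = 0.5), 15)
  expect_equal(combine_scores(7, 7, alpha = 0.123), 7) # fixed point
  expect_error(combine_scores(1, 2, alpha = 1), "alpha")
  expect_error(combine_scores(1, 2, alpha = 0), "alpha")
  # one missing component: flagged unless partial fallback requested
  expect_true(is.na(combine_scores(NA, 3, alpha = 0.5)))
  expect_equal(combine_scores(NA, 3, alpha = 0.5, partial = TRUE), 3)
  expect_equal(combine_scores(4, NA, alpha = 0.5, partial = TRUE), 4)
})

test_that("threshold calibration finds the separating gap when separable", {
  scores <- setNames(c(10, 11, 12, 13, 14, 1, 2, 3, 4, 4, 4, 4),
                     paste0("g", 1:12))
  training <- paste0("g", 1:5)
  tau <- estimate_threshold(scores, training, precision_target = 0.8,
                            seed = 9)
  # the separating gap is (4, 10); below it more than a quarter of the
  # negative pool is called and precision cannot stay at the target
  expect_equal(tau, 7)
  # exhaustive sweep oracle over the full negative pool under the same rule
  uniq <- sort(unique(scores))
  mids <- (uniq[-1] + uniq[-length(uniq)]) / 2
  ok <- vapply(mids, function(m) {
    tp <- sum(scores[training] > m)
    fp <- sum(scores[setdiff(names(scores), training)] > m)
    tp >= 0.5 * length(training) && tp + fp > 0 && tp / (tp + fp) >= 0.8
  }, logical(1))
  expect_equal(tau, min(mids[ok]))
})

test_that("shuffled labels cannot reach the precision target", {
  set.seed(13)
  scores <- setNames(runif(150), paste0("g", 1:150))
  for (k in 1:5) {
    fake_training <- sample(names(scores), 30)
    tau <- estimate_threshold(scores, fake_training, precision_target = 0.8,
                              seed = k)
    expect_true(is.na(tau))
  }
})

test_that("degenerate equal scores return the none-flag", {
  scores <- setNames(rep(2, 20), paste0("g", 1:20))
  expect_true(is.na(estimate_threshold(scores, paste0("g", 1:6), seed = 1)))
})

test_that("risk-gene calls use strict thresholds and are monotone", {
  sc <- data.frame(gene_id = c("a", "b", "c"),
                   s_network = 1, s_annotation = 1,
                   s_gene = c(1.0, 2.0, 3.0), scored = TRUE)
  out <- call_risk_genes(sc, tau_stringent = 2.0, tau_lenient = 1.0)
  expect_equal(out$call_stringent, c(FALSE, FALSE, TRUE)) # 2.0 not > 2.0
  expect_equal(out$call_lenient, c(FALSE, TRUE, TRUE))
  expect_true(all(which(out$call_stringent) %in% which(out$call_lenient)))
  # NA threshold -> no calls
  out2 <- call_risk_genes(sc, NA_real_, 1.0)
  expect_false(any(out2$call_stringent))
})

test_that("genes lacking both evidence sources are reported unscored", {
  net <- toy_network()
  terms <- list(hub = c("a"), t1 = c("a"), t2 = c("b"), t3 = c("c"),
                d1 = c("d"))
  sc <- score_genes(c("hub", "d1", "orphan"), net, terms,
                    c("t1", "t2", "t3"), n_perm = 200, seed = 2)
  expect_false(sc$scored[sc$gene_id == "orphan"])
  expect_true(sc$scored[sc$gene_id == "hub"])
})
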