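test_that("panel combination keeps the lineage-filtered union over shared subjects", {
  f1 <- tidyr::crossing(subject_id = c("s1", "s2", "s3"),
                        node_id = c("P1_N01", "P1_N02")) |>
    dplyr::mutate(cohort = "HC", panel = "P1",
                  lineage = ifelse(node_id == "P1_N01", "NK", "other"),
                  freq = 0.5)
  f2 <- tidyr::crossing(subject_id = c("s1", "s2"),
                        node_id = c("P2_N01", "P2_N02")) |>
    dplyr::mutate(cohort = "HC", panel = "P2",
                  lineage = ifelse(node_id == "P2_N01", "B", "MonoDC"),
                  freq = 0.5)
  expect_message(comb <- combine_panels(f1, f2), "excluded")
  expect_setequal(comb$subject_id, c("s1", "s2"))   # intersection policy
  nodes <- attr(comb, "nodes")
  # P1 contributes only the NK node; P2 both B and MonoDC nodes
  expect_setequal(nodes$node_id, c("P1_N01", "P2_N01", "P2_N02"))
  expect_equal(ncol(comb), 2 + 3)  # subject_id, cohort + retained nodes
  f2_other <- dplyr::mutate(f2, subject_id = paste0("x", subject_id))
  expect_error(combine_panels(f1, f2_other), "no subjects")
})

test_that("correlation matrix matches hand computation and flags zero variance", {
  wide <- tibble::tibble(
    subject_id = sprintf("s%d", 1:4), cohort = "HC",
    a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(1, 2, 3, 4),
    d = c(-1, -2, -3, -4), e = rep(2, 4))
  attr(wide, "nodes") <- tibble::tibble(
    node_id = c("a", "b", "c", "d", "e"), panel = "P1", lineage = "NK")
  class(wide) <- c("combined_freq", class(wide))
  R <- correlation_matrix(wide, "HC")
  expect_equal(R["a", "b"], 0.6)          # direct Pearson formula
  expect_equal(R["a", "c"], 1)            # duplicated column
  expect_equal(R["a", "d"], -1)           # negated column
  expect_true(is.na(R["a", "e"]))         # zero variance -> missing
  expect_equal(diag(R), setNames(rep(1, 5), letters[1:5]))
  expect_error(correlation_matrix(wide[1:2, ], "HC"), "at least 3")
})

test_that("thresholding is strict by default with the boundary configurable", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7
  R[1, 3] <- R[3, 1] <- -0.65
  R[1, 4] <- R[4, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.6    # exactly at the threshold
  nodes <- tibble::tibble(node_id = letters[1:4], lineage = "NK")
  net <- build_network(R, nodes)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("positive", "negative"))
  loose <- build_network(R, nodes, strict = FALSE)
  expect_equal(nrow(loose$edges), 3)       # the r = 0.6 pair joins
  # identity matrix -> no edges, nodes preserved
  empty <- build_network(diag(4), nodes)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 4)
  expect_error(build_network(R, nodes, threshold = 1.2), "threshold")
})

test_that("raising the threshold never adds edges", {
  net_at <- function(th) {
    R <- cor(matrix(rnorm(200), 20))
    dimnames(R) <- list(letters[1:10], letters[1:10])
    nodes <- tibble::tibble(node_id = letters[1:10], lineage = "NK")
    sapply(c(0.3, 0.5, 0.7, 0.9), function(t)
      nrow(build_network(R, nodes, threshold = t)$edges))
  }
  set.seed(20)
  for (i in 1:10) expect_true(all(diff(net_at()) <= 0))
})

test_that("edge density reproduces the published network arithmetic", {
  pairs <- utils::combn(72, 2)
  hc <- toy_net(72, lapply(seq_len(286), function(i) pairs[, i]))
  expect_equal(edge_density(hc), 0.111894, tolerance = 1e-5)
  hf <- toy_net(72, lapply(seq_len(161), function(i) pairs[, i]))
  expect_equal(edge_density(hf), 0.062989, tolerance = 1e-5)
  k4 <- toy_net(4, lapply(seq_len(6), function(i) utils::combn(4, 2)[, i]))
  expect_equal(edge_density(k4), 1)
  expect_equal(edge_density(hc) * (72 * 71 / 2), 286)  # exact inversion
  expect_error(edge_density(toy_net(1, list())), "at least 2")
})

test_that("signed edge shares reproduce the published percentages", {
  mk <- function(n_pos, n_neg) {
    pairs <- utils::combn(72, 2)
    net <- toy_net(72, lapply(seq_len(n_pos + n_neg),
                              function(i) pairs[, i]))
    net$edges$sign[seq_len(n_neg)] <- "negative"
    net$edges$r[seq_len(n_neg)] <- -net$edges$r[seq_len(n_neg)]
    net
  }
  hf <- signed_edge_summary(mk(142, 19))
  expect_equal(round(hf$pct_neg_edges, 1), 11.8)
  hc <- signed_edge_summary(mk(280, 6))
  expect_equal(round(hc$pct_neg_edges, 1), 2.1)
  none <- signed_edge_summary(toy_net(3, list()))
  expect_equal(none$n_pos_edges + none$n_neg_edges, 0)
  expect_true(is.na(none$pct_neg_edges))
})

test_that("degrees and lineage averages match hand counts", {
  star <- toy_net(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  ds <- degree_summary(star)
  expect_equal(sort(ds$node_degrees$degree), c(1, 1, 1, 1, 4))
  # mean degree = 2m/n
  expect_equal(mean(ds$node_degrees$degree), 2 * 4 / 5)
  # toy labeled graph: 3 NK, 2 B; 4 hand-drawn edges
  g <- toy_net(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
               lineage = c("NK", "NK", "NK", "B", "B"))
  ld <- degree_summary(g)$lineage_degrees
  expect_equal(ld$mean_degree[ld$lineage == "NK"], (1 + 2 + 2) / 3)
  expect_equal(ld$mean_degree[ld$lineage == "B"], (2 + 1) / 2)
})

test_that("edge classification separates intra- from inter-lineage contacts", {
  g <- toy_net(5, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)),
               lineage = c("NK", "NK", "B", "B", "CD4T"))
  cls <- classify_edges(g)
  expect_equal(cls$intra, 2)   # NK-NK and B-B
  expect_equal(cls$inter, 3)
  expect_equal(cls$intra + cls$inter, nrow(g$edges))
  bad <- g
  bad$nodes$lineage[1] <- NA
  expect_error(classify_edges(bad), "lineage")
})

test_that("betweenness centralization is 1 for stars, 0 for complete graphs", {
  for (n in c(5, 8)) {
    star <- toy_net(n, lapply(2:n, function(j) c(1, j)))
    expect_equal(betweenness_centralization(star), 1)
    kn <- toy_net(n, apply(utils::combn(n, 2), 2, identity,
                           simplify = FALSE))
    expect_equal(betweenness_centralization(kn), 0)
  }
  # path P4 against the brute-force betweenness oracle
  p4 <- toy_net(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(betweenness_centralization(p4),
               oracle_centralization_betweenness(net_adj(p4)))
  expect_error(betweenness_centralization(toy_net(2, list(c(1, 2)))),
               "at least 3")
})

test_that("transitivity matches triangle counting", {
  k3 <- toy_net(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(transitivity_global(k3), 1)
  star <- toy_net(5, lapply(2:5, function(j) c(1, j)))
  expect_equal(transitivity_global(star), 0)
  toy <- toy_net(5, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5)))
  expect_equal(transitivity_global(toy), oracle_transitivity(net_adj(toy)))
  # no connected triples -> missing
  k2 <- toy_net(3, list(c(1, 2)))
  expect_true(is.na(transitivity_global(k2)))
})

test_that("average path length uses reachable pairs only", {
  k4 <- toy_net(4, apply(utils::combn(4, 2), 2, identity, simplify = FALSE))
  expect_equal(average_path_length(k4), 1)
  p3 <- toy_net(3, list(c(1, 2), c(2, 3)))
  expect_equal(average_path_length(p3), 4 / 3)
  two_k2 <- toy_net(4, list(c(1, 2), c(3, 4)))
  expect_equal(average_path_length(two_k2), 1)
  expect_error(average_path_length(toy_net(3, list())), "edge")
})

test_that("modularity Q follows the direct formula", {
  ids <- sprintf("n%02d", 1:6)
  two_k3 <- toy_net(6, list(c(1, 2), c(2, 3), c(1, 3),
                            c(4, 5), c(5, 6), c(4, 6)))
  part <- setNames(c(1, 1, 1, 2, 2, 2), ids)
  expect_equal(modularity_q(two_k3, part), 0.5)
  # single community -> 0
  expect_equal(modularity_q(two_k3, setNames(rep(1, 6), ids)), 0)
  # planted partition beats a scrambled relabeling
  scram <- setNames(c(1, 2, 1, 2, 1, 2), ids)
  expect_gt(modularity_q(two_k3, part), modularity_q(two_k3, scram))
  expect_error(modularity_q(two_k3, part[1:3]), "cover")
  expect_error(modularity_q(toy_net(3, list()), setNames(1:3, sprintf("n%02d", 1:3))),
               "edge")
})

test_that("greedy community detection recovers joined cliques deterministically", {
  pairs4 <- apply(utils::combn(4, 2), 2, identity, simplify = FALSE)
  two_k4 <- toy_net(8, c(pairs4,
                         lapply(pairs4, function(p) p + 4L),
                         list(c(4, 5))))
  out <- detect_communities(two_k4)
  memb <- out$membership
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  expect_equal(out$q, modularity_q(two_k4, memb))
  # complete graph collapses to one community
  kn <- toy_net(5, apply(utils::combn(5, 2), 2, identity, simplify = FALSE))
  expect_equal(length(unique(detect_communities(kn)$membership)), 1)
  # determinism
  expect_identical(detect_communities(two_k4), detect_communities(two_k4))
  # edgeless graph: singleton partition with Q = 0 by convention
  lone <- detect_communities(toy_net(3, list()))
  expect_equal(unname(lone$membership), 1:3)
  expect_equal(lone$q, 0)
})

test_that("all graph metrics agree with brute-force oracles on random graphs", {
  for (i in 1:50) {
    n <- sample(4:12, 1)
    net <- random_net(n, p = runif(1, 0.15, 0.7), seed = 3000 + i)
    A <- net_adj(net)
    expect_equal(edge_density(net), sum(A) / 2 / (n * (n - 1) / 2),
                 tolerance = 1e-10)
    if (nrow(net$edges) > 0) {
      expect_equal(average_path_length(net), oracle_apl(A),
                   tolerance = 1e-10)
    }
    tt <- transitivity_global(net)
    ot <- oracle_transitivity(A)
    expect_equal(is.na(tt), is.na(ot))
    if (!is.na(tt)) expect_equal(tt, ot, tolerance = 1e-10)
    if (n >= 3) {
      expect_equal(betweenness_centralization(net),
                   oracle_centralization_betweenness(A), tolerance = 1e-10)
    }
    # modularity of the detected partition against the direct-formula oracle
    # and igraph's implementation
    if (nrow(net$edges) > 0) {
      det <- detect_communities(net)
      memb <- det$membership[net$nodes$node_id]
      expect_equal(det$q, oracle_modularity(A, memb), tolerance = 1e-10)
      expect_equal(det$q,
                   igraph::modularity(as_igraph(net), memb),
                   tolerance = 1e-10)
    }
    # conservation identities
    se <- signed_edge_summary(net)
    cls <- classify_edges(net)
    expect_equal(se$n_pos_edges + se$n_neg_edges, nrow(net$edges))
    expect_equal(cls$intra + cls$inter, nrow(net$edges))
  }
})

test_that("greedy Q is competitive with igraph's fast-greedy on random graphs", {
  for (i in 1:10) {
    net <- random_net(10, p = 0.35, seed = 4000 + i)
    if (nrow(net$edges) < 2) next
    ours <- detect_communities(net)$q
    g <- as_igraph(net)
    if (igraph::any_multiple(g)) next
    ref <- igraph::modularity(igraph::cluster_fast_greedy(g))
    expect_gte(ours, ref - 0.1)
  }
})

test_that("network comparison assembles the comparative property table", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40)
  wide <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                         cohort = rep(c("HC", "HF"), each = 20))
  wide <- dplyr::bind_cols(wide, tibble::as_tibble(
    `colnames<-`(X, sprintf("n%d", 1:6))))
  attr(wide, "nodes") <- tibble::tibble(node_id = sprintf("n%d", 1:6),
                                        panel = "P1",
                                        lineage = rep(c("NK", "B"), 3))
  class(wide) <- c("combined_freq", class(wide))
  cmp <- network_compare(wide, c("HC", "HF"), threshold = 0.3)
  expect_equal(cmp$properties$cohort, c("HC", "HF"))
  t3 <- table3_format(cmp)
  expect_equal(t3$property,
               c("edge_density", "centralization_betweenness",
                 "transitivity", "modularity", "average_path_length",
                 "no_neg_edges", "no_pos_edges"))
  expect_equal(names(t3), c("property", "HC", "HF"))
  # identical cohorts -> identical property vectors
  wide2 <- wide
  wide2$cohort <- rep(c("HC", "HF"), 20)
  half <- wide[wide$cohort == "HC", ]
  both <- dplyr::bind_rows(half, dplyr::mutate(half, cohort = "HF",
                                               subject_id = paste0("x", subject_id)))
  attr(both, "nodes") <- attr(wide, "nodes")
  class(both) <- class(wide)
  cmp2 <- network_compare(both, c("HC", "HF"), threshold = 0.3)
  num <- vapply(cmp2$properties, is.numeric, logical(1))
  expect_equal(unlist(cmp2$properties[1, num]),
               unlist(cmp2$properties[2, num]), tolerance = 1e-12)
})
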