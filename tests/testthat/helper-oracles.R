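# Brute-force graph oracles, independent of the package implementation
# (and of igraph): BFS distances, path-count betweenness, exhaustive
# triangle/triple counts, direct modularity formula.

# adjacency matrix of a signed_network
net_adj <- function(net) {
  ids <- net$nodes$node_id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    A[cbind(net$edges$from, net$edges$to)] <- 1L
    A[cbind(net$edges$to, net$edges$from)] <- 1L
  }
  A
}

oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(A[v, ] == 1L)
        new <- nb[D[s, nb] > d]
        D[s, new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
  }
  D
}

oracle_apl <- function(A) {
  D <- oracle_bfs_dist(A)
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0) NA_real_ else mean(vals)
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  tri <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] & A[j, k] & A[i, k]) tri <- tri + 1
    }
  }
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) NA_real_ else 3 * tri / triples
}

# betweenness by shortest-path counting (sigma DP over BFS levels),
# endpoints excluded, each unordered pair counted once
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_dist(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(A[v, ] == 1L & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || s == t) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  b
}

oracle_centralization_betweenness <- function(A) {
  n <- nrow(A)
  b <- oracle_betweenness(A)
  sum(max(b) - b) / ((n - 1)^2 * (n - 2) / 2)
}

oracle_modularity <- function(A, memb) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    q <- q + sum(A[idx, idx]) / 2 / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# exact two-sided rank-sum p by enumerating which observations fall in
# group x (values assumed untied)
oracle_rank_sum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  }
  obs <- u_of(seq_len(n))
  centre <- n * length(y) / 2
  combos <- utils::combn(N, n)
  us <- apply(combos, 2, u_of)
  mean(abs(us - centre) >= abs(obs - centre) - 1e-12)
}

# random signed_network on n nodes with edge probability p
random_net <- function(n, p, seed, lineages = c("NK", "B", "CD4T")) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  nodes <- tibble::tibble(node_id = ids,
                          lineage = sample(lineages, n, replace = TRUE))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  r <- stats::runif(sum(keep), 0.61, 0.99) *
    sample(c(-1, 1), sum(keep), replace = TRUE)
  edges <- tibble::tibble(from = ids[pairs[keep, 1]],
                          to = ids[pairs[keep, 2]],
                          r = r,
                          sign = ifelse(r >= 0, "positive", "negative"))
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

# signed_network with a given node count and explicit edge list (as index
# pairs), all-positive correlations
toy_net <- function(n, pairs, lineage = rep("NK", n), r = 0.9) {
  ids <- sprintf("n%02d", seq_len(n))
  i1 <- vapply(pairs, function(p) as.integer(p[1]), integer(1))
  i2 <- vapply(pairs, function(p) as.integer(p[2]), integer(1))
  rv <- rep_len(r, length(pairs))
  edges <- tibble::tibble(
    from = ids[i1], to = ids[i2], r = rv,
    sign = ifelse(rv >= 0, "positive", "negative"))
  structure(list(nodes = tibble::tibble(node_id = ids, lineage = lineage),
                 edges = edges),
            class = "signed_network")
}
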