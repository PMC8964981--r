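# Signed correlation networks over panel-combined node frequencies and the
# comparative graph-property suite. Topological metrics are computed on the
# unweighted, sign-blind graph; correlation signs are retained as edge
# attributes and summarized separately.

#' Combine node frequencies across panels by lineage
#'
#' Keeps T-lineage and NK nodes from panel 1 and B and monocyte/dendritic
#' nodes from panel 2, restricted to subjects present in both panels, as one
#' wide matrix ready for correlation.
#'
#' @param freq_p1,freq_p2 Long frequency tibbles ([frequency_matrix()]) for
#'   the two panels, carrying a `lineage` column.
#' @param p1_lineages,p2_lineages Lineages retained from each panel.
#' @return A `combined_freq` tibble: `subject_id`, `cohort`, (`subtype`,)
#'   then one column per retained node; node metadata (`node_id`, `panel`,
#'   `lineage`) in `attr(, "nodes")`.
#' @export
combine_panels <- function(freq_p1, freq_p2,
                           p1_lineages = c("CD4T", "CD8T", "MAIT", "Treg",
                                           "NK", "otherT"),
                           p2_lineages = c("B", "MonoDC")) {
  f1 <- filter(freq_p1, .data$lineage %in% p1_lineages)
  f2 <- filter(freq_p2, .data$lineage %in% p2_lineages)
  both <- intersect(unique(f1$subject_id), unique(f2$subject_id))
  if (length(both) == 0) abort("no subjects present in both panels")
  dropped <- setdiff(union(unique(freq_p1$subject_id),
                           unique(freq_p2$subject_id)), both)
  if (length(dropped) > 0) {
    message(length(dropped), " subject(s) absent from one panel excluded: ",
            paste(dropped, collapse = ", "))
  }
  long <- bind_rows(f1, f2) |> filter(.data$subject_id %in% both)
  nodes <- distinct(long, .data$node_id, .data$panel, .data$lineage)
  if (anyDuplicated(nodes$node_id)) abort("duplicated node ids across panels")
  meta <- intersect(c("subject_id", "cohort", "subtype"), names(long))
  wide <- long |>
    select(all_of(meta), "node_id", "freq") |>
    pivot_wider(names_from = "node_id", values_from = "freq")
  attr(wide, "nodes") <- nodes
  class(wide) <- c("combined_freq", class(wide))
  wide
}

#' Within-cohort correlation matrix of node frequencies
#'
#' @param combined A `combined_freq` tibble.
#' @param cohort Cohort label (rows with `cohort == cohort` are used); needs
#'   at least 3 subjects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix over the node columns;
#'   zero-variance columns yield `NA` entries (recorded as missing, never an
#'   edge).
#' @export
correlation_matrix <- function(combined, cohort,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  nodes <- attr(combined, "nodes")
  sub <- combined[combined$cohort == cohort, nodes$node_id, drop = FALSE]
  if (nrow(sub) < 3) abort("cohort needs at least 3 subjects for correlation")
  X <- as.matrix(sub)
  sdv <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X, method = method))
  R[sdv == 0, ] <- NA_real_
  R[, sdv == 0] <- NA_real_
  diag(R) <- 1
  R
}

#' Build a signed network by thresholding a correlation matrix
#'
#' Connects node pairs whose absolute correlation exceeds the threshold
#' (strictly by default; `strict = FALSE` uses `>=`), carrying the
#' correlation value and its sign on the edge. Isolated nodes are kept.
#'
#' @param corr Symmetric correlation matrix (NA entries never form edges).
#' @param nodes Tibble `node_id`, `lineage` (order defines the node set), or
#'   a named character vector of lineages.
#' @param threshold Absolute correlation threshold in (0, 1), default 0.6.
#' @param strict Logical; `TRUE` (default) uses `|r| > threshold`.
#' @return A `signed_network`: list with `nodes` (tibble `node_id`,
#'   `lineage`) and `edges` (tibble `from`, `to`, `r`, `sign`).
#' @export
build_network <- function(corr, nodes, threshold = 0.6, strict = TRUE) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (is.character(nodes)) nodes <- tibble(node_id = names(nodes), lineage = unname(nodes))
  ids <- nodes$node_id
  stopifnot(nrow(corr) == length(ids))
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  keep <- !is.na(r) & (if (strict) abs(r) > threshold else abs(r) >= threshold)
  r_keep <- r[keep]
  edges <- tibble(
    from = ids[ut[keep, 1]],
    to = ids[ut[keep, 2]],
    r = r_keep,
    sign = ifelse(r_keep >= 0, "positive", "negative")
  )
  structure(list(nodes = select(nodes, "node_id", "lineage"), edges = edges),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("Signed network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative )\n")
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param net A `signed_network`.
#' @return An undirected igraph graph with `lineage` vertex attribute and
#'   `r`, `sign` edge attributes.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Edge density
#'
#' Realized edges divided by all possible unordered node pairs.
#'
#' @param net A `signed_network` with at least 2 nodes.
#' @return Scalar in `[0, 1]`.
#' @export
edge_density <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2) abort("edge density needs at least 2 nodes")
  nrow(net$edges) / (n * (n - 1) / 2)
}

#' Signed edge counts
#'
#' @param net A `signed_network`.
#' @return One-row tibble `n_pos_edges`, `n_neg_edges`, `pct_neg_edges`
#'   (percent; `NA` for an edgeless network).
#' @export
signed_edge_summary <- function(net) {
  n_pos <- sum(net$edges$sign == "positive")
  n_neg <- sum(net$edges$sign == "negative")
  m <- n_pos + n_neg
  tibble(n_pos_edges = n_pos, n_neg_edges = n_neg,
         pct_neg_edges = if (m > 0) 100 * n_neg / m else NA_real_)
}

#' Node degrees and per-lineage average degree
#'
#' Degree is the unnormalized count of incident edges.
#'
#' @param net A `signed_network`.
#' @return List with `node_degrees` (tibble `node_id`, `lineage`, `degree`)
#'   and `lineage_degrees` (tibble `lineage`, `n_nodes`, `mean_degree`).
#' @export
degree_summary <- function(net) {
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$node_id))
  nd <- mutate(net$nodes, degree = as.integer(deg[.data$node_id]))
  ld <- nd |>
    group_by(.data$lineage) |>
    summarise(n_nodes = n(), mean_degree = mean(.data$degree),
              .groups = "drop")
  list(node_degrees = nd, lineage_degrees = ld)
}

#' Classify edges as intra- or inter-lineage
#'
#' An edge is intra-lineage iff both endpoints share a lineage label.
#'
#' @param net A `signed_network` with all nodes labeled.
#' @return List: `intra` and `inter` counts, plus `by_lineage` (tibble
#'   `lineage`, `intra`, `inter` counting each lineage's incident edges).
#' @export
classify_edges <- function(net) {
  lin <- setNames(net$nodes$lineage, net$nodes$node_id)
  if (anyNA(lin)) abort("all nodes must carry a lineage label")
  lf <- lin[net$edges$from]
  lt <- lin[net$edges$to]
  is_intra <- lf == lt
  per <- map(unique(lin), function(l) {
    touch <- lf == l | lt == l
    tibble(lineage = l, intra = sum(touch & is_intra),
           inter = sum(touch & !is_intra))
  }) |> list_rbind()
  list(intra = sum(is_intra), inter = sum(!is_intra), by_lineage = per)
}

#' Freeman betweenness centralization
#'
#' Vertex betweenness (shortest-path counts on the unweighted sign-blind
#' graph, endpoints excluded), centralized Freeman-style: the sum of
#' differences from the maximum, normalized by the star graph's maximum
#' `(n-1)^2 (n-2) / 2`.
#'
#' @param net A `signed_network` with at least 3 nodes.
#' @return Scalar in `[0, 1]` (1 for a star, 0 for a vertex-transitive
#'   graph such as a complete graph).
#' @export
betweenness_centralization <- function(net) {
  n <- nrow(net$nodes)
  if (n < 3) abort("betweenness centralization needs at least 3 nodes")
  b <- igraph::betweenness(as_igraph(net), directed = FALSE)
  sum(max(b) - b) / ((n - 1)^2 * (n - 2) / 2)
}

#' Global transitivity (clustering coefficient)
#'
#' `3 * triangles / connected triples` on the sign-blind graph; `NA` when
#' the graph has no connected triples.
#'
#' @param net A `signed_network`.
#' @return Scalar in `[0, 1]` or `NA`.
#' @export
transitivity_global <- function(net) {
  t <- igraph::transitivity(as_igraph(net), type = "global")
  if (is.nan(t)) NA_real_ else t
}

#' Average shortest-path length over reachable pairs
#'
#' Mean unweighted shortest-path length over all unordered reachable pairs;
#' pairs in different components are excluded.
#'
#' @param net A `signed_network` with at least one edge.
#' @return Scalar `>= 1`.
#' @export
average_path_length <- function(net) {
  if (nrow(net$edges) == 0) abort("average path length needs at least one edge")
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ m_c / m - (d_c / 2m)^2 ]` on the unweighted sign-blind
#' graph, where `m_c` is the number of edges inside community `c` and `d_c`
#' the total degree of its members.
#'
#' @param net A `signed_network` with at least one edge.
#' @param partition Named integer/character vector: community of every node.
#' @return Scalar Q.
#' @export
modularity_q <- function(net, partition) {
  m <- nrow(net$edges)
  if (m == 0) abort("modularity needs at least one edge")
  if (!all(net$nodes$node_id %in% names(partition))) {
    abort("partition must cover all nodes")
  }
  comm <- partition[net$nodes$node_id]
  cf <- comm[net$edges$from]
  ct <- comm[net$edges$to]
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$node_id))
  q <- 0
  for (c in unique(comm)) {
    m_c <- sum(cf == c & ct == c)
    d_c <- sum(deg[comm == c])
    q <- q + m_c / m - (d_c / (2 * m))^2
  }
  unname(q)
}

#' Greedy agglomerative community detection
#'
#' Deterministic Clauset-Newman-Moore-style agglomeration: starting from
#' singleton communities, repeatedly merge the edge-connected pair of
#' communities with the largest modularity gain (ties broken toward the
#' smallest community indices), and return the partition with maximal Q
#' along the merge path. An edgeless graph yields the singleton partition
#' with Q defined as 0.
#'
#' @param net A `signed_network`.
#' @param seed Unused (the algorithm is deterministic); kept so pipeline
#'   stage seeds are uniform.
#' @return List: `membership` (named vector node -> community index) and
#'   `q` (modularity of the returned partition).
#' @export
detect_communities <- function(net, seed = NULL) {
  ids <- net$nodes$node_id
  n <- length(ids)
  m <- nrow(net$edges)
  if (m == 0) {
    return(list(membership = setNames(seq_len(n), ids), q = 0))
  }
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  deg <- tabulate(c(ei, ej), nbins = n)
  memb <- seq_len(n)
  q_of <- function(mb) {
    within <- tapply(rep(1, m), paste(pmin(mb[ei], mb[ej]),
                                      pmax(mb[ei], mb[ej])), sum)
    w_cc <- sum(within[vapply(strsplit(names(within), " "),
                              function(p) p[1] == p[2], logical(1))])
    d_c <- tapply(deg, mb, sum)
    w_cc / m - sum((d_c / (2 * m))^2)
  }
  q <- q_of(memb)
  best_q <- q
  best_memb <- memb
  repeat {
    comms <- sort(unique(memb))
    if (length(comms) == 1) break
    cf <- pmin(memb[ei], memb[ej])
    ct <- pmax(memb[ei], memb[ej])
    between <- tibble(u = cf, v = ct) |>
      filter(.data$u != .data$v) |>
      count(.data$u, .data$v, name = "w")
    if (nrow(between) == 0) break  # disconnected communities only
    d_c <- tapply(deg, memb, sum)
    dq <- between$w / m -
      2 * (d_c[as.character(between$u)] / (2 * m)) *
          (d_c[as.character(between$v)] / (2 * m))
    pick <- order(-dq, between$u, between$v)[1]
    memb[memb == between$v[pick]] <- between$u[pick]
    q <- q + dq[pick]
    if (q > best_q + 1e-12) {
      best_q <- q
      best_memb <- memb
    }
  }
  comm <- match(best_memb, sort(unique(best_memb)))
  list(membership = setNames(comm, ids),
       q = modularity_q(net, setNames(comm, ids)))
}

#' Full network property vector
#'
#' The comparative property suite for one cohort's network: edge density,
#' Freeman betweenness centralization, transitivity, modularity (under
#' [detect_communities()]), average path length, signed edge counts and
#' percentages, and intra/inter-lineage edge counts.
#'
#' @param net A `signed_network`.
#' @return One-row tibble of properties.
#' @export
network_properties <- function(net) {
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  se <- signed_edge_summary(net)
  cls <- classify_edges(net)
  comm <- detect_communities(net)
  tibble(
    n_nodes = n,
    n_edges = m,
    edge_density = edge_density(net),
    centralization_betweenness = if (n >= 3) betweenness_centralization(net) else NA_real_,
    transitivity = transitivity_global(net),
    modularity = comm$q,
    average_path_length = if (m > 0) average_path_length(net) else NA_real_,
    no_neg_edges = se$n_neg_edges,
    no_pos_edges = se$n_pos_edges,
    pct_neg_edges = se$pct_neg_edges,
    intra_lineage_edges = cls$intra,
    inter_lineage_edges = cls$inter
  )
}

#' Compare cohort networks side by side
#'
#' Builds each cohort's signed network from the combined frequency matrix
#' and assembles the comparative property table plus lineage-degree and
#' edge-classification summaries.
#'
#' @param combined A `combined_freq` tibble covering both cohorts.
#' @param cohorts Character vector of cohort labels (default
#'   `c("HC", "HF")`).
#' @param threshold,strict Passed to [build_network()].
#' @param method Correlation method.
#' @return A `network_comparison` list: `properties` (tibble, one row per
#'   cohort), `lineage_degrees` (tibble with `cohort`), `networks` (named
#'   list of `signed_network`), `delta` (case minus control for numeric
#'   properties when exactly two cohorts are given).
#' @export
network_compare <- function(combined, cohorts = c("HC", "HF"),
                            threshold = 0.6, strict = TRUE,
                            method = "pearson") {
  nodes <- attr(combined, "nodes")
  nets <- map(setNames(cohorts, cohorts), function(co) {
    R <- correlation_matrix(combined, co, method = method)
    build_network(R, nodes, threshold = threshold, strict = strict)
  })
  props <- imap(nets, function(nt, co) {
    mutate(network_properties(nt), cohort = co, .before = 1)
  }) |> list_rbind()
  ldeg <- imap(nets, function(nt, co) {
    mutate(degree_summary(nt)$lineage_degrees, cohort = co, .before = 1)
  }) |> list_rbind()
  delta <- NULL
  if (length(cohorts) == 2) {
    num <- names(props)[vapply(props, is.numeric, logical(1))]
    delta <- props[props$cohort == cohorts[2], num] -
      props[props$cohort == cohorts[1], num]
  }
  structure(list(properties = props, lineage_degrees = ldeg,
                 networks = nets, delta = delta),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  print(table3_format(x))
  invisible(x)
}

#' Two-column comparative property table
#'
#' Pivots a [network_compare()] result into the conventional layout: one row
#' per property (`edge_density`, `centralization_betweenness`,
#' `transitivity`, `modularity`, `average_path_length`, `no_neg_edges`,
#' `no_pos_edges`), one column per cohort.
#'
#' @param comparison A `network_comparison`.
#' @return Tibble with a `property` column and one column per cohort.
#' @export
table3_format <- function(comparison) {
  rows <- c("edge_density", "centralization_betweenness", "transitivity",
            "modularity", "average_path_length", "no_neg_edges",
            "no_pos_edges")
  comparison$properties |>
    select("cohort", all_of(rows)) |>
    pivot_longer(-"cohort", names_to = "property") |>
    pivot_wider(names_from = "cohort", values_from = "value") |>
    arrange(match(.data$property, rows))
}
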