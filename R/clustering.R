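# Phenotype-node clustering: seeded k-means with careful (k-means++ style)
# initialization and restarts, elbow-based selection of k, node phenotype
# summaries and rule-based lineage annotation.

# k-means++ initial centers: first uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Cluster pooled cells into phenotype nodes by k-means
#'
#' Cells are pooled across all subjects and cohorts of one panel, so node
#' identities are shared across cohorts and node frequencies are comparable
#' between groups. Initialization is k-means++ style; the restart with the
#' lowest within-cluster sum of squares (WCSS) wins. Deterministic given
#' `seed`.
#'
#' @param cells Preprocessed cell tibble (one panel).
#' @param k Number of nodes; must satisfy `1 <= k <= n_cells`.
#' @param seed RNG seed.
#' @param n_restarts Number of restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart (default 50).
#' @return A `node_model`: list with `k`, `panel`, `node_ids`, `centroids`
#'   (k x markers), `assignments` (tibble `subject_id`, `panel`, `cell_id`,
#'   `node_id`, row-aligned with `cells`), `tot_withinss`, `markers`.
#' @export
kmeans_cluster <- function(cells, k, seed = 1L, n_restarts = 10,
                           iter_max = 50) {
  X <- cell_matrix(cells)
  if (k < 1 || k > nrow(X)) abort("k must be between 1 and the number of cells")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(X, k)
    fit <- suppressWarnings(
      kmeans(X, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  panel <- if ("panel" %in% names(cells)) cells$panel[1] else "P"
  node_ids <- sprintf("%s_N%02d", panel, seq_len(k))
  structure(
    list(k = k, panel = panel, node_ids = node_ids,
         centroids = `rownames<-`(best$centers, node_ids),
         assignments = tibble(
           subject_id = cells$subject_id,
           panel = panel,
           cell_id = cells$cell_id %||% seq_len(nrow(cells)),
           node_id = node_ids[best$cluster]),
         tot_withinss = best$tot.withinss,
         markers = colnames(X)),
    class = "node_model"
  )
}

#' @export
print.node_model <- function(x, ...) {
  cat("k-means node model:", x$k, "nodes on panel", x$panel,
      "|", length(x$markers), "markers |",
      nrow(x$assignments), "cells | WCSS",
      format(x$tot_withinss, digits = 6), "\n")
  invisible(x)
}

#' Select the number of nodes by the elbow method
#'
#' Fits k-means over a grid of k, records the WCSS curve, and returns the k
#' whose (k, WCSS) point lies farthest (perpendicular distance, after
#' min-max normalization of both axes) from the chord joining the curve's
#' endpoints. A flat (near-linear) curve triggers a warning and the smallest
#' interior k.
#'
#' @param cells Preprocessed cell tibble.
#' @param k_grid Increasing integer vector of at least 3 candidate k.
#' @param seed RNG seed.
#' @param n_restarts Restarts per k (default 3; the final model should be
#'   refit at the selected k with more restarts).
#' @return List with `k` (selected) and `curve` (tibble `k`, `wcss`,
#'   `distance`).
#' @export
elbow_select_k <- function(cells, k_grid, seed = 1L, n_restarts = 3) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) < 3 || any(diff(k_grid) <= 0)) {
    abort("k_grid must be at least 3 strictly increasing values")
  }
  wcss <- map_dbl(seq_along(k_grid), function(i) {
    kmeans_cluster(cells, k_grid[i], seed = seed + i,
                   n_restarts = n_restarts)$tot_withinss
  })
  sel <- elbow_point(k_grid, wcss)
  list(k = sel$k, curve = tibble(k = k_grid, wcss = wcss,
                                 distance = sel$distance))
}

# Pure elbow criterion on a precomputed (k, wcss) curve: max perpendicular
# distance to the endpoint chord in min-max-normalized coordinates.
elbow_point <- function(k_grid, wcss) {
  xr <- diff(range(k_grid))
  yr <- diff(range(wcss))
  x <- (k_grid - min(k_grid)) / xr
  y <- if (yr > 0) (wcss - min(wcss)) / yr else rep(0, length(wcss))
  # chord from (x1,y1) to (xn,yn); |cross product| / chord length
  dx <- x[length(x)] - x[1]
  dy <- y[length(y)] - y[1]
  dist <- abs(dx * (y[1] - y) - (x[1] - x) * dy) / sqrt(dx^2 + dy^2)
  if (max(dist) < 1e-8) {
    warn("WCSS curve is flat/linear over k_grid; selecting smallest interior k")
    return(list(k = k_grid[2], distance = dist))
  }
  list(k = k_grid[which.max(dist)], distance = dist)
}

#' Per-node phenotype summaries
#'
#' Per-node per-marker medians over member cells, plus across-node scaled
#' medians (per marker: subtract the mean across nodes, divide by the sd
#' across nodes) as used for heatmap display and positivity gating. Empty
#' nodes are retained with `NA` medians and flagged.
#'
#' @param model A `node_model`.
#' @param cells The cell tibble the model was fitted on (row-aligned with
#'   `model$assignments`).
#' @return A `node_phenotype` tibble: `node_id`, `n_cells`, `marker`,
#'   `median`, `scaled_median`.
#' @export
node_phenotype <- function(model, cells) {
  X <- cell_matrix(cells, model$markers)
  node <- factor(model$assignments$node_id, levels = model$node_ids)
  med <- apply(X, 2, function(col) tapply(col, node, median))
  med <- matrix(med, nrow = length(model$node_ids),
                dimnames = list(model$node_ids, model$markers))
  n_cells <- as.integer(table(node))
  if (any(n_cells == 0)) {
    warn(sprintf("%d empty node(s): medians undefined",
                 sum(n_cells == 0)))
  }
  mu <- colMeans(med, na.rm = TRUE)
  sdv <- apply(med, 2, sd, na.rm = TRUE)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf
  scl <- sweep(sweep(med, 2, mu, "-"), 2, sdv, "/")
  out <- tibble(
    node_id = rep(rownames(med), times = ncol(med)),
    n_cells = rep(n_cells, times = ncol(med)),
    marker = rep(colnames(med), each = nrow(med)),
    median = as.vector(med),
    scaled_median = as.vector(scl)
  )
  class(out) <- c("node_phenotype", class(out))
  out
}

#' Annotate node lineages from scaled median phenotypes
#'
#' Applies the ordered gating rules: a node matches a rule when all its
#' required-positive markers have scaled median above the threshold, all
#' required-negative markers are at or below it, and (if the rule has an
#' `any_positive` set) at least one of those markers is above it. First
#' match wins; unmatched nodes are labeled `"other"`. Pure function of the
#' phenotypes and gates (no RNG).
#'
#' @param phenotypes A `node_phenotype` tibble.
#' @param gates Gating table (default [default_gating_table()] restricted to
#'   the phenotype's markers is NOT applied automatically — pass a table
#'   whose markers all exist in the panel).
#' @param threshold Positivity threshold on scaled medians (default 0).
#' @return Tibble `node_id`, `lineage`.
#' @export
annotate_lineage <- function(phenotypes, gates = default_gating_table(),
                             threshold = 0) {
  wide <- phenotypes |>
    select("node_id", "marker", "scaled_median") |>
    pivot_wider(names_from = "marker", values_from = "scaled_median")
  gate_markers <- unique(unlist(gates[c("positive", "negative", "any_positive")]))
  missing <- setdiff(gate_markers, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("gating rules reference marker(s) absent from the panel: %s",
                  paste(missing, collapse = ", ")))
  }
  lineage <- map_chr(seq_len(nrow(wide)), function(i) {
    sm <- unlist(wide[i, -1])
    for (r in seq_len(nrow(gates))) {
      pos <- gates$positive[[r]]; neg <- gates$negative[[r]]
      any_pos <- gates$any_positive[[r]]
      ok <- all(sm[pos] > threshold) && all(sm[neg] <= threshold) &&
        (length(any_pos) == 0 || any(sm[any_pos] > threshold))
      if (isTRUE(ok)) return(gates$lineage[r])
    }
    "other"
  })
  tibble(node_id = wide$node_id, lineage = lineage)
}

#' Fit a panel's node model end to end
#'
#' Convenience wrapper: optional elbow selection, final k-means fit,
#' phenotype summaries, lineage annotation.
#'
#' @param cells Preprocessed cell tibble for one panel.
#' @param k Fixed number of nodes, or `NULL` to select via `k_grid`.
#' @param k_grid Grid for [elbow_select_k()] when `k` is `NULL`
#'   (default `seq(10, 120, by = 10)`; 80 reproduces the published preset).
#' @param seed RNG seed.
#' @param n_restarts Restarts for the final fit (default 10).
#' @param gates Gating table; defaults to [default_gating_table()] restricted
#'   to this panel's markers.
#' @param threshold Positivity threshold for gating.
#' @return List: `model` (`node_model`), `phenotypes`, `nodes` (tibble
#'   `node_id`, `panel`, `lineage`, `n_cells`), `elbow` (or `NULL`).
#' @export
cluster_panel <- function(cells, k = NULL, k_grid = seq(10, 120, by = 10),
                          seed = 1L, n_restarts = 10, gates = NULL,
                          threshold = 0) {
  elbow <- NULL
  if (is.null(k)) {
    elbow <- elbow_select_k(cells, k_grid, seed = seed)
    k <- elbow$k
  }
  model <- kmeans_cluster(cells, k, seed = seed, n_restarts = n_restarts)
  phen <- node_phenotype(model, cells)
  if (is.null(gates)) gates <- default_gating_table(model$markers)
  lin <- annotate_lineage(phen, gates, threshold = threshold)
  nodes <- phen |>
    distinct(.data$node_id, .data$n_cells) |>
    left_join(lin, by = "node_id") |>
    mutate(panel = model$panel, .after = "node_id")
  list(model = model, phenotypes = phen, nodes = nodes, elbow = elbow)
}
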